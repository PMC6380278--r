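make_vs <- function(pos, ref = "A", alt = "G", qual = 100, alt_obs = 10,
                    n_missing = 0, chrom = "chr1", geno = NULL) {
  n <- length(pos)
  variant_set(data.frame(chrom = rep_len(chrom, n), pos = pos,
                         ref = rep_len(ref, n), alt = rep_len(alt, n),
                         qual = rep_len(qual, n),
                         alt_obs = rep_len(alt_obs, n),
                         n_missing = rep_len(n_missing, n)), geno)
}

test_that("DNA subtraction keeps RNA-only variants, matching on alleles", {
  rna <- make_vs(1:10 * 100)
  dna <- make_vs(1:7 * 100)
  out <- subtract_dna(rna, dna)
  expect_equal(out$variants$pos, c(800, 900, 1000))

  # same position, different alleles: retained
  rna2 <- make_vs(500, ref = "A", alt = "G")
  dna2 <- make_vs(500, ref = "A", alt = "C")
  expect_equal(nrow(subtract_dna(rna2, dna2)$variants), 1L)

  # identical sets: empty
  expect_equal(nrow(subtract_dna(rna, rna)$variants), 0L)
})

test_that("subtraction refuses RNA animals missing from the DNA set", {
  gr <- matrix(0, 1, 2, dimnames = list(NULL, c("a1", "a2")))
  gd <- matrix(0, 1, 1, dimnames = list(NULL, "a1"))
  rna <- make_vs(100, geno = gr)
  dna <- make_vs(999, geno = gd)
  expect_error(subtract_dna(rna, dna), "absent from DNA")
})

test_that("quality filter applies the stated thresholds conjunctively", {
  cand <- variant_set(data.frame(
    chrom = "chr1", pos = c(10, 20, 30, 40),
    ref = "A", alt = "G",
    qual = c(29.9, 30, 100, 100),
    alt_obs = c(10, 6, 5, 10),
    n_missing = c(0, 1, 0, 2)))
  out <- quality_filter(cand)
  # 29.9 fails qual; exactly (30, 1 missing, 6 obs) passes; 5 obs fails
  # ("five or fewer"); 2 missing fails
  expect_equal(out$variants$pos, 20)
})

test_that("positional filter removes splice-adjacent, homopolymer, read-end and masked sites", {
  seq <- paste0(strrep("ACGT", 25),              # 1..100
                "AAAAA",                         # 101..105 homopolymer
                strrep("GTCA", 25))              # 106..205
  genome <- make_genome(chr1 = seq)
  gm <- list(gene_model("g1", "chr1", "+",
                        exons = rbind(c(1, 40), c(61, 205))))
  mask_path <- tempfile(fileext = ".bed")
  writeLines("chr1\t150\t160", mask_path)  # 1-based 151..160
  mask <- read_bed_mask(mask_path)
  offsets <- data.frame(chrom = "chr1", pos = c(170, 180, 180),
                        offset = c(3, 50, 40), read_len = 100)
  cand <- make_vs(c(42, 58, 100, 103, 155, 170, 180, 25),
                  ref = "G", alt = "A")
  cand$variants$ref <- get_base(genome, cand$variants$chrom,
                                cand$variants$pos)
  cand$variants$alt <- ifelse(cand$variants$ref == "A", "G", "A")
  out <- positional_filter(cand, gm, genome, mask, offsets)
  flags <- attr(out, "flags")
  expect_true(flags$near_splice[1])      # 42: 2 bp into intron after donor 40
  expect_true(flags$near_splice[2])      # 58: 3 bp before acceptor 61
  expect_true(flags$in_homopolymer[3])   # 100: adjacent to AAAAA run
  expect_true(flags$in_homopolymer[4])   # 103: inside the AAAAA run
  expect_true(flags$in_repeat_mask[5])   # 155 in mask
  expect_true(flags$read_end_only[6])    # 170: single read-end observation
  expect_false(flags$read_end_only[7])   # 180: one internal observation
  expect_false(any(unlist(flags[8, ])))  # 25: clean site retained
  expect_true(25 %in% out$variants$pos)
  expect_false(42 %in% out$variants$pos)
})

test_that("homopolymer rule covers inside, adjacent and clean cases", {
  genome <- make_genome(chr1 = "ACGTAAAAAGTACGTACGT")
  # run AAAAA at 5..9
  expect_true(editqtl:::in_homopolymer(genome, "chr1", 7))   # inside
  expect_true(editqtl:::in_homopolymer(genome, "chr1", 4))   # run starts at 5
  expect_true(editqtl:::in_homopolymer(genome, "chr1", 10))  # run ends at 9
  expect_false(editqtl:::in_homopolymer(genome, "chr1", 13))
})

test_that("cohort curation applies the two-thirds rules", {
  cand <- make_vs(c(100, 200, 300))
  keys <- c("chr1:100", "chr1:200", "chr1:300")
  # N = 9; threshold ceil(2*9/3) = 6
  edited <- rbind(c(rep(1, 6), rep(0, 3)),   # 6 animals with an edited read
                  c(rep(1, 5), rep(0, 4)),   # 5 -> removed
                  rep(1, 9))
  total <- rbind(rep(10, 9),
                 rep(10, 9),
                 rep(4, 9))                  # all depth 4 -> removed
  dimnames(edited) <- dimnames(total) <- list(keys, paste0("a", 1:9))
  out <- curate_cohort(cand, edited, total)
  expect_equal(out$sites$variants$pos, 100)
  expect_equal(out$stats$n_animals_with_edited_read, c(6, 5, 9))
  expect_equal(out$stats$n_animals_with_min_depth, c(9, 9, 0))
  expect_equal(unique(out$stats$cohort_size), 9)
})

test_that("edit classification is strand-resolved with A-to-I naming", {
  res <- classify_edit(c("A", "T", "T", "C", "G"),
                       c("G", "C", "C", "T", "A"),
                       c("+", "-", "+", "+", "-"))
  expect_equal(res$edit_class,
               c("A-to-I",   # A>G on +
                 "A-to-I",   # T>C on - complements to A>G
                 "U-to-C",   # T>C on + is the common noncanonical class
                 "C-to-U",
                 "C-to-U"))  # G>A on - complements to C>T
  expect_equal(res$is_A_to_I, c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("region assignment distinguishes intron, UTR reassignment and coding impact", {
  # gene g1 on +: exons 1..30 and 61..90, CDS 1..30 and 61..90
  # genome codons: positions 4..6 = GCA (Ala)
  seq <- paste0("ATG", "GCA", strrep("ACGT", 6), # 1..30
                strrep("T", 30),                 # intron 31..60
                strrep("GAC", 10),               # 61..90
                strrep("CTGA", 30))              # downstream
  genome <- make_genome(chr1 = seq)
  gm <- list(gene_model("g1", "chr1", "+",
                        exons = rbind(c(1, 30), c(61, 90)),
                        cds = rbind(c(1, 30), c(61, 90))))
  # intronic site
  expect_equal(assign_region("chr1", 45, "T", "C", gm, genome)$region,
               "intron")
  # 100 bp past the 3' end of a + strand gene: reassigned 3'UTR
  expect_equal(assign_region("chr1", 190, "C", "T", gm, genome)$region,
               "3'UTR")
  # upstream of a + strand gene would be 5'UTR; use a second gene to test -
  gm2 <- list(gene_model("g2", "chr1", "-", exons = rbind(c(61, 90))))
  expect_equal(assign_region("chr1", 95, "C", "T", gm2, genome)$region,
               "5'UTR")
  # GCA -> GCG is synonymous (both alanine): position 6, A>G
  expect_equal(assign_region("chr1", 6, "A", "G", gm, genome)$region,
               "synonymous")
  # GCA -> CCA is missense (Ala -> Pro): position 4, G>C
  expect_equal(assign_region("chr1", 4, "G", "C", gm, genome)$region,
               "missense")
  # far from any gene: intergenic
  expect_equal(assign_region("chr1", 100000, "A", "G", gm, genome,
                             max_utr_dist = 5000)$region, "intergenic")
})

test_that("summaries report rounded percentages and tolerate empty input", {
  sites <- data.frame(edit_class = c("A-to-I", "A-to-I", "A-to-I", "U-to-C"),
                      region = c("intron", "intron", "intron", "3'UTR"))
  s <- summarize_sites(sites)
  expect_equal(s$by_region$percent[s$by_region$level == "intron"], 75.0)
  expect_equal(s$by_class$percent[s$by_class$level == "A-to-I"], 75.0)
  empty <- summarize_sites(data.frame(edit_class = character(),
                                      region = character()))
  expect_equal(nrow(empty$by_class), 0L)
})

test_that("quality and positional filters commute", {
  set.seed(101)
  genome <- make_genome(chr1 = random_dna(2000))
  gm <- list(gene_model("g1", "chr1", "+",
                        exons = rbind(c(1, 800), c(1001, 2000))))
  pos <- sample(20:1980, 60)
  ref <- get_base(genome, rep("chr1", 60), pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  cand <- variant_set(data.frame(
    chrom = "chr1", pos = pos, ref = ref, alt = alt,
    qual = sample(c(10, 29, 31, 100), 60, replace = TRUE),
    alt_obs = sample(3:20, 60, replace = TRUE),
    n_missing = sample(0:2, 60, replace = TRUE)))
  a <- positional_filter(quality_filter(cand), gm, genome)
  b <- quality_filter(positional_filter(cand, gm, genome))
  expect_equal(a$variants, b$variants, ignore_attr = TRUE)
  # idempotence: every survivor passes all predicates when rechecked
  c2 <- positional_filter(quality_filter(a), gm, genome)
  expect_equal(nrow(c2$variants), nrow(a$variants))
})

test_that("planted edits are recovered and germline SNPs never survive subtraction", {
  set.seed(102)
  germline_pos <- sample(1:10000, 30)
  edit_pos <- sample(setdiff(1:10000, germline_pos), 10)
  rna <- make_vs(sort(c(germline_pos, edit_pos)))
  dna <- make_vs(sort(germline_pos))
  out <- subtract_dna(rna, dna)
  expect_setequal(out$variants$pos, edit_pos)
})
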