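# Fixture builders shared across test files. Everything is generated in code
# at test time; no binary fixtures.

# Write a minimal VCF from a data.frame (chrom, pos, ref, alt, qual, info)
# with optional per-animal GT strings (matrix, variants x animals).
write_test_vcf <- function(df, path, gt = NULL, samples = NULL) {
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"alt obs\">")
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(gt)) {
    lines <- c(lines, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">")
    if (is.null(samples)) samples <- paste0("s", seq_len(ncol(gt)))
    header <- c(header, "FORMAT", samples)
  }
  lines <- c(lines, paste(header, collapse = "\t"))
  for (i in seq_len(nrow(df))) {
    fields <- c(df$chrom[i], df$pos[i], ".", df$ref[i], df$alt[i],
                if (is.null(df$qual)) "100" else format(df$qual[i]), ".",
                if (is.null(df$info)) "." else df$info[i])
    if (!is.null(gt)) fields <- c(fields, "GT", gt[i, ])
    lines <- c(lines, paste(fields, collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Write a simple GFF3 gene (one transcript, optional CDS intervals).
write_test_gff <- function(path, genes) {
  lines <- "##gff-version 3"
  for (g in genes) {
    span <- c(min(g$exons[, 1]), max(g$exons[, 2]))
    lines <- c(lines,
               paste(g$chrom, "test", "gene", span[1], span[2], ".",
                     g$strand, ".", paste0("ID=", g$id), sep = "\t"),
               paste(g$chrom, "test", "mRNA", span[1], span[2], ".",
                     g$strand, ".", paste0("ID=", g$id, ".t1;Parent=", g$id),
                     sep = "\t"))
    for (k in seq_len(nrow(g$exons))) {
      lines <- c(lines,
                 paste(g$chrom, "test", "exon", g$exons[k, 1], g$exons[k, 2],
                       ".", g$strand, ".", paste0("Parent=", g$id, ".t1"),
                       sep = "\t"))
    }
    if (!is.null(g$cds)) {
      for (k in seq_len(nrow(g$cds))) {
        lines <- c(lines,
                   paste(g$chrom, "test", "CDS", g$cds[k, 1], g$cds[k, 2],
                         ".", g$strand, "0", paste0("Parent=", g$id, ".t1"),
                         sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  path
}

# Genome from named character sequences.
make_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

write_test_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  path
}

# Random DNA string.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Brute-force dot-plot oracle: full complementarity matrix plus window-shift
# sums (independent of the per-antidiagonal running-sum implementation).
naive_dotplot <- function(sequence, window = 15, min_match = 11) {
  s <- strsplit(toupper(chartr("U", "T", sequence)), "")[[1]]
  L <- length(s)
  h <- (window - 1L) %/% 2L
  if (L < window)
    return(data.frame(i = integer(), j = integer(), matches = integer()))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cs <- unname(comp[s])           # NA for non-ACGT
  C <- outer(seq_len(L), seq_len(L),
             function(i, j) !is.na(cs[i]) & cs[i] == s[j])
  M <- matrix(0L, L, L)
  for (k in -h:h) {
    ii <- seq_len(L) + k
    jj <- seq_len(L) - k
    ok_i <- ii >= 1 & ii <= L
    ok_j <- jj >= 1 & jj <= L
    M[ok_i, ok_j] <- M[ok_i, ok_j] + C[ii[ok_i], jj[ok_j]]
  }
  valid <- (h + 1):(L - h)
  hits <- which(M >= min_match, arr.ind = TRUE)
  hits <- hits[hits[, 1] %in% valid & hits[, 2] %in% valid &
                 hits[, 1] <= hits[, 2], , drop = FALSE]
  out <- data.frame(i = hits[, 1], j = hits[, 2],
                    matches = M[hits])
  out <- out[order(out$i + out$j, out$i), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Toy pedigree: founders then offspring rows (id, sire, dam).
make_pedigree <- function(id, sire, dam) {
  structure(data.frame(id = id, sire = sire, dam = dam),
            class = c("pedigree", "data.frame"))
}

# Small simulated cohort reused by assoc/integrate tests.
make_cohort <- function(seed = 42, ...) {
  cfg <- sim_config(seed = NULL, ...)
  set.seed(seed)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  list(cfg = cfg, ped = ped, geno = geno, A = a_matrix(ped))
}
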