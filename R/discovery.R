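# Discovery and curation of candidate RNA edit sites: DNA-from-RNA variant
# subtraction, quality / positional / cohort-level filters, strand-resolved
# classification and genic annotation.

#' Subtract DNA-called variants from RNA-called variants
#'
#' Variants present in the RNA call set but absent from the DNA call set form
#' the initial candidate edit set. A match requires identical chromosome,
#' position, reference and alternate allele; an RNA variant whose position is
#' shared with a DNA variant of different alleles is retained.
#'
#' @param rna_variants,dna_variants [variant_set()] objects called on the
#'   same animals
#' @return a \code{variant_set} of candidate edit sites
#' @export
subtract_dna <- function(rna_variants, dna_variants) {
  rn <- rna_variants$variants; dn <- dna_variants$variants
  rna_animals <- colnames(rna_variants$geno)
  dna_animals <- colnames(dna_variants$geno)
  if (!is.null(rna_animals) && !is.null(dna_animals) &&
      !all(rna_animals %in% dna_animals))
    stop("animal(s) present in RNA but absent from DNA call set: ",
         paste(setdiff(rna_animals, dna_animals), collapse = ", "))
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = "|")
  keep <- !(key(rn) %in% key(dn))
  variant_set(rn[keep, , drop = FALSE],
              if (!is.null(rna_variants$geno))
                rna_variants$geno[keep, , drop = FALSE])
}

#' Quality filter for candidate edit sites
#'
#' Retains candidates with call quality >= 30, at most one animal with a
#' missing genotype, and at least six observed alternate alleles.
#'
#' @param candidates a [variant_set()] with qual, n_missing and alt_obs
#'   columns
#' @param min_qual,max_missing,min_alt_obs thresholds (defaults 30, 1, 6)
#' @return the filtered \code{variant_set}
#' @export
quality_filter <- function(candidates, min_qual = 30, max_missing = 1,
                           min_alt_obs = 6) {
  v <- candidates$variants
  keep <- !is.na(v$qual) & v$qual >= min_qual &
    v$n_missing <= max_missing & v$alt_obs >= min_alt_obs
  variant_set(v[keep, , drop = FALSE],
              if (!is.null(candidates$geno))
                candidates$geno[keep, , drop = FALSE])
}

# Is the site within `window` bp on the intronic side of an annotated splice
# junction of any gene model?
near_splice_site <- function(chrom, pos, gene_models, window = 4) {
  for (gm in gene_models) {
    if (gm$chrom != chrom || nrow(gm$junctions) == 0) next
    don <- gm$junctions[, "donor"]; acc <- gm$junctions[, "acceptor"]
    if (any(pos > don & pos <= don + window) ||
        any(pos < acc & pos >= acc - window)) return(TRUE)
  }
  FALSE
}

# Is the site inside, or immediately adjacent to, a homopolymer run of
# >= min_len identical bases?
in_homopolymer <- function(genome, chrom, pos, min_len = 5) {
  win <- get_seq(genome, chrom, pos - min_len, pos + min_len)
  offset <- min(pos - 1L, min_len)       # index of `pos` inside the window
  bases <- strsplit(win, "")[[1]]
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  site_idx <- offset + 1L
  for (k in seq_along(r$lengths)) {
    if (r$lengths[k] < min_len) next
    if (site_idx >= starts[k] && site_idx <= ends[k]) return(TRUE)   # within
    if (starts[k] == site_idx + 1L || ends[k] == site_idx - 1L) return(TRUE) # adjacent
  }
  FALSE
}

# Per-site flag: edited reads observed only within the first or last
# `margin` bases of their reads. `read_offsets` has columns chrom, pos,
# offset, read_len (one row per edited-read observation).
read_end_only_flag <- function(chrom, pos, read_offsets, margin = 6) {
  if (is.null(read_offsets)) return(FALSE)
  sel <- read_offsets$chrom == chrom & read_offsets$pos == pos
  if (!any(sel)) return(FALSE)
  off <- read_offsets$offset[sel]
  len <- read_offsets$read_len[sel]
  all(off <= margin | off > len - margin)
}

#' Positional filter for candidate edit sites
#'
#' Removes candidates that sit within \code{splice_window} bp (intronic
#' side) of an annotated splice junction, inside or adjacent to a
#' homopolymer run of >= \code{homopolymer_len} identical bases, inside the
#' repeat/low-complexity mask, or whose edited reads were observed only
#' within the first or last \code{read_end_bases} bases of reads.
#'
#' @param candidates a [variant_set()]
#' @param gene_models list of [gene_model()] (for junctions)
#' @param genome \code{DNAStringSet} (for homopolymer detection)
#' @param mask optional \code{GRanges} from [read_bed_mask()]
#' @param read_offsets optional data.frame (chrom, pos, offset, read_len) of
#'   edited-read offsets within reads
#' @param splice_window,homopolymer_len,read_end_bases thresholds
#'   (defaults 4, 5, 6)
#' @return the filtered \code{variant_set}; attribute \code{flags} carries
#'   the per-candidate predicate table
#' @export
positional_filter <- function(candidates, gene_models, genome, mask = NULL,
                              read_offsets = NULL, splice_window = 4,
                              homopolymer_len = 5, read_end_bases = 6) {
  v <- candidates$variants
  n <- nrow(v)
  flags <- data.frame(
    near_splice = logical(n), in_homopolymer = logical(n),
    read_end_only = logical(n), in_repeat_mask = logical(n))
  for (i in seq_len(n)) {
    flags$near_splice[i] <- near_splice_site(v$chrom[i], v$pos[i],
                                             gene_models, splice_window)
    flags$in_homopolymer[i] <- in_homopolymer(genome, v$chrom[i], v$pos[i],
                                              homopolymer_len)
    flags$read_end_only[i] <- read_end_only_flag(v$chrom[i], v$pos[i],
                                                 read_offsets, read_end_bases)
  }
  if (!is.null(mask) && n > 0)
    flags$in_repeat_mask <- in_mask(mask, v$chrom, v$pos)
  keep <- !(flags$near_splice | flags$in_homopolymer |
              flags$read_end_only | flags$in_repeat_mask)
  out <- variant_set(v[keep, , drop = FALSE],
                     if (!is.null(candidates$geno))
                       candidates$geno[keep, , drop = FALSE])
  attr(out, "flags") <- flags
  out
}

#' Cohort-level curation of candidate edit sites
#'
#' Retains sites where at least two thirds of the animals (\code{ceil(2N/3)})
#' have at least one edited read, and at least two thirds have read depth
#' >= \code{min_depth}.
#'
#' @param candidates a [variant_set()]
#' @param edited,total matrices of per-site per-animal edited and total read
#'   counts; rows named by \code{chrom:pos} site keys
#' @param n_cohort cohort size N (default: number of count columns)
#' @param min_depth minimum per-animal depth (default 5)
#' @return list with \code{sites} (retained \code{variant_set}) and
#'   \code{stats} (per-candidate curation statistics)
#' @export
curate_cohort <- function(candidates, edited, total,
                          n_cohort = ncol(total), min_depth = 5) {
  v <- candidates$variants
  keys <- site_key(v$chrom, v$pos)
  if (!all(keys %in% rownames(total)))
    stop("count matrices lack rows for some candidate sites")
  ed <- edited[keys, , drop = FALSE]
  tot <- total[keys, , drop = FALSE]
  threshold <- ceiling(2 * n_cohort / 3)
  n_with_edit <- rowSums(!is.na(ed) & ed > 0)
  n_with_depth <- rowSums(!is.na(tot) & tot >= min_depth)
  keep <- n_with_edit >= threshold & n_with_depth >= threshold
  stats <- data.frame(site = keys, n_animals_with_edited_read = n_with_edit,
                      n_animals_with_min_depth = n_with_depth,
                      cohort_size = n_cohort, retained = keep,
                      row.names = NULL)
  list(sites = variant_set(v[keep, , drop = FALSE],
                           if (!is.null(candidates$geno))
                             candidates$geno[keep, , drop = FALSE]),
       stats = stats)
}

EDIT_CLASSES <- c("A-to-I", "A-to-C", "A-to-U",
                  "C-to-A", "C-to-G", "C-to-U",
                  "G-to-A", "G-to-C", "G-to-U",
                  "U-to-A", "U-to-G", "U-to-C")

#' Classify an edit by substitution type on the transcript strand
#'
#' On minus-strand genes the reference and alternate alleles are complemented
#' before classification. A-to-G substitutions on the transcript strand are
#' reported as A-to-I (inosine is read as guanosine by the sequencer); all
#' classes use the RNA alphabet.
#'
#' @param ref,alt genomic reference/alternate bases (DNA alphabet)
#' @param gene_strand "+" or "-" per site
#' @return data.frame with \code{edit_class} (one of 12 types) and
#'   \code{is_A_to_I}
#' @export
classify_edit <- function(ref, alt, gene_strand) {
  stopifnot(length(ref) == length(alt), length(alt) == length(gene_strand))
  neg <- gene_strand == "-"
  tref <- ifelse(neg, complement_base(ref), toupper(ref))
  talt <- ifelse(neg, complement_base(alt), toupper(alt))
  cls <- paste0(as_rna(tref), "-to-", as_rna(talt))
  cls[cls == "A-to-G"] <- "A-to-I"
  stopifnot(all(cls %in% EDIT_CLASSES))
  data.frame(edit_class = cls, is_A_to_I = cls == "A-to-I")
}

# Translate a codon via the standard genetic code.
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

# Coding impact of substituting `alt` for `ref` at genomic position pos of a
# gene with CDS intervals. Returns "missense", "synonymous" or NA when the
# site is not inside the CDS.
coding_impact <- function(gm, pos, ref, alt, genome) {
  if (is.null(gm$cds)) return(NA_character_)
  inside <- which(gm$cds[, 1] <= pos & pos <= gm$cds[, 2])
  if (length(inside) == 0) return(NA_character_)
  # CDS sequence in transcript order
  pieces <- vapply(seq_len(nrow(gm$cds)), function(i)
    get_seq(genome, gm$chrom, gm$cds[i, 1], gm$cds[i, 2]), character(1))
  cds_seq <- paste(pieces, collapse = "")
  # genomic offsets into the concatenated (+-strand) CDS
  offsets <- cumsum(c(0, gm$cds[, 2] - gm$cds[, 1] + 1))
  idx_plus <- offsets[inside] + (pos - gm$cds[inside, 1]) + 1L
  if (gm$strand == "-") {
    cds_seq <- revcomp(cds_seq)
    idx <- nchar(cds_seq) - idx_plus + 1L
    ref_t <- complement_base(ref); alt_t <- complement_base(alt)
  } else {
    idx <- idx_plus
    ref_t <- toupper(ref); alt_t <- toupper(alt)
  }
  codon_i <- (idx - 1L) %/% 3L
  within <- (idx - 1L) %% 3L + 1L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3) return(NA_character_)
  if (substr(codon, within, within) != ref_t) {
    warning("reference base mismatch in CDS of ", gm$gene_id, " at ", pos)
  }
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_t
  if (codon_aa(codon) == codon_aa(alt_codon)) "synonymous" else "missense"
}

#' Assign a genic region label to a site
#'
#' Sites inside a gene are labelled by exon/intron structure, with coding
#' impact (missense/synonymous) computed from the codon substitution when
#' inside an annotated CDS. Sites upstream/downstream of a gene (within
#' \code{max_utr_dist}) are reassigned to 5'/3'-UTR respectively
#' (strand-aware), reflecting that sites discovered in RNA must be expressed;
#' beyond that distance they are intergenic.
#'
#' @param chrom,pos site coordinates (scalars)
#' @param ref,alt site alleles (needed for coding impact; may be NA)
#' @param gene_models list of [gene_model()]
#' @param genome \code{DNAStringSet} (codon lookup); may be NULL if no CDS
#' @param max_utr_dist maximum distance for the UTR reassignment (default
#'   5000 bp)
#' @return list with \code{gene_id} (NA if intergenic), \code{strand} and
#'   \code{region} in \{intron, 3'UTR, 5'UTR, missense, synonymous,
#'   noncoding-exon, intergenic\}
#' @export
assign_region <- function(chrom, pos, ref = NA, alt = NA, gene_models,
                          genome = NULL, max_utr_dist = 5000) {
  best <- NULL; best_dist <- Inf
  for (gm in gene_models) {
    if (gm$chrom != chrom) next
    span <- c(min(gm$exons[, 1]), max(gm$exons[, 2]))
    d <- if (pos < span[1]) span[1] - pos
         else if (pos > span[2]) pos - span[2] else 0
    if (d < best_dist) { best <- gm; best_dist <- d }
  }
  if (is.null(best) || best_dist > max_utr_dist)
    return(list(gene_id = NA_character_, strand = NA_character_,
                region = "intergenic"))
  gm <- best
  span <- c(min(gm$exons[, 1]), max(gm$exons[, 2]))
  if (best_dist > 0) {
    upstream_side <- pos < span[1]
    region <- if (xor(upstream_side, gm$strand == "-")) "5'UTR" else "3'UTR"
    return(list(gene_id = gm$gene_id, strand = gm$strand, region = region))
  }
  in_exon <- any(gm$exons[, 1] <= pos & pos <= gm$exons[, 2])
  if (!in_exon)
    return(list(gene_id = gm$gene_id, strand = gm$strand, region = "intron"))
  if (!is.null(gm$cds) && !is.na(ref) && !is.na(alt) && !is.null(genome)) {
    impact <- coding_impact(gm, pos, ref, alt, genome)
    if (!is.na(impact))
      return(list(gene_id = gm$gene_id, strand = gm$strand, region = impact))
    cds_span <- c(min(gm$cds[, 1]), max(gm$cds[, 2]))
    utr5_side <- if (gm$strand == "+") pos < cds_span[1] else pos > cds_span[2]
    return(list(gene_id = gm$gene_id, strand = gm$strand,
                region = if (utr5_side) "5'UTR" else "3'UTR"))
  }
  list(gene_id = gm$gene_id, strand = gm$strand, region = "noncoding-exon")
}

#' Build the curated edit-site table
#'
#' Runs [classify_edit()] and [assign_region()] over a curated variant set.
#' Sites that do not resolve to a stranded gene keep the genomic-strand
#' classification.
#'
#' @param sites a [variant_set()] of curated sites
#' @param gene_models list of [gene_model()]
#' @param genome optional \code{DNAStringSet}
#' @param max_utr_dist see [assign_region()]
#' @return data.frame of edit sites (chrom, pos, ref, alt, gene_id,
#'   transcript_strand, region, edit_class, is_A_to_I)
#' @export
annotate_sites <- function(sites, gene_models, genome = NULL,
                           max_utr_dist = 5000) {
  v <- sites$variants
  n <- nrow(v)
  gene_id <- character(n); strand <- character(n); region <- character(n)
  for (i in seq_len(n)) {
    a <- assign_region(v$chrom[i], v$pos[i], v$ref[i], v$alt[i],
                       gene_models, genome, max_utr_dist)
    gene_id[i] <- a$gene_id; strand[i] <- a$strand; region[i] <- a$region
  }
  strand_use <- ifelse(is.na(strand), "+", strand)
  cls <- classify_edit(v$ref, v$alt, strand_use)
  data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
             gene_id = gene_id, transcript_strand = strand,
             region = region, edit_class = cls$edit_class,
             is_A_to_I = cls$is_A_to_I, stringsAsFactors = FALSE)
}

#' Summarize edit sites by class and region
#'
#' @param edit_sites data.frame from [annotate_sites()] (needs
#'   \code{edit_class} and \code{region} columns)
#' @return list of two data.frames (\code{by_class}, \code{by_region}) with
#'   counts and percentages (rounded to one decimal place)
#' @export
summarize_sites <- function(edit_sites) {
  summarize_one <- function(x) {
    if (length(x) == 0)
      return(data.frame(level = character(), count = integer(),
                        percent = numeric()))
    tab <- sort(table(x), decreasing = TRUE)
    data.frame(level = names(tab), count = as.integer(tab),
               percent = pct(as.integer(tab), length(x)),
               row.names = NULL)
  }
  list(by_class = summarize_one(edit_sites$edit_class),
       by_region = summarize_one(edit_sites$region))
}
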