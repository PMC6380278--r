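# Readers and writers for the standard formats the pipeline touches, plus the
# shared coordinate conventions. Positions are 1-based closed internally;
# BED (0-based half-open) is converted on read/write.

#' Construct a variant set
#'
#' A light container for SNV records: a data frame of per-variant fields and
#' an optional alt-allele dosage matrix (variants x animals, entries 0/1/2 or
#' NA for missing genotypes).
#'
#' @param variants data.frame with columns chrom, pos, ref, alt, qual,
#'   alt_obs, n_missing
#' @param geno optional dosage matrix, one row per variant, one column per
#'   animal (column names are animal ids)
#' @return an object of class \code{variant_set}
#' @export
variant_set <- function(variants, geno = NULL) {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants must have columns ", paste(need, collapse = ", "))
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref must differ from alt")
  if (!is.null(geno)) {
    geno <- as.matrix(geno)
    if (nrow(geno) != nrow(variants))
      stop("geno must have one row per variant")
  }
  structure(list(variants = variants, geno = geno), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "SNVs",
      if (!is.null(x$geno)) paste0("x ", ncol(x$geno), " animals"), "\n")
  invisible(x)
}

#' Number of animals genotyped in a variant set
#' @param vs a \code{variant_set}
#' @export
n_animals <- function(vs) if (is.null(vs$geno)) 0L else ncol(vs$geno)

# Convert a vcfR GT string ("0/1", "1|0", ".", "./.") to alt-allele dosage
# for allele index `allele`. Phased and unphased separators are equivalent.
gt_to_dosage <- function(gt, allele = 1L) {
  gt <- sub(":.*", "", gt)
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) == 0 || any(p == ".") || any(is.na(p))) return(NA_real_)
    sum(as.integer(p) == allele)
  }, numeric(1))
}

#' Read a VCF into a variant set
#'
#' Multi-allelic records are split into bi-allelic records on read; indel and
#' symbolic records are dropped (with a logged count). Genotypes are encoded
#' as alt-allele dosage \{0, 1, 2, NA\}. The per-variant count of observed
#' alternate alleles is taken from the INFO AO (or AC) field when present,
#' otherwise from the genotype dosages.
#'
#' @param path path to a VCF 4.x file
#' @return a [variant_set()]; attribute \code{n_indels_dropped} records how
#'   many non-SNV alleles were excluded
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- variant_set(data.frame(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  qual = numeric(), alt_obs = integer(),
                                  n_missing = integer()))
    attr(out, "n_indels_dropped") <- 0L
    return(out)
  }
  gt_raw <- if ("gt" %in% slotNames(v) && ncol(v@gt) > 1) {
    vcfR::extract.gt(v, element = "GT")
  } else NULL
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    ifelse(lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0,
           sub(paste0(".*", key, "="), "", m), NA_character_)
  }
  info <- vcfR::getINFO(v)
  ao_raw <- info_field(info, "AO")
  if (all(is.na(ao_raw))) ao_raw <- info_field(info, "AC")

  rows <- list()
  dosages <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    aos <- if (!is.na(ao_raw[i])) {
      suppressWarnings(as.numeric(strsplit(ao_raw[i], ",")[[1]]))
    } else rep(NA_real_, length(alts))
    for (a in seq_along(alts)) {
      ref <- toupper(fix$REF[i]); alt <- toupper(alts[a])
      if (nchar(ref) != 1 || nchar(alt) != 1 ||
          !(ref %in% DNA_BASES) || !(alt %in% DNA_BASES)) {
        n_dropped <- n_dropped + 1L
        next
      }
      dos <- if (!is.null(gt_raw)) gt_to_dosage(gt_raw[i, ], allele = a) else NULL
      n_missing <- if (is.null(dos)) 0L else sum(is.na(dos))
      alt_obs <- if (!is.na(aos[a])) {
        as.integer(aos[a])
      } else if (!is.null(dos)) {
        as.integer(sum(dos, na.rm = TRUE))
      } else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = ref, alt = alt,
        qual = suppressWarnings(as.numeric(fix$QUAL[i])),
        alt_obs = alt_obs, n_missing = n_missing,
        stringsAsFactors = FALSE)
      dosages[[length(dosages) + 1L]] <- dos
    }
  }
  if (n_dropped > 0)
    message(n_dropped, " indel/non-SNV allele(s) excluded from ", basename(path))
  if (length(rows) == 0) {
    out <- variant_set(data.frame(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  qual = numeric(), alt_obs = integer(),
                                  n_missing = integer()))
    attr(out, "n_indels_dropped") <- n_dropped
    return(out)
  }
  variants <- do.call(rbind, rows)
  geno <- if (!is.null(gt_raw)) {
    m <- do.call(rbind, dosages)
    colnames(m) <- colnames(gt_raw)
    m
  } else NULL
  out <- variant_set(variants, geno)
  attr(out, "n_indels_dropped") <- n_dropped
  out
}

#' Write a variant set to a minimal VCF 4.2 file
#'
#' @param vs a [variant_set()]
#' @param path output path
#' @param sample_names animal ids for the genotype columns (defaults to the
#'   dosage matrix column names)
#' @export
write_vcf <- function(vs, path, sample_names = NULL) {
  v <- vs$variants
  has_gt <- !is.null(vs$geno)
  if (has_gt && is.null(sample_names))
    sample_names <- colnames(vs$geno) %||% paste0("animal", seq_len(ncol(vs$geno)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observations\">",
               if (has_gt) "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (has_gt) header <- c(header, "FORMAT", sample_names)
  writeLines(paste(header, collapse = "\t"), con)
  gt_string <- function(d) {
    ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L])
  }
  for (i in seq_len(nrow(v))) {
    fields <- c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i],
                format(v$qual[i] %||% 100), ".",
                paste0("AO=", v$alt_obs[i] %||% 0L))
    if (has_gt) fields <- c(fields, "GT", gt_string(vs$geno[i, ]))
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a BED mask into merged genomic intervals
#'
#' BED is 0-based half-open on disk; the returned \code{GRanges} is 1-based
#' closed. Overlapping intervals are merged. Records with start >= end are
#' rejected with a warning.
#'
#' @param path path to a BED3+ file
#' @return a \code{GRanges} of merged mask intervals
#' @export
read_bed_mask <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 3) stop("BED needs at least 3 columns: ", path)
  bad <- raw[[2]] >= raw[[3]]
  if (any(bad)) {
    warning(sum(bad), " BED record(s) with start >= end rejected")
    raw <- raw[!bad, , drop = FALSE]
  }
  gr <- GenomicRanges::GRanges(raw[[1]],
                               IRanges::IRanges(start = raw[[2]] + 1L,
                                                end = raw[[3]]))
  GenomicRanges::reduce(gr)
}

#' Test whether 1-based positions fall inside a mask
#' @param mask a \code{GRanges} from [read_bed_mask()]
#' @param chrom chromosome names
#' @param pos 1-based positions
#' @return logical vector
#' @export
in_mask <- function(mask, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(q, mask)
}

#' Construct a gene model
#'
#' @param gene_id gene identifier
#' @param chrom chromosome
#' @param strand "+" or "-"
#' @param exons two-column matrix of 1-based inclusive exon intervals
#' @param cds optional two-column matrix of CDS intervals
#' @return an object of class \code{gene_model} with the derived set of
#'   annotated splice junctions (donor = last base of the upstream exon,
#'   acceptor = first base of the downstream exon, in genome coordinates)
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exons in gene ", gene_id)
  junctions <- if (nrow(exons) > 1) {
    cbind(donor = exons[-nrow(exons), 2], acceptor = exons[-1, 1])
  } else {
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("donor", "acceptor")))
  }
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
    cds <- cds[order(cds[, 1]), , drop = FALSE]
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, junctions = junctions),
            class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Exon (and CDS) features are grouped by their parent gene, following
#' Parent= links through transcript features where present. Exons of
#' alternative transcripts are unioned per gene. Exons without a resolvable
#' parent gene are skipped with a warning.
#'
#' @param path path to a GFF3 file
#' @return named list of [gene_model()] objects
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID %||% rep(NA_character_, length(gr)))
  parents <- md$Parent
  parent1 <- vapply(seq_along(gr), function(i) {
    p <- parents[[i]]
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))

  is_gene <- type == "gene"
  gene_ids <- ids[is_gene]
  id_to_idx <- stats::setNames(seq_along(gr), ids)
  resolve_gene <- function(i, depth = 0) {
    if (depth > 5) return(NA_character_)
    p <- parent1[i]
    if (is.na(p)) return(NA_character_)
    if (p %in% gene_ids) return(p)
    j <- id_to_idx[p]
    if (is.na(j)) return(NA_character_)
    resolve_gene(j, depth + 1)
  }

  models <- list()
  n_orphan <- 0L
  for (g in which(is_gene)) {
    models[[ids[g]]] <- list(chrom = as.character(GenomicRanges::seqnames(gr)[g]),
                             strand = as.character(BiocGenerics::strand(gr)[g]),
                             exons = NULL, cds = NULL)
  }
  for (i in which(type %in% c("exon", "CDS"))) {
    gid <- resolve_gene(i)
    if (is.na(gid) || is.null(models[[gid]])) { n_orphan <- n_orphan + 1L; next }
    iv <- c(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
    slot <- if (type[i] == "exon") "exons" else "cds"
    models[[gid]][[slot]] <- rbind(models[[gid]][[slot]], iv)
  }
  if (n_orphan > 0)
    warning(n_orphan, " exon/CDS feature(s) without a parent gene skipped")

  out <- list()
  for (gid in names(models)) {
    m <- models[[gid]]
    if (is.null(m$exons)) next
    ex <- IRanges::reduce(IRanges::IRanges(m$exons[, 1], m$exons[, 2]))
    cds <- if (!is.null(m$cds)) {
      cr <- IRanges::reduce(IRanges::IRanges(m$cds[, 1], m$cds[, 2]))
      cbind(IRanges::start(cr), IRanges::end(cr))
    } else NULL
    out[[gid]] <- gene_model(gid, m$chrom, m$strand,
                             cbind(IRanges::start(ex), IRanges::end(ex)), cds)
  }
  out
}

#' Read a genome FASTA
#' @param path path to a FASTA file
#' @return a named \code{DNAStringSet}; names are truncated at the first space
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*", "", names(g))
  g
}

#' Extract genome sequence for a 1-based closed interval
#'
#' @param genome a \code{DNAStringSet} from [read_genome()]
#' @param chrom chromosome name
#' @param start,end 1-based inclusive bounds (clipped to the chromosome)
#' @return character scalar (uppercase)
#' @export
get_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("chromosome not in genome: ", chrom)
  len <- length(genome[[chrom]])
  start <- max(1L, as.integer(start)); end <- min(len, as.integer(end))
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start, end)))
}

#' Fetch single reference bases
#' @inheritParams get_seq
#' @param pos 1-based positions
#' @return character vector of bases
#' @export
get_base <- function(genome, chrom, pos) {
  mapply(function(c1, p1) get_seq(genome, c1, p1, p1), chrom, pos,
         USE.NAMES = FALSE)
}
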