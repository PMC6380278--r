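# Dot-plot prediction of double-stranded pre-mRNA regions and location of
# each edit site's opposite base within its helix.

#' Extraction intervals for structure prediction
#'
#' For each gene with edit sites, the interval spanning the outermost sites
#' plus 1.5 kbp on each side, clipped at the chromosome ends. Intervals
#' longer than \code{max_len} are split into chunks of at most
#' \code{max_len} bp with \code{overlap} bp of overlap so that helices
#' spanning a cut are seen whole in one chunk.
#'
#' @param sites data.frame with chrom, pos, gene_id
#' @param genome \code{DNAStringSet}
#' @param flank flank size (default 1500 bp)
#' @param max_len maximum chunk length (default 15000 bp)
#' @param overlap chunk overlap (default = flank)
#' @return data.frame (gene_id, chrom, start, end, seq) with one row per
#'   chunk; coordinates 1-based inclusive
#' @export
extract_regions <- function(sites, genome, flank = 1500, max_len = 15000,
                            overlap = flank) {
  out <- list()
  for (gid in unique(stats::na.omit(sites$gene_id))) {
    sel <- sites[!is.na(sites$gene_id) & sites$gene_id == gid, ]
    chrom <- sel$chrom[1]
    chrlen <- length(genome[[chrom]])
    start <- max(1L, min(sel$pos) - flank)
    end <- min(chrlen, max(sel$pos) + flank)
    if (end - start + 1L <= max_len) {
      starts <- start; ends <- end
    } else {
      starts <- seq(start, end, by = max_len - overlap)
      ends <- pmin(starts + max_len - 1L, end)
      keep <- c(TRUE, ends[-length(ends)] < end)
      starts <- starts[keep]; ends <- ends[keep]
    }
    for (k in seq_along(starts)) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gid, chrom = chrom, start = starts[k], end = ends[k],
        seq = get_seq(genome, chrom, starts[k], ends[k]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), seq = character()))
  do.call(rbind, out)
}

#' Dot-plot scan of a sequence against its complement
#'
#' Places a dot at position pair (i, j) when at least \code{min_match} of
#' the \code{window} base pairs centered on (i, j) — sequence position
#' \code{i + k} against position \code{j - k} for k in
#' \code{-(window-1)/2 .. (window-1)/2} — are Watson-Crick complementary
#' (A:T/U and C:G only). Runs of dots along anti-diagonals mark potential
#' double-stranded helices. Positions within \code{(window-1)/2} of either
#' sequence end are not evaluated.
#'
#' Computed one anti-diagonal (constant i + j) at a time with a running
#' window sum, so the cost is O(n^2) rather than O(n^2 w).
#'
#' @param sequence character scalar (DNA alphabet; U treated as T)
#' @param window odd window length (default 15)
#' @param min_match minimum complementary pairs in the window (default 11)
#' @return data.frame (i, j, matches) of dot coordinates with i <= j
#' @export
dotplot_scan <- function(sequence, window = 15, min_match = 11) {
  stopifnot(window %% 2 == 1, min_match <= window)
  s <- toupper(chartr("U", "T", sequence))
  L <- nchar(s)
  h <- (window - 1L) %/% 2L
  empty <- data.frame(i = integer(), j = integer(), matches = integer())
  if (L < window) return(empty)
  x <- utf8ToInt(s)
  comp <- integer(128)
  comp[utf8ToInt("A")] <- utf8ToInt("T"); comp[utf8ToInt("T")] <- utf8ToInt("A")
  comp[utf8ToInt("C")] <- utf8ToInt("G"); comp[utf8ToInt("G")] <- utf8ToInt("C")
  xc <- comp[x]  # complement codes; 0 for non-ACGT
  res_i <- list(); res_j <- list(); res_m <- list()
  lo <- h + 1L; hi <- L - h
  for (d in (2L * lo):(2L * hi)) {
    i_min <- max(lo, d - hi); i_max <- min(hi, d - lo)
    if (i_max < i_min) next
    # complementarity along the full anti-diagonal, indices offset by h for
    # the window sum
    a_min <- i_min - h; a_max <- i_max + h
    ii <- a_min:a_max
    jj <- d - ii
    cvec <- as.integer(xc[ii] != 0L & xc[ii] == x[jj])
    cs <- cumsum(c(0L, cvec))
    n_eval <- i_max - i_min + 1L
    wsum <- cs[(window + 1L):(window + n_eval)] - cs[1:n_eval]
    hit <- which(wsum >= min_match)
    if (length(hit) > 0) {
      res_i[[length(res_i) + 1L]] <- i_min + hit - 1L
      res_j[[length(res_j) + 1L]] <- d - (i_min + hit - 1L)
      res_m[[length(res_m) + 1L]] <- wsum[hit]
    }
  }
  if (length(res_i) == 0) return(empty)
  out <- data.frame(i = as.integer(unlist(res_i)),
                    j = as.integer(unlist(res_j)),
                    matches = as.integer(unlist(res_m)))
  out <- out[out$i <= out$j, , drop = FALSE]
  out <- out[order(out$i + out$j, out$i), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract helices from a dot-plot match set
#'
#' Runs of at least \code{min_run} consecutive dots along an anti-diagonal
#' (constant i + j) become helices; the pairing map follows the run geometry
#' (position i pairs with i + j - i along the run). Bulges split helices
#' (gap tolerance zero).
#'
#' @param dots data.frame (i, j) from [dotplot_scan()]
#' @param min_run minimum run length (default 25)
#' @return list of helices, each a list with \code{forward} and
#'   \code{reverse} arm intervals (c(start, end)), \code{diag} (= i + j) and
#'   \code{pairing} (data.frame i, j)
#' @export
extract_helices <- function(dots, min_run = 25) {
  dots <- dots[dots$i < dots$j, , drop = FALSE]
  helices <- list()
  if (nrow(dots) == 0) return(helices)
  for (d in sort(unique(dots$i + dots$j))) {
    ii <- sort(dots$i[dots$i + dots$j == d])
    breaks <- c(0, which(diff(ii) != 1L), length(ii))
    for (b in seq_len(length(breaks) - 1L)) {
      run <- ii[(breaks[b] + 1L):breaks[b + 1L]]
      if (length(run) < min_run) next
      helices[[length(helices) + 1L]] <- list(
        forward = c(min(run), max(run)),
        reverse = c(d - max(run), d - min(run)),
        diag = d,
        pairing = data.frame(i = run, j = d - run))
    }
  }
  helices
}

# Paired position of `pos` in the first helix containing it (either arm),
# or NA if it lies in none.
paired_position <- function(pos, helices) {
  for (hx in helices) {
    in_fwd <- pos >= hx$forward[1] && pos <= hx$forward[2]
    in_rev <- pos >= hx$reverse[1] && pos <= hx$reverse[2]
    if (in_fwd || in_rev) return(hx$diag - pos)
  }
  NA_integer_
}

#' Base predicted to pair with a site inside a helix
#'
#' @param pos 1-based position of the site within the scanned sequence
#' @param helices list from [extract_helices()]
#' @param sequence the scanned sequence
#' @return the opposite base in the RNA alphabet, or NA when the site lies
#'   outside every helix
#' @export
opposite_base <- function(pos, helices, sequence) {
  j <- paired_position(pos, helices)
  if (is.na(j)) return(NA_character_)
  as_rna(substr(toupper(sequence), j, j))
}

#' Allele complementarity of a variant inside a helix
#'
#' For a variant inside a helix arm, flags each allele as complementary if
#' it Watson-Crick pairs the base at the variant's paired position. Variants
#' where neither allele is complementary are flagged unusable for the
#' complementarity sign test.
#'
#' @param ref,alt variant alleles (DNA alphabet, scanned-strand orientation)
#' @param pos 1-based variant position within the scanned sequence
#' @param helices list from [extract_helices()]
#' @param sequence the scanned sequence
#' @return list with \code{opposite} (RNA base or NA), \code{ref_complementary},
#'   \code{alt_complementary} and \code{usable}
#' @export
allele_complementarity <- function(ref, alt, pos, helices, sequence) {
  j <- paired_position(pos, helices)
  if (is.na(j))
    return(list(opposite = NA_character_, ref_complementary = NA,
                alt_complementary = NA, usable = FALSE))
  opp_dna <- substr(toupper(chartr("U", "T", sequence)), j, j)
  rc <- unname(wc_pair(ref, opp_dna))
  ac <- unname(wc_pair(alt, opp_dna))
  list(opposite = as_rna(opp_dna), ref_complementary = rc,
       alt_complementary = ac, usable = rc || ac)
}
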