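# Editing proportions (Phi), logit mapping phenotypes, neighbor-base context
# and sequence-logo information content.

#' Compute per-animal editing proportions
#'
#' Phi is the proportion of reads carrying the edited base at a site in an
#' animal: edited / total, missing when no reads cover the site.
#'
#' @param edited,total matrices (sites x animals) of edited and total read
#'   counts; NA marks uncovered site/animal combinations
#' @return list with \code{phi} (matrix), and per-site \code{mean} and
#'   \code{median} across animals (missing animals excluded)
#' @export
compute_phi <- function(edited, total) {
  edited <- as.matrix(edited); total <- as.matrix(total)
  stopifnot(all(dim(edited) == dim(total)))
  bad <- which(!is.na(edited) & !is.na(total) & edited > total, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("edited > total at site ",
         rownames(edited)[bad[1, 1]] %||% bad[1, 1],
         ", animal ", colnames(edited)[bad[1, 2]] %||% bad[1, 2])
  phi <- edited / total
  phi[is.na(total) | total == 0] <- NA_real_
  list(phi = phi,
       mean = rowMeans(phi, na.rm = TRUE),
       median = apply(phi, 1, stats::median, na.rm = TRUE))
}

#' Logit-transform editing proportions into mapping phenotypes
#'
#' Uses Haldane-Anscombe pseudocounts to keep boundary proportions finite:
#' \code{y = log((edited + 0.5) / (total - edited + 0.5))}, which is
#' \code{logit(phi*)} for \code{phi* = (edited + 0.5) / (total + 1)}. The
#' transform is strictly increasing in the edited count at fixed total.
#'
#' @param edited,total count matrices as in [compute_phi()]
#' @return matrix of logit phenotypes (NA where total is missing or zero)
#' @export
logit_phenotype <- function(edited, total) {
  edited <- as.matrix(edited); total <- as.matrix(total)
  y <- log((edited + 0.5) / (total - edited + 0.5))
  y[is.na(total) | total == 0] <- NA_real_
  y
}

# Strand-aware flanking base at a signed offset from the edit site
# (offset +1 = immediately downstream on the transcript strand).
flank_base <- function(genome, chrom, pos, strand, offset) {
  gpos <- if (strand == "-") pos - offset else pos + offset
  if (gpos < 1 || gpos > length(genome[[chrom]])) return(NA_character_)
  b <- get_base(genome, chrom, gpos)
  if (strand == "-") b <- complement_base(b)
  b
}

#' Neighbor-base frequencies at edit sites with enrichment tests
#'
#' Counts the base immediately upstream (-1) and downstream (+1) of each
#' edit site on the transcript strand, and tests each base's count against
#' background frequencies with a two-sided exact binomial test. Background
#' base frequencies are estimated from the +-\code{bg_halfwidth} bp flanks of
#' the same sites, excluding offsets -1, 0 and +1 (a self-contained
#' background that needs no genome-wide pass).
#'
#' @param sites data.frame with chrom, pos, transcript_strand (NA strand
#'   treated as "+")
#' @param genome \code{DNAStringSet}
#' @param bg_halfwidth background flank half-width (default 10)
#' @return list with \code{counts} (base x offset table, RNA alphabet),
#'   \code{freq}, \code{background} frequencies and \code{p_value} table
#' @export
neighbor_frequencies <- function(sites, genome, bg_halfwidth = 10) {
  strand <- ifelse(is.na(sites$transcript_strand), "+",
                   sites$transcript_strand)
  n <- nrow(sites)
  up <- character(n); down <- character(n)
  bg <- character(0)
  for (i in seq_len(n)) {
    up[i] <- flank_base(genome, sites$chrom[i], sites$pos[i], strand[i], -1L)
    down[i] <- flank_base(genome, sites$chrom[i], sites$pos[i], strand[i], 1L)
    offs <- setdiff(seq(-bg_halfwidth, bg_halfwidth), -1:1)
    bg <- c(bg, vapply(offs, function(o)
      flank_base(genome, sites$chrom[i], sites$pos[i], strand[i], o),
      character(1)))
  }
  rna <- c("A", "C", "G", "U")
  count_tab <- cbind(upstream = table(factor(as_rna(up), levels = rna)),
                     downstream = table(factor(as_rna(down), levels = rna)))
  bg_freq <- prop.table(table(factor(as_rna(bg), levels = rna)))
  pvals <- count_tab * NA_real_
  for (side in colnames(count_tab)) {
    n_side <- sum(count_tab[, side])
    for (b in rna) {
      pvals[b, side] <- stats::binom.test(count_tab[b, side], n_side,
                                          p = bg_freq[[b]])$p.value
    }
  }
  list(counts = count_tab, freq = prop.table(count_tab, 2),
       background = as.numeric(bg_freq) |> stats::setNames(rna),
       p_value = pvals)
}

#' Information content of one sequence-logo column
#'
#' \code{information = 2 - H - e(n)} bits, where H is the Shannon entropy of
#' the base frequencies (log base 2) and \code{e(n) = 3 / (2 ln 2 n)} is the
#' small-sample correction. Negative corrected values are clipped to zero.
#'
#' @param bases character vector of observed bases at this column (DNA or
#'   RNA alphabet)
#' @return list with \code{freq} (A/C/G/U), \code{n}, \code{entropy} and
#'   \code{information} (bits)
#' @export
logo_column <- function(bases) {
  rna <- c("A", "C", "G", "U")
  bases <- as_rna(bases)
  n <- length(bases)
  freq <- prop.table(table(factor(bases, levels = rna)))
  p <- as.numeric(freq)
  H <- -sum(ifelse(p > 0, p * log2(p), 0))
  e_n <- if (n > 0) 3 / (2 * log(2) * n) else 0
  info <- max(0, 2 - H - e_n)
  list(freq = stats::setNames(p, rna), n = n, entropy = H, information = info)
}

#' Sequence logo table around edit sites
#'
#' Builds per-offset base frequencies and information content for offsets
#' \code{-halfwidth .. +halfwidth} relative to each edit site, on the
#' transcript strand. The edit-site column (offset 0) uses the unedited
#' reference base.
#'
#' @param sites data.frame with chrom, pos, transcript_strand
#' @param genome \code{DNAStringSet}
#' @param halfwidth number of flanking positions each side (default 10)
#' @return data.frame with offset, n, freq_A..freq_U, entropy, information
#' @export
logo <- function(sites, genome, halfwidth = 10) {
  strand <- ifelse(is.na(sites$transcript_strand), "+",
                   sites$transcript_strand)
  rows <- lapply(seq(-halfwidth, halfwidth), function(o) {
    bases <- vapply(seq_len(nrow(sites)), function(i)
      flank_base(genome, sites$chrom[i], sites$pos[i], strand[i], o),
      character(1))
    col <- logo_column(bases)
    data.frame(offset = o, n = col$n,
               freq_A = col$freq[["A"]], freq_C = col$freq[["C"]],
               freq_G = col$freq[["G"]], freq_U = col$freq[["U"]],
               entropy = col$entropy, information = col$information)
  })
  do.call(rbind, rows)
}

#' Association between sequence context and editing proportion
#'
#' One-way analysis of variance of site-level mean Phi grouped by the
#' upstream base, the downstream base, and the joint 16-level
#' upstream/downstream grouping. Site-level means are the unit of analysis
#' (one value per site) to avoid pseudo-replication across animals.
#'
#' @param phi_site_means numeric vector, one mean Phi per site
#' @param upstream,downstream character vectors of neighbor bases per site
#' @return data.frame with grouping, F statistic, p-value and group-mean
#'   summary; degenerate inputs (no between-group variance) report F = 0,
#'   p = 1
#' @export
phi_by_context <- function(phi_site_means, upstream, downstream) {
  one <- function(groups, label) {
    ok <- !is.na(phi_site_means) & !is.na(groups)
    y <- phi_site_means[ok]; g <- factor(as_rna(groups[ok]))
    if (length(unique(g)) < 2 || stats::var(y) == 0) {
      return(data.frame(grouping = label, F = 0, p = 1,
                        n_groups = length(unique(g))))
    }
    a <- stats::anova(stats::lm(y ~ g))
    data.frame(grouping = label, F = a$`F value`[1], p = a$`Pr(>F)`[1],
               n_groups = nlevels(g))
  }
  joint <- paste0(as_rna(upstream), ".", as_rna(downstream))
  res <- rbind(one(upstream, "upstream"),
               one(downstream, "downstream"),
               one(joint, "joint"))
  means <- list(
    upstream = tapply(phi_site_means, as_rna(upstream), mean, na.rm = TRUE),
    downstream = tapply(phi_site_means, as_rna(downstream), mean, na.rm = TRUE),
    joint = tapply(phi_site_means, joint, mean, na.rm = TRUE))
  attr(res, "group_means") <- means
  res
}

#' Median editing proportion grouped by the predicted opposite base
#'
#' @param phi_site_means numeric vector, one mean Phi per site
#' @param opposite_bases character vector (RNA alphabet) of the base
#'   predicted to pair with each edit site, NA for sites outside any helix
#' @return data.frame with opposite base, n and median Phi; sites without a
#'   helix assignment are excluded
#' @export
paired_base_phi_summary <- function(phi_site_means, opposite_bases) {
  ok <- !is.na(opposite_bases) & !is.na(phi_site_means)
  b <- as_rna(opposite_bases[ok]); y <- phi_site_means[ok]
  if (length(y) == 0)
    return(data.frame(opposite = character(), n = integer(),
                      median_phi = numeric()))
  med <- tapply(y, b, stats::median)
  data.frame(opposite = names(med),
             n = as.integer(table(b)[names(med)]),
             median_phi = as.numeric(med), row.names = NULL)
}
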