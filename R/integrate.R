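# Cross-layer analyses: read-pair phase tests, the complementarity sign
# test, Phi-expression correlations with optional ADAR adjustment,
# edQTL/eQTL/trait-QTL cosegregation and effect-sign concordance.

#' Usability of a read-pair phase table
#'
#' A 2x2 edit-by-allele table is usable when every observed and every
#' expected (under independence) cell is at least \code{min_cell}, the pair
#' separation is at most \code{max_separation} bases, and the variant is in
#' LD (R^2 above \code{min_r2}) with the top associated variant.
#'
#' @param table 2x2 count matrix (edited/unedited x ref/alt)
#' @param separation distance in bases between edit site and variant
#' @param r2_with_top LD R^2 of the variant with the top associated variant
#' @param min_cell,max_separation,min_r2 thresholds (defaults 6, 150, 0.95)
#' @return list with \code{usable} and a \code{reason} code ("" when usable)
#' @export
phase_pair_usable <- function(table, separation = 0, r2_with_top = 1,
                              min_cell = 6, max_separation = 150,
                              min_r2 = 0.95) {
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  reason <- ""
  if (sum(table) == 0) reason <- "no_reads"
  else if (any(table < min_cell) || any(expected < min_cell))
    reason <- "small_cell"
  else if (separation > max_separation) reason <- "too_far"
  else if (r2_with_top < min_r2) reason <- "low_ld"
  list(usable = reason == "", reason = reason, expected = expected)
}

#' Chi-square phase test on a read-pair table
#'
#' Pearson chi-square test of independence on the 2x2 edited-by-allele
#' table, 1 df, without continuity correction (the minimum-expected-cell
#' usability filter already guards small counts).
#'
#' @param table 2x2 count matrix
#' @return one-row data.frame (chi2, p)
#' @export
phase_test <- function(table) {
  res <- stats::chisq.test(table, correct = FALSE)
  data.frame(chi2 = unname(res$statistic), p = unname(res$p.value))
}

#' One-sided complementarity sign test
#'
#' Tests whether the mean allele-substitution effect, oriented to the
#' noncomplementary allele, is negative — the expectation if alleles that
#' break base-pairing in the double-stranded region reduce editing.
#'
#' @param beta_noncomplementary effects oriented to the noncomplementary
#'   allele, one per eligible edit/variant pair
#' @return one-row data.frame (t, df, p, mean_beta, n)
#' @export
complementarity_test <- function(beta_noncomplementary) {
  b <- beta_noncomplementary[!is.na(beta_noncomplementary)]
  if (length(b) >= 2 && stats::sd(b) == 0) {
    # degenerate: constant effects; p is the limit of the t-test
    p <- if (mean(b) < 0) 0 else if (mean(b) > 0) 1 else 0.5
    return(data.frame(t = ifelse(mean(b) < 0, -Inf,
                                 ifelse(mean(b) > 0, Inf, 0)),
                      df = length(b) - 1, p = p, mean_beta = mean(b),
                      n = length(b)))
  }
  tt <- stats::t.test(b, alternative = "less", mu = 0)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, mean_beta = mean(b), n = length(b))
}

#' Correlation between editing and expression phenotypes
#'
#' Pearson correlation (and two-sided p-value) between each site's logit
#' editing phenotype and its gene's VST expression across animals with both
#' values, Bonferroni-corrected across tested pairs. If ADAR expression is
#' supplied, each gene's expression is first replaced by the residuals of an
#' ordinary least squares fit on ADAR expression.
#'
#' @param logit_phi matrix sites x animals
#' @param vst_expr matrix genes x animals (same animal order)
#' @param pairs data.frame (site, gene) of site/gene pairs to test; defaults
#'   to pairing row i of \code{logit_phi} with row i of \code{vst_expr}
#' @param adar_expr optional numeric vector of ADAR expression per animal
#' @return data.frame (site, gene, r, p, p_bonferroni, n)
#' @export
phi_expression_correlation <- function(logit_phi, vst_expr, pairs = NULL,
                                       adar_expr = NULL) {
  logit_phi <- rbind(logit_phi); vst_expr <- rbind(vst_expr)
  if (is.null(pairs)) {
    stopifnot(nrow(logit_phi) == nrow(vst_expr))
    pairs <- data.frame(site = seq_len(nrow(logit_phi)),
                        gene = seq_len(nrow(vst_expr)))
  }
  if (!is.null(adar_expr)) {
    for (g in unique(pairs$gene)) {
      e <- vst_expr[g, ]
      fit <- stats::lm(e ~ adar_expr, na.action = stats::na.exclude)
      vst_expr[g, ] <- stats::residuals(fit)
    }
  }
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    y1 <- logit_phi[pairs$site[k], ]
    y2 <- vst_expr[pairs$gene[k], ]
    ok <- !is.na(y1) & !is.na(y2)
    if (sum(ok) < 3 || stats::sd(y1[ok]) == 0 || stats::sd(y2[ok]) == 0)
      return(data.frame(site = pairs$site[k], gene = pairs$gene[k],
                        r = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- stats::cor.test(y1[ok], y2[ok], method = "pearson")
    data.frame(site = pairs$site[k], gene = pairs$gene[k],
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  res <- do.call(rbind, out)
  res$p_bonferroni <- pmin(1, res$p * sum(!is.na(res$p)))
  res
}

#' Cosegregation of two QTL association profiles
#'
#' Intersects the two profiles by variant position and computes the Spearman
#' rank correlation of their chi-square vectors (average ranks for ties).
#' Profiles with correlation above the threshold (default 0.707, i.e.
#' r^2 > 0.5) are classified as cosegregating, consistent with a shared
#' underlying causal variant.
#'
#' @param profile_a,profile_b data.frames with pos and chi2 columns (e.g.
#'   from [gls_scan()])
#' @param threshold classification threshold on r (default 0.707)
#' @return list with \code{r}, \code{n_shared} and \code{cosegregating}
#' @export
cosegregation <- function(profile_a, profile_b, threshold = 0.707) {
  m <- merge(profile_a[, c("pos", "chi2")], profile_b[, c("pos", "chi2")],
             by = "pos", suffixes = c("_a", "_b"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3)
    return(list(r = NA_real_, n_shared = nrow(m), cosegregating = NA))
  r <- stats::cor(m$chi2_a, m$chi2_b, method = "spearman")
  list(r = r, n_shared = nrow(m), cosegregating = r > threshold)
}

#' One-sided sign-concordance test across QTL pairs
#'
#' For each eligible (significantly correlated) QTL pair, the sign product
#' of the two top-variant effects (both oriented to the alternate allele) is
#' +1 for same-signed and -1 for opposite-signed effects; a one-sample,
#' one-sided t-test asks whether the mean sign is negative (antagonistic
#' effects, as expected if editing suppresses expression).
#'
#' @param beta_a,beta_b effect estimates for the two QTL of each pair,
#'   oriented to the same allele
#' @return one-row data.frame (t, df, p, mean_sign, n)
#' @export
sign_concordance <- function(beta_a, beta_b) {
  ok <- !is.na(beta_a) & !is.na(beta_b)
  s <- sign(beta_a[ok] * beta_b[ok])
  s <- s[s != 0]
  if (length(s) < 2 || stats::sd(s) == 0) {
    # degenerate: all signs equal; p limit 0 (all negative) or 1 (all positive)
    return(data.frame(t = ifelse(mean(s) < 0, -Inf, Inf), df = length(s) - 1,
                      p = ifelse(mean(s) < 0, 0, 1),
                      mean_sign = mean(s), n = length(s)))
  }
  tt <- stats::t.test(s, alternative = "less", mu = 0)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, mean_sign = mean(s), n = length(s))
}
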