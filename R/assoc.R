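# Pedigree numerator relationship matrix, GLS association engine with the
# fixed 0.3*A + 0.7*I covariance mixture, inflation diagnostic, thresholds,
# cis classification, exonic read counting and a closed-form VST.

# Median of the chi-square distribution with 1 df, as printed in the
# inflation-statistic definition (qchisq(0.5, 1) = 0.4549364).
CHISQ1_MEDIAN <- 0.4549

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive numerator relationship matrix A by the recursive
#' tabular method: \code{A[i,i] = 1 + 0.5 A[sire_i, dam_i]} and
#' \code{A[i,j] = 0.5 (A[j, sire_i] + A[j, dam_i])} for j earlier than i;
#' unknown parents contribute zero.
#'
#' @param pedigree data.frame (id, sire, dam) with parents preceding
#'   offspring; NA parent = unknown (founder)
#' @return N x N symmetric matrix, dimnames = animal ids
#' @export
a_matrix <- function(pedigree) {
  n <- nrow(pedigree)
  lookup <- stats::setNames(seq_len(n), as.character(pedigree$id))
  sire <- lookup[as.character(pedigree$sire)]
  dam <- lookup[as.character(pedigree$dam)]
  if (any(sire >= seq_len(n) | dam >= seq_len(n), na.rm = TRUE))
    stop("pedigree not topologically ordered (a parent follows its offspring)")
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                     (if (!is.na(d)) A[j, d] else 0))
      A[i, j] <- aj
      A[j, i] <- aj
    }
  }
  A
}

# Cholesky whitening context for the GLS covariance V = w1*A + w2*I,
# computed once per phenotype and reused across variants.
gls_context <- function(A, weights = c(0.3, 0.7)) {
  V <- weights[1] * A + weights[2] * diag(nrow(A))
  R <- tryCatch(chol(V), error = function(e)
    stop("GLS covariance is singular"))
  list(R = R, weights = weights)
  # whitening: z = solve(t(R)) %*% x, so z'z = x' V^-1 x
}

whiten <- function(ctx, x) {
  backsolve(ctx$R, as.matrix(x), transpose = TRUE)
}

#' Generalized least squares association fit for a single variant
#'
#' Fits \code{y = Xb + e}, \code{X = [1, dosage]},
#' \code{Var(e) = W = sigma2P (w1 A + w2 I)} with \code{sigma2P} the sample
#' variance of the analyzed phenotype vector. Reports the allele
#' substitution effect, its standard error, the Wald statistic
#' \code{chi2 = (beta/se)^2} and the 1-df chi-square p-value. Animals with a
#' missing phenotype or genotype are dropped pairwise.
#'
#' @param y phenotype vector
#' @param dosage alt-allele dosage vector (0/1/2, NA = missing)
#' @param A numerator relationship matrix for the same animals
#' @param weights covariance mixture \code{c(w_A, w_I)} (default 0.3, 0.7)
#' @return one-row data.frame (beta, se, chi2, p, n, testable); monomorphic
#'   dosage in the analyzed subset is flagged untestable with NA statistics
#' @export
gls_fit <- function(y, dosage, A, weights = c(0.3, 0.7)) {
  ok <- !is.na(y) & !is.na(dosage)
  y <- y[ok]; g <- dosage[ok]
  n <- length(y)
  if (n < 3 || stats::var(g) == 0) {
    return(data.frame(beta = NA_real_, se = NA_real_, chi2 = NA_real_,
                      p = NA_real_, n = n, testable = FALSE))
  }
  ctx <- gls_context(A[ok, ok, drop = FALSE], weights)
  sigma2 <- stats::var(y)
  Zw <- whiten(ctx, cbind(1, g))
  yw <- whiten(ctx, y)
  XtX <- crossprod(Zw)
  Xty <- crossprod(Zw, yw)
  beta_hat <- solve(XtX, Xty)
  covb <- sigma2 * solve(XtX)
  beta <- beta_hat[2, 1]
  se <- sqrt(covb[2, 2])
  chi2 <- (beta / se)^2
  data.frame(beta = beta, se = se, chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             n = n, testable = TRUE)
}

#' GLS association scan across a dosage matrix
#'
#' Equivalent to calling [gls_fit()] per variant, but the covariance is
#' factorized once per phenotype and reused; variants with missing dosages
#' fall back to the single-variant path.
#'
#' @param y phenotype vector (animals)
#' @param G dosage matrix, variants x animals
#' @param A numerator relationship matrix
#' @param weights covariance mixture (default \code{c(0.3, 0.7)})
#' @param positions optional variant positions carried into the result
#' @param chrom optional chromosome carried into the result
#' @return data.frame with one row per variant (beta, se, chi2, p, n,
#'   testable, and pos/chrom when supplied)
#' @export
gls_scan <- function(y, G, A, weights = c(0.3, 0.7), positions = NULL,
                     chrom = NULL) {
  ok <- !is.na(y)
  yy <- y[ok]
  Ak <- A[ok, ok, drop = FALSE]
  Gk <- G[, ok, drop = FALSE]
  n <- length(yy)
  ctx <- gls_context(Ak, weights)
  sigma2 <- stats::var(yy)
  yw <- drop(whiten(ctx, yy))
  ow <- drop(whiten(ctx, rep(1, n)))
  m <- nrow(Gk)
  beta <- se <- rep(NA_real_, m)
  nn <- rep(n, m); testable <- rep(FALSE, m)
  miss <- rowSums(is.na(Gk)) > 0
  if (any(!miss)) {
    Gw <- t(whiten(ctx, t(Gk[!miss, , drop = FALSE])))  # variants x n, whitened
    a11 <- sum(ow^2)
    a12 <- drop(Gw %*% ow)
    a22 <- rowSums(Gw^2)
    b1 <- sum(ow * yw)
    b2 <- drop(Gw %*% yw)
    det <- a11 * a22 - a12^2
    mono <- apply(Gk[!miss, , drop = FALSE], 1, stats::var) == 0
    good <- !mono & det > .Machine$double.eps * a11 * pmax(a22, 1)
    b_hat <- (a11 * b2 - a12 * b1) / det
    v_b <- sigma2 * a11 / det
    idx <- which(!miss)
    beta[idx[good]] <- b_hat[good]
    se[idx[good]] <- sqrt(v_b[good])
    testable[idx[good]] <- TRUE
  }
  for (v in which(miss)) {
    r <- gls_fit(yy, Gk[v, ], Ak, weights)
    beta[v] <- r$beta; se[v] <- r$se; nn[v] <- r$n; testable[v] <- r$testable
  }
  chi2 <- (beta / se)^2
  out <- data.frame(beta = beta, se = se, chi2 = chi2,
                    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                    n = nn, testable = testable)
  if (!is.null(positions)) out$pos <- positions
  if (!is.null(chrom)) out$chrom <- chrom
  out
}

#' Inflation statistic of an association scan
#'
#' The ratio of the observed median chi-square statistic to 0.4549, the
#' median of the 1-df chi-square distribution. Values near 1 indicate
#' well-calibrated tests; values above 1 indicate inflation.
#'
#' @param chi2 vector of per-variant chi-square statistics
#' @return lambda
#' @export
inflation <- function(chi2) {
  stats::median(chi2, na.rm = TRUE) / CHISQ1_MEDIAN
}

#' Bonferroni significance threshold
#' @param alpha family-wise error rate (default 0.05)
#' @param m number of tests
#' @return per-test threshold alpha / m
#' @export
bonferroni <- function(alpha = 0.05, m) {
  alpha / m
}

#' Classify a QTL as cis or trans
#'
#' The top variant is the one with the smallest p-value; ties are broken by
#' distance to the site, then by position. The QTL is cis when the top
#' variant lies on the site's chromosome within \code{window} bp.
#'
#' @param results data.frame from [gls_scan()] with pos (and optionally
#'   chrom) columns
#' @param site_chrom,site_pos coordinates of the regulated site
#' @param window cis window half-width (default 500 kbp)
#' @return list with \code{top} (row of results), \code{cis} (logical) and
#'   \code{distance}
#' @export
classify_cis <- function(results, site_chrom, site_pos, window = 5e5) {
  r <- results[results$testable & !is.na(results$p), , drop = FALSE]
  if (nrow(r) == 0) return(list(top = NULL, cis = NA, distance = NA_real_))
  same_chrom <- if ("chrom" %in% names(r)) r$chrom == site_chrom else TRUE
  dist <- ifelse(same_chrom, abs(r$pos - site_pos), Inf)
  ord <- order(r$p, dist, r$pos)
  top <- r[ord[1], , drop = FALSE]
  d <- dist[ord[1]]
  list(top = top, cis = is.finite(d) && d <= window, distance = d)
}

#' Exonic read counting for expression phenotypes
#'
#' A read counts toward a gene when all of its aligned blocks lie within
#' exons of that gene and every inter-block gap matches an annotated splice
#' junction; reads spliced at unannotated sites are excluded.
#'
#' @param read_blocks data.frame (read_id, animal, chrom, start, end) with
#'   one row per aligned block; blocks of a read share read_id
#' @param gene_models list of [gene_model()]
#' @return matrix of counts, genes x animals
#' @export
exonic_counts <- function(read_blocks, gene_models) {
  animals <- sort(unique(read_blocks$animal))
  counts <- matrix(0L, nrow = length(gene_models), ncol = length(animals),
                   dimnames = list(names(gene_models), animals))
  split_reads <- split(read_blocks, read_blocks$read_id)
  for (rb in split_reads) {
    rb <- rb[order(rb$start), , drop = FALSE]
    for (gid in names(gene_models)) {
      gm <- gene_models[[gid]]
      if (gm$chrom != rb$chrom[1]) next
      in_exon <- vapply(seq_len(nrow(rb)), function(k)
        any(gm$exons[, 1] <= rb$start[k] & rb$end[k] <= gm$exons[, 2]),
        logical(1))
      if (!all(in_exon)) next
      ok <- TRUE
      if (nrow(rb) > 1) {
        for (k in seq_len(nrow(rb) - 1L)) {
          gap <- c(rb$end[k], rb$start[k + 1L])
          hit <- any(gm$junctions[, "donor"] == gap[1] &
                       gm$junctions[, "acceptor"] == gap[2])
          if (!hit) { ok <- FALSE; break }
        }
      }
      if (ok) counts[gid, as.character(rb$animal[1])] <-
          counts[gid, as.character(rb$animal[1])] + 1L
    }
  }
  counts
}

#' Variance-stabilizing transformation for negative-binomial counts
#'
#' Closed-form VST for NB counts with common dispersion alpha:
#' \code{f(x) = (2 / sqrt(alpha)) asinh(sqrt(alpha x)) / ln 2}, which is
#' log2-like for large counts and linear in \code{sqrt(x)} as alpha -> 0.
#' When no dispersion is supplied it is estimated across genes by the method
#' of moments (\code{alpha = median((var - mean) / mean^2)} over genes with
#' var > mean).
#'
#' @param counts matrix, genes x animals
#' @param dispersion optional common dispersion alpha
#' @return list with \code{vst} (transformed matrix) and \code{dispersion}
#' @export
vst <- function(counts, dispersion = NULL) {
  counts <- as.matrix(counts)
  if (is.null(dispersion)) {
    m <- rowMeans(counts, na.rm = TRUE)
    v <- apply(counts, 1, stats::var, na.rm = TRUE)
    est <- (v - m) / m^2
    est <- est[is.finite(est) & est > 0]
    dispersion <- if (length(est) > 0) stats::median(est) else 1e-8
  }
  a <- max(dispersion, 1e-12)
  out <- (2 / sqrt(a)) * asinh(sqrt(a * counts)) / log(2)
  list(vst = out, dispersion = dispersion)
}

#' Minor allele frequency and Hardy-Weinberg screen of a dosage matrix
#'
#' Removes variants with minor allele frequency below \code{maf_min} and
#' variants failing an exact Hardy-Weinberg test at \code{hwe_p} (a screen
#' for erroneous assays).
#'
#' @param G dosage matrix, variants x animals
#' @param maf_min minimum minor allele frequency (default 0.01)
#' @param hwe_p exact-test rejection threshold (default 1e-30)
#' @return logical vector of variants passing the screen
#' @export
genotype_screen <- function(G, maf_min = 0.01, hwe_p = 1e-30) {
  p <- rowMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hw <- vapply(seq_len(nrow(G)), function(v) {
    g <- G[v, ]; g <- g[!is.na(g)]
    hwe_exact_p(sum(g == 1), sum(g == 2), sum(g == 0))
  }, numeric(1))
  maf >= maf_min & hw >= hwe_p
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on allele counts: the p-value sums the
#' probabilities of all heterozygote counts no more likely than the observed
#' one.
#'
#' @param n_het,n_hom_alt,n_hom_ref genotype counts
#' @return p-value
#' @export
hwe_exact_p <- function(n_het, n_hom_alt, n_hom_ref) {
  n <- n_het + n_hom_alt + n_hom_ref
  if (n == 0) return(1)
  n_a <- n_het + 2L * n_hom_alt  # minor-ish allele count
  if (n_a > n) n_a <- 2L * n - n_a
  hets <- seq(n_a %% 2L, n_a, by = 2L)
  # log probability of each possible heterozygote count given allele counts
  logp <- vapply(hets, function(h) {
    hom_a <- (n_a - h) %/% 2L
    hom_r <- n - h - hom_a
    lfactorial(n) - lfactorial(h) - lfactorial(hom_a) - lfactorial(hom_r) +
      h * log(2) + lfactorial(n_a) + lfactorial(2L * n - n_a) -
      lfactorial(2L * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) return(1)  # inconsistent counts
  sum(p[p <= p[obs] * (1 + 1e-12)])
}
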