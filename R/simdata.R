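# Synthetic-data generator. Emulates the statistical structure the analysis
# assumes: a multi-generation pedigree, gene-drop genotypes with
# distance-decaying LD, edit sites whose logit editing proportion depends on a
# cis dosage plus a pedigree-correlated polygenic term, binomial read
# sampling, planted inverted-repeat pre-mRNA, phased read pairs, and
# negative-binomial expression coupled to editing.

#' Simulation configuration
#'
#' Defaults describe the cohort the rest of the package is tested against:
#' 355 animals descending from 50 founders over three generations (matching a
#' quantification herd of a few hundred outbred dairy cattle), ~50x RNA read
#' depth at edit sites, and a polygenic:residual split of 0.3:0.7 on the
#' logit scale, the same mixture the GLS mapping model assumes.
#'
#' @param n_founders founder animals in generation 0
#' @param n_generations number of descendant generations
#' @param n_animals total pedigree size (founders + descendants)
#' @param n_variants biallelic variants on one synthetic chromosome
#' @param chrom_length chromosome length in bp (default 4 Mbp so 500 kbp cis
#'   windows are meaningful)
#' @param maf_range founder minor-allele-frequency range \code{c(lo, hi)}
#' @param ld_decay_rate per-bp decay rate of the latent haplotype
#'   correlation (default 2e-6: correlation ~0.4 at 500 kbp), giving
#'   genotypes in LD around any causal variant
#' @param transmission \code{"chromosome"} (recombination-free gene drop;
#'   LD preserved) or \code{"independent"} (per-variant independent founder
#'   draws and transmission; destroys LD, for null tests)
#' @param n_edit_sites number of edit sites
#' @param mu_logit baseline logit editing proportion (default
#'   \code{qlogis(0.165)}, a median site Phi of 16.5%)
#' @param causal_effect_logit per-allele additive effect of the causal
#'   variant on logit Phi (default 1.0, the strong-cis regime of clearly
#'   mapped edQTL, where top association statistics reach the chi-square
#'   ~100 range at a few hundred animals)
#' @param polygenic_variance variance of the pedigree-correlated polygenic
#'   term on the logit scale
#' @param residual_variance iid residual variance on the logit scale
#' @param depth_mean mean read depth per site per animal (Poisson)
#' @param expression_mean target mean expression count per gene
#' @param expression_dispersion negative-binomial dispersion alpha
#' @param phi_expression_slope effect of latent logit Phi on log expression
#' @param phase_odds_ratio odds ratio tying edited reads to the alt allele in
#'   read-pair tables
#' @param premrna_length,stem_length,loop_length pre-mRNA simulation geometry
#'   (stem default 100 nt, the scale of inverted SINE pairs)
#' @param n_stem_edits edit sites planted inside the stem
#' @param pleiotropic if TRUE the expression phenotype of each gene shares
#'   the edit site's causal variant (creates true cosegregating
#'   edQTL/eQTL pairs)
#' @param seed optional integer seed applied by the simulate_* functions
#' @return a list of class \code{sim_config}
#' @export
sim_config <- function(n_founders = 50,
                       n_generations = 3,
                       n_animals = 355,
                       n_variants = 400,
                       chrom_length = 4e6,
                       maf_range = c(0.1, 0.5),
                       ld_decay_rate = 2e-6,
                       transmission = c("chromosome", "independent"),
                       n_edit_sites = 20,
                       mu_logit = stats::qlogis(0.165),
                       causal_effect_logit = 1.0,
                       polygenic_variance = 0.3,
                       residual_variance = 0.7,
                       depth_mean = 50,
                       expression_mean = 500,
                       expression_dispersion = 0.1,
                       phi_expression_slope = -0.3,
                       phase_odds_ratio = 4,
                       premrna_length = 3000,
                       stem_length = 100,
                       loop_length = 30,
                       n_stem_edits = 5,
                       pleiotropic = TRUE,
                       seed = NULL) {
  transmission <- match.arg(transmission)
  cfg <- as.list(environment())
  if (cfg$n_founders < 2) stop("n_founders must be >= 2")
  if (cfg$n_generations < 1) stop("n_generations must be >= 1")
  if (!(cfg$maf_range[1] > 0 && cfg$maf_range[1] <= cfg$maf_range[2] &&
        cfg$maf_range[2] <= 0.5))
    stop("maf_range must satisfy 0 < lo <= hi <= 0.5")
  if (cfg$polygenic_variance < 0 || cfg$residual_variance < 0)
    stop("variances must be >= 0")
  if (cfg$depth_mean <= 0) stop("depth_mean must be > 0")
  if (cfg$expression_dispersion < 0) stop("expression_dispersion must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

maybe_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
}

#' Simulate a multi-generation pedigree
#'
#' Founders have unknown parents; every non-founder draws a sire and a dam
#' (two distinct animals) from the previous generation, so parents always
#' precede offspring in the record order.
#'
#' @param config a [sim_config()]
#' @return data.frame (id, sire, dam, generation) of class \code{pedigree};
#'   parent fields are NA for founders
#' @export
simulate_pedigree <- function(config = sim_config()) {
  maybe_seed(config)
  n_desc <- config$n_animals - config$n_founders
  if (n_desc < 0) stop("n_animals must be >= n_founders")
  per_gen <- rep(n_desc %/% config$n_generations, config$n_generations)
  extra <- n_desc %% config$n_generations
  if (extra > 0) per_gen[seq_len(extra)] <- per_gen[seq_len(extra)] + 1L
  id <- seq_len(config$n_founders)
  gen <- rep(0L, config$n_founders)
  sire <- rep(NA_integer_, config$n_founders)
  dam <- rep(NA_integer_, config$n_founders)
  prev <- id
  for (g in seq_len(config$n_generations)) {
    for (k in seq_len(per_gen[g])) {
      parents <- sample(prev, 2L, replace = FALSE)
      id <- c(id, length(id) + 1L)
      sire <- c(sire, parents[1]); dam <- c(dam, parents[2])
      gen <- c(gen, g)
    }
    prev <- id[gen == g]
    if (length(prev) < 2) prev <- id[gen >= g - 1L]
  }
  structure(data.frame(id = id, sire = sire, dam = dam, generation = gen),
            class = c("pedigree", "data.frame"))
}

# Founder haplotypes from a Gaussian-copula AR(1) model: a latent standard
# normal follows an AR(1) along the chromosome with correlation
# exp(-ld_decay_rate * distance); thresholding at qnorm(freq) gives alleles
# with exactly the requested marginal frequencies and LD decaying with
# distance. Haplotypes are mutually independent, so founder genotypes are
# Hardy-Weinberg draws at each variant.
founder_haplotypes <- function(n_hap, config, positions, freqs) {
  m <- length(freqs)
  phi <- exp(-config$ld_decay_rate * diff(positions))
  z <- matrix(0, nrow = m, ncol = n_hap)
  z[1, ] <- stats::rnorm(n_hap)
  for (v in seq_len(m - 1L)) {
    z[v + 1L, ] <- phi[v] * z[v, ] +
      sqrt(1 - phi[v]^2) * stats::rnorm(n_hap)
  }
  out <- matrix(0L, nrow = m, ncol = n_hap)
  thr <- stats::qnorm(freqs)
  for (v in seq_len(m)) out[v, ] <- as.integer(z[v, ] < thr[v])
  out
}

#' Simulate genotypes by Mendelian gene drop
#'
#' Founder haplotypes are drawn from a Gaussian-copula AR(1) haplotype model
#' (Hardy-Weinberg at each variant, LD decaying with distance at rate
#' \code{ld_decay_rate}); descendants inherit one whole parental haplotype
#' from each parent (recombination-free transmission). With
#' \code{transmission = "independent"}, founder alleles and transmissions are
#' drawn independently per variant, destroying LD (for null testing).
#'
#' @param pedigree a pedigree from [simulate_pedigree()]
#' @param config a [sim_config()]
#' @return list with \code{dosage} (variants x animals matrix, entries
#'   0/1/2), \code{positions}, \code{chrom}, \code{freqs} (founder allele
#'   frequencies) and \code{haplotypes} (two variants x animals matrices)
#' @export
simulate_genotypes <- function(pedigree, config = sim_config()) {
  maybe_seed(config)
  n <- nrow(pedigree)
  m <- config$n_variants
  positions <- sort(sample.int(config$chrom_length, m))
  freqs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  hap1 <- matrix(0L, nrow = m, ncol = n)
  hap2 <- matrix(0L, nrow = m, ncol = n)
  founders <- which(is.na(pedigree$sire))
  if (config$transmission == "chromosome") {
    fh <- founder_haplotypes(2L * length(founders), config, positions, freqs)
    hap1[, founders] <- fh[, seq_along(founders), drop = FALSE]
    hap2[, founders] <- fh[, length(founders) + seq_along(founders), drop = FALSE]
    for (i in seq_len(n)) {
      if (i %in% founders) next
      s <- pedigree$sire[i]; d <- pedigree$dam[i]
      hap1[, i] <- if (stats::runif(1) < 0.5) hap1[, s] else hap2[, s]
      hap2[, i] <- if (stats::runif(1) < 0.5) hap1[, d] else hap2[, d]
    }
  } else {
    hap1[, founders] <- stats::rbinom(m * length(founders), 1L, freqs)
    hap2[, founders] <- stats::rbinom(m * length(founders), 1L, freqs)
    for (i in seq_len(n)) {
      if (i %in% founders) next
      s <- pedigree$sire[i]; d <- pedigree$dam[i]
      pick_s <- stats::runif(m) < 0.5
      pick_d <- stats::runif(m) < 0.5
      hap1[, i] <- ifelse(pick_s, hap1[, s], hap2[, s])
      hap2[, i] <- ifelse(pick_d, hap1[, d], hap2[, d])
    }
  }
  dosage <- hap1 + hap2
  colnames(dosage) <- paste0("animal", pedigree$id)
  list(dosage = dosage, positions = positions, chrom = "chrSim",
       freqs = freqs, haplotypes = list(hap1 = hap1, hap2 = hap2))
}

#' Simulate per-animal edit counts at synthetic edit sites
#'
#' Each edit site gets one designated causal variant; the latent logit
#' editing proportion of animal i is
#' \code{mu + beta * dosage_i + g_i + e_i} with \code{g ~ MVN(0, sigma2_g A)}
#' (A the pedigree numerator relationship matrix) and
#' \code{e ~ N(0, sigma2_e)}. Read totals are Poisson(depth_mean) and edited
#' read counts Binomial(total, plogis(latent)); animals with zero total reads
#' get missing counts.
#'
#' @param genotypes output of [simulate_genotypes()]
#' @param pedigree the pedigree the genotypes were dropped on
#' @param config a [sim_config()]
#' @param causal_variants optional integer vector of causal variant row
#'   indices, one per edit site (default: sampled)
#' @param beta optional per-site causal effects (default
#'   \code{causal_effect_logit} for every site)
#' @return list with matrices \code{edited}, \code{total}, \code{latent}
#'   (sites x animals) and a \code{truth} data.frame (site, causal variant
#'   index/position, beta)
#' @export
simulate_editing <- function(genotypes, pedigree, config = sim_config(),
                             causal_variants = NULL, beta = NULL) {
  maybe_seed(config)
  n <- nrow(pedigree)
  s <- config$n_edit_sites
  if (is.null(causal_variants))
    causal_variants <- sample.int(nrow(genotypes$dosage), s, replace = TRUE)
  if (is.null(beta)) beta <- rep(config$causal_effect_logit, s)
  stopifnot(length(causal_variants) == s, length(beta) == s)
  L <- NULL
  if (config$polygenic_variance > 0) {
    A <- a_matrix(pedigree)
    L <- tryCatch(chol(A), error = function(e)
      stop("relationship matrix is singular; cannot draw polygenic values"))
  }
  latent <- matrix(NA_real_, nrow = s, ncol = n)
  for (k in seq_len(s)) {
    g <- if (is.null(L)) rep(0, n)
         else sqrt(config$polygenic_variance) * drop(crossprod(L, stats::rnorm(n)))
    e <- stats::rnorm(n, 0, sqrt(config$residual_variance))
    latent[k, ] <- config$mu_logit +
      beta[k] * genotypes$dosage[causal_variants[k], ] + g + e
  }
  total <- matrix(stats::rpois(s * n, config$depth_mean), nrow = s)
  edited <- matrix(stats::rbinom(s * n, as.vector(total),
                                 stats::plogis(as.vector(latent))), nrow = s)
  edited[total == 0] <- NA_integer_
  total[total == 0] <- NA_integer_
  site_pos <- genotypes$positions[causal_variants] + 1L  # site adjacent to its causal variant
  rn <- site_key(genotypes$chrom, site_pos)
  dimnames(latent) <- dimnames(total) <- dimnames(edited) <-
    list(rn, colnames(genotypes$dosage))
  list(edited = edited, total = total, latent = latent,
       truth = data.frame(site = rn, chrom = genotypes$chrom,
                          site_pos = site_pos,
                          causal_index = causal_variants,
                          causal_pos = genotypes$positions[causal_variants],
                          beta = beta))
}

#' Simulate a pre-mRNA sequence with a planted inverted repeat
#'
#' A random background sequence carries one stem-loop: an arm of
#' \code{stem_length} nt whose reverse complement is placed
#' \code{loop_length} nt downstream. Edit positions are adenosines inside the
#' forward arm. The truth table of paired positions supports oracle tests of
#' the dot-plot scan.
#'
#' @param config a [sim_config()]
#' @return list with \code{seq} (character), \code{arm1}, \code{arm2}
#'   (1-based inclusive intervals), \code{pairing} (data.frame i, j of true
#'   paired positions), and \code{edit_positions}
#' @export
simulate_premrna <- function(config = sim_config()) {
  maybe_seed(config)
  if (config$stem_length < 40) stop("stem_length must be >= 40")
  if (config$loop_length < 10) stop("loop_length must be >= 10")
  L <- config$premrna_length
  sl <- config$stem_length
  bg <- sample(DNA_BASES, L, replace = TRUE)
  arm <- sample(DNA_BASES, sl, replace = TRUE)
  # guarantee adenosines for edit sites in the arm interior
  a_slots <- sample(seq(8, sl - 8), max(config$n_stem_edits, 1L))
  arm[a_slots] <- "A"
  s1 <- max(1L, (L - (2L * sl + config$loop_length)) %/% 3L)
  s2 <- s1 + sl + config$loop_length
  if (s2 + sl - 1L > L) stop("premrna_length too short for the planted stem")
  bg[s1:(s1 + sl - 1L)] <- arm
  bg[s2:(s2 + sl - 1L)] <- strsplit(revcomp(paste(arm, collapse = "")), "")[[1]]
  k <- seq_len(sl) - 1L
  pairing <- data.frame(i = s1 + k, j = s2 + sl - 1L - k)
  edits <- s1 + sort(a_slots) - 1L
  edits <- edits[seq_len(min(config$n_stem_edits, length(edits)))]
  list(seq = paste(bg, collapse = ""),
       arm1 = c(s1, s1 + sl - 1L), arm2 = c(s2, s2 + sl - 1L),
       pairing = pairing, edit_positions = edits)
}

# Plackett solution: joint P(row1, col2) for given odds ratio and margins.
plackett_p11 <- function(theta, r, c) {
  if (!is.finite(theta)) return(min(r, c))
  if (theta == 1) return(r * c)
  if (theta <= 0) stop("odds ratio must be > 0")
  s <- 1 + (r + c) * (theta - 1)
  (s - sqrt(s^2 - 4 * theta * (theta - 1) * r * c)) / (2 * (theta - 1))
}

#' Simulate a read-pair phase table
#'
#' Counts of read pairs classified by edit status (edited/unedited) and
#' variant allele (ref/alt), drawn from a multinomial whose cell
#' probabilities have the requested odds ratio (edited-with-alt versus the
#' rest) at the requested margins.
#'
#' @param phase_odds_ratio target odds ratio (1 = independence, Inf = perfect
#'   phase: the edited state occurs only with the alt allele)
#' @param n_reads number of read pairs
#' @param margin_probs \code{c(p_edited, p_alt)} marginal probabilities
#' @return 2x2 integer matrix (rows edited/unedited, columns ref/alt) with
#'   attribute \code{usable} (FALSE when n_reads is 0)
#' @export
simulate_read_pairs <- function(phase_odds_ratio, n_reads,
                                margin_probs = c(0.3, 0.5)) {
  r <- margin_probs[1]; c <- margin_probs[2]
  p_ea <- plackett_p11(phase_odds_ratio, r, c)
  p <- c(edited_ref = r - p_ea, edited_alt = p_ea,
         unedited_ref = 1 - r - c + p_ea, unedited_alt = c - p_ea)
  p <- pmax(p, 0); p <- p / sum(p)
  counts <- if (n_reads > 0) drop(stats::rmultinom(1, n_reads, p)) else rep(0L, 4)
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(c("edited", "unedited"), c("ref", "alt")))
  attr(tab, "usable") <- n_reads > 0
  tab
}

#' Simulate negative-binomial expression counts coupled to editing
#'
#' Per gene g and animal i, counts are NB with mean
#' \code{exp(a_g + slope * latent_gi)} and dispersion alpha; the intercept
#' a_g is chosen so the gene's mean count equals \code{expression_mean}.
#' With alpha = 0 the Poisson limit is used.
#'
#' @param phi_logit matrix of latent logit editing values (genes/sites x
#'   animals)
#' @param config a [sim_config()]
#' @return integer count matrix of the same shape
#' @export
simulate_expression <- function(phi_logit, config = sim_config()) {
  maybe_seed(config)
  phi_logit <- rbind(phi_logit)
  slope <- config$phi_expression_slope
  a <- log(config$expression_mean) - slope * rowMeans(phi_logit, na.rm = TRUE)
  mu <- exp(a + slope * phi_logit)
  mu[is.na(mu)] <- config$expression_mean
  n <- length(mu)
  counts <- if (config$expression_dispersion > 0) {
    stats::rnbinom(n, mu = as.vector(mu), size = 1 / config$expression_dispersion)
  } else {
    stats::rpois(n, as.vector(mu))
  }
  matrix(counts, nrow = nrow(phi_logit), dimnames = dimnames(phi_logit))
}
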