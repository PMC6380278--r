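test_that("simulated pedigrees are topologically ordered", {
  cfg <- sim_config(n_founders = 2, n_generations = 1, n_animals = 3, seed = 1)
  trio <- simulate_pedigree(cfg)
  expect_equal(nrow(trio), 3L)
  expect_true(all(is.na(trio$sire[1:2])))
  expect_setequal(c(trio$sire[3], trio$dam[3]), c(1, 2))

  cfg <- sim_config(n_founders = 10, n_generations = 3, n_animals = 60, seed = 2)
  ped <- simulate_pedigree(cfg)
  nonf <- which(!is.na(ped$sire))
  expect_true(all(ped$sire[nonf] < ped$id[nonf]))
  expect_true(all(ped$dam[nonf] < ped$id[nonf]))
  expect_true(all(ped$sire[nonf] != ped$dam[nonf]))
  # same seed, same pedigree
  expect_identical(ped, simulate_pedigree(cfg))
})

test_that("gene drop obeys Mendelian transmission at fixed parents", {
  ped <- make_pedigree(1:3, c(NA, NA, 1L), c(NA, NA, 2L))
  cfg <- sim_config(n_variants = 50, seed = 3)
  g <- simulate_genotypes(ped, cfg)
  # force parental haplotypes and re-drop by hand through the public surface:
  # homozygous parents determine the offspring deterministically
  for (rep in 1:5) {
    g <- simulate_genotypes(ped, sim_config(n_variants = 50, seed = rep))
    hom00 <- g$dosage[, 1] == 0 & g$dosage[, 2] == 0
    hom22 <- g$dosage[, 1] == 2 & g$dosage[, 2] == 2
    expect_true(all(g$dosage[hom00, 3] == 0))
    expect_true(all(g$dosage[hom22, 3] == 2))
  }
})

test_that("founder allele frequencies are Hardy-Weinberg draws", {
  cfg <- sim_config(n_founders = 2000, n_generations = 1, n_animals = 2001,
                    n_variants = 30, maf_range = c(0.3, 0.3), seed = 4)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  founders <- which(is.na(ped$sire))
  freq <- rowMeans(g$dosage[, founders]) / 2
  se <- sqrt(0.3 * 0.7 / (2 * length(founders)))
  expect_true(all(abs(freq - 0.3) < 3 * se + 1e-9))
  # genotype frequencies consistent with HW at the pooled level
  het <- mean(g$dosage[, founders] == 1)
  expect_lt(abs(het - 2 * 0.3 * 0.7), 0.01)
})

test_that("genotypes carry LD that decays with distance", {
  cohort <- make_cohort(seed = 11, n_variants = 300)
  d <- cohort$geno$dosage
  pos <- cohort$geno$positions
  adj <- vapply(1:100, function(k) cor(d[k, ], d[k + 1, ])^2, numeric(1))
  far_pairs <- which(abs(outer(pos, pos, "-")) > 3e6, arr.ind = TRUE)
  far_pairs <- far_pairs[far_pairs[, 1] < far_pairs[, 2], , drop = FALSE][1:100, ]
  far <- vapply(seq_len(nrow(far_pairs)), function(k)
    cor(d[far_pairs[k, 1], ], d[far_pairs[k, 2], ])^2, numeric(1))
  expect_gt(mean(adj, na.rm = TRUE), 0.3)
  expect_lt(mean(far, na.rm = TRUE), 0.1)
})

test_that("editing counts follow the latent dosage model", {
  cohort <- make_cohort(seed = 21, n_variants = 100)
  cfg <- sim_config(n_edit_sites = 3, causal_effect_logit = 2,
                    polygenic_variance = 0, residual_variance = 0,
                    depth_mean = 200)
  set.seed(22)
  ed <- simulate_editing(cohort$geno, cohort$ped, cfg)
  phi <- ed$edited / ed$total
  # mean Phi strictly ordered by dosage group for a large effect
  for (k in 1:3) {
    dos <- cohort$geno$dosage[ed$truth$causal_index[k], ]
    if (length(unique(dos)) < 3) next
    m <- tapply(phi[k, ], dos, mean, na.rm = TRUE)
    expect_true(all(diff(m[as.character(0:2)]) > 0))
  }
  # zero-variance null: every animal shares the baseline proportion
  cfg0 <- sim_config(n_edit_sites = 2, causal_effect_logit = 0,
                     polygenic_variance = 0, residual_variance = 0,
                     depth_mean = 500)
  set.seed(23)
  ed0 <- simulate_editing(cohort$geno, cohort$ped, cfg0)
  expect_equal(unique(as.vector(ed0$latent)), cfg0$mu_logit)
  expect_lt(abs(mean(ed0$edited / ed0$total, na.rm = TRUE) -
                  plogis(cfg0$mu_logit)), 0.01)
})

test_that("animals with zero read depth get missing counts", {
  cohort <- make_cohort(seed = 31, n_founders = 10, n_animals = 40,
                        n_variants = 20)
  cfg <- sim_config(n_edit_sites = 2, depth_mean = 0.2)
  set.seed(32)
  ed <- simulate_editing(cohort$geno, cohort$ped, cfg)
  expect_true(anyNA(ed$total))
  expect_identical(is.na(ed$total), is.na(ed$edited))
})

test_that("polygenic values match the pedigree covariance across replicates", {
  ped <- make_pedigree(1:4, c(NA, NA, 1L, 1L), c(NA, NA, 2L, 2L))
  cfg <- sim_config(n_variants = 10, n_edit_sites = 200,
                    causal_effect_logit = 0, polygenic_variance = 1,
                    residual_variance = 0, depth_mean = 10)
  set.seed(33)
  g <- simulate_genotypes(ped, sim_config(n_variants = 10))
  ed <- simulate_editing(g, ped, cfg)
  centered <- ed$latent - cfg$mu_logit
  emp <- crossprod(centered) / nrow(centered)
  A <- a_matrix(ped)
  # 200 replicate draws: element-wise agreement within ~4 SE (~4/sqrt(200))
  expect_lt(max(abs(emp - A)), 0.35)
  # full sibs of unrelated parents correlate ~0.5
  expect_gt(emp[3, 4], 0.2)
})

test_that("planted pre-mRNA inverted repeats are self-consistent", {
  cfg <- sim_config(seed = 41)
  pre <- simulate_premrna(cfg)
  arm1 <- substr(pre$seq, pre$arm1[1], pre$arm1[2])
  arm2 <- substr(pre$seq, pre$arm2[1], pre$arm2[2])
  expect_equal(arm2, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(arm1))))
  # truth pairing positions are complementary bases
  b <- strsplit(pre$seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_true(all(comp[b[pre$pairing$i]] == b[pre$pairing$j]))
  # edit positions are adenosines inside the forward arm
  expect_true(all(b[pre$edit_positions] == "A"))
  expect_true(all(pre$edit_positions >= pre$arm1[1] &
                    pre$edit_positions <= pre$arm1[2]))
})

test_that("dot-plot scan recovers planted helices but not random sequence", {
  cfg <- sim_config(seed = 42)
  pre <- simulate_premrna(cfg)
  helices <- extract_helices(dotplot_scan(pre$seq))
  expect_gte(length(helices), 1L)
  found <- do.call(rbind, lapply(helices, function(h) h$pairing))
  truth_key <- paste(pre$pairing$i, pre$pairing$j)
  recovery <- mean(truth_key %in% paste(found$i, found$j))
  expect_gte(recovery, 0.9)
  # random sequence of the same length: no helix at the default threshold
  set.seed(43)
  rnd <- random_dna(cfg$premrna_length)
  expect_length(extract_helices(dotplot_scan(rnd)), 0L)
})

test_that("read-pair tables have the requested phase structure", {
  # perfect phase at equal margins: anti-diagonal cells empty
  set.seed(51)
  tab <- simulate_read_pairs(Inf, 500, margin_probs = c(0.5, 0.5))
  expect_equal(tab["edited", "ref"], 0)
  expect_equal(tab["unedited", "alt"], 0)
  expect_equal(sum(tab), 500)
  # no reads: flagged unusable
  tab0 <- simulate_read_pairs(2, 0)
  expect_false(attr(tab0, "usable"))
  expect_equal(sum(tab0), 0)
  # independence: chi-square p-values uniform over replicates
  set.seed(52)
  ps <- replicate(400, {
    t1 <- simulate_read_pairs(1, 10000)
    suppressWarnings(stats::chisq.test(t1, correct = FALSE)$p.value)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # a strong odds ratio is recovered from the empirical table
  set.seed(53)
  t4 <- simulate_read_pairs(4, 2e5) * 1.0
  or_hat <- (t4[1, 2] * t4[2, 1]) / (t4[1, 1] * t4[2, 2])
  expect_lt(abs(or_hat - 4), 0.4)
})

test_that("expression counts track the latent editing signal", {
  cohort <- make_cohort(seed = 61, n_variants = 50)
  cfg <- sim_config(n_edit_sites = 1, phi_expression_slope = 0)
  set.seed(62)
  ed <- simulate_editing(cohort$geno, cohort$ped, cfg)
  expr0 <- simulate_expression(ed$latent, cfg)
  r0 <- cor(ed$latent[1, ], vst(expr0)$vst[1, ])
  expect_lt(abs(r0), 0.15)
  # negative slope: negative correlation with high power at n = 355
  cfg_neg <- sim_config(n_edit_sites = 1, phi_expression_slope = -0.3)
  hits <- 0
  set.seed(63)
  for (rep in 1:20) {
    ed1 <- simulate_editing(cohort$geno, cohort$ped, cfg_neg)
    expr1 <- simulate_expression(ed1$latent, cfg_neg)
    ct <- cor.test(ed1$latent[1, ], vst(expr1)$vst[1, ])
    hits <- hits + (ct$estimate < 0 && ct$p.value < 0.05)
  }
  expect_gte(hits / 20, 0.9)
  # dispersion -> 0 limit: Poisson-like variance at constant mean
  cfg_p <- sim_config(expression_dispersion = 0, phi_expression_slope = 0,
                      expression_mean = 100)
  set.seed(64)
  expr_p <- simulate_expression(matrix(0, 1, 5000), cfg_p)
  expect_lt(abs(var(as.vector(expr_p)) / mean(expr_p) - 1), 0.1)
})

test_that("fixed seeds give identical synthetic cohorts", {
  a <- make_cohort(seed = 71, n_founders = 10, n_animals = 30, n_variants = 40)
  b <- make_cohort(seed = 71, n_founders = 10, n_animals = 30, n_variants = 40)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$geno$positions, b$geno$positions)
})
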