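# The synthetic-data generator and the power / type-I error evaluator.

test_that("ld_rho = 0 gives uncorrelated adjacent dosages", {
  sc <- sim_scenario(n_samples = 5000, n_windows = 1, variants_per_window = 10,
                     rare_fraction = 0, ld_rho = 0, seed = 61)
  sim <- simulate_genotypes(sc)
  D <- sim$genotypes$dosages
  r <- vapply(1:9, function(j) cor(D[, j], D[, j + 1]), numeric(1))
  expect_true(all(abs(r) < 0.05))
})

test_that("positive ld_rho induces positive adjacent-dosage correlation", {
  sc <- sim_scenario(n_samples = 3000, n_windows = 1, variants_per_window = 10,
                     rare_fraction = 0, ld_rho = 0.8, seed = 62)
  D <- simulate_genotypes(sc)$genotypes$dosages
  r <- vapply(1:9, function(j) cor(D[, j], D[, j + 1]), numeric(1))
  expect_true(all(r > 0.2))
})

test_that("realised MAF tracks the target within binomial error", {
  sc <- sim_scenario(n_samples = 5000, n_windows = 2, variants_per_window = 20,
                     rare_fraction = 0.5, seed = 63)
  sim <- simulate_genotypes(sc)
  maf <- sim$genotypes$variants$maf
  target <- sim$maf_target
  se <- sqrt(target * (1 - target) / (2 * 5000))  # 2n alleles drawn per variant
  expect_true(all(abs(maf - target) <= 3.5 * se))
  expect_true(all(maf <= 0.5 & maf >= 0))
})

test_that("an all-rare spectrum stays below the rare threshold band", {
  sc <- sim_scenario(n_samples = 5000, n_windows = 1, variants_per_window = 25,
                     rare_fraction = 1, seed = 64)
  maf <- simulate_genotypes(sc)$genotypes$variants$maf
  expect_true(all(maf < 0.05 + 3 * sqrt(0.05 * 0.95 / 10000)))
})

test_that("each simulated window maps to exactly one genomic window", {
  sc <- sim_scenario(n_samples = 30, n_windows = 7, variants_per_window = 9,
                     window_width = 5000, seed = 65)
  sim <- simulate_genotypes(sc)
  idx <- goftscan:::.window_index(sim$genotypes$variants$pos, 5000)
  expect_identical(sort(unique(idx)), 1:7)
  expect_identical(as.vector(table(idx)), rep(9L, 7))
  # positions strictly increasing
  expect_true(all(diff(sim$genotypes$variants$pos) > 0))
})

test_that("effect_size = 0 decouples phenotype from genotype", {
  sc <- sim_scenario(n_samples = 2000, n_windows = 2, variants_per_window = 10,
                     true_window_fraction = 1, effect_size = 0, seed = 66)
  sim <- simulate_genotypes(sc)
  ph <- simulate_phenotype(sim$genotypes, sim$causal, sc)
  burden <- rowSums(sim$genotypes$dosages[, sim$causal$variant, drop = FALSE])
  expect_gt(cor.test(ph$values, burden)$p.value, 1e-4)
})

test_that("a noiseless causal common variant is detected with certainty", {
  sc <- sim_scenario(n_samples = 500, n_windows = 1, variants_per_window = 10,
                     rare_fraction = 0, true_window_fraction = 1,
                     causal_per_true_window = 0, causal_common_per_window = 1,
                     common_effect_size = 0.5, trait_noise_sd = 0, seed = 67)
  sim <- simulate_genotypes(sc)
  ph <- simulate_phenotype(sim$genotypes, sim$causal, sc)
  v <- sim$causal$variant[1]
  out <- variant_pvalue(sim$genotypes$dosages[, v], ph)
  expect_lt(out$p, 1e-10)
})

test_that("realised variance explained matches the analytic decomposition", {
  sc <- sim_scenario(n_samples = 10000, n_windows = 1, variants_per_window = 5,
                     rare_fraction = 0, ld_rho = 0, true_window_fraction = 1,
                     causal_per_true_window = 0, causal_common_per_window = 1,
                     common_effect_size = 0.3, trait_noise_sd = 1, seed = 68)
  sim <- simulate_genotypes(sc)
  ph <- simulate_phenotype(sim$genotypes, sim$causal, sc)
  g <- sim$genotypes$dosages[, sim$causal$variant[1]]
  maf <- compute_maf(g)
  h2_analytic <- (0.3^2 * 2 * maf * (1 - maf)) /
    (0.3^2 * 2 * maf * (1 - maf) + 1)
  h2_realised <- summary(lm(ph$values ~ g))$r.squared
  expect_lt(abs(h2_realised - h2_analytic) / h2_analytic, 0.10)
})

test_that("replicates share the genetic component but not the noise", {
  sc <- sim_scenario(n_samples = 200, n_windows = 2, variants_per_window = 10,
                     true_window_fraction = 1, effect_size = 0.5, seed = 69)
  sim <- simulate_genotypes(sc)
  p1 <- simulate_phenotype(sim$genotypes, sim$causal, sc, replicate = 1)
  p1b <- simulate_phenotype(sim$genotypes, sim$causal, sc, replicate = 1)
  p2 <- simulate_phenotype(sim$genotypes, sim$causal, sc, replicate = 2)
  expect_identical(p1$values, p1b$values)
  expect_false(identical(p1$values, p2$values))
})

test_that("tpr and fpr are direct counts over the cutoff grid", {
  # constructed results: 10 of 100 false windows below 0.05
  p_false <- c(rep(0.01, 10), runif(90, 0.2, 1))
  p_true <- c(0.001, 0.04, 0.2, 0.6)
  ev <- evaluate_scan(c(p_true, p_false),
                      c(rep(TRUE, 4), rep(FALSE, 100)),
                      cutoffs = c(1, 0.05))
  expect_identical(ev$fpr[ev$cutoff == 0.05], 0.10)
  expect_identical(ev$tpr[ev$cutoff == 0.05], 0.5)
  expect_identical(ev$fpr[ev$cutoff == 1], 1)
  expect_identical(ev$tpr[ev$cutoff == 1], 1)

  # all p = 1 detects nothing below 1
  ev1 <- evaluate_scan(rep(1, 10), rep(c(TRUE, FALSE), 5), cutoffs = c(0.05))
  expect_identical(ev1$tpr, 0)
  expect_identical(ev1$fpr, 0)

  # no true windows: tpr undefined
  ev2 <- evaluate_scan(runif(10), rep(FALSE, 10))
  expect_true(all(is.na(ev2$tpr)))
  expect_true(all(!is.na(ev2$fpr)))
  # monotone in the cutoff
  expect_true(all(diff(ev2$fpr) <= 0))
})

test_that("windows much wider than the causal span lose power at strict cutoffs", {
  # 10 of 100 narrow windows carry a causal rare block; 100-kbp windows
  # cover the same span with ten-fold more noise variants, diluting the
  # signal at a strict cutoff
  sc <- sim_scenario(n_samples = 400, n_windows = 100, variants_per_window = 15,
                     rare_fraction = 0.8, true_window_fraction = 0.1,
                     causal_per_true_window = 8, effect_size = 0.45,
                     n_replicates = 3, seed = 70)
  sim <- simulate_genotypes(sc)
  p_narrow <- c(); p_wide <- c(); t_narrow <- c(); t_wide <- c()
  wide_truth <- tapply(sim$truth$is_true,
                       (seq_len(100) - 1) %/% 10, any)
  for (r in seq_len(sc$n_replicates)) {
    ph <- simulate_phenotype(sim$genotypes, sim$causal, sc, replicate = r)
    rn <- goft_scan(sim$genotypes, ph, window_width = 10000,
                    n_permutations = 200, seed = 100 + r)
    rw <- goft_scan(sim$genotypes, ph, window_width = 100000,
                    n_permutations = 200, seed = 100 + r)
    ord_n <- match(sim$truth$window_id, rn$window_id)
    p_narrow <- c(p_narrow, rn$p_empirical[ord_n])
    t_narrow <- c(t_narrow, sim$truth$is_true)
    p_wide <- c(p_wide, rw$p_empirical)
    t_wide <- c(t_wide, as.vector(wide_truth)[match(rw$start / 100000 + 1,
                                                    seq_along(wide_truth))])
  }
  alpha <- 0.005
  pow_narrow <- mean(p_narrow[t_narrow] <= alpha, na.rm = TRUE)
  pow_wide <- mean(p_wide[t_wide] <= alpha, na.rm = TRUE)
  expect_gt(pow_narrow, pow_wide)
})
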