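# Merging an external p-value source into window p-value sets.

# build a minimal tested p-value set for the merge surface
mk_pset <- function(values, keys, id) {
  structure(list(values = sort(values), L = length(values), window_id = id,
                 n_common = length(values), n_burden = 0L, status = "tested",
                 variant_keys = keys),
            class = "pvalue_set")
}

test_that("in-window external records grow L; duplicates and strays do not", {
  win <- make_windows("3", max_pos = 30000, width = 10000)
  psets <- list(
    "3:0-10000" = mk_pset(runif(60), paste0("3:", seq(100, 6000, by = 100)), "3:0-10000"),
    "3:10000-20000" = mk_pset(runif(5), paste0("3:", 10100 + 1:5), "3:10000-20000")
  )
  names(psets) <- win$window_id[1:2]

  ext <- data.frame(
    chrom = "3",
    pos = c(7001L, 7501L, 9999L,  # three new sites in window 1
            100L,                 # duplicates an internal variant
            25000L,               # falls in a window with no p-value set
            10200L),              # new site in window 2
    id = paste0("rs", 1:6),
    p = c(0.2, 0.4, 0.6, 0.1, 0.5, 0.3)
  )
  merged <- merge_sources(psets, ext, win)
  expect_identical(merged[[1]]$L, 63L)
  expect_identical(merged[[2]]$L, 6L)
  expect_false(is.unsorted(merged[[1]]$values))
  info <- attr(merged, "merge")
  expect_identical(info$added, 4L)
  expect_identical(info$duplicates, 1L)
  expect_identical(info$outside, 1L)
})

test_that("an empty external table is a no-op", {
  win <- make_windows("3", 10000, 10000)
  psets <- list(mk_pset(c(0.1, 0.9), c("3:100", "3:200"), win$window_id))
  names(psets) <- win$window_id
  ext0 <- data.frame(chrom = character(0), pos = integer(0),
                     id = character(0), p = numeric(0))
  merged <- merge_sources(psets, ext0, win)
  expect_identical(merged[[1]]$values, psets[[1]]$values)
})

test_that("merging the same table twice is idempotent", {
  win <- make_windows("3", 10000, 10000)
  psets <- list(mk_pset(c(0.1, 0.9), c("3:100", "3:200"), win$window_id))
  names(psets) <- win$window_id
  ext <- data.frame(chrom = "3", pos = c(300L, 400L), id = c("a", "b"),
                    p = c(0.5, 0.6))
  once <- merge_sources(psets, ext, win)
  twice <- merge_sources(once, ext, win)
  expect_identical(once[[1]]$values, twice[[1]]$values)
  expect_identical(attr(twice, "merge")$duplicates, 2L)
  expect_identical(attr(twice, "merge")$added, 0L)
})

test_that("invalid external p-values are rejected", {
  win <- make_windows("3", 10000, 10000)
  psets <- list(mk_pset(0.5, "3:100", win$window_id))
  names(psets) <- win$window_id
  bad <- data.frame(chrom = "3", pos = 200L, id = "x", p = 0)
  expect_error(merge_sources(psets, bad, win), "\\(0, 1\\]")
})

test_that("the scan merges external p-values with the same dedup rule", {
  set.seed(51)
  n <- 80
  d <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  gm <- toy_gm(d, pos = seq(500, 9500, length.out = 10), chrom = "7")
  ph <- toy_phen(gm, rnorm(n))
  ext <- data.frame(
    chrom = "7",
    pos = c(1234L, 500L, 99999L),  # new site, duplicate site, out of range
    id = c("rs1", "rs2", "rs3"),
    p = c(0.01, 0.02, 0.03)
  )
  res <- goft_scan(gm, ph, window_width = 10000, n_permutations = 30,
                   seed = 4, external = ext)
  expect_identical(res$n_external, 1L)
  expect_identical(res$L, 11L)
  mi <- attr(res, "external_merge")
  expect_identical(mi$duplicates, 1L)
  expect_identical(mi$outside, 1L)
  # the external null is declared as uniform resampling in the metadata
  expect_identical(attr(res, "params")$external_null, "uniform_resampling")
  # determinism with external resampling included
  res2 <- goft_scan(gm, ph, window_width = 10000, n_permutations = 30,
                    seed = 4, external = ext)
  expect_identical(res$p_empirical, res2$p_empirical)
})

test_that("merging a null-uniform external source keeps the scan calibrated", {
  sc <- sim_scenario(n_samples = 150, n_windows = 150, variants_per_window = 12,
                     true_window_fraction = 0, seed = 52)
  sim <- simulate_genotypes(sc)
  ph <- simulate_phenotype(sim$genotypes, sim$causal, sc)
  # three uniform external p-values per window, at positions the dose
  # matrix does not carry
  set.seed(53)
  w <- rep(seq_len(150) - 1, each = 3)
  ext <- data.frame(chrom = "3",
                    pos = as.integer(w * 10000 + c(11, 13, 17)),
                    id = paste0("e", seq_along(w)),
                    p = runif(length(w)))
  res <- goft_scan(sim$genotypes, ph, n_permutations = 150, seed = 54,
                   external = ext)
  p <- res$p_empirical[res$status == "tested"]
  hits <- sum(p <= 0.05)
  expect_gte(hits, qbinom(0.025, length(p), 0.05))
  expect_lte(hits, qbinom(0.975, length(p), 0.05))
})
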