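# Independent oracles and tiny fixture builders shared across tests.

# Term-by-term evaluation of the Berk-Jones statistic, written directly
# from the piecewise divergence definition. Deliberately naive (scalar
# loop, literal branches) and independent of the package's kernel.
naive_goft_G <- function(p) {
  p <- sort(p)
  L <- length(p)
  best <- 0
  for (j in seq_len(L)) {
    t <- j / L
    x <- p[j]
    k <- if (t <= x) {
      0
    } else if (x == 0) {
      Inf
    } else if (t < 1) {
      t * log(t / x) + (1 - t) * log((1 - t) / (1 - x))
    } else {
      -log(x)  # t = 1 limit
    }
    best <- max(best, 2 * k)
  }
  L * best
}

# Small genotype matrix from an explicit dosage matrix.
toy_gm <- function(dosages, pos = NULL, chrom = "1") {
  dosages <- as.matrix(dosages)
  if (is.null(pos)) pos <- seq_len(ncol(dosages)) * 100L
  genotype_matrix(
    dosages,
    data.frame(chrom = chrom, pos = pos,
               id = paste0("v", seq_len(ncol(dosages))),
               stringsAsFactors = FALSE)
  )
}

# Quantitative phenotype aligned to a genotype matrix.
toy_phen <- function(gm, values) {
  phenotype_vector(gm$sample_ids, values, "quantitative")
}
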