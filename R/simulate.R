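# Synthetic genotype/phenotype generation and power / type-I error
# evaluation. The generator targets the statistical regime the scan is
# designed for — a mixed rare/common allele-frequency spectrum, local
# linkage disequilibrium, and sparse, weak, same-direction rare effects
# on a Gaussian trait — rather than any particular cohort.

#' Parameterise a simulation scenario
#'
#' @param n_samples Number of unrelated individuals (default 142, a
#'   small sequencing-study cohort).
#' @param n_windows Number of genomic windows simulated.
#' @param variants_per_window Variants per window.
#' @param window_width Window width in base pairs; simulated positions
#'   are laid out so each simulated window maps to exactly one genomic
#'   window.
#' @param rare_fraction Fraction of variants drawn from the rare part
#'   of the MAF spectrum.
#' @param rare_maf_range MAF range for rare variants (default
#'   \code{c(0.001, 0.05)}, upper bound exclusive).
#' @param common_maf_range MAF range for common variants (default
#'   \code{c(0.05, 0.5)}).
#' @param ld_rho AR(1) autocorrelation of the latent Gaussian that
#'   generates haplotypes, in \eqn{[0, 1)}; controls local LD.
#' @param true_window_fraction Fraction of windows carrying causal
#'   variants.
#' @param causal_per_true_window Number of causal rare variants per true
#'   window (chosen as a contiguous block of rare variants, emulating a
#'   causal functional element).
#' @param effect_size Per-allele effect of each causal rare variant; all
#'   rare effects share one (positive) sign.
#' @param causal_common_per_window Number of additional causal common
#'   variants per true window (default 0).
#' @param common_effect_size Per-allele effect of causal common
#'   variants.
#' @param trait_noise_sd Standard deviation of the Gaussian trait noise.
#' @param n_replicates Number of phenotype replicates.
#' @param seed Base seed.
#' @param chrom Chromosome label for the simulated variants.
#' @return An object of class \code{"sim_scenario"} (a validated list).
#' @export
sim_scenario <- function(n_samples = 142,
                         n_windows = 100,
                         variants_per_window = 30,
                         window_width = 10000,
                         rare_fraction = 0.7,
                         rare_maf_range = c(0.001, 0.05),
                         common_maf_range = c(0.05, 0.5),
                         ld_rho = 0.5,
                         true_window_fraction = 0,
                         causal_per_true_window = 8,
                         effect_size = 0.25,
                         causal_common_per_window = 0,
                         common_effect_size = 0,
                         trait_noise_sd = 1,
                         n_replicates = 1,
                         seed = 1,
                         chrom = "3") {
  stopifnot(n_samples >= 2, n_windows >= 1, variants_per_window >= 1,
            rare_fraction >= 0, rare_fraction <= 1,
            ld_rho >= 0, ld_rho < 1,
            true_window_fraction >= 0, true_window_fraction <= 1,
            trait_noise_sd >= 0, n_replicates >= 1)
  structure(as.list(environment()), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "sim_scenario: n = %d, %d windows x %d variants (%.0f%% rare), ld_rho = %.2f, %d true window(s)\n",
    x$n_samples, x$n_windows, x$variants_per_window, 100 * x$rare_fraction,
    x$ld_rho, round(x$true_window_fraction * x$n_windows)
  ))
  invisible(x)
}

# AR(1) latent Gaussian matrix, n x k, unit marginals.
.ar1_latent <- function(n, k, rho) {
  Z <- matrix(stats::rnorm(n * k), n, k)
  if (rho > 0 && k > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:k) Z[, j] <- rho * Z[, j - 1] + s * Z[, j]
  }
  Z
}

#' Simulate genotype dosages with local LD
#'
#' Per window, variant MAFs are drawn from the scenario's mixed
#' rare/common spectrum and two haplotypes per individual are generated
#' by thresholding a latent Gaussian with AR(1) correlation
#' \code{ld_rho}: allele \eqn{= 1\{Z < \Phi^{-1}(\mathrm{MAF})\}}.
#' Dosage is the haplotype sum, so realised per-variant allele
#' frequencies are binomial around the target MAF and adjacent variants
#' are positively correlated. Positions are evenly spaced so each
#' simulated window occupies exactly one genomic window.
#'
#' Causal variants (the simulation truth) are chosen here:
#' \code{causal_per_true_window} rare variants per true window, as a
#' contiguous block of rare variants (a stand-in for a causal functional
#' element, and the structure burden collapsing assumes), each with
#' effect \code{+effect_size}; optionally
#' \code{causal_common_per_window} common variants with effect
#' \code{common_effect_size}.
#'
#' @param scenario A [sim_scenario()].
#' @return A list: \code{genotypes} (a [genotype_matrix()]),
#'   \code{truth} (data.frame per window: \code{window_id},
#'   \code{is_true}), \code{causal} (data.frame: variant column index,
#'   \code{beta}) and \code{maf_target} (the per-variant MAF each
#'   column was drawn at).
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  .with_seed(.mix_seed(scenario$seed, 0L), {
    n <- scenario$n_samples
    W <- scenario$n_windows
    k <- scenario$variants_per_window
    width <- scenario$window_width

    n_rare <- round(scenario$rare_fraction * k)
    dos <- matrix(0, n, W * k)
    maf_target <- numeric(W * k)
    is_rare <- logical(W * k)
    pos <- integer(W * k)
    for (w in seq_len(W)) {
      idx <- (w - 1L) * k + seq_len(k)
      rare_slots <- sort(sample.int(k, n_rare))
      common_slots <- setdiff(seq_len(k), rare_slots)
      m <- numeric(k)
      m[rare_slots] <- stats::runif(n_rare, scenario$rare_maf_range[1],
                                    scenario$rare_maf_range[2])
      m[common_slots] <- stats::runif(length(common_slots),
                                      scenario$common_maf_range[1],
                                      scenario$common_maf_range[2])
      thr <- stats::qnorm(m)
      h1 <- .ar1_latent(n, k, scenario$ld_rho)
      h2 <- .ar1_latent(n, k, scenario$ld_rho)
      dos[, idx] <- (sweep(h1, 2, thr, "<") + sweep(h2, 2, thr, "<"))
      maf_target[idx] <- m
      is_rare[idx] <- seq_len(k) %in% rare_slots
      pos[idx] <- (w - 1L) * width + round(seq(0.05, 0.95, length.out = k) * width)
    }

    variants <- data.frame(
      chrom = scenario$chrom,
      pos = pos,
      id = sprintf("sv%06d", seq_len(W * k)),
      stringsAsFactors = FALSE
    )
    gm <- genotype_matrix(dos, variants)

    n_true <- round(scenario$true_window_fraction * W)
    true_w <- sort(sample.int(W, n_true))
    causal <- data.frame(variant = integer(0), beta = numeric(0))
    for (w in true_w) {
      idx <- (w - 1L) * k + seq_len(k)
      rare_idx <- idx[is_rare[idx]]
      nc <- min(scenario$causal_per_true_window, length(rare_idx))
      if (nc > 0) {
        start <- sample.int(length(rare_idx) - nc + 1L, 1L)
        block <- rare_idx[start:(start + nc - 1L)]  # contiguous rare block
        causal <- rbind(causal, data.frame(variant = block,
                                           beta = scenario$effect_size))
      }
      if (scenario$causal_common_per_window > 0) {
        common_idx <- idx[!is_rare[idx]]
        ncc <- min(scenario$causal_common_per_window, length(common_idx))
        if (ncc > 0) {
          cc <- sort(sample(common_idx, ncc))
          causal <- rbind(causal, data.frame(variant = cc,
                                             beta = scenario$common_effect_size))
        }
      }
    }
    truth <- data.frame(
      window_id = sprintf("%s:%d-%d", scenario$chrom,
                          (seq_len(W) - 1L) * width, seq_len(W) * width),
      is_true = seq_len(W) %in% true_w,
      stringsAsFactors = FALSE
    )
    list(genotypes = gm, truth = truth, causal = causal,
         maf_target = maf_target)
  })
}

#' Simulate a phenotype from causal genotypes
#'
#' \eqn{y = \sum_k \beta_k g_k + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)} with
#' \eqn{\sigma = } \code{trait_noise_sd}. All rare causal effects share
#' one sign. The replicate index selects an independent noise stream, so
#' replicate phenotypes share the genetic component.
#'
#' @param genotypes A [genotype_matrix()].
#' @param causal Data.frame with columns \code{variant} (column index)
#'   and \code{beta}; may be empty (pure-noise trait).
#' @param scenario The [sim_scenario()] (for noise SD and seed).
#' @param replicate Replicate index (default 1).
#' @return A [phenotype_vector()] with a quantitative trait.
#' @export
simulate_phenotype <- function(genotypes, causal, scenario, replicate = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(scenario, "sim_scenario"))
  n <- nrow(genotypes$dosages)
  g <- if (nrow(causal) > 0) {
    as.numeric(genotypes$dosages[, causal$variant, drop = FALSE] %*% causal$beta)
  } else {
    numeric(n)
  }
  eps <- .with_seed(.mix_seed(scenario$seed, 1000000L + replicate),
                    stats::rnorm(n, 0, scenario$trait_noise_sd))
  phenotype_vector(genotypes$sample_ids, g + eps, "quantitative")
}

#' Power / type-I error curve over p-value cutoffs
#'
#' Power is the true-positive rate of true-association windows; the
#' type-I error rate is the false-positive rate of the null windows —
#' both as a function of the p-value cutoff, pooled over replicates.
#'
#' @param p_values Vector of window p-values, stacked over replicates.
#' @param is_true Logical vector (same length) labelling each window as
#'   carrying true signal.
#' @param cutoffs Decreasing vector of p-value cutoffs.
#' @return A data.frame of class \code{"evaluation_curve"} with columns
#'   \code{cutoff}, \code{tpr}, \code{fpr}. If no true (resp. false)
#'   windows exist, \code{tpr} (resp. \code{fpr}) is \code{NA}.
#' @export
evaluate_scan <- function(p_values, is_true,
                          cutoffs = c(1, 0.5, 0.1, 0.05, 0.01, 0.005, 0.001)) {
  stopifnot(length(p_values) == length(is_true))
  keep <- !is.na(p_values)
  p_values <- p_values[keep]
  is_true <- is_true[keep]
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  tpr <- if (any(is_true)) {
    vapply(cutoffs, function(cc) mean(p_values[is_true] <= cc), numeric(1))
  } else rep(NA_real_, length(cutoffs))
  fpr <- if (any(!is_true)) {
    vapply(cutoffs, function(cc) mean(p_values[!is_true] <= cc), numeric(1))
  } else rep(NA_real_, length(cutoffs))
  structure(data.frame(cutoff = cutoffs, tpr = tpr, fpr = fpr),
            class = c("evaluation_curve", "data.frame"))
}
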