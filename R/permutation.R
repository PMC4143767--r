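# Permutation null distribution of G and the genome-wide window scan.

# Deterministic per-(seed, m) stream id, kept inside the 32-bit integer
# range R's RNG seeds require.
.mix_seed <- function(seed, m) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 +
                as.numeric(m) * 16807) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state; the caller's stream is
# untouched.
.with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Reproducible permutation of sample indices
#'
#' Returns the \eqn{m}-th uniformly random permutation of
#' \code{1:n_samples} for a given base seed. The permutation depends
#' only on \code{(seed, m)}, so the same permutation \eqn{m} can be
#' reused for every window of a scan, and results are independent of
#' evaluation order or parallel scheduling. The caller's RNG state is
#' left untouched.
#'
#' @param n_samples Number of samples (\eqn{\ge 2}).
#' @param m Permutation index (positive integer).
#' @param seed Base seed.
#' @return An integer permutation of \code{1:n_samples}.
#' @export
permute_assignment <- function(n_samples, m, seed) {
  if (n_samples < 2L) stop("need at least 2 samples to permute")
  .with_seed(.mix_seed(seed, m), sample.int(n_samples))
}

#' Empirical p-value from a permutation null
#'
#' The empirical p-value of an observed statistic \eqn{G} against
#' permutation replicates \eqn{G^{(1)}, \dots, G^{(M)}} is
#' \eqn{\#\{G^{(m)} \ge G\}/M}; ties count as exceedances. The
#' add-one estimator \eqn{(\# + 1)/(M + 1)} is available behind a flag
#' (it never returns 0, which downstream \eqn{-\log_{10}} displays
#' need), but the plain ratio is the default.
#'
#' @param G_obs Observed statistic.
#' @param G_perm Numeric vector of permutation statistics (length
#'   \eqn{M \ge 1}).
#' @param add_one Use the \eqn{(\#+1)/(M+1)} estimator?
#' @param window_id Optional label.
#' @return An object of class \code{"goft_result"}: list with
#'   \code{window_id}, \code{G_observed}, \code{M},
#'   \code{exceed_count} and \code{p_empirical}.
#' @export
empirical_pvalue <- function(G_obs, G_perm, add_one = FALSE, window_id = NULL) {
  if (length(G_perm) == 0L) stop("empty permutation list")
  M <- length(G_perm)
  x <- sum(G_perm >= G_obs)
  structure(
    list(window_id = window_id, G_observed = G_obs, M = M, exceed_count = x,
         p_empirical = if (add_one) (x + 1) / (M + 1) else x / M),
    class = "goft_result"
  )
}

#' @export
print.goft_result <- function(x, ...) {
  cat(sprintf("goft_result%s: G = %.4g, exceed %d/%d, p = %.4g\n",
              if (is.null(x$window_id)) "" else paste0(" [", x$window_id, "]"),
              x$G_observed, x$exceed_count, x$M, x$p_empirical))
  invisible(x)
}

#' Genome-wide Berk-Jones window scan with permutation p-values
#'
#' Splits the genome into fixed-width windows anchored at coordinate 0,
#' collapses rare-variant runs within each window (optionally), computes
#' per-variant association p-values, forms the Berk-Jones statistic
#' \eqn{G_s} per window, and derives empirical p-values from \eqn{M}
#' phenotype permutations.
#'
#' Permutation shuffles the sample-to-phenotype assignment (equivalent
#' to jointly permuting whole genotype rows), so within-window linkage
#' disequilibrium is preserved; the genotype matrix is never shuffled
#' column-wise. One shared permutation per index \eqn{m} is applied to
#' all windows. The collapsing structure (which variants form which
#' runs) is frozen from the observed data, since MAF does not change
#' under permutation; only the regression p-values are recomputed.
#'
#' When an external p-value table is supplied (p-value-level
#' meta-analysis, e.g. adding array-based results to sequencing
#' windows), its in-window, non-duplicate records are appended to each
#' window's observed p-value set. Under each permutation the external
#' p-values are re-drawn from Uniform(0, 1) — they cannot be permuted
#' without the external genotypes — which is a declared approximation
#' recorded in the result metadata.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype A [phenotype_vector()]; joined to the genotypes on
#'   sample id, with dropped samples reported.
#' @param window_width Window width in base pairs (default 10000).
#' @param collapse Collapse rare-variant runs? (default \code{TRUE}).
#' @param rare_maf MAF threshold below which a variant is rare
#'   (default 0.05; strict comparison).
#' @param n_permutations Number of permutations \eqn{M} (default 1000).
#' @param seed Base seed for the permutation streams.
#' @param external Optional external p-value table: data.frame with
#'   columns \code{chrom}, \code{pos}, \code{id}, \code{p}.
#' @param add_one Use the add-one empirical p-value estimator?
#' @param missing How to handle missing genotype calls:
#'   \code{"complete"} drops samples with any missing call among the
#'   analysed variants, \code{"impute"} replaces missing calls by the
#'   per-variant mean dosage.
#' @param p_floor Clamp for zero p-values inside the statistic.
#' @return A data.frame of class \code{"goft_scan"} with one row per
#'   non-empty window: \code{window_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{n_variants}, \code{L}, \code{n_common},
#'   \code{n_burden}, \code{n_external}, \code{G}, \code{exceed_count},
#'   \code{M}, \code{p_empirical}, \code{status}. Attributes record the
#'   run parameters, dropped samples/variants and external-merge
#'   bookkeeping.
#' @export
goft_scan <- function(genotypes, phenotype, window_width = 10000,
                      collapse = TRUE, rare_maf = 0.05,
                      n_permutations = 1000, seed = 1,
                      external = NULL, add_one = FALSE,
                      missing = c("complete", "impute"),
                      p_floor = 1e-15) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(phenotype, "phenotype_vector"))
  missing <- match.arg(missing)
  if (n_permutations < 1L) stop("'n_permutations' must be >= 1")
  if (window_width <= 0) stop("'window_width' must be positive")

  ## --- align samples -------------------------------------------------
  keep <- intersect(phenotype$sample_ids, genotypes$sample_ids)
  n_dropped <- (length(phenotype$sample_ids) - length(keep)) +
    (length(genotypes$sample_ids) - length(keep))
  if (length(keep) < 3L) stop("fewer than 3 samples shared by genotypes and phenotype")
  gi <- match(keep, genotypes$sample_ids)
  pi <- match(keep, phenotype$sample_ids)
  D <- genotypes$dosages[gi, , drop = FALSE]
  y <- phenotype$values[pi]
  covar <- if (is.null(phenotype$covariates)) NULL else
    phenotype$covariates[pi, , drop = FALSE]

  ## --- missing genotypes --------------------------------------------
  if (anyNA(D)) {
    if (missing == "complete") {
      ok <- rowSums(is.na(D)) == 0L
      n_dropped <- n_dropped + sum(!ok)
      D <- D[ok, , drop = FALSE]
      y <- y[ok]
      keep <- keep[ok]
      if (!is.null(covar)) covar <- covar[ok, , drop = FALSE]
      if (length(y) < 3L) stop("too few complete-genotype samples")
    } else {
      cm <- colMeans(D, na.rm = TRUE)
      idx <- which(is.na(D), arr.ind = TRUE)
      D[idx] <- cm[idx[, 2]]
    }
  }
  n <- length(y)

  ## --- variant bookkeeping ------------------------------------------
  vinfo <- genotypes$variants
  ord <- order(vinfo$chrom, vinfo$pos)
  vinfo <- vinfo[ord, , drop = FALSE]
  D <- D[, ord, drop = FALSE]
  maf <- apply(D, 2L, compute_maf)  # MAF of the analysed sample set
  mono <- maf == 0
  n_mono <- sum(mono)
  if (all(mono)) stop("all variants are monomorphic in the analysed samples")
  D <- D[, !mono, drop = FALSE]
  vinfo <- vinfo[!mono, , drop = FALSE]
  maf <- maf[!mono]

  wnum <- .window_index(vinfo$pos, window_width)
  wkey <- paste0(vinfo$chrom, ":", wnum)
  wtab <- unique(data.frame(key = wkey, chrom = vinfo$chrom, idx = wnum,
                            stringsAsFactors = FALSE))
  wtab <- wtab[order(wtab$chrom, wtab$idx), , drop = FALSE]
  S <- nrow(wtab)

  ## --- collapsed design, stacked across windows ----------------------
  blocks <- vector("list", S)
  col_win <- integer(0)
  win_meta <- vector("list", S)
  for (s in seq_len(S)) {
    vi <- which(wkey == wtab$key[s])
    col <- collapse_rare(D[, vi, drop = FALSE], maf[vi],
                         rare_threshold = if (collapse) rare_maf else 0)
    blocks[[s]] <- col$design
    col_win <- c(col_win, rep.int(s, ncol(col$design)))
    win_meta[[s]] <- list(
      n_variants = length(vi),
      type = col$info$type,
      keys = paste0(vinfo$chrom[vi], ":", vinfo$pos[vi])
    )
  }
  X <- do.call(cbind, blocks)
  eng <- .assoc_engine(X, phenotype$trait_type, covar)

  ## --- observed statistics -------------------------------------------
  p_obs <- as.numeric(eng(y))
  testable <- !is.na(p_obs)
  cols_by_win <- lapply(seq_len(S), function(s) which(col_win == s & testable))

  ## --- external p-values ---------------------------------------------
  ext_by_win <- vector("list", S)
  n_ext_outside <- 0L
  n_ext_dup <- 0L
  if (!is.null(external)) {
    need <- c("chrom", "pos", "p")
    if (!all(need %in% names(external))) {
      stop("'external' needs columns chrom, pos, p")
    }
    if (any(external$p <= 0 | external$p > 1)) {
      external$p <- pmin(pmax(external$p, p_floor), 1)
    }
    ekey <- paste0(external$chrom, ":", .window_index(external$pos, window_width))
    slot <- match(ekey, wtab$key)
    n_ext_outside <- sum(is.na(slot))
    internal_keys <- paste0(external$chrom, ":", external$pos)
    for (s in seq_len(S)) {
      rows <- which(slot == s)
      if (!length(rows)) next
      dup <- internal_keys[rows] %in% win_meta[[s]]$keys
      n_ext_dup <- n_ext_dup + sum(dup)
      ext_by_win[[s]] <- external$p[rows[!dup]]
    }
  }
  n_ext <- lengths(ext_by_win)
  total_ext <- sum(n_ext)
  ext_start <- cumsum(c(0L, n_ext))  # eu offsets per window in the permutation loop

  clamp <- function(p) pmin(pmax(p, p_floor), 1)
  G_obs <- rep(NA_real_, S)
  L_win <- integer(S)
  for (s in seq_len(S)) {
    pw <- c(p_obs[cols_by_win[[s]]], ext_by_win[[s]])
    L_win[s] <- length(pw)
    if (length(pw)) G_obs[s] <- .goft_G(sort(clamp(pw)))
  }
  tested <- L_win > 0L

  ## --- permutation null ----------------------------------------------
  M <- as.integer(n_permutations)
  exceed <- integer(S)
  for (m in seq_len(M)) {
    res <- .with_seed(.mix_seed(seed, m), {
      perm <- sample.int(n)
      eu <- if (total_ext > 0L) stats::runif(total_ext) else numeric(0)
      list(perm = perm, eu = eu)
    })
    pp <- as.numeric(eng(y[res$perm]))
    for (s in which(tested)) {
      pw <- pp[cols_by_win[[s]]]
      if (n_ext[s] > 0L) {
        pw <- c(pw, res$eu[(ext_start[s] + 1L):(ext_start[s] + n_ext[s])])
      }
      if (.goft_G(sort(clamp(pw))) >= G_obs[s]) exceed[s] <- exceed[s] + 1L
    }
  }

  p_emp <- if (add_one) (exceed + 1) / (M + 1) else exceed / M

  out <- data.frame(
    window_id = sprintf("%s:%d-%d", wtab$chrom, (wtab$idx - 1L) * window_width,
                        wtab$idx * window_width),
    chrom = wtab$chrom,
    start = (wtab$idx - 1L) * window_width,
    end = wtab$idx * window_width,
    n_variants = vapply(win_meta, `[[`, integer(1), "n_variants"),
    L = L_win,
    n_common = vapply(seq_len(S), function(s)
      sum(win_meta[[s]]$type == "common" & testable[col_win == s]), integer(1)),
    n_burden = vapply(seq_len(S), function(s)
      sum(win_meta[[s]]$type == "burden" & testable[col_win == s]), integer(1)),
    n_external = n_ext,
    G = G_obs,
    exceed_count = ifelse(tested, exceed, NA_integer_),
    M = M,
    p_empirical = ifelse(tested, p_emp, NA_real_),
    status = ifelse(tested, "tested", "untested"),
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- list(
    window_width = window_width, collapse = collapse, rare_maf = rare_maf,
    n_permutations = M, seed = seed, add_one = add_one, missing = missing,
    p_floor = p_floor, trait_type = phenotype$trait_type,
    external_null = if (total_ext > 0L) "uniform_resampling" else NA_character_
  )
  attr(out, "n_samples") <- n
  attr(out, "n_dropped_samples") <- n_dropped
  attr(out, "n_monomorphic") <- n_mono
  attr(out, "external_merge") <- list(added = total_ext,
                                      duplicates = n_ext_dup,
                                      outside = n_ext_outside)
  class(out) <- c("goft_scan", "data.frame")
  out
}

#' @export
print.goft_scan <- function(x, ...) {
  pars <- attr(x, "params")
  cat(sprintf(
    "goft_scan: %d windows (%d tested) | width %g bp | M = %d | collapse = %s\n",
    nrow(x), sum(x$status == "tested"), pars$window_width, pars$n_permutations,
    pars$collapse
  ))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more windows\n", nrow(x) - 10))
  invisible(x)
}
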