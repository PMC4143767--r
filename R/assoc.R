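# Per-variant association tests feeding the goodness-of-fit statistic.
#
# The scan recomputes every per-variant p-value under each phenotype
# permutation, so the tests are implemented as a matrix engine: the
# design columns are prepared once and each phenotype evaluation is a
# single cross-product. For a quantitative trait this is the exact OLS
# slope t-test expressed through the partial correlation; for a binary
# trait it is the logistic score test under the null model, which needs
# no per-variant model fit.

# Build a closure p(y) over a fixed design matrix X (samples x columns).
# Covariates are projected out of X once (Frisch-Waugh); each phenotype
# is projected per call. Columns with (residual) variance ~0 are
# untestable and return NA.
.assoc_engine <- function(X, trait_type, covariates = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  q <- 0L
  Qc <- NULL
  if (!is.null(covariates)) {
    Qc <- qr(cbind(1, as.matrix(covariates)))
    q <- ncol(covariates)
    Xr <- qr.resid(Qc, X)
  } else {
    Xr <- X - rep(colMeans(X), each = n)
  }
  css <- colSums(Xr^2)
  testable <- css > n * 1e-12
  cssf <- ifelse(testable, css, 1)  # avoid 0/0; masked later

  if (trait_type == "quantitative") {
    df <- n - 2L - q
    if (df < 1L) stop("too few samples for the regression degrees of freedom")
    function(y) {
      yr <- if (is.null(Qc)) y - mean(y) else qr.resid(Qc, y)
      ssy <- sum(yr^2)
      num <- as.numeric(crossprod(Xr, yr))
      r <- num / sqrt(cssf * ssy)
      r <- pmin(pmax(r, -1), 1)
      tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(-abs(tt), df)
      p[!testable] <- NA_real_
      structure(pmax(p, .Machine$double.xmin), sign = sign(num))
    }
  } else {
    function(y) {
      if (is.null(Qc)) {
        mu <- mean(y)
        U <- as.numeric(crossprod(Xr, y))  # Xr centred, so y - mu implicit
        V <- mu * (1 - mu) * cssf
      } else {
        fit <- stats::glm.fit(qr.X(Qc), y, family = stats::binomial())
        mu <- fit$fitted.values
        w <- mu * (1 - mu)
        U <- as.numeric(crossprod(X, y - mu))
        Xw <- X * sqrt(w)
        Zw <- qr.X(Qc) * sqrt(w)
        V <- colSums(qr.resid(qr(Zw), Xw)^2)
        V[!testable | V <= 0] <- 1
      }
      p <- stats::pchisq(U^2 / V, df = 1, lower.tail = FALSE)
      p[!testable] <- NA_real_
      structure(pmax(p, .Machine$double.xmin), sign = sign(U))
    }
  }
}

#' Association p-value for a single variant
#'
#' Quantitative traits use the two-sided t-test on the slope of an
#' additive least-squares regression of trait on dosage; binary traits
#' use the two-sided score test of a logistic regression. Covariates in
#' the phenotype object are adjusted for. Fractional (imputed) dosages
#' are used as-is.
#'
#' @param dosages Numeric vector of dosages in \eqn{[0, 2]}, aligned to
#'   \code{phenotype$sample_ids}.
#' @param phenotype A [phenotype_vector()].
#' @return A list with \code{p} (in \eqn{(0, 1]}, or \code{NA} when the
#'   variant is untestable), \code{untestable} (logical; \code{TRUE} for
#'   zero-variance dosage), \code{effect_direction} (sign of the
#'   estimated effect) and \code{test_used}.
#' @export
variant_pvalue <- function(dosages, phenotype) {
  stopifnot(inherits(phenotype, "phenotype_vector"))
  if (length(dosages) != length(phenotype$values)) {
    stop("dosage vector and phenotype are not aligned")
  }
  eng <- .assoc_engine(matrix(as.numeric(dosages), ncol = 1),
                       phenotype$trait_type, phenotype$covariates)
  p <- eng(phenotype$values)
  list(
    p = as.numeric(p),
    untestable = is.na(p)[1],
    effect_direction = attr(p, "sign")[1],
    test_used = if (phenotype$trait_type == "quantitative") "ols_slope_t" else "logistic_score"
  )
}

#' Sorted p-value set of one window
#'
#' Applies rare-variant collapsing (optionally), computes the per-variant
#' association p-value for every resulting common variant and burden
#' pseudo-variant, and returns the sorted set that feeds
#' [goft_statistic()]. Monomorphic variants are dropped before
#' classification; windows where nothing remains testable are flagged
#' untested rather than assigned p = 1.
#'
#' @param dosages Samples x variants dosage matrix for the window, in
#'   positional order.
#' @param maf Per-column minor allele frequencies.
#' @param phenotype A [phenotype_vector()] aligned to the rows.
#' @param collapse Collapse rare runs? (default \code{TRUE}).
#' @param rare_threshold MAF threshold for rare classification.
#' @param window_id Optional label.
#' @param positions Optional 1-based variant positions (used for
#'   duplicate detection when merging external sources).
#' @param chrom Optional chromosome label accompanying \code{positions}.
#' @return An object of class \code{"pvalue_set"}: list with
#'   \code{values} (sorted ascending), \code{L}, \code{window_id},
#'   \code{n_common}, \code{n_burden}, \code{status} ("tested" or
#'   "untested") and \code{variant_keys} (chrom:pos of the internal
#'   variants that contributed). Untested windows have \code{L = 0}.
#' @export
window_pvalues <- function(dosages, maf, phenotype, collapse = TRUE,
                           rare_threshold = 0.05, window_id = NULL,
                           positions = NULL, chrom = NULL) {
  dosages <- as.matrix(dosages)
  if (length(maf) != ncol(dosages)) stop("'maf' must match dosage columns")
  poly <- maf > 0
  keys <- if (!is.null(positions)) paste0(chrom %||% "", ":", positions) else NULL
  if (!any(poly)) {
    return(structure(list(values = numeric(0), L = 0L, window_id = window_id,
                          n_common = 0L, n_burden = 0L, status = "untested",
                          variant_keys = character(0)),
                     class = "pvalue_set"))
  }
  dosages <- dosages[, poly, drop = FALSE]
  maf <- maf[poly]
  keys <- keys[poly]
  col <- collapse_rare(dosages, maf,
                       rare_threshold = if (collapse) rare_threshold else 0)
  eng <- .assoc_engine(col$design, phenotype$trait_type, phenotype$covariates)
  p <- as.numeric(eng(phenotype$values))
  ok <- !is.na(p)
  if (!any(ok)) {
    return(structure(list(values = numeric(0), L = 0L, window_id = window_id,
                          n_common = 0L, n_burden = 0L, status = "untested",
                          variant_keys = character(0)),
                     class = "pvalue_set"))
  }
  structure(
    list(values = sort(p[ok]), L = sum(ok), window_id = window_id,
         n_common = sum(col$info$type[ok] == "common"),
         n_burden = sum(col$info$type[ok] == "burden"),
         status = "tested",
         variant_keys = if (is.null(keys)) character(0) else
           keys[unlist(col$members[ok], use.names = FALSE)]),
    class = "pvalue_set"
  )
}

#' @export
print.pvalue_set <- function(x, ...) {
  cat(sprintf("pvalue_set%s: L = %d (%d common, %d burden), status = %s\n",
              if (is.null(x$window_id)) "" else paste0(" [", x$window_id, "]"),
              x$L, x$n_common, x$n_burden, x$status))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
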