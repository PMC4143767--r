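# Berk-Jones goodness-of-fit statistic on a set of p-values.

#' Binomial Kullback-Leibler divergence between two proportions
#'
#' Computes the divergence term
#' \deqn{K(t, x) = t \log(t/x) + (1 - t)\log\{(1 - t)/(1 - x)\}}
#' used by the Berk-Jones statistic. The term is zero whenever
#' \eqn{t \le x} (the empirical CDF does not exceed the uniform CDF at
#' that point), positive when \eqn{0 < x < t < 1}, and infinite when
#' \eqn{x = 0} with \eqn{t > 0}. At \eqn{t = 1} with \eqn{0 < x < 1}
#' the analytic limit \eqn{-\log(x)} is used (the \eqn{0 \cdot \log 0 = 0}
#' convention), so the top order statistic of a p-value set contributes a
#' finite, well-defined term.
#'
#' @param t Numeric vector of proportions in \eqn{[0, 1]} (typically
#'   \eqn{j/L} for the \eqn{j}-th order statistic of \eqn{L} p-values).
#' @param x Numeric vector of probabilities in \eqn{[0, 1]} (typically
#'   sorted p-values). Recycled against \code{t}.
#' @return Numeric vector of non-negative divergences; \code{Inf} marks
#'   the degenerate \eqn{x = 0, t > 0} case.
#' @examples
#' bj_divergence(0.2, 0.7)   # 0: t <= x
#' bj_divergence(0.5, 0.25)  # 0.5*log(2) + 0.5*log(2/3)
#' @seealso [goft_statistic()]
#' @export
bj_divergence <- function(t, x) {
  n <- max(length(t), length(x))
  t <- rep_len(as.numeric(t), n)
  x <- rep_len(as.numeric(x), n)
  if (anyNA(t) || anyNA(x) || any(t < 0 | t > 1) || any(x < 0 | x > 1)) {
    stop("'t' and 'x' must be probabilities in [0, 1]")
  }
  k <- numeric(n)
  active <- t > x
  inner <- active & x > 0 & t < 1
  if (any(inner)) {
    ti <- t[inner]
    xi <- x[inner]
    # log(t/x) as log(t) - log(x): stable at extreme ratios
    k[inner] <- ti * (log(ti) - log(xi)) +
      (1 - ti) * (log1p(-ti) - log1p(-xi))
  }
  top <- active & x > 0 & t == 1
  k[top] <- -log(x[top])
  k[active & x == 0] <- Inf
  pmax(k, 0)
}

#' Berk-Jones window statistic from a set of p-values
#'
#' For sorted p-values \eqn{p_1 \le \dots \le p_L} the statistic is
#' \deqn{G = L \cdot \max_{1 \le j \le L} 2 K(j/L, p_j),}
#' with \eqn{K} as in [bj_divergence()]. Large \eqn{G} indicates that the
#' empirical distribution of the p-values departs from Uniform(0,1)
#' towards small values, i.e. that the variant set carries association
#' signal. Input order is irrelevant: values are sorted internally.
#'
#' P-values of exactly zero (possible when the inputs are themselves
#' permutation-derived) are clamped to \code{p_floor} so that \eqn{G}
#' stays finite; the clamping is reported via a message.
#'
#' @param p Numeric vector of p-values in \eqn{[0, 1]}, length \eqn{\ge 1}.
#' @param p_floor Lower clamp applied to zero p-values (default
#'   \code{1e-15}).
#' @param window_id Optional label carried through to the result.
#' @return An object of class \code{"goft_stat"}: a list with elements
#'   \code{G} (the statistic), \code{argmax} (the index \eqn{j} attaining
#'   the maximum, after sorting), \code{L}, and \code{window_id}.
#' @examples
#' goft_statistic(c(0.5, 0.8, 1.0))     # all K terms zero: G = 0
#' goft_statistic(c(1/3, 2/3))          # G = 4 * log(3/2)
#' @export
goft_statistic <- function(p, p_floor = 1e-15, window_id = NULL) {
  if (length(p) == 0L) stop("empty p-value set")
  p <- as.numeric(p)
  if (anyNA(p)) stop("p-values must not contain NA")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  nz <- sum(p == 0)
  if (nz > 0L) {
    message(sprintf("goft_statistic: clamped %d zero p-value(s) to %g", nz, p_floor))
    p[p == 0] <- p_floor
  }
  p <- sort(p)
  L <- length(p)
  terms <- 2 * bj_divergence(seq_len(L) / L, p)
  j <- which.max(terms)
  structure(
    list(G = L * terms[j], argmax = j, L = L, window_id = window_id),
    class = "goft_stat"
  )
}

#' @export
print.goft_stat <- function(x, ...) {
  cat(sprintf(
    "Berk-Jones statistic%s: G = %.6g (L = %d, argmax j = %d)\n",
    if (is.null(x$window_id)) "" else paste0(" [", x$window_id, "]"),
    x$G, x$L, x$argmax
  ))
  invisible(x)
}

# Lean kernel used inside the permutation loop: `p` must already be
# sorted, strictly positive and <= 1. Returns the scalar G.
.goft_G <- function(p) {
  L <- length(p)
  if (L == 1L) {
    return(if (p < 1) -2 * log(p) else 0)
  }
  t <- seq_len(L - 1L) / L
  ph <- p[seq_len(L - 1L)]
  a <- t > ph
  m <- 0
  if (any(a)) {
    ta <- t[a]
    pa <- ph[a]
    m <- max(ta * (log(ta) - log(pa)) +
               (1 - ta) * (log1p(-ta) - log1p(-pa)))
  }
  if (p[L] < 1) m <- max(m, -log(p[L]))  # t = 1 limit at the top order statistic
  2 * L * m
}
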