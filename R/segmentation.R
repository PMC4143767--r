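# Fixed-width genome segmentation and rare-variant collapsing.

#' Minor allele frequency from dosages
#'
#' @param dosages Numeric vector of allele dosages in \eqn{[0, 2]};
#'   \code{NA} entries are ignored.
#' @return The minor allele frequency \eqn{\min(f, 1 - f)} where
#'   \eqn{f = \mathrm{mean}(dosage)/2}, in \eqn{[0, 0.5]}.
#' @examples
#' compute_maf(c(0, 1, 1, 2))  # 0.5
#' compute_maf(c(2, 2, 2, 2))  # 0: alternate allele fixed
#' @export
compute_maf <- function(dosages) {
  if (length(dosages) == 0L || all(is.na(dosages))) {
    stop("cannot compute MAF from an empty or all-missing dosage vector")
  }
  f <- mean(dosages, na.rm = TRUE) / 2
  min(f, 1 - f)
}

#' Tile a chromosome with fixed-width windows
#'
#' Windows are half-open \code{[start, end)} intervals in 0-based
#' coordinates, anchored at coordinate 0 (not at the first variant), so
#' that window boundaries are reproducible across datasets. A variant at
#' 1-based position \eqn{pos} falls in the window containing
#' \eqn{pos - 1}.
#'
#' @param chrom Chromosome label.
#' @param max_pos Largest 1-based variant position to cover.
#' @param width Window width in base pairs (> 0).
#' @param min_pos Smallest position (only checked against
#'   \code{max_pos}; tiling always starts at 0).
#' @return A data.frame with columns \code{window_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open).
#' @examples
#' make_windows("3", max_pos = 25000, width = 10000)  # 3 windows
#' @export
make_windows <- function(chrom, max_pos, width, min_pos = 1) {
  if (width <= 0) stop("window width must be positive")
  if (max_pos < min_pos) stop("max_pos must be >= min_pos")
  n <- ceiling(max_pos / width)
  start <- (seq_len(n) - 1) * width
  data.frame(
    window_id = sprintf("%s:%d-%d", chrom, start, start + width),
    chrom = chrom,
    start = start,
    end = start + width,
    stringsAsFactors = FALSE
  )
}

# 1-based position -> 1-based index of the 0-anchored window of `width`
# containing it.
.window_index <- function(pos, width) {
  as.integer((pos - 1) %/% width) + 1L
}

#' Collapse runs of rare variants between adjacent common variants
#'
#' Rare variants (MAF below \code{rare_threshold}) are partitioned into
#' maximal runs delimited by common variants; the run before the first
#' common variant and the run after the last one each form their own
#' group. Each run is collapsed into a single pseudo-variant whose
#' per-sample dosage is the sum of the run's dosages. Output columns are
#' the common variants plus one burden column per non-empty run, in
#' positional order. Collapsing never crosses a window boundary because
#' it is applied per window.
#'
#' Setting \code{rare_threshold = 0} disables collapsing exactly (no MAF
#' is below 0), returning the input columns unchanged.
#'
#' @param dosages Numeric matrix, samples x variants, columns in
#'   positional order.
#' @param maf Numeric vector of per-variant minor allele frequencies
#'   aligned to the columns.
#' @param rare_threshold MAF below which a variant is rare (strict
#'   comparison; default 0.05, so MAF = 0.05 exactly is common).
#' @return A list with \code{design} (samples x columns matrix),
#'   \code{info} (data.frame: \code{label}, \code{type} in
#'   \{"common","burden"\}, \code{n_variants}) and \code{members} (list
#'   of source column indices per output column).
#' @examples
#' d <- cbind(c(0, 1, 0), c(1, 0, 0))
#' collapse_rare(d, maf = c(0.01, 0.02), rare_threshold = 0.05)
#' @export
collapse_rare <- function(dosages, maf, rare_threshold = 0.05) {
  dosages <- as.matrix(dosages)
  k <- ncol(dosages)
  if (k == 0L) stop("no variant columns to collapse")
  if (length(maf) != k) stop("'maf' must have one entry per dosage column")
  rare <- maf < rare_threshold
  cn <- colnames(dosages)
  if (is.null(cn)) cn <- paste0("v", seq_len(k))

  if (!any(rare)) {
    colnames(dosages) <- cn
    return(list(
      design = dosages,
      info = data.frame(label = cn, type = "common",
                        n_variants = 1L, stringsAsFactors = FALSE),
      members = as.list(seq_len(k))
    ))
  }

  # run id g for a rare variant = number of common variants before it;
  # g = 0 is the run preceding the first common variant.
  run_id <- cumsum(!rare)
  runs <- split(which(rare), run_id[rare])
  common_idx <- which(!rare)

  # interleave: common j sits at key 2j, the run following it at 2j + 1
  # (run 0, before any common variant, gets key 1).
  key <- c(2 * seq_along(common_idx),
           2 * as.integer(names(runs)) + 1)
  ord <- order(key)

  cols <- c(
    lapply(common_idx, function(i) dosages[, i]),
    lapply(runs, function(idx) {
      if (length(idx) == 1L) dosages[, idx] else rowSums(dosages[, idx, drop = FALSE])
    })
  )
  members <- c(as.list(common_idx), unname(runs))
  labels <- c(cn[common_idx],
              vapply(runs, function(idx) {
                sprintf("burden(%s)", paste(cn[idx], collapse = "+"))
              }, character(1)))
  type <- c(rep("common", length(common_idx)), rep("burden", length(runs)))

  design <- do.call(cbind, cols[ord])
  colnames(design) <- labels[ord]
  list(
    design = design,
    info = data.frame(label = labels[ord], type = type[ord],
                      n_variants = lengths(members)[ord],
                      stringsAsFactors = FALSE),
    members = members[ord]
  )
}
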