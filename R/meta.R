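# P-value-level meta-analysis: merging an external p-value source
# (e.g. array-based association results) into window p-value sets
# before the goodness-of-fit statistic.

#' Merge an external p-value table into window p-value sets
#'
#' Each external record is assigned to its window by chromosomal
#' position (0-based half-open intervals). Records whose
#' \code{(chrom, pos)} duplicates a variant already tested internally
#' are dropped — the internal, sequencing-derived p-value wins, so the
#' same site is never counted twice. Remaining in-window external
#' p-values are appended and the merged set re-sorted; \eqn{L} grows by
#' the number appended. Re-applying the same table is a no-op because
#' every record has become a duplicate.
#'
#' @param window_psets Named list of [window_pvalues()] results, one per
#'   window, names matching \code{windows$window_id}.
#' @param external Data.frame with columns \code{chrom}, \code{pos}
#'   (1-based), \code{id}, \code{p}.
#' @param windows Data.frame as from [make_windows()] (columns
#'   \code{window_id}, \code{chrom}, \code{start}, \code{end}).
#' @return The list of p-value sets with external values merged; each
#'   merged set gains \code{n_external}. The attribute \code{"merge"}
#'   records counts of added, duplicate and out-of-window records.
#' @export
merge_sources <- function(window_psets, external, windows) {
  stopifnot(is.list(window_psets),
            all(c("chrom", "pos", "p") %in% names(external)),
            all(c("window_id", "chrom", "start", "end") %in% names(windows)))
  if (nrow(external) > 0 && any(external$p <= 0 | external$p > 1)) {
    stop("external p-values must lie in (0, 1]")
  }
  added <- 0L; dups <- 0L; outside <- 0L
  if (nrow(external) > 0) {
    for (r in seq_len(nrow(external))) {
      pos0 <- external$pos[r] - 1L
      hit <- which(windows$chrom == external$chrom[r] &
                     windows$start <= pos0 & pos0 < windows$end)
      if (!length(hit)) { outside <- outside + 1L; next }
      wid <- windows$window_id[hit[1]]
      ps <- window_psets[[wid]]
      if (is.null(ps)) { outside <- outside + 1L; next }
      key <- paste0(external$chrom[r], ":", external$pos[r])
      if (key %in% ps$variant_keys) { dups <- dups + 1L; next }
      ps$values <- sort(c(ps$values, external$p[r]))
      ps$L <- ps$L + 1L
      ps$n_external <- (ps$n_external %||% 0L) + 1L
      ps$variant_keys <- c(ps$variant_keys, key)
      if (ps$status == "untested") ps$status <- "tested"
      window_psets[[wid]] <- ps
      added <- added + 1L
    }
  }
  attr(window_psets, "merge") <- list(added = added, duplicates = dups,
                                      outside = outside)
  window_psets
}

#' Read an external p-value table
#'
#' Expects a TSV with header columns \code{chrom}, \code{pos},
#' \code{id}, \code{p}. Mapping marker ("rs") identifiers to positions
#' is the caller's responsibility.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with validated columns.
#' @export
read_external_tsv <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("chrom", "pos", "id", "p")
  if (!all(need %in% names(x))) {
    stop("external table needs header columns: ", paste(need, collapse = ", "))
  }
  x <- x[, need]
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  if (anyNA(x$pos) || any(x$pos < 1)) stop("positions must be 1-based positive integers")
  if (anyNA(x$p) || any(x$p <= 0 | x$p > 1)) stop("p-values must lie in (0, 1]")
  x
}
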