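# Core data containers: dosage genotype matrix and phenotype vector.

#' Construct a genotype dosage matrix
#'
#' The central genotype container: an \eqn{n \times p} matrix of
#' alternate-allele dosages in \eqn{[0, 2]} (fractional values from
#' imputation are allowed, as is \code{NA} for missing calls), plus a
#' per-variant metadata table. MAF is computed from the stored samples.
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns.
#' @param variants Data.frame with one row per column of \code{dosages}
#'   and columns \code{chrom}, \code{pos} (1-based), \code{id}.
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   \code{rownames(dosages)} or \code{"S1"...}.
#' @return An object of class \code{"genotype_matrix"}: a list with
#'   \code{dosages}, \code{sample_ids} and \code{variants} (the metadata
#'   augmented with a \code{maf} column).
#' @export
genotype_matrix <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("one sample id per dosage row required")
  }
  if (!is.data.frame(variants) || nrow(variants) != ncol(dosages)) {
    stop("'variants' must be a data.frame with one row per dosage column")
  }
  need <- c("chrom", "pos", "id")
  if (!all(need %in% names(variants))) {
    stop("'variants' needs columns: ", paste(need, collapse = ", "))
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]")
  }
  variants <- variants[, intersect(c(need, "maf"), names(variants)), drop = FALSE]
  variants$pos <- as.integer(variants$pos)
  if (is.null(variants$maf)) {
    variants$maf <- apply(dosages, 2L, compute_maf)
  }
  rownames(dosages) <- sample_ids
  structure(
    list(dosages = dosages, sample_ids = sample_ids, variants = variants),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants (%d rare at MAF < 0.05, %d monomorphic)\n",
    nrow(x$dosages), ncol(x$dosages),
    sum(x$variants$maf < 0.05 & x$variants$maf > 0),
    sum(x$variants$maf == 0)
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Construct a phenotype vector
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param values Trait values: numeric for a quantitative trait, 0/1 for
#'   a binary trait (at least one sample in each class).
#' @param trait_type \code{"quantitative"} or \code{"binary"}.
#' @param covariates Optional numeric matrix or data.frame of covariates,
#'   one row per sample, passed through to the per-variant regressions.
#' @return An object of class \code{"phenotype_vector"}.
#' @export
phenotype_vector <- function(sample_ids, values,
                             trait_type = c("quantitative", "binary"),
                             covariates = NULL) {
  trait_type <- match.arg(trait_type)
  sample_ids <- as.character(sample_ids)
  values <- as.numeric(values)
  if (length(values) != length(sample_ids)) {
    stop("'values' and 'sample_ids' must have equal length")
  }
  if (anyNA(values)) stop("missing trait values are not supported; filter first")
  if (trait_type == "binary") {
    if (!all(values %in% c(0, 1)) || length(unique(values)) < 2L) {
      stop("binary traits must contain only 0 and 1, with both present")
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(values)) {
      stop("'covariates' must have one row per sample")
    }
    storage.mode(covariates) <- "double"
  }
  structure(
    list(sample_ids = sample_ids, values = values,
         trait_type = trait_type, covariates = covariates),
    class = "phenotype_vector"
  )
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf(
    "phenotype_vector: %d samples, %s trait%s\n",
    length(x$values), x$trait_type,
    if (is.null(x$covariates)) "" else sprintf(", %d covariate(s)", ncol(x$covariates))
  ))
  invisible(x)
}
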