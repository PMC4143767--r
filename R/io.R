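# Readers and writers for the standard formats around the scan:
# VCF genotypes, dosage TSV, phenotype TSV, BED windows, results TSV.

# Imputation dose files commonly carry tiny numeric spill; values within
# this tolerance of [0, 2] are clamped, anything further out is an error.
.DOSE_TOL <- 0.01

.clamp_dosages <- function(d, what = "dosage") {
  bad <- !is.na(d) & (d < -.DOSE_TOL | d > 2 + .DOSE_TOL)
  if (any(bad)) {
    i <- which(bad, arr.ind = is.matrix(d))[1]
    stop(sprintf("%s value outside [%g, %g] (first offence at entry %s)",
                 what, -.DOSE_TOL, 2 + .DOSE_TOL, paste(i, collapse = ",")))
  }
  spill <- !is.na(d) & (d < 0 | d > 2)
  if (any(spill)) {
    warning(sprintf("clamped %d %s value(s) into [0, 2]", sum(spill), what))
    d[!is.na(d) & d < 0] <- 0
    d[!is.na(d) & d > 2] <- 2
  }
  d
}

#' Read genotypes from a VCF file
#'
#' Biallelic records are converted to alternate-allele dosages by
#' counting ALT alleles in the GT field; with \code{prefer_ds = TRUE}
#' the DS (imputed dosage) field is used where present. Multiallelic
#' records are skipped with a warning. Missing calls become \code{NA}.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param prefer_ds Prefer the DS FORMAT field over GT when available.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, prefer_ds = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns: ", path)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCFs drop dims
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sprintf("skipping %d multiallelic record(s)", sum(multi)))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic records in VCF: ", path)

  dos <- NULL
  if (prefer_ds && any(grepl("DS", v@gt[, "FORMAT"]))) {
    dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  }
  if (is.null(dos)) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    lev <- unique(as.vector(gt))
    map <- vapply(lev, function(g) {
      if (is.na(g)) return(NA_real_)
      a <- strsplit(g, "/", fixed = TRUE)[[1]]
      if (any(a == ".")) return(NA_real_)
      sum(as.integer(a))
    }, numeric(1))
    dos <- matrix(map[match(gt, lev)], nrow = nrow(gt),
                  dimnames = dimnames(gt))
  }
  dos <- .clamp_dosages(dos)
  variants <- data.frame(
    chrom = as.character(fix$CHROM),
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    stringsAsFactors = FALSE
  )
  genotype_matrix(t(dos), variants, sample_ids = colnames(dos))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Integer dosages are written as GT calls (0/0, 0/1, 1/1); fractional
#' dosages are written through the DS field with a placeholder GT.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  D <- genotypes$dosages
  v <- genotypes$variants
  integral <- all(is.na(D) | D == round(D))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!integral) '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_ids), collapse = "\t")
  ), con)
  gt_of <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    d <- D[, j]
    cells <- if (integral) {
      ifelse(is.na(d), "./.", gt_of[d + 1])
    } else {
      ifelse(is.na(d), "./.:.", paste0("./.", ":", formatC(d, format = "g")))
    }
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], "A", "G", ".", "PASS",
                       ".", if (integral) "GT" else "GT:DS", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a dosage TSV
#'
#' Default dialect: variants in rows; header columns \code{chrom},
#' \code{pos}, \code{id} followed by one dosage column per sample.
#' Transposed dialect (\code{transposed = TRUE}): samples in rows, first
#' column \code{sample_id}, remaining column names of the form
#' \code{chrom:pos:id}. Values within 0.01 of \eqn{[0, 2]} are clamped
#' with a warning; values further out are an error, as are ragged or
#' non-numeric rows and empty files.
#'
#' @param path Path to the TSV file.
#' @param transposed Use the samples-in-rows dialect?
#' @param missing_code Value treated as missing (default \code{NA};
#'   the literal string "NA" in the file always counts).
#' @return A [genotype_matrix()] with the dialect recorded in the
#'   \code{"dialect"} attribute.
#' @export
read_dose_tsv <- function(path, transposed = FALSE, missing_code = NA) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("empty or missing dosage file: ", path)
  }
  x <- data.table::fread(path, sep = "\t", data.table = FALSE, header = TRUE)
  if (nrow(x) == 0L) stop("dosage file has a header but no records: ", path)
  if (transposed) {
    if (names(x)[1] != "sample_id") stop("transposed dialect needs a 'sample_id' first column")
    meta <- strsplit(names(x)[-1], ":", fixed = TRUE)
    if (any(lengths(meta) != 3L)) {
      stop("transposed dialect needs variant columns named chrom:pos:id")
    }
    variants <- data.frame(
      chrom = vapply(meta, `[`, "", 1), pos = as.integer(vapply(meta, `[`, "", 2)),
      id = vapply(meta, `[`, "", 3), stringsAsFactors = FALSE
    )
    D <- as.matrix(x[, -1, drop = FALSE])
    sample_ids <- as.character(x$sample_id)
  } else {
    need <- c("chrom", "pos", "id")
    if (!all(need %in% names(x))) {
      stop("dosage file needs header columns chrom, pos, id")
    }
    variants <- data.frame(chrom = as.character(x$chrom),
                           pos = as.integer(x$pos),
                           id = as.character(x$id), stringsAsFactors = FALSE)
    D <- t(as.matrix(x[, setdiff(names(x), need), drop = FALSE]))
    sample_ids <- rownames(D)
  }
  if (!is.numeric(D)) {
    Dn <- suppressWarnings(as.numeric(D))
    bad <- which(is.na(Dn) & !is.na(D))
    if (length(bad)) {
      stop("non-numeric dosage value (entry ", bad[1], ") in ", path)
    }
    D <- matrix(Dn, nrow(D), ncol(D), dimnames = dimnames(D))
  }
  if (!is.na(missing_code)) D[D == missing_code] <- NA
  D <- .clamp_dosages(D)
  gm <- genotype_matrix(D, variants, sample_ids = sample_ids)
  attr(gm, "dialect") <- if (transposed) "samples_in_rows" else "variants_in_rows"
  gm
}

#' Read a phenotype table
#'
#' TSV with header \code{sample_id}, \code{trait}, plus optional
#' covariate columns (every remaining numeric column is taken as a
#' covariate).
#'
#' @param path Path to the TSV file.
#' @param trait_type \code{"quantitative"} or \code{"binary"}.
#' @return A [phenotype_vector()].
#' @export
read_phenotype_tsv <- function(path, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (!all(c("sample_id", "trait") %in% names(x))) {
    stop("phenotype file needs header columns sample_id, trait")
  }
  cov_cols <- setdiff(names(x), c("sample_id", "trait"))
  covariates <- if (length(cov_cols)) as.matrix(x[, cov_cols, drop = FALSE]) else NULL
  keep <- !is.na(x$trait)
  if (!all(keep)) {
    message(sprintf("dropped %d sample(s) with missing trait", sum(!keep)))
  }
  phenotype_vector(x$sample_id[keep], x$trait[keep], trait_type,
                   covariates = if (is.null(covariates)) NULL else
                     covariates[keep, , drop = FALSE])
}

#' Write scan results as TSV
#'
#' @param results A [goft_scan()] result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  data.table::fwrite(as.data.frame(results), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Write windows as a BED file (0-based half-open)
#'
#' @param windows Data.frame with \code{chrom}, \code{start},
#'   \code{end} (e.g. [make_windows()] output or a scan result).
#' @param path Output path.
#' @param names Optional name column (defaults to \code{window_id} when
#'   present).
#' @return \code{path}, invisibly.
#' @export
write_windows_bed <- function(windows, path, names = NULL) {
  if (is.null(names)) names <- windows$window_id %||% "."
  bed <- data.frame(windows$chrom, windows$start, windows$end, names)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-variant classification table
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @param rare_maf Rare/common MAF threshold.
#' @return \code{path}, invisibly.
#' @export
write_variant_classes_tsv <- function(genotypes, path, rare_maf = 0.05) {
  v <- genotypes$variants
  v$class <- ifelse(v$maf == 0, "monomorphic",
                    ifelse(v$maf < rare_maf, "rare", "common"))
  data.table::fwrite(v, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a dosage TSV (variants in rows)
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dose_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  out <- cbind(v[, c("chrom", "pos", "id")],
               as.data.frame(t(genotypes$dosages)))
  names(out) <- c("chrom", "pos", "id", genotypes$sample_ids)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a phenotype vector as TSV
#'
#' @param phenotype A [phenotype_vector()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_phenotype_tsv <- function(phenotype, path) {
  stopifnot(inherits(phenotype, "phenotype_vector"))
  out <- data.frame(sample_id = phenotype$sample_ids,
                    trait = phenotype$values)
  if (!is.null(phenotype$covariates)) {
    cv <- as.data.frame(phenotype$covariates)
    if (is.null(colnames(phenotype$covariates))) {
      names(cv) <- paste0("covar", seq_len(ncol(cv)))
    }
    out <- cbind(out, cv)
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
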