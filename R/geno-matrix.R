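#' Genotype matrix container
#'
#' A light container for hard-called genotypes: an integer matrix of
#' reference-allele counts (0, 1, 2, `NA` for missing) with one row per
#' individual and one column per variant, plus a variant metadata table.
#'
#' @param calls integer matrix, individuals x variants; entries in
#'   `{0, 1, 2, NA}` counting copies of the counted (A1) allele. Which
#'   allele is counted is an arbitrary labeling; all tests are invariant
#'   to relabeling `g -> 2 - g`.
#' @param variants data.frame with one row per variant and columns `id`
#'   (rsID, unique), `chrom`, `pos` (1-based bp), `ref`, `alt`; optional
#'   `info` (imputation info score) and `hidden` (logical, columns excluded
#'   from scans, used by the simulator to carry unobserved causal variants).
#' @param samples character vector of individual IDs, one per row of `calls`.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `variants`, `samples`.
#' @export
geno_matrix <- function(calls, variants, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- paste0("ind", seq_len(nrow(calls)))
  samples <- as.character(samples)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(
    nrow(calls) == length(samples),
    ncol(calls) == nrow(variants),
    all(c("id", "chrom", "pos") %in% names(variants))
  )
  if (anyDuplicated(variants$id))
    stop("variant ids must be unique within a dataset")
  if (any(variants$pos < 1))
    stop("positions are 1-based; pos must be >= 1")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("non-missing genotype calls must be in {0, 1, 2}")
  if (is.null(variants$hidden)) variants$hidden <- FALSE
  rownames(calls) <- samples
  colnames(calls) <- variants$id
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  nh <- sum(x$variants$hidden)
  cat(sprintf("geno_matrix: %d individuals x %d variants%s\n",
              length(x$samples), nrow(x$variants),
              if (nh) sprintf(" (%d hidden)", nh) else ""))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missingness: %.2f%%; chroms: %s\n", 100 * miss,
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i individual index (integer, logical or sample ID).
#' @param j variant index (integer, logical or variant ID).
#' @param ... unused.
#' @return A `geno_matrix` restricted to the selected rows/columns.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(j)) j <- match(j, x$variants$id)
  if (anyNA(j)) stop("unknown variant id in subset")
  if (is.character(i)) i <- match(i, x$samples)
  if (anyNA(i)) stop("unknown sample id in subset")
  geno_matrix(x$calls[i, j, drop = FALSE],
              x$variants[j, , drop = FALSE],
              x$samples[i])
}

#' Extract one genotype vector
#'
#' @param gm a [geno_matrix()].
#' @param id variant ID.
#' @return Integer vector of calls for that variant (named by sample).
#' @export
genotype_of <- function(gm, id) {
  j <- match(id, gm$variants$id)
  if (is.na(j)) stop("variant not found: ", id)
  gm$calls[, j]
}

#' Drop hidden (simulated causal) variants
#'
#' The synthetic-data generator carries unobserved causal variants as columns
#' flagged `hidden`; scans must never see them. This returns the observable
#' part of the matrix.
#'
#' @param gm a [geno_matrix()].
#' @return A `geno_matrix` without hidden columns.
#' @export
visible_variants <- function(gm) {
  keep <- !gm$variants$hidden
  gm[, which(keep)]
}
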