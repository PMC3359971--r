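#' Read genotypes from VCF or PLINK files
#'
#' VCF parsing is delegated to \pkg{VariantAnnotation}; PLINK binary triples
#' (`.bed`/`.bim`/`.fam`, SNP-major) are read natively. Multi-allelic VCF
#' records are skipped with a warning; missing genotypes (`./.`) become `NA`.
#'
#' @param path for `format = "vcf"` the VCF file; for `format = "plink-bed"`
#'   the path prefix of the `.bed`/`.bim`/`.fam` triple (with or without the
#'   `.bed` extension).
#' @param format `"vcf"` or `"plink-bed"`.
#' @return A [geno_matrix()] whose calls count copies of the counted allele:
#'   the ALT allele for VCF input, the A1 allele for PLINK input. The
#'   interaction F-test is invariant to which allele is counted.
#' @export
read_genotypes <- function(path, format = c("vcf", "plink-bed")) {
  format <- match.arg(format)
  switch(format,
         "vcf" = read_vcf_genotypes(path),
         "plink-bed" = read_plink(path))
}

read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "unknown"),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt > 1L
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped: ",
            paste(utils::head(names(vcf)[multi], 5), collapse = ", "))
    vcf <- vcf[!multi, ]
    alt <- alt[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT     # variants x samples, "0/0" etc.
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  alleles <- strsplit(gsub("\\|", "/", as.vector(gt)), "/", fixed = TRUE)
  dose <- vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    # counted-allele copies: ALT dosage (0/0 -> 0, 1/1 -> 2)
    sum(a == "1")
  }, integer(1))
  calls <- matrix(dose, nrow = nrow(gt), ncol = ncol(gt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    id = names(vcf),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(seq_along(alt), function(i) as.character(alt[[i]][1L]),
                 character(1)),
    stringsAsFactors = FALSE)
  geno_matrix(t(calls), variants, samples = colnames(gt))
}

#' Read imputed genotype posteriors from a VCF GP field
#'
#' @param path VCF with a `GP` FORMAT field holding per-genotype posterior
#'   probability triples (p0, p1, p2) ordered as REF-dosage 0/1/2.
#' @param info_scores optional named numeric vector of per-SNP imputation
#'   info scores; absent SNPs are treated as typed (info `NA`).
#' @return A `geno_posterior` object; see [geno_posterior()].
#' @export
read_vcf_posteriors <- function(path, info_scores = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gp <- VariantAnnotation::geno(vcf)$GP
  if (is.null(gp)) stop("VCF has no GP field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    id = names(vcf),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    stringsAsFactors = FALSE)
  # gp: variants x samples x 3 (or matrix-of-lists); normalize to array
  p <- array(NA_real_, dim = c(ncol(gp), nrow(gp), 3L))
  for (v in seq_len(nrow(gp))) for (s in seq_len(ncol(gp))) {
    trip <- unlist(gp[v, s])
    if (length(trip) == 3L) p[s, v, ] <- trip
  }
  info <- rep(NA_real_, nrow(variants))
  if (!is.null(info_scores))
    info <- unname(info_scores[variants$id])
  geno_posterior(p, variants, samples = colnames(gp), info = info)
}

#' Genotype posterior container
#'
#' @param p numeric array, individuals x variants x 3, each triple
#'   (p0, p1, p2) summing to 1.
#' @param variants variant metadata as in [geno_matrix()] (alleles optional).
#' @param samples individual IDs.
#' @param info per-variant imputation info score in `[0, 1]`, `NA` for typed.
#' @return Object of class `geno_posterior`.
#' @export
geno_posterior <- function(p, variants, samples, info = NULL) {
  stopifnot(length(dim(p)) == 3L, dim(p)[3] == 3L,
            dim(p)[1] == length(samples), dim(p)[2] == nrow(variants))
  sums <- apply(p, c(1, 2), sum)
  ok <- is.na(sums) | abs(sums - 1) < 1e-3
  if (!all(ok)) stop("posterior triples must sum to 1")
  if (any(p < -1e-9, na.rm = TRUE) || any(p > 1 + 1e-9, na.rm = TRUE))
    stop("posterior probabilities must lie in [0, 1]")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(info)) info <- rep(NA_real_, nrow(variants))
  variants$info <- info
  structure(list(p = p, variants = variants, samples = as.character(samples)),
            class = "geno_posterior")
}

# ---- PLINK binary triple -------------------------------------------------

#' Read a PLINK .bed/.bim/.fam triple
#'
#' SNP-major `.bed` only (magic bytes 0x6c 0x1b 0x01). Calls count copies of
#' the A1 allele from the `.bim` file.
#'
#' @param prefix path prefix (with or without `.bed`).
#' @return A [geno_matrix()].
#' @export
read_plink <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)
  bimt <- utils::read.table(bim, col.names = c("chrom", "id", "cm", "pos",
                                               "a1", "a2"),
                            colClasses = c("character", "character",
                                           "numeric", "numeric",
                                           "character", "character"))
  bimt$pos <- as.integer(round(bimt$pos))
  famt <- utils::read.table(fam)
  n <- nrow(famt); m <- nrow(bimt)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported: ", bed)
  bytes_per_snp <- ceiling(n / 4)
  if (length(raw) != 3L + bytes_per_snp * m)
    stop("bed file size inconsistent with .bim/.fam dimensions: ", bed)
  body <- raw[-(1:3)]
  # 2-bit codes per individual, little-endian within each byte:
  # 00 hom A1 (2 copies), 01 missing, 10 het, 11 hom A2 (0 copies)
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8L)
  codes <- bits[seq(1, 8, by = 2), , drop = FALSE] +
    2L * bits[seq(2, 8, by = 2), , drop = FALSE]
  codes <- matrix(as.vector(codes), nrow = bytes_per_snp * 4L, ncol = m)
  codes <- codes[seq_len(n), , drop = FALSE]
  calls <- matrix(c(2L, NA_integer_, 1L, 0L)[codes + 1L], nrow = n, ncol = m)
  variants <- data.frame(id = bimt$id, chrom = bimt$chrom, pos = bimt$pos,
                         ref = bimt$a1, alt = bimt$a2,
                         stringsAsFactors = FALSE)
  geno_matrix(calls, variants, samples = as.character(famt[[2]]))
}

#' Write a genotype matrix as a PLINK .bed/.bim/.fam triple
#'
#' @param gm a [geno_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  n <- length(gm$samples); m <- nrow(gm$variants)
  bimt <- data.frame(chrom = gm$variants$chrom, id = gm$variants$id, cm = 0,
                     pos = format(gm$variants$pos, scientific = FALSE,
                                  trim = TRUE),
                     a1 = if (!is.null(gm$variants$ref)) gm$variants$ref else "A",
                     a2 = if (!is.null(gm$variants$alt)) gm$variants$alt else "B")
  utils::write.table(bimt, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  famt <- data.frame(fid = gm$samples, iid = gm$samples, pat = 0, mat = 0,
                     sex = 0, pheno = -9)
  utils::write.table(famt, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  # genotype -> 2-bit code (see read_plink)
  code_of <- function(g) {
    out <- integer(length(g))
    out[is.na(g)] <- 1L
    out[!is.na(g) & g == 2L] <- 0L
    out[!is.na(g) & g == 1L] <- 2L
    out[!is.na(g) & g == 0L] <- 3L
    out
  }
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    codes <- code_of(gm$calls[, j])
    length(codes) <- bytes_per_snp * 4L          # pad with 0 (hom A1) bits
    codes[is.na(codes)] <- 0L
    cm <- matrix(codes, nrow = 4L)
    byte_vals <- cm[1, ] + 4L * cm[2, ] + 16L * cm[3, ] + 64L * cm[4, ]
    writeBin(as.raw(byte_vals), con)
  }
  invisible(prefix)
}

#' Read a delimited phenotype/covariate table
#'
#' Expects a header; the delimiter (tab or comma) is sniffed by
#' [data.table::fread()]. Typical columns: `sample_id`, `visit`, one column
#' per trait, `sex`, `age`, `bmi`, `plate`, a medication flag.
#'
#' @param path delimited text file.
#' @return A `data.frame`.
#' @export
read_pheno_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.data.frame(data.table::fread(path, header = TRUE))
}

#' Read a square kinship matrix from a text file
#'
#' Whitespace- or tab-delimited numeric square matrix; optional header row
#' and row-name column of sample IDs.
#'
#' @param path text file.
#' @return Numeric symmetric matrix.
#' @export
read_kinship <- function(path) {
  k <- as.matrix(utils::read.table(path, header = FALSE))
  if (!is.numeric(k[1, 1])) {  # header present
    k <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1))
  }
  storage.mode(k) <- "double"
  if (nrow(k) != ncol(k)) stop("kinship matrix must be square")
  if (max(abs(k - t(k))) > 1e-8) stop("kinship matrix must be symmetric")
  k
}
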