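#' Candidate SNP-pair set
#'
#' An ordered list of unordered SNP-id pairs with a provenance tag and the
#' Bonferroni denominator `m`. By design `m` counts the generated pairs
#' *before* per-cohort eligibility filtering (cell counts, pairwise r^2), so
#' that the correction matches the number of planned tests.
#'
#' @param snp1,snp2 character vectors of variant ids (pairwise).
#' @param provenance one of `"hits"`, `"ppi"`, `"pathway"`.
#' @return Object of class `pair_set`: data.frame `pairs` (snp1, snp2),
#'   `provenance`, `m`.
#' @export
pair_set <- function(snp1, snp2, provenance = c("hits", "ppi", "pathway")) {
  provenance <- match.arg(provenance)
  stopifnot(length(snp1) == length(snp2))
  keep <- snp1 != snp2
  a <- pmin(snp1[keep], snp2[keep]); b <- pmax(snp1[keep], snp2[keep])
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  pairs <- data.frame(snp1 = a[!dup], snp2 = b[!dup],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, provenance = provenance, m = nrow(pairs),
                 n_raw = length(snp1)),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set[%s]: %d unordered pairs (raw %d before de-dup)\n",
              x$provenance, x$m, x$n_raw))
  invisible(x)
}

#' Number of unordered pairs among n items
#'
#' Computed in double precision so genome-scale counts (e.g. all pairs among
#' millions of SNPs) do not overflow integer arithmetic.
#'
#' @param n number of items.
#' @return `n * (n - 1) / 2` as a double.
#' @export
n_pairs <- function(n) n * (n - 1) / 2

#' All pairs among a list of GWAS-hit SNPs
#'
#' @param snp_ids character vector of unique rsIDs.
#' @return A [pair_set()] with `m = n(n-1)/2`.
#' @export
pairs_from_hits <- function(snp_ids) {
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids in hit list")
  n <- length(snp_ids)
  if (n < 2) stop("need at least two SNPs")
  idx <- utils::combn(n, 2)
  pair_set(snp_ids[idx[1, ]], snp_ids[idx[2, ]], provenance = "hits")
}

#' Map SNPs to genes with a flank
#'
#' A SNP belongs to a gene iff `start - flank <= pos <= end + flank`
#' (inclusive both ends); a SNP may map to several genes. Flanks are purely
#' positional — gene orientation is ignored.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based).
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive); see [read_gene_intervals()].
#' @param flank flank size in bp (default 5000).
#' @return Named list: for each gene symbol, the character vector of mapped
#'   SNP ids (possibly empty).
#' @export
map_snps_to_genes <- function(variants, genes, flank = 5000) {
  stopifnot(all(c("id", "chrom", "pos") %in% names(variants)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene
  for (i in seq_len(nrow(genes))) {
    hit <- variants$chrom == genes$chrom[i] &
      variants$pos >= genes$start[i] - flank &
      variants$pos <= genes$end[i] + flank
    out[[i]] <- variants$id[hit]
  }
  out
}

#' Read gene intervals from BED or a 1-based 4-column table
#'
#' BED input (`.bed` extension or `format = "bed"`) is 0-based half-open and
#' converted to 1-based inclusive; otherwise a header-less table
#' `gene chrom start end` (1-based inclusive) is expected.
#'
#' @param path annotation file.
#' @param format `"auto"`, `"bed"` or `"table"`.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "table")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "table"
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (format == "bed") {
    data.frame(gene = tab[[4]], chrom = as.character(tab[[1]]),
               start = tab[[2]] + 1L, end = tab[[3]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = tab[[1]], chrom = as.character(tab[[2]]),
               start = tab[[3]], end = tab[[4]], stringsAsFactors = FALSE)
  }
}

#' Cross-gene SNP pairs from a gene-interaction (PPI) list
#'
#' For each gene pair, every SNP mapped to the first gene is paired with
#' every SNP mapped to the second (n1 x n2 tests per gene pair);
#' self-pairs (a SNP mapped to both genes) are removed and pairs repeated
#' across gene pairs are counted once.
#'
#' @param gene_pairs data.frame or 2-column matrix of gene symbol pairs.
#' @param mapping gene-to-SNP mapping from [map_snps_to_genes()].
#' @return A [pair_set()] with provenance `"ppi"`; `n_raw` carries the raw
#'   (pre-de-duplication) cross-product count.
#' @export
pairs_from_gene_pairs <- function(gene_pairs, mapping) {
  gene_pairs <- as.data.frame(gene_pairs, stringsAsFactors = FALSE)
  s1 <- character(0); s2 <- character(0)
  for (i in seq_len(nrow(gene_pairs))) {
    ga <- as.character(gene_pairs[i, 1]); gb <- as.character(gene_pairs[i, 2])
    if (!ga %in% names(mapping) || !gb %in% names(mapping)) {
      warning("gene pair skipped (absent from mapping): ", ga, " - ", gb)
      next
    }
    a <- mapping[[ga]]; b <- mapping[[gb]]
    if (!length(a) || !length(b)) next
    grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    s1 <- c(s1, grid$a); s2 <- c(s2, grid$b)
  }
  if (!length(s1)) stop("no SNP pairs generated from gene pairs")
  pair_set(s1, s2, provenance = "ppi")
}

#' All SNP pairs within a pathway gene set
#'
#' @param genes character vector of gene symbols in the set.
#' @param mapping gene-to-SNP mapping from [map_snps_to_genes()].
#' @return A [pair_set()] with provenance `"pathway"`: all unordered pairs
#'   among the union of SNPs mapped to any gene in the set.
#' @export
pairs_from_gene_set <- function(genes, mapping) {
  snps <- unique(unlist(mapping[intersect(genes, names(mapping))]))
  if (length(snps) < 2) stop("gene-set SNP union has fewer than two SNPs")
  idx <- utils::combn(length(snps), 2)
  pair_set(snps[idx[1, ]], snps[idx[2, ]], provenance = "pathway")
}
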