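#' Sites-by-samples genotype matrix
#'
#' The central container of the package: biallelic SNP calls for a cohort on
#' one chromosome, stored as diploid-style allele dosages. Haploid males are
#' stored exactly like diploid homozygotes (`0/0` or `1/1`), matching how
#' joint variant callers emit them; a truly heterozygous call in a haploid is
#' therefore a duplication signal, not a genotype.
#'
#' @param gt integer matrix, sites x samples; entries 0 (`0/0`), 1 (`0/1`),
#'   2 (`1/1`) or `NA` (`./.`).
#' @param dp integer matrix of per-genotype read depths, same dimensions.
#' @param chrom single chromosome name.
#' @param pos 1-based positions, one per row of `gt`, strictly increasing.
#' @param ref,alt single-base reference and alternative alleles per site.
#' @param qual per-site phred-scaled call quality.
#' @param samples sample identifiers, one per column of `gt`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(gt, dp, chrom, pos, ref, alt, qual, samples) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (is.null(dp)) stop("genotype matrix requires per-genotype depth ('dp')")
  dp <- as.matrix(dp)
  storage.mode(dp) <- "integer"
  n_sites <- nrow(gt)
  n_samples <- ncol(gt)
  stopifnot(
    identical(dim(dp), dim(gt)),
    length(chrom) == 1L,
    length(pos) == n_sites,
    length(ref) == n_sites,
    length(alt) == n_sites,
    length(qual) == n_sites,
    length(samples) == n_samples
  )
  if (any(!is.na(gt) & (gt < 0L | gt > 2L))) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  if (n_sites > 1L && any(diff(pos) <= 0L)) {
    stop("positions must be strictly increasing")
  }
  dimnames(gt) <- list(NULL, samples)
  dimnames(dp) <- list(NULL, samples)
  structure(
    list(gt = gt, dp = dp, chrom = as.character(chrom),
         pos = as.integer(pos), ref = as.character(ref),
         alt = as.character(alt), qual = as.numeric(qual),
         samples = as.character(samples)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic SNP sites x %d samples on %s\n",
              nrow(x$gt), ncol(x$gt), x$chrom))
  if (nrow(x$gt) > 0L) {
    cat(sprintf("  positions %d-%d; missing calls: %.2f%%\n",
                min(x$pos), max(x$pos), 100 * mean(is.na(x$gt))))
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$gt)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param gm a [genotype_matrix()].
#' @param sites logical or integer index over rows (sites).
#' @param samples logical, integer or character index over columns.
#' @return the subset `genotype_matrix`; site order is preserved.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(sites)) sites <- seq_len(nrow(gm$gt))
  if (is.null(samples)) samples <- seq_len(ncol(gm$gt))
  if (is.character(samples)) samples <- match(samples, gm$samples)
  genotype_matrix(
    gt = gm$gt[sites, samples, drop = FALSE],
    dp = gm$dp[sites, samples, drop = FALSE],
    chrom = gm$chrom,
    pos = gm$pos[sites],
    ref = gm$ref[sites],
    alt = gm$alt[sites],
    qual = gm$qual[sites],
    samples = gm$samples[samples]
  )
}

## allele counting used by QC and F_IS: alt allele count, called allele count
gm_allele_counts <- function(gm) {
  called <- !is.na(gm$gt)
  list(
    alt = rowSums(gm$gt, na.rm = TRUE),
    n_alleles = 2L * rowSums(called),
    n_het = rowSums(gm$gt == 1L, na.rm = TRUE),
    n_called = rowSums(called)
  )
}
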