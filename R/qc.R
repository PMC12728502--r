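#' Site- and sample-level filtering thresholds
#'
#' Defaults reproduce the standard hard-filter set for joint-called SNP
#' matrices: biallelic SNPs only, site quality >= 20, genotypes with depth
#' < 3 set missing, non-reference allele count >= 5, minor allele count
#' >= 5, at least 60% of samples called, sites heterozygous in more than
#' 90% of samples removed, and samples missing >= 10% of called sites
#' excluded.
#'
#' @param min_site_qual minimum phred site quality (QUAL) kept.
#' @param min_genotype_depth genotypes below this depth are set missing
#'   before any count-based rule.
#' @param min_nonref_allele_count minimum alternative allele count over
#'   non-missing genotypes.
#' @param min_minor_allele_count minimum count of the rarer allele.
#' @param min_nonmissing_fraction minimum fraction of samples with a call.
#' @param max_het_sample_fraction sites heterozygous in strictly more than
#'   this fraction of samples are removed.
#' @param max_sample_missing_fraction samples with missingness at or above
#'   this fraction are excluded.
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_site_qual = 20,
                              min_genotype_depth = 3,
                              min_nonref_allele_count = 5,
                              min_minor_allele_count = 5,
                              min_nonmissing_fraction = 0.6,
                              max_het_sample_fraction = 0.9,
                              max_sample_missing_fraction = 0.10) {
  th <- list(min_site_qual = min_site_qual,
             min_genotype_depth = min_genotype_depth,
             min_nonref_allele_count = min_nonref_allele_count,
             min_minor_allele_count = min_minor_allele_count,
             min_nonmissing_fraction = min_nonmissing_fraction,
             max_het_sample_fraction = max_het_sample_fraction,
             max_sample_missing_fraction = max_sample_missing_fraction)
  stopifnot(th$min_nonmissing_fraction >= 0, th$min_nonmissing_fraction <= 1,
            th$max_het_sample_fraction >= 0, th$max_het_sample_fraction <= 1,
            th$max_sample_missing_fraction >= 0,
            th$max_sample_missing_fraction <= 1,
            th$min_nonref_allele_count >= 0, th$min_minor_allele_count >= 0)
  structure(th, class = "filter_thresholds")
}

#' Site-level filtering
#'
#' Applies, in order: removal of non-biallelic-SNP records (and of records
#' with a non-PASS FILTER value when one is present), setting genotypes
#' below the depth threshold to missing, then the count-based site rules
#' (site quality, non-reference allele count, minor allele count,
#' non-missing fraction) and finally removal of sites heterozygous in more
#' than `max_het_sample_fraction` of all samples. Site order is preserved;
#' an empty input returns an empty output. A per-rule removal report is
#' attached as attribute `"qc_report"`.
#'
#' @param gm a [genotype_matrix()].
#' @param th a [filter_thresholds()].
#' @return the filtered `genotype_matrix`.
#' @export
filter_sites <- function(gm, th = filter_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(th, "filter_thresholds"))
  n_samples <- ncol(gm$gt)
  report <- list()

  biallelic <- !grepl(",", gm$alt, fixed = TRUE) &
    nchar(gm$ref) == 1L & nchar(gm$alt) == 1L &
    gm$ref %in% c("A", "C", "G", "T") & gm$alt %in% c("A", "C", "G", "T")
  filt <- attr(gm, "filter")
  if (!is.null(filt)) {
    biallelic <- biallelic & (filt %in% c("PASS", "."))
  }
  report$not_biallelic_snp <- sum(!biallelic)
  gm <- gm_subset(gm, sites = biallelic)

  low_dp <- !is.na(gm$dp) & gm$dp < th$min_genotype_depth
  low_dp[is.na(gm$dp)] <- TRUE
  report$genotypes_set_missing_low_depth <- sum(low_dp & !is.na(gm$gt))
  gm$gt[low_dp] <- NA_integer_

  if (nrow(gm$gt) == 0L) {
    attr(gm, "qc_report") <- report
    return(gm)
  }

  ## fraction rules compare exact rationals; the 1e-9 slack keeps binary
  ## floating point from misclassifying counts that sit exactly on the bound
  ac <- gm_allele_counts(gm)
  qual_ok <- !is.na(gm$qual) & gm$qual >= th$min_site_qual
  nonref_ok <- ac$alt >= th$min_nonref_allele_count
  mac <- pmin(ac$alt, ac$n_alleles - ac$alt)
  mac_ok <- mac >= th$min_minor_allele_count
  miss_ok <- (ac$n_called / n_samples) >= th$min_nonmissing_fraction - 1e-9
  het_ok <- (ac$n_het / n_samples) <= th$max_het_sample_fraction + 1e-9

  report$low_qual <- sum(!qual_ok)
  report$low_nonref_allele_count <- sum(qual_ok & !nonref_ok)
  report$low_minor_allele_count <- sum(qual_ok & nonref_ok & !mac_ok)
  report$too_missing <- sum(qual_ok & nonref_ok & mac_ok & !miss_ok)
  report$excess_heterozygosity <-
    sum(qual_ok & nonref_ok & mac_ok & miss_ok & !het_ok)

  keep <- qual_ok & nonref_ok & mac_ok & miss_ok & het_ok
  out <- gm_subset(gm, sites = keep)
  report$sites_kept <- nrow(out$gt)
  attr(out, "qc_report") <- report
  out
}

#' Sample-level filtering
#'
#' Excludes samples whose missing-genotype fraction is at or above
#' `max_sample_missing_fraction` (inclusive bound), after site filtering.
#'
#' @param gm a site-filtered [genotype_matrix()].
#' @param th a [filter_thresholds()].
#' @return list with elements `gm` (column-subset matrix) and `excluded`
#'   (ids of removed samples).
#' @export
filter_samples <- function(gm, th = filter_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$gt) == 0L) {
    return(list(gm = gm, excluded = character(0)))
  }
  miss <- colMeans(is.na(gm$gt))
  drop <- miss >= th$max_sample_missing_fraction - 1e-9
  list(gm = gm_subset(gm, samples = !drop), excluded = gm$samples[drop])
}
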