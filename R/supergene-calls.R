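#' Genotype a cohort at the supergene
#'
#' The full genotyping stage: per-sample inbreeding coefficients identify
#' highly heterozygous diploid workers (M/P carriers, `F_IS` strictly below
#' the threshold); a windowed heterozygosity scan over the carriers
#' delimits the supergene region; sites heterozygous in every called
#' carrier (with missingness below `max_missing_carriers`) form the
#' trans-species haplotype-specific SNP panel; and every sample is then
#' assigned a genotype class from its genotype proportions over that panel.
#' Diploid F_IS carriers keep the class `MP` regardless of the proportion
#' rule (the two agree on clean data).
#'
#' @param gm a [genotype_matrix()] (typically after [filter_sites()] and
#'   [filter_samples()]).
#' @param meta sample metadata with columns `id`, `species`, `ploidy`.
#' @param fis_threshold M/P carriers satisfy `F_IS <` this value (strict).
#' @param window_size heterozygosity scan window in bp.
#' @param max_missing_carriers missing tolerance for the trans-specific
#'   panel (strict `<`).
#' @param majority majority threshold for proportion-based assignment.
#' @param min_fold,min_run region-delimitation parameters
#'   (see [delimit_region()]).
#' @param chrom_length chromosome length for window tiling.
#' @return an object of class `supergene_calls` with elements `calls` (per
#'   sample data frame), `fis`, `carriers`, `scan`, `region`, `hset` and
#'   `params`.
#' @export
supergene_genotype <- function(gm, meta,
                               fis_threshold = -0.5,
                               window_size = 20000L,
                               max_missing_carriers = 0.2,
                               majority = 0.8,
                               min_fold = 5, min_run = 3L,
                               chrom_length = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  meta <- meta[match(gm$samples, meta$id), , drop = FALSE]
  if (anyNA(meta$id)) {
    stop("metadata missing for samples: ",
         paste(setdiff(gm$samples, meta$id), collapse = ", "))
  }
  fis <- compute_fis(gm)
  diploid <- gm$samples[meta$ploidy == 2L]
  carriers <- intersect(classify_by_fis(fis, fis_threshold), diploid)
  if (!length(carriers)) {
    stop("no diploid sample has F_IS below ", fis_threshold,
         "; cannot define the trans-species haplotype-specific panel")
  }
  scan <- window_het_scan(gm, carriers, window_size, chrom_length)
  region <- delimit_region(scan, min_fold = min_fold, min_run = min_run)
  hset <- extract_trans_specific(gm, carriers, max_missing_carriers)
  if (!length(hset$positions)) {
    stop("no trans-species haplotype-specific SNPs found for the carrier panel")
  }
  calls <- classify_by_proportions(gm, hset, gm$samples, meta$ploidy,
                                   majority)
  calls$f_is <- unname(fis[calls$sample_id])
  calls$species <- meta$species
  calls$ploidy <- meta$ploidy
  is_carrier <- calls$sample_id %in% carriers
  calls$assigned_class[is_carrier] <- "MP"
  calls <- calls[, c("sample_id", "species", "ploidy", "f_is",
                     "n_sites_used", "p00", "p01", "p11", "missing",
                     "assigned_class", "dup_flag", "reason")]
  structure(list(
    calls = calls, fis = fis, carriers = carriers, scan = scan,
    region = region, hset = hset,
    params = list(fis_threshold = fis_threshold, window_size = window_size,
                  max_missing_carriers = max_missing_carriers,
                  majority = majority, min_fold = min_fold,
                  min_run = min_run)
  ), class = "supergene_calls")
}

#' @export
print.supergene_calls <- function(x, ...) {
  cat("Supergene genotyping\n")
  cat(sprintf("  %d samples; %d M/P carriers (F_IS < %g)\n",
              nrow(x$calls), length(x$carriers), x$params$fis_threshold))
  cat(sprintf("  trans-species haplotype-specific SNPs: %d\n",
              length(x$hset$positions)))
  if (length(x$region)) {
    cat(sprintf("  supergene region: %s:%d-%d (%.2f Mb)\n", x$scan$chrom,
                x$region[1], x$region[2], diff(x$region) / 1e6))
  } else {
    cat("  supergene region: not delimited\n")
  }
  cat("  class counts:\n")
  print(table(x$calls$assigned_class))
  invisible(x)
}

#' @export
summary.supergene_calls <- function(object, ...) {
  tab <- table(object$calls$species, object$calls$assigned_class)
  out <- list(class_by_species = tab, region = object$region,
              n_hset = length(object$hset$positions),
              carriers = object$carriers)
  class(out) <- "summary.supergene_calls"
  out
}

#' @export
print.summary.supergene_calls <- function(x, ...) {
  cat("Genotype classes by species:\n")
  print(x$class_by_species)
  if (length(x$region)) {
    cat(sprintf("\nSupergene region: %d-%d bp\n", x$region[1], x$region[2]))
  }
  cat(sprintf("Trans-species haplotype-specific SNPs: %d\n", x$n_hset))
  invisible(x)
}

#' @export
as.data.frame.supergene_calls <- function(x, ...) x$calls

#' Plot the heterozygosity scan and per-sample F_IS
#'
#' Two base-graphics panels: the carrier-group mean heterozygote count per
#' window with the delimited region shaded, and per-sample F_IS with the
#' carrier threshold.
#'
#' @param x a [supergene_genotype()] result.
#' @param ... ignored.
#' @export
plot.supergene_calls <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  mid <- (x$scan$window_start + x$scan$window_end) / 2e6
  graphics::plot(mid, x$scan$mean, type = "l",
                 xlab = sprintf("%s position (Mb)", x$scan$chrom),
                 ylab = "mean het SNPs / window",
                 main = "Carrier heterozygosity scan")
  if (length(x$region)) {
    graphics::rect(x$region[1] / 1e6, 0, x$region[2] / 1e6,
                   max(x$scan$mean), col = grDevices::adjustcolor("grey", 0.4),
                   border = NA)
    graphics::lines(mid, x$scan$mean)
  }
  f <- x$calls$f_is
  graphics::plot(seq_along(f), f, pch = 19,
                 col = ifelse(x$calls$assigned_class == "MP", "red", "black"),
                 xlab = "sample", ylab = expression(F[IS]),
                 main = "Inbreeding coefficients")
  graphics::abline(h = x$params$fis_threshold, lty = 2)
  invisible(x)
}
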