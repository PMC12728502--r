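#' Per-sample inbreeding coefficients (F_IS)
#'
#' Method-of-moments estimator with finite-sample correction, as used for
#' per-individual heterozygosity screens on joint-called cohorts:
#' \deqn{F = (O_{hom} - E_{hom}) / (N - E_{hom})}
#' where, for a sample, \eqn{O_{hom}} is its observed count of homozygous
#' calls over its \eqn{N} non-missing sites and
#' \eqn{E_{hom} = \sum_i [1 - 2 p_i (1 - p_i) \, n_i/(n_i - 1)]}
#' uses the cohort alternative-allele frequency \eqn{p_i} and the number of
#' called alleles \eqn{n_i} at site i. Sites with fewer than 2 called
#' alleles are skipped. Strongly negative values flag samples heterozygous
#' far in excess of Hardy-Weinberg expectation, e.g. carriers of a long
#' non-recombining heterozygous tract such as an M/P supergene genotype.
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @param sample_id optional single sample id; default returns all samples.
#' @return named numeric vector of F values (`NA` with a warning where the
#'   denominator is zero).
#' @export
compute_fis <- function(gm, sample_id = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$gt) < 2L) {
    stop("F_IS needs cohort allele frequencies: at least 2 samples required")
  }
  ac <- gm_allele_counts(gm)
  usable <- ac$n_alleles >= 2L
  p <- ifelse(usable, ac$alt / ac$n_alleles, NA_real_)
  e_hom <- ifelse(usable,
                  1 - 2 * p * (1 - p) * ac$n_alleles / (ac$n_alleles - 1L),
                  0)
  called <- !is.na(gm$gt) & usable
  hom <- called & (gm$gt == 0L | gm$gt == 2L)
  n <- colSums(called)
  o_hom <- colSums(hom)
  e <- colSums(called * e_hom)
  denom <- n - e
  f <- ifelse(denom == 0, NA_real_, (o_hom - e) / denom)
  names(f) <- gm$samples
  if (anyNA(f)) {
    warning("F_IS undefined (zero denominator) for: ",
            paste(gm$samples[is.na(f)], collapse = ", "))
  }
  if (!is.null(sample_id)) {
    if (!sample_id %in% gm$samples) stop("unknown sample: ", sample_id)
    f <- f[sample_id]
  }
  f
}

#' Provisional M/P carriers from F_IS
#'
#' @param fis named F_IS vector from [compute_fis()].
#' @param het_threshold carriers satisfy `fis < het_threshold` (strict).
#' @return character vector of carrier sample ids.
#' @export
classify_by_fis <- function(fis, het_threshold = -0.5) {
  names(fis)[!is.na(fis) & fis < het_threshold]
}

#' Windowed heterozygous-SNP scan
#'
#' Counts heterozygous calls per carrier in non-overlapping windows tiling
#' the chromosome from position 1 (`[k w + 1, (k+1) w]` in 1-based
#' coordinates; the last partial window is retained).
#'
#' @param gm a [genotype_matrix()].
#' @param carriers sample ids whose heterozygosity is profiled.
#' @param window_size window width in bp (default 20 kb).
#' @param chrom_length chromosome length; defaults to the last site position.
#' @return a `region_scan` object: window bounds, per-carrier count matrix
#'   and the carrier-group mean per window.
#' @export
window_het_scan <- function(gm, carriers, window_size = 20000L,
                            chrom_length = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (window_size <= 0) stop("window_size must be positive")
  if (!length(carriers)) stop("carrier set is empty")
  missing_ids <- setdiff(carriers, gm$samples)
  if (length(missing_ids)) {
    stop("unknown carriers: ", paste(missing_ids, collapse = ", "))
  }
  if (is.null(chrom_length)) chrom_length <- max(gm$pos, 1L)
  n_win <- as.integer((chrom_length - 1L) %/% window_size + 1L)
  win <- as.integer((gm$pos - 1L) %/% window_size + 1L)
  het <- gm$gt[, carriers, drop = FALSE] == 1L
  het[is.na(het)] <- FALSE
  counts <- matrix(0L, nrow = n_win, ncol = length(carriers),
                   dimnames = list(NULL, carriers))
  agg <- rowsum(het + 0L, group = win)
  counts[as.integer(rownames(agg)), ] <- agg
  structure(list(
    chrom = gm$chrom, window_size = as.integer(window_size),
    window_start = (seq_len(n_win) - 1L) * as.integer(window_size) + 1L,
    window_end = pmin(seq_len(n_win) * as.integer(window_size),
                      as.integer(chrom_length)),
    counts = counts, mean = rowMeans(counts)
  ), class = "region_scan")
}

#' @export
print.region_scan <- function(x, ...) {
  cat(sprintf("region_scan: %d windows of %d bp on %s, %d carriers\n",
              length(x$mean), x$window_size, x$chrom, ncol(x$counts)))
  invisible(x)
}

#' Delimit the supergene region from a heterozygosity scan
#'
#' Finds the longest run of consecutive windows whose carrier-group mean
#' heterozygote count exceeds `min_fold` times the median count of the
#' windows outside the run, iterating run and threshold to a fixed point
#' (the first pass uses the lower quartile as the background level, since
#' the elevated region may span half the chromosome). Window counts are
#' noisy, so the run is made robust the way peak callers are: interior gaps
#' of at most `max_gap` below-threshold windows are closed, and the run
#' edges are extended by hysteresis while neighbouring windows stay above
#' half the fold threshold. Runs shorter than `min_run` windows are
#' ignored; ties on length keep the leftmost run.
#'
#' @param scan a [window_het_scan()] result.
#' @param min_fold fold-over-background threshold.
#' @param min_run minimum run length in windows.
#' @param max_gap longest interior dip (in windows) absorbed into a run.
#' @return `c(start, end)` in bp (outer bounds of the run), or `integer(0)`
#'   with a warning when no window exceeds the threshold.
#' @export
delimit_region <- function(scan, min_fold = 5, min_run = 3L, max_gap = 3L) {
  stopifnot(inherits(scan, "region_scan"))
  v <- scan$mean
  n <- length(v)
  run <- integer(0)
  for (iter in 1:20) {
    bg <- if (length(run)) {
      stats::median(v[-run])
    } else {
      stats::quantile(v, 0.25, names = FALSE)
    }
    above <- v > min_fold * bg
    if (!any(above)) {
      warning("no window exceeds the fold threshold; empty region")
      return(integer(0))
    }
    ## close interior gaps of <= max_gap windows
    r <- rle(above)
    if (length(r$lengths) > 2L) {
      interior <- seq_along(r$values)[-c(1L, length(r$values))]
      short_gap <- interior[!r$values[interior] &
                              r$lengths[interior] <= max_gap]
      r$values[short_gap] <- TRUE
      above <- inverse.rle(r)
      r <- rle(above)
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values & r$lengths >= min_run)
    if (!length(cand)) {
      warning("no run of at least ", min_run,
              " windows exceeds the fold threshold; empty region")
      return(integer(0))
    }
    best <- cand[which.max(r$lengths[cand])]
    lo <- starts[best]; hi <- ends[best]
    ## hysteresis: extend edges while neighbours clear half the threshold
    while (lo > 1L && v[lo - 1L] > min_fold / 2 * bg) lo <- lo - 1L
    while (hi < n && v[hi + 1L] > min_fold / 2 * bg) hi <- hi + 1L
    new_run <- lo:hi
    if (identical(new_run, run)) break
    run <- new_run
  }
  c(scan$window_start[run[1L]], scan$window_end[run[length(run)]])
}

#' Extract trans-species haplotype-specific SNPs
#'
#' A site is kept iff every non-missing carrier genotype is heterozygous
#' (`0/1`), at least one carrier is called, and the missing fraction among
#' carriers is strictly below `max_missing`.
#'
#' @param gm a [genotype_matrix()].
#' @param carriers M/P carrier sample ids (the defining panel).
#' @param max_missing maximum tolerated missing fraction among carriers
#'   (strict `<`).
#' @return a `haplotype_specific_set`: ordered site positions plus the
#'   defining carrier panel.
#' @export
extract_trans_specific <- function(gm, carriers, max_missing = 0.2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!length(carriers)) stop("carrier set is empty")
  sub <- gm$gt[, carriers, drop = FALSE]
  called <- !is.na(sub)
  n_called <- rowSums(called)
  n_het <- rowSums(sub == 1L, na.rm = TRUE)
  ## strict "< max_missing" on the exact fraction (1e-9 slack guards the
  ## binary representation of bounds like 1/5 vs 0.2)
  miss_frac <- 1 - n_called / length(carriers)
  keep <- n_called > 0L & n_het == n_called &
    miss_frac < max_missing - 1e-9
  structure(list(positions = gm$pos[keep], carriers = carriers,
                 max_missing = max_missing),
            class = "haplotype_specific_set")
}

#' @export
print.haplotype_specific_set <- function(x, ...) {
  cat(sprintf(
    "haplotype_specific_set: %d trans-species SNPs (panel of %d carriers, missing < %.0f%%)\n",
    length(x$positions), length(x$carriers), 100 * x$max_missing))
  invisible(x)
}

#' Genotype-class assignment from trans-species SNP proportions
#'
#' Computes the proportions of reference-homozygous (`p00`), heterozygous
#' (`p01`) and alternative-homozygous (`p11`) calls over the
#' haplotype-specific sites (denominators include missing calls, so
#' `p00 + p01 + p11 + missing = 1`), then assigns a class by majority rule
#' on the non-missing renormalized proportions: reference-homozygous
#' majority gives `MM` (diploid) or `hapM` (haploid); alternative-homozygous
#' majority gives `PP` or `hapP`; heterozygous majority gives `MP` for a
#' diploid and, for a haploid, `hapP` with a duplication flag (a haploid
#' cannot be truly heterozygous). Samples with fewer than 50% of the sites
#' called are `ambiguous`.
#'
#' @param gm a [genotype_matrix()].
#' @param hset a [extract_trans_specific()] result.
#' @param sample sample id (or ids; vectorized).
#' @param ploidy 1 or 2, recycled along `sample`.
#' @param majority majority threshold on renormalized proportions.
#' @return data frame with one row per sample: `sample_id`, `n_sites_used`,
#'   `p00`, `p01`, `p11`, `missing`, `assigned_class`, `dup_flag`, `reason`.
#' @export
classify_by_proportions <- function(gm, hset, sample, ploidy,
                                    majority = 0.8) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(hset, "haplotype_specific_set"))
  if (!length(hset$positions)) stop("haplotype-specific set is empty")
  idx <- match(hset$positions, gm$pos)
  if (anyNA(idx)) stop("haplotype-specific positions absent from matrix")
  ploidy <- rep(ploidy, length.out = length(sample))
  n_h <- length(idx)
  out <- lapply(seq_along(sample), function(k) {
    g <- gm$gt[idx, sample[k]]
    n_called <- sum(!is.na(g))
    p00 <- sum(g == 0L, na.rm = TRUE) / n_h
    p01 <- sum(g == 1L, na.rm = TRUE) / n_h
    p11 <- sum(g == 2L, na.rm = TRUE) / n_h
    missing <- 1 - n_called / n_h
    cls <- "ambiguous"; flag <- FALSE; reason <- NA_character_
    if (n_called / n_h < 0.5) {
      reason <- "more than 50% of haplotype-specific sites missing"
    } else {
      q <- c(p00, p01, p11) / (n_called / n_h)
      hap <- ploidy[k] == 1L
      if (q[1] >= majority) {
        cls <- if (hap) "hapM" else "MM"
      } else if (q[3] >= majority) {
        cls <- if (hap) "hapP" else "PP"
      } else if (q[2] >= majority) {
        if (hap) { cls <- "hapP"; flag <- TRUE } else cls <- "MP"
      } else {
        reason <- "no genotype class reaches the majority threshold"
      }
    }
    data.frame(sample_id = sample[k], n_sites_used = n_called,
               p00 = p00, p01 = p01, p11 = p11, missing = missing,
               assigned_class = cls, dup_flag = flag, reason = reason)
  })
  do.call(rbind, out)
}
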