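#' Per-sample mutation-load summary
#'
#' Restricts to sites inside `region` where the sample carries at least one
#' alternative allele (the per-sample minor-allele-count-1 extraction) and
#' whose predicted impact is `high`, `moderate` or `low`, and reports the
#' counts and proportions over those three categories. With no qualifying
#' SNP the proportions are returned missing.
#'
#' @param gm a [genotype_matrix()].
#' @param effects per-site effect table from [classify_effects()].
#' @param sample sample id (vectorized; see also [load_summaries()]).
#' @param region `c(start, end)` in bp, 1-based inclusive.
#' @return data frame per sample: counts `n_high`, `n_moderate`, `n_low`
#'   and proportions `p_high`, `p_moderate`, `p_low`.
#' @export
per_sample_load <- function(gm, effects, sample, region) {
  stopifnot(inherits(gm, "genotype_matrix"), length(region) == 2L)
  imp <- effects$impact[match(gm$pos, effects$pos)]
  in_region <- gm$pos >= region[1] & gm$pos <= region[2]
  qualifying <- in_region & imp %in% c("high", "moderate", "low")
  out <- lapply(sample, function(s) {
    g <- gm$gt[, s]
    carried <- qualifying & !is.na(g) & g >= 1L
    n <- c(high = sum(carried & imp == "high"),
           moderate = sum(carried & imp == "moderate"),
           low = sum(carried & imp == "low"))
    tot <- sum(n)
    p <- if (tot > 0L) n / tot else c(high = NA_real_, moderate = NA_real_,
                                      low = NA_real_)
    data.frame(sample_id = s, n_high = n[["high"]],
               n_moderate = n[["moderate"]], n_low = n[["low"]],
               n_total = tot, p_high = p[["high"]],
               p_moderate = p[["moderate"]], p_low = p[["low"]])
  })
  do.call(rbind, out)
}

#' Load summaries for a set of samples
#' @inheritParams per_sample_load
#' @param samples sample ids.
#' @param classes optional named class vector added as a column.
#' @return row-bound [per_sample_load()] results.
#' @export
load_summaries <- function(gm, effects, samples, region, classes = NULL) {
  out <- per_sample_load(gm, effects, samples, region)
  if (!is.null(classes)) out$class <- unname(classes[out$sample_id])
  out
}

#' Contrast load proportions between genotype groups
#'
#' Two-sided Wilcoxon rank-sum test on per-sample impact proportions,
#' group 1 (e.g. M/M workers) versus group 2 (e.g. M/P workers); the
#' reported `W` is the test statistic of group 1. Samples with undefined
#' proportions are dropped.
#'
#' @param summaries a [load_summaries()] data frame.
#' @param group1,group2 sample id sets.
#' @param category `"high"`, `"moderate"` or `"low"`.
#' @return list: `W`, `p`, `n1`, `n2`, `category`, group medians.
#' @export
contrast_load <- function(summaries, group1, group2, category = "high") {
  stopifnot(category %in% c("high", "moderate", "low"))
  if (!length(group1) || !length(group2)) {
    stop("both contrast groups must be non-empty")
  }
  col <- paste0("p_", category)
  x <- summaries[[col]][match(group1, summaries$sample_id)]
  y <- summaries[[col]][match(group2, summaries$sample_id)]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop("a contrast group has no sample with defined load proportions")
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value, n1 = length(x),
       n2 = length(y), category = category,
       median1 = stats::median(x), median2 = stats::median(y))
}
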