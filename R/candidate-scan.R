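#' Per-gene P-specific SNP counts
#'
#' A trans-species CDS site counts as "P-specific" in a sample when its
#' genotype is heterozygous or alternative-homozygous; missing genotypes
#' contribute nothing. Every gene appears in the output, including genes
#' with no trans-species CDS site (count 0).
#'
#' @param gm a [genotype_matrix()].
#' @param hset a [extract_trans_specific()] result.
#' @param genes a [gene_models()] table used to map sites to CDS.
#' @param samples sample ids (default all).
#' @return integer matrix, genes x samples, with attribute `"n_sites"`
#'   giving the number of trans-species CDS sites per gene.
#' @export
count_p_specific <- function(gm, hset, genes, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(hset, "haplotype_specific_set"))
  if (is.null(samples)) samples <- gm$samples
  gene_ids <- unique(genes$gene_id)
  idx <- build_cds_index(genes)
  row <- match(hset$positions, idx$site$pos)
  in_cds <- !is.na(row)
  site_gene <- idx$site$gene_id[row[in_cds]]
  site_pos <- hset$positions[in_cds]
  counts <- matrix(0L, nrow = length(gene_ids), ncol = length(samples),
                   dimnames = list(gene_ids, samples))
  n_sites <- stats::setNames(integer(length(gene_ids)), gene_ids)
  if (length(site_pos)) {
    g <- gm$gt[match(site_pos, gm$pos), samples, drop = FALSE]
    p_spec <- (!is.na(g) & g >= 1L) + 0L
    agg <- rowsum(p_spec, group = site_gene)
    counts[rownames(agg), ] <- agg
    tab <- table(site_gene)
    n_sites[names(tab)] <- as.integer(tab)
  }
  attr(counts, "n_sites") <- n_sites
  counts
}

## pooled-variance two-sample t-test (equal-variance form, the two-level
## linear model), with defined behaviour on zero-variance groups:
## equal means -> t = 0, p = 1; unequal means with zero pooled variance ->
## t = +/-Inf, p = 0
pooled_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2L
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  d <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (d == 0) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(d) * Inf, p = 0, df = df))
  }
  t <- d / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Contrast P-specific SNP counts between social forms
#'
#' Per gene, tests whether M/M workers of obligately polygynous (OP)
#' species carry more P-specific alleles than those of socially polymorphic
#' (SP) species. The default observational unit is the species mean (one
#' value per species, avoiding pseudo-replication); the test is the
#' equal-variance two-sample two-tailed t-test, equivalent to a one-factor
#' linear model with two levels. P-values are Bonferroni-adjusted over
#' `n_tests` (default: the number of genes with at least one trans-species
#' CDS site).
#'
#' @param counts genes x samples matrix from [count_p_specific()]
#'   (typically restricted to M/M workers).
#' @param species species of each sample (column of `counts`).
#' @param social_form named vector mapping species to `"OP"`/`"SP"`.
#' @param n_tests Bonferroni denominator; `NULL` for the number of tested
#'   genes.
#' @param use_species_means if `FALSE`, individual samples are the
#'   observations.
#' @return data frame per gene: `gene_id`, `n_sites`, group means and
#'   standard errors, `t`, `p`, `p_adj`.
#' @export
contrast_groups <- function(counts, species, social_form, n_tests = NULL,
                            use_species_means = TRUE) {
  stopifnot(ncol(counts) == length(species))
  form <- social_form[species]
  if (use_species_means) {
    obs <- t(rowsum(t(counts), group = species) /
               as.vector(table(species)[sort(unique(species))]))
    obs_form <- social_form[colnames(obs)]
  } else {
    obs <- counts
    obs_form <- form
  }
  op <- obs[, obs_form == "OP", drop = FALSE]
  sp <- obs[, obs_form == "SP", drop = FALSE]
  if (ncol(op) < 2L || ncol(sp) < 2L) {
    stop("need at least two observational units per social form")
  }
  n_sites <- attr(counts, "n_sites")
  if (is.null(n_sites)) n_sites <- rep(NA_integer_, nrow(counts))
  res <- lapply(seq_len(nrow(counts)), function(i) {
    tt <- pooled_t_test(op[i, ], sp[i, ])
    data.frame(
      gene_id = rownames(counts)[i], n_sites = n_sites[i],
      mean_OP = mean(op[i, ]), se_OP = stats::sd(op[i, ]) / sqrt(ncol(op)),
      mean_SP = mean(sp[i, ]), se_SP = stats::sd(sp[i, ]) / sqrt(ncol(sp)),
      t = tt$t, p = tt$p
    )
  })
  out <- do.call(rbind, res)
  if (is.null(n_tests)) n_tests <- sum(out$n_sites > 0, na.rm = TRUE)
  out$p_adj <- pmin(1, out$p * n_tests)
  out
}

#' Between-sample depth normalization
#'
#' Divides each sample's per-CDS depths by that sample's mean over all CDS
#' parts, so every sample has mean normalized depth exactly 1; collapsed
#' duplications then appear as per-gene values near the copy-number ratio.
#'
#' @param depth a `cds_depth` object (`$values` parts x samples, `$parts`).
#' @return a `cds_depth` object of normalized values.
#' @export
normalize_depth <- function(depth) {
  stopifnot(inherits(depth, "cds_depth"))
  m <- colMeans(depth$values)
  if (any(m <= 0)) {
    stop("sample(s) with non-positive mean depth: ",
         paste(colnames(depth$values)[m <= 0], collapse = ", "))
  }
  structure(list(values = sweep(depth$values, 2L, m, "/"),
                 parts = depth$parts),
            class = "cds_depth")
}

#' Per-gene per-sample mean normalized depth
#' @param depth a `cds_depth` object (typically [normalize_depth()] output).
#' @return matrix genes x samples of means over each gene's CDS parts.
#' @export
gene_depth <- function(depth) {
  stopifnot(inherits(depth, "cds_depth"))
  agg <- rowsum(depth$values, group = depth$parts$gene_id)
  n <- as.vector(table(depth$parts$gene_id)[rownames(agg)])
  agg / n
}

#' Depth contrast between genotype groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on normalized per-CDS-part
#' per-sample depth values (ties mid-ranked, normal approximation with
#' continuity correction), contrasting e.g. M/M against M/P workers.
#'
#' @param nd normalized `cds_depth` from [normalize_depth()].
#' @param group1,group2 disjoint sample id sets.
#' @param genes gene ids to test (default all).
#' @return data frame per gene: `gene_id`, `W` (statistic of `group1`),
#'   `p`, group means.
#' @export
depth_contrast <- function(nd, group1, group2, genes = NULL) {
  stopifnot(inherits(nd, "cds_depth"))
  if (!length(group1) || !length(group2)) {
    stop("both contrast groups must be non-empty")
  }
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  if (is.null(genes)) genes <- unique(nd$parts$gene_id)
  res <- lapply(genes, function(g) {
    rows <- nd$parts$gene_id == g
    x <- as.vector(nd$values[rows, group1, drop = FALSE])
    y <- as.vector(nd$values[rows, group2, drop = FALSE])
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    data.frame(gene_id = g, W = unname(wt$statistic), p = wt$p.value,
               mean_group1 = mean(x), mean_group2 = mean(y))
  })
  do.call(rbind, res)
}

#' Haploid pseudo-heterozygosity
#'
#' For each haploid male and gene, the fraction of trans-species CDS sites
#' called heterozygous (over the male's non-missing calls). A haploid
#' cannot be truly heterozygous, so fractions at or above `flag_threshold`
#' are flagged as evidence of a collapsed duplication — provided the gene
#' has at least `min_sites` called sites in the male (a fraction over one
#' or two sites can be a single miscall, not duplication evidence).
#'
#' @param gm a [genotype_matrix()].
#' @param hset a [extract_trans_specific()] result.
#' @param genes a [gene_models()] table.
#' @param males haploid sample ids.
#' @param flag_threshold het fraction at which a gene is flagged.
#' @param min_sites minimum called trans-species CDS sites for a flag.
#' @return list with `fractions` (genes x males matrix, `NA` for genes
#'   without called sites) and `flags` (logical matrix of the same shape).
#' @export
haploid_pseudo_het <- function(gm, hset, genes, males, flag_threshold = 0.9,
                               min_sites = 3L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gene_ids <- unique(genes$gene_id)
  idx <- build_cds_index(genes)
  row <- match(hset$positions, idx$site$pos)
  in_cds <- !is.na(row)
  site_gene <- idx$site$gene_id[row[in_cds]]
  site_pos <- hset$positions[in_cds]
  frac <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(males),
                 dimnames = list(gene_ids, males))
  enough <- matrix(FALSE, nrow = length(gene_ids), ncol = length(males),
                   dimnames = list(gene_ids, males))
  if (length(site_pos)) {
    g <- gm$gt[match(site_pos, gm$pos), males, drop = FALSE]
    het <- (g == 1L) + 0L
    n_called <- rowsum((!is.na(g)) + 0L, group = site_gene)
    n_het <- rowsum(ifelse(is.na(het), 0L, het), group = site_gene)
    f <- n_het / n_called
    f[n_called == 0L] <- NA_real_
    frac[rownames(f), ] <- f
    enough[rownames(f), ] <- n_called >= min_sites
  }
  flags <- !is.na(frac) & frac >= flag_threshold & enough
  list(fractions = frac, flags = flags)
}

#' Pairwise identity of two aligned sequences
#'
#' Case-insensitive percent identity: matching columns divided by columns
#' where not both sequences have a gap, times 100. A gap aligned to a base
#' counts as a mismatch; columns where both sequences are gapped are
#' dropped from the denominator.
#'
#' @param seq_a,seq_b aligned sequences of equal length (strings).
#' @return percent identity (0-100).
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  if (length(a) != length(b)) {
    stop("aligned sequences must have equal length (", length(a), " vs ",
         length(b), ")")
  }
  keep <- !(a == "-" & b == "-")
  if (!any(keep)) stop("alignment has no non-gap column")
  100 * sum(a[keep] == b[keep] & a[keep] != "-") / sum(keep)
}

#' Transcripts per million and expression class
#'
#' TPM per gene as `(count / length) / (total / 1e6)` with expression
#' classes at the public-atlas cutoffs: below < 0.5, low \[0.5, 10\],
#' medium (10, 1000\], high > 1000 TPM.
#'
#' @param gene_counts named (or plain) vector of read counts per gene.
#' @param gene_lengths gene lengths in bp, parallel to `gene_counts`.
#' @param total_read_count library size; defaults to `sum(gene_counts)`.
#' @return data frame: `gene_id`, `tpm`, `expression_class`.
#' @export
tpm <- function(gene_counts, gene_lengths,
                total_read_count = sum(gene_counts)) {
  stopifnot(length(gene_counts) == length(gene_lengths))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (total_read_count <= 0) stop("total read count must be positive")
  val <- (gene_counts / gene_lengths) / (total_read_count / 1e6)
  cls <- ifelse(val < 0.5, "below",
         ifelse(val <= 10, "low",
         ifelse(val <= 1000, "medium", "high")))
  ids <- names(gene_counts)
  if (is.null(ids)) ids <- as.character(seq_along(gene_counts))
  data.frame(gene_id = ids, tpm = val, expression_class = cls)
}
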