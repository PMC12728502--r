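#' Default synthetic cohort composition
#'
#' Six wood-ant-like species, three obligately polygynous (OP) and three
#' socially polymorphic (SP), 60 samples in total covering all five supergene
#' genotype classes (M/M, M/P, P/P, haploid M, haploid P). `mm_dup_freq` is
#' the per-species probability that an M/M worker carries the translocated
#' duplicated block (near-fixed in OP species, near-absent in SP species,
#' the configuration under which the duplicated block is discoverable).
#'
#' @return data frame with columns `species`, `social_form` (`OP`/`SP`),
#'   class counts `MM`, `MP`, `PP`, `hapM`, `hapP`, and `mm_dup_freq`.
#' @export
default_species_table <- function() {
  data.frame(
    species = c("aquilonia", "paralugubris", "polyctena",
                "lugubris", "pratensis", "rufa"),
    social_form = c("OP", "OP", "OP", "SP", "SP", "SP"),
    MM   = c(8L, 10L, 7L, 6L, 5L, 7L),
    MP   = c(0L, 0L, 3L, 2L, 3L, 2L),
    PP   = c(0L, 0L, 0L, 0L, 1L, 0L),
    hapM = c(2L, 0L, 0L, 1L, 0L, 1L),
    hapP = c(0L, 0L, 0L, 1L, 1L, 0L),
    mm_dup_freq = c(0.95, 0.95, 0.95, 0, 0, 0)
  )
}

#' Duplicated-block configuration
#'
#' Describes the collapsed duplication planted inside the supergene: two
#' adjacent genes whose paralogous copies map onto one locus, producing
#' pseudo-heterozygous calls (in carriers of any ploidy) and elevated read
#' depth. The per-gene pseudo-heterozygous site counts default to 22 and 5,
#' the counts observed for the two real candidate genes.
#'
#' @param n_pseudo_het_sites integer vector, pseudo-het trans-specific CDS
#'   sites planted in each of the two block genes.
#' @param depth_multiplier read-depth fold change over the block in carriers;
#'   2.0 corresponds to a collapsed two-copy duplication.
#' @param carrier_classes genotype classes that always carry the block
#'   (M/M carrier status is governed per species by `mm_dup_freq`).
#' @return a `dup_block` configuration list.
#' @export
dup_block_config <- function(n_pseudo_het_sites = c(22L, 5L),
                             depth_multiplier = 2.0,
                             carrier_classes = c("MP", "PP", "hapP")) {
  stopifnot(length(n_pseudo_het_sites) == 2L, all(n_pseudo_het_sites >= 0L),
            depth_multiplier >= 1)
  structure(list(n_pseudo_het_sites = as.integer(n_pseudo_het_sites),
                 depth_multiplier = depth_multiplier,
                 carrier_classes = carrier_classes),
            class = "dup_block_config")
}

#' Per-haplotype mutation-load planting rates
#'
#' Per-haplotype-copy, per-CDS-site probabilities that a private mutation of
#' the given impact category is planted on an M or P supergene haplotype
#' copy (an infinite-sites model: each mutation occupies its own CDS site,
#' with the alternative allele chosen from the codon table so the planted
#' impact is guaranteed). Deleterious variants are modeled as young,
#' copy-private mutations — the selection-skewed end of the frequency
#' spectrum — while ancient shared P-specific variation is carried by the
#' divergent-site channel. Defaults are equal on both haplotypes, i.e. no
#' differential load.
#'
#' @param M,P named numeric vectors with elements `high`, `moderate`, `low`.
#' @return a `load_rates` list.
#' @export
load_rates_config <- function(M = c(high = 5e-4, moderate = 2e-3, low = 1.5e-3),
                              P = c(high = 5e-4, moderate = 2e-3, low = 1.5e-3)) {
  for (r in list(M, P)) {
    stopifnot(all(c("high", "moderate", "low") %in% names(r)),
              all(r >= 0), sum(r) <= 1)
  }
  structure(list(M = M, P = P), class = "load_rates")
}

#' Synthetic cohort configuration
#'
#' Parameterizes [simulate_cohort()]. Defaults are the package's reference
#' study conditions: a 1 Mb chromosome with a 500 kb supergene aligned on
#' 20 kb window boundaries, 500 fixed M-vs-P divergent sites of which 15%
#' have been erased by between-haplotype homogenization, 60 samples across
#' six species (all five genotype classes), a planted duplicated two-gene
#' block, mean coverage 21.9x, 1% genotype error and 5% missingness.
#'
#' @param chrom chromosome name used in all emitted files.
#' @param chrom_length chromosome length in bp.
#' @param supergene_interval integer `c(start, end)`, 1-based inclusive.
#' @param n_sites_background count of class-independent polymorphic sites.
#' @param n_sites_divergent count of fixed M-vs-P differences inside the
#'   supergene.
#' @param homogenized_fraction fraction of divergent sites erased by M/P
#'   homogenization (they then segregate like background sites).
#' @param species_table see [default_species_table()].
#' @param dup_block a [dup_block_config()] or `NULL` for no duplication.
#' @param load_rates a [load_rates_config()].
#' @param depth_mean mean per-genotype sequencing depth (x coverage).
#' @param depth_dispersion overdispersion of depth (squared coefficient of
#'   variation of the gamma noise; 0 gives Poisson site depths and exact
#'   per-CDS means).
#' @param missing_rate per-genotype missingness probability; scalar or one
#'   value per sample.
#' @param genotype_error_rate probability a genotype call is replaced by one
#'   of the two other dosages (uniformly).
#' @param n_genes number of protein-coding genes tiled along the chromosome.
#' @param seed integer RNG seed; fixes every byte of the simulated outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chrom = "Scaffold03",
                       chrom_length = 1000000L,
                       supergene_interval = c(200001L, 700000L),
                       n_sites_background = 300L,
                       n_sites_divergent = 500L,
                       homogenized_fraction = 0.15,
                       species_table = default_species_table(),
                       dup_block = dup_block_config(),
                       load_rates = load_rates_config(),
                       depth_mean = 21.9,
                       depth_dispersion = 0.2,
                       missing_rate = 0.05,
                       genotype_error_rate = 0.01,
                       n_genes = 30L,
                       seed = 1L) {
  cfg <- list(
    chrom = chrom, chrom_length = as.integer(chrom_length),
    supergene_interval = as.integer(supergene_interval),
    n_sites_background = as.integer(n_sites_background),
    n_sites_divergent = as.integer(n_sites_divergent),
    homogenized_fraction = homogenized_fraction,
    species_table = species_table, dup_block = dup_block,
    load_rates = load_rates, depth_mean = depth_mean,
    depth_dispersion = depth_dispersion, missing_rate = missing_rate,
    genotype_error_rate = genotype_error_rate,
    n_genes = as.integer(n_genes), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  si <- cfg$supergene_interval
  if (length(si) != 2L || si[1] >= si[2]) {
    stop("supergene_interval must be c(start, end) with start < end")
  }
  if (si[1] < 1L || si[2] > cfg$chrom_length) {
    stop("supergene_interval must lie within [1, chrom_length]")
  }
  fracs <- c(cfg$homogenized_fraction, cfg$missing_rate,
             cfg$genotype_error_rate)
  if (any(fracs < 0 | fracs > 1)) {
    stop("homogenized_fraction, missing_rate and genotype_error_rate must be in [0, 1]")
  }
  if (cfg$n_sites_divergent > (si[2] - si[1] + 1L)) {
    stop("impossible config: more divergent sites (", cfg$n_sites_divergent,
         ") than supergene positions (", si[2] - si[1] + 1L, ")")
  }
  if (cfg$n_sites_background < 0L || cfg$n_sites_divergent < 0L) {
    stop("site counts must be non-negative")
  }
  st <- cfg$species_table
  req <- c("species", "social_form", "MM", "MP", "PP", "hapM", "hapP",
           "mm_dup_freq")
  if (!all(req %in% names(st))) {
    stop("species_table lacks columns: ",
         paste(setdiff(req, names(st)), collapse = ", "))
  }
  counts <- as.matrix(st[, c("MM", "MP", "PP", "hapM", "hapP")])
  if (any(counts < 0)) stop("species_table class counts must be non-negative")
  if (sum(counts) < 2L) stop("cohort must contain at least 2 samples")
  if (!all(st$social_form %in% c("OP", "SP"))) {
    stop("social_form must be 'OP' or 'SP'")
  }
  if (any(st$mm_dup_freq < 0 | st$mm_dup_freq > 1)) {
    stop("mm_dup_freq must be in [0, 1]")
  }
  if (cfg$depth_mean <= 0 || cfg$depth_dispersion < 0) {
    stop("depth_mean must be positive and depth_dispersion non-negative")
  }
  if (cfg$n_genes < 2L) stop("need at least 2 genes")
  nm <- length(cfg$missing_rate)
  if (!nm %in% c(1L, sum(counts))) {
    stop("missing_rate must be a scalar or one value per sample")
  }
  invisible(cfg)
}

#' Reference configurations for the mutation-load experiments
#'
#' Two fixed experimental designs used throughout the package's tests and
#' reproduction script. `"null"`: 40 workers (30 M/M vs 10 M/P), equal load
#' rates on both haplotypes and no divergent channel — simulating under the
#' rank-sum test's null so its type-I error can be measured. `"power"`: the
#' 5-vs-50 imbalanced design with the high-impact rate doubled on the P
#' haplotype, sized (about 26 kb of supergene CDS) so the planted effect
#' separates groups by roughly 2.4 standard deviations per sample. Both
#' designs switch the divergent-site channel off: fixed M/P differences are
#' a genuine coding difference between the groups, not differential load,
#' and would otherwise contaminate the calibration check.
#'
#' @param type `"null"` or `"power"`.
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
load_experiment_config <- function(type = c("null", "power"), seed = 1L) {
  type <- match.arg(type)
  if (type == "null") {
    sim_config(
      chrom_length = 240000L, supergene_interval = c(40001L, 200000L),
      n_sites_background = 60L, n_sites_divergent = 0L, n_genes = 8L,
      species_table = data.frame(
        species = "spA", social_form = "SP", MM = 30L, MP = 10L, PP = 0L,
        hapM = 0L, hapP = 0L, mm_dup_freq = 0),
      dup_block = NULL,
      load_rates = load_rates_config(
        M = c(high = 6e-4, moderate = 3e-3, low = 2.5e-3),
        P = c(high = 6e-4, moderate = 3e-3, low = 2.5e-3)),
      seed = seed
    )
  } else {
    sim_config(
      chrom_length = 720000L, supergene_interval = c(40001L, 680000L),
      n_sites_background = 60L, n_sites_divergent = 0L, n_genes = 24L,
      species_table = data.frame(
        species = "spA", social_form = "SP", MM = 50L, MP = 5L, PP = 0L,
        hapM = 0L, hapP = 0L, mm_dup_freq = 0),
      dup_block = NULL,
      load_rates = load_rates_config(
        M = c(high = 5e-4, moderate = 3e-3, low = 2.5e-3),
        P = c(high = 1e-3, moderate = 3e-3, low = 2.5e-3)),
      seed = seed
    )
  }
}
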