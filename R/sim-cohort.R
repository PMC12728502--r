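#' Simulate a multi-species cohort with a planted supergene
#'
#' Generates a genotype matrix, per-CDS depth table, sample metadata, gene
#' models, reference sequence, gene read counts and a ground-truth record
#' carrying the statistical structure the downstream analysis assumes:
#'
#' * M/P heterozygotes are heterozygous at every non-homogenized divergent
#'   site inside the supergene (before genotype error and missingness);
#'   haploid P males and P/P diploids carry the alternative allele there.
#' * Haploid males are emitted as diploid-style homozygous calls; truly
#'   heterozygous calls in haploids occur only at the planted duplicated
#'   block (pseudo-heterozygosity from collapsed paralogs).
#' * Carriers of the duplicated two-gene block have read depth
#'   `depth_multiplier` times baseline across the block.
#' * Background sites segregate independently of genotype class.
#' * Haplotype-linked deleterious variants are planted on CDS sites inside
#'   the supergene at per-category rates, with consequences guaranteed by
#'   construction (each planted allele is chosen from the codon table).
#'
#' The same seed reproduces every output byte for byte.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_cohort`: a list with elements `gm`
#'   ([genotype_matrix()]), `depth` (per-CDS depth table), `meta` (sample
#'   metadata), `genes` ([gene_models()]), `reference` (chromosome sequence
#'   string), `counts` (gene read counts), `truth` (`simulation_truth`) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  chrom_len <- config$chrom_length
  si <- config$supergene_interval

  meta <- expand_species_table(config$species_table)
  n_samp <- nrow(meta)
  cls <- meta$class
  haploid <- meta$ploidy == 1L

  genes <- simulate_gene_models(chrom_len, config$n_genes, config$chrom)
  dup <- pick_dup_genes(genes, si, config$dup_block)
  reference <- simulate_reference(chrom_len, genes)

  ## duplication carriers: carrier classes always; M/M workers per species
  carrier <- rep(FALSE, n_samp)
  if (!is.null(dup)) {
    carrier <- cls %in% config$dup_block$carrier_classes
    mm_freq <- config$species_table$mm_dup_freq[
      match(meta$species, config$species_table$species)]
    is_mm <- cls == "MM"
    carrier[is_mm] <- stats::runif(sum(is_mm)) < mm_freq[is_mm]
  }

  ## ---- site positions -------------------------------------------------
  psh_pos <- integer(0)
  psh_gene <- character(0)
  if (!is.null(dup)) {
    for (k in 1:2) {
      gpos <- cds_positions(genes, dup$gene_ids[k])
      n_k <- config$dup_block$n_pseudo_het_sites[k]
      if (n_k > length(gpos)) {
        stop("impossible config: more pseudo-het sites than CDS positions in ",
             dup$gene_ids[k])
      }
      take <- sort(sample(gpos, n_k))
      psh_pos <- c(psh_pos, take)
      psh_gene <- c(psh_gene, rep(dup$gene_ids[k], n_k))
    }
  }
  ## the divergent pool excludes the duplicated genes themselves: inside a
  ## collapsed duplication every trans-specific site reads as heterozygous
  ## in carriers, so the block genes' trans-specific sites are exactly the
  ## planted pseudo-het ones (the spacer between the two genes keeps normal
  ## divergent sites)
  dup_span <- if (is.null(dup)) integer(0) else {
    unlist(lapply(dup$gene_ids, function(g) {
      gp <- genes[genes$gene_id == g, ]
      min(gp$start):max(gp$end)
    }), use.names = FALSE)
  }
  sg_pool <- setdiff(si[1]:si[2], c(psh_pos, dup_span))
  div_pos <- sort(sample(sg_pool, config$n_sites_divergent))
  n_hom <- round(config$homogenized_fraction * config$n_sites_divergent)
  hom_pos <- sort(sample(div_pos, n_hom))
  div_strict <- setdiff(div_pos, hom_pos)
  bg_pool <- setdiff(seq_len(chrom_len), c(psh_pos, div_pos))
  bg_pos <- sort(sample(bg_pool, config$n_sites_background))

  load <- plant_load(genes, reference, si, config$load_rates,
                     exclude = c(psh_pos, div_pos, bg_pos), meta)

  ## ---- per-category true dosages --------------------------------------
  blocks <- list()
  site_tab <- list()

  add_block <- function(pos, gt, category, alt = NULL, haplotype = NA,
                        impact = NA) {
    refb <- ref_base_at(reference, pos)
    if (is.null(alt)) alt <- random_alt(refb)
    k <- length(blocks) + 1L
    blocks[[k]] <<- gt
    site_tab[[k]] <<- data.frame(
      pos = pos, ref = refb, alt = alt, category = category,
      haplotype = haplotype, impact = impact
    )
  }

  class_dosage <- c(MM = 0L, MP = 1L, PP = 2L, hapM = 0L, hapP = 2L)
  if (length(div_strict)) {
    gt <- matrix(rep(class_dosage[cls], each = length(div_strict)),
                 nrow = length(div_strict))
    add_block(div_strict, gt, "divergent")
  }
  if (length(hom_pos)) {
    add_block(hom_pos, background_genotypes(length(hom_pos), meta),
              "homogenized")
  }
  if (length(bg_pos)) {
    add_block(bg_pos, background_genotypes(length(bg_pos), meta),
              "background")
  }
  if (length(psh_pos)) {
    gt <- matrix(ifelse(rep(carrier, each = length(psh_pos)), 1L, 0L),
                 nrow = length(psh_pos))
    add_block(psh_pos, gt, "pseudo_het")
  }
  if (nrow(load)) {
    ## copy-private mutations: het in the owning diploid, hom-alt in the
    ## owning haploid, absent elsewhere
    gt <- matrix(0L, nrow = nrow(load), ncol = n_samp)
    dosage <- ifelse(meta$ploidy[load$owner] == 1L, 2L, 1L)
    gt[cbind(seq_len(nrow(load)), load$owner)] <- dosage
    add_block(load$pos, gt, "load", alt = load$alt,
              haplotype = load$haplotype, impact = load$impact)
  }

  sites <- do.call(rbind, site_tab)
  gt <- do.call(rbind, blocks)
  ord <- order(sites$pos)
  sites <- sites[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  n_sites <- nrow(sites)

  ## ---- genotype error and missingness ---------------------------------
  e <- config$genotype_error_rate
  if (e > 0) {
    err <- stats::runif(n_sites * n_samp) < e
    if (any(err)) {
      gt[err] <- (gt[err] + sample(1:2, sum(err), replace = TRUE)) %% 3L
    }
  }
  m_rate <- rep(config$missing_rate, length.out = n_samp)
  miss <- stats::runif(n_sites * n_samp) < rep(m_rate, each = n_sites)
  gt[miss] <- NA_integer_

  ## ---- depths ----------------------------------------------------------
  s_eff <- stats::rlnorm(n_samp, meanlog = -0.15^2 / 2, sdlog = 0.15)
  mu <- config$depth_mean * matrix(rep(s_eff, each = n_sites), nrow = n_sites)
  if (!is.null(dup)) {
    in_dup <- sites$pos >= dup$interval[1] & sites$pos <= dup$interval[2]
    mu[in_dup, carrier] <- mu[in_dup, carrier] * config$dup_block$depth_multiplier
  }
  disp <- config$depth_dispersion
  dp <- if (disp > 0) {
    matrix(stats::rnbinom(n_sites * n_samp, mu = mu, size = 1 / disp),
           nrow = n_sites)
  } else {
    matrix(stats::rpois(n_sites * n_samp, mu), nrow = n_sites)
  }
  qual <- sample(30:60, n_sites, replace = TRUE)

  gm <- genotype_matrix(gt, dp, config$chrom, sites$pos, sites$ref,
                        sites$alt, qual, meta$id)

  depth <- simulate_cds_depth(genes, meta, s_eff, carrier, dup, config)
  counts <- simulate_gene_counts(genes)

  truth <- structure(list(
    classes = stats::setNames(cls, meta$id),
    hset_pos = sort(c(div_strict, psh_pos)),
    divergent_pos = div_pos,
    homogenized_pos = hom_pos,
    pseudo_het_pos = sort(psh_pos),
    dup_genes = if (is.null(dup)) character(0) else dup$gene_ids,
    dup_interval = if (is.null(dup)) integer(0) else dup$interval,
    dup_carriers = meta$id[carrier],
    region = si,
    sites = sites[, c("pos", "category", "haplotype", "impact")]
  ), class = "simulation_truth")

  structure(list(gm = gm, depth = depth, meta = meta, genes = genes,
                 reference = reference, counts = counts, truth = truth,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d samples, %d sites on %s (%d bp), %d genes\n",
              nrow(x$meta), nrow(x$gm$gt), x$config$chrom,
              x$config$chrom_length, length(unique(x$genes$gene_id))))
  print(table(x$truth$classes))
  invisible(x)
}

expand_species_table <- function(st) {
  rows <- list()
  for (i in seq_len(nrow(st))) {
    for (class in c("MM", "MP", "PP", "hapM", "hapP")) {
      n <- st[[class]][i]
      if (n == 0L) next
      ploidy <- if (class %in% c("hapM", "hapP")) 1L else 2L
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_%s_%02d", st$species[i], class, seq_len(n)),
        species = st$species[i], social_form = st$social_form[i],
        class = class, ploidy = ploidy,
        caste = if (ploidy == 1L) "male" else "worker"
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## genes tiled at regular spacing, 4 CDS exons of 300 bp, 200 bp introns,
## alternating strand
simulate_gene_models <- function(chrom_length, n_genes, chrom) {
  n_exons <- 4L; exon_len <- 300L; intron_len <- 200L
  span <- n_exons * exon_len + (n_exons - 1L) * intron_len
  spacing <- chrom_length %/% (n_genes + 1L)
  if (spacing <= span) {
    stop("impossible config: chromosome too short for ", n_genes, " genes")
  }
  rows <- list()
  for (i in seq_len(n_genes)) {
    gs <- i * spacing
    starts <- gs + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
    strand <- if (i %% 2L == 1L) "+" else "-"
    rank <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
    cum_before <- (rank - 1L) * exon_len
    rows[[i]] <- data.frame(
      gene_id = sprintf("g%03d", i), chrom = chrom,
      start = starts, end = starts + exon_len - 1L,
      strand = strand, exon_rank = rank,
      phase = (3L - cum_before %% 3L) %% 3L
    )
  }
  gene_models(do.call(rbind, rows))
}

## two adjacent genes fully inside the supergene, nearest its 60% point
pick_dup_genes <- function(genes, si, dup_block) {
  if (is.null(dup_block)) return(NULL)
  per_gene <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L], start = min(g$start), end = max(g$end))
  }))
  per_gene <- per_gene[order(per_gene$start), , drop = FALSE]
  inside <- per_gene$start >= si[1] & per_gene$end <= si[2]
  idx <- which(inside)
  if (length(idx) < 2L) {
    stop("impossible config: need at least two genes inside the supergene ",
         "for the duplicated block")
  }
  target <- si[1] + 0.6 * (si[2] - si[1])
  first <- idx[which.min(abs(per_gene$start[idx] - target))]
  if (!((first + 1L) %in% idx)) first <- first - 1L
  pair <- per_gene[c(first, first + 1L), ]
  list(gene_ids = pair$gene_id,
       interval = c(pair$start[1L], pair$end[2L]))
}

## random chromosome with a well-formed ORF written into every gene:
## ATG start, non-stop internal codons, TAA terminal stop
simulate_reference <- function(chrom_length, genes) {
  bases <- c("A", "C", "G", "T")
  genome <- sample(bases, chrom_length, replace = TRUE)
  code <- Biostrings::GENETIC_CODE
  non_stop <- names(code)[code != "*"]
  idx <- build_cds_index(genes)
  for (g in unique(idx$site$gene_id)) {
    rows <- idx$site[idx$site$gene_id == g, , drop = FALSE]
    n_codons <- nrow(rows) %/% 3L
    codons <- c("ATG", sample(non_stop, n_codons - 2L, replace = TRUE), "TAA")
    tx_chars <- strsplit(paste(codons, collapse = ""), "")[[1L]]
    tx_chars <- tx_chars[seq_len(nrow(rows))]
    if (rows$strand[1L] == "-") tx_chars <- unname(COMPLEMENT[tx_chars])
    genome[rows$pos] <- tx_chars
  }
  paste(genome, collapse = "")
}

random_alt <- function(refb) {
  bases <- c("A", "C", "G", "T")
  alts <- matrix(c("C", "G", "T",  "A", "G", "T",
                   "A", "C", "T",  "A", "C", "G"), nrow = 4L, byrow = TRUE,
                 dimnames = list(bases, NULL))
  alts[cbind(match(refb, bases), sample.int(3L, length(refb), replace = TRUE))]
}

## class-independent genotypes at background-like sites
background_genotypes <- function(n_sites, meta) {
  p <- stats::runif(n_sites, 0.05, 0.95)
  n_samp <- nrow(meta)
  size <- ifelse(meta$ploidy == 2L, 2L, 1L)
  raw <- stats::rbinom(n_sites * n_samp, size = rep(size, each = n_sites),
                       prob = rep(p, times = n_samp))
  gt <- matrix(raw, nrow = n_sites)
  hap <- meta$ploidy == 1L
  gt[, hap] <- 2L * gt[, hap]
  gt
}

## Copy-private deleterious mutations on supergene CDS sites (infinite-sites
## model). Every M or P haplotype copy in the cohort receives mutations of
## each impact category at the per-copy per-site rate; each mutation gets a
## distinct CDS site whose alternative allele is chosen from the codon table
## so the planted impact is guaranteed. Categories are allocated scarcest
## pool first (high, then synonymous-limited low, then moderate).
plant_load <- function(genes, reference, si, load_rates, exclude, meta) {
  per_gene_start <- tapply(genes$start, genes$gene_id, min)
  per_gene_end <- tapply(genes$end, genes$gene_id, max)
  sg_genes <- names(per_gene_start)[per_gene_start >= si[1] &
                                    per_gene_end <= si[2]]
  empty <- data.frame(pos = integer(0), alt = character(0),
                      haplotype = character(0), impact = character(0),
                      owner = integer(0))
  if (!length(sg_genes)) return(empty)
  pool <- all_cds_consequences(genes, reference, gene_ids = sg_genes)
  pool <- pool[!(pool$pos %in% exclude), , drop = FALSE]
  n_cds <- length(unique(pool$pos))

  ## one row per haplotype copy: owning sample index and M/P class
  copy_class <- list(MM = c("M", "M"), MP = c("M", "P"), PP = c("P", "P"),
                     hapM = "M", hapP = "P")
  copies <- do.call(rbind, lapply(seq_len(nrow(meta)), function(j) {
    data.frame(owner = j, hap = copy_class[[meta$class[j]]])
  }))

  out <- list()
  used <- integer(0)
  for (cat in c("high", "low", "moderate")) {
    rate <- ifelse(copies$hap == "M", load_rates$M[[cat]],
                   load_rates$P[[cat]])
    n_k <- stats::rbinom(nrow(copies), n_cds, rate)
    total <- sum(n_k)
    if (total == 0L) next
    cand <- pool[pool$impact == cat & !(pool$pos %in% used), , drop = FALSE]
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    cand <- cand[!duplicated(cand$pos), , drop = FALSE]
    if (total > nrow(cand)) {
      warning("load planting: only ", nrow(cand), " of ", total,
              " requested '", cat, "' sites available; capping")
    }
    owners <- rep(seq_len(nrow(copies)), n_k)
    take_n <- min(total, nrow(cand))
    if (take_n < total) owners <- sample(owners, take_n)
    take <- cand[seq_len(take_n), , drop = FALSE]
    used <- c(used, take$pos)
    out[[length(out) + 1L]] <- data.frame(
      pos = take$pos, alt = take$alt, haplotype = copies$hap[owners],
      impact = cat, owner = copies$owner[owners]
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$pos), , drop = FALSE]
}

## per-CDS-part mean depths with per-sample efficiency and the duplication
## multiplier for carriers over the block genes
simulate_cds_depth <- function(genes, meta, s_eff, carrier, dup, config) {
  parts <- data.frame(
    part_id = sprintf("%s_e%d", genes$gene_id, genes$exon_rank),
    gene_id = genes$gene_id, start = genes$start, end = genes$end
  )
  n_parts <- nrow(parts)
  n_samp <- nrow(meta)
  mu <- config$depth_mean * matrix(rep(s_eff, each = n_parts), nrow = n_parts)
  if (!is.null(dup)) {
    in_dup <- parts$gene_id %in% dup$gene_ids
    mu[in_dup, carrier] <- mu[in_dup, carrier] * config$dup_block$depth_multiplier
  }
  disp <- config$depth_dispersion
  g <- if (disp > 0) {
    matrix(stats::rgamma(n_parts * n_samp, shape = 1 / disp, rate = 1 / disp),
           nrow = n_parts)
  } else {
    1
  }
  values <- mu * g
  dimnames(values) <- list(parts$part_id, meta$id)
  structure(list(values = values, parts = parts), class = "cds_depth")
}

simulate_gene_counts <- function(genes) {
  len <- cds_lengths(genes)
  rate <- stats::runif(length(len), 0.05, 5)
  data.frame(gene_id = names(len), length = as.integer(len),
             count = stats::rpois(length(len), len * rate))
}
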