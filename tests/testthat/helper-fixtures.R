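## Small-cohort configuration for unit tests (window-aligned supergene,
## seven genes inside it, so the duplicated block is placeable)
small_cohort_config <- function(seed = 1L, load = TRUE, ...) {
  zero <- c(high = 0, moderate = 0, low = 0)
  args <- list(
    chrom_length = 300000L, supergene_interval = c(60001L, 260000L),
    n_sites_background = 60L, n_sites_divergent = 200L, n_genes = 10L,
    seed = seed
  )
  if (!load) args$load_rates <- load_rates_config(M = zero, P = zero)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

## hand-built genotype matrix; gt given as sites x samples dosage matrix
make_gm <- function(gt, dp = 20L, qual = 50, pos = NULL, ref = NULL,
                    alt = NULL, chrom = "chr1", samples = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt); m <- ncol(gt)
  if (length(dp) == 1L) dp <- matrix(dp, n, m)
  if (length(qual) == 1L) qual <- rep(qual, n)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(m))
  genotype_matrix(gt, dp, chrom, pos, ref, alt, qual, samples)
}

## random genotype matrix for property tests
random_gm <- function(n_sites, n_samples, miss = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gt <- matrix(sample(c(0:2, NA), n_sites * n_samples, replace = TRUE,
                      prob = c((1 - miss) * c(0.5, 0.3, 0.2), miss)),
               n_sites, n_samples)
  dp <- matrix(sample(0:40, n_sites * n_samples, replace = TRUE),
               n_sites, n_samples)
  make_gm(gt, dp = dp, qual = sample(10:60, n_sites, replace = TRUE))
}

## ---- independent oracles ------------------------------------------------

## per-rule brute-force reimplementation of the site and sample filters
naive_filter_sites <- function(gm, th) {
  keep <- logical(nrow(gm$gt))
  filt <- attr(gm, "filter")
  n_samples <- ncol(gm$gt)
  for (i in seq_len(nrow(gm$gt))) {
    ok <- nchar(gm$ref[i]) == 1 && nchar(gm$alt[i]) == 1 &&
      !grepl(",", gm$alt[i]) && gm$ref[i] %in% c("A", "C", "G", "T") &&
      gm$alt[i] %in% c("A", "C", "G", "T")
    if (!is.null(filt) && !(filt[i] %in% c("PASS", "."))) ok <- FALSE
    if (ok) {
      g <- gm$gt[i, ]
      g[is.na(gm$dp[i, ]) | gm$dp[i, ] < th$min_genotype_depth] <- NA
      alt_count <- sum(g, na.rm = TRUE)
      n_alleles <- 2 * sum(!is.na(g))
      mac <- min(alt_count, n_alleles - alt_count)
      n_het <- sum(g == 1, na.rm = TRUE)
      ## exact-fraction comparisons, same 1e-9 slack convention
      ok <- !is.na(gm$qual[i]) && gm$qual[i] >= th$min_site_qual &&
        alt_count >= th$min_nonref_allele_count &&
        mac >= th$min_minor_allele_count &&
        (sum(!is.na(g)) / n_samples) >= th$min_nonmissing_fraction - 1e-9 &&
        (n_het / n_samples) <= th$max_het_sample_fraction + 1e-9
    }
    keep[i] <- ok
  }
  keep
}

naive_filter_samples <- function(gm, th) {
  excluded <- character(0)
  if (nrow(gm$gt) == 0L) return(excluded)
  for (j in seq_len(ncol(gm$gt))) {
    if (mean(is.na(gm$gt[, j])) >= th$max_sample_missing_fraction - 1e-9) {
      excluded <- c(excluded, gm$samples[j])
    }
  }
  excluded
}

## QC then genotyping, the documented stage order (F_IS and the windowed
## scan operate on the mac-filtered matrix, where copy-private singletons
## cannot exist)
genotype_after_qc <- function(co, ...) {
  fs <- filter_samples(filter_sites(co$gm), filter_thresholds())
  supergene_genotype(fs$gm, co$meta,
                     chrom_length = co$config$chrom_length, ...)
}

## spreadsheet-style F_IS: explicit loops over sites
naive_fis <- function(gm, sample_id) {
  j <- match(sample_id, gm$samples)
  n_used <- 0; o_hom <- 0; e_hom <- 0
  for (i in seq_len(nrow(gm$gt))) {
    n_alleles <- 2 * sum(!is.na(gm$gt[i, ]))
    if (n_alleles < 2) next
    if (is.na(gm$gt[i, j])) next
    p <- sum(gm$gt[i, ], na.rm = TRUE) / n_alleles
    n_used <- n_used + 1
    if (gm$gt[i, j] %in% c(0, 2)) o_hom <- o_hom + 1
    e_hom <- e_hom + (1 - 2 * p * (1 - p) * n_alleles / (n_alleles - 1))
  }
  if (n_used - e_hom == 0) return(NA_real_)
  (o_hom - e_hom) / (n_used - e_hom)
}

## full-protein-translation oracle for SNP consequences: mutate the genome,
## re-extract the CDS with Biostrings and compare translated proteins
oracle_effect <- function(pos, alt, genes, reference) {
  ids <- unique(genes$gene_id)
  for (g in ids) {
    gp <- genes[genes$gene_id == g, , drop = FALSE]
    gp <- gp[order(gp$start), , drop = FALSE]
    cds_pos <- unlist(mapply(seq, gp$start, gp$end, SIMPLIFY = FALSE))
    if (pos %in% cds_pos) {
      extract_protein <- function(genome_str) {
        seqs <- vapply(seq_len(nrow(gp)), function(i) {
          substr(genome_str, gp$start[i], gp$end[i])
        }, character(1))
        cds <- Biostrings::DNAString(paste(seqs, collapse = ""))
        if (gp$strand[1] == "-") cds <- Biostrings::reverseComplement(cds)
        as.character(Biostrings::translate(cds, no.init.codon = TRUE))
      }
      mutant <- reference
      substr(mutant, pos, pos) <- alt
      p_ref <- extract_protein(reference)
      p_alt <- extract_protein(mutant)
      ## transcript coordinate of the site, computed from scratch
      tx_order <- if (gp$strand[1] == "-") rev(cds_pos) else cds_pos
      tx_pos <- which(tx_order == pos)
      codon_idx <- (tx_pos - 1) %/% 3 + 1
      aa_ref <- substr(p_ref, codon_idx, codon_idx)
      aa_alt <- substr(p_alt, codon_idx, codon_idx)
      ref_codon1 <- substr(as.character({
        seqs <- vapply(seq_len(nrow(gp)), function(i)
          substr(reference, gp$start[i], gp$end[i]), character(1))
        cds <- Biostrings::DNAString(paste(seqs, collapse = ""))
        if (gp$strand[1] == "-") cds <- Biostrings::reverseComplement(cds)
        cds
      }), 1, 3)
      if (aa_ref == aa_alt) return("synonymous")
      if (codon_idx == 1 && ref_codon1 == "ATG") return("start_lost")
      if (aa_alt == "*") return("stop_gained")
      if (aa_ref == "*") return("stop_lost")
      return("missense")
    }
    ## splice: first/last 2 bp of each intron
    if (nrow(gp) > 1) {
      for (i in seq_len(nrow(gp) - 1)) {
        int <- (gp$end[i] + 1):(gp$start[i + 1] - 1)
        edge <- unique(c(utils::head(int, 2), utils::tail(int, 2)))
        if (pos %in% edge) return("splice_disrupting")
      }
    }
  }
  "non_coding"
}

## random single-gene models for classifier tests
random_gene <- function(chrom_length = 3000L, n_codons = 30L,
                        strand = "+", n_exons = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cds_len <- 3L * n_codons
  exon_len <- cds_len %/% n_exons
  lens <- rep(exon_len, n_exons)
  lens[n_exons] <- cds_len - sum(lens[-n_exons])
  intron <- 50L
  start <- 101L
  starts <- start + cumsum(c(0L, (lens + intron)[-n_exons]))
  rank <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
  parts <- data.frame(
    gene_id = "gX", chrom = "chr1", start = starts,
    end = starts + lens - 1L, strand = strand, exon_rank = rank,
    phase = 0L
  )
  ## consistent phase from transcript order
  ord <- order(parts$exon_rank)
  cum <- cumsum(c(0L, (parts$end - parts$start + 1L)[ord]))[seq_len(n_exons)]
  parts$phase[ord] <- (3L - cum %% 3L) %% 3L
  genes <- gene_models(parts)
  reference <- supergeneR:::simulate_reference(chrom_length, genes)
  list(genes = genes, reference = reference)
}
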