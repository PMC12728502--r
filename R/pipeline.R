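#' Default pipeline configuration
#'
#' All stage thresholds at their reference values: the hard-filter set of
#' [filter_thresholds()], F_IS carrier threshold -0.5, 20 kb scan windows,
#' carrier missing tolerance 0.2, proportion majority 0.8.
#'
#' @param outdir run directory for outputs.
#' @param seed integer seed driving the simulation stage.
#' @return nested configuration list understood by [run_pipeline()].
#' @export
default_run_config <- function(outdir = tempfile("supergene_run_"),
                               seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, qc = TRUE, genotype = TRUE,
                  scan = TRUE, load = TRUE),
    inputs = list(vcf = NULL, meta = NULL, gff = NULL, fasta = NULL,
                  depth = NULL),
    sim = list(),
    qc = list(),
    genotype = list(fis_threshold = -0.5, window_size = 20000L,
                    max_missing_carriers = 0.2, majority = 0.8,
                    min_fold = 5, min_run = 3L),
    scan = list(n_tests = NULL, alpha = 0.05, flag_threshold = 0.9),
    load = list(region = NULL)
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; missing fields take [default_run_config()] values.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_run_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      merge_config(base[[k]], user[[k]])
    } else {
      user[[k]]
    }
  }
  base
}

#' Run the full supergene analysis pipeline
#'
#' Executes the stages in dependency order: simulate (or read inputs),
#' variant QC, supergene genotyping, candidate-gene scan, mutation-load
#' contrast. Writes stage outputs, a `report.json` and a `MANIFEST` under
#' `config$outdir`. The same configuration and seed reproduce the report
#' byte for byte.
#'
#' @param config a configuration list ([default_run_config()]), or a path
#'   to a YAML file.
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list())
  files <- character(0)

  ## ---- inputs ----------------------------------------------------------
  truth <- NULL
  if (isTRUE(config$stages$simulate)) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    cohort <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(cohort)
    paths <- write_cohort(cohort, file.path(outdir, "data"))
    files <- c(files, paths)
    gm <- cohort$gm
    meta <- cohort$meta
    genes <- cohort$genes
    reference <- cohort$reference
    depth <- cohort$depth
    truth <- cohort$truth
    report$stages$simulate <- list(
      status = "done", n_samples = nrow(meta), n_sites = nrow(gm$gt),
      n_genes = length(unique(genes$gene_id)),
      true_region = as.integer(truth$region),
      dup_genes = truth$dup_genes
    )
  } else {
    inp <- config$inputs
    if (is.null(inp$vcf) || is.null(inp$meta)) {
      stop("with the simulate stage off, 'inputs' must name vcf and meta files")
    }
    gm <- read_vcf(inp$vcf)
    meta <- read_metadata_tsv(inp$meta)
    genes <- if (!is.null(inp$gff)) read_gff3(inp$gff) else NULL
    reference <- if (!is.null(inp$fasta)) {
      unname(read_reference_fasta(inp$fasta)[1L])
    } else NULL
    depth <- if (!is.null(inp$depth)) read_depth_tsv(inp$depth) else NULL
    report$stages$simulate <- list(status = "skipped")
  }

  ## ---- qc --------------------------------------------------------------
  if (isTRUE(config$stages$qc)) {
    th <- do.call(filter_thresholds, config$qc)
    gm <- filter_sites(gm, th)
    qc_rep <- attr(gm, "qc_report")
    fs <- filter_samples(gm, th)
    gm <- fs$gm
    meta <- meta[meta$id %in% gm$samples, , drop = FALSE]
    write_vcf(gm, file.path(outdir, "filtered.vcf"))
    files <- c(files, file.path(outdir, "filtered.vcf"))
    report$stages$qc <- list(status = "done", removed = qc_rep,
                             excluded_samples = fs$excluded,
                             sites_kept = nrow(gm$gt),
                             samples_kept = ncol(gm$gt))
  } else {
    report$stages$qc <- list(status = "skipped")
  }

  ## ---- genotype --------------------------------------------------------
  calls <- NULL
  if (isTRUE(config$stages$genotype)) {
    gp <- config$genotype
    calls <- supergene_genotype(
      gm, meta, fis_threshold = gp$fis_threshold,
      window_size = gp$window_size,
      max_missing_carriers = gp$max_missing_carriers,
      majority = gp$majority, min_fold = gp$min_fold, min_run = gp$min_run
    )
    utils::write.table(calls$calls, file.path(outdir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_region_bed(calls, file.path(outdir, "region.bed"))
    write_hset_tsv(calls$hset, gm$chrom, file.path(outdir, "hset.tsv"),
                   file.path(outdir, "hset.bed"))
    files <- c(files, file.path(outdir, c("calls.tsv", "region.bed",
                                          "hset.tsv", "hset.bed")))
    report$stages$genotype <- list(
      status = "done", n_carriers = length(calls$carriers),
      region = as.integer(calls$region),
      n_hset = length(calls$hset$positions),
      class_counts = as.list(table(calls$calls$assigned_class))
    )
  } else {
    report$stages$genotype <- list(status = "skipped")
  }

  ## ---- scan ------------------------------------------------------------
  if (isTRUE(config$stages$scan)) {
    if (is.null(calls) || is.null(genes)) {
      stop("scan stage requires the genotype stage and gene models")
    }
    cls <- stats::setNames(calls$calls$assigned_class,
                           calls$calls$sample_id)
    mm <- names(cls)[cls == "MM"]
    counts <- count_p_specific(gm, calls$hset, genes, samples = mm)
    sf <- stats::setNames(meta$social_form, meta$species)
    sf <- sf[!duplicated(names(sf))]
    gene_tab <- contrast_groups(counts, meta$species[match(mm, meta$id)],
                                sf, n_tests = config$scan$n_tests)
    candidates <- gene_tab$gene_id[gene_tab$p < config$scan$alpha]
    utils::write.table(gene_tab, file.path(outdir, "gene_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, file.path(outdir, "gene_scores.tsv"))

    depth_res <- NULL
    if (!is.null(depth) && length(candidates)) {
      nd <- normalize_depth(depth)
      ## depth contrast within species segregating for both genotypes
      mp <- names(cls)[cls == "MP"]
      seg_species <- intersect(unique(meta$species[match(mm, meta$id)]),
                               unique(meta$species[match(mp, meta$id)]))
      mm_seg <- mm[meta$species[match(mm, meta$id)] %in% seg_species]
      mp_seg <- mp[meta$species[match(mp, meta$id)] %in% seg_species]
      if (length(mm_seg) && length(mp_seg)) {
        depth_res <- depth_contrast(nd, mm_seg, mp_seg, genes = candidates)
        utils::write.table(depth_res, file.path(outdir, "depth_contrast.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, file.path(outdir, "depth_contrast.tsv"))
      }
    }
    males <- meta$id[meta$ploidy == 1L & meta$id %in% gm$samples]
    flags <- NULL
    if (length(males)) {
      ph <- haploid_pseudo_het(gm, calls$hset, genes, males,
                               config$scan$flag_threshold)
      flagged <- which(ph$flags, arr.ind = TRUE)
      flags <- data.frame(
        gene_id = rownames(ph$flags)[flagged[, 1L]],
        sample_id = colnames(ph$flags)[flagged[, 2L]]
      )
      utils::write.table(flags, file.path(outdir, "pseudo_het_flags.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, file.path(outdir, "pseudo_het_flags.tsv"))
    }
    report$stages$scan <- list(
      status = "done", n_genes_tested = sum(gene_tab$n_sites > 0),
      candidate_genes = candidates,
      depth_contrast = if (!is.null(depth_res)) {
        lapply(seq_len(nrow(depth_res)), function(i) as.list(depth_res[i, ]))
      },
      pseudo_het_flagged = if (!is.null(flags)) unique(flags$gene_id)
    )
  } else {
    report$stages$scan <- list(status = "skipped")
  }

  ## ---- load ------------------------------------------------------------
  if (isTRUE(config$stages$load)) {
    if (is.null(genes) || is.null(reference)) {
      stop("load stage requires gene models and a reference sequence")
    }
    region <- config$load$region
    if (is.null(region)) {
      if (is.null(calls) || !length(calls$region)) {
        stop("load stage needs a region: run the genotype stage or set load$region")
      }
      region <- calls$region
    }
    effects <- classify_effects(gm, genes, reference)
    utils::write.table(effects, file.path(outdir, "effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cls <- stats::setNames(calls$calls$assigned_class, calls$calls$sample_id)
    workers <- names(cls)[cls %in% c("MM", "MP")]
    summaries <- load_summaries(gm, effects, workers, region, cls)
    utils::write.table(summaries, file.path(outdir, "load_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mm <- names(cls)[cls == "MM"]; mp <- names(cls)[cls == "MP"]
    contrasts <- lapply(c("high", "moderate", "low"), function(cat) {
      contrast_load(summaries, mm, mp, cat)
    })
    names(contrasts) <- c("high", "moderate", "low")
    files <- c(files, file.path(outdir, c("effects.tsv",
                                          "load_summaries.tsv")))
    report$stages$load <- list(
      status = "done", region = as.integer(region),
      n_coding_snps = sum(effects$impact %in% c("high", "moderate", "low")),
      contrasts = contrasts
    )
  } else {
    report$stages$load <- list(status = "skipped")
  }

  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  rel <- sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", outdir),
                    "/?"), "", unname(files))
  writeLines(sort(unique(c(rel, "report.json"))),
             file.path(outdir, "MANIFEST"))
  invisible(report)
}

write_region_bed <- function(calls, path) {
  if (length(calls$region)) {
    ## BED: 0-based half-open
    writeLines(sprintf("%s\t%d\t%d\tsupergene", calls$scan$chrom,
                       calls$region[1] - 1L, calls$region[2]), path)
  } else {
    writeLines(character(0), path)
  }
  invisible(path)
}

write_hset_tsv <- function(hset, chrom, tsv_path, bed_path) {
  utils::write.table(
    data.frame(chrom = chrom, pos = hset$positions),
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(sprintf("%s\t%d\t%d", chrom, hset$positions - 1L,
                     hset$positions), bed_path)
  invisible(tsv_path)
}
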