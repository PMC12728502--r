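#' Write a genotype matrix as a VCF 4.2 file
#'
#' Emits biallelic SNP records with per-sample `GT:DP:GQ`, a per-site QUAL
#' column and 1-based positions. The writer formats records directly so the
#' output is byte-deterministic; reading is delegated to vcfR.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param chrom_length optional chromosome length for the `##contig` header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, chrom_length = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  contig <- if (is.null(chrom_length)) {
    sprintf("##contig=<ID=%s>", gm$chrom)
  } else {
    sprintf("##contig=<ID=%s,length=%d>", gm$chrom, chrom_length)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=supergeneR",
    contig,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")
  g <- matrix("./.", nrow = nrow(gm$gt), ncol = ncol(gm$gt))
  ok <- !is.na(gm$gt)
  g[ok] <- gt_str[gm$gt[ok] + 1L]
  gq <- pmin(99L, 30L + gm$dp)
  cell <- matrix(paste(g, gm$dp, gq, sep = ":"), nrow = nrow(gm$gt))
  sample_cols <- apply(cell, 1L, paste, collapse = "\t")
  if (nrow(gm$gt) == 0L) sample_cols <- character(0)
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt,
                format_qual(gm$qual), "PASS", ".", "GT:DP:GQ", sample_cols,
                sep = "\t")
  writeLines(c(header, body), con)
  invisible(path)
}

format_qual <- function(q) {
  ifelse(is.na(q), ".",
         ifelse(q == round(q), sprintf("%d", as.integer(round(q))),
                sprintf("%.2f", q)))
}

#' Read a VCF into a genotype matrix
#'
#' Parses with [vcfR::read.vcfR()]. Genotypes are stored as allele dosages
#' (count of non-reference alleles); multiallelic or non-SNP records are
#' retained as written (with their ALT string) so that site filtering can
#' remove them by rule. All records must be on one chromosome.
#'
#' @param path VCF file path.
#' @return a [genotype_matrix()] (with a `filter` attribute holding the
#'   FILTER column).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  chroms <- unique(fix[, "CHROM"])
  if (length(chroms) > 1L) {
    stop("expected a single-chromosome VCF, found: ",
         paste(chroms, collapse = ", "))
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ## dosage: number of non-reference alleles in the call
  a1 <- substr(gt_raw, 1L, 1L)
  a2 <- substr(gt_raw, 3L, 3L)
  dos <- (a1 != "0") + (a2 != "0")
  dos[a1 == "." | a2 == "." | is.na(gt_raw)] <- NA_integer_
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  gm <- genotype_matrix(
    gt = dos, dp = dp_raw, chrom = chroms,
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    qual = qual, samples = colnames(gt_raw)
  )
  attr(gm, "filter") <- unname(fix[, "FILTER"])
  gm
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features with 1-based inclusive coordinates and
#' CDS phase, via rtracklayer.
#'
#' @param genes a [gene_models()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  ids <- unique(genes$gene_id)
  per_gene <- do.call(rbind, lapply(ids, function(g) {
    gp <- genes[genes$gene_id == g, , drop = FALSE]
    data.frame(gene_id = g, chrom = gp$chrom[1L], start = min(gp$start),
               end = max(gp$end), strand = gp$strand[1L])
  }))
  mk <- function(chrom, start, end, strand, type, id, parent, phase) {
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start, end = end),
      strand = strand, type = type, ID = id, Parent = parent,
      phase = phase, source = "supergeneR"
    )
  }
  gene_gr <- mk(per_gene$chrom, per_gene$start, per_gene$end, per_gene$strand,
                "gene", per_gene$gene_id, NA_character_, NA_integer_)
  mrna_gr <- mk(per_gene$chrom, per_gene$start, per_gene$end, per_gene$strand,
                "mRNA", paste0(per_gene$gene_id, ".t1"), per_gene$gene_id,
                NA_integer_)
  cds_gr <- mk(genes$chrom, genes$start, genes$end, genes$strand, "CDS",
               sprintf("%s.t1.cds%d", genes$gene_id, genes$exon_rank),
               paste0(genes$gene_id, ".t1"), as.integer(genes$phase))
  gr <- c(gene_gr, mrna_gr, cds_gr)
  gr <- gr[order(GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports CDS features via rtracklayer, reconstructs transcript order from
#' coordinates and strand, and keeps the primary (longest-CDS) transcript
#' per gene.
#'
#' @param path GFF3 file path.
#' @return a [gene_models()] table.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (!length(cds)) stop("no CDS features in ", path)
  parent <- as.character(unlist(cds$Parent))
  tx2gene <- local({
    mrna <- gr[gr$type == "mRNA"]
    if (length(mrna)) {
      stats::setNames(as.character(unlist(mrna$Parent)), mrna$ID)
    } else {
      stats::setNames(parent, parent)
    }
  })
  parts <- data.frame(
    gene_id = unname(tx2gene[parent]),
    transcript_id = parent,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds)),
    phase = if (!is.null(cds$phase)) as.integer(cds$phase) else NA_integer_
  )
  parts$gene_id[is.na(parts$gene_id)] <- parts$transcript_id[is.na(parts$gene_id)]
  ## transcript order: ascending start on +, descending on -
  parts <- parts[order(parts$gene_id, ifelse(parts$strand == "-", -1L, 1L) *
                         parts$start), , drop = FALSE]
  parts$exon_rank <- stats::ave(seq_len(nrow(parts)), parts$transcript_id,
                                FUN = seq_along)
  primary_transcripts(parts)
}

#' Write / read the reference sequence as FASTA
#' @param reference chromosome sequence (single character string).
#' @param chrom sequence name.
#' @param path file path.
#' @return `path` (writer) or a character string (reader).
#' @export
write_reference_fasta <- function(reference, chrom, path) {
  x <- Biostrings::DNAStringSet(reference)
  names(x) <- chrom
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write all outputs of a simulated cohort
#'
#' Emits `cohort.vcf`, `depth.tsv`, `meta.tsv`, `genes.gff3`,
#' `reference.fa`, `counts.tsv` and `truth.json` under `dir`. All files are
#' plain text and round-trip through the package readers.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    depth = file.path(dir, "depth.tsv"),
    meta = file.path(dir, "meta.tsv"),
    gff = file.path(dir, "genes.gff3"),
    fasta = file.path(dir, "reference.fa"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(cohort$gm, paths["vcf"], chrom_length = cohort$config$chrom_length)
  write_depth_tsv(cohort$depth, paths["depth"])
  utils::write.table(cohort$meta, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gff3(cohort$genes, paths["gff"])
  write_reference_fasta(cohort$reference, cohort$config$chrom, paths["fasta"])
  utils::write.table(cohort$counts, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(classes = as.list(truth$classes), hset_pos = truth$hset_pos,
         divergent_pos = truth$divergent_pos,
         homogenized_pos = truth$homogenized_pos,
         pseudo_het_pos = truth$pseudo_het_pos, dup_genes = truth$dup_genes,
         dup_interval = truth$dup_interval, dup_carriers = truth$dup_carriers,
         region = truth$region, sites = truth$sites),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(paths)
}

write_depth_tsv <- function(depth, path) {
  df <- cbind(depth$parts,
              as.data.frame(round(depth$values, 4L), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-CDS depth table
#' @param path TSV with columns `part_id`, `gene_id`, `start`, `end` and one
#'   column per sample.
#' @return a `cds_depth` object (`$values` matrix parts x samples, `$parts`).
#' @export
read_depth_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta_cols <- c("part_id", "gene_id", "start", "end")
  values <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(values) <- df$part_id
  structure(list(values = values, parts = df[, meta_cols]),
            class = "cds_depth")
}

#' Read sample metadata
#' @param path TSV with columns `id`, `species`, `social_form`, `ploidy`,
#'   `caste`.
#' @return data frame of sample records.
#' @export
read_metadata_tsv <- function(path) {
  meta <- utils::read.delim(path)
  req <- c("id", "species", "social_form", "ploidy")
  if (!all(req %in% names(meta))) {
    stop("metadata lacks columns: ", paste(setdiff(req, names(meta)),
                                           collapse = ", "))
  }
  meta
}
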