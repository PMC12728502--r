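#' Gene models: CDS parts of protein-coding genes
#'
#' A `gene_models` object is a data frame with one row per CDS part (exon
#' segment of the coding sequence) and columns `gene_id`, `chrom`, `start`,
#' `end` (1-based inclusive), `strand` (`+`/`-`), `exon_rank` (transcript
#' order, 1 = 5' end of the CDS) and `phase` (GFF3 phase of the part).
#' One transcript per gene is represented; when several transcripts exist in
#' an imported annotation the longest CDS ("primary transcript") is kept.
#'
#' @param parts data frame with the columns above.
#' @return the validated `gene_models` data frame.
#' @export
gene_models <- function(parts) {
  req <- c("gene_id", "chrom", "start", "end", "strand", "exon_rank", "phase")
  missing_cols <- setdiff(req, names(parts))
  if (length(missing_cols)) {
    stop("gene model table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(parts$end >= parts$start), all(parts$strand %in% c("+", "-")))
  parts <- parts[order(parts$gene_id, parts$exon_rank), , drop = FALSE]
  rownames(parts) <- NULL
  class(parts) <- c("gene_models", "data.frame")
  parts
}

#' Total CDS length per gene
#' @param genes a [gene_models()] table.
#' @return named integer vector of summed CDS part lengths.
#' @export
cds_lengths <- function(genes) {
  len <- parts_len(genes)
  tapply(len, genes$gene_id, sum)[unique(genes$gene_id)]
}

parts_len <- function(genes) genes$end - genes$start + 1L

## Per-base CDS index in transcript order. Returns a list with
##   $site: data.frame(pos, gene_id, strand, tx_pos) ordered gene-by-gene in
##          transcript orientation (so codon mates are adjacent rows)
##   $splice: data.frame(pos, gene_id) for the 2 bp at each intron end
## Coding positions shared by overlapping genes are assigned to the first
## gene in table order (synthetic cohorts never overlap genes).
build_cds_index <- function(genes) {
  stopifnot(inherits(genes, "gene_models"))
  ids <- unique(genes$gene_id)
  site_list <- vector("list", length(ids))
  splice_list <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    gp <- genes[genes$gene_id == ids[k], , drop = FALSE]
    gp <- gp[order(gp$exon_rank), , drop = FALSE]
    pos <- unlist(lapply(seq_len(nrow(gp)), function(i) {
      if (gp$strand[i] == "+") gp$start[i]:gp$end[i] else gp$end[i]:gp$start[i]
    }), use.names = FALSE)
    site_list[[k]] <- data.frame(
      pos = pos, gene_id = ids[k], strand = gp$strand[1L],
      tx_pos = seq_along(pos)
    )
    ## introns in genomic coordinates: gaps between sorted parts
    sorted <- gp[order(gp$start), , drop = FALSE]
    if (nrow(sorted) > 1L) {
      int_start <- sorted$end[-nrow(sorted)] + 1L
      int_end <- sorted$start[-1L] - 1L
      ok <- int_end >= int_start
      sp <- unlist(mapply(function(s, e) {
        unique(c(s:min(s + 1L, e), max(e - 1L, s):e))
      }, int_start[ok], int_end[ok], SIMPLIFY = FALSE), use.names = FALSE)
      if (length(sp)) splice_list[[k]] <- data.frame(pos = sp, gene_id = ids[k])
    }
  }
  site <- do.call(rbind, site_list)
  dup <- duplicated(site$pos)
  if (any(dup)) site <- site[!dup, , drop = FALSE]
  splice <- do.call(rbind, splice_list)
  if (is.null(splice)) splice <- data.frame(pos = integer(0), gene_id = character(0))
  list(site = site, splice = splice)
}

## All genomic CDS positions of a set of genes (unordered use)
cds_positions <- function(genes, gene_ids = NULL) {
  gp <- genes
  if (!is.null(gene_ids)) gp <- gp[gp$gene_id %in% gene_ids, , drop = FALSE]
  unlist(mapply(function(s, e) s:e, gp$start, gp$end, SIMPLIFY = FALSE),
         use.names = FALSE)
}

#' Keep the primary (longest-CDS) transcript per gene
#'
#' Annotations may carry several transcripts per gene under distinct
#' `transcript_id`s; the effect classifier operates on one transcript per
#' gene, defined as the one with the longest summed CDS.
#'
#' @param parts data frame of CDS parts with a `transcript_id` column.
#' @return a [gene_models()] table with one transcript per gene.
#' @export
primary_transcripts <- function(parts) {
  if (!"transcript_id" %in% names(parts)) return(gene_models(parts))
  len <- (parts$end - parts$start + 1L)
  tx_len <- tapply(len, parts$transcript_id, sum)
  tx_gene <- tapply(parts$gene_id, parts$transcript_id, `[`, 1L)
  keep_tx <- vapply(split(names(tx_len), unlist(tx_gene)), function(txs) {
    txs[which.max(tx_len[txs])]
  }, character(1L))
  gene_models(parts[parts$transcript_id %in% keep_tx,
                    setdiff(names(parts), "transcript_id"), drop = FALSE])
}
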