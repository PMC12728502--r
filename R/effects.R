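## Minimal coding-consequence engine for biallelic SNPs.
##
## Codons are reconstructed from the CDS in transcript orientation (bases
## reverse-complemented on minus-strand genes) and translated with the
## standard genetic code. Fixed precedence at codon 1: when the reference
## codon is ATG, any amino-acid-changing substitution is start_lost, even if
## the alternative codon is also a stop.

CONSEQUENCE_IMPACT <- c(
  stop_gained = "high", stop_lost = "high", start_lost = "high",
  splice_disrupting = "high", frameshift = "high",
  missense = "moderate", synonymous = "low", non_coding = "modifier"
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                a = "t", c = "g", g = "c", t = "a")

ref_base_at <- function(reference, pos) {
  toupper(substring(reference, pos, pos))
}

## vectorized consequence call for (pos, alt) pairs against a CDS index
## alt is the genomic-strand alternative base
codon_consequences <- function(pos, alt, cds_index, reference) {
  n <- length(pos)
  stopifnot(length(alt) == n)
  site <- cds_index$site
  consequence <- rep("non_coding", n)
  gene_id <- rep(NA_character_, n)

  sp <- unique(cds_index$splice$pos)
  in_splice <- pos %in% sp
  if (any(in_splice)) {
    consequence[in_splice] <- "splice_disrupting"
    gene_id[in_splice] <- cds_index$splice$gene_id[
      match(pos[in_splice], cds_index$splice$pos)]
  }

  row <- match(pos, site$pos)
  cds <- !is.na(row)
  if (any(cds)) {
    ri <- row[cds]
    g <- site$gene_id[ri]
    strand <- site$strand[ri]
    tx <- site$tx_pos[ri]
    codon_off <- (tx - 1L) %% 3L
    codon_start_row <- ri - codon_off
    ## codon mates are adjacent rows of the transcript-ordered site table
    p1 <- site$pos[codon_start_row]
    p2 <- site$pos[codon_start_row + 1L]
    p3 <- site$pos[codon_start_row + 2L]
    b1 <- ref_base_at(reference, p1)
    b2 <- ref_base_at(reference, p2)
    b3 <- ref_base_at(reference, p3)
    minus <- strand == "-"
    if (any(minus)) {
      b1[minus] <- COMPLEMENT[b1[minus]]
      b2[minus] <- COMPLEMENT[b2[minus]]
      b3[minus] <- COMPLEMENT[b3[minus]]
    }
    alt_tx <- toupper(alt[cds])
    alt_tx[minus] <- COMPLEMENT[alt_tx[minus]]
    ref_codon <- paste0(b1, b2, b3)
    alt_codon <- ref_codon
    substr(alt_codon, codon_off + 1L, codon_off + 1L) <- alt_tx
    code <- Biostrings::GENETIC_CODE
    ref_aa <- unname(code[ref_codon])
    alt_aa <- unname(code[alt_codon])
    cons <- ifelse(ref_aa == alt_aa, "synonymous",
            ifelse(tx - codon_off == 1L & ref_codon == "ATG", "start_lost",
            ifelse(alt_aa == "*", "stop_gained",
            ifelse(ref_aa == "*", "stop_lost", "missense"))))
    consequence[cds] <- cons
    gene_id[cds] <- g
  }
  data.frame(pos = pos, gene_id = gene_id, consequence = consequence,
             impact = unname(CONSEQUENCE_IMPACT[consequence]))
}

#' Classify the coding consequence of one SNP
#'
#' Reconstructs the affected codon from the gene's CDS in transcript
#' orientation, translates reference and alternative codons with the
#' standard genetic code, and maps the consequence to an impact category:
#' stop_gained / stop_lost / start_lost / splice_disrupting are `high`,
#' missense is `moderate`, synonymous is `low`, and everything outside CDS
#' (and outside the 2 bp canonical splice positions at intron ends) is
#' `modifier`.
#'
#' @param pos 1-based genomic position of the SNP.
#' @param ref reference base; must match `reference` at `pos`.
#' @param alt alternative base.
#' @param genes a [gene_models()] table (primary transcripts).
#' @param reference chromosome sequence as a single character string.
#' @return one-row data frame: `pos`, `gene_id`, `consequence`, `impact`.
#' @export
classify_effect <- function(pos, ref, alt, genes, reference) {
  stopifnot(length(pos) == 1L)
  obs <- ref_base_at(reference, pos)
  if (obs != toupper(ref)) {
    stop(sprintf("reference mismatch at %d: expected %s, sequence has %s",
                 pos, ref, obs))
  }
  idx <- build_cds_index(genes)
  codon_consequences(pos, alt, idx, reference)
}

#' Classify coding consequences for all sites of a genotype matrix
#'
#' Vectorized form of [classify_effect()] over every site in `gm`; errors if
#' any stored REF allele disagrees with the reference sequence.
#'
#' @param gm a [genotype_matrix()].
#' @param genes a [gene_models()] table.
#' @param reference chromosome sequence as a single character string.
#' @param cds_index optional precomputed [build_cds_index()] result.
#' @return data frame with one row per site: `pos`, `gene_id`,
#'   `consequence`, `impact`.
#' @export
classify_effects <- function(gm, genes, reference, cds_index = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  obs <- ref_base_at(reference, gm$pos)
  bad <- which(obs != toupper(gm$ref))
  if (length(bad)) {
    stop(sprintf("reference mismatch at %d site(s), first at position %d",
                 length(bad), gm$pos[bad[1L]]))
  }
  if (is.null(cds_index)) cds_index <- build_cds_index(genes)
  codon_consequences(gm$pos, gm$alt, cds_index, reference)
}

## consequence of every possible substitution at every CDS position of the
## given genes; used for planting mutations with known impact
all_cds_consequences <- function(genes, reference, gene_ids = NULL) {
  gp <- genes
  if (!is.null(gene_ids)) {
    gp <- gene_models(as.data.frame(genes)[genes$gene_id %in% gene_ids, ,
                                           drop = FALSE])
  }
  idx <- build_cds_index(gp)
  pos <- idx$site$pos
  refb <- ref_base_at(reference, pos)
  bases <- c("A", "C", "G", "T")
  alt1 <- character(length(pos)); alt2 <- alt1; alt3 <- alt1
  for (b in seq_along(bases)) {
    others <- bases[-b]
    sel <- refb == bases[b]
    alt1[sel] <- others[1L]; alt2[sel] <- others[2L]; alt3[sel] <- others[3L]
  }
  out <- codon_consequences(rep(pos, 3L), c(alt1, alt2, alt3), idx, reference)
  out$alt <- c(alt1, alt2, alt3)
  out$ref <- rep(refb, 3L)
  out
}
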