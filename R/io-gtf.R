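# Gene models from GTF: per-transcript exon structure in cDNA coordinates.
#
# Genomic GTF coordinates are 1-based closed (the GTF standard); every cDNA
# coordinate in this toolkit is likewise 1-based and closed. Exon lengths are
# ordered 5'->3' in transcript orientation, so minus-strand transcripts have
# their genomic exon order reversed.

# Map a genomic position to a 1-based cDNA coordinate given exon intervals
# sorted in transcript orientation.
genomic_to_cdna <- function(pos, exon_start, exon_end, strand) {
  cum <- 0L
  for (i in seq_along(exon_start)) {
    len <- exon_end[i] - exon_start[i] + 1L
    if (pos >= exon_start[i] && pos <= exon_end[i]) {
      off <- if (strand == "+") pos - exon_start[i] + 1L
             else exon_end[i] - pos + 1L
      return(cum + off)
    }
    cum <- cum + len
  }
  NA_integer_
}

#' Read transcript gene models from a GTF file
#'
#' Parses `exon`, `CDS` and `start_codon` features (via
#' [rtracklayer::import()]; only the `gene_id` and `transcript_id` attributes
#' are used) and derives, per transcript, the exon length vector in
#' transcript orientation and the 1-based cDNA coordinate of the first
#' nucleotide of the start codon. Transcripts without CDS information get
#' `cds_start = NA`.
#'
#' @param path Path to a GTF file.
#' @param cdna_fasta Optional FASTA of transcript (cDNA) sequences named by
#'   `transcript_id`; lengths are validated against the exon structure.
#' @return Tibble with columns `gene_id`, `transcript_id`, `strand`,
#'   `n_exons`, `exon_lengths` (list column), `cds_start`, `cdna` (sequence
#'   or `NA`).
#' @export
read_gene_models <- function(path, cdna_fasta = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) {
                   abort_ps(sprintf("GTF parse error in %s: %s", path,
                                    conditionMessage(e)),
                            "psdosage_parse_error")
                 })
  df <- tibble::tibble(
    type = as.character(gr$type),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id
  )
  df <- df[df$type %in% c("exon", "CDS", "start_codon") &
             !is.na(df$transcript_id), , drop = FALSE]
  out <- lapply(split(df, df$transcript_id), function(tx) {
    txid <- tx$transcript_id[1]
    exons <- tx[tx$type == "exon", , drop = FALSE]
    cds <- tx[tx$type == "CDS", , drop = FALSE]
    startc <- tx[tx$type == "start_codon", , drop = FALSE]
    if (nrow(exons) == 0) {
      abort_ps(sprintf("transcript %s has CDS but no exons", txid),
               "psdosage_validation_error")
    }
    strand <- exons$strand[1]
    ord <- order(exons$start)
    exons <- exons[ord, , drop = FALSE]
    if (nrow(exons) > 1 &&
        any(exons$start[-1] <= exons$end[-nrow(exons)])) {
      abort_ps(sprintf("transcript %s has overlapping exons", txid),
               "psdosage_validation_error")
    }
    if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
    cds_start <- NA_integer_
    if (nrow(startc) > 0) {
      g <- if (strand == "+") min(startc$start) else max(startc$end)
      cds_start <- genomic_to_cdna(g, exons$start, exons$end, strand)
    } else if (nrow(cds) > 0) {
      g <- if (strand == "+") min(cds$start) else max(cds$end)
      cds_start <- genomic_to_cdna(g, exons$start, exons$end, strand)
    }
    tibble::tibble(
      gene_id = tx$gene_id[1], transcript_id = txid, strand = strand,
      n_exons = nrow(exons),
      exon_lengths = list(as.integer(exons$end - exons$start + 1L)),
      cds_start = cds_start, cdna = NA_character_)
  })
  models <- dplyr::bind_rows(out)
  if (!is.null(cdna_fasta)) {
    cdna <- read_cdna_fasta(cdna_fasta)
    models$cdna <- cdna$sequence[match(models$transcript_id, cdna$id)]
    lens <- vapply(models$exon_lengths, sum, integer(1))
    got <- !is.na(models$cdna)
    bad <- got & nchar(models$cdna) != lens
    if (any(bad)) {
      abort_ps(sprintf(
        "cDNA length mismatch for transcript(s): %s",
        paste(models$transcript_id[bad], collapse = ", ")),
        "psdosage_validation_error")
    }
  }
  models
}

#' Write an exon-level gene annotation as GTF
#'
#' The inverse of [read_gene_models()] for synthetic annotations: takes one
#' row per feature (`exon`, `CDS`, `start_codon`) with genomic coordinates
#' and writes standard 9-column GTF with `gene_id`/`transcript_id`
#' attributes.
#'
#' @param features Data frame with columns `seqname`, `source`, `type`,
#'   `start`, `end`, `strand`, `gene_id`, `transcript_id`.
#' @param path Output path.
#' @export
write_gene_models_gtf <- function(features, path) {
  lines <- sprintf(
    '%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    features$seqname, features$source %||% "psdosage", features$type,
    features$start, features$end, features$strand,
    features$gene_id, features$transcript_id)
  write_atomic(path, function(tmp) writeLines(lines, tmp))
}
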