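#' Gene model container
#'
#' Gene/transcript models with strand, ordered CDS intervals and a
#' canonical flag (standing in for presence in a curated gene-name
#' database). Intervals are 1-based closed. CDS intervals of a transcript
#' are non-overlapping and stored in transcription order (`exon_rank` 1 is
#' the 5' end of the transcript, i.e. the genomically last CDS interval for
#' minus-strand genes); the concatenated CDS length, including the stop
#' codon, must be divisible by 3.
#'
#' @param genes data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`) and optionally `canonical` (logical, default
#'   `TRUE`).
#' @param cds data.frame with columns `transcript_id`, `start`, `end`
#'   (1-based closed) and optionally `exon_rank`; if `exon_rank` is absent
#'   it is derived from genomic order and strand.
#' @param on_invalid what to do with transcripts whose CDS length is not a
#'   multiple of 3: `"drop"` (default; dropped with a warning), `"error"`
#'   (strict mode) or `"keep"`.
#' @return An object of class `gene_models`: list with `genes` (including a
#'   computed `cds_len`) and `cds` data.tables.
#' @export
gene_models <- function(genes, cds, on_invalid = c("drop", "error", "keep")) {
  on_invalid <- match.arg(on_invalid)
  genes <- data.table::as.data.table(genes)
  cds <- data.table::as.data.table(cds)
  stopifnot(
    all(c("gene_id", "transcript_id", "chrom", "strand") %in% names(genes)),
    all(genes$strand %in% c("+", "-")),
    !anyDuplicated(genes$transcript_id),
    all(c("transcript_id", "start", "end") %in% names(cds)),
    all(cds$end >= cds$start),
    all(cds$transcript_id %in% genes$transcript_id)
  )
  if (!"canonical" %in% names(genes)) genes[, canonical := TRUE]
  # order genomically, check non-overlap, then rank in transcription order
  data.table::setorder(cds, transcript_id, start)
  overlap_bad <- cds[, any(start[-1] <= utils::head(end, -1)), by = transcript_id]
  if (any(overlap_bad$V1)) {
    stop(
      "overlapping CDS intervals in transcript(s): ",
      paste(overlap_bad$transcript_id[overlap_bad$V1], collapse = ", ")
    )
  }
  strand_of <- stats::setNames(genes$strand, genes$transcript_id)
  cds[, exon_rank := {
    n <- .N
    if (strand_of[[.BY$transcript_id]] == "+") seq_len(n) else rev(seq_len(n))
  }, by = transcript_id]
  lens <- cds[, .(cds_len = sum(end - start + 1L)), by = transcript_id]
  genes[, cds_len := lens$cds_len[match(transcript_id, lens$transcript_id)]]
  bad <- genes$transcript_id[genes$cds_len %% 3L != 0L]
  if (length(bad)) {
    msg <- paste0(
      "CDS length not divisible by 3 for transcript(s): ",
      paste(bad, collapse = ", ")
    )
    if (on_invalid == "error") stop(msg)
    if (on_invalid == "drop") {
      warning(msg, "; model(s) rejected")
      genes <- genes[!transcript_id %in% bad]
      cds <- cds[!transcript_id %in% bad]
    }
  }
  data.table::setorder(cds, transcript_id, exon_rank)
  structure(
    list(genes = genes[], cds = cds[, .(transcript_id, start, end, exon_rank)][]),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf(
    "<gene_models> %d transcripts in %d genes; %d CDS intervals\n",
    nrow(x$genes), length(unique(x$genes$gene_id)), nrow(x$cds)
  ))
  invisible(x)
}

#' CDS intervals as GRanges
#'
#' @param gm a [gene_models()] object.
#' @return `GRanges` of CDS intervals with `transcript_id`, `gene_id`,
#'   `exon_rank` and strand.
#' @export
cds_granges <- function(gm) {
  j <- match(gm$cds$transcript_id, gm$genes$transcript_id)
  gr <- GenomicRanges::GRanges(
    seqnames = gm$genes$chrom[j],
    ranges = IRanges::IRanges(gm$cds$start, gm$cds$end),
    strand = gm$genes$strand[j]
  )
  gr$transcript_id <- gm$cds$transcript_id
  gr$gene_id <- gm$genes$gene_id[j]
  gr$exon_rank <- gm$cds$exon_rank
  gr
}

#' Transcript spans (CDS extent) as GRanges
#'
#' @param gm a [gene_models()] object.
#' @return One range per transcript covering its CDS extent.
#' @export
transcript_spans <- function(gm) {
  sp <- gm$cds[, .(start = min(start), end = max(end)), by = transcript_id]
  j <- match(sp$transcript_id, gm$genes$transcript_id)
  gr <- GenomicRanges::GRanges(
    seqnames = gm$genes$chrom[j],
    ranges = IRanges::IRanges(sp$start, sp$end),
    strand = gm$genes$strand[j]
  )
  gr$transcript_id <- sp$transcript_id
  gr$gene_id <- gm$genes$gene_id[j]
  gr
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 files are read with `rtracklayer` and must carry `CDS` features
#' whose `Parent` points at an `mRNA`/transcript feature (itself pointing at
#' a gene); a `canonical` attribute (`0`/`1`) on the transcript or gene is
#' honoured and defaults to canonical. In BED12 the blocks are taken as the
#' CDS intervals, the name column as `gene|transcript` (or both gene and
#' transcript id when no `|` is present).
#'
#' @param path file path (`.gff3`/`.gff` or `.bed`).
#' @param on_invalid see [gene_models()]; `"error"` is strict mode.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, on_invalid = c("drop", "error", "keep")) {
  on_invalid <- match.arg(on_invalid)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    name <- as.character(gr$name)
    gene <- sub("\\|.*$", "", name)
    tx <- ifelse(grepl("\\|", name), sub("^.*\\|", "", name), name)
    blocks <- gr$blocks
    nb <- lengths(blocks)
    abs_blocks <- IRanges::shift(unlist(blocks), rep(GenomicRanges::start(gr) - 1L, nb))
    cds <- data.table::data.table(
      transcript_id = rep(tx, nb),
      start = IRanges::start(abs_blocks),
      end = IRanges::end(abs_blocks)
    )
    genes <- data.table::data.table(
      gene_id = gene, transcript_id = tx,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      canonical = TRUE
    )
    return(gene_models(genes, cds, on_invalid = on_invalid))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  tx_feat <- gr[typ %in% c("mRNA", "transcript")]
  cds_feat <- gr[typ == "CDS"]
  if (length(cds_feat) == 0) stop("no CDS features in ", path)
  first_chr <- function(x) vapply(x, function(v) as.character(v)[1], character(1))
  tx_id <- as.character(tx_feat$ID)
  tx_gene <- first_chr(tx_feat$Parent)
  canonical <- rep(TRUE, length(tx_feat))
  if (!is.null(tx_feat$canonical)) {
    canonical <- !(as.character(tx_feat$canonical) %in% c("0", "false", "FALSE"))
  }
  cds_tx <- first_chr(cds_feat$Parent)
  if (!all(cds_tx %in% tx_id)) {
    # CDS attached directly to genes (no mRNA level): treat parent as both
    missing_tx <- setdiff(unique(cds_tx), tx_id)
    tx_id <- c(tx_id, missing_tx)
    tx_gene <- c(tx_gene, missing_tx)
    canonical <- c(canonical, rep(TRUE, length(missing_tx)))
    tx_feat <- c(tx_feat, cds_feat[match(missing_tx, cds_tx)])
  }
  j <- match(tx_id, cds_tx)
  genes <- data.table::data.table(
    gene_id = tx_gene, transcript_id = tx_id,
    chrom = as.character(GenomicRanges::seqnames(cds_feat))[j],
    strand = as.character(GenomicRanges::strand(cds_feat))[j],
    canonical = canonical
  )
  genes <- genes[transcript_id %in% cds_tx]
  cds <- data.table::data.table(
    transcript_id = cds_tx,
    start = GenomicRanges::start(cds_feat),
    end = GenomicRanges::end(cds_feat)
  )
  gene_models(genes, cds, on_invalid = on_invalid)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features with `ID`/`Parent` links and a
#' `canonical` attribute, readable by [read_gene_models()].
#'
#' @param gm a [gene_models()] object.
#' @param path output path.
#' @export
write_gene_models <- function(gm, path) {
  g <- gm$genes
  cds <- merge(gm$cds, g[, .(transcript_id, gene_id, chrom, strand)],
    by = "transcript_id"
  )
  span <- cds[, .(start = min(start), end = max(end)),
    by = .(transcript_id, gene_id, chrom, strand)
  ]
  span[, canonical := as.integer(g$canonical[match(transcript_id, g$transcript_id)])]
  lines <- c(
    "##gff-version 3",
    span[, .(start = min(start), end = max(end)), by = .(gene_id, chrom, strand)][
      , sprintf(
        "%s\tlofcohort\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
        chrom, start, end, strand, gene_id
      )
    ],
    span[, sprintf(
      "%s\tlofcohort\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;canonical=%d",
      chrom, start, end, strand, transcript_id, gene_id, canonical
    )],
    cds[, sprintf(
      "%s\tlofcohort\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s-%d;Parent=%s",
      chrom, start, end, strand, transcript_id, exon_rank, transcript_id
    )]
  )
  writeLines(lines, path)
  invisible(path)
}
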