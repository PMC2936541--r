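#' Annotate a cohort against gene models
#'
#' Classifies every variant by functional consequence against every
#' transcript whose CDS extent it touches. SNVs inside CDS are classified
#' by codon translation (standard genetic code, strand aware): an alternate
#' codon translating to stop where the reference does not is `stop_gain`,
#' the reverse is `stop_loss`, otherwise `synonymous`/`nonsynonymous`.
#' Coding indels are `frameshift` when the net length change is not a
#' multiple of 3, `inframe_indel` otherwise; deletions extending beyond a
#' CDS exon are flagged `junction_spanning` but still classified by net
#' coding-length change. Non-CDS positions route to `splice_boundary`
#' (within 2 bp of a CDS exon edge on the intron side), `intronic` (inside
#' the CDS extent), or `intergenic`. Coding variants also get a relative
#' CDS position in (0, 1]: coding index of the first affected CDS base over
#' CDS length.
#'
#' @param cohort a [cohort_table()].
#' @param genes a [gene_models()] object.
#' @param ref reference `DNAStringSet` (see [read_reference()]).
#' @param check_ref validate that SNV reference alleles match the reference
#'   sequence (error naming the first offending site).
#' @return An object of class `annotated_cohort`: list with the inputs plus
#'   `ann` (one row per variant x overlapping transcript: `site_id`,
#'   `gene_id`, `transcript_id`, `class`, `rel_cds_pos`,
#'   `junction_spanning`) and `gene_class` (per variant x gene: the most
#'   severe class across transcripts).
#' @export
annotate_cohort <- function(cohort, genes, ref, check_ref = TRUE) {
  ann <- annotate_variants(cohort$sites, genes, ref, check_ref = check_ref)
  sev <- stats::setNames(seq_along(FUNCTIONAL_CLASSES), FUNCTIONAL_CLASSES)
  genic <- ann[!is.na(gene_id)]
  gene_class <- if (nrow(genic)) {
    genic[order(sev[class]),
      .(class = class[1], rel_cds_pos = rel_cds_pos[1]),
      by = .(site_id, gene_id)
    ]
  } else {
    data.table::data.table(
      site_id = character(), gene_id = character(),
      class = character(), rel_cds_pos = numeric()
    )
  }
  structure(
    list(
      cohort = cohort, genes = genes, ref = ref,
      ann = ann, gene_class = gene_class
    ),
    class = "annotated_cohort"
  )
}

#' @export
print.annotated_cohort <- function(x, ...) {
  print(x$cohort)
  cl <- table(x$gene_class$class)
  cat(
    "  gene-level classes:",
    paste(sprintf("%s=%d", names(cl), cl), collapse = " "), "\n"
  )
  invisible(x)
}

# Core annotation engine: one row per variant x overlapping transcript
# (plus an intergenic row with NA transcript for unassigned variants).
annotate_variants <- function(sites, gm, ref, check_ref = TRUE) {
  sites <- data.table::as.data.table(sites)
  if (!"site_id" %in% names(sites)) {
    sites[, site_id := site_key(chrom, pos, ref, alt)]
  }
  if (!"kind" %in% names(sites)) sites[, kind := variant_kind(ref, alt)]
  chrom_str <- stats::setNames(as.character(ref), names(ref))
  if (check_ref && any(sites$kind == "SNV")) {
    sv <- sites[kind == "SNV"]
    have <- substring(chrom_str[sv$chrom], sv$pos, sv$pos)
    bad <- which(have != sv$ref)
    if (length(bad)) {
      stop(
        "reference mismatch at ", sv$site_id[bad[1]],
        ": reference has ", have[bad[1]]
      )
    }
  }

  fp <- sites_granges(sites)
  txs <- transcript_spans(gm)
  cdsg <- cds_granges(gm)

  # cumulative CDS length before each exon, in transcription order
  cum_dt <- data.table::as.data.table(gm$cds)
  data.table::setorder(cum_dt, transcript_id, exon_rank)
  cum_dt[, exon_len := end - start + 1L]
  cum_dt[, cum_before := cumsum(c(0L, utils::head(exon_len, -1))), by = transcript_id]
  cum_key <- paste(cum_dt$transcript_id, cum_dt$exon_rank)
  cum_before <- stats::setNames(cum_dt$cum_before, cum_key)

  gene_of_tx <- stats::setNames(gm$genes$gene_id, gm$genes$transcript_id)
  strand_of_tx <- stats::setNames(gm$genes$strand, gm$genes$transcript_id)
  len_of_tx <- stats::setNames(gm$genes$cds_len, gm$genes$transcript_id)

  ph <- GenomicRanges::findOverlaps(fp, txs, ignore.strand = TRUE)
  pairs <- data.table::data.table(
    si = S4Vectors::queryHits(ph),
    transcript_id = txs$transcript_id[S4Vectors::subjectHits(ph)]
  )

  ch <- GenomicRanges::findOverlaps(fp, cdsg, ignore.strand = TRUE)
  cds_ov <- data.table::data.table(
    si = S4Vectors::queryHits(ch),
    transcript_id = cdsg$transcript_id[S4Vectors::subjectHits(ch)],
    ex_start = GenomicRanges::start(cdsg)[S4Vectors::subjectHits(ch)],
    ex_end = GenomicRanges::end(cdsg)[S4Vectors::subjectHits(ch)],
    exon_rank = cdsg$exon_rank[S4Vectors::subjectHits(ch)]
  )
  cds_ov[, fp_start := GenomicRanges::start(fp)[si]]
  cds_ov[, fp_end := GenomicRanges::end(fp)[si]]
  cds_ov[, ov_start := pmax(fp_start, ex_start)]
  cds_ov[, ov_end := pmin(fp_end, ex_end)]
  cds_ov[, strand := strand_of_tx[transcript_id]]
  cds_ov[, cumb := cum_before[paste(transcript_id, exon_rank)]]
  # minimal coding index (transcription order) touched within this exon
  cds_ov[, min_cidx := data.table::fifelse(
    strand == "+",
    cumb + (ov_start - ex_start + 1L),
    cumb + (ex_end - ov_end + 1L)
  )]

  per_pair <- cds_ov[, .(
    min_cidx = if (.N) min(min_cidx) else NA_integer_,
    ov_width = sum(ov_end - ov_start + 1L),
    fp_width = fp_end[1] - fp_start[1] + 1L
  ), by = .(si, transcript_id)]

  pairs <- merge(pairs, per_pair, by = c("si", "transcript_id"), all.x = TRUE)
  pairs[, kind := sites$kind[si]]
  pairs[, strand := strand_of_tx[transcript_id]]
  pairs[, cds_len := len_of_tx[transcript_id]]
  pairs[, class := NA_character_]
  pairs[, rel_cds_pos := NA_real_]
  pairs[, junction_spanning := FALSE]

  coding <- !is.na(pairs$min_cidx)
  # coding indels
  ci <- which(coding & pairs$kind != "SNV")
  if (length(ci)) {
    net <- abs(nchar(sites$ref[pairs$si[ci]]) - nchar(sites$alt[pairs$si[ci]]))
    pairs$class[ci] <- ifelse(net %% 3L == 0L, "inframe_indel", "frameshift")
    pairs$junction_spanning[ci] <- pairs$ov_width[ci] < pairs$fp_width[ci]
    pairs$rel_cds_pos[ci] <- pairs$min_cidx[ci] / pairs$cds_len[ci]
  }
  # coding SNVs: codon translation, strand aware
  cs <- which(coding & pairs$kind == "SNV")
  if (length(cs)) {
    txp_cache <- new.env(parent = emptyenv())
    get_txp <- function(tx) {
      if (is.null(txp_cache[[tx]])) txp_cache[[tx]] <- tx_positions(gm, tx)
      txp_cache[[tx]]
    }
    for (i in cs) {
      si <- pairs$si[i]
      tx <- pairs$transcript_id[i]
      cidx <- pairs$min_cidx[i]
      txp <- get_txp(tx)
      codon_i <- (cidx - 1L) %/% 3L
      cpos <- txp[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
      ch_s <- chrom_str[sites$chrom[si]]
      bases <- substring(ch_s, cpos, cpos)
      minus <- pairs$strand[i] == "-"
      if (minus) bases <- chartr("ACGT", "TGCA", bases)
      ref_codon <- paste(bases, collapse = "")
      off <- (cidx - 1L) %% 3L + 1L
      alt_base <- sites$alt[si]
      if (minus) alt_base <- chartr("ACGT", "TGCA", alt_base)
      alt_codon <- ref_codon
      substr(alt_codon, off, off) <- alt_base
      ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
      alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
      pairs$class[i] <- if (alt_aa == "*" && ref_aa != "*") {
        "stop_gain"
      } else if (ref_aa == "*" && alt_aa != "*") {
        "stop_loss"
      } else if (ref_aa == alt_aa) {
        "synonymous"
      } else {
        "nonsynonymous"
      }
      pairs$rel_cds_pos[i] <- cidx / pairs$cds_len[i]
    }
  }
  # non-coding pairs: splice boundary (2 bp intron side of a CDS edge) or
  # intronic
  nc <- which(!coding)
  if (length(nc)) {
    flank_l <- GenomicRanges::flank(cdsg, 2L, start = TRUE, ignore.strand = TRUE)
    flank_r <- GenomicRanges::flank(cdsg, 2L, start = FALSE, ignore.strand = TRUE)
    flanks <- c(flank_l, flank_r)
    flanks$transcript_id <- c(cdsg$transcript_id, cdsg$transcript_id)
    fh <- GenomicRanges::findOverlaps(fp, flanks, ignore.strand = TRUE)
    near <- unique(data.table::data.table(
      si = S4Vectors::queryHits(fh),
      transcript_id = flanks$transcript_id[S4Vectors::subjectHits(fh)]
    ))
    near[, boundary := TRUE]
    pp <- pairs[nc]
    pp <- merge(pp, near, by = c("si", "transcript_id"), all.x = TRUE)
    # merge() reorders; recompute class on the merged copy then assign back
    pp[, class := data.table::fifelse(!is.na(boundary), "splice_boundary", "intronic")]
    key_nc <- paste(pairs$si[nc], pairs$transcript_id[nc])
    pairs$class[nc] <- pp$class[match(key_nc, paste(pp$si, pp$transcript_id))]
  }

  out <- pairs[, .(
    si, transcript_id,
    gene_id = gene_of_tx[transcript_id],
    class, rel_cds_pos, junction_spanning
  )]
  # intergenic rows for unassigned variants
  orphan <- setdiff(seq_len(nrow(sites)), unique(pairs$si))
  if (length(orphan)) {
    out <- rbind(out, data.table::data.table(
      si = orphan, transcript_id = NA_character_, gene_id = NA_character_,
      class = "intergenic", rel_cds_pos = NA_real_, junction_spanning = FALSE
    ))
  }
  out[, site_id := sites$site_id[si]]
  data.table::setorder(out, si, transcript_id, na.last = TRUE)
  out[, si := NULL]
  data.table::setcolorder(out, c(
    "site_id", "gene_id", "transcript_id", "class", "rel_cds_pos",
    "junction_spanning"
  ))
  out[]
}

#' Classify a single variant against one gene model
#'
#' Single-variant wrappers over the annotation engine, returning the class
#' (and relative CDS position) of a variant with respect to one transcript.
#' `classify_snv()` requires the reference base at the site to match the
#' variant's reference allele.
#'
#' @param variant a list or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param gene_model a [gene_models()] object (one or more transcripts; the
#'   first transcript is used).
#' @param reference `DNAStringSet`.
#' @return A one-row data.frame: `class`, `rel_cds_pos`,
#'   `junction_spanning`.
#' @export
classify_snv <- function(variant, gene_model, reference) {
  stopifnot(nchar(variant$ref) == 1L, nchar(variant$alt) == 1L)
  classify_one(variant, gene_model, reference, check_ref = TRUE)
}

#' @rdname classify_snv
#' @export
classify_indel <- function(variant, gene_model, reference) {
  stopifnot(nchar(variant$ref) != nchar(variant$alt))
  classify_one(variant, gene_model, reference, check_ref = FALSE)
}

classify_one <- function(variant, gene_model, reference, check_ref) {
  sites <- data.frame(
    chrom = variant$chrom, pos = variant$pos,
    ref = variant$ref, alt = variant$alt, known = FALSE
  )
  tx <- gene_model$genes$transcript_id[1]
  ann <- annotate_variants(sites, gene_model, reference, check_ref = check_ref)
  row <- ann[!is.na(ann$transcript_id) & ann$transcript_id == tx, ]
  if (nrow(row) == 0) row <- ann[1, ]
  as.data.frame(row[, c("class", "rel_cds_pos", "junction_spanning")])
}

#' Relative CDS position of a coding variant
#'
#' Coding-nucleotide index (transcription order) of the variant's first
#' affected CDS base, divided by CDS length; in (0, 1].
#'
#' @inheritParams classify_snv
#' @return numeric scalar.
#' @export
relative_cds_position <- function(variant, gene_model, reference) {
  row <- classify_one(variant, gene_model, reference, check_ref = FALSE)
  if (is.na(row$rel_cds_pos)) {
    stop("variant ", site_key(variant$chrom, variant$pos, variant$ref, variant$alt),
      " is not coding",
      call. = FALSE
    )
  }
  row$rel_cds_pos
}

#' Genes knocked out in a sample
#'
#' Genes carrying at least one protein-truncating or stop-loss variant
#' (stop gain, frameshift, stop loss) in homozygous form - homozygous
#' alternate, or hemizygous alternate on the male X - in the given sample.
#'
#' @param sample sample id.
#' @param annotated an [annotate_cohort()] result.
#' @param min_depth optional minimum depth for the call to count.
#' @return character vector of gene ids (possibly empty).
#' @export
knocked_out_genes <- function(sample, annotated, min_depth = 0) {
  stopifnot(inherits(annotated, "annotated_cohort"))
  gc <- annotated$gene_class[class %in% TRUNCATING_OR_STOPLOSS_CLASSES]
  if (nrow(gc) == 0) {
    return(character(0))
  }
  g <- annotated$cohort$geno[gc$site_id, sample]
  d <- annotated$cohort$depth[gc$site_id, sample]
  hom <- !is.na(g) & g %in% .GT_HOM_FORM & d >= min_depth
  sort(unique(gc$gene_id[hom]))
}

#' Universal homozygotes
#'
#' Variants called in homozygous (or hemizygous) form in every sample of
#' the cohort. Such variants typically indicate that the less common allele
#' is represented in the reference genome (or a reference error), and are
#' used as an exclusion list downstream.
#'
#' @param cohort a [cohort_table()] or [annotate_cohort()] result.
#' @return character vector of site ids.
#' @export
universal_homozygotes <- function(cohort) {
  if (inherits(cohort, "annotated_cohort")) cohort <- cohort$cohort
  if (nrow(cohort$samples) == 0) stop("empty cohort")
  g <- cohort$geno
  hom <- g %in% .GT_HOM_FORM
  dim(hom) <- dim(g)
  rownames(cohort$geno)[rowSums(hom) == ncol(g)]
}

#' Coding indel length summary
#'
#' Histogram of net length changes of coding indels (gene-level class
#' `frameshift` or `inframe_indel`) and the percentage that are multiples
#' of 3 bp.
#'
#' @param annotated an [annotate_cohort()] result.
#' @return list with `histogram` (data.table: `length`, `n`) and
#'   `pct_multiple_of_3` (`NA` if there are no coding indels).
#' @export
indel_length_summary <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_cohort"))
  gc <- unique(annotated$gene_class[
    class %in% c("frameshift", "inframe_indel"),
    .(site_id)
  ])
  if (nrow(gc) == 0) {
    return(list(
      histogram = data.table::data.table(length = integer(), n = integer()),
      pct_multiple_of_3 = NA_real_
    ))
  }
  s <- annotated$cohort$sites[match(gc$site_id, site_id)]
  len <- abs(nchar(s$ref) - nchar(s$alt))
  hist <- data.table::data.table(length = len)[, .(n = .N), by = length]
  data.table::setorder(hist, length)
  list(
    histogram = hist[],
    pct_multiple_of_3 = 100 * mean(len %% 3L == 0L)
  )
}
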