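#' Genotype state codes
#'
#' Genotype calls are stored in site-by-sample integer matrices using a
#' compact code: `0` = homozygous reference, `1` = heterozygous, `2` =
#' homozygous alternate, `3` = hemizygous alternate (single-copy male X
#' outside the pseudoautosomal region), `NA` = missing. Hemizygous calls are
#' kept as a distinct state rather than coerced to homozygous; downstream
#' operations decide equivalence explicitly (for example, gene knockouts and
#' qualifying-variant selection treat hemizygous alternate as "homozygous
#' form", while the homozygote/heterozygote QC ratio counts diploid calls
#' only).
#'
#' @format Integer scalar constants.
#' @name genotype-codes
NULL

#' @rdname genotype-codes
#' @export
GT_HOM_REF <- 0L
#' @rdname genotype-codes
#' @export
GT_HET <- 1L
#' @rdname genotype-codes
#' @export
GT_HOM_ALT <- 2L
#' @rdname genotype-codes
#' @export
GT_HEMI_ALT <- 3L

.GT_LABELS <- c("hom_ref", "het", "hom_alt", "hemizygous_alt")

#' Convert genotype codes to labels and back
#'
#' @param code integer vector of genotype codes (see [genotype-codes]).
#' @return `gt_label()` returns a character vector (`"missing"` for `NA`);
#'   `gt_code()` returns an integer vector (`NA` for `"missing"`).
#' @export
gt_label <- function(code) {
  out <- .GT_LABELS[code + 1L]
  out[is.na(code)] <- "missing"
  out
}

#' @rdname gt_label
#' @param label character vector of genotype labels.
#' @export
gt_code <- function(label) {
  out <- match(label, .GT_LABELS) - 1L
  bad <- is.na(out) & !(label %in% c("missing", NA))
  if (any(bad)) {
    stop("unknown genotype label(s): ", paste(unique(label[bad]), collapse = ", "))
  }
  out
}

# genotype codes that mean "carries the alternate allele"
.GT_CARRIER <- c(GT_HET, GT_HOM_ALT, GT_HEMI_ALT)
# codes that count as "homozygous form" for knockout / qualifying logic
.GT_HOM_FORM <- c(GT_HOM_ALT, GT_HEMI_ALT)

#' Functional class severity
#'
#' Ordering used to consolidate a variant's class across transcripts of the
#' same gene (most severe wins). Truncating classes (stop gain, frameshift)
#' and stop loss outrank missense, which outranks silent and non-coding
#' classes.
#'
#' @export
FUNCTIONAL_CLASSES <- c(
  "stop_gain", "frameshift", "stop_loss", "inframe_indel", "nonsynonymous",
  "synonymous", "utr", "splice_boundary", "intronic", "intergenic"
)

#' Variant class selectors
#'
#' `TRUNCATING_CLASSES` are the protein-truncating classes (premature stop
#' SNVs and frameshift indels). `TRUNCATING_OR_STOPLOSS_CLASSES` additionally
#' includes stop-loss SNVs, the grouping used for knocked-out genes,
#' prioritization and the knockout saturation curve.
#' @export
TRUNCATING_CLASSES <- c("stop_gain", "frameshift")

#' @rdname TRUNCATING_CLASSES
#' @export
TRUNCATING_OR_STOPLOSS_CLASSES <- c("stop_gain", "frameshift", "stop_loss")
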