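#' Cohort variant table
#'
#' The pipeline's central object: a site-by-sample table of genotype calls
#' with read depths, call qualities and a per-site known-variant flag.
#' Sites are keyed by `(chrom, pos, ref, alt)` (VCF-style 1-based position,
#' anchored indels) and every sample appears for every site; missing calls
#' are encoded explicitly (`NA` genotype), never dropped.
#'
#' @param samples data.frame with columns `sample_id`, `sex` (`"M"`/`"F"`),
#'   `phenotype` (`"case"`/`"control"`), and optionally `ancestry`.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `known` (logical). A `kind` column (`"SNV"`, `"insertion"`,
#'   `"deletion"`) is derived from the alleles if absent.
#' @param geno integer site x sample matrix of genotype codes
#'   (see [genotype-codes]).
#' @param depth integer site x sample matrix of read depths (`>= 0`).
#' @param qual optional numeric site x sample matrix of Phred-like call
#'   qualities; defaults to a depth-derived placeholder.
#' @return An object of class `cohort_table`: a list with elements
#'   `samples`, `sites` (a `data.table` keyed and sorted by site), `geno`,
#'   `depth` and `qual`; matrix rows are ordered like `sites` and named by
#'   `sites$site_id`.
#' @export
cohort_table <- function(samples, sites, geno, depth, qual = NULL) {
  samples <- as.data.frame(samples)
  stopifnot(
    all(c("sample_id", "sex", "phenotype") %in% names(samples)),
    !anyDuplicated(samples$sample_id),
    all(samples$sex %in% c("M", "F")),
    all(samples$phenotype %in% c("case", "control"))
  )
  sites <- data.table::as.data.table(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "known") %in% names(sites)))
  if (!"kind" %in% names(sites)) sites[, kind := variant_kind(ref, alt)]
  sites[, site_id := site_key(chrom, pos, ref, alt)]
  if (anyDuplicated(sites$site_id)) {
    stop("duplicate site keys: ", paste(utils::head(
      sites$site_id[duplicated(sites$site_id)]
    ), collapse = ", "))
  }
  geno <- as.matrix(geno)
  depth <- as.matrix(depth)
  ns <- nrow(sites)
  nk <- nrow(samples)
  stopifnot(
    nrow(geno) == ns, ncol(geno) == nk,
    nrow(depth) == ns, ncol(depth) == nk
  )
  if (is.null(qual)) qual <- pmin(pmax(depth * 1.5, 1), 99)
  qual <- as.matrix(qual)
  stopifnot(nrow(qual) == ns, ncol(qual) == nk)
  ok <- geno %in% c(0L, 1L, 2L, 3L) | is.na(geno)
  if (!all(ok)) stop("invalid genotype codes in `geno`")
  stopifnot(all(depth >= 0, na.rm = TRUE))

  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  sites <- sites[ord]
  geno <- geno[ord, , drop = FALSE]
  depth <- depth[ord, , drop = FALSE]
  qual <- qual[ord, , drop = FALSE]
  dimnames(geno) <- dimnames(depth) <- dimnames(qual) <-
    list(sites$site_id, samples$sample_id)
  data.table::setcolorder(sites, c("site_id", "chrom", "pos", "ref", "alt", "kind", "known"))
  structure(
    list(samples = samples, sites = sites, geno = geno, depth = depth, qual = qual),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d sites x %d samples (%d cases, %d controls)\n",
    nrow(x$sites), nrow(x$samples),
    sum(x$samples$phenotype == "case"), sum(x$samples$phenotype == "control")
  ))
  kinds <- table(x$sites$kind)
  cat("  ", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

#' Site keys and variant kinds
#'
#' `site_key()` builds the canonical `(chrom, pos, ref, alt)` key string;
#' `variant_kind()` classifies anchored alleles as `"SNV"`, `"insertion"`
#' or `"deletion"`.
#'
#' @param chrom,pos,ref,alt site fields (vectors).
#' @export
site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @rdname site_key
#' @export
variant_kind <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  out <- character(length(lr))
  out[lr == 1L & la == 1L] <- "SNV"
  out[la > lr] <- "insertion"
  out[la < lr] <- "deletion"
  if (any(out == "")) stop("cannot classify alleles with equal length > 1")
  out
}

#' Sample id helpers
#'
#' @param cohort a [cohort_table()].
#' @return character vector of case / control / male sample ids.
#' @export
case_ids <- function(cohort) {
  cohort$samples$sample_id[cohort$samples$phenotype == "case"]
}

#' @rdname case_ids
#' @export
control_ids <- function(cohort) {
  cohort$samples$sample_id[cohort$samples$phenotype == "control"]
}

#' @rdname case_ids
#' @export
male_ids <- function(cohort) {
  cohort$samples$sample_id[cohort$samples$sex == "M"]
}

#' Subset a cohort table
#'
#' @param cohort a [cohort_table()].
#' @param sample_ids samples to keep (order preserved as given).
#' @param site_ids optional site keys to keep.
#' @return A [cohort_table()] restricted to the requested samples/sites.
#' @export
subset_cohort <- function(cohort, sample_ids = cohort$samples$sample_id,
                          site_ids = NULL) {
  stopifnot(all(sample_ids %in% cohort$samples$sample_id))
  keep_s <- match(sample_ids, cohort$samples$sample_id)
  keep_v <- if (is.null(site_ids)) {
    seq_len(nrow(cohort$sites))
  } else {
    match(site_ids, cohort$sites$site_id)
  }
  stopifnot(!anyNA(keep_v))
  cohort_table(
    samples = cohort$samples[keep_s, , drop = FALSE],
    sites = cohort$sites[keep_v],
    geno = cohort$geno[keep_v, keep_s, drop = FALSE],
    depth = cohort$depth[keep_v, keep_s, drop = FALSE],
    qual = cohort$qual[keep_v, keep_s, drop = FALSE]
  )
}

#' GRanges view of cohort sites
#'
#' Variant footprints as 1-based closed intervals: an SNV covers its base,
#' a deletion covers the deleted bases (anchor excluded), and an insertion
#' is assigned to the base after its anchor.
#'
#' @param sites the `sites` table of a [cohort_table()] (or compatible
#'   data.frame).
#' @return A `GRanges` with `site_id` metadata, in site order.
#' @export
sites_granges <- function(sites) {
  lr <- nchar(sites$ref)
  la <- nchar(sites$alt)
  start <- ifelse(lr == 1L & la == 1L, sites$pos, sites$pos + 1L)
  end <- ifelse(lr > la, sites$pos + (lr - 1L), start)
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = start, end = end)
  )
  gr$site_id <- sites$site_id
  gr
}
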