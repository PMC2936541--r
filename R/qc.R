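#' Sequencing-versus-chip genotype concordance
#'
#' Compares sequencing genotype calls against genotyping-chip calls at the
#' chip's sites, per sample. Sites missing in either platform are excluded
#' from a sample's denominator; hemizygous sequencing calls are compared as
#' homozygous alternate (chips report diploid codes). Discordances are
#' binned into category 1 - homozygous by sequencing but heterozygous by
#' chip, the dominant low-coverage sequencing error mode - and category 2,
#' any other mismatch.
#'
#' @param cohort a [cohort_table()] (sequencing calls). Chip sites absent
#'   from the cohort's emitted sites are compared as homozygous-reference
#'   sequencing calls (the site was not called a variant).
#' @param chip integer genotype-code matrix (chip sites x samples,
#'   rownames = site ids, colnames = sample ids).
#' @param mean_coverage optional named per-sample mean coverage to include
#'   in the report (for concordance-versus-coverage pairing).
#' @return An object of class `concordance_report`: data.table with per
#'   sample `n_compared`, `n_concordant`, `concordance`, `category1`,
#'   `category2` and optionally `mean_coverage`; attribute `overall` holds
#'   the mean concordance across samples.
#' @export
concordance <- function(cohort, chip, mean_coverage = NULL) {
  shared_samples <- intersect(colnames(chip), cohort$samples$sample_id)
  if (length(shared_samples) == 0) stop("no shared samples")
  site_ids <- rownames(chip)
  if (is.null(site_ids)) stop("chip matrix needs site_id rownames")
  in_cohort <- site_ids %in% cohort$sites$site_id
  if (!any(in_cohort) && nrow(cohort$sites) > 0 && length(site_ids) == 0) {
    stop("zero shared sites")
  }
  seq_g <- matrix(GT_HOM_REF, length(site_ids), length(shared_samples),
    dimnames = list(site_ids, shared_samples)
  )
  if (any(in_cohort)) {
    seq_g[in_cohort, ] <- cohort$geno[site_ids[in_cohort], shared_samples]
  }
  seq_g[seq_g == GT_HEMI_ALT] <- GT_HOM_ALT
  chip_g <- chip[, shared_samples, drop = FALSE]
  chip_g[chip_g == GT_HEMI_ALT] <- GT_HOM_ALT

  rows <- lapply(shared_samples, function(sm) {
    s <- seq_g[, sm]
    c_ <- chip_g[, sm]
    ok <- !is.na(s) & !is.na(c_)
    n <- sum(ok)
    if (n == 0) stop("zero shared sites for sample ", sm)
    agree <- s[ok] == c_[ok]
    cat1 <- s[ok] %in% c(GT_HOM_REF, GT_HOM_ALT) & c_[ok] == GT_HET
    data.table::data.table(
      sample_id = sm,
      n_compared = n,
      n_concordant = sum(agree),
      concordance = mean(agree),
      category1 = sum(!agree & cat1),
      category2 = sum(!agree & !cat1)
    )
  })
  out <- data.table::rbindlist(rows)
  if (!is.null(mean_coverage)) {
    out[, mean_coverage := mean_coverage[sample_id]]
  }
  data.table::setattr(out, "overall", mean(out$concordance))
  data.table::setattr(out, "class", c("concordance_report", class(out)))
  out[]
}

#' Coverage summary from per-base depths and qualities
#'
#' A base is "covered" when it has at least `covered_min_reads` reads and
#' a Phred-like consensus quality strictly greater than
#' `covered_min_quality`. The percentage uses the non-N reference length
#' as denominator.
#'
#' @param depths integer vector of per-base read depths.
#' @param quals numeric vector of per-base consensus qualities (aligned
#'   with `depths`).
#' @param config an [analysis_config()].
#' @param denominator reference length to report the percentage against
#'   (default: `length(depths)`; pass the non-N genome length when the
#'   vectors cover the whole reference).
#' @return list: `covered_bases`, `pct_covered`, `mean_coverage`.
#' @export
coverage_summary <- function(depths, quals, config = analysis_config(),
                             denominator = length(depths)) {
  if (length(depths) == 0) stop("empty depth input")
  stopifnot(length(depths) == length(quals), denominator > 0)
  covered <- depths >= config$covered_min_reads &
    quals > config$covered_min_quality
  list(
    covered_bases = sum(covered),
    pct_covered = 100 * sum(covered) / denominator,
    mean_coverage = mean(depths)
  )
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; everything else is a transversion.
#' About 2.0-2.1 genome-wide in humans; a standard call-quality indicator.
#'
#' @param snvs data.frame with single-base `ref` and `alt` columns (one
#'   row per SNV observation).
#' @return ratio (transitions / transversions), `NA` if there are no
#'   transversions.
#' @export
titv_ratio <- function(snvs) {
  stopifnot(all(nchar(snvs$ref) == 1), all(nchar(snvs$alt) == 1))
  pur <- c("A", "G")
  ts <- (snvs$ref %in% pur) == (snvs$alt %in% pur)
  n_tv <- sum(!ts)
  if (n_tv == 0) {
    return(NA_real_)
  }
  sum(ts) / n_tv
}

#' Homozygote/heterozygote ratio per sample
#'
#' Ratio of homozygous-alternate to heterozygous calls per sample over
#' diploid calls (hemizygous male X calls are excluded from both counts),
#' plus the cohort mean.
#'
#' @param cohort a [cohort_table()].
#' @param kinds variant kinds to include (default SNVs only).
#' @return list: `per_sample` (data.table `sample_id`, `n_hom`, `n_het`,
#'   `ratio`; ratio `NA` when a sample has no heterozygotes), `mean`
#'   (cohort mean over defined ratios).
#' @export
hom_het_ratio <- function(cohort, kinds = "SNV") {
  rows <- cohort$sites$kind %in% kinds
  g <- cohort$geno[rows, , drop = FALSE]
  n_hom <- colSums(g == GT_HOM_ALT, na.rm = TRUE)
  n_het <- colSums(g == GT_HET, na.rm = TRUE)
  per <- data.table::data.table(
    sample_id = colnames(g),
    n_hom = n_hom, n_het = n_het,
    ratio = ifelse(n_het > 0, n_hom / n_het, NA_real_)
  )
  list(per_sample = per[], mean = mean(per$ratio, na.rm = TRUE))
}

#' Known-variant overlap per sample
#'
#' Fraction of each sample's SNV calls flagged as present in the known
#' variant catalogue, and the per-genome mean.
#'
#' @param cohort a [cohort_table()].
#' @return list: `per_sample` (data.table `sample_id`, `n_snv`, `n_known`,
#'   `fraction`), `mean`.
#' @export
known_overlap <- function(cohort) {
  rows <- cohort$sites$kind == "SNV"
  g <- cohort$geno[rows, , drop = FALSE]
  known <- cohort$sites$known[rows]
  carrier <- g %in% .GT_CARRIER
  dim(carrier) <- dim(g)
  n_snv <- colSums(carrier)
  n_known <- colSums(carrier & known)
  per <- data.table::data.table(
    sample_id = colnames(g),
    n_snv = n_snv, n_known = n_known,
    fraction = ifelse(n_snv > 0, n_known / n_snv, NA_real_)
  )
  list(per_sample = per[], mean = mean(per$fraction, na.rm = TRUE))
}

#' Validation concordance percentage
#'
#' Simple concordance arithmetic for orthogonal-validation summaries
#' (for example Sanger re-sequencing of selected calls): the percentage of
#' concordant genotype calls, rounded to one decimal.
#'
#' @param concordant_count,total_count call counts
#'   (`0 <= concordant <= total`, `total > 0`).
#' @return percentage with one decimal.
#' @export
validation_summary <- function(concordant_count, total_count) {
  stopifnot(
    total_count > 0, concordant_count >= 0, concordant_count <= total_count
  )
  round(100 * concordant_count / total_count, 1)
}
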