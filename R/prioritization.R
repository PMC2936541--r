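#' Qualifying protein-truncating events in cases
#'
#' Finds, for each case, the protein-truncating or stop-loss variants in
#' homozygous form on the autosomes, or homozygous/hemizygous on the X
#' chromosome, that survive the control filters. A variant qualifies when:
#' (1) it is never observed in homozygous form in the controls; (2) no
#' other truncating/stop-loss variant in the same gene is homozygous in a
#' control; (3) its control heterozygous-carrier count is at most
#' `floor(control_het_max_fraction * 2 * n_controls)` (5 of 10 controls at
#' defaults, i.e. control minor-allele frequency below about 25%); (4) the
#' case call has at least 10x depth on autosomes or 5x on the sex
#' chromosome - the same depth rule decides whether a control call counts
#' as a homozygote in (1)-(2); and (5) the gene carries the canonical
#' (curated-name) flag. With zero controls, (1)-(3) pass vacuously.
#'
#' @param annotated an [annotate_cohort()] result.
#' @param case_ids,control_ids disjoint sample id sets.
#' @param config an [analysis_config()].
#' @param x_chrom name of the X chromosome (sex-chromosome depth rule).
#' @return data.table of events: `gene_id`, `sample_id`, `site_id`,
#'   `class`, `zygosity`, `depth`, `kind`, `control_het_carriers`.
#' @export
qualifying_variants <- function(annotated, case_ids, control_ids,
                                config = analysis_config(),
                                x_chrom = "chrX") {
  stopifnot(inherits(annotated, "annotated_cohort"))
  if (length(intersect(case_ids, control_ids))) {
    stop("case and control sets overlap")
  }
  cohort <- annotated$cohort
  stopifnot(all(c(case_ids, control_ids) %in% cohort$samples$sample_id))

  gc <- annotated$gene_class[class %in% TRUNCATING_OR_STOPLOSS_CLASSES]
  # drop genes without the canonical flag (criterion 5)
  canon <- unique(annotated$genes$genes[canonical == TRUE, gene_id])
  gc <- gc[gene_id %in% canon]
  if (nrow(gc) == 0) {
    return(empty_events())
  }

  sites <- cohort$sites[match(gc$site_id, site_id)]
  on_sex <- sites$chrom == x_chrom
  min_depth <- ifelse(on_sex, config$hom_min_depth_sex, config$hom_min_depth_autosome)

  g <- cohort$geno[gc$site_id, , drop = FALSE]
  d <- cohort$depth[gc$site_id, , drop = FALSE]
  hom <- (g == GT_HOM_ALT | g == GT_HEMI_ALT) & !is.na(g) & d >= min_depth
  if (!is.null(config$high_depth_exclusion)) {
    hom <- hom & d <= config$high_depth_exclusion
  }
  het <- g == GT_HET & !is.na(g)

  ctrl <- intersect(control_ids, colnames(g))
  hom_ctrl <- rowSums(hom[, ctrl, drop = FALSE]) # criterion 1 (per variant)
  het_ctrl <- rowSums(het[, ctrl, drop = FALSE]) # criterion 3
  max_het <- floor(config$control_het_max_fraction * 2 * length(ctrl))

  # criterion 2: gene-wide control homozygosity
  gene_hom_ctrl <- tapply(hom_ctrl, gc$gene_id, sum)
  bad_gene <- names(gene_hom_ctrl)[gene_hom_ctrl > 0]

  pass <- hom_ctrl == 0 & het_ctrl <= max_het & !(gc$gene_id %in% bad_gene)
  if (!any(pass)) {
    return(empty_events())
  }

  keep <- which(pass)
  ev <- lapply(case_ids, function(cs) {
    hit <- keep[hom[keep, cs]]
    if (!length(hit)) {
      return(NULL)
    }
    data.table::data.table(
      gene_id = gc$gene_id[hit],
      sample_id = cs,
      site_id = gc$site_id[hit],
      class = gc$class[hit],
      zygosity = gt_label(g[hit, cs]),
      depth = d[hit, cs],
      kind = sites$kind[hit],
      control_het_carriers = het_ctrl[hit]
    )
  })
  ev <- data.table::rbindlist(ev)
  if (nrow(ev) == 0) empty_events() else ev[]
}

empty_events <- function() {
  data.table::data.table(
    gene_id = character(), sample_id = character(), site_id = character(),
    class = character(), zygosity = character(), depth = integer(),
    kind = character(), control_het_carriers = integer()
  )
}

#' Rank genes by number of affected cases
#'
#' Aggregates qualifying events per gene and ranks genes by the number of
#' distinct affected cases, descending, with competition ranking (tied
#' genes share the best rank of their block). SNV and indel counts are
#' distinct qualifying variants of each kind; `control_het_max` is the
#' largest control heterozygous-carrier count among the gene's qualifying
#' variants.
#'
#' @param events output of [qualifying_variants()].
#' @return data.table: `rank`, `gene_id`, `n_cases`, `snv_count`,
#'   `indel_count`, `total_count`, `control_het_max`.
#' @export
rank_genes <- function(events) {
  if (nrow(events) == 0) {
    return(data.table::data.table(
      rank = integer(), gene_id = character(), n_cases = integer(),
      snv_count = integer(), indel_count = integer(),
      total_count = integer(), control_het_max = integer()
    ))
  }
  tab <- events[, .(
    n_cases = data.table::uniqueN(sample_id),
    snv_count = data.table::uniqueN(site_id[kind == "SNV"]),
    indel_count = data.table::uniqueN(site_id[kind != "SNV"]),
    total_count = data.table::uniqueN(site_id),
    control_het_max = max(control_het_carriers)
  ), by = gene_id]
  data.table::setorder(tab, -n_cases, gene_id)
  tab[, rank := as.integer(rank(-n_cases, ties.method = "min"))]
  data.table::setcolorder(tab, c(
    "rank", "gene_id", "n_cases", "snv_count", "indel_count", "total_count",
    "control_het_max"
  ))
  tab[]
}

#' Causal-gene rank as a function of control count
#'
#' For each permutation, draws `n_controls` controls without replacement
#' from the control pool, reruns [qualifying_variants()] and
#' [rank_genes()], and records the rank of `causal_gene`; returns the mean
#' over permutations. A gene absent from the ranking is assigned rank
#' (number of ranked genes + 1) and flagged.
#'
#' @param annotated an [annotate_cohort()] result.
#' @param causal_gene gene id whose rank is tracked.
#' @param n_controls number of controls per permutation.
#' @param n_permutations number of control subsets (default 5).
#' @param seed integer seed for the subset draws.
#' @param case_ids,control_pool sample sets (defaults: the cohort's cases
#'   and controls).
#' @param config an [analysis_config()].
#' @param x_chrom name of the X chromosome.
#' @return list: `mean_rank`, `ranks` (per permutation), `unranked` (how
#'   many permutations lacked the gene entirely).
#' @export
control_titration <- function(annotated, causal_gene, n_controls,
                              n_permutations = 5, seed = 1L,
                              case_ids = NULL, control_pool = NULL,
                              config = analysis_config(),
                              x_chrom = "chrX") {
  stopifnot(inherits(annotated, "annotated_cohort"), n_permutations >= 1)
  if (is.null(case_ids)) case_ids <- case_ids(annotated$cohort)
  if (is.null(control_pool)) control_pool <- control_ids(annotated$cohort)
  stopifnot(n_controls >= 0, n_controls <= length(control_pool))
  set.seed(seed)
  ranks <- numeric(n_permutations)
  unranked <- 0L
  for (p in seq_len(n_permutations)) {
    ctrl <- sample(control_pool, n_controls)
    ev <- qualifying_variants(annotated, case_ids, ctrl,
      config = config, x_chrom = x_chrom
    )
    tab <- rank_genes(ev)
    i <- match(causal_gene, tab$gene_id)
    if (is.na(i)) {
      ranks[p] <- nrow(tab) + 1L
      unranked <- unranked + 1L
    } else {
      ranks[p] <- tab$rank[i]
    }
  }
  list(mean_rank = mean(ranks), ranks = ranks, unranked = unranked)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's. With 10 cases
#' all carrying a variant absent from 10 controls this gives
#' 2 / choose(20, 10) = 1.08e-5.
#'
#' @param a,b,c,d non-negative integer cell counts (`a`,`b` = carriers in
#'   cases/controls; `c`,`d` = non-carriers).
#' @return p-value in (0, 1]; degenerate all-zero margins give 1.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(
    length(a) == 1, a >= 0, b >= 0, c >= 0, d >= 0,
    a == round(a), b == round(b), c == round(c), d == round(d)
  )
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (sum(m) == 0) {
    return(1)
  }
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Power of the maximally imbalanced variant test
#'
#' The most extreme association any variant can show in a cohort of
#' `n_cases` cases and `n_controls` controls is presence in every case and
#' absence from every control; this computes that best-case Fisher p-value,
#' the Bonferroni threshold for `m_tests` tests, and whether significance
#' is achievable at all. With 10 cases, 10 controls and 39,374 variant
#' tests the minimum p (1.08e-5) cannot reach the 1.27e-6 threshold: no
#' single-variant result can be significant in a dataset of this size.
#'
#' @param n_cases,n_controls sample counts.
#' @param m_tests number of tests for the Bonferroni correction.
#' @param alpha significance level.
#' @return list: `min_p`, `threshold`, `achievable`.
#' @export
max_imbalance_power <- function(n_cases, n_controls, m_tests, alpha = 0.05) {
  stopifnot(n_cases >= 1, n_controls >= 1, m_tests >= 1)
  min_p <- fisher_exact_two_sided(n_cases, 0, 0, n_controls)
  threshold <- bonferroni_threshold(alpha, m_tests)
  list(min_p = min_p, threshold = threshold, achievable = min_p <= threshold)
}
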