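#' Exact Hardy-Weinberg test with an excess-heterozygosity direction
#'
#' Exact conditional test of Hardy-Weinberg proportions for one bi-allelic
#' site: conditioning on the observed allele counts, the heterozygote count
#' follows a known distribution over values sharing the parity of the minor
#' allele count, and p-values are exact sums over that distribution
#' (computed by the standard parity-respecting recurrence). Returns the
#' two-sided p (probability-mass rule), the one-sided excess-heterozygote
#' p (`P(het >= observed)`), and the direction of departure relative to
#' the conditional expectation. Heterozygote excess is the signature of
#' collapsed duplicated sequence: reads from two diverged loci aligned onto
#' one create apparent heterozygotes in every carrier of the duplication.
#'
#' @param n_hom_ref,n_het,n_hom_alt diploid genotype counts.
#' @return list: `p_two_sided`, `p_excess_het`, `direction`
#'   (`"excess_het"`, `"deficit_het"`, `"none"`), `testable` (FALSE for
#'   monomorphic sites, where both p-values are 1).
#' @export
hwe_exact_excess_het <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(
    length(n_hom_ref) == 1, n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0,
    n_hom_ref == round(n_hom_ref), n_het == round(n_het),
    n_hom_alt == round(n_hom_alt)
  )
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_alt + n_het # alt allele count
  n_minor <- min(n_a, 2 * n - n_a)
  if (n == 0 || n_minor == 0) {
    return(list(
      p_two_sided = 1, p_excess_het = 1, direction = "none", testable = FALSE
    ))
  }
  dist <- hwe_het_distribution(n_minor, n)
  probs <- dist$prob
  hets <- dist$het
  obs <- n_het
  i_obs <- match(obs, hets)
  if (is.na(i_obs)) stop("inconsistent genotype counts (parity)")
  p_obs <- probs[i_obs]
  p_two <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p_excess <- sum(probs[hets >= obs])
  e_het <- n_minor * (2 * n - n_minor) / (2 * n - 1)
  direction <- if (obs > e_het) {
    "excess_het"
  } else if (obs < e_het) {
    "deficit_het"
  } else {
    "none"
  }
  list(
    p_two_sided = min(1, p_two), p_excess_het = min(1, p_excess),
    direction = direction, testable = TRUE
  )
}

# Conditional distribution of the heterozygote count given the minor allele
# count n_minor among n diploids. Parity-respecting recurrence:
# P(h+2)/P(h) = (n_minor - h) (n_major - h) / ((h+2)(h+1) ... ) in the
# standard exact-test form; normalized at the end.
hwe_het_distribution <- function(n_minor, n) {
  n_major <- 2L * n - n_minor
  h_min <- if (n_minor %% 2L == 0L) max(0L, n_minor - n_major) else 1L
  hets <- seq.int(h_min, n_minor, by = 2L)
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i] - 2L # previous value
    # P(h+2)/P(h) = 4 * n_hom_minor(h) * n_hom_major(h) / ((h+2)(h+1))
    ratio <- 4 * ((n_minor - h) / 2) * ((n_major - h) / 2) /
      ((h + 2) * (h + 1))
    lp[i] <- lp[i - 1] + log(ratio)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  list(het = hets, prob = p)
}

#' Vectorized HWE testing for a genotype-count table
#'
#' Applies [hwe_exact_excess_het()] to many sites efficiently by computing
#' each distinct genotype configuration once.
#'
#' @param counts matrix or data.frame with columns `n_hom_ref`, `n_het`,
#'   `n_hom_alt` (one row per site).
#' @return data.table with `p_two_sided`, `p_excess_het`, `direction`,
#'   `testable`, row order preserved.
#' @export
hwe_test_counts <- function(counts) {
  counts <- as.data.frame(counts)
  key <- paste(counts$n_hom_ref, counts$n_het, counts$n_hom_alt)
  uk <- !duplicated(key)
  res <- lapply(which(uk), function(i) {
    hwe_exact_excess_het(
      counts$n_hom_ref[i], counts$n_het[i], counts$n_hom_alt[i]
    )
  })
  res <- data.table::rbindlist(res)
  res[match(key, key[uk])]
}

#' Call copy-number segments from window read depths
#'
#' Minimal three-state read-depth segmentation: deletion, normal and
#' duplication states with Poisson emission means `lambda/2`, `lambda` and
#' `3*lambda/2` (`lambda` = the sample's mean coverage per window),
#' decoded by the most probable (Viterbi) path of a hidden Markov model
#' with self-transition probability 0.999 and uniform switching. Adjacent
#' same-state windows are merged into segments.
#'
#' @param window_depths data.frame with `chrom`, `start`, `end`, `depth`
#'   for one sample (windows contiguous within chromosome).
#' @param mean_coverage expected depth of a copy-number-2 window (> 0).
#' @param self_prob self-transition probability.
#' @return `GRanges` of segments with a `state` column (`"deletion"`,
#'   `"normal"`, `"duplication"`).
#' @export
call_depth_cnv <- function(window_depths, mean_coverage, self_prob = 0.999) {
  stopifnot(mean_coverage > 0, all(window_depths$depth >= 0))
  wd <- data.table::as.data.table(window_depths)
  states <- c("deletion", "normal", "duplication")
  lam <- mean_coverage * c(0.5, 1, 1.5)
  log_a <- matrix(log((1 - self_prob) / 2), 3, 3)
  diag(log_a) <- log(self_prob)
  log_init <- log(c(0.0005, 0.999, 0.0005))
  out <- list()
  for (cc in unique(wd$chrom)) {
    d <- wd[chrom == cc]
    data.table::setorder(d, start)
    n <- nrow(d)
    emis <- vapply(lam, function(l) {
      stats::dpois(d$depth, l, log = TRUE)
    }, numeric(n))
    emis <- matrix(emis, nrow = n)
    path <- viterbi_path(log_init, log_a, emis)
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gr <- GenomicRanges::GRanges(
      cc, IRanges::IRanges(d$start[starts], d$end[ends])
    )
    gr$state <- states[r$values]
    out[[cc]] <- gr
  }
  res <- suppressWarnings(do.call(c, unname(out)))
  sort(res)
}

# Log-space Viterbi decoding; emis is n x k log-likelihoods.
viterbi_path <- function(log_init, log_a, emis) {
  n <- nrow(emis)
  k <- ncol(emis)
  delta <- matrix(-Inf, n, k)
  psi <- matrix(0L, n, k)
  delta[1, ] <- log_init + emis[1, ]
  for (t in 2:n) {
    for (s in 1:k) {
      v <- delta[t - 1, ] + log_a[, s]
      psi[t, s] <- which.max(v)
      delta[t, s] <- v[psi[t, s]] + emis[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Classify sites into duplication categories A/B/C
#'
#' Category A: sites inside regions called duplicated in every sample;
#' B: duplicated in at least one but not all samples; C: duplicated in
#' none. Also reports each category's share of genomic length.
#'
#' @param sites `GRanges` of site positions (or a cohort `sites` table).
#' @param cnv_sets named list (per sample) of `GRanges` with a `state`
#'   column; only `"duplication"` segments are used.
#' @param genome_length total genomic length (bp) for the length
#'   fractions (e.g. the non-N autosome length).
#' @return list: `category` (factor A/B/C per site), `table` (data.table
#'   with per-category site counts and length fractions).
#' @export
classify_site_categories <- function(sites, cnv_sets, genome_length) {
  if (!inherits(sites, "GRanges")) sites <- sites_granges(sites)
  stopifnot(length(cnv_sets) >= 1, genome_length > 0)
  dups <- lapply(cnv_sets, function(g) {
    if (length(g) == 0 || is.null(g$state)) {
      return(GenomicRanges::GRanges())
    }
    GenomicRanges::reduce(g[g$state == "duplication"])
  })
  n_samp <- length(dups)
  hit <- vapply(dups, function(d) {
    GenomicRanges::countOverlaps(sites, d) > 0
  }, logical(length(sites)))
  hit <- matrix(hit, nrow = length(sites))
  n_hit <- rowSums(hit)
  category <- factor(
    ifelse(n_hit == n_samp, "A", ifelse(n_hit > 0, "B", "C")),
    levels = c("A", "B", "C")
  )
  dup_all <- suppressWarnings(Reduce(GenomicRanges::intersect, dups))
  dup_any <- GenomicRanges::reduce(suppressWarnings(do.call(c, unname(dups))))
  len_a <- sum(GenomicRanges::width(dup_all))
  len_any <- sum(GenomicRanges::width(dup_any))
  len_b <- len_any - len_a
  len_c <- genome_length - len_any
  tab <- data.table::data.table(
    category = factor(c("A", "B", "C"), levels = c("A", "B", "C")),
    n_sites = as.integer(table(category)),
    length_fraction = c(len_a, len_b, len_c) / genome_length
  )
  list(category = category, table = tab)
}

#' Concentration of HWE outliers in duplication categories
#'
#' Tests every polymorphic autosomal site for Hardy-Weinberg departure in
#' a designated diploid subset (typically one homogeneous-ancestry group),
#' flags excess-heterozygote outliers (two-sided p below the threshold
#' with excess-het direction; the one-sided count is also reported), and
#' summarizes how outliers concentrate in duplication categories: each
#' category's share of outliers versus its share of genomic length, and
#' their ratio (fold concentration).
#'
#' @param cohort a [cohort_table()].
#' @param categories result of [classify_site_categories()] on the same
#'   site set (see `site_ids`).
#' @param site_ids site ids (rows of `categories$category`); defaults to
#'   all cohort sites.
#' @param subset_samples sample ids for genotype counting (must be diploid
#'   at the tested sites: use autosomal sites).
#' @param config an [analysis_config()] (`hwe_p_threshold`).
#' @return list: `per_site` (data.table with p-values, direction,
#'   category, outlier flag), `enrichment` (per category: outlier share,
#'   length share, fold), `outlier_rate` (share of testable sites that are
#'   excess-het outliers), `n_outliers_one_sided`.
#' @export
hwe_outlier_enrichment <- function(cohort, categories, site_ids = NULL,
                                   subset_samples = cohort$samples$sample_id,
                                   config = analysis_config()) {
  if (is.null(site_ids)) site_ids <- cohort$sites$site_id
  stopifnot(length(site_ids) == length(categories$category))
  g <- cohort$geno[site_ids, subset_samples, drop = FALSE]
  counts <- data.frame(
    n_hom_ref = rowSums(g == GT_HOM_REF, na.rm = TRUE),
    n_het = rowSums(g == GT_HET, na.rm = TRUE),
    n_hom_alt = rowSums(g == GT_HOM_ALT, na.rm = TRUE)
  )
  if (any(g == GT_HEMI_ALT, na.rm = TRUE)) {
    stop("hemizygous calls in the HWE subset; test autosomal sites only")
  }
  res <- hwe_test_counts(counts)
  res[, site_id := site_ids]
  res[, category := categories$category]
  res[, outlier := testable & p_two_sided < config$hwe_p_threshold &
    direction == "excess_het"]
  n_test <- sum(res$testable)
  if (n_test == 0) stop("no testable sites")
  n_out <- sum(res$outlier)
  enr <- res[, .(n_outliers = sum(outlier)), by = category][
    order(category)
  ]
  enr <- merge(
    data.table::data.table(category = factor(c("A", "B", "C"), levels = c("A", "B", "C"))),
    enr,
    by = "category", all.x = TRUE
  )
  enr[is.na(n_outliers), n_outliers := 0L]
  enr[, outlier_share := if (n_out > 0) n_outliers / n_out else NA_real_]
  enr[, length_share := categories$table$length_fraction]
  enr[, fold := outlier_share / length_share]
  list(
    per_site = res[],
    enrichment = enr[],
    outlier_rate = n_out / n_test,
    n_outliers_one_sided = sum(
      res$testable & res$p_excess_het < config$hwe_p_threshold &
        res$direction == "excess_het"
    )
  )
}

#' Male X-chromosome heterozygosity summary
#'
#' Heterozygous calls on the male X are impossible for a single-copy
#' chromosome and therefore diagnose alignment artifacts. For each male,
#' reports the fraction of X-chromosome variant calls assigned
#' heterozygous status and partitions those heterozygotes by location:
#' inside the pseudoautosomal region (masked-Y pile-up), inside
#' duplication-called regions, or elsewhere (buckets are exclusive, PAR
#' first).
#'
#' @param cohort a [cohort_table()].
#' @param par_intervals `GRanges` of PAR interval(s).
#' @param cnv_sets named per-sample list of CNV `GRanges` (with `state`),
#'   or `NULL` to skip the duplication bucket.
#' @param x_chrom X chromosome name.
#' @return data.table: per male `n_x_calls`, `n_het`, `het_fraction`,
#'   `par_share`, `dup_share`, `other_share`; empty when there are no
#'   males.
#' @export
male_x_het_summary <- function(cohort, par_intervals, cnv_sets = NULL,
                               x_chrom = "chrX") {
  males <- male_ids(cohort)
  if (length(males) == 0) {
    return(data.table::data.table(
      sample_id = character(), n_x_calls = integer(), n_het = integer(),
      het_fraction = numeric(), par_share = numeric(), dup_share = numeric(),
      other_share = numeric()
    ))
  }
  on_x <- cohort$sites$chrom == x_chrom
  x_sites <- cohort$sites[on_x]
  x_gr <- sites_granges(x_sites)
  in_par <- GenomicRanges::countOverlaps(x_gr, par_intervals) > 0
  rows <- lapply(males, function(m) {
    g <- cohort$geno[on_x, m]
    called <- !is.na(g) & g %in% .GT_CARRIER
    het <- !is.na(g) & g == GT_HET
    n_het <- sum(het)
    in_dup <- if (!is.null(cnv_sets)) {
      dup <- cnv_sets[[m]]
      dup <- dup[dup$state == "duplication"]
      GenomicRanges::countOverlaps(x_gr, dup) > 0
    } else {
      rep(FALSE, length(x_gr))
    }
    par_n <- sum(het & in_par)
    dup_n <- sum(het & !in_par & in_dup)
    data.table::data.table(
      sample_id = m,
      n_x_calls = sum(called),
      n_het = n_het,
      het_fraction = if (sum(called) > 0) n_het / sum(called) else 0,
      par_share = if (n_het > 0) par_n / n_het else NA_real_,
      dup_share = if (n_het > 0) dup_n / n_het else NA_real_,
      other_share = if (n_het > 0) (n_het - par_n - dup_n) / n_het else NA_real_
    )
  })
  data.table::rbindlist(rows)
}

#' Fraction of segments overlapping a reference set
#'
#' Share of query segments at least `min_overlap` of whose length is
#' covered by the reference segment set (one-way overlap; a segment
#' overlapping exactly the threshold counts).
#'
#' @param segments query `GRanges`.
#' @param reference_segments reference `GRanges`.
#' @param min_overlap minimum covered fraction of the query length.
#' @return numeric fraction, or `NA` for an empty query.
#' @export
cnv_overlap_fraction <- function(segments, reference_segments,
                                 min_overlap = 0.5) {
  if (length(segments) == 0) {
    return(NA_real_)
  }
  red <- GenomicRanges::reduce(reference_segments)
  ov <- GenomicRanges::findOverlaps(segments, red)
  cov <- numeric(length(segments))
  if (length(ov)) {
    qs <- GenomicRanges::start(segments)[S4Vectors::queryHits(ov)]
    qe <- GenomicRanges::end(segments)[S4Vectors::queryHits(ov)]
    rs <- GenomicRanges::start(red)[S4Vectors::subjectHits(ov)]
    re <- GenomicRanges::end(red)[S4Vectors::subjectHits(ov)]
    w <- pmin(qe, re) - pmax(qs, rs) + 1
    cov <- as.vector(tapply(
      w, factor(S4Vectors::queryHits(ov), levels = seq_along(segments)), sum
    ))
    cov[is.na(cov)] <- 0
  }
  mean(cov / GenomicRanges::width(segments) >= min_overlap)
}
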