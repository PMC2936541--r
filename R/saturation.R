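#' Permutation-averaged discovery saturation curves
#'
#' Walks the cohort's genomes in random order and counts, at each
#' incremental step, how many new items the newly added genome contributes:
#' items not flagged as known and not already seen in the genomes walked so
#' far. The sample order is permuted `n_perm` times (Fisher-Yates draws
#' from one seeded generator) and the per-step counts averaged.
#'
#' For `novel_snv_curve()` the items are SNV site keys (a site carried as
#' heterozygote or homozygote counts once) and "known" is the site's
#' known-variant flag. For `knockout_gene_curve()` the items are genes
#' knocked out in the sample (see [knocked_out_genes()]), optionally
#' excluding genes hit only by universal-homozygote variants; gene items
#' have no known flag.
#'
#' @param cohort a [cohort_table()].
#' @param n_perm number of order permutations (>= 1).
#' @param seed integer seed.
#' @param permutations optional list of explicit sample-index orderings
#'   (each a permutation of `1:n_samples`), overriding random draws; used
#'   for exhaustive small-n checks.
#' @return An object of class `saturation_curve`: data.table with `step`
#'   and `mean_novel`, with attributes `n_perm` and `seed`.
#' @export
novel_snv_curve <- function(cohort, n_perm = 1000, seed = 1L,
                            permutations = NULL) {
  snv <- cohort$sites$kind == "SNV"
  unknown <- snv & !cohort$sites$known
  g <- cohort$geno[unknown, , drop = FALSE]
  carrier <- g %in% .GT_CARRIER
  dim(carrier) <- dim(g)
  saturation_from_carriers(carrier, n_perm, seed, permutations)
}

#' @rdname novel_snv_curve
#' @param annotated an [annotate_cohort()] result.
#' @param exclude_universal drop genes whose truncating variants are all
#'   universal homozygotes.
#' @export
knockout_gene_curve <- function(annotated, n_perm = 1000, seed = 1L,
                                exclude_universal = TRUE,
                                permutations = NULL) {
  stopifnot(inherits(annotated, "annotated_cohort"))
  cohort <- annotated$cohort
  gc <- annotated$gene_class[class %in% TRUNCATING_OR_STOPLOSS_CLASSES]
  if (exclude_universal && nrow(gc)) {
    uni <- universal_homozygotes(cohort)
    keep_gene <- gc[, .(any_non_universal = any(!site_id %in% uni)), by = gene_id]
    gc <- gc[gene_id %in% keep_gene$gene_id[keep_gene$any_non_universal]]
  }
  genes <- sort(unique(gc$gene_id))
  samp <- cohort$samples$sample_id
  carrier <- matrix(FALSE, length(genes), length(samp),
    dimnames = list(genes, samp)
  )
  if (nrow(gc)) {
    g <- cohort$geno[gc$site_id, , drop = FALSE]
    hom <- (g == GT_HOM_ALT | g == GT_HEMI_ALT) & !is.na(g)
    for (j in seq_along(samp)) {
      ko <- unique(gc$gene_id[hom[, j]])
      carrier[match(ko, genes), j] <- TRUE
    }
  }
  saturation_from_carriers(carrier, n_perm, seed, permutations)
}

# Shared engine: items x samples carrier matrix -> mean per-step novel count
saturation_from_carriers <- function(carrier, n_perm, seed, permutations) {
  n_samp <- ncol(carrier)
  stopifnot(n_samp >= 1)
  if (is.null(permutations)) {
    stopifnot(n_perm >= 1)
    set.seed(seed)
    permutations <- lapply(seq_len(n_perm), function(i) sample.int(n_samp))
  } else {
    stopifnot(all(vapply(
      permutations,
      function(p) identical(as.integer(sort(p)), seq_len(n_samp)),
      logical(1)
    )))
    n_perm <- length(permutations)
  }
  acc <- numeric(n_samp)
  for (ord in permutations) {
    seen <- rep(FALSE, nrow(carrier))
    for (j in seq_len(n_samp)) {
      cj <- carrier[, ord[j]]
      acc[j] <- acc[j] + sum(cj & !seen)
      seen <- seen | cj
    }
  }
  out <- data.table::data.table(step = seq_len(n_samp), mean_novel = acc / n_perm)
  data.table::setattr(out, "n_perm", n_perm)
  data.table::setattr(out, "seed", seed)
  data.table::setattr(out, "class", c("saturation_curve", class(out)))
  out[]
}

#' Cohort size needed to exhaust a gene catalogue
#'
#' Propagates the observed asymptotic discovery rate: with about two new
#' knocked-out genes per additional genome, cataloguing 20,000 genes takes
#' about 10,000 genomes. The rate is an observed statistic supplied by the
#' caller, not a model fit.
#'
#' @param total_genes catalogue size to cover.
#' @param rate_per_genome new items discovered per additional genome (> 0).
#' @return `ceiling(total_genes / rate_per_genome)` (integer).
#' @export
extrapolate_cohort_size <- function(total_genes, rate_per_genome) {
  stopifnot(total_genes > 0, rate_per_genome > 0)
  as.integer(ceiling(total_genes / rate_per_genome))
}
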