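#' Analysis configuration
#'
#' Thresholds used across the annotation, prioritization, HWE/duplication and
#' QC stages. Defaults reproduce the study conventions: homozygotes require
#' 10x depth on autosomes and 5x on the sex chromosomes; a base is "covered"
#' with at least five reads of consensus quality greater than zero; HWE
#' outliers use p < 0.01; copy-number states are inferred in 2 kb read-depth
#' windows; saturation curves average 1000 sample-order permutations and the
#' control-titration curve averages 5 control subsets.
#'
#' @param hom_min_depth_autosome minimum read depth for a call to count as a
#'   homozygote on an autosome (x-fold, default 10).
#' @param hom_min_depth_sex minimum depth for homozygous/hemizygous calls on
#'   a sex chromosome (default 5).
#' @param control_het_max_fraction maximum control minor-allele fraction for
#'   a qualifying variant; at the default 0.25 with 10 controls this allows
#'   heterozygous carriers in at most 5 of the 10 controls.
#' @param covered_min_reads,covered_min_quality a base is covered when its
#'   depth is at least `covered_min_reads` and its consensus quality is
#'   strictly greater than `covered_min_quality`.
#' @param hwe_p_threshold p-value threshold for HWE outlier calls.
#' @param cnv_window read-depth window size in bp.
#' @param saturation_permutations,titration_permutations permutation counts
#'   for the discovery curves and the control titration.
#' @param alpha significance level for multiple-testing arithmetic.
#' @param high_depth_exclusion optional depth ceiling above which variants are
#'   excluded from prioritization (off by default; extremely high-coverage
#'   sites are a known source of calling errors).
#' @param seed optional integer seed recorded with the configuration.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(hom_min_depth_autosome = 10,
                            hom_min_depth_sex = 5,
                            control_het_max_fraction = 0.25,
                            covered_min_reads = 5,
                            covered_min_quality = 0,
                            hwe_p_threshold = 0.01,
                            cnv_window = 2000,
                            saturation_permutations = 1000,
                            titration_permutations = 5,
                            alpha = 0.05,
                            high_depth_exclusion = NULL,
                            seed = NULL) {
  stopifnot(
    hom_min_depth_autosome > 0, hom_min_depth_sex > 0,
    control_het_max_fraction > 0, control_het_max_fraction <= 1,
    covered_min_reads > 0, covered_min_quality >= 0,
    hwe_p_threshold > 0, hwe_p_threshold < 1,
    cnv_window > 0, saturation_permutations >= 1,
    titration_permutations >= 1, alpha > 0, alpha < 1
  )
  if (!is.null(high_depth_exclusion)) stopifnot(high_depth_exclusion > 0)
  structure(
    list(
      hom_min_depth_autosome = hom_min_depth_autosome,
      hom_min_depth_sex = hom_min_depth_sex,
      control_het_max_fraction = control_het_max_fraction,
      covered_min_reads = covered_min_reads,
      covered_min_quality = covered_min_quality,
      hwe_p_threshold = hwe_p_threshold,
      cnv_window = cnv_window,
      saturation_permutations = saturation_permutations,
      titration_permutations = titration_permutations,
      alpha = alpha,
      high_depth_exclusion = high_depth_exclusion,
      seed = seed
    ),
    class = "analysis_config"
  )
}

#' Synthetic cohort generator configuration
#'
#' Defines the study conditions emulated by [generate_cohort()]: a desk-scale
#' diploid cohort (default 10 male cases and 10 controls over a ~10 Mb toy
#' genome) whose summary statistics are calibrated to a high-coverage
#' whole-genome study: transition probability 0.6753 (Ti/Tv about 2.08), a
#' site-frequency mixture solved so the expected per-genome
#' homozygote/heterozygote ratio is 0.59, 51% of indel lengths multiples of
#' 3 bp, 87.28% of SNVs flagged as known, regions duplicated in all samples
#' covering 0.41% and in some samples 1.16% of the autosomes, and an
#' X-linked causal-gene scenario with planted truncating variants.
#'
#' @param n_cases,n_controls sample counts.
#' @param case_sex,control_sex per-sample sex (`"M"`/`"F"`); cases default to
#'   all male (the planted disease is X-linked and recessive/hemizygous).
#' @param control_ancestry,case_ancestry ancestry labels; defaults mirror a
#'   17-European-ancestry subset used for the HWE scan.
#' @param chrom_lengths named integer vector of chromosome lengths; must
#'   include `x_chrom`.
#' @param x_chrom name of the X chromosome.
#' @param par_interval two integers, start/end (1-based, inclusive) of the
#'   pseudoautosomal region at the head of the X.
#' @param n_gap_frac fraction of each chromosome end written as `N` gap.
#' @param n_genes number of protein-coding gene models to place.
#' @param cds_len_range CDS length range in nt (values are rounded to
#'   multiples of 3).
#' @param max_exons maximum CDS exon count per gene.
#' @param canonical_prob probability a gene carries the canonical
#'   (HGNC-like) flag; the causal gene is always canonical.
#' @param n_snv,n_indel population SNV and indel site counts.
#' @param q_min lower truncation of the neutral 1/q site-frequency spectrum.
#' @param ref_minor_q_range frequency range of the reference-minor mixture
#'   component (sites whose alternate allele is nearly fixed, emulating
#'   "universal homozygote" sites where the less common allele is in the
#'   reference).
#' @param hom_het_target expected per-genome hom_alt/het ratio the mixture
#'   weight is solved for (see [solve_sfs_mixture()]).
#' @param sfs_weight mixture weight of the reference-minor component; if
#'   `NULL` (default) it is solved from `hom_het_target`.
#' @param p_ts probability that an SNV is a transition.
#' @param indel_max_len maximum indel length (bp).
#' @param indel_frac3 probability an indel length is a multiple of 3.
#' @param indel_decay exponential length-decay scale within each length
#'   class (weights proportional to `exp(-len/indel_decay)`).
#' @param p_known_snv,p_known_indel probability a site is flagged as known
#'   (present in the external variant catalogue).
#' @param dup_frac_all,dup_frac_some fractions of autosomal length duplicated
#'   in all samples (category A regions) and in one or more but not all
#'   samples (category B).
#' @param dup_seg_windows min/max duplication segment length in 2 kb windows.
#' @param dup_some_carrier_prob probability that a given sample carries a
#'   category-B duplication segment.
#' @param deletion_frac per-sample fraction of autosomal length deleted
#'   (private deletions).
#' @param x_dup_frac fraction of the X chromosome duplicated in all samples
#'   (centromere-like unmasked repeats; their collapse artifacts are the
#'   non-PAR source of male X heterozygote calls).
#' @param artifact_rate probability a site inside a duplicated region is a
#'   paralog-collapse artifact site (forced heterozygous in duplication
#'   carriers).
#' @param par_artifact_rate probability a PAR site is a Y-collapse artifact
#'   (forced heterozygous in males: with the Y copy of the PAR masked, Y
#'   reads align to the X and diverged Y alleles are called as
#'   heterozygotes).
#' @param mean_coverage mean genomic read depth per sample.
#' @param chip_density fraction of SNV sites present on the genotyping chip.
#' @param chip_error chip genotyping error probability.
#' @param undercall_a,undercall_b intercept and slope of the logistic
#'   depth-dependent heterozygote undercall probability
#'   `plogis(undercall_a + undercall_b * depth)` (about 3% at 5x and below
#'   0.1% at 30x): at low depth only one allele of a true heterozygote may be
#'   sampled, producing a homozygous sequencing call (the dominant,
#'   "category 1" discordance against chip genotypes).
#' @param missing_rate probability a sequencing genotype is missing.
#' @param causal_scenario logical; plant the X-linked causal-gene scenario.
#' @param cnv_window read-depth window size (bp).
#' @param seed integer seed; all generator randomness flows from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_cases = 10,
                             n_controls = 10,
                             case_sex = rep("M", n_cases),
                             control_sex = rep(c("M", "F"),
                               times = c(
                                 ceiling(0.7 * n_controls),
                                 n_controls - ceiling(0.7 * n_controls)
                               )
                             ),
                             case_ancestry = rep("EUR", n_cases),
                             control_ancestry = rep_len(
                               c(rep("EUR", max(0L, n_controls - 3L)), "HIS", "HIS", "AFR"),
                               n_controls
                             ),
                             chrom_lengths = c(chr1 = 4e6, chr2 = 3e6, chrX = 3e6),
                             x_chrom = "chrX",
                             par_interval = c(1L, 150000L),
                             n_gap_frac = 0.005,
                             n_genes = 200,
                             cds_len_range = c(300, 1500),
                             max_exons = 3,
                             canonical_prob = 0.9,
                             n_snv = 1e5,
                             n_indel = 2e4,
                             q_min = 0.01,
                             ref_minor_q_range = c(0.9, 1),
                             hom_het_target = 0.59,
                             sfs_weight = NULL,
                             p_ts = 0.6753,
                             indel_max_len = 30,
                             indel_frac3 = 0.51,
                             indel_decay = 6,
                             p_known_snv = 0.8728,
                             p_known_indel = 0.05,
                             dup_frac_all = 0.0041,
                             dup_frac_some = 0.0116,
                             dup_seg_windows = c(5, 25),
                             dup_some_carrier_prob = 0.5,
                             deletion_frac = 0.004,
                             x_dup_frac = 0.01,
                             artifact_rate = 0.1,
                             par_artifact_rate = 0.15,
                             mean_coverage = 30,
                             chip_density = 0.05,
                             chip_error = 0.002,
                             undercall_a = -2.79,
                             undercall_b = -0.1372,
                             missing_rate = 0.001,
                             causal_scenario = TRUE,
                             cnv_window = 2000,
                             seed = 1L) {
  stopifnot(
    n_cases >= 0, n_controls >= 0, n_cases + n_controls >= 1,
    length(case_sex) == n_cases, length(control_sex) == n_controls,
    all(c(case_sex, control_sex) %in% c("M", "F")),
    x_chrom %in% names(chrom_lengths),
    all(chrom_lengths > 0),
    length(par_interval) == 2, par_interval[1] >= 1,
    par_interval[2] <= chrom_lengths[[x_chrom]],
    n_gap_frac >= 0, n_gap_frac < 0.5,
    n_genes >= 1, cds_len_range[1] >= 9, cds_len_range[2] >= cds_len_range[1],
    max_exons >= 1,
    canonical_prob >= 0, canonical_prob <= 1,
    n_snv >= 1, n_indel >= 0,
    q_min > 0, q_min < 1,
    ref_minor_q_range[1] > 0, ref_minor_q_range[2] <= 1,
    ref_minor_q_range[1] < ref_minor_q_range[2],
    hom_het_target > 0, hom_het_target < 2,
    p_ts > 0, p_ts < 1,
    indel_max_len >= 3, indel_frac3 >= 0, indel_frac3 <= 1, indel_decay > 0,
    p_known_snv >= 0, p_known_snv <= 1, p_known_indel >= 0, p_known_indel <= 1,
    dup_frac_all >= 0, dup_frac_some >= 0, dup_frac_all + dup_frac_some < 1,
    dup_some_carrier_prob > 0, dup_some_carrier_prob < 1,
    deletion_frac >= 0, deletion_frac < 1,
    x_dup_frac >= 0, x_dup_frac < 1,
    artifact_rate >= 0, artifact_rate <= 1,
    par_artifact_rate >= 0, par_artifact_rate <= 1,
    mean_coverage > 0,
    chip_density >= 0, chip_density <= 1, chip_error >= 0, chip_error < 1,
    missing_rate >= 0, missing_rate < 1,
    is.logical(causal_scenario),
    cnv_window > 0
  )
  if (!is.null(sfs_weight)) stopifnot(sfs_weight >= 0, sfs_weight <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf(
    "  %d cases + %d controls; genome %.1f Mb (%s); %d genes\n",
    x$n_cases, x$n_controls, sum(x$chrom_lengths) / 1e6,
    paste(names(x$chrom_lengths), collapse = ","), x$n_genes
  ))
  cat(sprintf(
    "  %d SNV + %d indel sites; p_ts=%.4f; hom/het target=%.2f; known=%.4f\n",
    x$n_snv, x$n_indel, x$p_ts, x$hom_het_target, x$p_known_snv
  ))
  cat(sprintf(
    "  causal scenario: %s; seed=%s\n", x$causal_scenario, x$seed
  ))
  invisible(x)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
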