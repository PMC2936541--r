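---
title: "Characterizing rare loss-of-function variation in a small sequenced cohort"
author: "lofcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing rare loss-of-function variation in a small sequenced cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

When a handful of whole genomes are sequenced for a case/control question -
say ten patients with a severe X-linked Mendelian disease and ten unrelated
controls - the analysis that matters is not association testing. A back-of-
the-envelope calculation settles that immediately: the most extreme result
any single variant can show in 10 cases versus 10 controls is presence in
every case and absence from every control, whose two-sided Fisher exact
p-value is `2 / choose(20, 10)`, about `1.1e-5`. Against a Bonferroni
threshold of roughly `1.3e-6` for the tens of thousands of coding variants
seen in two or more cases, no variant can reach significance
(`max_imbalance_power()`). What *does* work at this scale is qualitative
prioritization: find genes where several cases, and no controls, carry
clearly damaging genotypes.

`lofcohort` implements that workflow - functional annotation of SNVs and
indels, gene ranking by affected-case counts under explicit control
filters, discovery saturation curves, exact Hardy-Weinberg (HWE)
diagnostics for duplication-driven artifact calls, and sequencing-versus-
chip concordance QC - together with a synthetic diploid cohort generator
that reproduces the statistical structure such a study sees, including a
planted X-linked causal-gene scenario. The generator is first-class,
tested code: every analysis in the package can be exercised end to end
against known truth.

## Variant annotation

Variants are classified per transcript against gene models with explicit
CDS intervals. For SNVs inside CDS the containing codon is translated for
the reference and alternate alleles (standard genetic code, table 1;
reverse-complemented for minus-strand transcripts): an alternate codon
translating to stop is `stop_gain`, a reference stop codon lost is
`stop_loss`, otherwise `synonymous`/`nonsynonymous`. Coding indels are
`frameshift` when the net length change is not a multiple of 3 and
`inframe_indel` otherwise; a deletion running over a CDS/intron junction is
still classified by its net coding-length change but flagged
`junction_spanning` rather than dropped. Non-CDS positions route to
`splice_boundary`, `intronic`, `utr` (only when exon annotation beyond the
CDS is available) or `intergenic`.

Two definitional choices deserve comment, since gene-model annotation
tools differ here and neither convention is forced by the data:

* **Splice boundary window.** "Intron-exon boundary" is implemented as
  within 2 bp of a CDS exon edge on the intron side - the two bases whose
  disruption breaks the canonical splice dinucleotides.
* **Severity order across transcripts.** A variant's gene-level class is
  its most severe class over the gene's transcripts, with order
  `stop_gain`/`frameshift`/`stop_loss` > `inframe_indel` >
  `nonsynonymous` > `synonymous` > `utr` > `splice_boundary` >
  `intronic` > `intergenic`.

Throughout the package, "protein-truncating" means `stop_gain` +
`frameshift` (`TRUNCATING_CLASSES`); analyses of protein-integrity
variants add `stop_loss` (`TRUNCATING_OR_STOPLOSS_CLASSES`). A gene is
*knocked out* in a genome when it carries at least one such variant in
homozygous form - homozygous-alternate, or hemizygous-alternate on the
male X. Variants homozygous in *every* genome (`universal_homozygotes()`)
most likely mark positions where the minor allele sits in the reference,
and are treated as an exclusion list, not as biology.

Coding variants also get a relative CDS position (first affected coding
base over CDS length, in transcription direction), which is how the
N-/C-terminal clustering of truncating variants is examined.

## Case/control gene prioritization

`qualifying_variants()` applies five filters to each truncating/stop-loss
variant seen in homozygous form in a case (homozygous on the autosomes, or
homozygous/hemizygous on the X): never homozygous in a control; no other
truncating/stop-loss variant of the same gene homozygous in a control;
control heterozygous carriers at most
`floor(control_het_max_fraction * 2 * n_controls)` (5 of 10 controls at
defaults - the operational form of "control minor-allele frequency below
25%"); at least 10x depth on autosomes or 5x on sex chromosomes for any
call counted as a homozygote, in cases *and* controls (a control
homozygote below the depth threshold does not disqualify - its evidence is
too weak either way); and a canonical (curated-name) gene flag.
`rank_genes()` then orders genes by distinct affected cases.

Ties use competition ranking: tied genes share the best rank of their
block. The "rank of the causal gene" reported by `control_titration()` is
evaluated under this convention, which is the generous-but-standard
choice; the ranking output records the tie structure so a stricter reading
can be recomputed.

`control_titration()` re-runs the ranking with `n` controls drawn without
replacement from the control pool, averaged over 5 permutations by
default, producing the rank-versus-control-count curve that shows how few
controls are needed before the planted gene surfaces.

## Saturation curves

`novel_snv_curve()` and `knockout_gene_curve()` answer "how much new
variation does each additional genome contribute?" Samples are walked in
random order; a sample's novel items are those neither flagged as known
(the catalogue stand-in) nor seen in previously walked samples. The order
is permuted 1000 times (Fisher-Yates from one seeded generator) and the
per-step counts averaged. Items are site keys for SNVs - a site carried
het or hom counts once - and knocked-out genes for the gene curve, which
by default excludes genes hit only by universal-homozygote variants. The
curves obey two exact invariants the tests enforce: per-step means sum to
the total distinct unknown item count, and for small `n` the permutation
mean equals the full-ordering enumeration. `extrapolate_cohort_size()` is
deliberately dumb - ceiling division of a catalogue size by an observed
per-genome rate - because propagating the observed trend is all the data
supports; no discovery model is fitted.

## HWE diagnostics and duplication artifacts

Collapsed duplicated sequence creates apparent heterozygotes: reads from
two diverged copies align to one locus, and every carrier of the
duplication is called het. Genome-wide, such sites are far out of HWE in
the excess-heterozygote direction. `hwe_exact_excess_het()` implements the
exact conditional test - given the allele counts, the heterozygote count
distribution over values of matching parity, computed with the standard
recurrence - and reports the probability-mass two-sided p, the one-sided
excess-het p, and the direction relative to the conditional expectation
`n_minor * n_major / (2n - 1)`. The exact construction matters: with ~17
diploids most sites have small minor-allele counts where chi-square
approximations misbehave. The test is one-sided-able but the headline
outlier definition used by `hwe_outlier_enrichment()` is two-sided
p < 0.01 filtered to the excess-het direction; the one-sided count is
reported alongside.

Copy-number context comes from a deliberately minimal read-depth
segmentation (`call_depth_cnv()`): a 3-state hidden Markov model over 2 kb
windows with Poisson emissions at `lambda/2`, `lambda`, `3*lambda/2`
(deletion, normal, duplication), self-transition probability 0.999, and
Viterbi decoding. A genotype-aware, absolute-copy-number caller is out of
scope by design; three states suffice to partition sites into category A
(duplicated in all samples), B (in some), and C (in none)
(`classify_site_categories()`), and to ask whether excess-het outliers
concentrate where duplications are (`hwe_outlier_enrichment()` reports
each category's outlier share over its genomic length share). HWE is
computed on a designated diploid, single-ancestry-group subset passed by
the caller; no ancestry inference is attempted.

The male X chromosome provides an internal positive control: heterozygous
calls on a single-copy chromosome are artifacts by definition.
`male_x_het_summary()` reports each male's X het fraction and partitions
the hets by location - pseudoautosomal region (PAR; with the Y copy of
the PAR masked in the reference, Y reads pile onto the X and diverged
sites are called het), duplication-called regions, and elsewhere.

## QC and concordance

`concordance()` compares sequencing genotypes against chip genotypes at
chip sites, per sample, excluding sites missing on either platform and
comparing hemizygous sequencing calls as homozygous-alternate (chips
report diploid codes). Full-genotype matching is used (the stricter
reading). Discordances split into category 1 (homozygous by sequencing,
heterozygous by chip - the signature of sampling only one allele of a true
het at low depth) and category 2 (anything else). `coverage_summary()`
implements the covered-base convention - at least 5 reads with consensus
quality strictly greater than zero - against the non-N reference length.
`titv_ratio()`, `hom_het_ratio()` (diploid calls only; hemizygous calls
are excluded from both counts), `known_overlap()` and
`validation_summary()` complete the standard cohort QC table.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a 20-genome
study on a desk-scale toy genome. Defaults (all in `generator_config()`):

* **Cohort**: 10 male cases and 10 controls (7 male, 3 female); 17 of the
  20 samples share the majority ancestry label, matching the size of a
  homogeneous HWE subset. All cases are male because the planted disease
  is X-linked.
* **Genome**: 10 Mb in three chromosomes (4 + 3 Mb autosomes, 3 Mb X with
  a 150 kb PAR), 0.5% trailing N gap per chromosome, 200 intact gene
  models (CDS 300-1500 nt, up to 3 exons, ATG start, single terminal
  stop, no internal stops by construction), 90% carrying the canonical
  flag.
* **Sites**: 1e5 SNVs and 2e4 anchored indels - roughly 1/35 of a real
  genome's per-sample yield, over 1/300 of its length; all analyses are
  scale-free in site density. Transitions with probability 0.6753, giving
  the expected transition/transversion ratio of about 2.08. Indel lengths
  1-30 bp with 51% multiples of 3 and exponential within-class decay
  (scale 6 bp). SNVs are flagged "known" with probability 0.8728, indels
  0.05 (external indel catalogues are thin).
* **Frequencies**: a truncated neutral spectrum (density proportional to
  `1/q`, `q >= 0.01`) mixed with a reference-minor component
  (`q ~ U(0.9, 1)`); the mixture weight is solved numerically
  (`solve_sfs_mixture()`) so the expected per-genome homozygote/
  heterozygote ratio is 0.59. The reference-minor component is what makes
  universal homozygotes appear at a realistic rate. Genotypes are drawn
  from Hardy-Weinberg proportions at each site's frequency; male X
  genotypes outside the PAR are hemizygous.
* **Duplications and artifacts**: autosomal regions duplicated in all
  samples cover 0.41% of the autosomes and in some samples (carrier
  probability 0.5) 1.16%, in segments of 5-25 windows; 1% of the X is
  duplicated in all samples (centromere-like repeats); each sample also
  carries private deletions over 0.4% of the autosomes. Sites inside
  duplicated sequence become paralog-collapse artifacts with probability
  0.1 (forced het in duplication carriers); PAR sites become Y-collapse
  artifacts with probability 0.15 (forced het in males). These rates were
  chosen once as a realistic middle ground - strong enough that
  excess-het outliers concentrate measurably in category A, weak enough
  not to distort cohort-level ratios - and are not tuned per analysis.
* **Depth and errors**: per-variant and per-window depths are Poisson
  with rate `mean_coverage * copy / 2` (default 30x; male non-PAR X gets
  copy 1, duplications 3, the male PAR 3 because of the Y pile-up). True
  heterozygotes are undercalled to a homozygote with probability
  `plogis(-2.79 - 0.1372 * depth)` - about 3% at 5x, under 0.1% at 30x, a
  logistic shape chosen because the real phenomenon (sampling one allele)
  decays smoothly with depth and no functional form is dictated by data.
  Genotypes go missing at rate 0.001. Chip genotypes copy the *true*
  genotypes at 5% of SNV sites with error 0.002.
* **Causal scenario** (`plant_causal_scenario()`): in one designated
  canonical gene on the non-PAR X, one stop-gain SNV and four frameshift
  indels are planted hemizygous in five distinct male cases, plus one
  frameshift deletion called *heterozygous* in a sixth case - a carrier
  the caller under-genotyped, which therefore never qualifies and is
  visible only in the truth track. Controls carry none of the planted
  variants. The causal gene is modeled as intolerant of standing
  loss-of-function variation: population sites are not placed in its CDS,
  so its only coding variants are the planted ones. Without that
  constraint a common truncating polymorphism can land in the causal gene
  and - being homozygous in some control - disqualify the whole gene
  under the gene-wide control filter, which is not the biology the
  scenario represents (a gene whose disruption causes severe disease does
  not segregate common homozygous truncating alleles).

Determinism: every draw flows from `config$seed` through one RNG stream;
identical configurations reproduce byte-identical outputs, which the
pipeline manifest (file digests) makes checkable.

### What the generator does and does not emulate

The generator reproduces site-frequency structure, depth-dependent
genotyping error, duplication-collapse artifacts, chip error, and an
X-linked causal architecture. It does **not** emulate: linkage
disequilibrium (sites are independent), population structure within the
ancestry labels, alignment-level error correlation (indel realignment
artifacts, strand bias), version-dependent caller behavior on indel
zygosity, inversions (invisible to this design, exactly as in real
short-read studies), or selection beyond the single constrained causal
gene. Consequently, passing tests demonstrate that the *methods* are
implemented correctly and behave as expected under the stated statistical
structure - not that real-genome quantities (for example per-genome novel
SNV plateaus or genome-wide outlier rates, which depend on real LD,
demography and reference quality) are reproduced. Cohort-level summary
calibrations (Ti/Tv near 2.08, hom/het near 0.59, 51% in-frame coding
indels, 87.28% known overlap) are reproduced because they are explicit
generator conditions; the emitted hom/het ratio runs a percent or two
below the solved mixture target because artifact heterozygotes and
depth-dependent undercalls perturb the clean Hardy-Weinberg expectation,
as they do in real data.

## Numerical and convention choices

* Internal coordinates are 1-based closed (the `GenomicRanges`
  convention); BED I/O converts to 0-based half-open at the boundary, VCF
  and GFF are 1-based natively. Round-trips are lossless and tested.
* Indels are stored VCF-style anchored (first base shared), giving
  deterministic `(chrom, pos, ref, alt)` site keys; multi-allelic VCF
  records are split into bi-allelic keys on input.
* Hemizygous male X calls are a distinct genotype state end to end
  (haploid `1` in VCF), never silently coerced; each consumer decides
  equivalence (knockouts and prioritization count them as homozygous
  form, hom/het QC excludes them, concordance compares them as
  homozygous-alternate).
* The known-variant flag travels as INFO `KNOWN=1`, so no external
  catalogue file is needed at runtime.
* The two-sided Fisher p-value uses the probability-mass rule (the
  `fisher.test` convention), which reproduces the canonical
  `2/choose(20,10)` worked example; the HWE test is the exact conditional
  test computed by parity recurrence, cross-checked in the tests against
  an independent log-multinomial formula and, for small n, a complete
  allele-placement enumeration.
* HMM tuning (self-transition 0.999, uniform switching, Poisson
  emissions at half-integer copy ratios) is recorded in the function
  signature; it is not estimated from data.
* CNV overlap ("at least 50%") is one-way - covered fraction of the query
  segment - since reciprocality is a stricter convention than the
  phrasing implies; the threshold is inclusive.
* An optional high-depth exclusion (`analysis_config(high_depth_exclusion=)`)
  mirrors the observation that kilo-fold coverage sites are error-prone;
  it is off by default because the appropriate ceiling is data-dependent.

## Problem sizes

The shipped defaults are sized for interactive use: a full
generate-to-report pipeline run (1.2e5 sites, 20 genomes, 1000 saturation
permutations, per-sample HMM segmentation and genome-wide exact HWE) takes
on the order of half a minute. The test suite builds its cohorts at
4e3-2e4 sites; the acceptance script uses the full default scale. All
analyses are linear in site count except the HWE scan, which is effectively
linear because p-values are computed once per distinct genotype
configuration.

## Known limitations

* Gene models carry CDS only; UTR classification activates only if exon
  annotation beyond the CDS is supplied, and the generator emits none.
* The depth HMM reports states, not absolute copy numbers, and has no
  sensitivity below its window size - small CNVs are invisible, exactly
  the failure mode the male X "elsewhere" het bucket is there to expose.
* The criterion-3 control-frequency filter generalizes the "5 of 10"
  rule by carrier count, which at odd control counts is marginally
  stricter than a true frequency threshold.
* `read_vcf()` supports the subset of VCF the pipeline emits (GT/DP/GQ,
  bi- and multi-allelic SNV/indel records); symbolic alleles and phasing
  are out of scope.
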