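test_that("the exact HWE distribution matches the direct-formula oracle for all tables up to 40 alleles", {
  for (n in 1:20) {
    for (n_minor in 0:n) {
      if (n_minor == 0) next
      want <- oracle_hwe_dist_formula(n_minor, n)
      got <- lofcohort:::hwe_het_distribution(n_minor, n)
      expect_equal(got$het, want$het)
      expect_equal(got$prob, want$prob, tolerance = 1e-12)
    }
  }
})

test_that("the exact HWE distribution matches exhaustive allele placement for small n", {
  for (n in 2:8) {
    for (n_minor in 1:n) {
      want <- oracle_hwe_dist_placement(n_minor, n)
      got <- lofcohort:::hwe_het_distribution(n_minor, n)
      expect_equal(got$het[got$prob > 1e-14], want$het)
      expect_equal(got$prob[match(want$het, got$het)], want$prob,
        tolerance = 1e-12
      )
    }
  }
})

test_that("excess-het p-values and directions behave on the canonical examples", {
  # all-homozygote split: observed het is the minimum, so P(het >= 0) = 1
  r <- hwe_exact_excess_het(5, 0, 5)
  expect_equal(r$p_excess_het, 1)
  expect_equal(r$direction, "deficit_het")

  # 17 diploids all heterozygous: compare against the formula oracle
  r <- hwe_exact_excess_het(0, 17, 0)
  d <- oracle_hwe_dist_formula(17, 17)
  expect_equal(r$p_excess_het, sum(d$prob[d$het >= 17]), tolerance = 1e-12)
  expect_equal(r$direction, "excess_het")
  expect_lt(r$p_two_sided, 0.01)

  # monomorphic site: not testable
  r <- hwe_exact_excess_het(17, 0, 0)
  expect_false(r$testable)
  expect_equal(r$p_two_sided, 1)
})

test_that("p-values agree with the oracle across every genotype configuration up to 40 alleles", {
  for (n in c(2, 5, 11, 17, 20)) {
    for (n_het in 0:n) {
      for (n_hom_alt in 0:(n - n_het)) {
        n_hom_ref <- n - n_het - n_hom_alt
        r <- hwe_exact_excess_het(n_hom_ref, n_het, n_hom_alt)
        n_a <- 2 * n_hom_alt + n_het
        n_minor <- min(n_a, 2 * n - n_a)
        if (n_minor == 0) {
          expect_false(r$testable)
          next
        }
        d <- oracle_hwe_dist_formula(n_minor, n)
        p_obs <- d$prob[d$het == n_het]
        expect_equal(
          r$p_two_sided, sum(d$prob[d$prob <= p_obs * (1 + 1e-7)]),
          tolerance = 1e-12
        )
        expect_equal(
          r$p_excess_het, sum(d$prob[d$het >= n_het]),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("constant read depth decodes to a single normal segment", {
  wd <- data.frame(
    chrom = "chr1",
    start = seq(1, by = 2000, length.out = 200),
    end = seq(2000, by = 2000, length.out = 200),
    depth = rpois(200, 30)
  )
  set.seed(8)
  wd$depth <- rpois(200, 30)
  segs <- call_depth_cnv(wd, 30)
  expect_equal(length(segs), 1L)
  expect_equal(segs$state, "normal")
})

test_that("planted duplication and deletion blocks are recovered at 90% window accuracy", {
  sens_n <- sens_d <- prec_n <- prec_d <- 0
  del_hit <- del_tot <- 0
  for (s in 1:5) {
    cfg <- generator_config(
      seed = 7000 + s, n_snv = 500, n_indel = 50,
      chrom_lengths = c(chr1 = 2e6, chr2 = 1e6, chrX = 4e5),
      par_interval = c(1, 40000), n_genes = 12,
      dup_frac_all = 0.02, dup_frac_some = 0.02,
      dup_seg_windows = c(10, 25), deletion_frac = 0.01,
      causal_scenario = FALSE
    )
    sc <- suppressWarnings(generate_cohort(cfg))
    sm <- sc$cohort$samples$sample_id[1]
    wd <- sc$windows[sc$windows$sample_id == sm & sc$windows$chrom != "chrX", ]
    called <- call_depth_cnv(wd, stats::median(wd$depth))
    truth <- sc$truth$cnv[[sm]]
    truth <- truth[GenomicRanges::seqnames(truth) != "chrX"]
    for (st in c("duplication", "deletion")) {
      td <- GenomicRanges::reduce(truth[truth$state == st])
      cd <- GenomicRanges::reduce(called[called$state == st])
      inter <- sum(GenomicRanges::width(GenomicRanges::intersect(td, cd)))
      if (st == "duplication") {
        sens_n <- sens_n + inter
        sens_d <- sens_d + sum(GenomicRanges::width(td))
        prec_n <- prec_n + inter
        prec_d <- prec_d + sum(GenomicRanges::width(cd))
      } else {
        del_hit <- del_hit + inter
        del_tot <- del_tot + sum(GenomicRanges::width(td))
      }
    }
  }
  expect_gte(sens_n / sens_d, 0.90)
  expect_gte(prec_n / prec_d, 0.90)
  expect_gte(del_hit / del_tot, 0.90)
})

test_that("site categories partition A/B/C by per-sample duplication status", {
  gr <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  dup <- function(s, e) {
    g <- gr(s, e)
    g$state <- "duplication"
    g
  }
  cnv_sets <- list(
    s1 = dup(1000, 2999),
    s2 = suppressWarnings(c(dup(1000, 2999), dup(5000, 5999))),
    s3 = dup(1000, 2999)
  )
  sites <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1500, 5500, 8000), width = 1)
  )
  r <- classify_site_categories(sites, cnv_sets, genome_length = 10000)
  expect_equal(as.character(r$category), c("A", "B", "C"))
  expect_equal(sum(r$table$n_sites), 3L)
  expect_equal(sum(r$table$length_fraction), 1, tolerance = 1e-9)
  expect_equal(r$table$length_fraction[1], 2000 / 10000)
  expect_equal(r$table$length_fraction[2], 1000 / 10000)

  # no duplications anywhere: everything is C with 100% of the length
  none <- lapply(cnv_sets, function(x) GenomicRanges::GRanges())
  r0 <- classify_site_categories(sites, none, genome_length = 10000)
  expect_true(all(r0$category == "C"))
  expect_equal(r0$table$length_fraction, c(0, 0, 1))
})

test_that("excess-het outliers concentrate in duplicated categories on artifact cohorts", {
  sc <- tiny_cohort()
  co <- sc$cohort
  auto <- co$sites$chrom != "chrX"
  auto_sites <- co$sites[auto, ]
  cats <- classify_site_categories(
    sites_granges(auto_sites), sc$truth$cnv,
    genome_length = sum(non_n_lengths(sc$ref)[c("chr1", "chr2")])
  )
  eur <- co$samples$sample_id[co$samples$ancestry == "EUR"]
  enr <- hwe_outlier_enrichment(
    co, cats,
    site_ids = auto_sites$site_id, subset_samples = eur
  )
  e <- enr$enrichment
  expect_equal(sum(e$n_outliers[!is.na(e$outlier_share)]) / sum(e$n_outliers), 1)
  expect_equal(sum(e$outlier_share), 1, tolerance = 1e-9)
  expect_gt(e$fold[e$category == "A"], e$fold[e$category == "C"])
  expect_gt(e$fold[e$category == "A"], 1)
})

test_that("on artifact-free cohorts outliers scatter in proportion to length", {
  sc <- clean_cohort()
  co <- sc$cohort
  auto <- co$sites$chrom != "chrX"
  auto_sites <- co$sites[auto, ]
  # no duplications exist; use window-derived CNV calls, which should find
  # none, leaving everything category C
  sm <- co$samples$sample_id
  cnv_sets <- lapply(sm, function(s) {
    wd <- sc$windows[sc$windows$sample_id == s & sc$windows$chrom != "chrX", ]
    call_depth_cnv(wd, stats::median(wd$depth))
  })
  names(cnv_sets) <- sm
  cats <- classify_site_categories(
    sites_granges(auto_sites), cnv_sets,
    genome_length = sum(non_n_lengths(sc$ref)[c("chr1", "chr2")])
  )
  eur <- co$samples$sample_id[co$samples$ancestry == "EUR"]
  enr <- hwe_outlier_enrichment(
    co, cats,
    site_ids = auto_sites$site_id, subset_samples = eur
  )
  e <- enr$enrichment
  # outlier share of category C is consistent with its length share
  n_out <- sum(e$n_outliers)
  if (n_out > 0) {
    pv <- stats::binom.test(
      e$n_outliers[e$category == "C"], n_out,
      p = e$length_share[e$category == "C"]
    )$p.value
    expect_gt(pv, 1e-3)
  }
  expect_lte(enr$outlier_rate, 0.015)
})

test_that("male X heterozygote calls are summarized by PAR and duplication buckets", {
  samples <- data.frame(
    sample_id = c("m1", "m2", "f1"), sex = c("M", "M", "F"),
    phenotype = "control"
  )
  sites <- data.frame(
    chrom = "chrX", pos = c(100L, 5000L, 9000L), ref = "A", alt = "T",
    known = FALSE
  )
  co <- manual_cohort(
    c(
      "het", "hom_ref", "het", # in PAR
      "het", "hom_ref", "hom_ref", # in a duplication (m1)
      "hemizygous_alt", "hemizygous_alt", "hom_alt" # ordinary non-PAR
    ),
    sites, samples
  )
  par <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 1000))
  dup <- GenomicRanges::GRanges("chrX", IRanges::IRanges(4000, 6000))
  dup$state <- "duplication"
  cnv <- list(m1 = dup, m2 = GenomicRanges::GRanges(), f1 = GenomicRanges::GRanges())
  r <- male_x_het_summary(co, par, cnv)
  expect_equal(nrow(r), 2L)
  m1 <- r[r$sample_id == "m1", ]
  expect_equal(m1$n_het, 2L)
  expect_equal(m1$het_fraction, 2 / 3)
  expect_equal(m1$par_share, 0.5)
  expect_equal(m1$dup_share, 0.5)
  expect_equal(m1$other_share, 0)
  m2 <- r[r$sample_id == "m2", ]
  expect_equal(m2$n_het, 0L)
  expect_equal(m2$het_fraction, 0)
})

test_that("generated male X heterozygotes sit in the PAR and duplicated regions", {
  sc <- tiny_cohort()
  r <- male_x_het_summary(sc$cohort, sc$par, sc$truth$cnv)
  expect_true(all(r$het_fraction > 0))
  expect_true(all(r$par_share + r$dup_share > 0.9))
  expect_true(all(r$par_share > r$dup_share))
})

test_that("CNV overlap fractions respect the at-least-50% convention", {
  q <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 1000, 5000), width = 100)
  )
  expect_equal(cnv_overlap_fraction(q, q), 1)
  far <- GenomicRanges::shift(q, 100000)
  expect_equal(cnv_overlap_fraction(q, far), 0)
  # exactly 50 of 100 bp covered counts
  half <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 100))
  expect_equal(
    cnv_overlap_fraction(
      GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)), half
    ),
    1
  )
  under <- GenomicRanges::GRanges("chr1", IRanges::IRanges(52, 100))
  expect_equal(
    cnv_overlap_fraction(
      GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)), under
    ),
    0
  )
  expect_true(is.na(cnv_overlap_fraction(GenomicRanges::GRanges(), q)))
})
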