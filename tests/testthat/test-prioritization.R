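# Hand-built annotated cohort exercising the qualifying criteria: 2 cases,
# 10 controls, truncating variants in several configurations.
criteria_fixture <- function() {
  samples <- data.frame(
    sample_id = c("k1", "k2", paste0("c", 1:10)),
    sex = c("M", "M", rep("F", 10)),
    phenotype = c("case", "case", rep("control", 10))
  )
  mk <- function(n, lab) rep(lab, n)
  sites <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chrX", "chr2"),
    pos = c(100L, 200L, 300L, 400L, 100L, 500L, 900L),
    ref = c("A", "C", "G", "T", "A", "C", "G"),
    alt = c("T", "CT", "A", "A", "G", "A", "GT"),
    known = FALSE
  )
  # genotypes, site-major (12 samples per row)
  labels <- c(
    # V1 gene G1: hom in case k1, absent everywhere else -> qualifies
    "hom_alt", "hom_ref", mk(10, "hom_ref"),
    # V2 gene G2: hom in k1 but also hom in control c1 -> criterion 1
    "hom_alt", "hom_ref", "hom_alt", mk(9, "hom_ref"),
    # V3 gene G3: hom in k1, het in 6 controls -> criterion 3
    "hom_alt", "hom_ref", mk(6, "het"), mk(4, "hom_ref"),
    # V4 gene G4: hom in k1 at insufficient depth -> criterion 4
    "hom_alt", "hom_ref", mk(10, "hom_ref"),
    # V5 gene G5: hom in k1; G5 also has V7 hom in a control -> criterion 2
    "hom_alt", "hom_ref", mk(10, "hom_ref"),
    # V6 gene GX (chrX): hemizygous in male case k2 -> qualifies at 5x
    "hom_ref", "hemizygous_alt", mk(10, "hom_ref"),
    # V7 gene G5: hom in control c2 (adequate depth)
    "hom_ref", "hom_ref", "hom_ref", "hom_alt", mk(8, "hom_ref")
  )
  co <- manual_cohort(labels, sites, samples)
  # depths: default 30x; V4 in k1 at 9x; V6 in k2 at 6x (sex threshold 5x)
  co$depth["chr1:400:T:A", "k1"] <- 9L
  co$depth["chrX:500:C:A", "k2"] <- 6L
  genes <- data.table::data.table(
    gene_id = c("G1", "G2", "G3", "G4", "G5", "GX"),
    transcript_id = paste0("t", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chrX"),
    strand = "+", canonical = TRUE, cds_len = 300L
  )
  gene_class <- data.table::data.table(
    site_id = c(
      "chr1:100:A:T", "chr1:200:C:CT", "chr1:300:G:A", "chr1:400:T:A",
      "chr2:100:A:G", "chrX:500:C:A", "chr2:900:G:GT"
    ),
    gene_id = c("G1", "G2", "G3", "G4", "G5", "GX", "G5"),
    class = c(
      "stop_gain", "frameshift", "stop_gain", "stop_gain", "stop_loss",
      "frameshift", "frameshift"
    ),
    rel_cds_pos = 0.5
  )
  structure(
    list(
      cohort = co, genes = list(genes = genes), ref = NULL,
      gene_class = gene_class
    ),
    class = "annotated_cohort"
  )
}

test_that("the five qualifying criteria admit and reject the right variants", {
  ann <- criteria_fixture()
  ev <- qualifying_variants(
    ann, c("k1", "k2"), paste0("c", 1:10),
    x_chrom = "chrX"
  )
  expect_setequal(ev$gene_id, c("G1", "GX"))
  expect_equal(ev$zygosity[ev$gene_id == "GX"], "hemizygous_alt")
  expect_equal(ev$control_het_carriers[ev$gene_id == "G1"], 0)
  # G2 fails criterion 1, G3 criterion 3 (6 > 5 het carriers), G4
  # criterion 4 (9x < 10x), G5 criterion 2 (other variant hom in control)
  expect_false(any(c("G2", "G3", "G4", "G5") %in% ev$gene_id))
})

test_that("a control homozygote below the depth threshold does not disqualify", {
  ann <- criteria_fixture()
  ann$cohort$depth["chr1:200:C:CT", "c1"] <- 7L # below the 10x autosome rule
  ev <- qualifying_variants(ann, c("k1", "k2"), paste0("c", 1:10))
  expect_true("G2" %in% ev$gene_id)
})

test_that("non-canonical genes are excluded (criterion 5)", {
  ann <- criteria_fixture()
  ann$genes$genes$canonical[ann$genes$genes$gene_id == "G1"] <- FALSE
  ev <- qualifying_variants(ann, c("k1", "k2"), paste0("c", 1:10))
  expect_false("G1" %in% ev$gene_id)
})

test_that("with zero controls the control criteria pass vacuously", {
  ann <- criteria_fixture()
  ev <- qualifying_variants(ann, c("k1", "k2"), character(0))
  expect_true(all(c("G1", "G2", "G3", "G5", "GX") %in% ev$gene_id))
  expect_false("G4" %in% ev$gene_id) # depth is not a control criterion
  expect_error(qualifying_variants(ann, c("k1", "k2"), c("k1")), "overlap")
})

test_that("gene ranking counts distinct cases with competition ties", {
  ev <- data.table::data.table(
    gene_id = c("A", "A", "A", "B", "B", "B", "C"),
    sample_id = c("s1", "s2", "s3", "s4", "s5", "s6", "s1"),
    site_id = c("v1", "v1", "v2", "v3", "v4", "v5", "v6"),
    class = "stop_gain",
    zygosity = "hom_alt", depth = 30L,
    kind = c("SNV", "SNV", "deletion", "SNV", "SNV", "SNV", "SNV"),
    control_het_carriers = c(1L, 1L, 0L, 2L, 2L, 2L, 0L)
  )
  tab <- rank_genes(ev)
  expect_equal(tab$rank, c(1L, 1L, 3L))
  expect_equal(tab$n_cases, c(3L, 3L, 1L))
  expect_equal(tab$snv_count[tab$gene_id == "A"], 1L)
  expect_equal(tab$indel_count[tab$gene_id == "A"], 1L)
  expect_equal(nrow(rank_genes(empty <- ev[0])), 0L)
})

test_that("two-sided Fisher p-values match the printed worked example and an enumeration oracle", {
  expect_equal(
    fisher_exact_two_sided(10, 0, 0, 10), 2 / choose(20, 10),
    tolerance = 1e-12
  )
  expect_equal(signif(fisher_exact_two_sided(10, 0, 0, 10), 1), 1e-5)
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_equal(
    fisher_exact_two_sided(3, 7, 0, 10),
    oracle_fisher_two_sided(3, 7, 0, 10),
    tolerance = 1e-12
  )
  expect_equal(fisher_exact_two_sided(0, 0, 0, 0), 1)
})

test_that("Bonferroni thresholds reproduce the study arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 39374), 0.05 / 39374)
  expect_equal(signif(bonferroni_threshold(0.05, 39374), 2), 1.3e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("maximal-imbalance power analysis matches a brute-force scan over test counts", {
  r <- max_imbalance_power(10, 10, 39374, 0.05)
  expect_false(r$achievable)
  expect_true(max_imbalance_power(10, 10, 1, 0.05)$achievable)
  # smallest m making the design unachievable
  min_p <- fisher_exact_two_sided(10, 0, 0, 10)
  brute <- which(!vapply(
    1:10000, function(m) min_p <= 0.05 / m, logical(1)
  ))[1]
  scan <- which(!vapply(
    1:10000, function(m) max_imbalance_power(10, 10, m, 0.05)$achievable,
    logical(1)
  ))[1]
  expect_equal(scan, brute)
  expect_lt(brute, 39374)
})

test_that("control titration is deterministic under a fixed seed and finds the planted gene", {
  ann <- tiny_annotated()
  sc <- tiny_cohort()
  r1 <- control_titration(ann, sc$causal_gene, 5, n_permutations = 1, seed = 99)
  r2 <- control_titration(ann, sc$causal_gene, 5, n_permutations = 1, seed = 99)
  expect_identical(r1$ranks, r2$ranks)

  full <- control_titration(ann, sc$causal_gene, 10, n_permutations = 1, seed = 1)
  expect_equal(full$mean_rank, 1)

  five <- control_titration(ann, sc$causal_gene, 5, n_permutations = 5, seed = 1)
  expect_lte(five$mean_rank, 5)
})

test_that("adding controls never increases a gene's affected-case count", {
  ann <- tiny_annotated()
  sc <- tiny_cohort()
  cases <- case_ids(sc$cohort)
  ctrl <- control_ids(sc$cohort)
  t5 <- rank_genes(qualifying_variants(ann, cases, ctrl[1:5]))
  t10 <- rank_genes(qualifying_variants(ann, cases, ctrl))
  shared <- merge(
    t5[, c("gene_id", "n_cases")], t10[, c("gene_id", "n_cases")],
    by = "gene_id", all = TRUE
  )
  shared$n_cases.x[is.na(shared$n_cases.x)] <- 0L
  shared$n_cases.y[is.na(shared$n_cases.y)] <- 0L
  expect_true(all(shared$n_cases.y <= shared$n_cases.x))
  # the causal gene is untouched: controls carry none of its variants
  expect_equal(
    t10$n_cases[t10$gene_id == sc$causal_gene],
    t5$n_cases[t5$gene_id == sc$causal_gene]
  )
})
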