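# The toy gene CDS is ATG AAA TGC TAC GGA TGA; on the plus strand it
# occupies coding bases 1-9 at positions 11-19 and 10-18 at 40-48.

test_that("SNVs in CDS classify by codon translation on the plus strand", {
  tg <- toy_gene("+")
  # codon 4 TAC -> TAA (Tyr -> stop): coding base 12 = genomic 42, C>A
  r <- classify_snv(
    list(chrom = "toy", pos = 42, ref = "C", alt = "A"), tg$gm, tg$ref
  )
  expect_equal(r$class, "stop_gain")
  expect_equal(r$rel_cds_pos, 12 / 18)
  # terminal codon TGA -> TGG: coding base 18 = genomic 48, A>G
  r <- classify_snv(
    list(chrom = "toy", pos = 48, ref = "A", alt = "G"), tg$gm, tg$ref
  )
  expect_equal(r$class, "stop_loss")
  # codon 2 AAA -> AAG (Lys -> Lys): coding base 6 = genomic 16
  r <- classify_snv(
    list(chrom = "toy", pos = 16, ref = "A", alt = "G"), tg$gm, tg$ref
  )
  expect_equal(r$class, "synonymous")
  # codon 2 AAA -> ACA: coding base 5 = genomic 15
  r <- classify_snv(
    list(chrom = "toy", pos = 15, ref = "A", alt = "C"), tg$gm, tg$ref
  )
  expect_equal(r$class, "nonsynonymous")
})

test_that("a reference-allele mismatch is an error naming the site", {
  tg <- toy_gene("+")
  expect_error(
    classify_snv(list(chrom = "toy", pos = 42, ref = "G", alt = "A"), tg$gm, tg$ref),
    "reference mismatch at toy:42"
  )
})

test_that("minus-strand SNV classes match an independent transcript-space annotator", {
  tg <- toy_gene("-")
  chrom_seq <- as.character(tg$ref[["toy"]])
  cds_pos <- c(11:19, 40:48)
  set.seed(31)
  for (pos in cds_pos) {
    ref_b <- substr(chrom_seq, pos, pos)
    for (alt_b in setdiff(c("A", "C", "G", "T"), ref_b)) {
      v <- list(chrom = "toy", pos = pos, ref = ref_b, alt = alt_b)
      got <- classify_snv(v, tg$gm, tg$ref)
      want <- oracle_snv_class(v, tg$gm, tg$ref)
      expect_equal(got$class, want$class, info = paste("pos", pos, alt_b))
      expect_equal(got$rel_cds_pos, want$rel, info = paste("pos", pos, alt_b))
    }
  }
})

test_that("annotation is strand-consistent between a gene and its mirrored twin", {
  plus <- toy_gene("+")
  minus <- toy_gene("-")
  count_classes <- function(tg) {
    chrom_seq <- as.character(tg$ref[["toy"]])
    cls <- character(0)
    for (pos in c(11:19, 40:48)) {
      ref_b <- substr(chrom_seq, pos, pos)
      for (alt_b in setdiff(c("A", "C", "G", "T"), ref_b)) {
        cls <- c(cls, classify_snv(
          list(chrom = "toy", pos = pos, ref = ref_b, alt = alt_b),
          tg$gm, tg$ref
        )$class)
      }
    }
    table(cls)
  }
  expect_equal(count_classes(plus), count_classes(minus))
})

test_that("indels classify by net coding-length change, with junction flagging", {
  tg <- toy_gene("+")
  chrom_seq <- as.character(tg$ref[["toy"]])
  del4 <- list(
    chrom = "toy", pos = 12, ref = substr(chrom_seq, 12, 16), alt = substr(chrom_seq, 12, 12)
  )
  r <- classify_indel(del4, tg$gm, tg$ref)
  expect_equal(r$class, "frameshift")
  expect_false(r$junction_spanning)

  ins3 <- list(chrom = "toy", pos = 13, ref = substr(chrom_seq, 13, 13), alt = paste0(substr(chrom_seq, 13, 13), "AGG"))
  r <- classify_indel(ins3, tg$gm, tg$ref)
  expect_equal(r$class, "inframe_indel")

  # 2 bp deletion in the middle of the intron (positions 20-39)
  del_intron <- list(
    chrom = "toy", pos = 27, ref = substr(chrom_seq, 27, 29), alt = substr(chrom_seq, 27, 27)
  )
  r <- classify_indel(del_intron, tg$gm, tg$ref)
  expect_equal(r$class, "intronic")

  # deletion spanning the exon1/intron junction: bases 18-22 deleted
  del_junction <- list(
    chrom = "toy", pos = 17, ref = substr(chrom_seq, 17, 22), alt = substr(chrom_seq, 17, 17)
  )
  r <- classify_indel(del_junction, tg$gm, tg$ref)
  expect_equal(r$class, "frameshift") # net 5, 2 coding bases lost
  expect_true(r$junction_spanning)
})

test_that("non-coding positions route to splice boundary, intron, or intergenic", {
  tg <- toy_gene("+")
  chrom_seq <- as.character(tg$ref[["toy"]])
  at <- function(pos, alt = "A") {
    ref_b <- substr(chrom_seq, pos, pos)
    if (ref_b == alt) alt <- "C"
    classify_snv(list(chrom = "toy", pos = pos, ref = ref_b, alt = alt), tg$gm, tg$ref)$class
  }
  expect_equal(at(20), "splice_boundary") # 1 bp into the intron
  expect_equal(at(21), "splice_boundary")
  expect_equal(at(38), "splice_boundary") # 2 bp before exon 2
  expect_equal(at(30), "intronic")
  expect_equal(at(5), "intergenic")
})

test_that("relative CDS positions follow the coding-index arithmetic", {
  tg <- toy_gene("+")
  # CDS length 18: coding base 9 (end of exon 1, genomic 19) -> 0.5
  expect_equal(
    relative_cds_position(list(chrom = "toy", pos = 19, ref = "C", alt = "A"), tg$gm, tg$ref),
    0.5
  )
  # final codon position -> 1.0
  expect_equal(
    relative_cds_position(list(chrom = "toy", pos = 48, ref = "A", alt = "G"), tg$gm, tg$ref),
    1.0
  )
  expect_error(
    relative_cds_position(list(chrom = "toy", pos = 30, ref = "T", alt = "A"), tg$gm, tg$ref),
    "not coding"
  )
})

test_that("knockouts need homozygous or hemizygous truncating calls", {
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3"), sex = c("F", "F", "M"),
    phenotype = c("case", "case", "case")
  )
  sites <- data.frame(
    chrom = c("chr1", "chr1", "chrX"), pos = c(100L, 200L, 300L),
    ref = c("A", "C", "G"), alt = c("T", "CT", "GA"), known = FALSE
  )
  co <- manual_cohort(
    c(
      "hom_alt", "het", "hom_ref", # stop_gain in GA
      "het", "het", "hom_ref", # frameshift in GB
      "hom_ref", "hom_ref", "hemizygous_alt" # frameshift in GX (male X)
    ),
    sites, samples
  )
  fake_ann <- structure(
    list(
      cohort = co,
      gene_class = data.table::data.table(
        site_id = co$sites$site_id,
        gene_id = c("GA", "GB", "GX"),
        class = c("stop_gain", "frameshift", "frameshift"),
        rel_cds_pos = 0.5
      )
    ),
    class = "annotated_cohort"
  )
  expect_equal(knocked_out_genes("s1", fake_ann), "GA")
  expect_equal(knocked_out_genes("s2", fake_ann), character(0))
  expect_equal(knocked_out_genes("s3", fake_ann), "GX")
})

test_that("universal homozygotes require homozygous form in every sample", {
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3"), sex = c("F", "F", "M"),
    phenotype = rep("control", 3)
  )
  sites <- data.frame(
    chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T", known = FALSE
  )
  co <- manual_cohort(
    c(
      "hom_alt", "hom_alt", "hemizygous_alt",
      "hom_alt", "het", "hom_alt"
    ),
    sites, samples
  )
  expect_equal(universal_homozygotes(co), "chr1:10:A:T")
})

test_that("universal homozygote yield matches the analytic expectation from truth frequencies", {
  sc <- default_cohort()
  uni <- universal_homozygotes(sc$cohort)
  sites <- sc$cohort$sites
  q <- sc$truth$q[sites$site_id]
  n_male <- sum(sc$cohort$samples$sex == "M")
  n_fem <- nrow(sc$cohort$samples) - n_male
  on_x <- sites$chrom == "chrX"
  in_par <- on_x & sites$pos <= sc$config$par_interval[2]
  expected <- sum(ifelse(on_x & !in_par, q^(2 * n_fem + n_male),
    q^(2 * (n_male + n_fem))
  ))
  expect_gt(expected, 100)
  expect_equal(length(uni) / expected, 1, tolerance = 0.15)
})

test_that("planted truncating variants are annotated with their planted classes", {
  sc <- tiny_cohort()
  ann <- tiny_annotated()
  pl <- sc$truth$planted
  got <- ann$gene_class[match(pl$site_id, ann$gene_class$site_id)]
  expect_equal(got$class, pl$class)
  expect_equal(got$gene_id, rep(sc$causal_gene, nrow(pl)))
})

test_that("indel length summary arithmetic matches a direct recomputation", {
  ann <- tiny_annotated()
  s <- indel_length_summary(ann)
  gc <- ann$gene_class
  ids <- unique(gc$site_id[gc$class %in% c("frameshift", "inframe_indel")])
  lens <- with(
    ann$cohort$sites[match(ids, ann$cohort$sites$site_id)],
    abs(nchar(ref) - nchar(alt))
  )
  expect_equal(sum(s$histogram$n), length(lens))
  expect_equal(s$pct_multiple_of_3, 100 * mean(lens %% 3 == 0))

  # all-3n toy case
  tg <- toy_gene("+")
  chrom_seq <- as.character(tg$ref[["toy"]])
  sites <- data.frame(
    chrom = "toy", pos = 13L, ref = substr(chrom_seq, 13, 13),
    alt = paste0(substr(chrom_seq, 13, 13), "TTT"), known = FALSE
  )
  samples <- data.frame(sample_id = "s1", sex = "F", phenotype = "case")
  co <- manual_cohort("het", sites, samples)
  a2 <- annotate_cohort(co, tg$gm, tg$ref)
  expect_equal(indel_length_summary(a2)$pct_multiple_of_3, 100)
})

test_that("every variant receives exactly one class per overlapping transcript", {
  ann <- tiny_annotated()
  tab <- ann$ann
  genic <- tab[!is.na(tab$transcript_id)]
  expect_false(any(duplicated(paste(genic$site_id, genic$transcript_id))))
  expect_false(any(is.na(tab$class)))
  expect_true(all(tab$class %in% FUNCTIONAL_CLASSES))
  # coding positions carry a relative position in (0, 1]
  coding <- tab$class %in% c(
    "stop_gain", "stop_loss", "synonymous", "nonsynonymous",
    "frameshift", "inframe_indel"
  )
  expect_true(all(tab$rel_cds_pos[coding] > 0 & tab$rel_cds_pos[coding] <= 1))
})
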