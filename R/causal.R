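#' Plant the X-linked causal-gene scenario
#'
#' Inserts the hemophilia-like truth into a synthetic cohort: in the
#' designated causal gene on the non-PAR X, one stop-gain SNV and four
#' frameshift indels are planted as hemizygous calls in five distinct male
#' cases, and one additional frameshift deletion is planted as a
#' heterozygous call in a sixth case (emulating a real carrier whose variant
#' the caller genotyped as a heterozygote, which therefore does not qualify
#' in prioritization). Controls carry none of the planted variants.
#'
#' Called automatically by [generate_cohort()] when
#' `config$causal_scenario` is `TRUE`; the RNG stream is continued, not
#' reseeded.
#'
#' @param sc a `synthetic_cohort` bundle (see [generate_cohort()]).
#' @param config the [generator_config()] used to build `sc`.
#' @return The bundle with planted sites added to `sc$cohort` and a
#'   `sc$truth$planted` table (site, gene, carrier, genotype, expected
#'   class).
#' @export
plant_causal_scenario <- function(sc, config = sc$config) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  cohort <- sc$cohort
  gm <- sc$genes
  gene <- sc$causal_gene
  gidx <- which(gm$genes$gene_id == gene)
  stopifnot(length(gidx) == 1, gm$genes$chrom[gidx] == config$x_chrom)
  tx <- gm$genes$transcript_id[gidx]
  strand <- gm$genes$strand[gidx]
  chrom <- gm$genes$chrom[gidx]

  male_cases <- cohort$samples$sample_id[
    cohort$samples$phenotype == "case" & cohort$samples$sex == "M"
  ]
  if (length(male_cases) < 6) {
    stop("causal scenario needs at least 6 male cases; have ", length(male_cases))
  }
  carriers <- sample(male_cases, 6L)

  txp <- tx_positions(gm, tx)
  cds_seq <- tx_cds_seq(gm, tx, sc$ref)
  n_codon <- nchar(cds_seq) %/% 3L
  chrom_s <- as.character(sc$ref[[chrom]])

  ## stop-gain SNV: single-base change in an internal codon creating a stop
  cand <- list()
  for (ci in seq(2L, n_codon - 1L)) {
    codon <- substr(cds_seq, 3L * ci - 2L, 3L * ci)
    if (codon %in% .STOP_CODONS) next
    for (off in 1:3) {
      for (b in setdiff(.BASES, substr(codon, off, off))) {
        mut <- codon
        substr(mut, off, off) <- b
        if (mut %in% .STOP_CODONS) {
          cand[[length(cand) + 1L]] <- c(ci, off, b)
        }
      }
    }
  }
  stopifnot(length(cand) > 0)
  repeat {
    pickc <- cand[[sample.int(length(cand), 1L)]]
    cidx <- 3L * as.integer(pickc[1]) - 3L + as.integer(pickc[2])
    gpos <- txp[cidx]
    tx_alt <- pickc[3]
    g_ref <- substring(chrom_s, gpos, gpos)
    g_alt <- if (strand == "+") tx_alt else chartr("ACGT", "TGCA", tx_alt)
    if (!site_key(chrom, gpos, g_ref, g_alt) %in% cohort$sites$site_id) break
  }
  snv_site <- data.frame(
    chrom = chrom, pos = gpos, ref = g_ref, alt = g_alt, known = FALSE,
    class = "stop_gain"
  )

  ## frameshift indels: anchored events fully inside one CDS exon
  cds_iv <- gm$cds[gm$cds$transcript_id == tx, ]
  pick_indel <- function(len, kind, used_pos) {
    repeat {
      e <- sample.int(nrow(cds_iv), 1L)
      lo <- cds_iv$start[e] + 1L # anchor must sit inside the exon too
      hi <- cds_iv$end[e] - len - 1L
      if (hi <= lo) next
      p <- sample(lo:hi, 1L)
      if (p %in% used_pos) next
      if (kind == "deletion") {
        ref <- substring(chrom_s, p, p + len)
        alt <- substring(chrom_s, p, p)
      } else {
        ref <- substring(chrom_s, p, p)
        alt <- paste0(ref, paste(sample(.BASES, len, replace = TRUE), collapse = ""))
      }
      if (site_key(chrom, p, ref, alt) %in% cohort$sites$site_id) next
      return(data.frame(
        chrom = chrom, pos = p, ref = ref, alt = alt, known = FALSE,
        class = "frameshift"
      ))
    }
  }
  lens <- c(1L, 2L, 1L, 4L, 2L) # non-multiples of 3: all frameshifts
  kinds <- c("deletion", "insertion", "insertion", "deletion", "deletion")
  indel_sites <- list()
  used <- gpos
  for (k in seq_len(5L)) {
    s <- pick_indel(lens[k], kinds[k], used)
    used <- c(used, s$pos)
    indel_sites[[k]] <- s
  }
  planted_sites <- rbind(snv_site, do.call(rbind, indel_sites))
  keys <- site_key(planted_sites$chrom, planted_sites$pos, planted_sites$ref, planted_sites$alt)
  stopifnot(!any(keys %in% cohort$sites$site_id), !anyDuplicated(keys))

  n_samp <- nrow(cohort$samples)
  geno <- matrix(0L, 6L, n_samp, dimnames = list(keys, cohort$samples$sample_id))
  # variants 1..5 are hemizygous in carriers 1..5; variant 6 het in carrier 6
  for (k in 1:5) geno[k, carriers[k]] <- GT_HEMI_ALT
  geno[6L, carriers[6]] <- GT_HET
  lambda <- ifelse(cohort$samples$sex == "M", config$mean_coverage / 2,
    config$mean_coverage
  )
  depth <- matrix(
    stats::rpois(6L * n_samp, rep(lambda, each = 6L)), 6L, n_samp
  )

  new_cohort <- cohort_table(
    samples = cohort$samples,
    sites = rbind(
      cohort$sites[, .(chrom, pos, ref, alt, known)],
      planted_sites[, c("chrom", "pos", "ref", "alt", "known")]
    ),
    geno = rbind(cohort$geno, geno),
    depth = rbind(cohort$depth, depth)
  )
  planted <- data.table::data.table(
    site_id = keys,
    gene_id = gene,
    sample_id = carriers,
    genotype = c(rep(GT_HEMI_ALT, 5L), GT_HET),
    class = planted_sites$class,
    qualifying = c(rep(TRUE, 5L), FALSE)
  )
  sc$cohort <- new_cohort
  sc$truth$planted <- planted
  sc$truth$q <- c(sc$truth$q, stats::setNames(rep(1 / (2 * n_samp), 6L), keys))
  sc
}
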