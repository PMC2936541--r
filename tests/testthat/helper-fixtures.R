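# Shared fixtures are generated once per session and cached; every fixture
# is fully determined by its seed and configuration.

.fixtures <- new.env(parent = emptyenv())

with_fixture <- function(key, fn) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fn()
  .fixtures[[key]]
}

# Desk-scale default study cohort (the hemophilia fixture): 10 male cases,
# 10 controls, default calibrations, causal scenario planted.
default_cohort <- function(seed = 1L) {
  with_fixture(paste0("default", seed), function() {
    suppressWarnings(generate_cohort(generator_config(seed = seed)))
  })
}

default_annotated <- function(seed = 1L) {
  with_fixture(paste0("default_ann", seed), function() {
    sc <- default_cohort(seed)
    annotate_cohort(sc$cohort, sc$genes, sc$ref)
  })
}

# Small, fast cohort for structural tests.
tiny_config <- function(seed = 101L, ...) {
  generator_config(
    seed = seed,
    n_snv = 4000, n_indel = 800,
    chrom_lengths = c(chr1 = 6e5, chr2 = 4e5, chrX = 4e5),
    par_interval = c(1, 40000),
    n_genes = 40,
    ...
  )
}

tiny_cohort <- function(seed = 101L) {
  with_fixture(paste0("tiny", seed), function() {
    suppressWarnings(generate_cohort(tiny_config(seed)))
  })
}

tiny_annotated <- function(seed = 101L) {
  with_fixture(paste0("tiny_ann", seed), function() {
    sc <- tiny_cohort(seed)
    annotate_cohort(sc$cohort, sc$genes, sc$ref)
  })
}

# Artifact-free configuration: no duplications, no collapse artifacts, no
# planted scenario (used for null-calibration checks).
clean_config <- function(seed = 201L, ...) {
  generator_config(
    seed = seed,
    n_snv = 20000, n_indel = 2000,
    chrom_lengths = c(chr1 = 1e6, chr2 = 8e5, chrX = 6e5),
    par_interval = c(1, 50000),
    n_genes = 50,
    dup_frac_all = 0, dup_frac_some = 0, x_dup_frac = 0,
    artifact_rate = 0, par_artifact_rate = 0, deletion_frac = 0,
    causal_scenario = FALSE,
    ...
  )
}

clean_cohort <- function(seed = 201L) {
  with_fixture(paste0("clean", seed), function() {
    suppressWarnings(generate_cohort(clean_config(seed)))
  })
}

# ---------------------------------------------------------------------------
# Hand-built two-exon toy gene (one per strand) on a tiny reference, for
# annotation unit tests. The CDS is ATG AAA TGC TAC GGA TGA (6 codons,
# MKCY G*), split 9 + 9 across two exons separated by a 20 bp intron.
toy_gene <- function(strand = "+") {
  cds_seq <- "ATGAAATGCTACGGATGA"
  intron <- paste(rep("T", 20), collapse = "")
  lead <- paste(rep("C", 10), collapse = "")
  tail <- paste(rep("G", 10), collapse = "")
  genomic <- if (strand == "+") cds_seq else as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(cds_seq))
  )
  seq <- paste0(
    lead, substr(genomic, 1, 9), intron, substr(genomic, 10, 18), tail
  )
  ref <- Biostrings::DNAStringSet(c(toy = seq))
  gm <- gene_models(
    genes = data.frame(
      gene_id = "G1", transcript_id = "T1", chrom = "toy",
      strand = strand, canonical = TRUE
    ),
    cds = data.frame(
      transcript_id = "T1", start = c(11L, 40L), end = c(19L, 48L)
    )
  )
  list(ref = ref, gm = gm, cds_seq = cds_seq)
}

# Independent transcript-space annotation oracle: rebuilds the transcript
# sequence from scratch, substitutes the variant in transcript coordinates
# and translates both sequences with Biostrings.
oracle_snv_class <- function(variant, gm, ref) {
  tx <- gm$genes$transcript_id[1]
  strand <- gm$genes$strand[1]
  cds <- gm$cds[order(gm$cds$exon_rank), ]
  chrom_seq <- as.character(ref[[variant$chrom]])
  pieces <- vapply(seq_len(nrow(cds)), function(i) {
    substr(chrom_seq, cds$start[i], cds$end[i])
  }, character(1))
  # exon_rank is transcription order; genomic pieces need strand handling
  if (strand == "+") {
    tx_seq <- paste(pieces, collapse = "")
  } else {
    tx_seq <- paste(vapply(pieces, function(p) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
    }, character(1)), collapse = "")
  }
  # transcript coordinate of the variant base
  coords <- unlist(lapply(seq_len(nrow(cds)), function(i) {
    if (strand == "+") cds$start[i]:cds$end[i] else cds$end[i]:cds$start[i]
  }))
  ci <- match(variant$pos, coords)
  if (is.na(ci)) {
    return(list(class = "non_coding", rel = NA_real_))
  }
  alt_tx <- if (strand == "+") variant$alt else chartr("ACGT", "TGCA", variant$alt)
  mut_seq <- tx_seq
  substr(mut_seq, ci, ci) <- alt_tx
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(tx_seq),
    no.init.codon = TRUE
  ))
  aa_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(mut_seq),
    no.init.codon = TRUE
  ))
  codon <- (ci - 1) %/% 3 + 1
  r <- substr(aa_ref, codon, codon)
  a <- substr(aa_alt, codon, codon)
  cls <- if (a == "*" && r != "*") {
    "stop_gain"
  } else if (r == "*" && a != "*") {
    "stop_loss"
  } else if (r == a) "synonymous" else "nonsynonymous"
  list(class = cls, rel = ci / nchar(tx_seq))
}

# ---------------------------------------------------------------------------
# Exact-test oracles.

# Fisher two-sided oracle by hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + c # col-1 margin (carriers)
  n <- b + d
  k <- a + b # row-1 margin (cases)
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# HWE conditional distribution oracle 1: direct log-multinomial formula.
oracle_hwe_dist_formula <- function(n_minor, n) {
  n_major <- 2 * n - n_minor
  h_min <- if (n_minor %% 2 == 0) max(0, n_minor - n_major) else 1
  hets <- seq(h_min, n_minor, by = 2)
  lp <- vapply(hets, function(h) {
    n_aa <- (n_minor - h) / 2
    n_bb <- (n_major - h) / 2
    h * log(2) + lfactorial(n) - lfactorial(n_aa) - lfactorial(h) -
      lfactorial(n_bb) + lfactorial(n_minor) + lfactorial(n_major) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp))
  data.frame(het = hets, prob = p / sum(p))
}

# HWE oracle 2 (n <= 8): exhaustive placement of the minor alleles over the
# 2n chromosome slots; slots (1,2), (3,4), ... form the diploids.
oracle_hwe_dist_placement <- function(n_minor, n) {
  slots <- 2 * n
  placements <- utils::combn(slots, n_minor)
  pair_of <- (seq_len(slots) + 1) %/% 2
  hets <- apply(placements, 2, function(idx) {
    counts <- tabulate(pair_of[idx], nbins = n)
    sum(counts == 1)
  })
  tab <- table(factor(hets, levels = 0:n_minor))
  data.frame(
    het = as.integer(names(tab)[tab > 0]),
    prob = as.numeric(tab[tab > 0]) / ncol(placements)
  )
}

# Exhaustive saturation-curve oracle: average per-step novel counts over
# every ordering of the samples' item sets.
oracle_saturation <- function(item_sets) {
  n <- length(item_sets)
  perms <- all_permutations(n)
  acc <- numeric(n)
  for (ord in perms) {
    seen <- character(0)
    for (j in seq_len(n)) {
      new <- setdiff(item_sets[[ord[j]]], seen)
      acc[j] <- acc[j] + length(new)
      seen <- union(seen, item_sets[[ord[j]]])
    }
  }
  acc / length(perms)
}

all_permutations <- function(n) {
  if (n == 1) {
    return(list(1L))
  }
  sub <- all_permutations(n - 1)
  out <- list()
  for (p in sub) {
    for (i in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}

# Build a small in-memory cohort from explicit genotype labels.
manual_cohort <- function(geno_labels, sites, samples) {
  geno <- matrix(gt_code(geno_labels),
    nrow = nrow(sites), byrow = TRUE, # labels given site-major
    dimnames = list(NULL, samples$sample_id)
  )
  depth <- matrix(30L, nrow(sites), nrow(samples))
  cohort_table(samples, sites, geno, depth)
}
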