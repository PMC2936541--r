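`%||%` <- function(a, b) if (is.null(a)) b else a

.BASES <- c("A", "C", "G", "T")
.STOP_CODONS <- c("TAA", "TAG", "TGA")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Generate a synthetic reference genome with gene models
#'
#' Builds the toy genome the synthetic cohort lives on: random sequence
#' chromosomes (with an `N` gap at each chromosome end), non-overlapping
#' protein-coding gene models whose CDS starts with `ATG`, ends with a
#' single stop codon and contains no internal in-frame stop, an X
#' chromosome with a designated pseudoautosomal region (PAR), and one
#' designated causal gene on the non-PAR X. Seeds the RNG from
#' `config$seed`; a fixed seed gives byte-identical output.
#'
#' @param config a [generator_config()].
#' @return list with `ref` (`DNAStringSet`), `genes` ([gene_models()]),
#'   `causal_gene`, `par` (`GRanges`), and `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  chroms <- names(config$chrom_lengths)
  lens <- as.integer(config$chrom_lengths)
  names(lens) <- chroms

  seqs <- lapply(lens, function(L) {
    s <- charToRaw(paste(rep("A", 0), collapse = ""))
    s <- charToRaw("ACGT")[sample.int(4L, L, replace = TRUE)]
    gap <- as.integer(ceiling(config$n_gap_frac * L))
    if (gap > 0) s[(L - gap + 1L):L] <- charToRaw("N")
    s
  })

  # allocate genes to chromosomes proportionally to usable length
  usable_from <- stats::setNames(rep(1L, length(chroms)), chroms)
  usable_from[config$x_chrom] <- as.integer(config$par_interval[2] + 1000L)
  usable_to <- as.integer(floor(lens * (1 - config$n_gap_frac))) - 100L
  names(usable_to) <- chroms
  usable_len <- stats::setNames(pmax(usable_to - usable_from + 1L, 0L), chroms)
  n_per_chrom <- as.vector(stats::rmultinom(1, config$n_genes, prob = usable_len))
  names(n_per_chrom) <- chroms
  # every chromosome should host at least one gene when possible
  for (cc in chroms) {
    donor <- names(which.max(n_per_chrom))
    if (n_per_chrom[cc] == 0L && usable_len[cc] > 0L && n_per_chrom[donor] >= 2L) {
      n_per_chrom[donor] <- n_per_chrom[donor] - 1L
      n_per_chrom[cc] <- 1L
    }
  }

  max_extent <- config$cds_len_range[2] + (config$max_exons - 1L) * 2000L + 200L
  genes_list <- list()
  cds_list <- list()
  gi <- 0L
  for (cc in chroms) {
    ng <- n_per_chrom[cc]
    if (ng == 0L) next
    slot_w <- usable_len[cc] %/% ng
    if (slot_w < max_extent + 100L) {
      stop(sprintf(
        "chromosome %s too short for %d genes (slot %d bp < gene extent %d bp)",
        cc, ng, slot_w, max_extent
      ))
    }
    for (k in seq_len(ng)) {
      gi <- gi + 1L
      gene_id <- sprintf("GENE%04d", gi)
      tx_id <- sprintf("TX%04d", gi)
      slot_start <- usable_from[cc] + (k - 1L) * slot_w
      start <- slot_start + sample.int(slot_w - max_extent, 1L)
      n_ex <- sample.int(config$max_exons, 1L)
      cds_len <- 3L * sample(
        seq.int(config$cds_len_range[1] %/% 3L, config$cds_len_range[2] %/% 3L),
        1L
      )
      # exon lengths: random composition with every part >= 3
      repeat {
        cuts <- if (n_ex > 1L) sort(sample.int(cds_len - 1L, n_ex - 1L)) else integer(0)
        ex_len <- diff(c(0L, cuts, cds_len))
        if (all(ex_len >= 3L)) break
      }
      introns <- if (n_ex > 1L) sample(100:2000, n_ex - 1L, replace = TRUE) else integer(0)
      ex_start <- start + cumsum(c(0L, utils::head(ex_len, -1) + introns))
      ex_end <- ex_start + ex_len - 1L
      strand <- sample(c("+", "-"), 1L)
      n_codon <- cds_len %/% 3L
      codons <- c(
        "ATG",
        sample(.NONSTOP_CODONS, n_codon - 2L, replace = TRUE),
        sample(.STOP_CODONS, 1L)
      )
      cds_seq <- paste(codons, collapse = "")
      genomic_seq <- if (strand == "+") cds_seq else revcomp(cds_seq)
      offs <- cumsum(c(0L, utils::head(ex_len, -1)))
      for (e in seq_len(n_ex)) {
        chunk <- substr(genomic_seq, offs[e] + 1L, offs[e] + ex_len[e])
        seqs[[cc]][ex_start[e]:ex_end[e]] <- charToRaw(chunk)
      }
      genes_list[[gi]] <- data.frame(
        gene_id = gene_id, transcript_id = tx_id, chrom = cc, strand = strand,
        canonical = stats::runif(1) < config$canonical_prob
      )
      cds_list[[gi]] <- data.frame(
        transcript_id = tx_id, start = ex_start, end = ex_end
      )
    }
  }
  genes <- do.call(rbind, genes_list)
  # causal gene: a canonical gene on the non-PAR X
  on_x <- which(genes$chrom == config$x_chrom)
  if (length(on_x) == 0) stop("no gene could be placed on the X chromosome")
  causal <- sample(on_x, 1L)
  genes$canonical[causal] <- TRUE
  gm <- gene_models(genes, do.call(rbind, cds_list))

  ref <- Biostrings::DNAStringSet(vapply(seqs, rawToChar, character(1)))
  names(ref) <- chroms
  attr(ref, "non_n_lengths") <- non_n_lengths(ref)
  par <- GenomicRanges::GRanges(
    config$x_chrom,
    IRanges::IRanges(config$par_interval[1], config$par_interval[2])
  )
  list(
    ref = ref, genes = gm, causal_gene = genes$gene_id[causal],
    par = par, config = config
  )
}

.NONSTOP_CODONS <- {
  all64 <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0
  ))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Reverse complement of a DNA string
#' @param s character vector of DNA strings.
#' @export
revcomp <- function(s) {
  vapply(s, function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }, character(1), USE.NAMES = FALSE)
}

#' Draw indel lengths from the generator's length distribution
#'
#' Net length changes are categorical over `1..indel_max_len` with total
#' probability `indel_frac3` on multiples of 3 (in-frame events are
#' tolerated in coding sequence, so real coding indels are strongly
#' enriched for them) and exponential within-class decay
#' `exp(-len/indel_decay)`. Uses the current RNG state.
#'
#' @param n number of lengths to draw.
#' @param config a [generator_config()].
#' @return integer vector of lengths.
#' @export
draw_indel_lengths <- function(n, config = generator_config()) {
  lens <- seq_len(config$indel_max_len)
  is3 <- lens %% 3L == 0L
  wts <- exp(-lens / config$indel_decay)
  p <- numeric(length(lens))
  if (any(is3)) p[is3] <- config$indel_frac3 * wts[is3] / sum(wts[is3])
  if (any(!is3)) p[!is3] <- (1 - config$indel_frac3) * wts[!is3] / sum(wts[!is3])
  sample(lens, n, replace = TRUE, prob = p)
}

#' Generate a synthetic diploid cohort
#'
#' Produces the full bundle of inputs the analyses consume: a
#' [cohort_table()] of per-sample SNV/indel calls, per-window read depths,
#' chip genotypes, and truth tracks. Genotypes are drawn per site from
#' Hardy-Weinberg proportions at the site's true frequency; paralog-collapse
#' artifact sites inside duplicated regions force heterozygous calls in
#' duplication carriers (and PAR artifact sites in males, emulating masked-Y
#' read pile-up); per-variant and per-window depths are Poisson with rate
#' proportional to local copy number; low-depth heterozygotes may be
#' undercalled to homozygotes; chip genotypes copy the true genotypes with a
#' small error rate; male X genotypes outside the PAR are hemizygous. If
#' `config$causal_scenario` is set, the X-linked causal-gene scenario is
#' planted (see [plant_causal_scenario()]).
#'
#' @param config a [generator_config()].
#' @return An object of class `synthetic_cohort`: list with `cohort`
#'   ([cohort_table()]), `genes`, `ref`, `par`, `causal_gene`, `windows`
#'   (per-sample 2 kb window depths), `chip` (genotype-code matrix for chip
#'   sites), `truth` (CNV segments per sample, artifact site ids, planted
#'   variants, true frequencies) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_samp <- config$n_cases + config$n_controls
  if (n_samp == 0) stop("zero samples requested")
  if (config$n_snv + config$n_indel == 0) stop("zero sites requested")
  rb <- generate_reference(config) # seeds the RNG

  samples <- data.frame(
    sample_id = c(
      sprintf("case%02d", seq_len(config$n_cases)),
      sprintf("ctrl%02d", seq_len(config$n_controls))
    ),
    sex = c(config$case_sex, config$control_sex),
    phenotype = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    ancestry = c(config$case_ancestry, config$control_ancestry)
  )

  chroms <- names(config$chrom_lengths)
  lens <- as.integer(config$chrom_lengths)
  names(lens) <- chroms
  autosomes <- setdiff(chroms, config$x_chrom)
  chrom_str <- stats::setNames(as.character(rb$ref), names(rb$ref))

  ## --- population sites ------------------------------------------------
  n_sites <- config$n_snv + config$n_indel
  margin <- config$indel_max_len + 2L
  hi <- as.integer(floor(lens * (1 - config$n_gap_frac))) - margin
  pick <- as.vector(stats::rmultinom(1, n_sites, prob = pmax(hi - 1L, 0L)))
  # the designated causal gene is modeled as intolerant of standing
  # variation in its CDS (strong purifying selection): population sites are
  # not placed there, so planted variants are its only coding variants
  causal_tx <- rb$genes$genes$transcript_id[
    rb$genes$genes$gene_id == rb$causal_gene
  ]
  causal_cds <- rb$genes$cds[rb$genes$cds$transcript_id == causal_tx, ]
  excl <- unlist(lapply(seq_len(nrow(causal_cds)), function(e) {
    (causal_cds$start[e] - margin):(causal_cds$end[e] + margin)
  }))
  pos_list <- lapply(seq_along(chroms), function(i) {
    pool <- 2:hi[i]
    if (chroms[i] == config$x_chrom) pool <- setdiff(pool, excl)
    sort(sample(pool, pick[i], replace = FALSE))
  })
  site_chrom <- rep(chroms, pick)
  site_pos <- unlist(pos_list)
  is_snv <- rep(FALSE, n_sites)
  is_snv[sample.int(n_sites, config$n_snv)] <- TRUE

  ref_al <- alt_al <- character(n_sites)
  base_at <- function(chrom, pos) {
    substring(chrom_str[chrom], pos, pos)
  }
  # SNVs: transition with probability p_ts, else one of the two transversions
  sidx <- which(is_snv)
  rb1 <- base_at(site_chrom[sidx], site_pos[sidx])
  ts <- stats::runif(length(sidx)) < config$p_ts
  alt1 <- character(length(sidx))
  alt1[ts] <- .TRANSITION[rb1[ts]]
  if (any(!ts)) {
    tv_pick <- stats::runif(sum(!ts)) < 0.5
    tv_opts <- matrix(c(
      "C", "T", # A -> C/T
      "A", "G", # C -> A/G
      "C", "T", # G -> C/T
      "A", "G" # T -> A/G
    ), nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
    alt1[!ts] <- tv_opts[cbind(
      match(rb1[!ts], rownames(tv_opts)), ifelse(tv_pick, 1L, 2L)
    )]
  }
  ref_al[sidx] <- rb1
  alt_al[sidx] <- alt1
  # indels: anchored at the base before the event
  iidx <- which(!is_snv)
  ilen <- draw_indel_lengths(length(iidx), config)
  is_del <- stats::runif(length(iidx)) < 0.5
  anchor <- base_at(site_chrom[iidx], site_pos[iidx])
  ref_al[iidx] <- anchor
  alt_al[iidx] <- anchor
  del_i <- iidx[is_del]
  ref_al[del_i] <- substring(
    chrom_str[site_chrom[del_i]], site_pos[del_i], site_pos[del_i] + ilen[is_del]
  )
  ins_i <- iidx[!is_del]
  if (length(ins_i)) {
    ins_seq <- vapply(ilen[!is_del], function(L) {
      paste(sample(.BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    alt_al[ins_i] <- paste0(anchor[!is_del], ins_seq)
  }

  sf <- draw_site_freqs(
    n_sites,
    w = config$sfs_weight %||%
      solve_sfs_mixture(config$hom_het_target, config$q_min, config$ref_minor_q_range)$w,
    q_min = config$q_min, ref_minor_q_range = config$ref_minor_q_range
  )
  q <- sf$q
  known <- stats::runif(n_sites) <
    ifelse(is_snv, config$p_known_snv, config$p_known_indel)

  ## --- CNV truth: duplication categories and private deletions ---------
  win <- as.integer(config$cnv_window)
  windows_by_chrom <- lapply(chroms, function(cc) {
    n_win <- lens[[cc]] %/% win
    GenomicRanges::GRanges(
      cc, IRanges::IRanges(start = (seq_len(n_win) - 1L) * win + 1L, width = win)
    )
  })
  names(windows_by_chrom) <- chroms
  all_windows <- suppressWarnings(do.call(c, unname(windows_by_chrom)))

  draw_segments <- function(target_len, taken, chrom_pool = autosomes,
                            min_start = 1L) {
    segs <- GenomicRanges::GRanges()
    guard <- 0L
    pool_len <- lens[chrom_pool]
    while (sum(GenomicRanges::width(segs)) < target_len && guard < 10000L) {
      guard <- guard + 1L
      cc <- if (length(chrom_pool) == 1L) chrom_pool else
        sample(chrom_pool, 1L, prob = pool_len)
      n_win_c <- lens[[cc]] %/% win
      w_min <- (min_start - 1L) %/% win + 1L
      nw <- sample(config$dup_seg_windows[1]:config$dup_seg_windows[2], 1L)
      if (n_win_c - nw <= w_min) next
      w0 <- w_min + sample.int(n_win_c - nw - w_min + 1L, 1L) - 1L
      cand <- GenomicRanges::GRanges(
        cc, IRanges::IRanges((w0 - 1L) * win + 1L, width = nw * win)
      )
      if (length(GenomicRanges::findOverlaps(cand, taken)) == 0 &&
        length(GenomicRanges::findOverlaps(cand, segs)) == 0) {
        segs <- suppressWarnings(c(segs, cand))
      }
    }
    sort(segs)
  }
  auto_total <- sum(lens[autosomes])
  empty <- GenomicRanges::GRanges()
  seg_all <- draw_segments(config$dup_frac_all * auto_total, empty)
  seg_some <- draw_segments(config$dup_frac_some * auto_total, seg_all)
  # X regions duplicated in all samples (unmasked centromere-like repeats);
  # their collapse artifacts are the non-PAR source of male X het calls
  seg_x <- draw_segments(
    config$x_dup_frac * lens[[config$x_chrom]], empty,
    chrom_pool = config$x_chrom,
    min_start = as.integer(config$par_interval[2] + 1L)
  )
  # category-B carrier matrix: each sample carries a segment independently,
  # resampled so that no segment is carried by none or all samples
  carrier <- matrix(FALSE, length(seg_some), n_samp)
  for (i in seq_len(length(seg_some))) {
    repeat {
      v <- stats::runif(n_samp) < config$dup_some_carrier_prob
      if (any(v) && !all(v)) break
    }
    carrier[i, ] <- v
  }
  del_segs <- lapply(seq_len(n_samp), function(j) {
    draw_segments(
      config$deletion_frac * auto_total,
      suppressWarnings(c(seg_all, seg_some))
    )
  })

  ## --- site context ----------------------------------------------------
  site_gr <- GenomicRanges::GRanges(site_chrom, IRanges::IRanges(site_pos, site_pos))
  in_all_dup <- GenomicRanges::countOverlaps(site_gr, seg_all) > 0
  some_hit <- GenomicRanges::findOverlaps(site_gr, seg_some)
  some_seg_of_site <- rep(NA_integer_, n_sites)
  some_seg_of_site[S4Vectors::queryHits(some_hit)] <- S4Vectors::subjectHits(some_hit)
  in_x_dup <- GenomicRanges::countOverlaps(site_gr, seg_x) > 0
  on_x <- site_chrom == config$x_chrom
  in_par <- on_x & site_pos >= config$par_interval[1] & site_pos <= config$par_interval[2]
  male <- samples$sex == "M"

  artifact <- (in_all_dup | !is.na(some_seg_of_site) | in_x_dup) &
    stats::runif(n_sites) < config$artifact_rate
  par_artifact <- in_par & stats::runif(n_sites) < config$par_artifact_rate

  ## --- true genotypes --------------------------------------------------
  g_true <- matrix(
    stats::rbinom(n_sites * n_samp, 2L, rep(q, n_samp)),
    n_sites, n_samp
  )
  hemi_rows <- which(on_x & !in_par)
  if (length(hemi_rows)) {
    for (j in which(male)) {
      g_true[hemi_rows, j] <-
        3L * stats::rbinom(length(hemi_rows), 1L, q[hemi_rows])
    }
  }

  ## --- copy number per site x sample -----------------------------------
  copy <- matrix(2L, n_sites, n_samp)
  for (j in seq_len(n_samp)) {
    dup_j <- in_all_dup |
      (!is.na(some_seg_of_site) & carrier[cbind(pmax(some_seg_of_site, 1L), j)])
    dup_j[is.na(dup_j)] <- FALSE
    copy[dup_j, j] <- 3L
    in_del <- GenomicRanges::countOverlaps(site_gr, del_segs[[j]]) > 0
    copy[in_del, j] <- 1L
    if (male[j]) {
      copy[on_x & !in_par, j] <- 1L
      copy[in_x_dup, j] <- 2L
      copy[in_par, j] <- 3L # masked-Y PAR reads pile onto the X
    } else {
      copy[in_x_dup, j] <- 3L
    }
  }

  ## --- sequencing calls: artifacts, depth, undercall, missing ----------
  g_seq <- g_true
  for (j in seq_len(n_samp)) {
    # paralog-collapse sites: carriers of the duplication get het calls
    dup_art <- artifact & (copy[, j] == 3L | (male[j] & in_x_dup))
    g_seq[dup_art, j] <- 1L
    if (male[j]) g_seq[par_artifact, j] <- 1L
  }
  depth <- matrix(
    stats::rpois(n_sites * n_samp, config$mean_coverage * as.vector(copy) / 2),
    n_sites, n_samp
  )
  p_uc <- stats::plogis(config$undercall_a + config$undercall_b * depth)
  uc <- g_seq == 1L & matrix(stats::runif(n_sites * n_samp), n_sites, n_samp) < p_uc
  if (any(uc)) {
    g_seq[uc] <- sample(c(0L, 2L), sum(uc), replace = TRUE)
  }
  miss <- matrix(stats::runif(n_sites * n_samp), n_sites, n_samp) < config$missing_rate
  g_seq[miss] <- NA_integer_

  ## --- chip genotypes (diploid-coded truth + error) --------------------
  chip_site <- is_snv & stats::runif(n_sites) < config$chip_density
  chip <- g_true[chip_site, , drop = FALSE]
  chip[chip == 3L] <- 2L
  err <- matrix(stats::runif(length(chip)), nrow(chip)) < config$chip_error
  if (any(err)) {
    cur <- chip[err]
    shift <- sample.int(2L, length(cur), replace = TRUE)
    chip[err] <- (cur + shift) %% 3L
  }

  ## --- window depths ----------------------------------------------------
  win_tabs <- vector("list", n_samp)
  for (j in seq_len(n_samp)) {
    wcopy <- rep(2L, length(all_windows))
    wcopy[GenomicRanges::countOverlaps(all_windows, seg_all) > 0] <- 3L
    if (length(seg_some)) {
      sel <- GenomicRanges::countOverlaps(
        all_windows, seg_some[carrier[, j]]
      ) > 0
      wcopy[sel] <- 3L
    }
    wcopy[GenomicRanges::countOverlaps(all_windows, del_segs[[j]]) > 0] <- 1L
    wx <- as.character(GenomicRanges::seqnames(all_windows)) == config$x_chrom
    wpar <- wx & GenomicRanges::start(all_windows) <= config$par_interval[2]
    wxdup <- GenomicRanges::countOverlaps(all_windows, seg_x) > 0
    if (male[j]) {
      wcopy[wx & !wpar] <- 1L
      wcopy[wxdup] <- 2L
      wcopy[wpar] <- 3L
    } else {
      wcopy[wxdup] <- 3L
    }
    win_tabs[[j]] <- data.table::data.table(
      sample_id = samples$sample_id[j],
      chrom = as.character(GenomicRanges::seqnames(all_windows)),
      start = GenomicRanges::start(all_windows),
      end = GenomicRanges::end(all_windows),
      depth = stats::rpois(length(all_windows), config$mean_coverage * wcopy / 2)
    )
  }
  windows <- data.table::rbindlist(win_tabs)

  ## --- assemble emitted cohort (observed sites only) --------------------
  carrier_call <- g_seq %in% c(1L, 2L, 3L)
  dim(carrier_call) <- dim(g_seq)
  observed <- rowSums(carrier_call, na.rm = TRUE) > 0
  sites <- data.frame(
    chrom = site_chrom, pos = site_pos, ref = ref_al, alt = alt_al,
    known = known
  )
  keys <- site_key(site_chrom, site_pos, ref_al, alt_al)
  chip_keys <- keys[chip_site]
  rownames(chip) <- chip_keys
  colnames(chip) <- samples$sample_id

  cohort <- cohort_table(
    samples = samples,
    sites = sites[observed, , drop = FALSE],
    geno = g_seq[observed, , drop = FALSE],
    depth = depth[observed, , drop = FALSE]
  )

  cnv_truth <- lapply(seq_len(n_samp), function(j) {
    dup <- suppressWarnings(c(
      seg_all, seg_x,
      if (length(seg_some)) seg_some[carrier[, j]] else empty
    ))
    if (length(dup)) dup$state <- "duplication"
    del <- del_segs[[j]]
    if (length(del)) del$state <- "deletion"
    sort(suppressWarnings(c(dup, del)))
  })
  names(cnv_truth) <- samples$sample_id

  truth <- list(
    population_sites = data.table::data.table(
      site_id = keys, chrom = site_chrom, pos = site_pos,
      ref = ref_al, alt = alt_al,
      kind = variant_kind(ref_al, alt_al),
      known = known, q = q, artifact = artifact,
      par_artifact = par_artifact, observed = observed
    ),
    cnv = cnv_truth,
    dup_all_segments = seg_all,
    dup_some_segments = seg_some,
    x_dup_segments = seg_x,
    dup_some_carriers = carrier,
    artifact_sites = keys[artifact],
    par_artifact_sites = keys[par_artifact],
    q = stats::setNames(q, keys),
    ref_minor_sites = keys[sf$ref_minor],
    planted = NULL
  )

  out <- structure(
    list(
      cohort = cohort, genes = rb$genes, ref = rb$ref, par = rb$par,
      causal_gene = rb$causal_gene, windows = windows, chip = chip,
      truth = truth, config = config,
      sfs_weight = config$sfs_weight %||%
        solve_sfs_mixture(config$hom_het_target, config$q_min, config$ref_minor_q_range)$w
    ),
    class = "synthetic_cohort"
  )
  if (config$causal_scenario) out <- plant_causal_scenario(out, config)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  print(x$cohort)
  cat(sprintf(
    "  causal gene: %s (%s); %d chip sites; %d window-depth rows\n",
    x$causal_gene,
    if (is.null(x$truth$planted)) "no planted scenario" else "scenario planted",
    nrow(x$chip), nrow(x$windows)
  ))
  invisible(x)
}
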