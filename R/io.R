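#' Read a reference FASTA
#'
#' Sequences are uppercased and checked for duplicate chromosome names.
#' Gaps (`N` runs) are excluded from the usable genome length: the per
#' chromosome non-N length is the denominator used for coverage and
#' genomic-length-fraction reporting.
#'
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet` with a `non_n_lengths` attribute
#'   (named integer vector).
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  if (length(ref) == 0) stop("empty FASTA: ", path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (anyDuplicated(names(ref))) {
    stop("duplicate chromosome names in ", path)
  }
  ref <- Biostrings::DNAStringSet(toupper(ref))
  attr(ref, "non_n_lengths") <- non_n_lengths(ref)
  ref
}

#' @rdname read_reference
#' @param ref a `DNAStringSet`.
#' @return `non_n_lengths()`: named integer vector of non-N lengths.
#' @export
non_n_lengths <- function(ref) {
  n <- Biostrings::letterFrequency(ref, "N")[, 1]
  stats::setNames(Biostrings::width(ref) - as.integer(n), names(ref))
}

#' @rdname read_reference
#' @export
write_reference <- function(ref, path) {
  Biostrings::writeXStringSet(ref, path, width = 70L)
  invisible(path)
}

#' Read a cohort VCF
#'
#' Reads VCF 4.x (via `vcfR`) into a [cohort_table()]. Multi-allelic
#' records are split into bi-allelic site keys, with each split genotype
#' counting copies of its own alternate allele. Haploid genotypes (`1`)
#' become hemizygous-alternate calls; `./.` stays an explicit missing call.
#' The known-variant flag is taken from the `KNOWN` INFO tag.
#'
#' @param path VCF file (with `GT` and optionally `DP`, `GQ` FORMAT
#'   fields).
#' @param sample_metadata optional data.frame (`sample_id`, `sex`,
#'   `phenotype`, optionally `ancestry`); must match the VCF sample
#'   columns. When absent, all samples are labelled sex `"F"`, phenotype
#'   `"control"`.
#' @return A [cohort_table()].
#' @export
read_vcf <- function(path, sample_metadata = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vcf_samples <- colnames(v@gt)[-1]
  if (is.null(sample_metadata)) {
    sample_metadata <- data.frame(
      sample_id = vcf_samples, sex = "F", phenotype = "control"
    )
  }
  if (!setequal(sample_metadata$sample_id, vcf_samples) ||
    length(sample_metadata$sample_id) != length(vcf_samples)) {
    stop(
      "sample metadata does not match VCF samples (",
      paste(vcf_samples, collapse = ","), ")"
    )
  }
  sample_metadata <- sample_metadata[match(vcf_samples, sample_metadata$sample_id), ]

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  if (is.null(dp) || is.null(dim(dp))) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  if (is.null(gq) || is.null(dim(gq))) gq <- matrix(NA_real_, nrow(gt), ncol(gt))

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_field <- fix[, "ALT"]
  info <- fix[, "INFO"]
  known <- grepl("(^|;)KNOWN(=1)?(;|$)", info)
  bad <- which(is.na(pos) | is.na(ref) | ref == "" | is.na(alt_field) | alt_field == "")
  if (length(bad)) {
    stop("malformed VCF record at data line ", bad[1], " of ", path)
  }

  alt_list <- strsplit(alt_field, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec <- rep(seq_along(pos), n_alt) # source record per output site
  alt_idx <- unlist(lapply(n_alt, seq_len))
  ns <- length(rec)
  nk <- length(vcf_samples)
  # fast path: bi-allelic diploid/haploid genotype strings
  fast_map <- c(
    "0/0" = GT_HOM_REF, "0|0" = GT_HOM_REF,
    "0/1" = GT_HET, "1/0" = GT_HET, "0|1" = GT_HET, "1|0" = GT_HET,
    "1/1" = GT_HOM_ALT, "1|1" = GT_HOM_ALT,
    "1" = GT_HEMI_ALT, "0" = GT_HOM_REF
  )
  gtm <- gt[rec, , drop = FALSE]
  geno <- matrix(fast_map[gtm], ns, nk)
  geno[n_alt[rec] > 1L, ] <- NA_integer_ # multi-allelic: general remap below
  slow <- which(is.na(geno) & !is.na(gtm) & !gtm %in% c(".", "./.", ".|."))
  for (idx in slow) {
    i <- (idx - 1L) %% ns + 1L
    j <- (idx - 1L) %/% ns + 1L
    a <- strsplit(gt[rec[i], j], "[/|]")[[1]]
    if (length(a) == 0 || any(a %in% c(".", ""))) next
    copies <- sum(a == as.character(alt_idx[i]))
    geno[i, j] <- if (length(a) == 1L) {
      if (copies >= 1L) GT_HEMI_ALT else GT_HOM_REF
    } else if (copies > 2L) {
      GT_HOM_ALT
    } else {
      c(GT_HOM_REF, GT_HET, GT_HOM_ALT)[copies + 1L]
    }
  }
  depth <- matrix(as.integer(round(dp[rec, , drop = FALSE])), ns, nk)
  depth[is.na(depth)] <- 0L
  qual <- matrix(gq[rec, , drop = FALSE], ns, nk)
  qual[is.na(qual)] <- 1

  cohort_table(
    samples = sample_metadata,
    sites = data.frame(
      chrom = chrom[rec], pos = pos[rec], ref = ref[rec],
      alt = unlist(alt_list), known = known[rec]
    ),
    geno = geno, depth = depth, qual = qual
  )
}

#' Write a cohort table as VCF
#'
#' Inverse of [read_vcf()]: genotype, depth, quality and known flag all
#' round-trip. Hemizygous-alternate calls are written as haploid `1`,
#' missing as `./.`; the known flag as INFO `KNOWN=1`.
#'
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @export
write_vcf <- function(cohort, path) {
  s <- cohort$sites
  gt_str <- matrix("./.", nrow(s), nrow(cohort$samples))
  gt_str[which(cohort$geno == GT_HOM_REF)] <- "0/0"
  gt_str[which(cohort$geno == GT_HET)] <- "0/1"
  gt_str[which(cohort$geno == GT_HOM_ALT)] <- "1/1"
  gt_str[which(cohort$geno == GT_HEMI_ALT)] <- "1"
  dp <- cohort$depth
  gq <- round(cohort$qual)
  body <- if (nrow(s)) {
    cols <- vapply(seq_len(ncol(gt_str)), function(j) {
      paste(gt_str[, j], dp[, j], gq[, j], sep = ":")
    }, character(nrow(s)))
    cols <- matrix(cols, nrow = nrow(s))
    paste(
      s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS",
      ifelse(s$known, "KNOWN=1", "."), "GT:DP:GQ",
      apply(cols, 1, paste, collapse = "\t"),
      sep = "\t"
    )
  } else {
    character(0)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lofcohort",
    "##INFO=<ID=KNOWN,Number=1,Type=Integer,Description=\"Present in the known-variant list\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", cohort$samples$sample_id
    ), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' BED interval I/O
#'
#' Thin wrappers over `rtracklayer` converting between 0-based half-open
#' BED records on disk and the 1-based closed `GRanges` used internally;
#' the conversion round-trips losslessly.
#'
#' @param path BED file.
#' @return `read_bed()`: a `GRanges`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  GenomicRanges::granges(gr, use.mcols = TRUE)
}

#' @rdname read_bed
#' @param gr a `GRanges`.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  extra <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(extra)) {
    df$name <- extra$name
  } else if ("state" %in% names(extra)) {
    df$name <- extra$state
  }
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Chip genotype and window depth TSV I/O
#'
#' Chip genotypes are a site-by-sample TSV of genotype labels (first column
#' `site_id`); window depths a long TSV with columns `sample_id`, `chrom`,
#' `start`, `end`, `depth` (1-based closed windows).
#'
#' @param x chip genotype matrix (site x sample, genotype labels or codes)
#'   or window-depth data.frame.
#' @param path file path.
#' @export
write_chip_tsv <- function(x, path) {
  stopifnot(is.matrix(x))
  lab <- if (is.numeric(x)) matrix(gt_label(x), nrow(x), dimnames = dimnames(x)) else x
  df <- data.frame(site_id = rownames(lab), lab, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chip_tsv
#' @return `read_chip_tsv()`: integer genotype-code matrix with site_id
#'   rownames.
#' @export
read_chip_tsv <- function(path) {
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, check.names = FALSE,
    colClasses = "character"
  )
  m <- as.matrix(df[, -1, drop = FALSE])
  out <- matrix(gt_code(m), nrow(m), dimnames = list(df$site_id, colnames(m)))
  out
}

#' @rdname write_chip_tsv
#' @export
write_window_depths <- function(x, path) {
  stopifnot(all(c("sample_id", "chrom", "start", "end", "depth") %in% names(x)))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chip_tsv
#' @export
read_window_depths <- function(path) {
  data.table::fread(path, sep = "\t")
}
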