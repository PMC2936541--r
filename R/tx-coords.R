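# Transcript-space coordinate helpers shared by the annotation core and the
# causal-scenario planting.

# Genomic positions of a transcript's CDS bases in transcription order
# (1-based; descending genomic positions for minus-strand transcripts).
tx_positions <- function(gm, tx) {
  cds <- gm$cds[gm$cds$transcript_id == tx, ]
  cds <- cds[order(cds$exon_rank), ]
  j <- match(tx, gm$genes$transcript_id)
  strand <- gm$genes$strand[j]
  pos <- unlist(lapply(seq_len(nrow(cds)), function(e) {
    if (strand == "+") cds$start[e]:cds$end[e] else cds$end[e]:cds$start[e]
  }))
  as.integer(pos)
}

# Coding index (1..cds_len, transcription order) of a genomic position, or
# NA if the position is not in the transcript's CDS.
coding_index <- function(gm, tx, genomic_pos) {
  txp <- tx_positions(gm, tx)
  match(genomic_pos, txp)
}

# The CDS nucleotide sequence of a transcript in transcript orientation.
tx_cds_seq <- function(gm, tx, ref) {
  j <- match(tx, gm$genes$transcript_id)
  chrom <- gm$genes$chrom[j]
  strand <- gm$genes$strand[j]
  txp <- tx_positions(gm, tx)
  s <- as.character(ref[[chrom]])
  bases <- substring(s, txp, txp)
  seqstr <- paste(bases, collapse = "")
  if (strand == "-") seqstr <- chartr("ACGT", "TGCA", seqstr)
  seqstr
}

# Translate a nucleotide string (length divisible by 3) with the standard
# genetic code; returns a vector of single-letter amino acids ("*" = stop).
translate_codons <- function(ntseq) {
  n <- nchar(ntseq) %/% 3L
  starts <- (seq_len(n) - 1L) * 3L + 1L
  codons <- substring(ntseq, starts, starts + 2L)
  unname(Biostrings::GENETIC_CODE[codons])
}
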