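#' Load a reference annotation and genome
#'
#' Reads a GTF (exon and UTR features) and a genome FASTA into a single
#' annotation object used by junction classification and transcript
#' engineering. Exons are ordered 5' to 3' within each transcript;
#' minus-strand transcript sequences are reverse-complemented on access.
#'
#' @param gtf_path GTF file with `exon` features carrying `transcript_id`
#'   and `gene_id` attributes; `UTR` / `five_prime_utr` /
#'   `three_prime_utr` features are captured when present.
#' @param fasta_path Genome FASTA indexed by chromosome name (first token
#'   of each header).
#' @return An object of class `genome_annotation`: a list with
#'   `transcripts` (one row per transcript, with a `has_utr` flag),
#'   `exons` (with transcriptional `rank`), `introns` (one row per
#'   annotated intron) and `genome` (a `DNAStringSet`).
#' @export
read_annotation <- function(gtf_path, fasta_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  df <- data.frame(
    type   = as.character(gr$type),
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr),
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    gene_name = if (!is.null(gr$gene_name)) as.character(gr$gene_name)
                else as.character(gr$gene_id),
    stringsAsFactors = FALSE
  )
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("annotation has no exon features")
  if (any(is.na(ex$transcript_id)))
    stop("exon feature without transcript_id")
  missing_chr <- setdiff(unique(ex$chrom), names(genome))
  if (length(missing_chr))
    stop("exon references chromosome absent from genome FASTA: ",
         missing_chr[1])

  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  # transcriptional rank: ascending genomic order on +, descending on -
  rank <- unlist(lapply(split(seq_len(nrow(ex)), ex$transcript_id),
                        function(i) {
    n <- length(i)
    if (ex$strand[i[1]] == "-") rev(seq_len(n)) else seq_len(n)
  }), use.names = FALSE)
  ex$rank <- NA_integer_
  ex$rank[order(ex$transcript_id, ex$start)] <- rank
  ex <- ex[order(ex$transcript_id, ex$rank), , drop = FALSE]
  rownames(ex) <- NULL

  # overlapping exons within one transcript are malformed input
  by_tx <- split(ex, ex$transcript_id)
  for (tx in by_tx) {
    s <- tx[order(tx$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping exons in transcript ", tx$transcript_id[1])
  }

  utr <- df[df$type %in% c("UTR", "five_prime_utr", "three_prime_utr"),
            , drop = FALSE]
  tx_first <- ex[!duplicated(ex$transcript_id), , drop = FALSE]
  transcripts <- data.frame(
    transcript_id = tx_first$transcript_id,
    gene_id   = tx_first$gene_id,
    gene_name = tx_first$gene_name,
    chrom     = tx_first$chrom,
    strand    = tx_first$strand,
    has_utr   = tx_first$transcript_id %in% utr$transcript_id,
    stringsAsFactors = FALSE
  )
  rownames(transcripts) <- NULL

  introns <- annotation_introns(ex)
  ann <- list(transcripts = transcripts, exons = ex[, c(
    "transcript_id", "gene_id", "chrom", "start", "end", "strand", "rank")],
    utrs = utr, introns = introns, genome = genome)
  class(ann) <- "genome_annotation"
  ann
}

# one row per annotated intron (gap between genomically adjacent exons of
# a transcript); intron coordinates 1-based closed
annotation_introns <- function(ex) {
  parts <- lapply(split(ex, ex$transcript_id), function(tx) {
    if (nrow(tx) < 2L) return(NULL)
    s <- tx[order(tx$start), , drop = FALSE]
    data.frame(
      transcript_id = s$transcript_id[-1],
      gene_id = s$gene_id[-1],
      chrom  = s$chrom[-1],
      intron_start = s$end[-nrow(s)] + 1L,
      intron_end   = s$start[-1] - 1L,
      strand = s$strand[-1],
      stringsAsFactors = FALSE
    )
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons,", nrow(x$introns), "annotated introns,",
      length(x$genome), "sequences\n")
  n_utr <- sum(x$transcripts$has_utr)
  if (n_utr == 0L) cat("  (no annotated UTRs)\n")
  invisible(x)
}

tx_exons <- function(ann, tx_id) {
  ex <- ann$exons[ann$exons$transcript_id == tx_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown transcript: ", tx_id)
  ex[order(ex$rank), , drop = FALSE]
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences of a transcript in transcriptional
#' order; minus-strand transcripts are reverse-complemented, so the
#' returned string always reads 5' to 3'.
#'
#' @param ann A `genome_annotation`.
#' @param tx_id Transcript identifier.
#' @return Character scalar nucleotide sequence.
#' @export
transcript_seq <- function(ann, tx_id) {
  ex <- tx_exons(ann, tx_id)
  s <- ex[order(ex$start), , drop = FALSE]
  chrom <- ann$genome[[s$chrom[1]]]
  pieces <- Biostrings::extractAt(
    chrom, IRanges::IRanges(start = s$start, end = s$end))
  seq <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (s$strand[1] == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}

# map a genomic base position to its 1-based transcript coordinate, or NA
# if the position is intronic / outside the transcript
genomic_to_tx <- function(ann, tx_id, pos) {
  ex <- tx_exons(ann, tx_id)  # transcriptional order
  offset <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex$end[i] - ex$start[i] + 1L
    if (pos >= ex$start[i] && pos <= ex$end[i]) {
      within <- if (ex$strand[i] == "-") ex$end[i] - pos else pos - ex$start[i]
      return(offset + within + 1L)
    }
    offset <- offset + w
  }
  NA_integer_
}
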