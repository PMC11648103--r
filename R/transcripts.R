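#' Select flanking transcript pairs for a junction
#'
#' The upstream flank of a junction is the last transcribed base before
#' the intron and the downstream flank the first transcribed base after
#' it. A transcript is an upstream (downstream) candidate when one of its
#' exons contains that base; the containing exon is the flanking exon.
#' All upstream x downstream combinations are formed, then pruned:
#' \itemize{
#'   \item annotated junctions keep only pairs where upstream and
#'     downstream transcript are the same and the flanking exons are
#'     directly consecutive in it;
#'   \item unannotated junctions keep all pairs, unless some pair has
#'     directly adjacent flanking exons, in which case only such pairs
#'     survive.
#' }
#'
#' @param junction One-row junction data.frame with a `classification`
#'   column (see [classify_junctions()]).
#' @param ann A `genome_annotation`.
#' @return data.frame of pairs: `up_tx`, `down_tx`, `up_exon_rank`,
#'   `down_exon_rank`, `adjacent`. Zero rows (with attribute `reason`)
#'   when no flank exists on one side.
#' @export
select_flanking_pairs <- function(junction, ann) {
  stopifnot(nrow(junction) == 1L)
  s <- junction$intron_start
  e <- junction$intron_end
  plus <- junction$strand == "+"
  up_base   <- if (plus) s - 1L else e + 1L
  down_base <- if (plus) e + 1L else s - 1L

  ex <- ann$exons[ann$exons$chrom == junction$chrom &
                  ann$exons$strand == junction$strand, , drop = FALSE]
  up_hits <- ex[ex$start <= up_base & ex$end >= up_base, , drop = FALSE]
  down_hits <- ex[ex$start <= down_base & ex$end >= down_base, , drop = FALSE]

  empty <- data.frame(up_tx = character(), down_tx = character(),
                      up_exon_rank = integer(), down_exon_rank = integer(),
                      adjacent = logical(), stringsAsFactors = FALSE)
  if (nrow(up_hits) == 0L || nrow(down_hits) == 0L) {
    attr(empty, "reason") <- if (nrow(up_hits) == 0L)
      "no flanking exon on upstream side" else
      "no flanking exon on downstream side"
    return(empty)
  }
  pairs <- expand.grid(u = seq_len(nrow(up_hits)),
                       d = seq_len(nrow(down_hits)))
  out <- data.frame(
    up_tx = up_hits$transcript_id[pairs$u],
    down_tx = down_hits$transcript_id[pairs$d],
    up_exon_rank = up_hits$rank[pairs$u],
    down_exon_rank = down_hits$rank[pairs$d],
    stringsAsFactors = FALSE
  )
  out$adjacent <- out$up_tx == out$down_tx &
    out$down_exon_rank == out$up_exon_rank + 1L

  if (identical(junction$classification, "annotated")) {
    out <- out[out$adjacent, , drop = FALSE]
  } else if (any(out$adjacent)) {
    out <- out[out$adjacent, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Fuse a flanking transcript pair at a junction
#'
#' The full spliced upstream transcript is truncated at the junction
#' donor and concatenated with the full spliced downstream transcript
#' starting at the acceptor. The joined product is flagged protein-coding
#' when both flanking transcripts carry annotated UTRs; coding products
#' are ORF-scanned and translated.
#'
#' @param pair One row of [select_flanking_pairs()] output (or a list
#'   with `up_tx` / `down_tx`).
#' @param junction One-row junction data.frame.
#' @param ann A `genome_annotation`.
#' @return A list of class `joined_transcript`: `junction` (key),
#'   `up_tx`, `down_tx`, `seq`, `coding`, `orf` (list with `start`,
#'   `end`, `seq`, or NULL), `protein` (or NA), `modification` (text log).
#' @export
join_transcripts <- function(pair, junction, ann) {
  stopifnot(nrow(junction) == 1L)
  plus <- junction$strand == "+"
  up_base   <- if (plus) junction$intron_start - 1L else junction$intron_end + 1L
  down_base <- if (plus) junction$intron_end + 1L else junction$intron_start - 1L

  p_u <- genomic_to_tx(ann, pair$up_tx, up_base)
  p_d <- genomic_to_tx(ann, pair$down_tx, down_base)
  if (is.na(p_u))
    stop("donor boundary falls outside the exons of ", pair$up_tx)
  if (is.na(p_d))
    stop("acceptor boundary falls outside the exons of ", pair$down_tx)

  up_seq <- transcript_seq(ann, pair$up_tx)
  down_seq <- transcript_seq(ann, pair$down_tx)
  fused <- paste0(substr(up_seq, 1L, p_u),
                  substring(down_seq, p_d))

  tx <- ann$transcripts
  coding <- tx$has_utr[tx$transcript_id == pair$up_tx] &&
            tx$has_utr[tx$transcript_id == pair$down_tx]

  orf <- NULL
  protein <- NA_character_
  modification <- if (coding) "coding: both flanks carry annotated UTRs"
                  else "noncoding: a flank lacks annotated UTRs"
  if (coding) {
    orf <- find_orf(fused)
    if (is.null(orf)) {
      modification <- paste0(modification, "; no complete ORF found")
    } else {
      protein <- translate_orf(orf$seq)
      ref_orf <- find_orf(up_seq)
      same <- !is.null(ref_orf) && identical(ref_orf$seq, orf$seq)
      modification <- paste0(
        modification, "; ORF at ", orf$start, "-", orf$end,
        if (same) "; ORF identical to upstream flank"
        else "; ORF differs from upstream flank")
    }
  }
  structure(list(
    junction = junction_key(junction),
    up_tx = pair$up_tx, down_tx = pair$down_tx,
    seq = fused, coding = coding, orf = orf, protein = protein,
    modification = modification
  ), class = "joined_transcript")
}

#' @export
print.joined_transcript <- function(x, ...) {
  cat("joined_transcript", x$junction, "\n")
  cat("  ", x$up_tx, "->", x$down_tx, "|", nchar(x$seq), "nt |",
      if (x$coding) "coding" else "noncoding", "\n")
  if (!is.null(x$orf))
    cat("   ORF", x$orf$start, "-", x$orf$end, "->",
        nchar(x$protein), "aa\n")
  invisible(x)
}

#' Find the first complete open reading frame
#'
#' Scans 5' to 3' for the first ATG and extends in that frame to the
#' first stop codon. Sequences without an ATG, or whose first ATG never
#' reaches an in-frame stop, have no ORF (NULL).
#'
#' @param seq Uppercase A/C/G/T/N nucleotide string.
#' @return NULL, or a list with `start` and `end` (1-based offsets of the
#'   ORF including the stop codon) and `seq` (the ORF nucleotides).
#' @export
find_orf <- function(seq) {
  n <- nchar(seq)
  start <- regexpr("ATG", seq, fixed = TRUE)
  if (start < 0L) return(NULL)
  pos <- as.integer(start)
  j <- pos
  repeat {
    if (j + 2L > n) return(NULL)  # ran off the end without a stop
    codon <- substr(seq, j, j + 2L)
    if (codon %in% c("TAA", "TAG", "TGA")) {
      return(list(start = pos, end = j + 2L,
                  seq = substr(seq, pos, j + 2L)))
    }
    j <- j + 3L
  }
}

# standard genetic code, indexed by codon
codon_table <- local({
  std <- c(
    TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
    ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
    TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
    ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
    TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
    AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
    TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
    AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  std
})

#' Translate an ORF with the standard genetic code
#'
#' @param orf_seq Nucleotide string: length divisible by 3, starting with
#'   ATG and ending with a stop codon. The terminal stop is dropped; an
#'   internal stop is an error. Codons containing N translate to X.
#' @return Amino-acid string.
#' @export
translate_orf <- function(orf_seq) {
  n <- nchar(orf_seq)
  if (n %% 3L != 0L) stop("ORF length not divisible by 3")
  if (substr(orf_seq, 1L, 3L) != "ATG") stop("ORF must start with ATG")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(orf_seq, starts, starts + 2L)
  last <- codons[length(codons)]
  if (!last %in% c("TAA", "TAG", "TGA"))
    stop("ORF must end with a stop codon")
  codons <- codons[-length(codons)]
  aa <- unname(codon_table[codons])
  aa[is.na(aa)] <- "X"  # any codon containing N (or other ambiguity)
  if (any(aa == "*")) stop("internal stop codon in ORF")
  paste(aa, collapse = "")
}

#' Build all joined transcripts for a set of junctions
#'
#' Convenience driver: for each junction, selects flanking pairs
#' (optionally capped) and fuses each pair.
#'
#' @param junctions Classified junction data.frame.
#' @param ann A `genome_annotation`.
#' @param max_pairs Cap on pairs per junction (default Inf); truncation
#'   is recorded in the returned attribute `truncated`.
#' @return List of `joined_transcript` objects; junctions with no viable
#'   flanking pair contribute nothing.
#' @export
build_transcripts <- function(junctions, ann, max_pairs = Inf) {
  out <- list()
  truncated <- character()
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, , drop = FALSE]
    pairs <- select_flanking_pairs(j, ann)
    if (nrow(pairs) > max_pairs) {
      truncated <- c(truncated, junction_key(j))
      pairs <- pairs[seq_len(max_pairs), , drop = FALSE]
    }
    for (k in seq_len(nrow(pairs))) {
      out[[length(out) + 1L]] <-
        join_transcripts(pairs[k, , drop = FALSE], j, ann)
    }
  }
  attr(out, "truncated") <- truncated
  out
}
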