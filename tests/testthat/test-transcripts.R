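local_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- write_toy_annotation()
      cache <<- list(toy = toy, ann = read_annotation(toy$gtf, toy$fasta))
    }
    cache
  }
})

classified <- function(j, ann) classify_junctions(j, ann)

test_that("annotated junctions keep only same-transcript adjacent pairs", {
  ann <- local_toy()$ann
  j <- classified(toy_junction("chrT", 201, 300, "+"), ann)
  pairs <- select_flanking_pairs(j, ann)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$up_tx, "T1")
  expect_equal(pairs$down_tx, "T1")
  expect_true(pairs$adjacent)

  # the skip intron is annotated in T2 but non-consecutive in T1
  j2 <- classified(toy_junction("chrT", 201, 500, "+"), ann)
  pairs2 <- select_flanking_pairs(j2, ann)
  expect_equal(nrow(pairs2), 1L)
  expect_equal(unique(c(pairs2$up_tx, pairs2$down_tx)), "T2")
})

test_that("unannotated junctions form cross products unless a pair is adjacent", {
  ann <- local_toy()$ann
  # donor mid-exon1 (shared by T1, T2) to mid-exon2 of T4: no adjacency
  j <- classified(toy_junction("chrT", 150, 910, "+"), ann)
  pairs <- select_flanking_pairs(j, ann)
  expect_equal(nrow(pairs), 2L)   # {T1,T2} x {T4}
  expect_setequal(pairs$up_tx, c("T1", "T2"))
  expect_false(any(pairs$adjacent))

  # within T1, exon1 -> mid-exon2 has an adjacent pair, which wins
  j2 <- classified(toy_junction("chrT", 201, 310, "+"), ann)
  pairs2 <- select_flanking_pairs(j2, ann)
  expect_true(all(pairs2$adjacent))
  expect_true(all(pairs2$up_tx == pairs2$down_tx))

  # acceptor deep inside an intron: no downstream flanking exon
  j3 <- classified(toy_junction("chrT", 201, 250, "+"), ann)
  pairs3 <- select_flanking_pairs(j3, ann)
  expect_equal(nrow(pairs3), 0L)
  expect_match(attr(pairs3, "reason"), "downstream")
})

test_that("joining an annotated junction reconstructs the transcript", {
  ann <- local_toy()$ann
  j <- classified(toy_junction("chrT", 201, 300, "+"), ann)
  pairs <- select_flanking_pairs(j, ann)
  jt <- join_transcripts(pairs[1, ], j, ann)
  expect_identical(jt$seq, transcript_seq(ann, "T1"))
  expect_true(jt$coding)

  # minus strand: annotated intron of T3 reconstructs T3
  j3 <- classified(toy_junction("chrT", 1201, 1300, "-", motif = 2), ann)
  p3 <- select_flanking_pairs(j3, ann)
  jt3 <- join_transcripts(p3[1, ], j3, ann)
  expect_identical(jt3$seq, transcript_seq(ann, "T3"))
})

test_that("mid-exon donors shorten the fusion by the skipped exon tail", {
  ann <- local_toy()$ann
  j <- classified(toy_junction("chrT", 150, 300, "+"), ann)
  pairs <- select_flanking_pairs(j, ann)
  pairs <- pairs[pairs$up_tx == "T1" & pairs$down_tx == "T1", , drop = FALSE]
  jt <- join_transcripts(pairs[1, ], j, ann)
  # prefix 101..149 (49 nt) + T1 minus its first exon (200 nt)
  expect_equal(nchar(jt$seq), 49L + 200L)
  expect_identical(jt$seq, paste0(substr(transcript_seq(ann, "T1"), 1, 49),
                                  substr(transcript_seq(ann, "T1"), 101, 300)))
})

test_that("concatenation conserves length for every fixture junction", {
  sc <- shared_cohort()
  ann <- read_annotation(sc$cohort$paths$gtf, sc$cohort$paths$genome)
  tj <- sc$cohort$truth_junctions
  tj <- tj[tj$motif != 0, ]
  cls <- classify_junctions(
    cbind(tj[, c("chrom", "intron_start", "intron_end", "strand",
                 "motif")],
          unique_reads = 5L, multi_reads = 0L), ann)
  for (i in seq_len(nrow(cls))) {
    j <- cls[i, , drop = FALSE]
    pairs <- select_flanking_pairs(j, ann)
    if (nrow(pairs) == 0L) next
    jt <- join_transcripts(pairs[1, ], j, ann)
    up <- transcript_seq(ann, pairs$up_tx[1])
    down <- transcript_seq(ann, pairs$down_tx[1])
    expect_true(nchar(jt$seq) <= nchar(up) + nchar(down))
    expect_true(startsWith(up, substr(jt$seq, 1, 10)))
  }
})

test_that("a flank without annotated UTRs makes the product noncoding", {
  ann <- local_toy()$ann
  j <- classified(toy_junction("chrT", 150, 910, "+"), ann)
  pairs <- select_flanking_pairs(j, ann)
  p <- pairs[pairs$up_tx == "T1", , drop = FALSE]   # T4 lacks UTRs
  jt <- join_transcripts(p[1, ], j, ann)
  expect_false(jt$coding)
  expect_true(is.null(jt$orf))
  expect_match(jt$modification, "noncoding")
})

test_that("ORF finding follows the first-start-first-stop rule", {
  expect_equal(find_orf("GGGATGAAATAGGG")$seq, "ATGAAATAG")
  expect_null(find_orf("CCCCCC"))
  # an ORF without an in-frame stop is treated as absent
  expect_null(find_orf("ATGAAACCC"))
  # the first ATG fixes the frame even if a later ATG would find a stop
  expect_null(find_orf("ATGAAAAATGTAA"))
  orf <- find_orf("TTATGCCCTGAXX")
  expect_equal(orf$start, 3L)
  expect_equal(orf$end, 11L)
})

test_that("ORF finder agrees with the exhaustive scan oracle", {
  set.seed(77)
  for (i in 1:1000) {
    s <- random_dna(sample(30:600, 1))
    got <- find_orf(s)
    want <- oracle_orf(s)
    expect_identical(got, want)
  }
})

test_that("translation matches the standard code", {
  expect_equal(translate_orf("ATGAAATAG"), "MK")
  expect_equal(translate_orf("ATGTAA"), "M")
  expect_equal(translate_orf("ATGNNNTGA"), "MX")
  expect_error(translate_orf("ATGAAA"), "stop")
  expect_error(translate_orf("ATGAA"), "divisible")
  expect_error(translate_orf("ATGTAATAA"), "internal stop")
})

test_that("translation agrees with an independent codon-table oracle", {
  set.seed(99)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  for (i in 1:25) {
    body <- sample(sense, 99, replace = TRUE)
    orf <- paste0("ATG", paste(body, collapse = ""), "TAA")
    got <- translate_orf(orf)
    want <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(orf, 1, nchar(orf) - 3))))
    expect_identical(got, want)
  }
})

test_that("self-reconstruction holds for every annotated fixture junction", {
  sc <- shared_cohort()
  ann <- read_annotation(sc$cohort$paths$gtf, sc$cohort$paths$genome)
  tj <- sc$cohort$truth_junctions
  ann_j <- tj[tj$truth_class == "annotated", ]
  for (i in seq_len(nrow(ann_j))) {
    j <- classify_junctions(
      cbind(ann_j[i, c("chrom", "intron_start", "intron_end", "strand",
                       "motif")],
            unique_reads = 5L, multi_reads = 0L), ann)
    pairs <- select_flanking_pairs(j, ann)
    expect_gt(nrow(pairs), 0)
    jt <- join_transcripts(pairs[1, ], j, ann)
    ref <- transcript_seq(ann, pairs$up_tx[1])
    expect_identical(jt$seq, ref)
    ref_orf <- find_orf(ref)
    expect_identical(jt$protein, translate_orf(ref_orf$seq))
  }
})
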