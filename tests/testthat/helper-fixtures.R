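# Hand-built two-gene toy annotation, independent of the cohort
# generator: gene A (plus strand, two transcripts sharing exons) and
# gene B (minus strand). Coordinates are chosen so that every interval
# is easy to verify by hand.

write_toy_annotation <- function(dir = tempfile("toyann")) {
  dir.create(dir, showWarnings = FALSE)
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  seq_chr <- paste(sample(bases, 2000, replace = TRUE), collapse = "")
  # gene A on +: T1 exons 101-200, 301-400, 501-600 (introns 201-300,
  # 401-500); T2 shares exon1/exon3 but skips exon2 (intron 201-500)
  # splice motifs at annotated intron boundaries
  patch <- function(s, at, repl) {
    paste0(substr(s, 1, at - 1), repl, substr(s, at + nchar(repl), nchar(s)))
  }
  seq_chr <- patch(seq_chr, 201, "GT"); seq_chr <- patch(seq_chr, 299, "AG")
  seq_chr <- patch(seq_chr, 401, "GT"); seq_chr <- patch(seq_chr, 499, "AG")
  # gene C on +: T4 exons 701-800, 901-1000 (intron 801-900), no UTRs
  seq_chr <- patch(seq_chr, 801, "GT"); seq_chr <- patch(seq_chr, 899, "AG")
  # gene B on -: T3 exons 1101-1200, 1301-1400 (intron 1201-1300);
  # sense (transcribed) motifs are reverse-complemented on the genome
  seq_chr <- patch(seq_chr, 1201, "CT"); seq_chr <- patch(seq_chr, 1299, "AC")

  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">chrT", seq_chr), fasta)

  att <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  gtf_lines <- c(
    paste("chrT", "toy", "exon", 101, 200, ".", "+", ".", att("GA", "T1"),
          sep = "\t"),
    paste("chrT", "toy", "exon", 301, 400, ".", "+", ".", att("GA", "T1"),
          sep = "\t"),
    paste("chrT", "toy", "exon", 501, 600, ".", "+", ".", att("GA", "T1"),
          sep = "\t"),
    paste("chrT", "toy", "five_prime_utr", 101, 130, ".", "+", ".",
          att("GA", "T1"), sep = "\t"),
    paste("chrT", "toy", "three_prime_utr", 571, 600, ".", "+", ".",
          att("GA", "T1"), sep = "\t"),
    paste("chrT", "toy", "exon", 101, 200, ".", "+", ".", att("GA", "T2"),
          sep = "\t"),
    paste("chrT", "toy", "exon", 501, 600, ".", "+", ".", att("GA", "T2"),
          sep = "\t"),
    paste("chrT", "toy", "exon", 701, 800, ".", "+", ".", att("GC", "T4"),
          sep = "\t"),
    paste("chrT", "toy", "exon", 901, 1000, ".", "+", ".", att("GC", "T4"),
          sep = "\t"),
    paste("chrT", "toy", "exon", 1101, 1200, ".", "-", ".",
          att("GB", "T3"), sep = "\t"),
    paste("chrT", "toy", "exon", 1301, 1400, ".", "-", ".",
          att("GB", "T3"), sep = "\t")
  )
  gtf <- file.path(dir, "toy.gtf")
  writeLines(gtf_lines, gtf)
  list(dir = dir, gtf = gtf, fasta = fasta, seq = seq_chr)
}

toy_junction <- function(chrom, s, e, strand, motif = 1L, reads = 5L) {
  data.frame(chrom = chrom, intron_start = as.integer(s),
             intron_end = as.integer(e), strand = strand,
             motif = as.integer(motif), unique_reads = as.integer(reads),
             multi_reads = 0L, stringsAsFactors = FALSE)
}

# brute-force ORF oracle: try every ATG position in reading order and
# return the first one that reaches an in-frame stop starting from the
# overall first ATG (mirrors the first-ATG-only rule)
oracle_orf <- function(seq) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  first_atg <- NA_integer_
  for (i in seq_len(max(0, n - 2))) {
    if (chars[i] == "A" && chars[i + 1] == "T" && chars[i + 2] == "G") {
      first_atg <- i
      break
    }
  }
  if (is.na(first_atg)) return(NULL)
  j <- first_atg
  while (j + 2L <= n) {
    codon <- paste(chars[j:(j + 2L)], collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) {
      return(list(start = first_atg, end = j + 2L,
                  seq = substr(seq, first_atg, j + 2L)))
    }
    j <- j + 3L
  }
  NULL
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small shared cohort for pipeline-level tests (built once per test run)
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "splicetope-shared-cohort")
      spec <- fixture_spec(seed = 7, n_genes = 8, n_tumor = 3,
                           n_normal = 3)
      cohort <- generate_cohort(spec, d)
      cache <<- list(dir = d, spec = spec, cohort = cohort)
    }
    cache
  }
})

# independent connected-components oracle (breadth-first search over the
# pairwise overlap graph)
oracle_components <- function(j) {
  n <- nrow(j)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    adj[a, b] <- j$chrom[a] == j$chrom[b] && j$strand[a] == j$strand[b] &&
      j$intron_start[a] <= j$intron_end[b] &&
      j$intron_start[b] <= j$intron_end[a]
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (a in seq_len(n)) {
    if (!is.na(comp[a])) next
    cur <- cur + 1L
    queue <- a
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}
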