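#' Read a STAR SJ.out.tab splice-junction table
#'
#' Parses the 9-column tab-separated junction table emitted by the STAR
#' aligner. Coordinates are kept in STAR's convention: 1-based, fully
#' closed, `intron_start` is the first base of the intron and `intron_end`
#' the last. Strand code 0 becomes `"*"` (undefined), 1 becomes `"+"`,
#' 2 becomes `"-"`.
#'
#' @param path Path to an SJ.out.tab file.
#' @return A data.frame with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand`, `motif`, `unique_reads`, `multi_reads`. One row per input
#'   line; an empty file yields a zero-row frame.
#' @examples
#' tf <- tempfile()
#' writeLines("chr1\t1001\t1100\t1\t1\t0\t5\t2\t20", tf)
#' read_star_sj(tf)
#' @export
read_star_sj <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_junction_frame())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("malformed SJ.out.tab line(s) (fewer than 9 columns): line ",
         paste(which(nf < 9L), collapse = ", "))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  bad <- which(apply(num, 1, function(r) any(is.na(r))))
  if (length(bad)) {
    stop("non-integer field in SJ.out.tab: line ",
         paste(bad, collapse = ", "))
  }
  motif <- num[, 4]
  bad_motif <- which(motif < 0 | motif > 6)
  if (length(bad_motif)) {
    stop("motif code outside 0-6 in SJ.out.tab: line ",
         paste(bad_motif, collapse = ", "))
  }
  strand_code <- num[, 3]
  bad_strand <- which(!strand_code %in% 0:2)
  if (length(bad_strand)) {
    stop("strand code outside 0-2 in SJ.out.tab: line ",
         paste(bad_strand, collapse = ", "))
  }
  out <- data.frame(
    chrom        = m[, 1],
    intron_start = as.integer(num[, 1]),
    intron_end   = as.integer(num[, 2]),
    strand       = c("*", "+", "-")[strand_code + 1L],
    motif        = as.integer(motif),
    unique_reads = as.integer(num[, 6]),
    multi_reads  = as.integer(num[, 7]),
    stringsAsFactors = FALSE
  )
  if (any(out$intron_start > out$intron_end)) {
    stop("intron_start > intron_end: line ",
         paste(which(out$intron_start > out$intron_end), collapse = ", "))
  }
  out
}

empty_junction_frame <- function() {
  data.frame(chrom = character(), intron_start = integer(),
             intron_end = integer(), strand = character(),
             motif = integer(), unique_reads = integer(),
             multi_reads = integer(), stringsAsFactors = FALSE)
}

#' Filter junctions to canonical motifs and a read floor
#'
#' Reproduces the SJ-to-junc conversion step: junctions with a
#' non-canonical splice motif (STAR motif code 0) are dropped, as are
#' junctions supported by fewer than `min_unique_reads` uniquely mapping
#' reads. Canonical motifs are STAR codes 1-6 (GT/AG, CT/AC, GC/AG,
#' CT/GC, AT/AC, GT/AT).
#'
#' @param records Junction data.frame as from [read_star_sj()].
#' @param min_unique_reads Minimum unique read support (default 3,
#'   echoing the clustering read floor).
#' @param keep_noncanonical If TRUE, motif-0 junctions are retained
#'   (read-floor filter still applies).
#' @return The filtered data.frame (always a subset of the input rows).
#' @export
sj_to_junc <- function(records, min_unique_reads = 3L,
                       keep_noncanonical = FALSE) {
  stopifnot(min_unique_reads >= 0)
  keep <- records$unique_reads >= min_unique_reads
  if (!keep_noncanonical) keep <- keep & records$motif %in% 1:6
  records[keep, , drop = FALSE]
}

#' Write junctions as a BED-like .junc file
#'
#' Columns: chrom, start (0-based), end (half-open, equal to the 1-based
#' last intron base), name, unique read count, strand. The 1-based closed
#' internal representation `[intron_start, intron_end]` maps to the
#' half-open interval `[intron_start - 1, intron_end)`.
#'
#' @param records Junction data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_junc <- function(records, path) {
  name <- junction_key(records)
  df <- data.frame(records$chrom, records$intron_start - 1L,
                   records$intron_end, name, records$unique_reads,
                   records$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like .junc file written by [write_junc()]
#'
#' @param path Path to a .junc file.
#' @return Junction data.frame in the internal 1-based closed convention.
#'   Motif and multi-read columns are not represented in .junc and come
#'   back as NA / 0.
#' @export
read_junc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, n = 1L)) == 0L) return(empty_junction_frame())
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(
    chrom        = df[[1]],
    intron_start = as.integer(df[[2]]) + 1L,
    intron_end   = as.integer(df[[3]]),
    strand       = df[[6]],
    motif        = NA_integer_,
    unique_reads = as.integer(df[[5]]),
    multi_reads  = 0L,
    stringsAsFactors = FALSE
  )
  out
}

#' Canonical junction key string
#'
#' @param j Junction data.frame (or any frame with `chrom`,
#'   `intron_start`, `intron_end`, `strand`).
#' @return Character vector `chrom:start-end:strand`.
#' @export
junction_key <- function(j) {
  paste0(j$chrom, ":", j$intron_start, "-", j$intron_end, ":", j$strand)
}

#' Split junction keys back into coordinate columns
#'
#' @param keys Character vector as produced by [junction_key()].
#' @return data.frame with `chrom`, `intron_start`, `intron_end`, `strand`.
#' @export
parse_junction_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+)-([0-9]+):([+*-])$", keys))
  bad <- which(lengths(m) != 5L)
  if (length(bad)) stop("malformed junction key: ", keys[bad[1]])
  data.frame(
    chrom        = vapply(m, `[`, "", 2L),
    intron_start = as.integer(vapply(m, `[`, "", 3L)),
    intron_end   = as.integer(vapply(m, `[`, "", 4L)),
    strand       = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

#' Read per-sample HLA class-I genotypes
#'
#' Expects a two-column tab-separated file: sample identifier and a
#' semicolon-separated list of HLA class-I alleles in two-field notation
#' (e.g. `A*02:01`). A header line `sample<TAB>alleles` is allowed.
#'
#' @param path Path to the genotype table.
#' @return Named list mapping sample_id to a character vector of alleles.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("sample", "alleles"))
  if (nrow(df) && df$sample[1] == "sample") df <- df[-1, , drop = FALSE]
  dup <- df$sample[duplicated(df$sample)]
  if (length(dup)) stop("duplicate sample in genotype table: ", dup[1])
  alleles <- strsplit(df$alleles, ";", fixed = TRUE)
  alleles <- lapply(alleles, function(a) {
    a <- trimws(a)
    bad <- a[!grepl("^[A-Z]+[0-9]*\\*[0-9]+:[0-9]+$", a)]
    if (length(bad)) stop("invalid HLA allele name: ", bad[1])
    if (length(a) < 1L || length(a) > 6L)
      stop("each sample must carry 1-6 class-I alleles")
    unique(a)
  })
  stats::setNames(alleles, df$sample)
}

#' Write a genotype table in the dialect read by [read_genotypes()]
#' @param genotypes Named list of allele vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(sample = names(genotypes),
                   alleles = vapply(genotypes, paste, "", collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential / outlier splicing result table
#'
#' Adapter for the output of an upstream differential-splicing or
#' outlier-splicing analysis (e.g. an intron-cluster based method). The
#' table assigns each target junction to a cluster, a group label and a
#' gene.
#'
#' @param path Tab-separated file with header columns `chrom`,
#'   `intron_start`, `intron_end`, `strand`, `cluster`, `group`, `gene`,
#'   `p_adjust`.
#' @return data.frame with those columns; group is validated against the
#'   closed vocabulary tumor_specific / normal_specific / outlier.
#' @export
read_splicing_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "intron_start", "intron_end", "strand", "cluster",
            "group", "gene", "p_adjust")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("splicing result table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ok <- df$group %in% c("tumor_specific", "normal_specific", "outlier")
  if (!all(ok)) stop("unknown group label: ", df$group[!ok][1])
  key <- junction_key(df)
  if (anyDuplicated(key)) stop("duplicate junction key in results: ",
                               key[duplicated(key)][1])
  df
}

#' Read a reference proteome FASTA
#'
#' Sequences are uppercased and trailing stop symbols (`*`) stripped, as
#' in the GENCODE `pc_translations` dialect.
#'
#' @param path FASTA file of protein sequences.
#' @return Character vector of unique protein sequences.
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty proteome FASTA: ", path)
  seqs <- toupper(as.character(aa))
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  unique(unname(seqs))
}

#' Read per-sample ESTIMATE scores
#'
#' @param path Tab-separated file with header columns `sample`, `estimate`.
#' @return Named numeric vector of ESTIMATE scores.
#' @export
read_estimate_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample)) stop("duplicate sample in ESTIMATE table")
  stats::setNames(df$estimate, df$sample)
}

#' Read a junction-by-sample count matrix
#'
#' @param path Tab-separated file; first column `junction` holds junction
#'   keys, remaining columns are per-sample integer counts.
#' @return Numeric matrix, junction keys as rownames.
#' @export
read_junction_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  if (any(m < 0)) stop("negative junction count")
  m
}
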