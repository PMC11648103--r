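#' Classify splice junctions against a reference annotation
#'
#' Each junction's two splice sites are compared with the donor and
#' acceptor sites of the reference annotation (exact coordinate match,
#' strand-aware):
#' \itemize{
#'   \item both sites known and spliced together as consecutive exon
#'     boundaries of some transcript: \code{annotated};
#'   \item both sites known but never co-spliced: \code{novel_annotated};
#'   \item only the 5' (donor) site known: \code{cryptic_threeprime}
#'     (the 3' site is the cryptic one);
#'   \item only the 3' (acceptor) site known: \code{cryptic_fiveprime};
#'   \item neither known: \code{cryptic_unanchored}.
#' }
#' Orientation is transcriptional: on the minus strand the donor lies at
#' the genomic right (intron_end) edge. Junctions with undefined strand
#' (`*`) are not classifiable and raise an error; drop them upstream.
#'
#' @param junctions Junction data.frame (1-based closed intron
#'   coordinates, defined strand).
#' @param ann A [read_annotation()] object.
#' @return The input data.frame with added columns
#'   `fiveprime_site_known`, `threeprime_site_known`, `classification`
#'   and `gene_candidates` (comma-separated gene_ids: genes owning a
#'   matching site, else genes whose span contains the junction).
#' @export
classify_junctions <- function(junctions, ann) {
  if (nrow(junctions) == 0L) {
    junctions$fiveprime_site_known <- logical()
    junctions$threeprime_site_known <- logical()
    junctions$classification <- character()
    junctions$gene_candidates <- character()
    return(junctions)
  }
  if (any(junctions$strand == "*"))
    stop("cannot classify junctions with undefined strand")
  missing_chr <- setdiff(unique(junctions$chrom),
                         unique(c(ann$exons$chrom, names(ann$genome))))
  if (length(missing_chr))
    stop("junction on chromosome absent from annotation: ", missing_chr[1])

  intr <- ann$introns
  # site keys are chrom/strand-qualified genomic positions
  donor_pos    <- ifelse(intr$strand == "+", intr$intron_start, intr$intron_end)
  acceptor_pos <- ifelse(intr$strand == "+", intr$intron_end, intr$intron_start)
  donor_keys    <- paste(intr$chrom, intr$strand, donor_pos)
  acceptor_keys <- paste(intr$chrom, intr$strand, acceptor_pos)
  pair_keys <- paste(intr$chrom, intr$strand, intr$intron_start,
                     intr$intron_end)

  j_donor    <- ifelse(junctions$strand == "+", junctions$intron_start,
                       junctions$intron_end)
  j_acceptor <- ifelse(junctions$strand == "+", junctions$intron_end,
                       junctions$intron_start)
  jd_key <- paste(junctions$chrom, junctions$strand, j_donor)
  ja_key <- paste(junctions$chrom, junctions$strand, j_acceptor)
  jp_key <- paste(junctions$chrom, junctions$strand,
                  junctions$intron_start, junctions$intron_end)

  donor_known    <- jd_key %in% donor_keys
  acceptor_known <- ja_key %in% acceptor_keys
  co_spliced     <- jp_key %in% pair_keys

  classification <- ifelse(
    donor_known & acceptor_known,
    ifelse(co_spliced, "annotated", "novel_annotated"),
    ifelse(donor_known, "cryptic_threeprime",
           ifelse(acceptor_known, "cryptic_fiveprime",
                  "cryptic_unanchored")))

  # gene candidates: genes owning a matching site, else genes whose span
  # contains the junction (same chrom+strand)
  gene_of_donor <- split(intr$gene_id, donor_keys)
  gene_of_acceptor <- split(intr$gene_id, acceptor_keys)
  spans <- gene_spans(ann)
  gene_candidates <- vapply(seq_len(nrow(junctions)), function(i) {
    g <- unique(c(gene_of_donor[[jd_key[i]]], gene_of_acceptor[[ja_key[i]]]))
    if (!length(g)) {
      sp <- spans[spans$chrom == junctions$chrom[i] &
                  spans$strand == junctions$strand[i] &
                  spans$start <= junctions$intron_start[i] &
                  spans$end >= junctions$intron_end[i], , drop = FALSE]
      g <- sp$gene_id
    }
    paste(sort(unique(g)), collapse = ",")
  }, "")

  junctions$fiveprime_site_known <- donor_known
  junctions$threeprime_site_known <- acceptor_known
  junctions$classification <- classification
  junctions$gene_candidates <- gene_candidates
  junctions
}

gene_spans <- function(ann) {
  key <- paste(ann$exons$gene_id, ann$exons$chrom, ann$exons$strand)
  first <- !duplicated(key)
  data.frame(
    gene_id = ann$exons$gene_id[first],
    chrom   = ann$exons$chrom[first],
    strand  = ann$exons$strand[first],
    start   = as.integer(tapply(ann$exons$start, key, min)[key[first]]),
    end     = as.integer(tapply(ann$exons$end, key, max)[key[first]]),
    stringsAsFactors = FALSE
  )
}

#' Group junctions into overlap clusters
#'
#' Connected components of the intron-interval overlap graph: two
#' junctions are linked when their introns share at least one base on the
#' same chromosome and strand (`mode = "overlap"`, the default), or when
#' they share a splice-site coordinate (`mode = "shared-site"`). Clusters
#' whose total unique read count falls below `min_cluster_reads` are
#' dropped (default 3, the conventional read floor for evidence that a
#' splicing event exists).
#'
#' @param junctions Junction data.frame.
#' @param min_cluster_reads Minimum summed unique reads per cluster.
#' @param mode Overlap rule; see above.
#' @return The input rows that survive, with a `cluster` column
#'   (`clu_1`, `clu_2`, ... in genomic order).
#' @export
cluster_junctions <- function(junctions, min_cluster_reads = 3L,
                              mode = c("overlap", "shared-site")) {
  mode <- match.arg(mode)
  if (nrow(junctions) == 0L) {
    junctions$cluster <- character()
    return(junctions)
  }
  n <- nrow(junctions)
  comp <- integer(n)
  grp <- paste(junctions$chrom, junctions$strand)
  next_comp <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (mode == "overlap") {
      o <- idx[order(junctions$intron_start[idx], junctions$intron_end[idx])]
      cur_end <- -Inf
      for (i in o) {
        if (junctions$intron_start[i] > cur_end) next_comp <- next_comp + 1L
        comp[i] <- next_comp
        cur_end <- max(cur_end, junctions$intron_end[i])
      }
    } else {
      # union-find on shared start or end coordinates
      parent <- seq_along(idx)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      link_by <- function(vals) {
        for (v in split(seq_along(idx), vals)) {
          if (length(v) > 1L) {
            r <- find(v[1])
            for (w in v[-1]) parent[find(w)] <<- r
          }
        }
      }
      link_by(junctions$intron_start[idx])
      link_by(junctions$intron_end[idx])
      roots <- vapply(seq_along(idx), find, 1L)
      for (r in unique(roots)) {
        next_comp <- next_comp + 1L
        comp[idx[roots == r]] <- next_comp
      }
    }
  }
  totals <- tapply(junctions$unique_reads, comp, sum)
  keep_comp <- as.integer(names(totals)[totals >= min_cluster_reads])
  keep <- comp %in% keep_comp
  out <- junctions[keep, , drop = FALSE]
  comp <- comp[keep]
  if (nrow(out) == 0L) {
    out$cluster <- character()
    return(out)
  }
  # stable cluster ids in genomic order of first member
  first_pos <- tapply(seq_len(nrow(out)), comp, function(i) min(i))
  relabel <- stats::setNames(seq_along(first_pos),
                             names(sort(first_pos)))
  out$cluster <- paste0("clu_", relabel[as.character(comp)])
  rownames(out) <- NULL
  out
}
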