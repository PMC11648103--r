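#' Specification for a synthetic splicing cohort
#'
#' Describes the study conditions emulated by [generate_cohort()]: a toy
#' multi-exon genome with annotated baseline junctions, per-gene injected
#' alternative junctions spanning all five classification classes, a
#' tumor/normal sample design with group-biased junction expression, a
#' tumor-purity gradient, genotypes and a reference proteome.
#'
#' Injected cryptic junctions reuse the annotated donor of the first
#' intron and shift the acceptor into exon 2 (frame-shifting the
#' downstream CDS, which is built from A/C/G-only sense codons so the
#' shifted frame reads through to a stop cassette at the start of the
#' 3'UTR and yields a long novel peptide tail). Canonical GT..AG
#' dinucleotides are patched into the genome at every injected intron
#' boundary, so motif-based filtering sees only canonical events plus
#' the explicitly non-canonical decoys.
#'
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param n_genes Number of genes (default 50).
#' @param n_tumor,n_normal Samples per group (default 6 and 6).
#' @param cds_codon_range Range of CDS sense-codon counts per gene.
#' @param top_gene_codons CDS codons for the designated top-effect gene.
#' @param intron_len_range Intron length range (nt).
#' @param utr_fraction Fraction of genes with annotated UTRs.
#' @param effect_size Fold-change on tumor-specific junction counts in
#'   tumor samples (1 = null, exchangeable design).
#' @param top_gene_boost Extra fold-change on the top gene's
#'   tumor-specific junction (its normal-specific junction is suppressed
#'   to mean 2); ignored at effect_size = 1.
#' @param mu_base,mu_cryptic,mu_lo,nb_size Negative-binomial count means
#'   for annotated junctions, group-biased junctions in their own group,
#'   biased junctions in the other group, and the common dispersion.
#' @param est_tumor_range,est_normal_range Uniform ranges for ESTIMATE
#'   scores per group.
#' @param purity_capture If TRUE, tumor-sample counts of biased junctions
#'   scale linearly with the sample's pseudo purity (junction capture
#'   proportional to tumor content).
#' @param low_purity_sample If TRUE, the first tumor sample is pinned at
#'   the cohort-maximum ESTIMATE score (pseudo purity ~ 2e-16), so it
#'   must be excluded at the 0.01 purity floor.
#' @param noncanonical_decoys If TRUE, each gene also emits a motif-0
#'   junction that canonical-motif filtering must drop.
#' @param mode `"differential"` (tumor_specific / normal_specific labels)
#'   or `"outlier"` (all injected junctions labelled outlier).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 50L, n_tumor = 6L,
                         n_normal = 6L,
                         cds_codon_range = c(200L, 260L),
                         top_gene_codons = 320L,
                         intron_len_range = c(60L, 100L),
                         utr_fraction = 1.0,
                         effect_size = 4,
                         top_gene_boost = 16,
                         mu_base = 30, mu_cryptic = 30, mu_lo = 2,
                         nb_size = 10,
                         est_tumor_range = c(2000, 8000),
                         est_normal_range = c(500, 2500),
                         purity_capture = FALSE,
                         low_purity_sample = FALSE,
                         noncanonical_decoys = TRUE,
                         mode = c("differential", "outlier")) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_tumor = as.integer(n_tumor),
               n_normal = as.integer(n_normal),
               cds_codon_range = cds_codon_range,
               top_gene_codons = top_gene_codons,
               intron_len_range = intron_len_range,
               utr_fraction = utr_fraction,
               effect_size = effect_size,
               top_gene_boost = top_gene_boost,
               mu_base = mu_base, mu_cryptic = mu_cryptic, mu_lo = mu_lo,
               nb_size = nb_size,
               est_tumor_range = est_tumor_range,
               est_normal_range = est_normal_range,
               purity_capture = isTRUE(purity_capture),
               low_purity_sample = isTRUE(low_purity_sample),
               noncanonical_decoys = isTRUE(noncanonical_decoys),
               mode = match.arg(mode))
  class(spec) <- "fixture_spec"
  spec
}

# sense codons over {A,C,G}: no T anywhere, hence no stop codon in any
# reading frame of a sequence built from them
acg_codons <- local({
  b <- c("A", "C", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
})

# stop cassette: contains an in-frame stop within 4 codons in every frame
stop_cassette <- "TAGATAGATAGA"

rand_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# build one gene in sense orientation; returns sequences, local layout,
# injected junctions (local coordinates) and the reference protein
build_gene <- function(spec, gi) {
  n_codons <- if (gi == 1L && spec$effect_size != 1)
    spec$top_gene_codons
  else sample(seq(spec$cds_codon_range[1], spec$cds_codon_range[2]), 1L)
  utr5 <- rand_string(24L, c("C", "G", "T"))     # no A: no ATG before CDS
  body <- sample(acg_codons, n_codons, replace = TRUE)
  cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
  utr3 <- paste0(stop_cassette, rand_string(24L, c("A", "C", "G", "T")))
  mrna <- paste0(utr5, cds, utr3)
  lm <- nchar(mrna)

  e1_cds <- 45L
  exon1_len <- 24L + e1_cds
  exon2_len <- 60L
  exon3_len <- lm - exon1_len - exon2_len
  stopifnot(exon3_len >= nchar(utr3) + 30L)
  il <- sample(seq(spec$intron_len_range[1], spec$intron_len_range[2]), 2L,
               replace = TRUE)
  intr1 <- paste0("GT", rand_string(il[1] - 4L, c("A", "C", "G", "T")), "AG")
  intr2 <- paste0("GT", rand_string(il[2] - 4L, c("A", "C", "G", "T")), "AG")

  ex1 <- substr(mrna, 1L, exon1_len)
  ex2 <- substr(mrna, exon1_len + 1L, exon1_len + exon2_len)
  ex3 <- substr(mrna, exon1_len + exon2_len + 1L, lm)
  s <- paste0(ex1, intr1, ex2, intr2, ex3)

  # local layout (sense coordinates within the gene)
  e1 <- c(1L, exon1_len)
  i1 <- c(exon1_len + 1L, exon1_len + il[1])
  e2 <- c(i1[2] + 1L, i1[2] + exon2_len)
  i2 <- c(e2[2] + 1L, e2[2] + il[2])
  e3 <- c(i2[2] + 1L, i2[2] + exon3_len)

  # genome patches for injected splice sites
  # cryptic acceptors: exon2 local delta, preceding two bases become AG
  delta_t <- 10L; delta_n <- 17L           # frame shifts 1 and 2
  s <- patch_str(s, e2[1] + delta_t - 2L, "AG")
  s <- patch_str(s, e2[1] + delta_n - 2L, "AG")
  # cryptic donor in exon1: first two intron bases become GT; pick the
  # shift so the patched T cannot start a stop codon in the CDS frame
  d <- NA_integer_
  for (cand in 10:15) {
    p <- exon1_len - cand + 1L
    if (((p - 24L - 1L) %% 3L) %in% c(0L, 1L)) { d <- cand; break }
  }
  p_donor <- exon1_len - d + 1L
  s <- patch_str(s, p_donor, "GT")

  junctions <- list(
    annotated_1 = c(i1[1], i1[2]),
    annotated_2 = c(i2[1], i2[2]),
    skip        = c(i1[1], i2[2]),
    cryptic_t   = c(i1[1], i1[2] + delta_t),
    cryptic_n   = c(i1[1], i1[2] + delta_n),
    cryptic_5p  = c(p_donor, i1[2]),
    unanchored  = c(p_donor, i1[2] + delta_t)
  )
  truth_class <- c(
    annotated_1 = "annotated", annotated_2 = "annotated",
    skip = "novel_annotated",
    cryptic_t = "cryptic_threeprime", cryptic_n = "cryptic_threeprime",
    cryptic_5p = "cryptic_fiveprime", unanchored = "cryptic_unanchored")

  # reference protein from the patched CDS
  cds_patched <- substr(paste0(substr(s, e1[1], e1[2]),
                               substr(s, e2[1], e2[2]),
                               substr(s, e3[1], e3[2])),
                        25L, 24L + nchar(cds))
  protein <- translate_orf(cds_patched)

  list(seq = s, len = nchar(s), exons = list(e1, e2, e3),
       utr5 = c(1L, 24L),
       utr3 = c(i1[2] - i1[1] + 1L + i2[2] - i2[1] + 1L + lm -
                  nchar(utr3) + 1L,
                i1[2] - i1[1] + 1L + i2[2] - i2[1] + 1L + lm),
       junctions = junctions, truth_class = truth_class,
       delta_t = delta_t, delta_n = delta_n,
       protein = protein, n_codons = n_codons)
}

patch_str <- function(s, at, repl) {
  paste0(substr(s, 1L, at - 1L), repl,
         substr(s, at + nchar(repl), nchar(s)))
}

# map a local sense interval to genomic coordinates
local_to_genomic <- function(interval, gstart, glen, strand) {
  if (strand == "+") {
    c(gstart + interval[1] - 1L, gstart + interval[2] - 1L)
  } else {
    c(gstart + glen - interval[2], gstart + glen - interval[1])
  }
}

#' Generate a synthetic splicing cohort
#'
#' Writes a complete set of pipeline inputs to `dir`: genome FASTA,
#' annotation GTF (with UTR features), per-sample STAR-style SJ.out.tab
#' tables, a junction-by-sample count matrix, a splicing result table
#' (group-labelled injected junctions), genotypes, ESTIMATE scores, a
#' reference proteome (translations of every unmodified transcript) and
#' truth tables recording each junction's classification and each gene's
#' expected effect direction.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list: `dir`, `paths` (file paths) and the
#'   in-memory `truth_junctions`, `truth_genes`, `samples` data.frames.
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  gap <- 300L
  genes <- vector("list", spec$n_genes)
  offsets <- integer(spec$n_genes)
  pos <- 1L
  chrom_parts <- character(0)
  strands <- rep(c("+", "-"), length.out = spec$n_genes)
  for (gi in seq_len(spec$n_genes)) {
    g <- build_gene(spec, gi)
    genes[[gi]] <- g
    chrom_parts <- c(chrom_parts, rand_string(gap, c("C", "G", "T")),
                     if (strands[gi] == "+") g$seq else revcomp(g$seq))
    offsets[gi] <- pos + gap
    pos <- pos + gap + g$len
  }
  chrom_seq <- paste(chrom_parts, collapse = "")
  chrom <- "chr1"

  has_utr <- rep(TRUE, spec$n_genes)
  if (spec$utr_fraction < 1) {
    n_no <- round((1 - spec$utr_fraction) * spec$n_genes)
    if (n_no > 0) has_utr[sample(seq_len(spec$n_genes), n_no)] <- FALSE
  }

  # GTF
  gtf_lines <- character(0)
  for (gi in seq_len(spec$n_genes)) {
    g <- genes[[gi]]; st <- strands[gi]; off <- offsets[gi]
    gid <- sprintf("G%03d", gi); tid <- sprintf("T%03d", gi)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     gid, tid, gid)
    feats <- lapply(g$exons, function(e) c("exon", e))
    if (has_utr[gi]) {
      feats <- c(feats, list(c("five_prime_utr", g$utr5)),
                 list(c("three_prime_utr", g$utr3)))
    }
    for (f in feats) {
      iv <- local_to_genomic(as.integer(f[2:3]), off, g$len, st)
      gtf_lines <- c(gtf_lines, paste(
        chrom, "synth", f[1], iv[1], iv[2], ".", st, ".", attrs,
        sep = "\t"))
    }
  }

  # junction truth table (genomic coordinates)
  jt <- list()
  for (gi in seq_len(spec$n_genes)) {
    g <- genes[[gi]]; st <- strands[gi]; off <- offsets[gi]
    gid <- sprintf("G%03d", gi)
    for (nm in names(g$junctions)) {
      iv <- local_to_genomic(g$junctions[[nm]], off, g$len, st)
      jt[[length(jt) + 1L]] <- data.frame(
        gene = gid, role = nm, chrom = chrom,
        intron_start = iv[1], intron_end = iv[2], strand = st,
        truth_class = unname(g$truth_class[nm]),
        motif = if (st == "+") 1L else 2L,
        stringsAsFactors = FALSE)
    }
    if (spec$noncanonical_decoys) {
      ann1 <- g$junctions$annotated_1
      iv <- local_to_genomic(c(ann1[1] + 3L, ann1[2] - 3L), off, g$len, st)
      jt[[length(jt) + 1L]] <- data.frame(
        gene = gid, role = "noncanonical", chrom = chrom,
        intron_start = iv[1], intron_end = iv[2], strand = st,
        truth_class = "noncanonical", motif = 0L,
        stringsAsFactors = FALSE)
    }
  }
  truth_junctions <- do.call(rbind, jt)
  truth_junctions$key <- junction_key(truth_junctions)
  truth_junctions$group <- "none"
  truth_junctions$group[truth_junctions$role == "cryptic_t"] <- "tumor"
  truth_junctions$group[truth_junctions$role == "cryptic_n"] <- "normal"

  # samples, genotypes, purity
  samples <- data.frame(
    sample = c(sprintf("TUM%02d", seq_len(spec$n_tumor)),
               sprintf("NRM%02d", seq_len(spec$n_normal))),
    group = c(rep("tumor", spec$n_tumor), rep("normal", spec$n_normal)),
    stringsAsFactors = FALSE)
  pool <- c("A*01:01", "A*02:01", "A*03:01", "B*07:02", "B*08:01",
            "B*15:01", "B*44:02", "C*03:04", "C*07:01", "C*07:02")
  genotypes <- lapply(seq_len(nrow(samples)),
                      function(i) sort(sample(pool, 6L)))
  names(genotypes) <- samples$sample
  est <- c(stats::runif(spec$n_tumor, spec$est_tumor_range[1],
                        spec$est_tumor_range[2]),
           stats::runif(spec$n_normal, spec$est_normal_range[1],
                        spec$est_normal_range[2]))
  if (spec$low_purity_sample) est[1] <- max(est) * 1.05
  names(est) <- samples$sample
  pur <- pseudo_purity(est)$purity
  samples$estimate <- est
  samples$purity <- pur

  # counts
  n_s <- nrow(samples)
  counts <- matrix(0L, nrow = nrow(truth_junctions), ncol = n_s,
                   dimnames = list(truth_junctions$key, samples$sample))
  is_tumor_s <- samples$group == "tumor"
  for (r in seq_len(nrow(truth_junctions))) {
    role <- truth_junctions$role[r]
    gi <- as.integer(sub("G", "", truth_junctions$gene[r]))
    top <- gi == 1L && spec$effect_size != 1
    mu <- rep(NA_real_, n_s)
    if (role %in% c("annotated_1", "annotated_2")) {
      mu[] <- spec$mu_base
    } else if (role %in% c("skip", "cryptic_5p", "unanchored",
                           "noncanonical")) {
      mu[] <- 5
    } else if (role == "cryptic_t") {
      mu[is_tumor_s] <- spec$mu_cryptic * spec$effect_size *
        (if (top) spec$top_gene_boost else 1)
      mu[!is_tumor_s] <- spec$mu_lo
    } else if (role == "cryptic_n") {
      mu[!is_tumor_s] <- if (top) 2 else spec$mu_cryptic
      mu[is_tumor_s] <- spec$mu_lo
    }
    if (spec$purity_capture && role %in% c("cryptic_t", "cryptic_n")) {
      mu[is_tumor_s] <- mu[is_tumor_s] * samples$purity[is_tumor_s]
    }
    counts[r, ] <- stats::rnbinom(n_s, mu = mu, size = spec$nb_size)
  }

  # splicing result table: the injected group-biased junctions
  sel <- truth_junctions$role %in% c("cryptic_t", "cryptic_n")
  res <- truth_junctions[sel, c("chrom", "intron_start", "intron_end",
                                "strand", "gene"), drop = FALSE]
  res$cluster <- paste0("clu_", res$gene)
  res$group <- if (spec$mode == "outlier") "outlier" else
    ifelse(truth_junctions$group[sel] == "tumor",
           "tumor_specific", "normal_specific")
  res$p_adjust <- signif(stats::runif(nrow(res), 1e-6, 0.05), 3)
  res <- res[, c("chrom", "intron_start", "intron_end", "strand",
                 "cluster", "group", "gene", "p_adjust")]

  # truth per gene
  truth_genes <- data.frame(
    gene = sprintf("G%03d", seq_len(spec$n_genes)),
    strand = strands,
    top_gene = seq_len(spec$n_genes) == 1L & spec$effect_size != 1,
    n_codons = vapply(genes, function(g) g$n_codons, 1L),
    has_utr = has_utr,
    stringsAsFactors = FALSE)

  # write everything
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    proteome = file.path(dir, "proteome.fa"),
    genotypes = file.path(dir, "genotypes.tsv"),
    estimate = file.path(dir, "estimate.tsv"),
    counts = file.path(dir, "counts.tsv"),
    splicing_results = file.path(dir, "splicing_results.tsv"),
    sj_dir = file.path(dir, "sj"),
    samples = file.path(dir, "samples.tsv"),
    truth_junctions = file.path(dir, "truth_junctions.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"))

  writeLines(c(paste0(">", chrom), chunk_fasta(chrom_seq)), paths$genome)
  writeLines(gtf_lines, paths$gtf)
  prot_lines <- unlist(lapply(seq_len(spec$n_genes), function(gi)
    c(paste0(">P", sprintf("%03d", gi)), genes[[gi]]$protein)))
  writeLines(prot_lines, paths$proteome)
  write_genotypes(genotypes, paths$genotypes)
  utils::write.table(
    data.frame(sample = samples$sample, estimate = samples$estimate),
    paths$estimate, sep = "\t", quote = FALSE, row.names = FALSE)
  cnt_df <- data.frame(junction = rownames(counts), counts,
                       check.names = FALSE)
  utils::write.table(cnt_df, paths$counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res, paths$splicing_results, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dir.create(paths$sj_dir, showWarnings = FALSE)
  strand_code <- c("+" = 1L, "-" = 2L)
  for (si in seq_len(n_s)) {
    keep <- counts[, si] > 0
    sj <- data.frame(truth_junctions$chrom,
                     truth_junctions$intron_start,
                     truth_junctions$intron_end,
                     strand_code[truth_junctions$strand],
                     truth_junctions$motif, 0L,
                     counts[, si], 1L, 20L)[keep, , drop = FALSE]
    utils::write.table(sj,
      file.path(paths$sj_dir, paste0(samples$sample[si], ".SJ.out.tab")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(samples[, c("sample", "group")], paths$samples,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth_junctions, paths$truth_junctions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_genes, paths$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(dir = dir, paths = paths,
                 truth_junctions = truth_junctions,
                 truth_genes = truth_genes, samples = samples))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

chunk_fasta <- function(seq, width = 70L) {
  starts <- seq(1L, nchar(seq), by = width)
  substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))
}
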