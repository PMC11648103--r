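#' Configuration for an end-to-end antigenicity run
#'
#' @param gtf,genome,splicing_results,counts,genotypes,estimate,proteome
#'   Input file paths (formats as in the corresponding readers).
#' @param sample_groups Mapping of sample to group (`tumor` / `normal`):
#'   either a named character vector or a path to a two-column
#'   tab-separated file with header `sample`, `group`. Required in
#'   differential mode; optional in outlier mode.
#' @param mode `"differential"` (cross-group binder filtering within each
#'   junction cluster) or `"outlier"` (cross-group filtering skipped).
#' @param kmer_lengths MHC class-I kmer lengths (default 9).
#' @param ic50_threshold Binder threshold in nmol/L (default 500,
#'   boundary inclusive).
#' @param purity_floor Pseudo-purity exclusion floor (default 0.01).
#' @param min_len Minimum fused-transcript length scored for coding
#'   potential (default 100 nt).
#' @param coeffs LGC coefficient list or path to a coefficient file;
#'   NULL for the packaged defaults.
#' @param predictor Binding predictor function `(kmers, alleles) ->
#'   data.frame(kmer, allele, ic50)`; NULL for the deterministic stub
#'   seeded from `seed`.
#' @param seed Integer seed for the stub predictor.
#' @param binder_fraction Stub-predictor binder fraction at 500 nmol/L.
#' @param vst Variance-stabilizing transform applied to counts
#'   (default `log2(x + 1)`).
#' @param gc_on GC content on `"transcript"` or `"orf"`.
#' @param max_pairs Cap on flanking-transcript pairs per junction.
#' @param log_path Optional path for JSON-lines stage logs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gtf, genome, splicing_results, counts,
                            genotypes, estimate, proteome,
                            sample_groups = NULL,
                            mode = c("differential", "outlier"),
                            kmer_lengths = 9L, ic50_threshold = 500,
                            purity_floor = 0.01, min_len = 100L,
                            coeffs = NULL, predictor = NULL, seed = 1L,
                            binder_fraction = 0.02,
                            vst = function(x) log2(x + 1),
                            gc_on = "transcript", max_pairs = Inf,
                            log_path = NULL) {
  cfg <- list(gtf = gtf, genome = genome,
              splicing_results = splicing_results, counts = counts,
              genotypes = genotypes, estimate = estimate,
              proteome = proteome, sample_groups = sample_groups,
              mode = match.arg(mode),
              kmer_lengths = kmer_lengths,
              ic50_threshold = ic50_threshold,
              purity_floor = purity_floor, min_len = min_len,
              coeffs = coeffs, predictor = predictor,
              seed = as.integer(seed),
              binder_fraction = binder_fraction, vst = vst,
              gc_on = gc_on, max_pairs = max_pairs, log_path = log_path)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Convenience: configuration for a [generate_cohort()] directory
#' @param dir Directory written by [generate_cohort()].
#' @param ... Passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
cohort_config <- function(dir, ...) {
  pipeline_config(
    gtf = file.path(dir, "annotation.gtf"),
    genome = file.path(dir, "genome.fa"),
    splicing_results = file.path(dir, "splicing_results.tsv"),
    counts = file.path(dir, "counts.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    estimate = file.path(dir, "estimate.tsv"),
    proteome = file.path(dir, "proteome.fa"),
    sample_groups = file.path(dir, "samples.tsv"), ...)
}

#' Run the splicing-antigenicity pipeline end to end
#'
#' Stages: load inputs; classify the target junctions against the
#' reference; build junction-modified transcripts; score coding
#' potential and retain genes with positive mean coding potential;
#' kmerize; predict MHC binding; apply IC50, cross-group (differential
#' mode only) and reference-peptidome filtering; variance-stabilize
#' counts; compute per-gene and per-sample splicing antigenicity, purity
#' normalization and (differential mode) per-gene differential
#' agretopicity.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `splicing_antigenicity`; see the components
#'   documented in the package vignette. Re-running with an identical
#'   configuration is deterministic.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    entry <- c(list(stage = stage), list(...))
    log[[length(log) + 1L]] <<- entry
    if (!is.null(config$log_path))
      cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
          sep = "", file = config$log_path, append = TRUE)
  }

  ann <- read_annotation(config$gtf, config$genome)
  results <- read_splicing_results(config$splicing_results)
  counts <- read_junction_counts(config$counts)
  genotypes <- read_genotypes(config$genotypes)
  estimate <- read_estimate_scores(config$estimate)
  proteome <- read_proteome_fasta(config$proteome)
  group_map <- config$sample_groups
  if (is.character(group_map) && length(group_map) == 1L &&
      file.exists(group_map)) {
    gdf <- utils::read.table(group_map, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    group_map <- stats::setNames(gdf$group, gdf$sample)
  }
  if (config$mode == "differential") {
    if (is.null(group_map))
      stop("differential mode requires sample_groups")
    if (!all(group_map %in% c("tumor", "normal")))
      stop("sample groups must be tumor or normal")
  }
  note("load", junctions = nrow(results), samples = length(genotypes),
       proteins = length(proteome))

  coeffs <- config$coeffs
  if (is.null(coeffs)) coeffs <- lgc_default_coefficients()
  else if (is.character(coeffs)) coeffs <- read_lgc_coefficients(coeffs)
  predictor <- config$predictor
  if (is.null(predictor))
    predictor <- stub_predictor(config$seed, config$binder_fraction)

  junctions <- results[, c("chrom", "intron_start", "intron_end",
                           "strand"), drop = FALSE]
  junctions$motif <- NA_integer_
  junctions$unique_reads <- NA_integer_
  junctions$multi_reads <- NA_integer_
  junctions <- classify_junctions(junctions, ann)
  junctions$key <- junction_key(junctions)
  junctions$cluster <- results$cluster
  junctions$group <- results$group
  junctions$gene <- results$gene
  note("classify", classified = nrow(junctions))

  joined <- build_transcripts(junctions, ann, max_pairs = config$max_pairs)
  note("build_transcripts", transcripts = length(joined),
       truncated = length(attr(joined, "truncated")))

  scores <- score_coding(joined, coeffs = coeffs,
                         min_len = config$min_len, gc_on = config$gc_on)
  gene_of <- stats::setNames(junctions$gene, junctions$key)
  genes_retained <- filter_by_coding(scores, gene_of)
  note("score_coding", scored = sum(scores$scored),
       genes_retained = length(genes_retained))

  # kmer sets per junction (union over its joined transcripts)
  kmers_by_junction <- lapply(stats::setNames(junctions$key,
                                              junctions$key),
                              function(k) character())
  for (jt in joined) {
    if (is.na(jt$protein)) next
    kmers_by_junction[[jt$junction]] <- unique(c(
      kmers_by_junction[[jt$junction]],
      kmerize(jt$protein, config$kmer_lengths)))
  }
  k_total <- vapply(kmers_by_junction, length, 1L)

  all_kmers <- unique(unlist(kmers_by_junction, use.names = FALSE))
  all_alleles <- sort(unique(unlist(genotypes, use.names = FALSE)))
  predictions <- predictor(all_kmers, all_alleles)
  if (nrow(predictions) < length(all_kmers) * length(all_alleles))
    stop("binding predictor did not cover every (kmer, allele) pair")
  note("predict", kmers = length(all_kmers), alleles = length(all_alleles),
       binder_pairs = sum(predictions$ic50 <= config$ic50_threshold))

  ref_kmers <- proteome_kmers(proteome, config$kmer_lengths)

  # cluster-level kmer pools for cross-group filtering
  cluster_kmers <- function(grp) {
    sel <- junctions$group == grp
    tapply(junctions$key[sel], junctions$cluster[sel], function(keys)
      unique(unlist(kmers_by_junction[keys], use.names = FALSE)))
  }
  tumor_pool <- if (config$mode == "differential")
    cluster_kmers("tumor_specific") else list()
  normal_pool <- if (config$mode == "differential")
    cluster_kmers("normal_specific") else list()

  purity_df <- pseudo_purity(estimate, floor = config$purity_floor)
  purity <- stats::setNames(purity_df$purity, names(estimate))
  excluded <- names(estimate)[purity_df$excluded]
  note("purity", excluded = length(excluded))

  samples <- intersect(names(genotypes), colnames(counts))
  samples <- setdiff(samples, excluded)

  r_mat <- variance_stabilize(counts, config$vst)

  # the junction flavour a sample is scored on: its own group's
  # junctions in differential mode, everything in outlier mode
  junction_idx_for <- function(s) {
    if (config$mode == "outlier") return(seq_len(nrow(junctions)))
    grp <- paste0(group_map[[s]], "_specific")
    which(junctions$group == grp)
  }

  # per-sample, per-junction surviving binder counts
  binder_rows <- list()
  for (s in samples) {
    sample_binders <- call_binders(predictions, config$ic50_threshold,
                                   genotype = genotypes[[s]])
    for (i in junction_idx_for(s)) {
      key <- junctions$key[i]
      b <- intersect(kmers_by_junction[[key]], sample_binders)
      if (config$mode == "differential") {
        cl <- junctions$cluster[i]
        if (junctions$group[i] == "tumor_specific") {
          other <- normal_pool[[cl]]
          if (!is.null(other)) b <- setdiff(b, other)
        } else if (junctions$group[i] == "normal_specific") {
          other <- tumor_pool[[cl]]
          if (!is.null(other)) b <- setdiff(b, other)
        }
      }
      b <- filter_reference_peptidome(b, ref_kmers,
                                      config$kmer_lengths,
                                      precomputed = TRUE)
      binder_rows[[length(binder_rows) + 1L]] <- data.frame(
        sample = s, junction = key, group = junctions$group[i],
        gene = junctions$gene[i], cluster = junctions$cluster[i],
        k_group = length(b), k_total = k_total[[key]],
        stringsAsFactors = FALSE)
    }
  }
  binder_counts <- do.call(rbind, binder_rows)
  note("filter_binders", rows = nrow(binder_counts),
       surviving = sum(binder_counts$k_group))

  # per-gene SA per sample (each sample scored on its own flavour)
  sa_rows <- list()
  for (s in samples) {
    gsel <- binder_counts[binder_counts$sample == s &
                          binder_counts$gene %in% genes_retained, ,
                          drop = FALSE]
    if (nrow(gsel) == 0L) next
    flavour <- if (config$mode == "outlier") "outlier"
               else group_map[[s]]
    for (g in unique(gsel$gene)) {
      rows <- gsel[gsel$gene == g, , drop = FALSE]
      rows <- rows[rows$junction %in% rownames(r_mat), , drop = FALSE]
      if (nrow(rows) == 0L) next
      r <- r_mat[rows$junction, s]
      sa <- gene_antigenicity(r, rows$k_group, rows$k_total)
      if (is.na(sa)) next
      sa_rows[[length(sa_rows) + 1L]] <- data.frame(
        gene = g, sample = s, group = flavour,
        sa = sa, sa_norm = normalize_antigenicity(sa, purity[[s]]),
        stringsAsFactors = FALSE)
    }
  }
  gene_sa <- if (length(sa_rows)) do.call(rbind, sa_rows) else
    data.frame(gene = character(), sample = character(),
               group = character(), sa = numeric(), sa_norm = numeric())
  note("antigenicity", gene_sample_pairs = nrow(gene_sa))

  # sample summaries: mean over the sample's scored genes
  sample_rows <- list()
  for (s in samples) {
    own <- gene_sa[gene_sa$sample == s, , drop = FALSE]
    if (nrow(own) == 0L) next
    sample_rows[[length(sample_rows) + 1L]] <- data.frame(
      sample = s, group = own$group[1], purity = purity[[s]],
      n_genes = nrow(own),
      mean_sa = sample_antigenicity(own$sa),
      mean_sa_norm = sample_antigenicity(own$sa_norm),
      stringsAsFactors = FALSE)
  }
  sample_sa <- if (length(sample_rows)) do.call(rbind, sample_rows) else
    data.frame(sample = character(), group = character(),
               purity = numeric(), n_genes = integer(),
               mean_sa = numeric(), mean_sa_norm = numeric())

  # per-gene differential agretopicity from cohort-mean normalized SA
  gene_da <- NULL
  if (config$mode == "differential" && nrow(gene_sa)) {
    mt <- tapply(gene_sa$sa_norm[gene_sa$group == "tumor"],
                 gene_sa$gene[gene_sa$group == "tumor"], mean)
    mn <- tapply(gene_sa$sa_norm[gene_sa$group == "normal"],
                 gene_sa$gene[gene_sa$group == "normal"], mean)
    genes <- sort(unique(gene_sa$gene))
    sa_t <- as.numeric(mt[genes]); sa_n <- as.numeric(mn[genes])
    gene_da <- data.frame(
      gene = genes, sa_t = sa_t, sa_n = sa_n,
      da = differential_agretopicity(sa_t, sa_n),
      stringsAsFactors = FALSE)
    gene_da <- gene_da[order(-ifelse(is.na(gene_da$da), -Inf,
                                     gene_da$da)), , drop = FALSE]
    rownames(gene_da) <- NULL
  }

  stamp <- list(
    config_hash = sprintf("%012.0f",
                          string_hash(paste(deparse(config[setdiff(
                            names(config), c("vst", "predictor"))]),
                            collapse = ""))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("splicetope")))

  structure(list(
    junctions = junctions, transcripts = joined, scores = scores,
    genes_retained = genes_retained, k_total = k_total,
    binder_counts = binder_counts, gene_sa = gene_sa,
    sample_sa = sample_sa, gene_da = gene_da,
    excluded_samples = excluded, purity = purity,
    mode = config$mode, stamp = stamp, log = log
  ), class = "splicing_antigenicity")
}

#' @export
print.splicing_antigenicity <- function(x, ...) {
  cat("splicing_antigenicity (", x$mode, " mode)\n", sep = "")
  cat("  junctions:", nrow(x$junctions),
      "| joined transcripts:", length(x$transcripts),
      "| genes retained:", length(x$genes_retained), "\n")
  cat("  samples scored:", nrow(x$sample_sa),
      "| excluded (purity):", length(x$excluded_samples), "\n")
  if (!is.null(x$gene_da) && nrow(x$gene_da)) {
    top <- x$gene_da[!is.na(x$gene_da$da), , drop = FALSE]
    if (nrow(top))
      cat("  top gene by differential agretopicity:", top$gene[1],
          sprintf("(DA = %.2f)", top$da[1]), "\n")
  }
  invisible(x)
}

#' @export
summary.splicing_antigenicity <- function(object, ...) {
  s <- object$sample_sa
  out <- list(mode = object$mode,
              n_junctions = nrow(object$junctions),
              n_transcripts = length(object$transcripts),
              n_genes_retained = length(object$genes_retained),
              sample_sa = s)
  if (nrow(s) && length(unique(s$group)) == 2L) {
    t_v <- s$mean_sa_norm[s$group == "tumor"]
    n_v <- s$mean_sa_norm[s$group == "normal"]
    out$wilcoxon_p <- stats::wilcox.test(t_v, n_v)$p.value
    out$cohens_d <- tryCatch(cohens_d(t_v, n_v), error = function(e) NA)
  }
  class(out) <- "summary.splicing_antigenicity"
  out
}

#' @export
print.summary.splicing_antigenicity <- function(x, ...) {
  cat("splicing antigenicity summary (", x$mode, " mode)\n", sep = "")
  cat("  junctions:", x$n_junctions, "| transcripts:", x$n_transcripts,
      "| genes retained:", x$n_genes_retained, "\n")
  if (!is.null(x$wilcoxon_p)) {
    cat(sprintf("  tumor vs normal mean SA_norm: Wilcoxon p = %.3g, Cohen's d = %.2f\n",
                x$wilcoxon_p, x$cohens_d))
  }
  if (nrow(x$sample_sa)) {
    print(x$sample_sa, row.names = FALSE)
  }
  invisible(x)
}
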