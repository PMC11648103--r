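#' Pseudo tumor purity from ESTIMATE scores
#'
#' `P = 1 - estimate / (max + max * eps)` with eps the double-precision
#' machine epsilon (2.220446e-16). The offset keeps the cohort-maximum
#' sample strictly above zero purity. Samples with P <= 0.01 are flagged
#' for exclusion from antigenicity scoring.
#'
#' @param estimate Numeric vector of ESTIMATE scores (one per sample).
#' @param cohort_max Cohort maximum ESTIMATE score (default
#'   `max(estimate)`).
#' @param floor Exclusion floor on purity (default 0.01).
#' @return data.frame with `purity` and logical `excluded`.
#' @export
pseudo_purity <- function(estimate, cohort_max = max(estimate),
                          floor = 0.01) {
  if (cohort_max <= 0) stop("cohort_max must be positive")
  if (any(estimate > cohort_max)) stop("estimate exceeds cohort_max")
  eps <- 2.220446e-16
  p <- 1 - estimate / (cohort_max + cohort_max * eps)
  data.frame(purity = p, excluded = p <= floor)
}

#' Variance-stabilize junction counts
#'
#' Default transform `log2(count + 1)`: monotone, zero-preserving, and a
#' reasonable stand-in for model-based variance stabilization at
#' junction-count scale. Alternative transforms plug in via `transform`.
#'
#' @param counts Non-negative numeric vector or matrix of junction read
#'   counts.
#' @param transform Function applied elementwise (default
#'   `function(x) log2(x + 1)`).
#' @return Transformed counts, same shape as the input.
#' @export
variance_stabilize <- function(counts, transform = function(x) log2(x + 1)) {
  if (any(counts < 0)) stop("negative counts")
  transform(counts)
}

#' Per-gene splicing antigenicity
#'
#' `SA = ( sum_i R_i * k_group_i / k_i ) / |I|` over the gene's
#' group-specific junctions I: the stabilized read count of each
#' junction weighted by the fraction of its transcript's kmers that are
#' group-specific binders, averaged over the junction set. Junctions
#' with `k_i = 0` (no kmers at all) are excluded from I.
#'
#' @param r Stabilized read counts R_i for the gene's junctions (one
#'   sample).
#' @param k_group Group-specific binder counts per junction.
#' @param k_total Total kmer counts per junction.
#' @return The SA value (NA when no junction has kmers).
#' @export
gene_antigenicity <- function(r, k_group, k_total) {
  stopifnot(length(r) == length(k_group), length(r) == length(k_total))
  ok <- k_total > 0
  if (!any(ok)) return(NA_real_)
  if (any(k_group[ok] > k_total[ok])) stop("k_group exceeds k_total")
  sum(r[ok] * k_group[ok] / k_total[ok]) / sum(ok)
}

#' Purity-normalize a splicing antigenicity value
#'
#' @param sa Raw SA value(s).
#' @param purity Pseudo purity P in (0, 1]; samples at or below the
#'   exclusion floor should never reach this point.
#' @return `sa / purity`.
#' @export
normalize_antigenicity <- function(sa, purity) {
  if (any(purity <= 0)) stop("purity must be positive")
  sa / purity
}

#' Per-sample splicing antigenicity
#'
#' Arithmetic mean of a sample's per-gene SA values across the
#' splicing-impacted genes of the analysis.
#'
#' @param gene_sa Numeric vector of per-gene SA values for one sample
#'   (NAs dropped).
#' @return Mean SA; error when no gene is scored.
#' @export
sample_antigenicity <- function(gene_sa) {
  v <- gene_sa[!is.na(gene_sa)]
  if (length(v) == 0L) stop("no scored genes for sample")
  mean(v)
}

#' Differential agretopicity per gene
#'
#' `DA = log2(SA_T / SA_N)`: positive values mark genes whose
#' tumor-specific splicing is more antigenic than their normal-specific
#' splicing. Zero or missing SA on either side leaves DA missing (NA)
#' rather than zero-filled.
#'
#' @param sa_t,sa_n Tumor and normal splicing antigenicity (vectorised).
#' @return DA in bits, NA where undefined.
#' @export
differential_agretopicity <- function(sa_t, sa_n) {
  out <- rep(NA_real_, length(sa_t))
  ok <- !is.na(sa_t) & !is.na(sa_n) & sa_t > 0 & sa_n > 0
  out[ok] <- log2(sa_t[ok] / sa_n[ok])
  out
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean_a - mean_b) / s_p` with
#' `s_p = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return Effect size d; error when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(a) - mean(b)) / sp
}

#' Stratify samples by tumor mutational burden
#'
#' @param tmb Non-negative TMB values (nonsilent mutations per megabase).
#' @param threshold High/low boundary (default 10; the boundary itself is
#'   high).
#' @return Character vector of labels `"high"` / `"low"`.
#' @export
tmb_stratify <- function(tmb, threshold = 10) {
  if (any(tmb < 0)) stop("TMB must be non-negative")
  ifelse(tmb >= threshold, "high", "low")
}
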