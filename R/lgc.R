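#' GC fraction of a nucleotide sequence
#'
#' (G + C) / length. Ambiguous bases (N) count toward the length but not
#' the numerator.
#'
#' @param seq Non-empty nucleotide string.
#' @return GC fraction in [0, 1].
#' @export
gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  gc <- nchar(gsub("[^GCgc]", "", seq))
  gc / n
}

#' Stop-codon probability from the GC cubic
#'
#' Evaluates `f = a0 + a1*PGC + a2*PGC^2 + a3*PGC^3` and clamps the
#' result into [1e-9, 1 - 1e-9] so that downstream ORF probabilities and
#' their logs stay finite.
#'
#' @param pgc GC fraction in [0, 1] (vectorised).
#' @param coeffs Numeric vector of length 4: a0..a3.
#' @return Clamped per-codon stop probability.
#' @export
stop_probability <- function(pgc, coeffs) {
  stopifnot(length(coeffs) == 4L, all(pgc >= 0 & pgc <= 1))
  f <- coeffs[1] + coeffs[2] * pgc + coeffs[3] * pgc^2 + coeffs[4] * pgc^3
  eps <- 1e-9
  pmin(pmax(f, eps), 1 - eps)
}

#' Probability of an ORF of n sense codons
#'
#' Geometric form `P = (1 - f)^(n - 1) * f`: the chance of n - 1
#' non-stop codons followed by a stop, under per-codon stop probability
#' f. Strictly decreasing in n for fixed f in (0, 1).
#'
#' @param f Per-codon stop probability in (0, 1) (vectorised).
#' @param n Number of sense codons in the ORF (integer >= 1).
#' @return ORF probability.
#' @export
orf_probability <- function(f, n) {
  if (any(n < 1)) stop("n must be >= 1")
  (1 - f)^(n - 1) * f
}

#' Differential coding potential
#'
#' `L = log2(P_c / P_nc)`, the log-ratio of the ORF probability under the
#' coding-trained model to that under the noncoding-trained model.
#' Positive L marks coding-like transcripts.
#'
#' @param p_c,p_nc Positive ORF probabilities (vectorised).
#' @return L in bits; antisymmetric under swapping the two models.
#' @export
differential_coding_potential <- function(p_c, p_nc) {
  if (any(p_c <= 0) || any(p_nc <= 0)) stop("nonpositive ORF probability")
  log2(p_c / p_nc)
}

#' Default LGC coefficient sets
#'
#' Cubic stop-probability coefficients (a0..a3) for the coding-trained
#' and noncoding-trained models, fit with [fit_lgc_coefficients()] on the
#' package's seeded synthetic training corpus
#' (`lgc_synthetic_corpus(n_per_label = 400, seed = 20240101)`).
#' Scores are reproducible only relative to a stated coefficient set;
#' supply your own (e.g. fit on real transcripts) via the `coeffs`
#' argument of [score_coding()] or a coefficient file.
#'
#' @return List with numeric(4) elements `coding` and `noncoding`.
#' @export
lgc_default_coefficients <- function() {
  list(
    coding    = .lgc_default_coding,
    noncoding = .lgc_default_noncoding
  )
}

# frozen fit on lgc_synthetic_corpus(400, seed = 20240101); regenerated by
# fit_lgc_coefficients(lgc_synthetic_corpus(400, 20240101)) up to numeric noise
.lgc_default_coding    <- c(0.11939075896709425, -0.22736812058605099,
                            0.15889151315858502, -0.07715735922143238)
.lgc_default_noncoding <- c(0.09109904217298258, 0.08191329380203564,
                            -0.51975700139373460, 0.36416767256833282)

#' Synthetic training corpus for the LGC cubic
#'
#' Noncoding examples are i.i.d. base sequences over a gradient of GC
#' content; coding examples are constructed ORFs (start codon, sense
#' codons drawn with the same GC gradient, terminal stop), whose reading
#' frames deplete stop codons relative to the i.i.d. background.
#'
#' @param n_per_label Sequences per label.
#' @param seed RNG seed.
#' @param length_range Sequence length range in nt.
#' @return data.frame with columns `seq`, `label`.
#' @export
lgc_synthetic_corpus <- function(n_per_label = 400, seed = 1,
                                 length_range = c(300, 1500)) {
  stopifnot(n_per_label >= 50)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gc_targets <- stats::runif(2 * n_per_label, 0.25, 0.75)
  lens <- sample(seq(length_range[1], length_range[2]), 2 * n_per_label,
                 replace = TRUE)
  seqs <- character(2 * n_per_label)
  labels <- rep(c("noncoding", "coding"), each = n_per_label)
  sense <- names(codon_table)[codon_table != "*" & codon_table != "M"]
  sense_gc <- vapply(sense, gc_fraction, 0)
  for (i in seq_len(2 * n_per_label)) {
    p <- gc_targets[i]
    if (labels[i] == "noncoding") {
      probs <- c(A = (1 - p) / 2, C = p / 2, G = p / 2, T = (1 - p) / 2)
      seqs[i] <- paste(sample(names(probs), lens[i], replace = TRUE,
                              prob = probs), collapse = "")
    } else {
      n_codons <- max(10L, lens[i] %/% 3L - 2L)
      w <- exp(-((sense_gc - p) / 0.25)^2)  # bias codon usage toward target GC
      body <- sample(sense, n_codons, replace = TRUE, prob = w)
      seqs[i] <- paste0("ATG", paste(body, collapse = ""), "TAA")
    }
  }
  data.frame(seq = seqs, label = labels, stringsAsFactors = FALSE)
}

# empirical per-codon stop frequency: non-overlapping codons in all three
# frames of the sequence
empirical_stop_frequency <- function(seq) {
  n <- nchar(seq)
  total <- 0L
  stops <- 0L
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(seq, starts, starts + 2L)
    stops <- stops + sum(codons %in% c("TAA", "TAG", "TGA"))
    total <- total + length(codons)
  }
  c(f = stops / total, codons = total)
}

#' Fit LGC cubic coefficients from labelled transcripts
#'
#' For each label, computes per-transcript GC fraction and the empirical
#' per-codon stop frequency (non-overlapping codons over all three
#' frames), bins transcripts by GC, and fits the cubic
#' `f(PGC) = a0 + a1*PGC + a2*PGC^2 + a3*PGC^3` by weighted least
#' squares (weights = codons per bin).
#'
#' @param corpus data.frame with columns `seq` and
#'   `label` in {coding, noncoding}; at least 50 transcripts per label.
#' @param n_bins Number of GC bins (default 20).
#' @return List with numeric(4) coefficient vectors `coding` and
#'   `noncoding` (usable directly as [lgc_default_coefficients()]
#'   output).
#' @export
fit_lgc_coefficients <- function(corpus, n_bins = 20) {
  stopifnot(all(c("seq", "label") %in% names(corpus)))
  out <- list()
  for (lab in c("coding", "noncoding")) {
    sel <- corpus[corpus$label == lab, , drop = FALSE]
    if (nrow(sel) < 50) stop("need >= 50 transcripts for label ", lab)
    pgc <- vapply(sel$seq, gc_fraction, 0, USE.NAMES = FALSE)
    if (diff(range(pgc)) < 1e-8)
      stop("degenerate GC range for label ", lab)
    emp <- t(vapply(sel$seq, empirical_stop_frequency, c(f = 0, codons = 0),
                    USE.NAMES = FALSE))
    emp_f <- emp[, 1]; emp_n <- emp[, 2]
    bins <- cut(pgc, breaks = n_bins, include.lowest = TRUE)
    bw <- tapply(emp_n, bins, sum)
    # codon-weighted mean stop frequency and GC per bin
    bf <- tapply(emp_f * emp_n, bins, sum) / bw
    bg <- tapply(pgc * emp_n, bins, sum) / bw
    ok <- !is.na(bf)
    fit <- stats::lm(bf[ok] ~ bg[ok] + I(bg[ok]^2) + I(bg[ok]^3),
                     weights = bw[ok])
    out[[lab]] <- unname(stats::coef(fit))
  }
  out
}

#' Score the coding potential of joined transcripts
#'
#' For each joined transcript with a found ORF and a fused sequence of at
#' least `min_len` nucleotides, computes the GC fraction, the per-codon
#' stop probability under the coding and noncoding cubics, the ORF
#' probabilities (n = sense codons in the ORF, stop excluded) and the
#' differential coding potential L.
#'
#' @param joined List of `joined_transcript` objects.
#' @param coeffs Coefficient list as from [lgc_default_coefficients()].
#' @param min_len Minimum fused-transcript length to score (default 100
#'   nt); shorter transcripts appear in the output with `scored = FALSE`
#'   and NA scores.
#' @param gc_on Compute GC on the whole fused `"transcript"` (default) or
#'   the `"orf"` only.
#' @return data.frame: `junction`, `up_tx`, `down_tx`, `length`, `scored`,
#'   `pgc`, `n`, `p_c`, `p_nc`, `L`.
#' @export
score_coding <- function(joined, coeffs = lgc_default_coefficients(),
                         min_len = 100L,
                         gc_on = c("transcript", "orf")) {
  gc_on <- match.arg(gc_on)
  rows <- lapply(joined, function(jt) {
    len <- nchar(jt$seq)
    has_orf <- !is.null(jt$orf)
    scored <- has_orf && len >= min_len
    if (scored) {
      pgc <- gc_fraction(if (gc_on == "orf") jt$orf$seq else jt$seq)
      n <- nchar(jt$orf$seq) %/% 3L - 1L  # sense codons, stop excluded
      f_c <- stop_probability(pgc, coeffs$coding)
      f_nc <- stop_probability(pgc, coeffs$noncoding)
      p_c <- orf_probability(f_c, n)
      p_nc <- orf_probability(f_nc, n)
      L <- differential_coding_potential(p_c, p_nc)
    } else {
      pgc <- NA_real_; n <- NA_integer_
      p_c <- NA_real_; p_nc <- NA_real_; L <- NA_real_
    }
    data.frame(junction = jt$junction, up_tx = jt$up_tx,
               down_tx = jt$down_tx, length = len, scored = scored,
               pgc = pgc, n = n, p_c = p_c, p_nc = p_nc, L = L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    junction = character(), up_tx = character(), down_tx = character(),
    length = integer(), scored = logical(), pgc = numeric(),
    n = integer(), p_c = numeric(), p_nc = numeric(), L = numeric())
  rownames(out) <- NULL
  out
}

#' Retain genes with positive mean coding potential
#'
#' Genes are retained when the mean differential coding potential L over
#' their scored junction-modified transcripts is strictly greater than
#' zero. Unscored transcripts (too short, or no ORF) do not contribute.
#'
#' @param scores Output of [score_coding()].
#' @param gene_of Named character vector mapping junction key to gene.
#' @return Character vector of retained gene ids.
#' @export
filter_by_coding <- function(scores, gene_of) {
  sc <- scores[scores$scored, , drop = FALSE]
  if (nrow(sc) == 0L) return(character())
  gene <- unname(gene_of[sc$junction])
  mean_l <- tapply(sc$L, gene, mean)
  names(mean_l)[mean_l > 0]
}

#' Read / write an LGC coefficient file
#'
#' Small key-value format: lines `coding: a0 a1 a2 a3` and
#' `noncoding: a0 a1 a2 a3`.
#'
#' @param path File path.
#' @return `read_lgc_coefficients`: coefficient list;
#'   `write_lgc_coefficients`: invisibly, `path`.
#' @export
read_lgc_coefficients <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines[nzchar(lines)]) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    vals <- as.numeric(strsplit(trimws(parts[2]), "\\s+")[[1]])
    if (length(vals) != 4L || any(is.na(vals)))
      stop("bad coefficient line: ", ln)
    out[[key]] <- vals
  }
  if (!all(c("coding", "noncoding") %in% names(out)))
    stop("coefficient file must define coding and noncoding sets")
  out
}

#' @rdname read_lgc_coefficients
#' @param coeffs Coefficient list.
#' @export
write_lgc_coefficients <- function(coeffs, path) {
  writeLines(c(
    paste("coding:", paste(format(coeffs$coding, digits = 17),
                           collapse = " ")),
    paste("noncoding:", paste(format(coeffs$noncoding, digits = 17),
                              collapse = " "))), path)
  invisible(path)
}

# save/restore global RNG state so seeded generators do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
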