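#' Kmerize a protein sequence
#'
#' All contiguous substrings of each requested length, de-duplicated.
#' Kmers containing anything other than the 20 canonical residues
#' (e.g. X from an ambiguous codon) are excluded.
#'
#' @param protein Amino-acid string (or vector; kmers are pooled).
#' @param lengths Integer kmer lengths, a subset of 8..11 in MHC class-I
#'   practice (default 9, the modal class-I peptide length).
#' @return Character vector of unique kmers.
#' @export
kmerize <- function(protein, lengths = 9L) {
  out <- character()
  for (p in protein) {
    n <- nchar(p)
    for (k in lengths) {
      if (n < k) next
      starts <- seq_len(n - k + 1L)
      out <- c(out, substring(p, starts, starts + k - 1L))
    }
  }
  out <- unique(out)
  out[grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", out)]
}

#' Deterministic stub MHC-binding predictor
#'
#' A seeded hash of (kmer, allele) mapped to an IC50 in nmol/L:
#' a configurable fraction of pairs (default 2%) falls at or below the
#' 500 nmol/L binder threshold (log-uniform in [1, 500]); the rest are
#' log-uniform in (500, 50000]. The stub exists so that the filtering
#' and scoring stages can be exercised deterministically; real
#' predictors attach through the same contract (a function
#' `predict(kmers, alleles) -> data.frame(kmer, allele, ic50)`).
#'
#' @param seed Integer seed folded into the hash.
#' @param binder_fraction Fraction of (kmer, allele) pairs that are
#'   binders at 500 nmol/L.
#' @return A predictor function with signature `(kmers, alleles)`
#'   returning a data.frame `kmer`, `allele`, `ic50` covering every
#'   requested pair.
#' @export
stub_predictor <- function(seed = 1L, binder_fraction = 0.02) {
  force(seed); force(binder_fraction)
  function(kmers, alleles) {
    grid <- expand.grid(kmer = kmers, allele = alleles,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (nrow(grid) == 0L)
      return(data.frame(kmer = character(), allele = character(),
                        ic50 = numeric()))
    h <- string_hash(paste0(grid$kmer, "|", grid$allele))
    u1 <- hash_uniform(h, seed, 1L)
    u2 <- hash_uniform(h, seed, 2L)
    is_binder <- u1 < binder_fraction
    ic50 <- ifelse(is_binder,
                   10^(u2 * log10(500)),            # log-uniform [1, 500]
                   10^(log10(500) + u2 * (log10(50000) - log10(500))))
    ic50 <- pmax(ic50, 1)
    ic50[!is_binder] <- pmax(ic50[!is_binder], 500 * (1 + 1e-9))
    data.frame(kmer = grid$kmer, allele = grid$allele, ic50 = ic50,
               stringsAsFactors = FALSE)
  }
}

# vectorised polynomial rolling hash (mod 2^31 - 1), platform independent
string_hash <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric())
  width <- max(nchar(x))
  padded <- formatC(x, width = width, flag = "-")
  codes <- matrix(utf8ToInt(paste(padded, collapse = "")),
                  nrow = n, byrow = TRUE)
  m <- 2147483647
  h <- numeric(n)
  for (j in seq_len(width)) h <- (h * 31 + codes[, j]) %% m
  h
}

# deterministic uniform in [0,1) from a hash, a seed and a stream index
hash_uniform <- function(h, seed, stream) {
  m <- 2^31
  x <- (h * 2654435761 + (seed %% m) * 40503 + stream * 97 + 1) %% m
  x <- (x * 48271) %% 2147483647
  x / 2147483647
}

#' Call binders at an IC50 threshold
#'
#' A (kmer, allele) pair is a binder when its predicted IC50 is less
#' than or equal to the threshold (boundary inclusive, 500 nmol/L by
#' convention). A kmer is a binder for a genotype when it binds at least
#' one of the genotype's alleles.
#'
#' @param predictions data.frame `kmer`, `allele`, `ic50`.
#' @param threshold_nM IC50 threshold in nmol/L (default 500).
#' @param genotype Optional character vector of alleles; when given, the
#'   returned kmers are restricted to pairs involving those alleles.
#' @return Character vector of binder kmers.
#' @export
call_binders <- function(predictions, threshold_nM = 500,
                         genotype = NULL) {
  stopifnot(all(c("kmer", "allele", "ic50") %in% names(predictions)))
  if (any(predictions$ic50 <= 0)) stop("IC50 must be positive")
  sel <- predictions$ic50 <= threshold_nM
  if (!is.null(genotype)) {
    if (length(genotype) == 0L) return(character())
    sel <- sel & predictions$allele %in% genotype
  }
  unique(predictions$kmer[sel])
}

#' Cross-group binder filtering within an alternative event
#'
#' Within a junction cluster (the alternative-splicing event), tumor
#' binders that also occur among the kmers of the cluster's
#' normal-specific transcripts are removed, and symmetrically for normal
#' binders against tumor kmers. Outlier analyses skip this filter
#' entirely.
#'
#' @param tumor_binders,normal_binders Character vectors of binder kmers
#'   for one cluster.
#' @param tumor_kmers,normal_kmers Full kmer sets of the cluster's tumor
#'   and normal transcripts; default to the binder sets.
#' @return List with `tumor_specific` and `normal_specific` kmer vectors.
#' @export
filter_cross_group <- function(tumor_binders, normal_binders,
                               tumor_kmers = tumor_binders,
                               normal_kmers = normal_binders) {
  list(
    tumor_specific  = setdiff(tumor_binders, normal_kmers),
    normal_specific = setdiff(normal_binders, tumor_kmers)
  )
}

#' Kmerize a reference proteome
#'
#' @param proteome Character vector of protein sequences.
#' @param lengths Kmer lengths (same set as the query kmers).
#' @return Character vector of unique reference kmers.
#' @export
proteome_kmers <- function(proteome, lengths = 9L) {
  kmerize(proteome, lengths)
}

#' Remove binders present in the reference peptidome
#'
#' Exact substring membership against the kmerized reference proteome:
#' any binder found verbatim within a reference protein (at any of the
#' configured lengths) is discarded, so that only kmers spanning
#' non-reference sequence survive.
#'
#' @param binders Character vector of binder kmers.
#' @param proteome Character vector of reference proteins, or a
#'   pre-computed kmer set from [proteome_kmers()] (marked by
#'   `precomputed = TRUE`).
#' @param lengths Kmer lengths used for the reference kmerization.
#' @param precomputed Set TRUE when `proteome` is already a kmer set.
#' @return The surviving binders (subset of the input).
#' @export
filter_reference_peptidome <- function(binders, proteome, lengths = 9L,
                                       precomputed = FALSE) {
  ref <- if (precomputed) proteome else proteome_kmers(proteome, lengths)
  binders[!binders %in% ref]
}
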