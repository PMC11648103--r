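test_that("GC fraction counts G and C over the full length", {
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("AAAA"), 0)
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction("GCNN"), 0.5)   # N counts in the denominator
  expect_error(gc_fraction(""), "empty")
})

test_that("the stop-probability cubic evaluates and clamps", {
  expect_equal(stop_probability(0.3, c(0.2, 0, 0, 0)), 0.2)
  expect_equal(stop_probability(0, c(0.07, 1, 1, 1)), 0.07)
  expect_equal(stop_probability(0.5, c(0.1, -0.1, 0, 0)), 0.05)
  # clamping keeps f inside (0, 1)
  expect_equal(stop_probability(1, c(-5, 0, 0, 0)), 1e-9)
  expect_equal(stop_probability(1, c(5, 0, 0, 0)), 1 - 1e-9)
})

test_that("ORF probability has geometric form and normalizes", {
  expect_equal(orf_probability(0.37, 1), 0.37)
  expect_equal(orf_probability(0.05, 10), 0.95^9 * 0.05, tolerance = 1e-12)
  expect_equal(orf_probability(0.05, 10), 0.031512, tolerance = 1e-4)
  expect_error(orf_probability(0.1, 0), "n must be")
  # sum over n >= 1 equals 1 (to 1e-9, by partial sums)
  for (f in c(0.01, 0.1, 0.5)) {
    n_max <- ceiling(log(1e-12) / log(1 - f)) + 1
    expect_equal(sum(orf_probability(f, seq_len(n_max))), 1,
                 tolerance = 1e-9)
  }
  # strictly decreasing in n
  p <- orf_probability(0.2, 1:50)
  expect_true(all(diff(p) < 0))
})

test_that("differential coding potential is a log2 ratio, antisymmetric", {
  expect_equal(differential_coding_potential(0.2, 0.2), 0)
  expect_equal(differential_coding_potential(0.4, 0.2), 1)
  expect_equal(differential_coding_potential(0.03, 0.004), log2(7.5))
  expect_equal(differential_coding_potential(0.03, 0.004), 2.9069,
               tolerance = 1e-4)
  expect_equal(differential_coding_potential(0.1, 0.3),
               -differential_coding_potential(0.3, 0.1))
  expect_error(differential_coding_potential(0, 0.1), "nonpositive")
})

test_that("coefficient fitting recovers the i.i.d. base-composition cubic", {
  # under i.i.d. bases with GC fraction p (A/T and G/C symmetric), the
  # 64-codon enumeration gives stop probability
  # P(TAA) + P(TAG) + P(TGA) = (1-p)^2 (1+p) / 8, a cubic in p
  analytic <- function(p) (1 - p - p^2 + p^3) / 8
  expect_equal(analytic(0.5), 3 / 64)

  corpus <- lgc_synthetic_corpus(200, seed = 303)
  fit <- fit_lgc_coefficients(corpus)
  p <- seq(0.3, 0.7, by = 0.01)
  fitted <- stop_probability(p, fit$noncoding)
  expect_lt(sqrt(mean((fitted - analytic(p))^2)), 0.01)
  # uniform composition: fitted curve hits 3/64 at PGC = 0.5
  expect_lt(abs(stop_probability(0.5, fit$noncoding) - 3 / 64), 0.005)
  # coding-trained curve is stop-depleted relative to noncoding
  expect_true(all(stop_probability(p, fit$coding) <
                  stop_probability(p, fit$noncoding)))
})

test_that("a constant stop frequency fits a flat cubic", {
  # stop-free sequences (no T) over a GC gradient: f == 0 everywhere
  set.seed(404)
  seqs <- vapply(runif(120, 0.3, 0.7), function(p) {
    probs <- c(A = 1 - p, C = p / 2, G = p / 2)
    paste(sample(names(probs), 600, replace = TRUE, prob = probs),
          collapse = "")
  }, "")
  corpus <- data.frame(seq = rep(seqs, 2),
                       label = rep(c("coding", "noncoding"), each = 120))
  fit <- fit_lgc_coefficients(corpus)
  expect_equal(fit$noncoding[2:4], c(0, 0, 0), tolerance = 1e-6)
  expect_equal(fit$noncoding[1], 0, tolerance = 1e-6)
})

test_that("fitting validates its inputs", {
  corpus <- lgc_synthetic_corpus(60, seed = 1)
  expect_error(fit_lgc_coefficients(corpus[corpus$label == "coding", ]),
               ">= 50")
  same <- data.frame(seq = rep("ATGCATGCATGC", 60),
                     label = rep("coding", 60))
  same <- rbind(same, transform(same, label = "noncoding"))
  expect_error(fit_lgc_coefficients(same), "degenerate GC range")
})

test_that("default coefficients regenerate from the documented corpus", {
  fit <- fit_lgc_coefficients(lgc_synthetic_corpus(400, seed = 20240101))
  defaults <- lgc_default_coefficients()
  expect_equal(fit$coding, defaults$coding, tolerance = 1e-10)
  expect_equal(fit$noncoding, defaults$noncoding, tolerance = 1e-10)
})

test_that("coefficient files round-trip", {
  co <- lgc_default_coefficients()
  tf <- withr::local_tempfile()
  write_lgc_coefficients(co, tf)
  expect_equal(read_lgc_coefficients(tf), co, tolerance = 1e-15)
  writeLines("coding: 1 2 3", tf)
  expect_error(read_lgc_coefficients(tf), "bad coefficient line")
})

fake_joined <- function(junction, seq, orf_len_codons) {
  # a joined transcript whose ORF spans the first orf_len_codons + stop
  orf_seq <- substr(seq, 1, 3 * (orf_len_codons + 1))
  structure(list(junction = junction, up_tx = "U", down_tx = "D",
                 seq = seq, coding = TRUE,
                 orf = list(start = 1L, end = nchar(orf_seq),
                            seq = orf_seq),
                 protein = NA_character_, modification = ""),
            class = "joined_transcript")
}

test_that("short fusions are never scored; gene filter uses mean L", {
  set.seed(5)
  long_seq <- random_dna(300)
  short_seq <- random_dna(99)
  joined <- list(fake_joined("j1", long_seq, 40),
                 fake_joined("j2", short_seq, 20))
  sc <- score_coding(joined)
  expect_true(sc$scored[1])
  expect_false(sc$scored[2])
  expect_true(is.na(sc$L[2]))
  expect_equal(sc$n[1], 40L)

  scores <- data.frame(junction = c("a", "b", "c", "d"),
                       up_tx = "u", down_tx = "d", length = 200L,
                       scored = TRUE, pgc = 0.5, n = 50L,
                       p_c = 1, p_nc = 1,
                       L = c(1.0, -0.2, 0, 0))
  gene_of <- c(a = "G1", b = "G1", c = "G2", d = "G2")
  kept <- filter_by_coding(scores, gene_of)
  expect_equal(kept, "G1")   # mean(1, -0.2) > 0; mean(0, 0) is not > 0
})
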