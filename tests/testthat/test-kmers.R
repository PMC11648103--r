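# independent kmer oracle: positional loop with explicit de-duplication
oracle_kmers <- function(protein, k) {
  seen <- character()
  n <- nchar(protein)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      km <- substr(protein, i, i + k - 1)
      if (!km %in% seen) seen <- c(seen, km)
    }
  }
  seen[!grepl("[^ACDEFGHIKLMNPQRSTVWY]", seen)]
}

test_that("kmerization enumerates contiguous substrings uniquely", {
  expect_setequal(kmerize("MKLVN", 3), c("MKL", "KLV", "LVN"))
  expect_equal(kmerize("MK", 9), character())
  # kmers containing non-canonical residues are excluded
  expect_setequal(kmerize("MKXVNQWERT", 3),
                  setdiff(oracle_kmers("MKXVNQWERT", 3), NA))
  expect_false(any(grepl("X", kmerize("MXMKLVNPQ", 3))))
  # multiple lengths pool
  expect_setequal(kmerize("MKLVN", c(4, 5)),
                  c("MKLV", "KLVN", "MKLVN"))
})

test_that("kmerization equals brute-force enumeration on random proteins", {
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    p <- paste(sample(aa, 500, replace = TRUE), collapse = "")
    expect_setequal(kmerize(p, 9), oracle_kmers(p, 9))
    expect_lte(length(kmerize(p, 9)), 492)
  }
})

test_that("binder calling is boundary-inclusive at the IC50 threshold", {
  pred <- data.frame(kmer = c("AAA", "BBB", "CCC"),
                     allele = "A*02:01",
                     ic50 = c(450, 500, 501))
  expect_setequal(call_binders(pred, 500), c("AAA", "BBB"))
  expect_equal(call_binders(pred, 500, genotype = character()),
               character())
  expect_equal(call_binders(pred, 0), character())
  pred$ic50[1] <- -1
  expect_error(call_binders(pred, 500), "positive")
})

test_that("a kmer binds a genotype through any of its alleles", {
  pred <- data.frame(kmer = c("AAA", "AAA", "BBB"),
                     allele = c("A*02:01", "B*07:02", "C*07:01"),
                     ic50 = c(5000, 100, 100))
  expect_equal(call_binders(pred, 500, genotype = "A*02:01"), character())
  expect_equal(call_binders(pred, 500,
                            genotype = c("A*02:01", "B*07:02")), "AAA")
})

test_that("cross-group filtering removes shared binders symmetrically", {
  out <- filter_cross_group(c("X", "Y"), "Y")
  expect_equal(out$tumor_specific, "X")
  expect_equal(out$normal_specific, character())

  out2 <- filter_cross_group(c("A", "B"), c("C", "D"))
  expect_setequal(out2$tumor_specific, c("A", "B"))
  expect_setequal(out2$normal_specific, c("C", "D"))

  out3 <- filter_cross_group(c("A", "B"), c("A", "B"))
  expect_equal(out3$tumor_specific, character())
  expect_equal(out3$normal_specific, character())

  # filtering is against the other group's full kmer pool, not only its
  # binders
  out4 <- filter_cross_group("K", character(), normal_kmers = "K")
  expect_equal(out4$tumor_specific, character())
})

test_that("reference-peptidome filtering is exact substring membership", {
  proteome <- c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", "GGGGGGGGGG")
  inref <- substr(proteome[1], 5, 13)
  expect_equal(filter_reference_peptidome(inref, proteome, 9),
               character())
  novel <- "WWWWWWWWW"
  expect_equal(filter_reference_peptidome(c(inref, novel), proteome, 9),
               novel)
  expect_equal(filter_reference_peptidome(novel, character(), 9), novel)
})

test_that("reference filtering equals brute-force membership on 100 proteins", {
  set.seed(55)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  proteome <- vapply(1:100, function(i)
    paste(sample(aa, sample(30:80, 1), replace = TRUE), collapse = ""), "")
  queries <- c(
    vapply(1:50, function(i) {            # guaranteed hits
      p <- sample(proteome, 1)
      st <- sample(nchar(p) - 8, 1)
      substr(p, st, st + 8)
    }, ""),
    vapply(1:50, function(i)
      paste(sample(aa, 9, replace = TRUE), collapse = ""), ""))
  queries <- unique(queries)
  got <- filter_reference_peptidome(queries, proteome, 9)
  want <- queries[!vapply(queries, function(q)
    any(grepl(q, proteome, fixed = TRUE)), TRUE)]
  expect_setequal(got, want)
})

test_that("the stub predictor is deterministic and seed-sensitive", {
  pred1 <- stub_predictor(seed = 1)
  pred2 <- stub_predictor(seed = 2)
  kmers <- kmerize(paste(rep("MKLVNQWERT", 20), collapse = ""), 9)
  a <- pred1(kmers, c("A*02:01", "B*07:02"))
  b <- pred1(kmers, c("A*02:01", "B*07:02"))
  expect_identical(a, b)
  c_ <- pred2(kmers, c("A*02:01", "B*07:02"))
  expect_true(mean(a$ic50 == c_$ic50) < 0.01)
  expect_true(all(a$ic50 > 0))
  # full coverage of the request grid
  expect_equal(nrow(a), length(kmers) * 2)
})

test_that("the stub's binder fraction matches its configuration", {
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  kmers <- unique(vapply(1:10000, function(i)
    paste(sample(aa, 9, replace = TRUE), collapse = ""), ""))
  pred <- stub_predictor(seed = 3, binder_fraction = 0.02)
  out <- pred(kmers, "A*02:01")
  frac <- mean(out$ic50 <= 500)
  expect_equal(frac, 0.02, tolerance = 0.3)   # ~3 binomial SDs
  # distinct hashes: essentially no repeated IC50s
  expect_gt(length(unique(out$ic50)) / nrow(out), 0.99)
})

test_that("the filtering cascade is monotone", {
  set.seed(19)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  protein <- paste(sample(aa, 400, replace = TRUE), collapse = "")
  kmers <- kmerize(protein, 9)
  pred <- stub_predictor(seed = 4, binder_fraction = 0.2)
  out <- pred(kmers, c("A*02:01", "B*07:02"))
  binders <- call_binders(out, 500)
  expect_lte(length(binders), length(kmers))
  crossed <- filter_cross_group(binders, binders[1:5])$tumor_specific
  expect_lte(length(crossed), length(binders))
  proteome <- substr(protein, 1, 120)
  final <- filter_reference_peptidome(crossed, proteome, 9)
  expect_lte(length(final), length(crossed))
  expect_true(all(final %in% binders))
})
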