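test_that("PWM cells follow the log-likelihood formula", {
  bg <- uniform_background()
  # N = 1, alpha = 0: observed cells log2(20), the rest floored at -10
  m1 <- build_pwm("ACDEFGHSIKLMNPQ", bg, alpha = 0)
  expect_equal(m1$matrix["A", "-7"], log2(20), tolerance = 1e-12)
  expect_equal(m1$matrix["S", "0"], log2(20), tolerance = 1e-12)
  expect_identical(m1$matrix["C", "-7"], -10)
  # N = 2 agreeing on S at the centre: log2(2 / (2 * 0.05)) = log2(20)
  m2 <- build_pwm(c("ACDEFGHSIKLMNPQ", "CDEFGHISKLMNPQR"), bg, 0)
  expect_equal(m2$matrix["S", "0"], log2(20), tolerance = 1e-12)
  # N = 2 disagreeing (S vs T at position +1): count 1 of 2 -> log2(10)
  expect_equal(m2$matrix["I", "1"], log2(10), tolerance = 1e-12)
  expect_error(build_pwm(character(0)), "zero peptides")
  expect_error(build_pwm("ACDEFGHSIKLMNPQ", bg, alpha = -1), "alpha")
})

test_that("padding columns renormalize over observed residues", {
  bg <- uniform_background()
  m <- build_pwm(c("_______SAAAAAAA", "C______SAAAAAAA"), bg, alpha = 0)
  # position -7 has one observed residue (C): count 1, N_obs 1
  expect_equal(m$matrix["C", "-7"], log2(1 / 0.05), tolerance = 1e-12)
  # position -6: no observations at all -> floor everywhere
  expect_true(all(m$matrix[, "-6"] == -10))
})

test_that("profile reconstruction: columns sum to 1 under the background", {
  set.seed(21)
  peps <- replicate(12, rand_peptide())
  for (bg in list(uniform_background(), pooled_background(peps))) {
    m <- build_pwm(peps, bg, alpha = 0.5)
    probs <- 2^m$matrix * bg
    expect_equal(unname(colSums(probs)), rep(1, 15), tolerance = 1e-9)
  }
})

test_that("pwm_score sums positional log-likelihoods, skipping padding", {
  bg <- uniform_background()
  m <- build_pwm("ACDEFGHSIKLMNPQ", bg, 0)
  expect_equal(pwm_score(m, "ACDEFGHSIKLMNPQ"), 15 * log2(20),
               tolerance = 1e-10)
  expect_identical(pwm_score(m, strrep("_", 15)), 0)
  # an all-uniform profile scores every peptide 0
  flat <- build_pwm(replicate(40, rand_peptide("S")), bg, 0)
  flat$matrix[] <- 0
  expect_identical(pwm_score(flat, "ACDEFGHSIKLMNPQ"), 0)
  expect_error(pwm_score(m, "SHORT"), "15 characters")
})

test_that("a PWM built from one peptide is maximized by that peptide", {
  set.seed(22)
  for (i in 1:5) {
    p <- rand_peptide()
    m <- build_pwm(rep(p, 3), uniform_background(), alpha = 0)
    best <- pwm_score(m, p)
    for (j in 1:20) expect_lte(pwm_score(m, rand_peptide()), best)
  }
})

test_that("blosum similarity matches hand-computed diagonal sums", {
  expect_identical(blosum_similarity("AAAAAAASAAAAAAA", "AAAAAAASAAAAAAA"),
                   14L * 4L + 4L)
  expect_identical(blosum_similarity("_______SAAAAAAA", "AAAAAAASAAAAAAA"),
                   0L)
  expect_identical(blosum_similarity("AAAAAAASAAAAAAA", "AAAAAAAS_______"),
                   0L)
  set.seed(23)
  for (i in 1:25) {
    s1 <- rand_peptide(); s2 <- rand_peptide("T")
    v <- blosum_similarity(s1, s2)
    expect_identical(v, blosum_similarity(s2, s1))
    expect_true(is.integer(v))
  }
})

test_that("bundled BLOSUM62 matches the Biostrings reference on AA20", {
  skip_if_not_installed("Biostrings")
  ref <- get(data("BLOSUM62", package = "Biostrings",
                  envir = environment()), envir = environment())
  aa <- kspnet:::AA20
  expect_identical(unname(blosum62()[aa, aa]), unname(ref[aa, aa]))
})

test_that("CBS neighbourhood size, fractions and tie-breaks", {
  expect_identical(kspnet:::cbs_k(40, 0.075), 3L)     # round(3.0)
  expect_identical(kspnet:::cbs_k(5, 0.075), 1L)      # floor at 1
  expect_identical(kspnet:::cbs_k(100, 0.075), 8L)    # half-up: 7.5 -> 8

  set.seed(24)
  # corpus where K1 owns every neighbour of the query
  q <- rand_peptide()
  near <- vapply(1:5, function(i) {
    p <- q; substr(p, i, i) <- "A"; p
  }, character(1))
  far <- replicate(35, rand_peptide("Y"))
  corpus <- build_cbs_corpus(toy_pairs(list(K1 = unique(c(near, q)),
                                            K2 = far)))
  sc <- cbs_score(corpus, q, k_fraction = 0.075)
  expect_identical(names(sc), "K1")
  expect_identical(unname(sc), 1)

  # fractions are counts / k
  sc2 <- cbs_score(corpus, q, k_fraction = 10 / nrow(corpus))
  expect_equal(sum(sc2), 1)
  expect_true(all(sc2 >= 0 & sc2 <= 1))

  # truncated-flank query: similarity 0 everywhere, warning emitted
  expect_warning(sc3 <- cbs_score(corpus, "_______SAAAAAAA", 0.075),
                 "truncated")
  expect_equal(sum(sc3), 1)
  expect_error(cbs_score(corpus, q, k_fraction = 0), "k_fraction")
})

test_that("CBS scores sum to 1 for any query", {
  set.seed(25)
  corpus <- build_cbs_corpus(toy_pairs(list(
    K1 = replicate(20, rand_peptide()),
    K2 = replicate(20, rand_peptide("T")),
    K3 = replicate(20, rand_peptide("Y")))))
  for (i in 1:10)
    expect_equal(sum(cbs_score(corpus, rand_peptide())), 1)
})

test_that("sequence ranking orders by score with lexicographic ties", {
  set.seed(26)
  peps <- replicate(18, rand_peptide())
  models <- list(K1 = build_pwm(peps, alpha = 0.1, kinase_id = "K1"))
  corpus <- build_cbs_corpus(toy_pairs(list(K1 = peps)))
  rk <- rank_kinases_sequence(models, corpus, rand_peptide())
  expect_identical(rk$pwm$kinase_id, "K1")  # single model ranks first
  expect_identical(rk$cbs$kinase_id, "K1")

  # equal CBS scores -> lexicographic order
  sc <- c(B = 0.5, A = 0.5)
  dt <- data.table::data.table(kinase_id = names(sc), score = unname(sc))
  expect_identical(kspnet:::rank_candidates(dt, 10)$kinase_id, c("A", "B"))
})

test_that("PWM models round-trip through TSV + JSON sidecar", {
  set.seed(27)
  peps <- replicate(17, rand_peptide())
  m <- build_pwm(peps, alpha = 0.25, kinase_id = "K9")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(m, f)
  back <- read_pwm(f)
  expect_equal(back$matrix, m$matrix, tolerance = 1e-12)
  expect_equal(back$background, m$background, tolerance = 1e-12)
  expect_identical(back$kinase_id, "K9")
  expect_identical(back$n_sites, m$n_sites)
  set.seed(28)
  q <- rand_peptide()
  expect_equal(pwm_score(back, q), pwm_score(m, q), tolerance = 1e-12)
})

test_that("train_pwms applies the site filter and shares the background", {
  set.seed(29)
  pairs <- toy_pairs(list(K1 = replicate(20, rand_peptide()),
                          K2 = replicate(8, rand_peptide())))
  models <- train_pwms(pairs, min_sites = 15)
  expect_identical(names(models), "K1")
  models2 <- train_pwms(pairs, min_sites = 5)
  expect_identical(names(models2), c("K1", "K2"))
  expect_identical(models2$K1$background, models2$K2$background)
  expect_error(train_pwms(pairs, min_sites = 50), "no kinase")
})
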