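curve20 <- build_curve(20)

test_that("segment emission probabilities take their closed-form values", {
  prof_hom <- nucleotide_profile("AAAA")
  expect_equal(f0("A", 45, prof_hom, curve20), 1)
  prof_mix <- nucleotide_profile("ACGT")
  expect_equal(f0("A", 20, prof_mix, curve20), 0.125) # 0.5 * 0.25
  expect_equal(f0("A", 0, prof_mix, curve20), 1e-30) # floored
  expect_equal(f1_quality(0, curve20), 0.25)
  expect_equal(f1_quality(20, curve20), 0.125)
  expect_equal(f1_quality(45, curve20), 1e-30)
  expect_equal(f1_polyN("A", 45, "A", curve20), 1)
  expect_equal(f1_polyN("C", 0, "A", curve20), 0.25)
  expect_equal(f1_polyN("A", 20, "A", curve20), 0.5)
  expect_error(f1_polyN("A", 20, "X", curve20), "poly-N letter")
})

test_that("nucleotide profile is the empirical frequency over the IUPAC alphabet", {
  p <- nucleotide_profile("AACGN")
  expect_equal(sum(p), 1)
  expect_equal(unname(p["A"]), 0.4)
  expect_equal(unname(p["N"]), 0.2)
  expect_error(nucleotide_profile("AXQ"), "IUPAC")
  expect_error(nucleotide_profile(""), "empty")
})

test_that("cut log-likelihood matches the naive oracle at every k", {
  # single-nucleotide read: empty tail contributes nothing
  expect_equal(loglik_at_cut("A", 45L, 1, curve20), 0)
  # homogeneous maximal-quality read: -m log m
  m <- 8
  expect_equal(loglik_at_cut(strrep("A", m), rep(45L, m), m, curve20), -m * log(m))
  set.seed(101)
  for (i in 1:15) {
    r <- random_read(sample(2:25, 1))
    s <- paste(r$chars, collapse = "")
    for (k in seq_along(r$chars)) {
      expect_equal(
        loglik_at_cut(s, r$qual, k, curve20),
        oracle_loglik(r$chars, r$qual, k, curve20)
      )
      expect_equal(
        loglik_at_cut(s, r$qual, k, curve20, polyN = "A"),
        oracle_loglik(r$chars, r$qual, k, curve20, polyN = "A")
      )
    }
  }
  expect_error(loglik_at_cut("ACGT", rep(40L, 4), 5, curve20), "outside")
})

test_that("tail cut-point matches frozen step-profile cases", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  # uniformly excellent quality: keep everything
  expect_equal(estimate_tail_cut(s, rep(45L, 50), curve20), 50)
  # 25 nt at q40 then 25 nt at q2: cut exactly at the step
  expect_equal(estimate_tail_cut(s, c(rep(40L, 25), rep(2L, 25)), curve20), 25)
  # fully uninformative read degenerates to the smallest segment
  expect_equal(estimate_tail_cut(substr(s, 1, 10), rep(0L, 10), curve20), 1)
})

test_that("head cut-point mirrors the tail search on [1, k1]", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  expect_equal(estimate_head_cut(s, rep(45L, 50), 50, curve20), 1)
  expect_equal(
    estimate_head_cut(s, c(rep(2L, 5), rep(40L, 45)), 50, curve20), 6
  )
})

test_that("production cuts equal exhaustive naive search on random reads", {
  set.seed(202)
  for (i in 1:120) {
    r <- random_read(sample(2:28, 1))
    s <- paste(r$chars, collapse = "")
    for (polyN in list(NULL, "A")) {
      k1 <- estimate_tail_cut(s, r$qual, curve20, polyN = polyN)
      expect_identical(k1, oracle_k1(r$chars, r$qual, curve20, polyN))
      # reverse-and-reuse head estimate equals the direct head formulation
      expect_identical(
        estimate_head_cut(s, r$qual, k1, curve20, polyN = polyN),
        oracle_k2_direct(r$chars, r$qual, k1, curve20, polyN)
      )
    }
  }
})

test_that("argmax ties keep the most nucleotides", {
  # poly-A model on an all-A max-quality read: f0 = f1 = 1 everywhere, so
  # the likelihood depends only on the segment-size normalizers and ties
  # appear between cuts splitting equally.  m = 3 ties k in {1, 2}.
  expect_equal(estimate_tail_cut("AAA", rep(45L, 3), curve20, polyN = "A"), 2)
  # mirrored search resolves the same tie toward the smallest k2
  expect_equal(estimate_head_cut("AAA", rep(45L, 3), 3, curve20, polyN = "A"), 2)
})

test_that("segment_read fits both cuts in order and its methods are coherent", {
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  q <- c(rep(2L, 5), rep(40L, 40), rep(2L, 5))
  fit <- segment_read(s, q, t = 20)
  expect_s3_class(fit, "read_segmentation")
  expect_equal(unname(coef(fit)), c(6, 45))
  expect_equal(fit$loglik_tail, vapply(
    1:50, function(k) loglik_at_cut(s, q, k, curve20), 0
  ))
  expect_equal(as.numeric(logLik(fit)), fit$loglik_head[fit$k2])
  out <- capture.output(print(fit))
  expect_match(out, "retained \\[6, 45\\]")
  smry <- summary(fit)
  expect_equal(smry$retained, 40)
  expect_gt(smry$mean_q_retained, smry$mean_q_trimmed)
  expect_error(segment_read("", integer(0)), "empty")
})

test_that("trimming returns the contiguous retained substring", {
  set.seed(77)
  for (i in 1:25) {
    r <- random_read(sample(3:40, 1), with_n = FALSE)
    s <- paste(r$chars, collapse = "")
    tr <- trim_read(s, r$qual, t = 20)
    expect_true(tr$kept)
    expect_identical(tr$sequence, substr(s, tr$k2, tr$k1))
    expect_identical(tr$quality, r$qual[tr$k2:tr$k1])
  }
})

test_that("trim_read honours the minimum-length filter and degenerate reads", {
  s10 <- strrep("A", 10)
  tr <- trim_read(s10, rep(0L, 10), t = 20, min_length = 2)
  expect_false(tr$kept) # best informative segment is 1 nt
  tr <- trim_read(s10, rep(45L, 10), t = 20)
  expect_true(tr$kept)
  expect_equal(c(tr$k2, tr$k1), c(1, 10))
  empty <- trim_read("", integer(0))
  expect_false(empty$kept)
  expect_identical(empty$sequence, "")
})

test_that("poly-N trimming removes moderate-quality homopolymer ends", {
  set.seed(5)
  core <- paste(sample(c("C", "G", "T"), 40, TRUE), collapse = "")
  # 40 nt random (q40) + 20 nt poly-A (q30): the letter-aware model cuts
  # exactly at the homopolymer block despite its moderate quality
  s <- paste0(core, strrep("A", 20))
  q <- c(rep(40L, 40), rep(30L, 20))
  tr <- trim_polyN(s, q, "A", t = 20)
  expect_equal(tr$k1, 40)
  # 20 nt poly-T (q35) + 40 nt random: k2 lands after the block
  core2 <- paste(sample(c("A", "C", "G"), 40, TRUE), collapse = "")
  s2 <- paste0(strrep("T", 20), core2)
  q2 <- c(rep(35L, 20), rep(40L, 40))
  expect_equal(trim_polyN(s2, q2, "T", t = 20)$k2, 21)
  # no homopolymer at the extremities and maximal quality: full read kept
  tr3 <- trim_polyN(core, rep(45L, 40), "A", t = 20)
  expect_equal(c(tr3$k2, tr3$k1), c(1, 40))
})

test_that("planted step profiles are recovered within one position", {
  prof <- sim_profile(
    m = 50, k2 = 6, k1 = 45, q_low_head = 2, q_high = 40,
    q_low_tail = 2, q_sd = 0
  )
  set.seed(303)
  hits <- 0L
  n <- 300L
  for (i in seq_len(n)) {
    r <- simulate_read(prof, seed = NULL)
    tr <- trim_read(r$sequence, r$quality, curve = curve20)
    if (abs(tr$k2 - 6) <= 1 && abs(tr$k1 - 45) <= 1) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("segmentation is deterministic", {
  set.seed(13)
  r <- random_read(60)
  s <- paste(r$chars, collapse = "")
  f1 <- segment_read(s, r$qual, t = 20)
  f2 <- segment_read(s, r$qual, t = 20)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loglik_tail, f2$loglik_tail)
})
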