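test_that("hypergeometric overlap matches brute-force enumeration", {
  ov <- hypergeometric_overlap(10, 20, 30, 100)
  expect_equal(ov$expected, 6)
  expect_equal(ov$representation_factor, 10 / 6)
  oracle <- brute_hyper(10, 20, 30, 100)
  expect_equal(ov$p_over, oracle$p_over, tolerance = 1e-12)
  expect_equal(ov$p_under, oracle$p_under, tolerance = 1e-12)

  # overlap exactly at expectation
  ov <- hypergeometric_overlap(1, 10, 10, 100)
  expect_equal(ov$expected, 1)
  expect_equal(ov$representation_factor, 1)

  # certain overlap: the second list is the whole universe
  ov <- hypergeometric_overlap(12, 12, 50, 50)
  expect_equal(ov$representation_factor, 1)
  expect_equal(ov$p_over, 1)
})

test_that("infeasible overlap configurations error", {
  expect_error(hypergeometric_overlap(11, 10, 30, 100), "infeasible")
  expect_error(hypergeometric_overlap(0, 80, 80, 100), "infeasible") # x < lower bound
  expect_error(hypergeometric_overlap(1, 10, 10, 0), "universe")
  expect_error(hypergeometric_overlap(1, 101, 10, 100), "list sizes")
})

test_that("p_over decreases in x and RF times expected recovers x", {
  p_prev <- 1
  for (x in 0:20) {
    ov <- hypergeometric_overlap(x, 20, 30, 100)
    expect_lte(ov$p_over, p_prev + 1e-12)
    p_prev <- ov$p_over
    expect_equal(ov$representation_factor * ov$expected, x, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact tails at moderate sizes", {
  for (N in c(2000, 5000)) {
    n1 <- round(0.2 * N); n2 <- round(0.3 * N)
    mu <- n1 * n2 / N
    for (x in round(mu + c(-2, 0, 2) * sqrt(mu))) {
      e <- hypergeometric_overlap(x, n1, n2, N, "exact")
      a <- hypergeometric_overlap(x, n1, n2, N, "normal")
      expect_lt(abs(e$p_over - a$p_over), 0.01)
      expect_lt(abs(e$p_under - a$p_under), 0.01)
    }
  }
})

test_that("gene list intersection normalizes symbols", {
  expect_equal(intersect_lists(c("A", "B", "C"), c("B", "C", "D")),
               c("B", "C"))
  expect_length(intersect_lists(c("A"), c("B")), 0)
  expect_equal(intersect_lists("Cul2", "CUL2"), "CUL2")
})

test_that("movement patterns follow the significance flags", {
  m <- classify_movement(45.88953277, 36.94494826, 33.3796977,
                         sig_first = TRUE, sig_second = FALSE)
  expect_equal(m$pattern, "Down—same")
  m <- classify_movement(10.9300058, 12.60999224, 16.5514561,
                         sig_first = TRUE, sig_second = TRUE)
  expect_equal(m$pattern, "Up—up")
  expect_equal(classify_movement(5, 5, 5, FALSE, FALSE)$pattern, "Same—same")
  # a non-significant segment is Same regardless of the means
  expect_equal(classify_movement(10, 50, 10, FALSE, FALSE)$pattern,
               "Same—same")
  expect_error(classify_movement(5, 5, 9, TRUE, TRUE), "equal means")
})

test_that("movement classification is shift-invariant", {
  set.seed(9)
  for (i in 1:20) {
    v <- runif(3, 1, 50)
    sig <- runif(2) < 0.7
    base <- classify_movement(v[1], v[2], v[3], sig[1], sig[2])$pattern
    shifted <- classify_movement(v[1] + 100, v[2] + 100, v[3] + 100,
                                 sig[1], sig[2])$pattern
    expect_identical(shifted, base)
  }
})

test_that("consistent responders need opposite moves on addition vs withdrawal", {
  resp <- data.frame(
    gene = c("G1", "G1", "G1", "G2", "G2", "G3"),
    segment = c("B1H", "BH2", "H1B", "B1H", "H1B", "B1H"),
    direction = c("up", "up", "down", "up", "up", "down"))
  # G1: up on both additions, down on withdrawal -> included
  # G2: same direction on addition and withdrawal -> excluded
  # G3: single condition -> excluded
  expect_equal(consistent_responders(resp), "G1")
  # the mirrored orientation also qualifies
  flip <- resp; flip$direction <- ifelse(resp$direction == "up", "down", "up")
  expect_equal(consistent_responders(flip), "G1")
  expect_length(consistent_responders(resp[0, ]), 0)
})

test_that("arm sharing splits lists into specific and shared", {
  sh <- shared_between_arms(c("A", "B"), c("B", "C"))
  expect_equal(sh$specific_a, "A")
  expect_equal(sh$specific_b, "C")
  expect_equal(sh$shared, "B")
  expect_length(shared_between_arms(c("A"), c("B"))$shared, 0)
  expect_equal(shared_between_arms(c("A", "B"), c("b", "a"))$shared,
               c("A", "B"))
})

test_that("Welch t matches the textbook formulas", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5)
  got <- welch_t(x, y)
  # independent hand evaluation
  se2x <- var(x) / length(x); se2y <- var(y) / length(y)
  t_hand <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df_hand <- (se2x + se2y)^2 /
    (se2x^2 / (length(x) - 1) + se2y^2 / (length(y) - 1))
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, df_hand, tolerance = 1e-12)
  expect_equal(got$p, p_hand, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # p decreases monotonically as the separation grows
  ps <- vapply(c(5, 10, 20, 40), function(shift)
    welch_t(x + shift, y)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))

  expect_error(welch_t(c(1, 1, 1), y), "variance")
  expect_error(welch_t(1, y), "at least 2")
})

test_that("DBP comparisons validate arm/segment pairing and p range", {
  e <- data.frame(re_id = "chr1_1_2", gene = "G1", direction = "up",
                  empirical_p = 0.01)
  cmp <- dbp_comparison("B1HB2", "B1H", e)
  expect_s3_class(cmp, "dbp_comparison")
  expect_error(dbp_comparison("B1HB2", "H1B", e), "belongs to arm")
  bad <- e; bad$empirical_p <- 0.2
  expect_error(dbp_comparison("B1HB2", "B1H", bad), "0.05")
})
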