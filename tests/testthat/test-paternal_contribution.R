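test_that("contribution decomposition matches hand-evaluated cases", {
  pc <- compute_contribution(Z = 20, s = 30, o = 10)
  expect_equal(pc$Pc, 15)
  expect_equal(pc$Mc, 5)
  expect_false(pc$capped)

  # zygote above sperm + oocyte: contributions cap at the gamete abundances
  pc <- compute_contribution(Z = 100, s = 40, o = 10)
  expect_true(pc$capped)
  expect_equal(pc$Pc, 40)
  expect_equal(pc$Mc, 10)

  # symmetric gametes split the zygote in half
  expect_equal(compute_contribution(10, 7, 7)$Pc, 5)

  # absent oocyte: the formula limit assigns the whole zygote paternally
  pc <- compute_contribution(Z = 8, s = 10, o = 0)
  expect_equal(pc$Pc, 8)
  expect_equal(pc$Mc, 0)

  expect_error(compute_contribution(5, 0, 0), "undefined contribution")
  expect_equal(compute_contribution(0, 0, 0)$Pc, 0)
})

test_that("contribution conservation, equivariance and monotonicity hold", {
  set.seed(5)
  Z <- runif(500, 0, 120); s <- runif(500, 0, 60); o <- runif(500, 0, 60)
  pc <- compute_contribution(Z, s, o)
  expect_true(all(pc$Pc >= 0 & pc$Mc >= 0))
  # conservation on the uncapped branch
  i <- !pc$capped
  expect_lt(max(abs(pc$Pc[i] + pc$Mc[i] - Z[i]) / pmax(1, Z[i])), 1e-12)
  # capped branch returns the gamete abundances themselves
  expect_equal(pc$Pc[!i], s[!i])
  expect_equal(pc$Mc[!i], o[!i])
  # scale equivariance
  for (k in c(0.25, 3)) {
    pk <- compute_contribution(k * Z, k * s, k * o)
    expect_equal(pk$Pc, k * pc$Pc, tolerance = 1e-12)
    expect_equal(pk$Mc, k * pc$Mc, tolerance = 1e-12)
  }
  # Pc non-decreasing in s with Z, o fixed
  s_grid <- seq(0, 100, length.out = 40)
  pcs <- compute_contribution(rep(30, 40), s_grid, rep(12, 40))$Pc
  expect_true(all(diff(pcs) >= -1e-12))
})

test_that("fivefold rule uses strict inequalities at the printed thresholds", {
  expect_true(classify_fivefold(30, 1, 15))
  expect_false(classify_fivefold(25, 1, 15))  # sperm must exceed 25
  expect_false(classify_fivefold(30, 5, 15))  # oocyte must be below 5
  expect_false(classify_fivefold(30, 1, 10))  # zygote must exceed 10
})

test_that("twofold rule combines the ratio and presence-floor clauses", {
  # Pc > 2 Mc with the zygote gate passed
  c1 <- compute_contribution(20, 15, 5)
  expect_true(classify_twofold(c1))
  # oocyte below the floor with sperm in (2, 25): the OR clause
  c2 <- data.frame(Z = 12, s = 4, o = 1.5, Pc = 4, Mc = 0, capped = TRUE)
  expect_true(classify_twofold(c2))
  # neither clause: ratio 6/5 and oocyte present
  c3 <- data.frame(Z = 12, s = 6, o = 3, Pc = 6, Mc = 5, capped = FALSE)
  expect_false(classify_twofold(c3))
  # zygote gate blocks everything
  expect_false(classify_twofold(compute_contribution(9, 8, 1)))
  # prior-set exclusion
  expect_false(classify_twofold(c1, excluded = TRUE))
})

test_that("classify_res recovers classes and flags from tissue matrices", {
  ids <- c("chr1_100_200", "chr1_300_400", "chr1_500_600", "chr1_700_800")
  # RE1 fivefold; RE2 twofold (ratio); RE3 sperm-specific twofold; RE4 none
  sperm <- make_am(c(40, 10, 10, 3), 3, "sperm", re_ids = ids)
  oocyte <- make_am(c(1, 3, 0.5, 3), 3, "oocyte", re_ids = ids)
  zygote <- make_am(c(30, 13, 12, 12), 3, "zygote", re_ids = ids)
  gm <- data.frame(re_id = ids, gene = c("GA", "GB", "GC", "GD"))
  cls <- classify_res(sperm, oocyte, zygote, gene_map = gm)
  expect_equal(cls$label,
               c("FIVEFOLD_PATERNAL", "TWOFOLD_PATERNAL",
                 "TWOFOLD_PATERNAL", "NONE"))
  expect_equal(cls$sperm_specific, c(TRUE, FALSE, TRUE, FALSE))

  # a supplied prior fivefold set is excluded from the twofold candidates
  cls2 <- classify_res(sperm, oocyte, zygote, gene_map = gm,
                       prior_5x = c("chr1_100_200", "chr1_300_400"))
  expect_equal(cls2$label[2], "NONE")
  expect_equal(cls2$excluded_reason[2], "prior_set")
  # the twofold set never intersects the prior fivefold set
  expect_length(intersect(cls2$re_id[cls2$label == "TWOFOLD_PATERNAL"],
                          c("chr1_100_200", "chr1_300_400")), 0)
})

test_that("undefined decompositions are excluded, not fatal, in classify_res", {
  ids <- c("chr1_1_2", "chr1_3_4")
  sperm <- make_am(c(0, 30), 3, "sperm", re_ids = ids)
  oocyte <- make_am(c(0, 1), 3, "oocyte", re_ids = ids)
  zygote <- make_am(c(12, 15), 3, "zygote", re_ids = ids)
  cls <- classify_res(sperm, oocyte, zygote)
  expect_equal(cls$excluded_reason[1], "undefined_contribution")
  expect_equal(cls$label, c("NONE", "FIVEFOLD_PATERNAL"))
})

test_that("gene rollup labels a gene from any of its REs", {
  cls <- data.frame(
    re_id = sprintf("chr1_%d_%d", 1:5, 2:6),
    gene = c("G1", "G1", "G1", "G2", NA),
    label = c("FIVEFOLD_PATERNAL", "NONE", "TWOFOLD_PATERNAL",
              "NONE", "FIVEFOLD_PATERNAL"),
    sperm_specific = c(FALSE, FALSE, TRUE, FALSE, TRUE))
  ag <- aggregate_to_rernas(cls)
  expect_equal(ag$fivefold, "G1")
  expect_equal(ag$twofold, "G1")   # a gene can sit in both lists
  expect_equal(ag$sperm_specific, "G1")
  expect_equal(ag$paternal, "G1")
  expect_equal(ag$n_dropped, 1)    # classified RE without a gene

  empty <- aggregate_to_rernas(cls[cls$label == "NONE", ])
  expect_length(empty$paternal, 0)
})

test_that("zygote-excess flags respect the presence gate", {
  ga <- data.frame(gene = c("A", "B", "C"),
                   sperm = c(8, 20, 3), zygote = c(12, 12, 4))
  expect_equal(zygote_excess(ga), "A")           # B: sperm higher; C: gated
  # gate on zygote only keeps C excluded too (zygote 4 < 5)
  expect_equal(zygote_excess(ga, gate_both = FALSE), "A")
})
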