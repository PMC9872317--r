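test_that("abundance simulation is deterministic and plants exact counts", {
  cfg <- sim_config(seed = 7, n_res = 1000)
  a <- simulate_abundances(cfg)
  b <- simulate_abundances(cfg)
  expect_identical(a, b)
  expect_equal(sum(a$truth$class == "fivefold"), 100)
  expect_equal(sum(a$truth$class == "twofold"), 100)
  expect_equal(sum(a$truth$class == "maternal"), 100)
  expect_false(identical(a$sperm$values,
                         simulate_abundances(sim_config(seed = 8))$sperm$values))
})

test_that("planted medians keep the configured margin from every threshold", {
  cfg <- sim_config(seed = 19, n_res = 800, margin = 0.2)
  sim <- simulate_abundances(cfg)
  th <- re_thresholds()
  s <- apply(sim$sperm$values, 1, median)
  o <- apply(sim$oocyte$values, 1, median)
  z <- apply(sim$zygote$values, 1, median)
  five <- sim$truth$class == "fivefold"
  expect_true(all(s[five] >= th$sperm_min_5x * 1.2))
  expect_true(all(o[five] <= th$oocyte_max_5x * 0.8))
  expect_true(all(z[five] >= th$zygote_min * 1.2))
  spec <- sim$truth$sperm_specific
  expect_true(all(o[spec] <= th$oocyte_absent * 0.8))
  expect_true(all(o[sim$truth$class %in% c("fivefold", "twofold") & !spec] >=
                    th$oocyte_absent * 1.2))
  two <- sim$truth$class == "twofold"
  two_ns <- two & !spec
  pc <- compute_contribution(z[two_ns], s[two_ns], o[two_ns])
  expect_true(all(pc$Pc / pc$Mc >= 2 * 1.2))
  # sperm-specific twofold REs satisfy the presence-floor clause with margin
  two_sp <- two & spec
  expect_true(all(s[two_sp] >= th$sperm_specific_2x_lower * 1.2 &
                    s[two_sp] <= th$sperm_specific_2x_upper * 0.8))
  expect_true(all(z[two] >= th$zygote_min * 1.2))
  # both contribution branches are exercised
  pc_all <- compute_contribution(z[!five], s[!five], o[!five])
  expect_gt(sum(pc_all$capped), 0)
  expect_gt(sum(!pc_all$capped), 0)
})

test_that("classifier recovers all planted labels at a comfortable margin", {
  cfg <- sim_config(seed = 99, n_res = 600, margin = 0.5)
  sim <- simulate_abundances(cfg)
  cls <- classify_res(sim$sperm, sim$oocyte, sim$zygote,
                      gene_map = sim$gene_map,
                      prior_maternal = sim$truth$re_id[
                        sim$truth$class == "maternal"])
  expect_identical(cls$label == "FIVEFOLD_PATERNAL",
                   sim$truth$class == "fivefold")
  expect_identical(cls$label == "TWOFOLD_PATERNAL",
                   sim$truth$class == "twofold")
  expect_identical(cls$sperm_specific, sim$truth$sperm_specific)
})

test_that("simulated data satisfy the reader invariants round-trip", {
  sim <- simulate_abundances(sim_config(seed = 3, n_res = 50))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(sim$sperm, f1, f2)
  back <- read_abundance(f1, f2)
  expect_identical(back$values, sim$sperm$values)
  expect_identical(format_re_id(parse_re_id(sim$truth$re_id)),
                   sim$truth$re_id)
})

test_that("DBP list simulation plants overlap and consistent responders", {
  cfg <- sim_config(seed = 23)
  sim <- simulate_abundances(cfg)
  dbp <- simulate_dbp_lists(cfg, sim)
  expect_setequal(names(dbp$comparisons), c("B1H", "H1B", "HB2", "BH2"))
  paternal <- unique(sim$truth$gene[sim$truth$class %in%
                                      c("fivefold", "twofold")])
  for (seg in names(dbp$comparisons)) {
    cmp <- dbp$comparisons[[seg]]
    expect_true(all(cmp$empirical_p > 0 & cmp$empirical_p <= 0.05))
    expect_setequal(intersect_lists(cmp$gene, paternal),
                    dbp$truth$overlap_genes[[seg]])
  }
  resp <- do.call(rbind, lapply(dbp$comparisons, function(x)
    x[, c("gene", "segment", "direction")]))
  expect_identical(consistent_responders(resp), dbp$truth$consistent)
  expect_gt(length(dbp$truth$consistent), 0)

  # planted representation factor approaches f * N / n2
  seg <- dbp$comparisons$B1H
  N <- length(unique(sim$truth$gene))
  n1 <- length(unique(seg$gene))
  n2 <- length(paternal)
  x <- length(intersect_lists(seg$gene, paternal))
  rf <- hypergeometric_overlap(x, n1, n2, N)$representation_factor
  f <- x / n1
  expect_equal(rf, f * N / n2, tolerance = 1e-9)

  # zero planted overlap gives disjoint lists
  cfg0 <- sim_config(seed = 23, dbp = list(n_per_segment = 80,
                                           overlap_frac = 0,
                                           frac_consistent = 0))
  dbp0 <- simulate_dbp_lists(cfg0, sim)
  expect_length(intersect_lists(dbp0$comparisons$B1H$gene, paternal), 0)
})

test_that("coverage simulation plants degraded tracks that fail as designed", {
  cfg <- sim_config(seed = 41)
  cov <- simulate_coverage(cfg)
  expect_length(cov$panel, 22)
  bad <- cov$truth$degraded_samples
  good <- setdiff(names(cov$tracks), bad)
  # a degraded track (decay over 60% of bases) fails the 50% coverage rule
  sm <- bad[1]
  deg_tx <- cov$truth$degraded[[sm]][1]
  expect_false(transcript_pass(cov$tracks[[sm]][[deg_tx]]))
  expect_true(transcript_pass(cov$tracks[[good[1]]][[deg_tx]]))
  # degraded samples score 1 - degrade_frac, good samples score 1
  tii <- lapply(cov$tracks, compute_tii, panel = cov$panel)
  scores <- vapply(tii, `[[`, numeric(1), "tii_score")
  expect_true(all(scores[good] == 1))
  n_deg <- round(cfg$coverage$degrade_frac * length(cov$panel))
  expect_equal(unname(scores[bad]),
               rep((length(cov$panel) - n_deg) / length(cov$panel),
                   length(bad)))
  # all-sample integrity on a degraded transcript is PARTIAL
  any_deg <- cov$truth$degraded[[bad[1]]][2]
  tracks_tx <- lapply(cov$tracks, `[[`, any_deg)
  expect_equal(call_integrity(unname(tracks_tx))$status, "PARTIAL")
})

test_that("GMT simulation plants one recoverable enriched set", {
  cfg <- sim_config(seed = 47)
  universe <- sprintf("U%04d", 1:2000)
  g <- simulate_gmt(cfg, universe)
  expect_length(g$collection, cfg$gmt$n_sets)
  expect_true(g$planted %in% names(g$collection))
  g2 <- simulate_gmt(sim_config(seed = 48), universe)
  expect_false(identical(g$collection, g2$collection))
  set.seed(1)
  query <- c(sample(g$planted_genes, 15),
             sample(setdiff(universe, g$planted_genes), 15))
  res <- ora(query, g$collection, universe)
  expect_equal(res$set_name[1], g$planted)
  expect_lt(res$q[1], 0.05)
})
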