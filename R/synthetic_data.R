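# Seeded synthetic-data generator with planted ground truth: log-normal
# RPKM abundance matrices with planted fivefold / twofold / sperm-specific
# / maternal RE classes at a configurable margin from every classification
# threshold, DBP-responsive lists with planted overlap fractions and
# consistent responders, exon coverage tracks with full-length vs degraded
# profiles, and GMT collections with one planted enriched set.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline targets: 7 sperm
#' samples and 3 oocyte / 3 zygote replicates; 10% of REs planted in each
#' of the fivefold-paternal, twofold-paternal and maternal classes (30% of
#' planted paternal REs sperm-specific); log-normal per-sample variation
#' around a planted per-tissue median; every planted quantity kept at a
#' relative margin `margin` from the classification threshold it must
#' clear, so threshold calls on the planted medians are unambiguous.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param n_res Number of REs.
#' @param n_genes Size of the gene pool REs map to.
#' @param n_sperm,n_oocyte,n_zygote Samples per tissue.
#' @param frac_fivefold,frac_twofold,frac_maternal Planted class fractions
#'   (the remainder is unclassified background).
#' @param frac_sperm_specific Fraction of each planted paternal class with
#'   oocyte abundance below the presence floor.
#' @param margin Relative distance of planted medians from every threshold
#'   (delta), default 0.2.
#' @param sigma Log-normal per-sample noise SD (log scale), default 0.25.
#' @param cap_rate Fraction of planted paternal REs whose zygote abundance
#'   is inflated above sperm + oocyte, exercising the capping branch.
#' @param thresholds An [re_thresholds()] object the margins are measured
#'   against.
#' @param dbp List: `n_per_segment` responsive REs per exposure segment,
#'   `overlap_frac` planted fraction overlapping the paternal gene list,
#'   `frac_consistent` fraction of the overlapping genes planted as
#'   consistent responders.
#' @param coverage List: `n_transcripts` panel size (default 22),
#'   `n_samples`, `n_degraded` poor-quality samples, `degrade_frac`
#'   fraction of panel transcripts degraded in a poor sample,
#'   `decay_fraction` fraction of bases a degraded track decays below
#'   threshold.
#' @param gmt List: `n_sets`, `set_size` (min, max), `planted_size`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_res = 1000L, n_genes = 250L,
                       n_sperm = 7L, n_oocyte = 3L, n_zygote = 3L,
                       frac_fivefold = 0.10, frac_twofold = 0.10,
                       frac_maternal = 0.10, frac_sperm_specific = 0.30,
                       margin = 0.2, sigma = 0.25, cap_rate = 0.05,
                       thresholds = re_thresholds(),
                       dbp = list(n_per_segment = 120L, overlap_frac = 0.8,
                                  frac_consistent = 0.2),
                       coverage = list(n_transcripts = 22L, n_samples = 8L,
                                       n_degraded = 2L, degrade_frac = 0.75,
                                       decay_fraction = 0.6),
                       gmt = list(n_sets = 50L, set_size = c(10L, 40L),
                                  planted_size = 30L)) {
  if (frac_fivefold + frac_twofold + frac_maternal > 1)
    stop("infeasible fractions: class fractions sum above 1")
  if (margin <= 0 || margin >= 1) stop("margin must lie in (0, 1)")
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(seed = as.integer(seed), n_res = as.integer(n_res),
                 n_genes = as.integer(n_genes), n_sperm = as.integer(n_sperm),
                 n_oocyte = as.integer(n_oocyte),
                 n_zygote = as.integer(n_zygote),
                 frac_fivefold = frac_fivefold, frac_twofold = frac_twofold,
                 frac_maternal = frac_maternal,
                 frac_sperm_specific = frac_sperm_specific,
                 margin = margin, sigma = sigma, cap_rate = cap_rate,
                 thresholds = thresholds, dbp = dbp, coverage = coverage,
                 gmt = gmt),
            class = "sim_config")
}

# per-sample values around a planted median: multiplicative log-normal
# noise, re-centred so the realised median equals the planted value exactly
.noisy_row <- function(med, n, sigma) {
  m <- exp(stats::rnorm(n, 0, sigma))
  med * m / stats::median(m)
}

#' Simulate sperm, oocyte and zygote abundance matrices with planted truth
#'
#' Plants four RE classes at per-tissue medians a relative margin away from
#' every classification threshold: fivefold-paternal (sperm above, oocyte
#' below, zygote above their thresholds), twofold-paternal (paternal/
#' maternal contribution ratio above `2 * (1 + margin)`, zygote gate
#' cleared, sperm safely below the fivefold bound), sperm-specific variants
#' of both (oocyte below the presence floor), maternal (high oocyte, trace
#' sperm), and background REs that clear no rule. Zygote medians that must
#' exceed sperm + oocyte to clear the gate take the capped branch of the
#' contribution model; an additional `cap_rate` fraction is inflated
#' deliberately. Per-sample values add log-normal noise re-centred so the
#' sample median equals the planted median exactly.
#'
#' @param cfg A [sim_config()].
#' @return List: `sperm`, `oocyte`, `zygote` ([abundance_matrix()]),
#'   `gene_map` (`re_id`, `gene`), `truth` (`re_id`, `gene`, `class`,
#'   `sperm_specific`), `config`.
#' @export
simulate_abundances <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  th <- cfg$thresholds
  d <- cfg$margin
  n <- cfg$n_res

  n5 <- round(cfg$frac_fivefold * n)
  n2 <- round(cfg$frac_twofold * n)
  nm <- round(cfg$frac_maternal * n)
  n0 <- n - n5 - n2 - nm
  if (n0 < 0) stop("infeasible fractions for n_res")
  class <- sample(rep(c("fivefold", "twofold", "maternal", "none"),
                      c(n5, n2, nm, n0)))

  chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
  start <- sample.int(2e8L, n)
  width <- sample(50:500, n, replace = TRUE)
  re_id <- sprintf("%s_%d_%d", chrom, start, start + width)
  if (anyDuplicated(re_id)) stop("internal: duplicate synthetic RE ids")
  gene <- sprintf("G%04d", sample.int(cfg$n_genes, n, replace = TRUE))

  specific <- rep(FALSE, n)
  s_med <- o_med <- z_med <- numeric(n)
  zg_hi <- function(k) th$zygote_min * (1 + d) * stats::runif(k, 1.05, 1.5)

  i5 <- which(class == "fivefold")
  if (length(i5)) {
    spec5 <- stats::runif(length(i5)) < cfg$frac_sperm_specific
    o_lo <- th$oocyte_absent * (1 + d)
    o_hi <- th$oocyte_max_5x * (1 - d)
    if (o_lo >= o_hi) spec5[] <- TRUE  # non-specific band closed at this margin
    specific[i5] <- spec5
    s_med[i5] <- th$sperm_min_5x * (1 + d) * stats::runif(length(i5), 1.05, 3)
    o_med[i5] <- ifelse(spec5,
                        stats::runif(length(i5), 0.02,
                                     th$oocyte_absent * (1 - d)),
                        stats::runif(length(i5), min(o_lo, o_hi), o_hi))
    z_med[i5] <- zg_hi(length(i5)) * stats::runif(length(i5), 1, 3)
  }

  i2 <- which(class == "twofold")
  if (length(i2)) {
    spec2 <- stats::runif(length(i2)) < cfg$frac_sperm_specific
    specific[i2] <- spec2
    # non-specific: ratio s/o comfortably above the fold threshold while
    # sperm stays below the fivefold bound
    r_lo <- th$fold_2x * (1 + d) * 1.1
    r_hi <- r_lo + 0.5
    o_lo <- th$oocyte_absent * (1 + d) + 0.05
    o_hi <- min(6, th$sperm_min_5x * (1 - d) * 0.95 / r_hi)
    if (o_hi <= o_lo)
      stop("infeasible margin: no oocyte band for non-specific twofold REs")
    r <- stats::runif(length(i2), r_lo, r_hi)
    o_ns <- stats::runif(length(i2), o_lo, o_hi)
    s_lo <- th$sperm_specific_2x_lower * (1 + d) * 1.05
    s_hi <- th$sperm_specific_2x_upper * (1 - d) * 0.95
    o_med[i2] <- ifelse(spec2,
                        stats::runif(length(i2), 0.02,
                                     th$oocyte_absent * (1 - d)),
                        o_ns)
    s_med[i2] <- ifelse(spec2, stats::runif(length(i2), s_lo, s_hi),
                        o_ns * r)
    # the zygote gate can force Z above s + o: that is the capped branch
    z_med[i2] <- pmax(s_med[i2] + o_med[i2], zg_hi(length(i2)))
  }

  im <- which(class == "maternal")
  if (length(im)) {
    o_med[im] <- th$sperm_min_5x * (1 + d) * stats::runif(length(im), 1, 2)
    s_med[im] <- stats::runif(length(im), 0.02, th$oocyte_absent * (1 - d))
    z_med[im] <- zg_hi(length(im)) * stats::runif(length(im), 1, 3)
  }

  i0 <- which(class == "none")
  if (length(i0)) {
    # half fail the zygote gate outright; half pass it with a mid ratio
    gated <- stats::runif(length(i0)) < 0.5
    o0 <- stats::runif(length(i0), th$oocyte_absent * (1 + d) + 0.05, 8)
    r0 <- stats::runif(length(i0), 0.3, th$fold_2x * (1 - d) / 1.05)
    s0 <- o0 * r0
    o_med[i0] <- o0
    s_med[i0] <- s0
    z_med[i0] <- ifelse(gated,
                        stats::runif(length(i0), 0.2, th$zygote_min * (1 - d)),
                        pmax(s0 + o0, zg_hi(length(i0))))
  }

  # deliberate capping-branch contamination among paternal REs
  pat <- which(class %in% c("fivefold", "twofold"))
  bump <- pat[stats::runif(length(pat)) < cfg$cap_rate]
  z_med[bump] <- pmax(z_med[bump],
                      (s_med[bump] + o_med[bump]) *
                        stats::runif(length(bump), 1.1, 1.4))

  mk <- function(meds, n_samp, tissue, prefix) {
    vals <- t(vapply(meds, .noisy_row, numeric(n_samp),
                     n = n_samp, sigma = cfg$sigma))
    dimnames(vals) <- list(re_id, sprintf("%s_%d", prefix, seq_len(n_samp)))
    abundance_matrix(vals, data.frame(
      sample_id = colnames(vals), tissue = tissue,
      study_arm = "none", visit = "none", stringsAsFactors = FALSE))
  }
  list(sperm = mk(s_med, cfg$n_sperm, "sperm", "sperm"),
       oocyte = mk(o_med, cfg$n_oocyte, "oocyte", "oocyte"),
       zygote = mk(z_med, cfg$n_zygote, "zygote", "zygote"),
       gene_map = data.frame(re_id = re_id, gene = gene,
                             stringsAsFactors = FALSE),
       truth = data.frame(re_id = re_id, gene = gene, class = class,
                          sperm_specific = specific,
                          stringsAsFactors = FALSE),
       config = cfg)
}

#' Simulate DBP-responsive RE lists for the four exposure segments
#'
#' Each segment's list contains a planted fraction of genes drawn from the
#' paternal gene list (the overlap), the rest from non-paternal genes, with
#' empirical p values Uniform(0, 0.05]. A planted subset of overlapping
#' genes is made consistent responders: present in every segment, moving in
#' one direction under DBP addition (B1H, BH2) and the opposite under
#' withdrawal (H1B, HB2). All other genes carry one fixed direction across
#' their segments, so they can never satisfy the consistency rule and the
#' planted set is recovered exactly.
#'
#' @param cfg A [sim_config()].
#' @param abund Output of [simulate_abundances()] (supplies the gene map
#'   and planted paternal classes).
#' @return List: `comparisons` (named list of [dbp_comparison()] data
#'   frames, one per segment), `truth` (list with `consistent` genes and
#'   per-segment `overlap_genes`).
#' @export
simulate_dbp_lists <- function(cfg, abund) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  truth <- abund$truth
  paternal <- sort(unique(truth$gene[truth$class %in% c("fivefold", "twofold")]))
  all_genes <- sort(unique(truth$gene))
  nonpat <- setdiff(all_genes, paternal)

  n_seg <- cfg$dbp$n_per_segment
  n_pat <- min(round(cfg$dbp$overlap_frac * n_seg), length(paternal))
  n_cons <- min(round(cfg$dbp$frac_consistent * n_pat), n_pat)
  cons <- if (n_cons > 0) sample(paternal, n_cons) else character(0)
  orient <- stats::setNames(sample(c("up", "down"), n_cons, replace = TRUE),
                            cons)
  other_dir <- stats::setNames(
    sample(c("up", "down"), length(all_genes), replace = TRUE), all_genes)

  arm_of <- c(B1H = "B1HB2", HB2 = "B1HB2", H1B = "H1BH2", BH2 = "H1BH2")
  pick_re <- function(genes) {
    vapply(genes, function(g) {
      res <- abund$gene_map$re_id[abund$gene_map$gene == g]
      if (length(res) == 1L) res else sample(res, 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  comparisons <- list()
  overlap_genes <- list()
  for (seg in re_segments) {
    fill_pat <- sample(setdiff(paternal, cons), max(0L, n_pat - n_cons))
    fill_non <- sample(nonpat, min(n_seg - n_pat, length(nonpat)))
    genes <- c(cons, fill_pat, fill_non)
    addition <- seg %in% dbp_addition_segments
    dir <- ifelse(genes %in% cons,
                  ifelse(rep(addition, length(genes)),
                         orient[genes], ifelse(orient[genes] == "up",
                                               "down", "up")),
                  other_dir[genes])
    comparisons[[seg]] <- dbp_comparison(
      arm_of[[seg]], seg,
      data.frame(re_id = pick_re(genes), gene = genes,
                 direction = unname(dir),
                 empirical_p = stats::runif(length(genes), 1e-6, 0.05),
                 stringsAsFactors = FALSE))
    overlap_genes[[seg]] <- sort(c(cons, fill_pat))
  }
  list(comparisons = comparisons,
       truth = list(consistent = sort(cons), overlap_genes = overlap_genes))
}

#' Simulate exon coverage tracks with planted degraded samples
#'
#' Builds a stable-transcript panel (default 22 transcripts) and per-sample
#' coverage tracks. Good samples cover every panel transcript above
#' threshold at the configured margin; planted poor-quality samples have
#' `degrade_frac` of their panel transcripts decayed 5' to 3' below
#' threshold over `decay_fraction` of their bases, so those transcripts
#' fail the 50%-coverage rule and the sample's TII score drops to
#' `1 - degrade_frac`.
#'
#' @param cfg A [sim_config()].
#' @param rpm_threshold Depth threshold the profiles are built around,
#'   default 5.
#' @return List: `tracks` (named list per sample of [coverage_track()]
#'   lists), `panel` (transcript ids), `transcripts` (exon models with
#'   `transcript_id`, `chrom`, `start`, `end`), `truth` (list with
#'   `degraded_samples` and per-sample degraded transcript ids).
#' @export
simulate_coverage <- function(cfg, rpm_threshold = 5) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  cv <- cfg$coverage
  d <- cfg$margin
  panel <- sprintf("TX%02d", seq_len(cv$n_transcripts))
  exons <- lapply(panel, function(tx) {
    n_ex <- sample(2:4, 1L)
    widths <- sample(100:400, n_ex, replace = TRUE)
    gaps <- sample(200:1000, n_ex, replace = TRUE)
    starts <- sample.int(1e6L, 1L) +
      cumsum(gaps) + c(0L, cumsum(widths[-n_ex]))
    data.frame(start = starts, end = starts + widths - 1L)
  })
  names(exons) <- panel

  samples <- sprintf("cov_%d", seq_len(cv$n_samples))
  bad <- sample(samples, cv$n_degraded)
  n_deg_tx <- round(cv$degrade_frac * cv$n_transcripts)

  full_depth <- function(L)
    stats::runif(L, rpm_threshold * (1 + d), rpm_threshold * 3)
  degraded_depth <- function(L) {
    keep <- floor((1 - cv$decay_fraction) * L)
    c(full_depth(keep),
      seq(rpm_threshold * (1 - d), 0.01, length.out = L - keep))
  }

  degraded_tx <- list()
  tracks <- lapply(samples, function(sm) {
    deg <- if (sm %in% bad) sample(panel, n_deg_tx) else character(0)
    degraded_tx[[sm]] <<- sort(deg)
    trs <- lapply(panel, function(tx) {
      ex <- exons[[tx]]
      L <- sum(ex$end - ex$start + 1L)
      depth <- if (tx %in% deg) degraded_depth(L) else full_depth(L)
      coverage_track(tx, sm, ex, depth, units = "RPM")
    })
    names(trs) <- panel
    trs
  })
  names(tracks) <- samples
  tx_table <- do.call(rbind, lapply(panel, function(tx)
    data.frame(transcript_id = tx, chrom = "chrS", exons[[tx]],
               stringsAsFactors = FALSE)))
  list(tracks = tracks, panel = panel, transcripts = tx_table,
       truth = list(degraded_samples = sort(bad), degraded = degraded_tx))
}

#' Simulate a GMT collection with one planted enriched set
#'
#' @param cfg A [sim_config()].
#' @param universe Character vector of gene symbols sets are drawn from.
#' @return List: `collection` (named list of sets), `planted` (name of the
#'   planted set), `planted_genes`.
#' @export
simulate_gmt <- function(cfg, universe) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  universe <- unique(normalize_symbols(universe))
  g <- cfg$gmt
  sizes <- sample(g$set_size[1]:g$set_size[2], g$n_sets, replace = TRUE)
  collection <- lapply(sizes, function(k) sample(universe, min(k, length(universe))))
  names(collection) <- sprintf("GENESET_%03d", seq_len(g$n_sets))
  planted <- sample(names(collection), 1L)
  collection[[planted]] <- sample(universe, min(g$planted_size,
                                                length(universe)))
  list(collection = collection, planted = planted,
       planted_genes = collection[[planted]])
}
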