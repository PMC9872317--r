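# Overlap of DBP-responsive RE/gene lists with paternally provided lists:
# hypergeometric overlap statistics and representation factors (exact or
# normal approximation), movement-pattern classification across the
# crossover-crossback segments, consistent-responder detection, arm
# sharing, and the Welch t test used for contribution fold changes.

# DBP addition vs withdrawal segments of the crossover-crossback design:
# B1H (background baseline -> high-DBP crossover) and BH2 (background
# crossover -> high-DBP crossback) add DBP; H1B and HB2 withdraw it.
dbp_addition_segments <- c("B1H", "BH2")
dbp_withdrawal_segments <- c("H1B", "HB2")

#' A DBP-responsive RE list for one exposure segment
#'
#' @param arm `"B1HB2"` or `"H1BH2"`.
#' @param segment `"B1H"`, `"HB2"` (B1HB2 arm) or `"H1B"`, `"BH2"` (H1BH2
#'   arm).
#' @param entries Data.frame with columns `re_id`, `gene`, `direction`
#'   (`"up"`/`"down"`), `empirical_p` in (0, 0.05].
#' @return Data.frame of class `dbp_comparison` with `arm`/`segment`
#'   columns attached.
#' @export
dbp_comparison <- function(arm, segment, entries) {
  arm <- match.arg(arm, c("B1HB2", "H1BH2"))
  segment <- match.arg(segment, re_segments)
  arm_of <- c(B1H = "B1HB2", HB2 = "B1HB2", H1B = "H1BH2", BH2 = "H1BH2")
  if (arm_of[[segment]] != arm)
    stop(sprintf("segment %s belongs to arm %s, not %s",
                 segment, arm_of[[segment]], arm))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("re_id", "gene", "direction", "empirical_p")
  if (!all(need %in% names(entries)))
    stop("entries must have columns: ", paste(need, collapse = ", "))
  if (nrow(entries)) {
    if (!all(entries$direction %in% c("up", "down")))
      stop("direction must be 'up' or 'down'")
    if (any(entries$empirical_p <= 0 | entries$empirical_p > 0.05))
      stop("empirical_p must lie in (0, 0.05]")
  }
  entries$gene <- normalize_symbols(entries$gene)
  entries$arm <- arm
  entries$segment <- segment
  class(entries) <- c("dbp_comparison", "data.frame")
  entries
}

#' Hypergeometric overlap statistics with representation factor
#'
#' For an overlap of `x` genes between lists of sizes `n1` and `n2` drawn
#' from a universe of size `N`, reports the expected overlap
#' `n1 * n2 / N`, the representation factor `x / expected` (observed over
#' expected under the hypergeometric null), and one-sided over- and
#' under-representation probabilities. The exact method sums the
#' hypergeometric mass over the tails including `x`
#' (`p_over = P[X >= x]`, `p_under = P[X <= x]`); the normal approximation
#' uses the hypergeometric mean and variance with a +/-0.5 continuity
#' correction (can be disabled).
#'
#' @param x Observed overlap count.
#' @param n1,n2 List sizes.
#' @param N Universe size.
#' @param method `"exact"` or `"normal"`.
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default TRUE).
#' @return A list of class `overlap_result`: `x`, `n1`, `n2`, `N`,
#'   `expected`, `representation_factor`, `p_over`, `p_under`, `method`.
#' @examples
#' hypergeometric_overlap(10, 20, 30, 100)  # representation factor 1.667
#' @export
hypergeometric_overlap <- function(x, n1, n2, N,
                                   method = c("exact", "normal"),
                                   continuity = TRUE) {
  method <- match.arg(method)
  stopifnot(length(x) == 1L, length(N) == 1L)
  if (N <= 0) stop("universe size N must be positive")
  if (n1 < 0 || n2 < 0 || n1 > N || n2 > N)
    stop("list sizes must satisfy 0 <= n1, n2 <= N")
  if (x < max(0, n1 + n2 - N) || x > min(n1, n2))
    stop(sprintf("infeasible overlap x = %d for n1 = %d, n2 = %d, N = %d",
                 x, n1, n2, N))
  expected <- n1 * n2 / N
  rf <- if (expected > 0) x / expected else NA_real_
  if (method == "exact") {
    p_over <- stats::phyper(x - 1, n1, N - n1, n2, lower.tail = FALSE)
    p_under <- stats::phyper(x, n1, N - n1, n2)
  } else {
    v <- n1 * n2 * (N - n1) * (N - n2) / (N^2 * (N - 1))
    if (v <= 0) {
      # degenerate null: all mass at the expected value
      p_over <- as.numeric(x <= expected)
      p_under <- as.numeric(x >= expected)
    } else {
      cc <- if (continuity) 0.5 else 0
      p_over <- stats::pnorm((x - cc - expected) / sqrt(v), lower.tail = FALSE)
      p_under <- stats::pnorm((x + cc - expected) / sqrt(v))
    }
  }
  structure(list(x = x, n1 = n1, n2 = n2, N = N, expected = expected,
                 representation_factor = rf,
                 p_over = min(1, p_over), p_under = min(1, p_under),
                 method = if (method == "exact") "exact" else "normal_approx"),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d of %d x %d in universe %d | expected %.3f | RF %.3f | p_over %.3g (%s)\n",
    x$x, x$n1, x$n2, x$N, x$expected, x$representation_factor, x$p_over,
    x$method))
  invisible(x)
}

#' Intersect two gene lists after symbol normalization
#'
#' @param a,b Character vectors of gene symbols.
#' @return Sorted, deduplicated intersection; its length feeds
#'   [hypergeometric_overlap()] as `x`.
#' @export
intersect_lists <- function(a, b) {
  sort(intersect(unique(normalize_symbols(a)), unique(normalize_symbols(b))))
}

#' Classify an RE's movement pattern across the two exposure segments
#'
#' Each study arm contributes a baseline -> crossover and a crossover ->
#' crossback comparison. A segment is rendered `Up`/`Down` only when that
#' segment is flagged significant (membership in the segment's
#' DBP-responsive list) and the means differ in that direction; otherwise
#' `Same`. A significant segment with exactly equal means has no defined
#' direction and errors. The rendered label is capitalized-first, e.g.
#' `"Down—same"`.
#'
#' @param mean_baseline,mean_crossover,mean_crossback Non-negative mean
#'   abundances at the three visits.
#' @param sig_first,sig_second Significance flags for the baseline ->
#'   crossover and crossover -> crossback segments.
#' @return A list of class `movement_pattern`: `first`, `second` (each
#'   `"Up"`/`"Down"`/`"Same"`), `pattern` (rendered label).
#' @examples
#' classify_movement(45.89, 36.94, 33.38, sig_first = TRUE,
#'                   sig_second = FALSE)$pattern  # "Down—same"
#' @export
classify_movement <- function(mean_baseline, mean_crossover, mean_crossback,
                              sig_first, sig_second) {
  stopifnot(mean_baseline >= 0, mean_crossover >= 0, mean_crossback >= 0)
  seg_dir <- function(from, to, sig) {
    if (!sig) return("Same")
    if (to > from) "Up"
    else if (to < from) "Down"
    else stop("significant segment with exactly equal means: direction undefined")
  }
  first <- seg_dir(mean_baseline, mean_crossover, sig_first)
  second <- seg_dir(mean_crossover, mean_crossback, sig_second)
  structure(list(first = first, second = second,
                 pattern = paste0(first, "—", tolower(second))),
            class = "movement_pattern")
}

#' Detect consistent responders across DBP addition and withdrawal
#'
#' A gene responds consistently when, over the segments where it is
#' significant, its abundance moves in one direction under every
#' DBP-addition segment (B1H, BH2) and in the opposite direction under
#' every DBP-withdrawal segment (H1B, HB2). Genes observed under only one
#' condition, or with contradictory directions within or across conditions,
#' are excluded.
#'
#' @param responses Data.frame with columns `gene`, `segment` (one of B1H,
#'   H1B, HB2, BH2) and `direction` (`"up"`/`"down"`), one row per
#'   significant gene-segment observation.
#' @return Sorted character vector of consistent-responder genes.
#' @export
consistent_responders <- function(responses) {
  stopifnot(all(c("gene", "segment", "direction") %in% names(responses)))
  if (!nrow(responses)) return(character(0))
  if (!all(responses$segment %in% re_segments))
    stop("segment must be one of: ", paste(re_segments, collapse = ", "))
  if (!all(responses$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  responses$gene <- normalize_symbols(responses$gene)
  keep <- vapply(split(responses, responses$gene), function(df) {
    add <- unique(df$direction[df$segment %in% dbp_addition_segments])
    wd <- unique(df$direction[df$segment %in% dbp_withdrawal_segments])
    length(add) == 1L && length(wd) == 1L && add != wd
  }, logical(1))
  sort(names(keep)[keep])
}

#' Split gene lists into arm-specific and shared sets
#'
#' @param arm_a,arm_b Character vectors of genes per study arm.
#' @return List with `specific_a`, `specific_b`, `shared` (sorted,
#'   deduplicated).
#' @export
shared_between_arms <- function(arm_a, arm_b) {
  a <- unique(normalize_symbols(arm_a))
  b <- unique(normalize_symbols(arm_b))
  list(specific_a = sort(setdiff(a, b)),
       specific_b = sort(setdiff(b, a)),
       shared = sort(intersect(a, b)))
}

#' Two-tailed t test for two samples of unequal variance
#'
#' Welch's t statistic with Welch-Satterthwaite degrees of freedom, as used
#' for paternal/maternal contribution fold changes. Each sample needs at
#' least two values and nonzero variance.
#'
#' @param x,y Numeric vectors.
#' @param two_tailed Report the two-sided p value (default).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y, two_tailed = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate (zero) variance in one of the samples")
  ht <- stats::t.test(x, y, var.equal = FALSE,
                      alternative = "two.sided")
  p <- ht$p.value
  if (!two_tailed) p <- p / 2
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = p)
}
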