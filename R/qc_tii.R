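# Transcript Integrity Index (TII) sample QC: per-transcript coverage
# pass/fail over a panel of stable sperm transcripts, a per-sample score,
# and fourth-quartile exclusion of poor-quality samples.

#' Does a coverage track pass the transcript-coverage rule?
#'
#' A transcript passes when at least `coverage_fraction` of its exon bases
#' are covered at a depth of at least `rpm_threshold` (both comparisons use
#' `>=`: "at least 5 reads per million" reads as `>=`, and the 50% side
#' follows the same convention).
#'
#' @param track A [coverage_track()].
#' @param rpm_threshold Minimum per-base depth, default 5 RPM.
#' @param coverage_fraction Minimum fraction of exon bases at threshold,
#'   default 0.5.
#' @return Logical scalar.
#' @export
transcript_pass <- function(track, rpm_threshold = 5, coverage_fraction = 0.5) {
  stopifnot(inherits(track, "coverage_track"))
  if (length(track$depth) == 0L) stop("coverage track with no exon bases")
  mean(track$depth >= rpm_threshold) >= coverage_fraction
}

#' Compute the Transcript Integrity Index for one sample
#'
#' The TII score is the fraction of panel transcripts (by default the 22
#' stable sperm-specific transcripts, supplied by the user) passing the
#' coverage rule. A panel transcript with no track for the sample counts as
#' fraction 0 (fails).
#'
#' @param tracks List of [coverage_track()] objects for one sample.
#' @param panel Character vector of panel transcript ids.
#' @param rpm_threshold,coverage_fraction Passed to [transcript_pass()].
#' @return A list of class `tii_result`: `sample_id`,
#'   `per_transcript_fraction` (named), `n_pass`, `tii_score`, and
#'   placeholders `quartile`/`pass` filled by [filter_q4()].
#' @export
compute_tii <- function(tracks, panel, rpm_threshold = 5,
                        coverage_fraction = 0.5) {
  if (length(panel) == 0L) stop("empty transcript panel")
  sample_ids <- unique(vapply(tracks, `[[`, character(1), "sample_id"))
  if (length(tracks) && length(sample_ids) != 1L)
    stop("tracks must all belong to one sample")
  track_ids <- vapply(tracks, `[[`, character(1), "transcript_id")
  frac <- vapply(panel, function(tx) {
    i <- match(tx, track_ids)
    if (is.na(i)) return(0)
    mean(tracks[[i]]$depth >= rpm_threshold)
  }, numeric(1))
  pass_tx <- frac >= coverage_fraction
  structure(list(sample_id = if (length(tracks)) sample_ids else NA_character_,
                 per_transcript_fraction = frac,
                 n_pass = sum(pass_tx),
                 tii_score = sum(pass_tx) / length(panel),
                 quartile = NA_integer_, pass = NA),
            class = "tii_result")
}

#' Assign TII quartiles and exclude fourth-quartile samples
#'
#' Samples whose TII score falls strictly below the 25th percentile of all
#' scores (linear-interpolation percentile, [stats::quantile()] type 7) are
#' assigned quartile 4 and removed as poor-quality RNA; ties at the
#' percentile are kept. Quartiles 3/2/1 are assigned analogously against
#' the 50th and 75th percentiles. Removal is deterministic given the score
#' vector and invariant to sample order.
#'
#' @param results List of `tii_result` objects from [compute_tii()] (at
#'   least 4, otherwise quartiles are undefined).
#' @return List with `kept` and `removed` (lists of `tii_result` with
#'   `quartile` and `pass` filled in) and a summary data.frame `table`
#'   (`sample_id`, `tii_score`, `quartile`, `pass`).
#' @export
filter_q4 <- function(results) {
  stopifnot(is.list(results), all(vapply(results, inherits, logical(1),
                                         "tii_result")))
  if (length(results) < 4L)
    stop("quartiles are undefined for fewer than 4 samples")
  scores <- vapply(results, `[[`, numeric(1), "tii_score")
  qs <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  quartile <- ifelse(scores < qs[1], 4L,
                     ifelse(scores < qs[2], 3L,
                            ifelse(scores < qs[3], 2L, 1L)))
  results <- Map(function(r, q) {
    r$quartile <- q
    r$pass <- q != 4L
    r
  }, results, quartile)
  tab <- data.frame(
    sample_id = vapply(results, `[[`, character(1), "sample_id"),
    tii_score = scores,
    quartile = quartile,
    pass = quartile != 4L,
    stringsAsFactors = FALSE)
  list(kept = results[quartile != 4L],
       removed = results[quartile == 4L],
       table = tab)
}
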