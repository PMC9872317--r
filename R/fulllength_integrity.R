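# Programmatic full-length transcript calls from per-sample exon coverage,
# replacing visual genome-browser inspection: a sample supports a
# transcript when its coverage clears the 5 RPKM confidence floor across
# the transcript's exons.

#' Call transcript integrity across samples
#'
#' A sample passes when at least `min_fraction` of the transcript's exon
#' bases have depth `>= rpkm_min` (the default `min_fraction = 1` is the
#' strictest reading of "covered across all exons"; visual calls tolerate
#' small gaps, so a relaxation is available). The transcript is
#' `FULL_LENGTH` when every sample passes, `PARTIAL` when some but not all
#' do, and `FAIL` when none does. All samples must share the same exon
#' model.
#'
#' @param tracks List of [coverage_track()] objects for one transcript, one
#'   per sample.
#' @param rpkm_min Per-base depth floor, default 5 RPKM.
#' @param min_fraction Minimum fraction of exon bases at the floor for a
#'   sample to pass, default 1 (every base).
#' @return A list of class `integrity_call`: `transcript_id`, `status`,
#'   `n_pass`, `n_total`, `rpkm_min`, `sample_pass` (named logical).
#' @export
call_integrity <- function(tracks, rpkm_min = 5, min_fraction = 1) {
  stopifnot(is.list(tracks), length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "coverage_track")))
  tx <- unique(vapply(tracks, `[[`, character(1), "transcript_id"))
  if (length(tx) != 1L) stop("tracks must all belong to one transcript")
  ref_exons <- tracks[[1]]$exons
  same <- vapply(tracks, function(t) identical(t$exons, ref_exons), logical(1))
  if (!all(same)) stop("inconsistent exon models across samples for ", tx)
  pass <- vapply(tracks, function(t) mean(t$depth >= rpkm_min) >= min_fraction,
                 logical(1))
  names(pass) <- vapply(tracks, `[[`, character(1), "sample_id")
  n_pass <- sum(pass)
  n_total <- length(pass)
  status <- if (n_pass == n_total) "FULL_LENGTH"
            else if (n_pass >= 1L) "PARTIAL"
            else "FAIL"
  structure(list(transcript_id = tx, status = status, n_pass = n_pass,
                 n_total = n_total, rpkm_min = rpkm_min,
                 sample_pass = pass),
            class = "integrity_call")
}

#' Render an integrity call in the reported style
#'
#' `FULL_LENGTH` renders as `"Full-length"`, `PARTIAL` as
#' `"Full-length (>= 1 < n samples)"` with the assessed sample count, and
#' `FAIL` as `"Fail"`.
#'
#' @param call An `integrity_call` from [call_integrity()].
#' @return Character scalar.
#' @export
render_integrity <- function(call) {
  stopifnot(inherits(call, "integrity_call"))
  switch(call$status,
         FULL_LENGTH = "Full-length",
         PARTIAL = sprintf("Full-length (≥ 1 < %d samples)", call$n_total),
         FAIL = "Fail")
}

#' @export
print.integrity_call <- function(x, ...) {
  cat(sprintf("integrity %s: %s (%d/%d samples at >= %g RPKM)\n",
              x$transcript_id, render_integrity(x), x$n_pass, x$n_total,
              x$rpkm_min))
  invisible(x)
}
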