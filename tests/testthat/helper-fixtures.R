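# In-code fixture builders shared across test files.

# single-exon coverage track with the given per-base depths
make_track <- function(depth, transcript_id = "tx1", sample_id = "s1",
                       start = 101, units = "RPM") {
  coverage_track(transcript_id, sample_id,
                 data.frame(start = start, end = start + length(depth) - 1),
                 depth, units = units)
}

# abundance matrix with constant per-RE values replicated across samples
make_am <- function(meds, n_samples, tissue, prefix = tissue,
                    re_ids = sprintf("chr1_%d_%d", seq_along(meds) * 1000,
                                     seq_along(meds) * 1000 + 100)) {
  vals <- matrix(rep(meds, n_samples), nrow = length(meds),
                 dimnames = list(re_ids,
                                 sprintf("%s_%d", prefix, seq_len(n_samples))))
  abundance_matrix(vals, data.frame(
    sample_id = colnames(vals), tissue = tissue,
    study_arm = "none", visit = "none", stringsAsFactors = FALSE))
}

# brute-force hypergeometric tail probabilities from first principles
brute_hyper <- function(x, n1, n2, N) {
  lo <- max(0, n1 + n2 - N)
  hi <- min(n1, n2)
  k <- lo:hi
  probs <- choose(n1, k) * choose(N - n1, n2 - k) / choose(N, n2)
  list(p_over = sum(probs[k >= x]), p_under = sum(probs[k <= x]))
}

# Benjamini-Hochberg step-up from first principles
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
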