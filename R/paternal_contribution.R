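# Decomposition of zygotic RE abundance into paternal and maternal parts,
# and the RPKM-threshold classifiers for fivefold / twofold paternally
# enriched and sperm-specific REs, with gene-level (RE-RNA) rollup.

#' Classification thresholds (RPKM)
#'
#' All published thresholds, as strict inequalities with the printed
#' defaults: fivefold paternal enrichment requires median sperm > 25 RPKM,
#' oocyte < 5 RPKM and zygote > 10 RPKM; twofold enrichment requires the
#' paternal contribution to exceed twice the maternal, or oocyte < 2 RPKM
#' (the floor below which RE presence cannot be confirmed) with sperm
#' between 2 and 25 RPKM; gene-level presence uses a 5 RPKM gate.
#'
#' @param sperm_min_5x,oocyte_max_5x,zygote_min,fold_2x,oocyte_absent,sperm_specific_2x_lower,sperm_specific_2x_upper,rerna_present
#'   Numeric thresholds; see Details.
#' @return A list of class `re_thresholds`.
#' @export
re_thresholds <- function(sperm_min_5x = 25, oocyte_max_5x = 5,
                          zygote_min = 10, fold_2x = 2, oocyte_absent = 2,
                          sperm_specific_2x_lower = 2,
                          sperm_specific_2x_upper = 25,
                          rerna_present = 5) {
  t <- list(sperm_min_5x = sperm_min_5x, oocyte_max_5x = oocyte_max_5x,
            zygote_min = zygote_min, fold_2x = fold_2x,
            oocyte_absent = oocyte_absent,
            sperm_specific_2x_lower = sperm_specific_2x_lower,
            sperm_specific_2x_upper = sperm_specific_2x_upper,
            rerna_present = rerna_present)
  if (any(unlist(t) <= 0)) stop("all thresholds must be positive")
  if (fold_2x <= 1) stop("fold_2x must exceed 1")
  structure(t, class = "re_thresholds")
}

#' Decompose zygote RE abundance into paternal and maternal contributions
#'
#' For each RE with zygote abundance Z, sperm abundance s and oocyte
#' abundance o (all RPKM), the paternal contribution is
#' `Pc = Z - Z / (1 + s/o)` (equivalently `Z * s / (s + o)`) and the
#' maternal contribution `Mc = Z - Pc`, provided `Z <= s + o`. When the
#' zygote abundance exceeds the sum of sperm and oocyte, the contributions
#' are capped at the gamete abundances themselves: `Pc = s`, `Mc = o`.
#' The `o = 0` case is the formula's limit `Pc = Z` (paternal-only); it is
#' only meaningful when not capped, i.e. `Z <= s`. `Z > 0` with
#' `s = o = 0` has no defined decomposition and errors.
#'
#' @param Z,s,o Numeric vectors (recycled) of zygote, sperm and oocyte RPKM.
#' @return Data.frame with columns `Z`, `s`, `o`, `Pc`, `Mc`, `capped`.
#' @examples
#' compute_contribution(Z = 20, s = 30, o = 10)   # Pc = 15, Mc = 5
#' compute_contribution(Z = 100, s = 40, o = 10)  # capped: Pc = 40, Mc = 10
#' @export
compute_contribution <- function(Z, s, o) {
  n <- max(length(Z), length(s), length(o))
  Z <- rep_len(as.numeric(Z), n)
  s <- rep_len(as.numeric(s), n)
  o <- rep_len(as.numeric(o), n)
  if (any(Z < 0 | s < 0 | o < 0) || anyNA(Z + s + o))
    stop("Z, s, o must be non-negative and non-missing")
  undef <- Z > 0 & s == 0 & o == 0
  if (any(undef))
    stop("undefined contribution: Z > 0 with s = 0 and o = 0 (",
         sum(undef), " RE(s))")
  capped <- Z > s + o
  Pc <- numeric(n); Mc <- numeric(n)
  Pc[capped] <- s[capped]
  Mc[capped] <- o[capped]
  i <- !capped
  denom <- s[i] + o[i]
  frac <- ifelse(denom > 0, s[i] / denom, 0)  # Z = 0 with s = o = 0: Pc = 0
  Pc[i] <- Z[i] * frac
  Mc[i] <- Z[i] - Pc[i]
  data.frame(Z = Z, s = s, o = o, Pc = Pc, Mc = Mc, capped = capped)
}

#' Fivefold paternal-enrichment rule on per-tissue median abundances
#'
#' An RE is fivefold paternally enriched when its median abundance is
#' > 25 RPKM in sperm, < 5 RPKM in the oocyte and > 10 RPKM in the zygote
#' (strict inequalities, thresholds configurable).
#'
#' @param s_med,o_med,z_med Numeric vectors of per-tissue median RPKM.
#' @param thresholds An [re_thresholds()] object.
#' @return Logical vector.
#' @export
classify_fivefold <- function(s_med, o_med, z_med,
                              thresholds = re_thresholds()) {
  s_med > thresholds$sperm_min_5x &
    o_med < thresholds$oocyte_max_5x &
    z_med > thresholds$zygote_min
}

#' Twofold paternal-enrichment rule
#'
#' Applied to REs not already in the fivefold set or a prior maternal set:
#' an RE passing the zygote gate (`z > 10` RPKM) is twofold paternally
#' enriched when `Pc > 2 * Mc`, or when the oocyte abundance is below the
#' 2 RPKM presence floor with sperm abundance strictly between 2 and
#' 25 RPKM. The sperm-specific flag marks oocyte abundance below the floor.
#'
#' @param contrib Data.frame from [compute_contribution()] (columns `Z`,
#'   `s`, `o`, `Pc`, `Mc`).
#' @param excluded Logical vector: RE already in a prior fivefold or
#'   maternal set.
#' @param thresholds An [re_thresholds()] object.
#' @return Logical vector: twofold paternally enriched.
#' @export
classify_twofold <- function(contrib, excluded = FALSE,
                             thresholds = re_thresholds()) {
  excluded <- rep_len(excluded, nrow(contrib))
  gate <- contrib$Z > thresholds$zygote_min
  ratio_rule <- contrib$Pc > thresholds$fold_2x * contrib$Mc
  absent_rule <- contrib$o < thresholds$oocyte_absent &
    contrib$s > thresholds$sperm_specific_2x_lower &
    contrib$s < thresholds$sperm_specific_2x_upper
  !excluded & gate & (ratio_rule | absent_rule)
}

#' Classify REs as fivefold / twofold paternally enriched
#'
#' Full RE classification: per-tissue medians are computed across
#' biological samples (configurable to means), the fivefold rule is applied
#' first, then the twofold rule on the remaining REs excluding any supplied
#' prior fivefold and maternal sets. When no prior fivefold set is given,
#' the set computed here is excluded from the twofold candidates. The
#' sperm-specific flag is set for classified REs whose oocyte abundance is
#' below the 2 RPKM presence floor.
#'
#' REs with zygote signal but zero abundance in both gametes have no
#' defined decomposition and are excluded with reason
#' `"undefined_contribution"`; REs failing the zygote gate carry reason
#' `"zygote_gate"`, prior-set members `"prior_set"`.
#'
#' @param sperm,oocyte,zygote [abundance_matrix()] objects sharing RE ids.
#' @param gene_map Optional data.frame `re_id`, `gene` mapping REs to their
#'   RE-RNA gene symbols.
#' @param prior_5x,prior_maternal Optional character vectors of RE ids from
#'   previously defined fivefold-paternal and maternal sets.
#' @param thresholds An [re_thresholds()] object.
#' @param aggregate `"median"` (default) or `"mean"` across samples.
#' @return Data.frame with one row per RE: `re_id`, `gene`, `Z`, `s`, `o`,
#'   `Pc`, `Mc`, `capped`, `label` (`FIVEFOLD_PATERNAL`,
#'   `TWOFOLD_PATERNAL`, `NONE`), `sperm_specific`, `excluded_reason`.
#' @export
classify_res <- function(sperm, oocyte, zygote, gene_map = NULL,
                         prior_5x = NULL, prior_maternal = NULL,
                         thresholds = re_thresholds(),
                         aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  for (m in list(sperm, oocyte, zygote))
    stopifnot(inherits(m, "abundance_matrix"))
  ids <- rownames(zygote$values)
  if (!setequal(ids, rownames(sperm$values)) ||
      !setequal(ids, rownames(oocyte$values)))
    stop("sperm, oocyte and zygote matrices must share the same RE ids")
  agg <- if (aggregate == "median") stats::median else mean
  s_med <- apply(sperm$values[ids, , drop = FALSE], 1L, agg)
  o_med <- apply(oocyte$values[ids, , drop = FALSE], 1L, agg)
  z_med <- apply(zygote$values[ids, , drop = FALSE], 1L, agg)

  res <- data.frame(re_id = ids, stringsAsFactors = FALSE)
  res$gene <- if (!is.null(gene_map)) {
    normalize_symbols(gene_map$gene)[match(ids, gene_map$re_id)]
  } else NA_character_
  undef <- z_med > 0 & s_med == 0 & o_med == 0
  contrib <- data.frame(Z = z_med, s = s_med, o = o_med,
                        Pc = NA_real_, Mc = NA_real_, capped = NA)
  if (any(!undef))
    contrib[!undef, ] <- compute_contribution(z_med[!undef], s_med[!undef],
                                              o_med[!undef])
  res <- cbind(res, contrib)

  fivefold <- !undef & classify_fivefold(s_med, o_med, z_med, thresholds)
  five_set <- if (is.null(prior_5x)) ids[fivefold] else as.character(prior_5x)
  excluded_prior <- ids %in% c(five_set, as.character(prior_maternal))
  twofold <- rep(FALSE, length(ids))
  cand <- !undef & !fivefold & !excluded_prior
  if (any(cand))
    twofold[cand] <- classify_twofold(contrib[cand, , drop = FALSE],
                                      excluded = FALSE, thresholds)

  res$label <- ifelse(fivefold, "FIVEFOLD_PATERNAL",
                      ifelse(twofold, "TWOFOLD_PATERNAL", "NONE"))
  res$sperm_specific <- res$label != "NONE" & o_med < thresholds$oocyte_absent
  res$excluded_reason <- NA_character_
  res$excluded_reason[undef] <- "undefined_contribution"
  res$excluded_reason[!undef & !fivefold & excluded_prior] <- "prior_set"
  res$excluded_reason[!undef & !excluded_prior & res$label == "NONE" &
                        z_med <= thresholds$zygote_min] <- "zygote_gate"
  rownames(res) <- NULL
  res
}

#' Roll RE classifications up to RE-RNA (gene) level
#'
#' A gene carries a class if at least one of its REs carries that class; a
#' gene with REs in both classes appears in both gene lists. REs without a
#' gene assignment are dropped (their count is reported).
#'
#' @param classified Data.frame from [classify_res()].
#' @return List with sorted, deduplicated character vectors `fivefold`,
#'   `twofold`, `sperm_specific`, `paternal` (union), and `n_dropped` (REs
#'   without a gene).
#' @export
aggregate_to_rernas <- function(classified) {
  stopifnot(all(c("gene", "label", "sperm_specific") %in% names(classified)))
  has_gene <- !is.na(classified$gene) & nzchar(classified$gene)
  n_dropped <- sum(!has_gene & classified$label != "NONE")
  x <- classified[has_gene, , drop = FALSE]
  pick <- function(keep) sort(unique(x$gene[keep]))
  five <- pick(x$label == "FIVEFOLD_PATERNAL")
  two <- pick(x$label == "TWOFOLD_PATERNAL")
  list(fivefold = five, twofold = two,
       sperm_specific = pick(x$sperm_specific),
       paternal = sort(unique(c(five, two))),
       n_dropped = n_dropped)
}

#' Flag RE-RNAs more abundant in the zygote than in sperm
#'
#' The zygote gate (> 10 RPKM) allows zygotic abundance to exceed the
#' combined gamete abundance; this flags the paternally provided genes
#' where, above the 5 RPKM presence gate, the zygote abundance exceeds the
#' sperm abundance.
#'
#' @param gene_abund Data.frame with columns `gene`, `sperm`, `zygote`
#'   (gene-level RPKM).
#' @param thresholds An [re_thresholds()] object.
#' @param gate_both Apply the presence gate to both sperm and zygote
#'   (default) or to the zygote only.
#' @return Character vector of flagged genes.
#' @export
zygote_excess <- function(gene_abund, thresholds = re_thresholds(),
                          gate_both = TRUE) {
  stopifnot(all(c("gene", "sperm", "zygote") %in% names(gene_abund)))
  gate <- gene_abund$zygote > thresholds$rerna_present
  if (gate_both) gate <- gate & gene_abund$sperm > thresholds$rerna_present
  sort(unique(gene_abund$gene[gate & gene_abund$zygote > gene_abund$sperm]))
}
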