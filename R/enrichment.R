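# Empirical-p-value stratification of DBP-responsive RE lists, local
# over-representation analysis (ORA) against GMT collections with the
# top-100 / FDR q < 0.05 / two-gene-overlap thresholds, keyword-based
# biological-process categorization, and CRREW/TF proportion tests.

#' Default empirical-p-value group boundaries
#'
#' The six groups used to keep every stratified query under the 500
#' recognized-gene cap: group 1 = p < 0.013, then (0.013, 0.023],
#' (0.023, 0.032], (0.032, 0.041], (0.041, 0.045], (0.045, 0.05].
#' @return Numeric vector of the six upper cut points.
#' @export
pvalue_group_boundaries <- function() c(0.013, 0.023, 0.032, 0.041, 0.045, 0.05)

#' Partition RE entries into empirical-p-value groups
#'
#' Entries are assigned to the first interval containing their p value:
#' group 1 is open on the right (`p < 0.013`), the remaining intervals are
#' left-open/right-closed. Every entry must have `0 < p <= 0.05`. Each
#' group's recognized gene count (intersection of its unique gene symbols
#' with the supplied symbol universe) must stay at or below `cap`; a group
#' over cap raises an error naming the group.
#'
#' @param entries Data.frame with columns `re_id`, `gene`, `empirical_p`.
#' @param boundaries Strictly increasing upper cut points ending at 0.05.
#' @param universe Optional character vector of recognized gene symbols;
#'   when `NULL` all genes count as recognized.
#' @param cap Maximum recognized genes per group (default 500).
#' @return List of class `pvalue_groups`: `groups` (list of data.frames,
#'   one per interval), `boundaries`, `recognized_counts`.
#' @export
partition_by_pvalue <- function(entries, boundaries = pvalue_group_boundaries(),
                                universe = NULL, cap = 500) {
  stopifnot(all(c("re_id", "gene", "empirical_p") %in% names(entries)))
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  p <- entries$empirical_p
  if (nrow(entries) && any(p <= 0 | p > boundaries[length(boundaries)]))
    stop(sprintf("empirical p values must lie in (0, %g]",
                 boundaries[length(boundaries)]))
  # group 1: p < boundaries[1]; group j > 1: left-open/right-closed
  # (boundaries[j-1], boundaries[j]], with the lower edge of group 2 closed
  # so that p = boundaries[1] falls in group 2, not group 1.
  grp <- findInterval(p, boundaries, left.open = TRUE) + 1L
  grp[p == boundaries[1]] <- 2L
  groups <- lapply(seq_along(boundaries), function(j)
    entries[grp == j, , drop = FALSE])
  recog <- vapply(groups, function(g) {
    genes <- unique(normalize_symbols(g$gene))
    if (is.null(universe)) length(genes)
    else length(intersect(genes, unique(normalize_symbols(universe))))
  }, numeric(1))
  over <- which(recog > cap)
  if (length(over))
    stop(sprintf("group %d exceeds the %d recognized-gene cap (%d genes)",
                 over[1], cap, recog[over[1]]))
  structure(list(groups = groups, boundaries = boundaries,
                 recognized_counts = recog),
            class = "pvalue_groups")
}

#' Local over-representation analysis against a gene-set collection
#'
#' For each set in the collection, the upper-tail hypergeometric
#' probability `P[X >= k]` of observing `k` query genes in the set is
#' computed against the supplied symbol universe, and q values are
#' Benjamini-Hochberg adjusted within the collection (each collection is
#' considered separately). Reported rows require at least `min_overlap`
#' query genes in the set and `q < q_max`, sorted by p ascending and
#' truncated to `top`. Query genes outside the universe are dropped with a
#' warning; a set with no genes in the universe is an error.
#'
#' @param query Character vector of gene symbols.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector: the recognized symbol universe.
#' @param q_max FDR threshold, default 0.05.
#' @param min_overlap Minimum query/set overlap, default 2.
#' @param top Maximum reported rows, default 100.
#' @return Data.frame with columns `set_name`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, one row per reported set (possibly zero rows).
#' @export
ora <- function(query, collection, universe, q_max = 0.05, min_overlap = 2,
                top = 100) {
  if (!length(collection)) stop("empty gene-set collection")
  universe <- unique(normalize_symbols(universe))
  query <- unique(normalize_symbols(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  sets <- lapply(collection, function(s) intersect(unique(normalize_symbols(s)),
                                                   universe))
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty))
    stop("gene set(s) with no genes in the universe: ",
         paste(names(sets)[empty], collapse = ", "))
  K <- vapply(sets, length, integer(1))
  k <- vapply(sets, function(s) length(intersect(query, s)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(set_name = names(collection), k = k, K = K, n = n,
                    N = N, p = p, q = q, stringsAsFactors = FALSE,
                    row.names = NULL)
  res <- res[res$k >= min_overlap & res$q < q_max, , drop = FALSE]
  res <- res[order(res$p, res$set_name), , drop = FALSE]
  utils::head(res, top)
}

#' Default keyword map from gene-set names to biological processes
#'
#' A reconstruction of the five-process assignment (cellular stress, cell
#' cycle, apoptosis, DNA damage response, gene regulation) as an explicit,
#' editable ordered map of regular expressions; the original assignment was
#' curatorial, so this default is a documented approximation, not a fact of
#' the source data.
#'
#' @return Named character vector: names are case-insensitive regular
#'   expressions matched against set names (spaces treated as
#'   underscores), values are categories. First match in order wins.
#' @export
default_category_map <- function() {
  c("APOPTOSIS|CELL_DEATH|CASPASE" = "apoptosis",
    "CELL_CYCLE|G2M|G1_S|MITOTIC|CHECKPOINT|DREAM_TARGETS" = "cell cycle",
    "DNA_DAMAGE|DNA_REPAIR|UV_RESPONSE|RADIATION" = "DNA damage response",
    "STRESS|RESPONSE_TO_STIMUL|RESPONSES_TO_STIMUL|HEAT_SHOCK|TRETINOIN" =
      "cellular stress",
    "TRANSCRIPTION|CHROMATIN|CHROMOSOME|HISTONE|RNA_METABOLIC|POLYMERASE|HDAC|GENE_REGULATION|EXPRESSION" =
      "gene regulation")
}

#' Categorize a gene-set name into a biological process
#'
#' @param set_name Character vector of set names.
#' @param keyword_map Ordered named vector of regex -> category (default
#'   [default_category_map()]).
#' @return Character vector of categories (`"uncategorized"` when no
#'   pattern matches).
#' @export
categorize <- function(set_name, keyword_map = default_category_map()) {
  nm <- gsub("[ -]", "_", toupper(set_name))
  vapply(nm, function(s) {
    for (i in seq_along(keyword_map)) {
      if (grepl(names(keyword_map)[i], s)) return(unname(keyword_map[i]))
    }
    "uncategorized"
  }, character(1), USE.NAMES = FALSE)
}

#' Test whether an annotation class is over-represented in a gene list
#'
#' Delegates to [hypergeometric_overlap()] with `x` the number of list
#' genes carrying the annotation (e.g. CRREW or TF), against the background
#' universe.
#'
#' @param genes Non-empty character vector of query genes.
#' @param annotation Character vector of annotated genes (e.g. all CRREWs).
#' @param background Character vector: the gene universe.
#' @param method Passed to [hypergeometric_overlap()].
#' @return An `overlap_result`.
#' @export
proportion_test <- function(genes, annotation, background,
                            method = c("exact", "normal")) {
  genes <- unique(normalize_symbols(genes))
  if (!length(genes)) stop("empty gene list")
  background <- unique(normalize_symbols(background))
  annotation <- intersect(unique(normalize_symbols(annotation)), background)
  genes <- intersect(genes, background)
  hypergeometric_overlap(length(intersect(genes, annotation)),
                         length(genes), length(annotation),
                         length(background), method = method)
}
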