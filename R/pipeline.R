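# End-to-end orchestration: sample QC -> RE classification -> gene rollup
# -> DBP overlap statistics -> movement/consistency -> enrichment -> CRREW
# annotation -> network export, with a machine-readable run report whose
# every count is recomputable from the returned tables.

#' Run the full paternal-RE / DBP analysis
#'
#' Executes the pipeline stages in analysis order on in-memory inputs.
#' Coverage-based sample QC is applied when coverage tracks are supplied;
#' RE classification and gene rollup always run; DBP overlap, movement
#' consistency, CRREW annotation, enrichment and network export run when
#' their inputs are present. The run is a pure function of its inputs:
#' repeated calls return identical reports.
#'
#' @param sperm,oocyte,zygote [abundance_matrix()] objects sharing RE ids.
#' @param gene_map Data.frame `re_id`, `gene`.
#' @param dbp Optional named list of [dbp_comparison()] data frames keyed
#'   by segment (`B1H`, `H1B`, `HB2`, `BH2`).
#' @param gmt Optional named list of gene sets for enrichment.
#' @param crrew Optional CRREW annotation data.frame (see [read_crrew()]).
#' @param coverage Optional list per sample of [coverage_track()] lists for
#'   TII QC; requires `panel`.
#' @param panel Transcript ids of the TII panel.
#' @param prior_5x,prior_maternal Optional prior RE-id sets passed to
#'   [classify_res()].
#' @param thresholds An [re_thresholds()].
#' @param universe Optional gene universe for overlap/enrichment tests;
#'   defaults to all genes with at least one detected (non-zero) RE in the
#'   zygote input.
#' @param category_map Keyword map for [categorize()].
#' @param outdir Optional directory; when given, per-stage TSVs and the
#'   network tables are written there.
#' @return A list of class `re_run_report`: `classification`, `gene_lists`,
#'   `tii`, `overlaps`, `consistent`, `crrew`, `enrichment`, `network`,
#'   `counts`, `universe_size`.
#' @export
run_pipeline <- function(sperm, oocyte, zygote, gene_map, dbp = NULL,
                         gmt = NULL, crrew = NULL, coverage = NULL,
                         panel = NULL, prior_5x = NULL, prior_maternal = NULL,
                         thresholds = re_thresholds(), universe = NULL,
                         category_map = default_category_map(),
                         outdir = NULL) {
  report <- list()

  # -- stage 1: TII sample QC ------------------------------------------------
  if (!is.null(coverage)) {
    if (is.null(panel)) stop("TII stage: coverage supplied without a panel")
    tii_res <- lapply(coverage, compute_tii, panel = panel)
    report$tii <- filter_q4(tii_res)
  } else report$tii <- NULL

  # -- stage 2: RE classification -------------------------------------------
  report$classification <- classify_res(
    sperm, oocyte, zygote, gene_map = gene_map, prior_5x = prior_5x,
    prior_maternal = prior_maternal, thresholds = thresholds)

  # -- stage 3: RE-RNA rollup -----------------------------------------------
  report$gene_lists <- aggregate_to_rernas(report$classification)

  # universe: genes with >= 1 detected RE in the zygote input
  if (is.null(universe)) {
    detected <- rownames(zygote$values)[
      apply(zygote$values, 1L, function(v) any(v > 0))]
    universe <- unique(normalize_symbols(
      gene_map$gene[gene_map$re_id %in% detected]))
  } else universe <- unique(normalize_symbols(universe))
  report$universe_size <- length(universe)

  # -- stage 4: DBP overlap -------------------------------------------------
  paternal <- report$gene_lists$paternal
  if (!is.null(dbp)) {
    report$overlaps <- lapply(dbp, function(cmp) {
      genes <- unique(cmp$gene)
      ov <- intersect_lists(genes, paternal)
      stat <- hypergeometric_overlap(
        length(ov), length(intersect(genes, universe)),
        length(intersect(paternal, universe)), length(universe))
      list(segment = cmp$segment[1], genes = ov, stat = stat)
    })
    all_resp <- do.call(rbind, lapply(dbp, function(cmp)
      cmp[, c("gene", "segment", "direction")]))
    report$consistent <- consistent_responders(all_resp)
  } else {
    report$overlaps <- NULL
    report$consistent <- character(0)
  }

  # -- stage 5: CRREW annotation --------------------------------------------
  if (!is.null(crrew) && !is.null(dbp)) {
    arm_genes <- function(arm) {
      segs <- names(dbp)[vapply(dbp, function(cmp) cmp$arm[1] == arm,
                                logical(1))]
      resp <- unique(unlist(lapply(dbp[segs], function(cmp) cmp$gene)))
      intersect_lists(intersect(resp, paternal), crrew$gene)
    }
    arms <- shared_between_arms(arm_genes("B1HB2"), arm_genes("H1BH2"))
    overlap_all <- unique(unlist(lapply(report$overlaps, `[[`, "genes")))
    prop <- if (length(overlap_all))
      proportion_test(overlap_all, crrew$gene, universe) else NULL
    report$crrew <- list(arms = arms, proportion = prop)
  } else report$crrew <- NULL

  # -- stage 6: enrichment --------------------------------------------------
  if (!is.null(gmt) && !is.null(dbp)) {
    query <- unique(unlist(lapply(report$overlaps, `[[`, "genes")))
    enr <- ora(query, gmt, universe)
    if (nrow(enr)) enr$category <- categorize(enr$set_name, category_map)
    report$enrichment <- enr
  } else report$enrichment <- NULL

  # -- stage 7: network export ----------------------------------------------
  if (!is.null(dbp)) {
    gene_cat <- NULL
    if (!is.null(report$enrichment) && nrow(report$enrichment)) {
      gene_cat <- do.call(rbind, lapply(seq_len(nrow(report$enrichment)),
        function(i) {
          genes <- intersect_lists(gmt[[report$enrichment$set_name[i]]],
                                   universe)
          if (!length(genes)) return(NULL)
          data.frame(gene = genes,
                     category = report$enrichment$category[i],
                     stringsAsFactors = FALSE)
        }))
      if (!is.null(gene_cat)) gene_cat <- unique(gene_cat)
    }
    report$network <- export_network(dbp, paternal, gene_cat)
  } else report$network <- NULL

  # -- run report counts ----------------------------------------------------
  cls <- report$classification
  report$counts <- list(
    n_res = nrow(cls),
    n_fivefold_res = sum(cls$label == "FIVEFOLD_PATERNAL"),
    n_twofold_res = sum(cls$label == "TWOFOLD_PATERNAL"),
    n_sperm_specific_res = sum(cls$sperm_specific),
    n_fivefold_genes = length(report$gene_lists$fivefold),
    n_twofold_genes = length(report$gene_lists$twofold),
    n_paternal_genes = length(paternal),
    n_samples_dropped_tii = if (is.null(report$tii)) 0L
                            else length(report$tii$removed),
    n_consistent = length(report$consistent),
    n_crrew_shared = if (is.null(report$crrew)) NA_integer_
                     else length(report$crrew$arms$shared),
    n_enriched_sets = if (is.null(report$enrichment)) NA_integer_
                      else nrow(report$enrichment))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(cls, file.path(outdir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$tii))
      utils::write.table(report$tii$table, file.path(outdir, "tii.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$enrichment))
      utils::write.table(report$enrichment,
                         file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$network))
      write_network(report$network$nodes, report$network$edges,
                    file.path(outdir, "network_nodes.tsv"),
                    file.path(outdir, "network_edges.tsv"))
  }
  class(report) <- "re_run_report"
  report
}

#' @export
print.re_run_report <- function(x, ...) {
  cat("paternal-RE pipeline report\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-24s %s\n", nm, format(x$counts[[nm]])))
  invisible(x)
}

#' Build network node and edge tables from DBP responses
#'
#' Nodes are the biological-process categories plus the four
#' direction-by-condition classes (abundance up/down on DBP exposure,
#' up/down on withdrawal); each edge connects a process to a direction
#' class, carries the number of supporting paternally provided
#' DBP-responsive REs (`n_res`) and the exposure segment it came from.
#' Without gene categories all genes fall under a single
#' `"paternally_provided"` process node.
#'
#' @param dbp Named list of [dbp_comparison()] data frames.
#' @param paternal_genes Character vector: the paternally provided gene
#'   list.
#' @param gene_categories Optional data.frame `gene`, `category`.
#' @return List with data.frames `nodes` (`id`, `type`, `class`) and
#'   `edges` (`source`, `target`, `n_res`, `segment`).
#' @export
export_network <- function(dbp, paternal_genes, gene_categories = NULL) {
  paternal_genes <- unique(normalize_symbols(paternal_genes))
  dir_node <- function(segment, direction) {
    cond <- ifelse(segment %in% dbp_addition_segments,
                   "exposure", "withdrawal")
    paste0(direction, "_on_", cond)
  }
  edges <- do.call(rbind, lapply(dbp, function(cmp) {
    keep <- as.data.frame(cmp)[cmp$gene %in% paternal_genes, , drop = FALSE]
    if (!nrow(keep)) return(NULL)
    if (is.null(gene_categories)) {
      keep$category <- "paternally_provided"
    } else {
      keep <- merge(keep, gene_categories, by = "gene")
      if (!nrow(keep)) return(NULL)
    }
    stats::aggregate(
      list(n_res = keep$re_id),
      by = list(source = keep$category,
                target = dir_node(keep$segment, keep$direction),
                segment = keep$segment),
      FUN = function(x) length(unique(x)))
  }))
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        n_res = integer(0), segment = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- edges[, c("source", "target", "n_res", "segment")]
    edges <- edges[order(edges$segment, edges$source, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  procs <- sort(unique(edges$source))
  dirs <- sort(unique(edges$target))
  nodes <- rbind(
    data.frame(id = procs, type = rep("process", length(procs)),
               class = rep("biological_process", length(procs)),
               stringsAsFactors = FALSE),
    data.frame(id = dirs, type = rep("direction", length(dirs)),
               class = vapply(strsplit(dirs, "_on_"), `[[`, character(1),
                              1L, USE.NAMES = FALSE),
               stringsAsFactors = FALSE))
  list(nodes = nodes, edges = edges)
}
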