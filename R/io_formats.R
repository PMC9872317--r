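# Readers and writers for the external representations the pipeline touches:
# RE identifiers ("chr_start_end"), RPKM abundance matrices with sample
# metadata, GMT gene-set collections, CRREW annotation tables, bedGraph
# coverage, BED and node/edge network tables.

#' Parse RE identifiers of the form "chrom_start_end"
#'
#' RE (RNA element) identifiers embed a genomic interval in the name, e.g.
#' `"chr10_35049683_35049765"`. Coordinates are taken as 1-based inclusive
#' (UCSC browser display convention). Chromosome names may themselves contain
#' underscores (`"chrUn_KI270742v1_100_200"`): the parse splits on the final
#' two underscore-delimited integer tokens only.
#'
#' @param id Character vector of RE identifiers.
#' @return A data.frame with columns `id`, `chrom`, `start`, `end`.
#' @examples
#' parse_re_id("chr10_35049683_35049765")
#' parse_re_id("chrUn_KI270742v1_100_200")
#' @export
parse_re_id <- function(id) {
  stopifnot(is.character(id), length(id) >= 1L)
  m <- regmatches(id, regexec("^(.+)_([0-9]+)_([0-9]+)$", id))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed RE id(s): ", paste(id[bad], collapse = ", "),
         " (expected \"chrom_start_end\" with integer coordinates)")
  }
  chrom <- vapply(m, `[[`, character(1), 2L)
  start <- as.numeric(vapply(m, `[[`, character(1), 3L))
  end <- as.numeric(vapply(m, `[[`, character(1), 4L))
  rev_ord <- start > end
  if (any(rev_ord)) {
    stop("malformed RE id(s): ", paste(id[rev_ord], collapse = ", "),
         " (start > end)")
  }
  if (any(!nzchar(chrom))) stop("malformed RE id(s): empty chromosome name")
  data.frame(id = id, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Format REs back into "chrom_start_end" identifiers
#'
#' Inverse of [parse_re_id()]: `format_re_id(parse_re_id(x))` reproduces `x`.
#'
#' @param re A data.frame with columns `chrom`, `start`, `end`.
#' @return Character vector of identifiers.
#' @export
format_re_id <- function(re) {
  stopifnot(all(c("chrom", "start", "end") %in% names(re)))
  sprintf("%s_%d_%d", re$chrom, as.integer(re$start), as.integer(re$end))
}

#' Normalize gene symbols for matching
#'
#' Gene symbols from mixed-case sources (curated tables vs GMT files) are
#' matched after uppercasing both sides.
#'
#' @param x Character vector of gene symbols.
#' @return Uppercased, whitespace-trimmed symbols.
#' @export
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

re_tissues <- c("sperm", "oocyte", "zygote")
re_arms <- c("B1HB2", "H1BH2", "none")
re_visits <- c("baseline", "crossover", "crossback", "none")
re_segments <- c("B1H", "H1B", "HB2", "BH2")

#' Construct an RE abundance matrix
#'
#' A light container (in the style of list-based expression containers) for
#' per-RE RPKM values across samples plus per-sample metadata.
#'
#' @param values Numeric matrix, rows = REs (rownames = RE ids), columns =
#'   samples (colnames = sample ids). All values must be non-negative and
#'   non-missing.
#' @param meta Data.frame with columns `sample_id`, `tissue`
#'   (`sperm`/`oocyte`/`zygote`), `study_arm` (`B1HB2`/`H1BH2`/`none`),
#'   `visit` (`baseline`/`crossover`/`crossback`/`none`). One row per sample.
#' @return An object of class `abundance_matrix` (a list with elements
#'   `values` and `meta`).
#' @export
abundance_matrix <- function(values, meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs RE ids as rownames and sample ids as colnames")
  if (anyNA(values)) stop("missing abundance cells are errors, not zeros")
  if (any(values < 0)) stop("negative RPKM value in abundance matrix")
  if (anyDuplicated(rownames(values))) stop("duplicate re_id in abundance matrix")
  if (anyDuplicated(colnames(values))) stop("duplicate sample_id in abundance matrix")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "study_arm", "visit")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta))
    stop("sample(s) in matrix absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  if (!all(meta$tissue %in% re_tissues))
    stop("tissue must be one of: ", paste(re_tissues, collapse = ", "))
  if (!all(meta$study_arm %in% re_arms))
    stop("study_arm must be one of: ", paste(re_arms, collapse = ", "))
  if (!all(meta$visit %in% re_visits))
    stop("visit must be one of: ", paste(re_visits, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d REs x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$meta$tissue), collapse = "/")))
  invisible(x)
}

#' Read an RE abundance matrix and its sample metadata from TSV
#'
#' The matrix TSV has a header `re_id` followed by sample ids; the metadata
#' TSV has columns `sample_id`, `tissue`, `study_arm`, `visit`. Missing
#' cells, negative values, duplicate RE ids and samples without metadata are
#' all errors (silent zero-filling would corrupt threshold classification).
#'
#' @param path Path to the abundance TSV.
#' @param meta_path Path to the metadata TSV.
#' @return An [abundance_matrix()].
#' @export
read_abundance <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "re_id") stop("abundance TSV must start with a 're_id' column")
  if (anyDuplicated(tab$re_id)) stop("duplicate re_id in ", path)
  values <- as.matrix(tab[, -1, drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- tab$re_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  abundance_matrix(values, meta)
}

#' Write an RE abundance matrix (and optionally its metadata) to TSV
#'
#' @param x An [abundance_matrix()].
#' @param path Output path for the matrix TSV.
#' @param meta_path Optional output path for the metadata TSV.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  # 17 significant digits so values round-trip bit-for-bit
  txt <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values),
                dimnames = dimnames(x$values))
  out <- data.frame(re_id = rownames(x$values), txt,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then one or more gene symbols,
#' tab-separated (the standard MSigDB layout). Empty sets and duplicated set
#' names are errors.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3L
  if (any(short)) stop("GMT line(s) with an empty gene set in ", path)
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicated set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- nm
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

crrew_classes <- c("chromatin remodeler cofactor", "RNA interactor",
                   "reader", "eraser", "writer")

#' Read a curated CRREW annotation table
#'
#' CRREWs are the five curated classes of epigenetic mediators: chromatin
#' remodeler cofactors, RNA interactors, readers, erasers and writers. The
#' TSV has columns `gene`, `crrew_class`, `in_sperm_proteome` (logical).
#'
#' @param path Path to the TSV.
#' @return Data.frame with normalized gene symbols.
#' @export
read_crrew <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "crrew_class", "in_sperm_proteome")
  if (!all(need %in% names(tab)))
    stop("CRREW table must have columns: ", paste(need, collapse = ", "))
  if (!all(tab$crrew_class %in% crrew_classes))
    stop("crrew_class must be one of: ", paste(crrew_classes, collapse = ", "))
  tab$gene <- normalize_symbols(tab$gene)
  tab$in_sperm_proteome <- as.logical(tab$in_sperm_proteome)
  tab
}

#' Construct a per-sample exon coverage track
#'
#' Holds normalized per-base depth (RPM or RPKM, declared in `units`) over
#' the union of a transcript's exons, ordered 5' to 3' along the
#' concatenated exons.
#'
#' @param transcript_id Transcript identifier.
#' @param sample_id Sample identifier.
#' @param exons Data.frame with columns `start`, `end` (1-based inclusive,
#'   sorted, non-overlapping).
#' @param depth Numeric vector, one value per exon base.
#' @param units `"RPM"` or `"RPKM"`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(transcript_id, sample_id, exons, depth,
                           units = c("RPM", "RPKM")) {
  units <- match.arg(units)
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)), nrow(exons) >= 1L)
  if (any(exons$start > exons$end)) stop("exon with start > end")
  if (is.unsorted(exons$start)) stop("exons must be sorted by start")
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping")
  n_bases <- sum(exons$end - exons$start + 1)
  if (length(depth) != n_bases)
    stop(sprintf("depth has %d values but exons span %d bases",
                 length(depth), n_bases))
  if (anyNA(depth) || any(depth < 0)) stop("depth must be non-negative and complete")
  structure(list(transcript_id = transcript_id, sample_id = sample_id,
                 exons = exons[, c("start", "end")], depth = as.numeric(depth),
                 units = units),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s / %s: %d exon(s), %d bases, median depth %.2f %s\n",
              x$transcript_id, x$sample_id, nrow(x$exons), length(x$depth),
              stats::median(x$depth), x$units))
  invisible(x)
}

#' Read a bedGraph coverage file into a coverage track over given exons
#'
#' bedGraph intervals are 0-based half-open; exon coordinates are 1-based
#' inclusive. Bases not covered by any bedGraph interval get depth 0.
#'
#' @param path Path to a bedGraph file.
#' @param exons Data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) describing the transcript's exons (single chromosome).
#' @param transcript_id,sample_id Identifiers stored on the track.
#' @param units Depth units, `"RPM"` or `"RPKM"`.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, exons, transcript_id = "tx",
                          sample_id = "sample", units = c("RPM", "RPKM")) {
  units <- match.arg(units)
  exons <- as.data.frame(exons)
  stopifnot(all(c("chrom", "start", "end") %in% names(exons)))
  if (length(unique(exons$chrom)) != 1L)
    stop("exons must lie on a single chromosome")
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- GenomicRanges::coverage(gr, weight = "score")
  chrom <- as.character(exons$chrom[1])
  depth <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    pos <- seq.int(exons$start[i], exons$end[i])
    if (chrom %in% names(cov)) {
      rl <- cov[[chrom]]
      d <- numeric(length(pos))
      inside <- pos <= length(rl)
      if (any(inside)) d[inside] <- as.numeric(rl[pos[inside]])
      d
    } else {
      numeric(length(pos))
    }
  }), use.names = FALSE)
  coverage_track(transcript_id, sample_id,
                 exons[, c("start", "end")], depth, units)
}

#' Write a coverage track as bedGraph
#'
#' @param track A [coverage_track()].
#' @param chrom Chromosome name for the output intervals.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, chrom, path) {
  stopifnot(inherits(track, "coverage_track"))
  pos <- unlist(lapply(seq_len(nrow(track$exons)), function(i)
    seq.int(track$exons$start[i], track$exons$end[i])), use.names = FALSE)
  keep <- track$depth > 0
  if (!any(keep)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  pos <- pos[keep]; depth <- track$depth[keep]
  brk <- c(TRUE, diff(pos) != 1 | diff(depth) != 0)
  grp <- cumsum(brk)
  starts <- tapply(pos, grp, min) - 1L    # bedGraph is 0-based half-open
  ends <- tapply(pos, grp, max)
  vals <- tapply(depth, grp, `[`, 1L)
  utils::write.table(
    data.frame(chrom = chrom, start = as.integer(starts),
               end = as.integer(ends), value = as.numeric(vals)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write REs to BED6
#'
#' Converts the 1-based inclusive RE interval to the 0-based half-open BED
#' convention: BED start = start - 1, BED end = end.
#'
#' @param re Data.frame from [parse_re_id()] (columns `id`, `chrom`,
#'   `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(re, path) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(re)))
  bed <- data.frame(chrom = re$chrom,
                    start = as.integer(re$start) - 1L,
                    end = as.integer(re$end),
                    name = re$id, score = 0L, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file back into RE form
#'
#' @param path Path to a BED6 file written by [write_bed()].
#' @return Data.frame with columns `id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(id = bed[[4]], chrom = bed[[1]],
             start = as.numeric(bed[[2]]) + 1, end = as.numeric(bed[[3]]),
             stringsAsFactors = FALSE)
}

#' Write network node and edge tables
#'
#' Mirrors a Cytoscape-style export: a node table (`id`, `type`, `class`)
#' and an edge table (`source`, `target`, `n_res`, `segment`), where
#' `segment` is one of the four crossover-crossback comparisons
#' (B1H, H1B, HB2, BH2) and `n_res` the number of supporting REs.
#'
#' @param nodes Data.frame with columns `id`, `type`, `class`.
#' @param edges Data.frame with columns `source`, `target`, `n_res`,
#'   `segment`.
#' @param node_path,edge_path Output paths.
#' @return A list with the two paths, invisibly.
#' @export
write_network <- function(nodes, edges, node_path, edge_path) {
  stopifnot(all(c("id", "type", "class") %in% names(nodes)))
  stopifnot(all(c("source", "target", "n_res", "segment") %in% names(edges)))
  if (nrow(edges) && !all(edges$segment %in% re_segments))
    stop("edge segment must be one of: ", paste(re_segments, collapse = ", "))
  utils::write.table(nodes[, c("id", "type", "class")], node_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(edges[, c("source", "target", "n_res", "segment")],
                     edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(nodes = node_path, edges = edge_path))
}

#' Read network node and edge tables written by [write_network()]
#'
#' @param node_path,edge_path Paths to the two TSVs.
#' @return List with data.frames `nodes` and `edges`.
#' @export
read_network <- function(node_path, edge_path) {
  nodes <- utils::read.delim(node_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE)
  if (nrow(edges)) edges$n_res <- as.integer(edges$n_res)
  list(nodes = nodes, edges = edges)
}
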