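#' Abundance table for one omics layer
#'
#' A features x samples matrix of non-negative abundances with a layer tag
#' (\code{"virome"}, \code{"bacteria"} or \code{"metabolite"}) and optional
#' per-feature annotations (taxonomy string, SCFA-producer flag, metabolite
#' class, ...).
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   have unique row and column names, finite non-negative entries.
#' @param layer one of \code{"virome"}, \code{"bacteria"}, \code{"metabolite"}.
#' @param annotations optional data.frame with one row per annotated feature
#'   and a \code{feature_id} column; annotated ids must be a subset of the
#'   table's feature ids.
#' @return an object of class \code{abundance_table}: a list with elements
#'   \code{values}, \code{layer}, \code{annotations}.
#' @export
abundance_table <- function(values, layer, annotations = NULL) {
  layer <- match.arg(layer, c("virome", "bacteria", "metabolite"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)")
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must have feature row names and sample column names")
  if (anyDuplicated(fid)) stop("duplicate feature ids: ",
                               paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid)) stop("duplicate sample ids: ",
                               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(!is.finite(values))) stop("non-finite abundance values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at feature '%s', sample '%s'",
                 fid[bad[1]], sid[bad[2]]))
  }
  if (!is.null(annotations)) {
    if (!is.data.frame(annotations) || is.null(annotations$feature_id))
      stop("`annotations` must be a data.frame with a feature_id column")
    unknown <- setdiff(annotations$feature_id, fid)
    if (length(unknown))
      stop("annotations refer to unknown features: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  structure(list(values = values, layer = layer, annotations = annotations),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> layer=%s: %d features x %d samples\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

layer_prefix <- c(virome = "vir", bacteria = "bac", metabolite = "met",
                  symptom = "sym")

#' Namespace feature ids by layer
#'
#' Prefixes ids with \code{vir:}, \code{bac:}, \code{met:} or \code{sym:} so
#' that merged multi-layer networks have globally unique node ids.
#'
#' @param ids character vector of feature ids.
#' @param layer layer name (\code{virome}, \code{bacteria}, \code{metabolite},
#'   \code{symptom}).
#' @return prefixed ids; already-prefixed ids are returned unchanged.
#' @export
namespace_ids <- function(ids, layer) {
  pre <- layer_prefix[[match.arg(layer, names(layer_prefix))]]
  ifelse(grepl(sprintf("^%s:", pre), ids), ids, paste0(pre, ":", ids))
}

#' Infer the layer of namespaced node ids
#' @param ids character vector of prefixed node ids.
#' @return character vector of layer names.
#' @export
id_layer <- function(ids) {
  pre <- sub(":.*$", "", ids)
  out <- names(layer_prefix)[match(pre, layer_prefix)]
  if (anyNA(out)) stop("ids without a recognised layer prefix: ",
                       paste(utils::head(ids[is.na(out)], 5), collapse = ", "))
  out
}

read_strict_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol0 <- length(parts[[1]])
  ragged <- which(vapply(parts, length, 1L) != ncol0)
  if (length(ragged))
    stop(sprintf("ragged row %d in %s (expected %d fields)", ragged[1], path, ncol0))
  do.call(rbind, parts)
}

#' Read an abundance table from TSV
#'
#' Expects a tab-delimited file whose header row holds sample ids and whose
#' first column holds feature ids. Cells must parse as finite non-negative
#' numbers; malformed input is rejected with the offending row/column named.
#'
#' @param path TSV file path.
#' @param layer layer tag for the resulting table.
#' @param annotations_path optional sidecar TSV with a \code{feature_id}
#'   column plus arbitrary annotation columns.
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path, layer, annotations_path = NULL) {
  m <- read_strict_tsv(path)
  if (nrow(m) < 2 || ncol(m) < 2) stop("abundance TSV needs >=1 feature and >=1 sample")
  sid <- m[1, -1]; fid <- m[-1, 1]
  vals <- suppressWarnings(matrix(as.numeric(m[-1, -1, drop = FALSE]),
                                  nrow = length(fid)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at feature '%s', sample '%s' in %s",
                 fid[bad[1]], sid[bad[2]], path))
  }
  rownames(vals) <- fid; colnames(vals) <- sid
  ann <- NULL
  if (!is.null(annotations_path)) {
    a <- read_strict_tsv(annotations_path)
    ann <- as.data.frame(a[-1, , drop = FALSE], stringsAsFactors = FALSE)
    names(ann) <- a[1, ]
    if (is.null(ann$feature_id)) stop("annotation TSV lacks a feature_id column")
  }
  abundance_table(vals, layer, ann)
}

#' Write an abundance table to TSV
#' @param table an [abundance_table()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_abundance <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  header <- paste(c("feature_id", colnames(v)), collapse = "\t")
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t"), "")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Default symptom-scale definitions
#'
#' Declares the three questionnaires used as symptom factors: a 7-item
#' gastrointestinal symptom scale (GSS, items scored 0-4) and the 20-item
#' Zung self-rating depression (SDS) and anxiety (SAS) scales (items scored
#' 1-4). The SDS is split into the conventional Zung sub-scales: affective
#' items (1, 3), eight physiological items (2, 4-10) and ten psychological
#' items (11-20).
#'
#' @return named list of scale definitions, each with \code{items},
#'   \code{range} and optional \code{subscales}.
#' @export
default_scale_defs <- function() {
  sds_items <- sprintf("sds_%02d", 1:20)
  list(
    GSS = list(items = sprintf("gss_%d", 1:7), range = c(0L, 4L)),
    SDS = list(items = sds_items, range = c(1L, 4L),
               subscales = list(
                 affective     = sds_items[c(1, 3)],
                 physiological = sds_items[c(2, 4:10)],
                 psychological = sds_items[11:20])),
    SAS = list(items = sprintf("sas_%02d", 1:20), range = c(1L, 4L))
  )
}

#' Sample metadata table
#'
#' Holds group labels (\code{case}/\code{control}) and per-item symptom
#' scores for each sample.
#'
#' @param sample_ids unique sample ids.
#' @param group character/factor of \code{"case"}/\code{"control"}, one per
#'   sample.
#' @param symptom_items optional data.frame (samples x items) of ordinal
#'   scores; row order must match \code{sample_ids}.
#' @param scale_defs scale definitions as from [default_scale_defs()]; item
#'   scores are validated against each scale's declared range.
#' @return an object of class \code{sample_table}.
#' @export
sample_table <- function(sample_ids, group, symptom_items = NULL,
                         scale_defs = default_scale_defs()) {
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  group <- as.character(group)
  if (length(group) != length(sample_ids)) stop("one group label per sample required")
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  all_items <- unlist(lapply(scale_defs, `[[`, "items"), use.names = FALSE)
  if (anyDuplicated(all_items)) stop("item ids duplicated across scales")
  if (!is.null(symptom_items)) {
    symptom_items <- as.data.frame(symptom_items)
    rownames(symptom_items) <- sample_ids
    unknown <- setdiff(names(symptom_items), all_items)
    if (length(unknown)) stop("items not declared in scale_defs: ",
                              paste(unknown, collapse = ", "))
    for (sc in names(scale_defs)) {
      its <- intersect(scale_defs[[sc]]$items, names(symptom_items))
      if (!length(its)) next
      rg <- scale_defs[[sc]]$range
      v <- as.matrix(symptom_items[, its, drop = FALSE])
      if (anyNA(v) || any(v < rg[1] | v > rg[2])) {
        bad <- which(is.na(v) | v < rg[1] | v > rg[2], arr.ind = TRUE)[1, ]
        stop(sprintf("item '%s' of sample '%s' outside declared range [%d,%d]",
                     its[bad[2]], sample_ids[bad[1]], rg[1], rg[2]))
      }
    }
  }
  structure(list(sample_ids = sample_ids, group = stats::setNames(group, sample_ids),
                 symptom_items = symptom_items, scale_defs = scale_defs),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples (%d case / %d control), %d symptom items\n",
              length(x$sample_ids), sum(x$group == "case"),
              sum(x$group == "control"),
              if (is.null(x$symptom_items)) 0L else ncol(x$symptom_items)))
  invisible(x)
}

#' Read sample metadata from TSV
#'
#' Expects columns \code{sample_id}, \code{group}, plus one column per
#' declared symptom item. Unknown group labels and out-of-range item scores
#' are rejected.
#'
#' @param path TSV path.
#' @param scale_defs scale definitions; see [default_scale_defs()].
#' @return a [sample_table()].
#' @export
read_metadata <- function(path, scale_defs = default_scale_defs()) {
  m <- read_strict_tsv(path)
  df <- as.data.frame(m[-1, , drop = FALSE], stringsAsFactors = FALSE)
  names(df) <- m[1, ]
  if (is.null(df$sample_id) || is.null(df$group))
    stop("metadata TSV needs sample_id and group columns")
  item_cols <- setdiff(names(df), c("sample_id", "group"))
  items <- NULL
  if (length(item_cols)) {
    items <- as.data.frame(lapply(df[item_cols], function(x) {
      v <- suppressWarnings(as.numeric(x))
      if (anyNA(v)) stop("non-numeric symptom score in ", path)
      v
    }))
  }
  sample_table(df$sample_id, df$group, items, scale_defs)
}

#' Write sample metadata to TSV
#' @param samples a [sample_table()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_metadata <- function(samples, path) {
  stopifnot(inherits(samples, "sample_table"))
  df <- data.frame(sample_id = samples$sample_ids,
                   group = unname(samples$group), stringsAsFactors = FALSE)
  if (!is.null(samples$symptom_items)) df <- cbind(df, samples$symptom_items)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(df, 1, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a co-occurrence network
#'
#' Wraps the edge list of significant pairwise correlations into a simple
#' undirected \pkg{igraph} graph whose vertices carry \code{layer} (inferred
#' from the \code{vir:}/\code{bac:}/\code{met:}/\code{sym:} id prefix) and
#' whose edges carry \code{r}, \code{p}, \code{q} and \code{sign}.
#'
#' @param edges data.frame with columns \code{u}, \code{v}, \code{r},
#'   \code{p}, \code{q}; self-loops and duplicate pairs are rejected.
#' @param nodes optional character vector of node ids to include even when
#'   isolated (default: endpoints of \code{edges} only).
#' @param annotations optional data.frame with \code{feature_id} and
#'   annotation columns copied onto matching vertices.
#' @return an \code{igraph} object (class also \code{omics_network}).
#' @export
omics_network <- function(edges, nodes = NULL, annotations = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("u", "v", "r", "p", "q") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$u == edges$v)) stop("self-loops are not allowed")
    if (any(abs(edges$r) > 1)) stop("|r| must not exceed 1")
    key <- ifelse(edges$u < edges$v, paste(edges$u, edges$v), paste(edges$v, edges$u))
    if (anyDuplicated(key)) stop("duplicate edges for the same node pair")
  }
  ids <- unique(c(nodes, edges$u, edges$v))
  g <- igraph::graph_from_data_frame(
    edges[, c("u", "v", "r", "p", "q"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = ids, layer = id_layer(ids),
                          stringsAsFactors = FALSE))
  if (igraph::ecount(g)) igraph::E(g)$sign <- ifelse(igraph::E(g)$r > 0, 1L, -1L)
  if (!is.null(annotations) && nrow(annotations)) {
    idx <- match(igraph::V(g)$name, annotations$feature_id)
    for (col in setdiff(names(annotations), "feature_id"))
      g <- igraph::set_vertex_attr(g, col, value = annotations[[col]][idx])
  }
  class(g) <- c("omics_network", class(g))
  g
}

#' Write a network to GraphML or edge TSV
#'
#' GraphML keeps all vertex and edge attributes; \code{edge_tsv} writes one
#' edge per line with columns \code{u, v, r, p, q, sign} at full double
#' precision.
#'
#' @param net an \code{igraph}/\code{omics_network}.
#' @param path output path.
#' @param format \code{"graphml"} or \code{"edge_tsv"}.
#' @return invisibly, the path.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- net; class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(net, what = "edges")
    header <- "u\tv\tr\tp\tq\tsign"
    body <- if (nrow(el))
      sprintf("%s\t%s\t%.17g\t%.17g\t%.17g\t%d",
              el$from, el$to, el$r, el$p, el$q, as.integer(el$sign))
    else character()
    writeLines(c(header, body), path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path file path.
#' @param format \code{"graphml"} or \code{"edge_tsv"}.
#' @return an \code{omics_network}.
#' @export
read_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    class(g) <- c("omics_network", class(g))
    return(g)
  }
  m <- read_strict_tsv(path)
  if (nrow(m) == 1) {
    edges <- data.frame(u = character(), v = character(), r = numeric(),
                        p = numeric(), q = numeric())
  } else {
    edges <- data.frame(u = m[-1, 1], v = m[-1, 2],
                        r = as.numeric(m[-1, 3]), p = as.numeric(m[-1, 4]),
                        q = as.numeric(m[-1, 5]), stringsAsFactors = FALSE)
  }
  omics_network(edges)
}

#' Overlap accounting for two feature-id sets
#'
#' Venn-style accounting used e.g. to reconcile OTU inventories of two
#' groups: shared, group-unique and union counts.
#'
#' @param ids_a,ids_b character vectors of feature ids (duplicates ignored).
#' @return list with \code{shared}, \code{only_a}, \code{only_b},
#'   \code{union} counts and the corresponding id vectors.
#' @export
feature_set_overlap <- function(ids_a, ids_b) {
  a <- unique(ids_a); b <- unique(ids_b)
  shared <- intersect(a, b)
  list(shared = length(shared), only_a = length(setdiff(a, b)),
       only_b = length(setdiff(b, a)), union = length(union(a, b)),
       shared_ids = shared, only_a_ids = setdiff(a, b),
       only_b_ids = setdiff(b, a))
}
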