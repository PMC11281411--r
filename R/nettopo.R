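#' Node-level centralities of a co-occurrence network
#'
#' Degree, betweenness, closeness and local clustering coefficient are
#' computed on the unweighted thresholded graph (the significance threshold
#' has already binarised association strength); eigenvector centrality uses
#' |r| edge weights. Betweenness is normalised to [0, 1]. Closeness is
#' computed within each connected component with the Wasserman-Faust
#' correction \eqn{((n_c-1)/\sum d) \cdot ((n_c-1)/(n-1))} so that
#' disconnected networks (common after thresholding) yield finite values;
#' isolated nodes score 0.
#'
#' @param net an [omics_network()] (or any igraph graph; missing \code{r}
#'   weights default to 1).
#' @param weighted_paths if TRUE, betweenness/closeness use 1/|r| path
#'   costs instead of hop counts (non-default variant).
#' @return data.frame with \code{node_id}, \code{degree},
#'   \code{betweenness}, \code{closeness}, \code{eigenvector},
#'   \code{clustering}.
#' @export
centralities <- function(net, weighted_paths = FALSE) {
  if (!igraph::vcount(net)) stop("empty network")
  w <- if (igraph::ecount(net) && !is.null(igraph::E(net)$r))
    abs(igraph::E(net)$r) else rep(1, igraph::ecount(net))
  n <- igraph::vcount(net)
  pw <- if (weighted_paths) 1 / w else NA  # NA => unweighted paths in igraph
  btw <- igraph::betweenness(net, weights = pw, normalized = TRUE)
  comp <- igraph::components(net)
  clo <- numeric(n)
  dmat <- igraph::distances(net, weights = pw)
  for (c_id in seq_len(comp$no)) {
    idx <- which(comp$membership == c_id)
    nc <- length(idx)
    if (nc == 1) { clo[idx] <- 0; next }
    sumd <- rowSums(dmat[idx, idx, drop = FALSE])
    clo[idx] <- ((nc - 1) / sumd) * ((nc - 1) / (n - 1))
  }
  eig <- if (igraph::ecount(net)) {
    ec <- igraph::eigen_centrality(
      net, weights = w,
      options = list(maxiter = 1000L, tol = 1e-8))
    ec$vector
  } else rep(0, n)
  cl <- igraph::transitivity(net, type = "local", isolates = "zero")
  data.frame(node_id = igraph::V(net)$name,
             degree = unname(igraph::degree(net)),
             betweenness = unname(btw), closeness = unname(clo),
             eigenvector = unname(eig), clustering = unname(cl),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Louvain module detection
#'
#' Louvain community detection on |r| edge weights. The run is seeded, so a
#' fixed seed gives an identical partition; modules are relabelled 1, 2, ...
#' by descending size.
#'
#' @param net network with >= 1 edge.
#' @param seed integer seed.
#' @param resolution Louvain resolution parameter (default 1).
#' @return list of class \code{module_partition} with \code{membership}
#'   (named integer vector), \code{modularity} (Q of the returned
#'   partition), \code{sizes}, \code{seed}, \code{resolution}.
#' @export
detect_modules <- function(net, seed = 1, resolution = 1) {
  if (!igraph::ecount(net)) stop("cannot detect modules on an empty edge set")
  w <- if (!is.null(igraph::E(net)$r)) abs(igraph::E(net)$r)
  else rep(1, igraph::ecount(net))
  set.seed(seed)
  cl <- igraph::cluster_louvain(net, weights = w, resolution = resolution)
  memb <- igraph::membership(cl)
  # relabel by descending module size (ties: by smallest original label)
  sz <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sz), names(sz))
  memb <- stats::setNames(as.integer(relab[as.character(memb)]), names(memb))
  structure(list(membership = memb,
                 modularity = igraph::modularity(net, memb, weights = w),
                 sizes = as.integer(table(memb)), seed = seed,
                 resolution = resolution),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules over %d nodes, Q = %.3f\n",
              length(x$sizes), length(x$membership), x$modularity))
  invisible(x)
}

#' Within/among-module connectivity (Zi-Pi) node roles
#'
#' For each node i with degree \eqn{k_i}: the within-module degree z-score
#' \eqn{Z_i = (\kappa_i - \bar\kappa_{m(i)}) / \sigma_{\kappa, m(i)}}
#' (\eqn{\kappa_i} = links of i into its own module; \eqn{Z_i = 0} when the
#' module's sd is zero) and the participation coefficient
#' \eqn{P_i = 1 - \sum_s (\kappa_{is}/k_i)^2}. Roles follow the
#' Guimera-Amaral convention: module hub (\eqn{Z_i \ge} \code{z_thr},
#' \eqn{P_i <} \code{p_thr}), connector (\eqn{Z_i <} \code{z_thr},
#' \eqn{P_i \ge} \code{p_thr}), network hub (both), peripheral (neither).
#' Degree-0 nodes have undefined Pi (NA) and are flagged peripheral.
#'
#' @param net the network.
#' @param partition a \code{module_partition} (or named membership vector)
#'   covering all nodes.
#' @param z_thr,p_thr role thresholds (defaults 2.5 and 0.62).
#' @return data.frame with \code{node_id}, \code{degree}, \code{Zi},
#'   \code{Pi}, \code{role}.
#' @export
zi_pi <- function(net, partition, z_thr = 2.5, p_thr = 0.62) {
  memb <- if (inherits(partition, "module_partition")) partition$membership
  else partition
  ids <- igraph::V(net)$name
  if (!all(ids %in% names(memb))) stop("partition must cover all nodes")
  memb <- memb[ids]
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE) > 0
  k <- rowSums(adj)
  mods <- sort(unique(memb))
  # kappa[i, s] = links from node i into module s
  kappa <- vapply(mods, function(s) rowSums(adj[, memb == s, drop = FALSE]),
                  numeric(length(ids)))
  if (is.null(dim(kappa))) kappa <- matrix(kappa, nrow = length(ids))
  own <- kappa[cbind(seq_along(ids), match(memb, mods))]
  zi <- numeric(length(ids))
  for (s in mods) {
    idx <- which(memb == s)
    mu <- mean(own[idx]); sdv <- stats::sd(own[idx])
    zi[idx] <- if (length(idx) < 2 || is.na(sdv) || sdv == 0) 0
    else (own[idx] - mu) / sdv
  }
  pi_v <- ifelse(k == 0, NA_real_, 1 - rowSums((kappa / pmax(k, 1))^2))
  role <- ifelse(is.na(pi_v), "peripheral",
          ifelse(zi >= z_thr & pi_v >= p_thr, "network hub",
          ifelse(zi >= z_thr, "module hub",
          ifelse(pi_v >= p_thr, "connector", "peripheral"))))
  data.frame(node_id = ids, degree = unname(k), Zi = zi, Pi = unname(pi_v),
             role = role, row.names = NULL, stringsAsFactors = FALSE)
}

#' Log-log least-squares power-law fit of the degree distribution
#'
#' Regresses log(frequency) on log(degree) over observed degrees >= 1 and
#' reports the slope and R^2. A descriptive check of scale-free shape, not
#' a maximum-likelihood fit.
#'
#' @param net network whose positive-degree distribution spans >= 5
#'   distinct degrees.
#' @return list with \code{slope}, \code{R2}, \code{n_degrees}.
#' @export
degree_powerlaw <- function(net) {
  k <- igraph::degree(net)
  tab <- table(k[k >= 1])
  if (length(tab) < 5)
    stop("need >= 5 distinct positive degrees for a power-law fit")
  x <- log(as.numeric(names(tab))); y <- log(as.numeric(tab))
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; an R^2 of 1 is a legitimate outcome here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]), R2 = r2, n_degrees = length(tab))
}

#' Fraction of positive-correlation edges
#' @param net network with >= 1 edge and edge attribute \code{r}.
#' @return fraction of edges with r > 0.
#' @export
positive_edge_fraction <- function(net) {
  if (!igraph::ecount(net)) stop("network has no edges")
  mean(igraph::E(net)$r > 0)
}

top_modules <- function(partition, top_k) {
  memb <- if (inherits(partition, "module_partition")) partition$membership
  else partition
  sz <- sort(table(memb), decreasing = TRUE)
  utils::head(names(sz), top_k)
}

#' Shared-node accounting between the largest modules of two partitions
#'
#' For the \code{top_k} largest modules of each partition, an UpSet-style
#' table of pairwise intersection sizes and the percentage each
#' intersection represents of the union of the two modules.
#'
#' @param part_a,part_b \code{module_partition}s (or named membership
#'   vectors) over overlapping node universes.
#' @param top_k number of largest modules per partition (default 5).
#' @return data.frame with \code{module_a}, \code{module_b}, \code{size_a},
#'   \code{size_b}, \code{shared}, \code{pct_of_union}.
#' @export
module_overlap <- function(part_a, part_b, top_k = 5) {
  ma <- if (inherits(part_a, "module_partition")) part_a$membership else part_a
  mb <- if (inherits(part_b, "module_partition")) part_b$membership else part_b
  ta <- top_modules(ma, top_k); tb <- top_modules(mb, top_k)
  grid <- expand.grid(module_a = ta, module_b = tb, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    na <- names(ma)[ma == grid$module_a[i]]
    nb <- names(mb)[mb == grid$module_b[i]]
    sh <- length(intersect(na, nb))
    data.frame(module_a = grid$module_a[i], module_b = grid$module_b[i],
               size_a = length(na), size_b = length(nb), shared = sh,
               pct_of_union = 100 * sh / length(union(na, nb)))
  })
  do.call(rbind, res)
}

#' Compare node-level metrics between two networks
#'
#' Two-sided Mann-Whitney U test per metric between the node-level values
#' of two [centralities()] tables, optionally restricted to a node subset
#' (e.g. SCFA-producing bacteria).
#'
#' @param topo_a,topo_b data.frames as returned by [centralities()].
#' @param subset optional character vector of node ids; must intersect both
#'   tables.
#' @return data.frame with \code{metric}, \code{U}, \code{p},
#'   \code{median_a}, \code{median_b}.
#' @export
compare_node_metrics <- function(topo_a, topo_b, subset = NULL) {
  if (!nrow(topo_a) || !nrow(topo_b)) stop("both topology tables must be non-empty")
  if (!is.null(subset)) {
    ka <- topo_a$node_id %in% subset; kb <- topo_b$node_id %in% subset
    if (!any(ka) || !any(kb))
      stop("subset does not intersect the nodes of both networks")
    topo_a <- topo_a[ka, , drop = FALSE]; topo_b <- topo_b[kb, , drop = FALSE]
  }
  metrics <- setdiff(names(topo_a), "node_id")
  res <- lapply(metrics, function(m) {
    a <- topo_a[[m]]; b <- topo_b[[m]]
    wt <- if (length(unique(c(a, b))) == 1)
      list(statistic = c(W = length(a) * length(b) / 2), p.value = 1)
    else suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    data.frame(metric = m, U = unname(wt$statistic), p = wt$p.value,
               median_a = stats::median(a), median_b = stats::median(b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-module composition and concentration summary
#'
#' For every module: size, share of network nodes and (when annotations are
#' given) the percentage composition over an annotation column. Also
#' reports the share of nodes held by the \code{ceiling(0.25 * n_modules)}
#' largest modules.
#'
#' @param net the network.
#' @param partition a \code{module_partition} or named membership vector.
#' @param annotation optional name of a vertex attribute (e.g.
#'   \code{"taxonomy"}) to tabulate within modules.
#' @return list with \code{modules} (data.frame: module, size, node_share),
#'   \code{top25_share} (percentage of nodes in the top-25% largest
#'   modules) and, if requested, \code{composition} (long data.frame:
#'   module, annotation value, count, pct).
#' @export
module_summary <- function(net, partition, annotation = NULL) {
  memb <- if (inherits(partition, "module_partition")) partition$membership
  else partition
  ids <- igraph::V(net)$name
  if (!all(ids %in% names(memb))) stop("partition must cover all nodes")
  memb <- memb[ids]
  sz <- sort(table(memb), decreasing = TRUE)
  mods <- data.frame(module = names(sz), size = as.integer(sz),
                     node_share = 100 * as.integer(sz) / length(ids),
                     stringsAsFactors = FALSE)
  n_top <- ceiling(0.25 * nrow(mods))
  out <- list(modules = mods,
              top25_share = sum(mods$size[seq_len(n_top)]) / length(ids) * 100)
  if (!is.null(annotation)) {
    ann <- igraph::vertex_attr(net, annotation)
    if (is.null(ann)) stop("no vertex attribute named '", annotation, "'")
    comp <- lapply(names(sz), function(m) {
      vals <- ann[memb == m]
      tb <- sort(table(vals, useNA = "ifany"), decreasing = TRUE)
      data.frame(module = m, value = names(tb), count = as.integer(tb),
                 pct = 100 * as.integer(tb) / length(vals),
                 stringsAsFactors = FALSE)
    })
    out$composition <- do.call(rbind, comp)
  }
  out
}

#' Count symptom-incident edges by partner layer
#'
#' In a symptom-augmented network, tabulates edges incident to symptom
#' nodes by the layer of the non-symptom endpoint.
#'
#' @param net a symptom-augmented network.
#' @return named integer vector of symptom-incident edge counts keyed by
#'   partner layer (virome, bacteria, metabolite).
#' @export
symptom_edge_counts <- function(net) {
  if (!igraph::ecount(net)) stop("network has no edges")
  el <- igraph::as_data_frame(net, what = "edges")
  lu <- id_layer(el$from); lv <- id_layer(el$to)
  inc <- xor(lu == "symptom", lv == "symptom")
  partner <- ifelse(lu[inc] == "symptom", lv[inc], lu[inc])
  counts <- table(factor(partner, levels = c("virome", "bacteria", "metabolite")))
  stats::setNames(as.integer(counts), names(counts))
}

#' Distribution of symptom factors over network modules
#'
#' Counts and percentages of symptom-layer nodes per module, plus the
#' cumulative share captured by the top-k modules ranked by symptom count.
#'
#' @param net a symptom-augmented network.
#' @param partition a \code{module_partition} or named membership vector.
#' @return data.frame with \code{module}, \code{n_symptom},
#'   \code{pct_symptom}, \code{cum_pct} (rows ordered by descending symptom
#'   count; percentages are of all symptom nodes in the network).
#' @export
symptom_clustering <- function(net, partition) {
  memb <- if (inherits(partition, "module_partition")) partition$membership
  else partition
  ids <- igraph::V(net)$name
  sym <- ids[igraph::V(net)$layer == "symptom"]
  if (!length(sym)) stop("network contains no symptom nodes")
  if (!all(sym %in% names(memb))) stop("partition must cover all symptom nodes")
  tb <- sort(table(memb[sym]), decreasing = TRUE)
  data.frame(module = names(tb), n_symptom = as.integer(tb),
             pct_symptom = 100 * as.integer(tb) / length(sym),
             cum_pct = cumsum(100 * as.integer(tb) / length(sym)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score symptom questionnaires
#'
#' Per-sample totals: GSS total is the plain item sum; the Zung SDS and SAS
#' use the standard index \code{round(raw sum * 1.25)}. Declared sub-scales
#' (e.g. the SDS physiological/psychological item sets) are summed as raw
#' sub-scores.
#'
#' @param samples a [sample_table()] with symptom items.
#' @return data.frame with one row per sample: raw totals, Zung indices and
#'   any sub-scale sums.
#' @export
score_scales <- function(samples) {
  stopifnot(inherits(samples, "sample_table"))
  if (is.null(samples$symptom_items)) stop("sample_table has no symptom items")
  items <- samples$symptom_items
  out <- data.frame(sample_id = samples$sample_ids, stringsAsFactors = FALSE)
  for (sc in names(samples$scale_defs)) {
    def <- samples$scale_defs[[sc]]
    missing <- setdiff(def$items, names(items))
    if (length(missing))
      stop(sprintf("missing item '%s' for scale %s", missing[1], sc))
    raw <- rowSums(items[, def$items, drop = FALSE])
    out[[paste0(sc, "_raw")]] <- raw
    if (sc %in% c("SDS", "SAS"))
      out[[paste0(sc, "_index")]] <- round(raw * 1.25)
    for (sub in names(def$subscales))
      out[[paste(sc, sub, sep = "_")]] <-
        rowSums(items[, def$subscales[[sub]], drop = FALSE])
  }
  out
}
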