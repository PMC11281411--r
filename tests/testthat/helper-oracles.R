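# Brute-force graph oracles, independent of igraph: plain Floyd-Warshall
# distances, geodesic counting by dynamic programming, and direct formula
# evaluation. Used to validate the centrality surface on small graphs.

bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf); diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bf_geodesic_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(adj[, t] > 0 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

bf_centralities <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  sigma <- bf_geodesic_counts(adj, d)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || sigma[s, t] == 0) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- acc
  }
  btw_norm <- if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
  clo <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    nc <- length(reach) + 1
    clo[v] <- if (nc > 1)
      ((nc - 1) / sum(d[v, reach])) * ((nc - 1) / (n - 1)) else 0
  }
  clust <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0); k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, 0)
  deg <- rowSums(adj > 0)
  list(degree = deg, betweenness = btw_norm, betweenness_raw = btw,
       closeness = clo, clustering = clust)
}

random_adj <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  adj + t(adj)
}

graph_from_adj <- function(adj, prefix = "vir") {
  rownames(adj) <- colnames(adj) <- sprintf("%s:n%02d", prefix, seq_len(nrow(adj)))
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(u = rownames(adj)[idx[, 1]], v = rownames(adj)[idx[, 2]],
                      r = 0.9, p = 1e-6, q = 1e-5, stringsAsFactors = FALSE)
  omics_network(edges, nodes = rownames(adj))
}

pair_key <- function(u, v) paste(pmin(u, v), pmax(u, v))

# tiny deterministic abundance table
toy_table <- function(values, layer = "bacteria") {
  abundance_table(values, layer)
}
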