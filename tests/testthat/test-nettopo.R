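test_that("centralities match hand values on star, triangle and cycle", {
  # star K_{1,3}
  adj <- matrix(0, 4, 4); adj[1, 2:4] <- 1; adj <- adj + t(adj)
  net <- graph_from_adj(adj)
  ct <- centralities(net)
  expect_equal(ct$degree, c(3, 1, 1, 1))
  expect_equal(ct$betweenness[1] * choose(3, 2), 3)  # 3 leaf pairs via centre
  expect_equal(ct$betweenness[2], 0)
  # triangle: clustering 1 everywhere
  tri <- matrix(1, 3, 3) - diag(3)
  ct2 <- centralities(graph_from_adj(tri))
  expect_true(all(ct2$clustering == 1))
  # 6-cycle: vertex-transitive, all metrics equal across nodes
  cyc <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; cyc[i, j] <- 1; cyc[j, i] <- 1 }
  ct3 <- centralities(graph_from_adj(cyc))
  for (m in c("degree", "betweenness", "closeness", "eigenvector", "clustering"))
    expect_equal(diff(range(ct3[[m]])), 0, tolerance = 1e-6)
})

test_that("centralities agree with brute-force path enumeration on small graphs", {
  cases <- c(lapply(1:12, function(s) random_adj(sample(4:7, 1), 0.45, s)),
             lapply(13:18, function(s) random_adj(7, 0.25, s)))  # disconnected-prone
  for (adj in cases) {
    if (sum(adj) == 0) next
    net <- graph_from_adj(adj)
    got <- centralities(net)
    want <- bf_centralities(adj)
    expect_equal(got$degree, unname(want$degree))
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
    expect_equal(got$clustering, want$clustering, tolerance = 1e-12)
    # eigenvector centrality against a dense eigendecomposition
    if (igraph::ecount(net)) {
      comp <- igraph::components(net)
      ev <- eigen(adj * 0.9)$vectors[, 1]   # |r| weights are all 0.9
      ev <- abs(ev) / max(abs(ev))
      # compare on the dominant component only (power iteration lives there)
      main <- comp$membership == which.max(tabulate(comp$membership))
      if (sum(main) == nrow(adj))
        expect_equal(got$eigenvector, ev, tolerance = 1e-5)
    }
  }
})

test_that("Louvain modules: disjoint triangles, single clique, determinism", {
  tri2 <- matrix(0, 6, 6)
  for (off in c(0, 3)) tri2[off + 1:3, off + 1:3] <- 1
  diag(tri2) <- 0
  net <- graph_from_adj(tri2)
  part <- detect_modules(net, seed = 3)
  expect_equal(length(part$sizes), 2)
  expect_equal(part$modularity, 0.5)    # 2 * (3/6 - (6/12)^2)
  expect_equal(sort(part$sizes), c(3L, 3L))
  clique <- matrix(1, 5, 5) - diag(5)
  p2 <- detect_modules(graph_from_adj(clique), seed = 3)
  expect_equal(length(p2$sizes), 1)
  expect_equal(p2$modularity, 0)
  # fixed seed -> identical partition
  set.seed(99)  # outer RNG state must not leak in
  p3 <- detect_modules(net, seed = 3)
  expect_identical(part$membership, p3$membership)
  expect_error(detect_modules(omics_network(
    data.frame(u = character(), v = character(), r = numeric(),
               p = numeric(), q = numeric()))), "empty")
  # never below the trivial single-module partition's Q
  for (s in 1:5) {
    adj <- random_adj(10, 0.3, s + 100)
    if (sum(adj) == 0) next
    g <- graph_from_adj(adj)
    triv <- igraph::modularity(g, rep(1, 10), weights = abs(igraph::E(g)$r))
    expect_gte(detect_modules(g, seed = 1)$modularity, triv)
  }
})

test_that("Zi-Pi definitions and role assignment", {
  # node vir:n01 with k = 2 split across two modules -> Pi = 0.5
  edges <- data.frame(u = c("vir:n01", "vir:n01", "vir:n02", "vir:n04"),
                      v = c("vir:n02", "vir:n04", "vir:n03", "vir:n05"),
                      r = 0.9, p = 1e-6, q = 1e-5)
  net <- omics_network(edges)
  memb <- c("vir:n01" = 1L, "vir:n02" = 1L, "vir:n03" = 1L,
            "vir:n04" = 2L, "vir:n05" = 2L)
  tb <- zi_pi(net, memb)
  expect_equal(tb$Pi[tb$node_id == "vir:n01"], 0.5)
  # all links inside own module -> Pi = 0
  expect_equal(tb$Pi[tb$node_id == "vir:n03"], 0)
  # within-module degree equal to the module mean -> Zi = 0
  tri2 <- matrix(0, 6, 6)
  for (off in c(0, 3)) tri2[off + 1:3, off + 1:3] <- 1
  diag(tri2) <- 0
  net2 <- graph_from_adj(tri2)
  memb2 <- setNames(rep(1:2, each = 3L), igraph::V(net2)$name)
  tb2 <- zi_pi(net2, memb2)
  expect_true(all(tb2$Zi == 0))
  expect_true(all(tb2$Pi == 0))
  expect_true(all(tb2$role == "peripheral"))
  # invariants on random graphs: module-mean Zi = 0, Pi in [0, 1)
  for (s in 1:5) {
    adj <- random_adj(12, 0.35, s + 40)
    g <- graph_from_adj(adj)
    if (!igraph::ecount(g)) next
    part <- detect_modules(g, seed = 1)
    roles <- zi_pi(g, part)
    for (m in unique(part$membership)) {
      idx <- roles$node_id %in% names(part$membership)[part$membership == m]
      if (sum(idx) >= 2) expect_lt(abs(mean(roles$Zi[idx])), 1e-9)
    }
    expect_true(all(is.na(roles$Pi) | (roles$Pi >= 0 & roles$Pi < 1)))
    expect_true(all(roles$role[is.na(roles$Pi)] == "peripheral"))
  }
})

test_that("degree power-law fit recovers a constructed k^-2 histogram", {
  # degree histogram exactly freq = 3600 * k^-2 for k = 1..5, built from
  # disjoint pieces with known degrees: matched pairs (k=1), a cycle (k=2),
  # and complete graphs K4/K5/K6 (k=3,4,5)
  pieces <- c(replicate(1800, igraph::make_full_graph(2), simplify = FALSE),
              list(igraph::make_ring(900)),
              replicate(100, igraph::make_full_graph(4), simplify = FALSE),
              replicate(45, igraph::make_full_graph(5), simplify = FALSE),
              replicate(24, igraph::make_full_graph(6), simplify = FALSE))
  g <- do.call(igraph::disjoint_union, pieces)
  expect_equal(as.integer(table(igraph::degree(g))), c(3600L, 900L, 400L, 225L, 144L))
  res <- degree_powerlaw(g)
  expect_equal(res$slope, -2, tolerance = 1e-9)
  expect_equal(res$R2, 1, tolerance = 1e-9)
  # off-trend noise at an extra degree lowers R^2
  g2 <- igraph::disjoint_union(g, do.call(igraph::disjoint_union,
    replicate(50, igraph::make_full_graph(9), simplify = FALSE)))
  expect_lt(degree_powerlaw(g2)$R2, res$R2)
  # regular graph (one distinct degree) -> error
  tri <- matrix(1, 3, 3) - diag(3)
  expect_error(degree_powerlaw(graph_from_adj(tri)), "distinct")
})

test_that("positive edge fraction", {
  edges <- data.frame(u = c("vir:a", "vir:b", "vir:c", "vir:d"),
                      v = c("vir:b", "vir:c", "vir:d", "vir:a"),
                      r = c(0.9, 0.85, -0.82, -0.95), p = 1e-6, q = 1e-5)
  expect_equal(positive_edge_fraction(omics_network(edges)), 0.5)
  expect_equal(positive_edge_fraction(omics_network(edges[1:2, ])), 1.0)
  expect_error(positive_edge_fraction(omics_network(edges[0, ])), "no edges")
})

test_that("module overlap matches brute-force set intersections", {
  a <- setNames(c(1, 1, 1, 2, 2, 3), paste0("vir:n", 1:6))
  b <- setNames(c(1, 1, 2, 2, 2, 2), paste0("vir:n", 1:6))
  ov <- module_overlap(a, b, top_k = 2)
  for (i in seq_len(nrow(ov))) {
    na <- names(a)[a == ov$module_a[i]]
    nb <- names(b)[b == ov$module_b[i]]
    expect_equal(ov$shared[i], length(intersect(na, nb)))
    expect_equal(ov$pct_of_union[i],
                 100 * length(intersect(na, nb)) / length(union(na, nb)))
  }
  # identical partitions: diagonal intersections equal module sizes
  ov2 <- module_overlap(a, a, top_k = 3)
  diag_rows <- ov2[ov2$module_a == ov2$module_b, ]
  expect_equal(diag_rows$shared, diag_rows$size_a)
  # disjoint node universes: all zeros
  b2 <- setNames(c(1, 1, 2), paste0("vir:m", 1:3))
  expect_true(all(module_overlap(a, b2, top_k = 2)$shared == 0))
})

test_that("node-metric comparison: identity, shift power, subset contract", {
  set.seed(60)
  adj <- random_adj(50, 0.15, 61)
  topo <- centralities(graph_from_adj(adj))
  same <- compare_node_metrics(topo, topo)
  expect_true(all(same$p == 1))
  shifted <- topo
  for (m in setdiff(names(topo), "node_id")) shifted[[m]] <- shifted[[m]] + 100
  res <- compare_node_metrics(topo, shifted)
  expect_true(all(res$p < 0.001))
  expect_error(compare_node_metrics(topo, shifted, subset = "vir:nope"),
               "subset")
  sub <- topo$node_id[1:10]
  res_sub <- compare_node_metrics(topo, shifted, subset = sub)
  expect_true(all(res_sub$p < 0.01))
  # swap symmetry of the two-sided p
  expect_equal(compare_node_metrics(shifted, topo)$p, res$p)
})

test_that("module summary: shares, composition percentages, top-25% capture", {
  edges <- data.frame(u = paste0("vir:a", 1:4), v = paste0("vir:b", 1:4),
                      r = 0.9, p = 1e-6, q = 1e-5)
  ann <- data.frame(feature_id = c(paste0("vir:a", 1:4), paste0("vir:b", 1:4)),
                    family = c("Sipho", "Sipho", "Micro", "Myo",
                               "Sipho", "Micro", "Micro", "Myo"))
  net <- omics_network(edges, annotations = ann)
  memb <- setNames(rep(1L, 8), igraph::V(net)$name)
  ms <- module_summary(net, memb, annotation = "family")
  expect_equal(ms$modules$node_share, 100)
  expect_equal(ms$top25_share, 100)
  expect_equal(sum(ms$composition$pct), 100, tolerance = 1e-9)
  sipho <- ms$composition$pct[ms$composition$value == "Sipho"]
  expect_equal(sipho, 100 * 3 / 8)
  # worked composition check: 84 of 259 nodes labelled X -> 32.4%
  expect_equal(round(100 * 84 / 259, 1), 32.4)
})

test_that("symptom clustering percentages and scale scoring", {
  # network whose largest module holds 21 of 48 symptom nodes
  sym <- sprintf("sym:item%02d", 1:48)
  anchor <- sprintf("vir:a%02d", 1:48)
  edges <- data.frame(u = sym, v = anchor, r = 0.9, p = 1e-6, q = 1e-5)
  net <- omics_network(edges)
  memb <- setNames(c(rep(1L, 21), rep(2L, 15), rep(3L, 12),
                     rep(4L, 48)), c(sym, anchor))
  sc <- symptom_clustering(net, memb)
  expect_equal(sc$pct_symptom[1], 43.75)
  expect_equal(sum(sc$pct_symptom), 100, tolerance = 1e-9)
  one <- symptom_clustering(net, setNames(rep(1L, 96), c(sym, anchor)))
  expect_equal(one$pct_symptom, 100)
  expect_error(symptom_clustering(graph_from_adj(random_adj(4, 1, 1)),
                                  setNames(rep(1L, 4), sprintf("vir:n%02d", 1:4))),
               "no symptom nodes")
})

test_that("scale scoring follows the Zung index convention", {
  defs <- default_scale_defs()
  n_items <- vapply(defs, function(d) length(d$items), 1L)
  expect_identical(unname(n_items), c(7L, 20L, 20L))
  items <- as.data.frame(matrix(1, 2, 40))
  names(items) <- c(defs$SDS$items, defs$SAS$items)
  items <- cbind(items, setNames(as.data.frame(matrix(0, 2, 7)), defs$GSS$items))
  st <- sample_table(c("s1", "s2"), c("case", "control"), items, defs)
  sc <- score_scales(st)
  expect_equal(sc$SDS_raw, c(20, 20))
  expect_equal(sc$SDS_index, c(25, 25))       # round(20 * 1.25)
  expect_equal(sc$GSS_raw, c(0, 0))
  expect_equal(sc$SDS_physiological, c(8, 8))
  expect_equal(sc$SDS_psychological, c(10, 10))
  expect_true(all(sc$SDS_physiological + sc$SDS_psychological +
                    sc$SDS_affective == sc$SDS_raw))
  st_missing <- sample_table(c("s1", "s2"), c("case", "control"),
                             items[, -1], defs)
  expect_error(score_scales(st_missing), "missing item")
})
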