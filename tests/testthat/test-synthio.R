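small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_features_per_layer = c(virome = 60, bacteria = 50, metabolite = 40),
         n_modules = 3, block_size = 6, n_diff_features = 5),
    list(...))
  do.call(sim_config, args)
}

test_that("config invariants are enforced", {
  expect_error(sim_config(n_case = 2), ">= 3")
  expect_error(sim_config(rho_within = 1), "rho_within")
  expect_error(sim_config(zero_prob = 1), "zero_prob")
  expect_error(small_cfg(n_diff_features = 1000), "exceed")
  expect_error(sim_config(n_features_per_layer = c(virome = 10)), "must name")
})

test_that("identical seeds give bit-identical datasets, different seeds differ", {
  a <- generate_multiomics(small_cfg(seed = 7))
  b <- generate_multiomics(small_cfg(seed = 7))
  expect_identical(a$tables$virome$values, b$tables$virome$values)
  expect_identical(a$tables$bacteria$values, b$tables$bacteria$values)
  expect_identical(a$truth, b$truth)
  sa <- generate_symptoms(small_cfg(seed = 7), a$truth)
  sb <- generate_symptoms(small_cfg(seed = 7), b$truth)
  expect_identical(sa$symptom_items, sb$symptom_items)
  c <- generate_multiomics(small_cfg(seed = 8))
  expect_false(identical(a$tables$virome$values, c$tables$virome$values))
  # serialization round-trip is stable too
  d1 <- withr::local_tempdir()
  write_simulation(a, sa, d1, small_cfg(seed = 7))
  back <- read_abundance(file.path(d1, "virome.tsv"), "virome")
  expect_equal(back$values, a$tables$virome$values, tolerance = 1e-15)
})

test_that("planted structure has the declared shape", {
  cfg <- small_cfg(seed = 3)
  sim <- generate_multiomics(cfg)
  memb <- sim$truth$block_membership
  expect_equal(sum(memb > 0), 3 * 6 * 3)       # blocks x size x layers
  # true edges are exactly the within-block pairs
  for (b in 1:3) {
    ids <- names(memb)[memb == b]
    expect_equal(sum(sim$truth$true_edges$block == b), choose(length(ids), 2))
  }
  te <- sim$truth$true_edges
  expect_true(all(memb[te$u] == memb[te$v]))
  # cross-layer blocks contain features from several layers
  expect_gt(length(unique(id_layer(names(memb)[memb == 1]))), 1)
  # layer-private blocks do not
  simp <- generate_multiomics(small_cfg(seed = 3, cross_layer = FALSE))
  membp <- simp$truth$block_membership
  for (b in unique(membp[membp > 0]))
    expect_length(unique(id_layer(names(membp)[membp == b])), 1)
  # diff features are background features, present per layer
  expect_equal(nrow(sim$truth$diff_features), 5 * 3)
  expect_true(all(memb[sim$truth$diff_features$feature_id] == 0))
  # zero fraction approximates zero_prob under censoring
  zf <- mean(sim$tables$virome$values == 0)
  expect_lt(abs(zf - cfg$zero_prob), 0.05)
})

test_that("rho_within = 0 gives null-calibrated planted pairs", {
  # with no correlation and no group effect, block pairs behave as nulls
  hits <- 0; total <- 0
  for (s in 1:6) {
    cfg <- sim_config(n_case = 30, n_control = 30,
                      n_features_per_layer = c(virome = 60, bacteria = 40,
                                               metabolite = 40),
                      n_modules = 4, block_size = 10, rho_within = 0,
                      n_diff_features = 0, seed = 100 + s)
    sim <- generate_multiomics(cfg)
    cm <- spearman_matrix(sim$tables$virome)
    ps <- cm$p[upper.tri(cm$p)]
    hits <- hits + sum(ps < 0.01, na.rm = TRUE)
    total <- total + sum(!is.na(ps))
  }
  rate <- hits / total
  se <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(rate - 0.01), 3 * se + 0.003)
})

test_that("true-edge recovery is strong at high rho and monotone in rho and n", {
  recall_at <- function(rho, n_per_group, seed) {
    cfg <- sim_config(n_case = n_per_group, n_control = n_per_group,
                      n_features_per_layer = c(virome = 60, bacteria = 50,
                                               metabolite = 40),
                      n_modules = 3, block_size = 6, rho_within = rho,
                      n_diff_features = 0, seed = seed)
    sim <- generate_multiomics(cfg)
    case <- sim$samples$group == "case"
    rec <- vapply(sim$tables, function(tb) {
      tb$values <- tb$values[, case]
      cm <- spearman_matrix(tb)
      el <- igraph::as_data_frame(build_network(cm, mode = "single"), "edges")
      te <- sim$truth$true_edges
      lay <- id_layer(rownames(tb$values))[1]
      te <- te[id_layer(te$u) == lay & id_layer(te$v) == lay, ]
      mean(pair_key(te$u, te$v) %in% pair_key(el$from, el$to))
    }, 0)
    mean(rec)
  }
  r95 <- vapply(1:5, function(s) recall_at(0.95, 60, 200 + s), 0)
  expect_gte(mean(r95), 0.9)
  # monotone (up to simulation noise) over a 3-point rho grid and n grid
  r_grid <- vapply(c(0.5, 0.8, 0.95), function(rho)
    mean(vapply(1:3, function(s) recall_at(rho, 40, 300 + s), 0)), 0)
  expect_true(all(diff(r_grid) >= -0.02))
  n_grid <- vapply(c(12, 30, 60), function(n)
    mean(vapply(1:3, function(s) recall_at(0.9, n, 400 + s), 0)), 0)
  expect_true(all(diff(n_grid) >= -0.02))
})

test_that("censoring zeros preserve planted rank structure better than independent masking", {
  obs_rho <- function(zero_mode) {
    cfg <- sim_config(n_case = 60, n_control = 60, rho_within = 0.95,
                      n_features_per_layer = c(virome = 60, bacteria = 50,
                                               metabolite = 40),
                      n_modules = 3, block_size = 6, n_diff_features = 0,
                      zero_prob = 0.1, zero_mode = zero_mode, seed = 77)
    sim <- generate_multiomics(cfg)
    v <- sim$tables$virome$values
    te <- sim$truth$true_edges
    te <- te[id_layer(te$u) == "virome" & id_layer(te$v) == "virome", ]
    mean(vapply(seq_len(nrow(te)), function(i)
      cor(v[te$u[i], ], v[te$v[i], ], method = "spearman"), 0))
  }
  r_cens <- obs_rho("censor")
  r_ind <- obs_rho("independent")
  expect_gt(r_cens, 0.9)         # censoring keeps the target in reach
  expect_gt(r_cens, r_ind + 0.1) # independent masking attenuates sharply
})

test_that("symptom items couple to their latent blocks as configured", {
  cfg <- sim_config(n_case = 20, n_control = 20, rho_within = 0.9,
                    n_features_per_layer = c(virome = 60, bacteria = 50,
                                             metabolite = 40),
                    n_modules = 3, block_size = 6, n_diff_features = 0,
                    seed = 17)
  sim <- generate_multiomics(cfg)
  # zero loading: symptom-factor correlations centred at 0
  st0 <- generate_symptoms(cfg, sim$truth,
                           item_loadings = default_item_loadings(0))
  r0 <- cor(st0$symptom_items$gss_1, sim$truth$latent_factors[, 1],
            method = "spearman")
  expect_lt(abs(r0), 0.45)
  # loading 1, no discretization: perfect rank correlation with the factor
  st1 <- generate_symptoms(cfg, sim$truth,
                           item_loadings = default_item_loadings(1),
                           discretize = FALSE)
  expect_equal(cor(st1$symptom_items$gss_1, sim$truth$latent_factors[, 1],
                   method = "spearman"), 1)
  # loading 0.9 with discretization: strong rank correlation survives
  st9 <- generate_symptoms(cfg, sim$truth,
                           item_loadings = default_item_loadings(0.9))
  expect_gt(cor(st9$symptom_items$sds_01, sim$truth$latent_factors[, 2],
                method = "spearman"), 0.6)
  # items are on the declared ordinal grids
  expect_true(all(st9$symptom_items$gss_1 %in% 0:4))
  expect_true(all(st9$symptom_items$sds_01 %in% 1:4))
})

test_that("planted symptom-omics edges are recovered at heatmap thresholds", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_case = 20, n_control = 20, rho_within = 0.9,
                      n_features_per_layer = c(virome = 60, bacteria = 50,
                                               metabolite = 40),
                      n_modules = 3, block_size = 6, n_diff_features = 0,
                      seed = 500 + s)
    sim <- generate_multiomics(cfg)
    st <- generate_symptoms(cfg, sim$truth,
                            item_loadings = default_item_loadings(0.9))
    # block-1 virome features vs the gss_1 item that loads on block 1
    memb <- sim$truth$block_membership
    feats <- names(memb)[memb == 1 & grepl("^vir:", names(memb))]
    x <- sim$tables$virome$values[feats, , drop = FALSE]
    y <- t(as.matrix(st$symptom_items[, "gss_1", drop = FALSE]))
    rownames(y) <- "sym:gss_1"
    scr <- correlation_screen(x, y, r_min = 0.6, p_max = 0.05)
    nrow(scr) / length(feats)
  }, 0)
  expect_gte(mean(hits >= 0.5), 0.8)
  expect_gt(mean(hits), 0.6)
})
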