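#' Simulation configuration for synthetic multiomics data
#'
#' Defines a two-group (case/control) study with three abundance layers and
#' planted structure: latent correlation blocks (within or across layers),
#' group-differential features, zero inflation and symptom items coupled to
#' the latent blocks. Defaults mirror the emulated study design: 12 case vs
#' 8 control samples; block correlations that survive the per-layer
#' marginal transforms because the generator is a latent Gaussian copula
#' and Spearman correlation is rank-invariant.
#'
#' @param n_case,n_control samples per group (>= 3 each; defaults 12 and 8).
#' @param n_features_per_layer named integer vector of feature counts for
#'   \code{virome}, \code{bacteria}, \code{metabolite}.
#' @param n_modules number of latent blocks (default 4).
#' @param block_size features per block per layer (default 8).
#' @param rho_within target observed Spearman correlation between features
#'   of the same block, in [0, 1) (default 0.8). Internally converted to
#'   the latent Pearson loading via the Gaussian-copula relation
#'   \eqn{\rho_P = 2 \sin(\pi \rho_S / 6)}.
#' @param cross_layer if TRUE (default), each block spans all layers
#'   (features of the same block in different layers share the latent
#'   factor); if FALSE, blocks are layer-private.
#' @param n_diff_features group-differential features per layer (default
#'   10); drawn from background (non-block) features so that differential
#'   and correlation structure stay identifiable.
#' @param effect_log2fc log2 fold change applied to case samples on
#'   differential features, alternating sign by feature (default 2).
#' @param zero_prob per-feature zero fraction in [0, 1) (default 0.1).
#' @param zero_mode \code{"censor"} (default): the lowest \code{zero_prob}
#'   quantile of each feature is set to zero, emulating detection-limit
#'   dropouts; \code{"independent"}: i.i.d. Bernoulli masking.
#' @param dispersion negative-binomial dispersion phi for the count layer
#'   (variance mu + phi mu^2; default 0.1).
#' @param latent_sd per-feature latent log-scale standard deviation
#'   (default 1.5).
#' @param feature_mean_sd between-feature spread of baseline log-abundance
#'   (default 1).
#' @param seed integer seed (default 1).
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_case = 12, n_control = 8,
                       n_features_per_layer = c(virome = 150, bacteria = 120,
                                                metabolite = 80),
                       n_modules = 4, block_size = 8, rho_within = 0.8,
                       cross_layer = TRUE, n_diff_features = 10,
                       effect_log2fc = 2, zero_prob = 0.1,
                       zero_mode = c("censor", "independent"),
                       dispersion = 0.1, latent_sd = 1.5,
                       feature_mean_sd = 1, seed = 1) {
  zero_mode <- match.arg(zero_mode)
  layers <- c("virome", "bacteria", "metabolite")
  if (!all(layers %in% names(n_features_per_layer)))
    stop("n_features_per_layer must name virome, bacteria and metabolite")
  n_features_per_layer <- n_features_per_layer[layers]
  if (n_case < 3 || n_control < 3) stop("n_case and n_control must be >= 3")
  if (rho_within < 0 || rho_within >= 1) stop("rho_within must be in [0, 1)")
  if (zero_prob < 0 || zero_prob >= 1) stop("zero_prob must be in [0, 1)")
  if (any(n_diff_features > n_features_per_layer))
    stop("n_diff_features exceeds a layer's feature count")
  if (n_modules * block_size + n_diff_features > min(n_features_per_layer))
    stop("blocks plus differential features exceed a layer's feature count")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(n_case = n_case, n_control = n_control,
                 n_features_per_layer = n_features_per_layer,
                 n_modules = n_modules, block_size = block_size,
                 rho_within = rho_within, cross_layer = cross_layer,
                 n_diff_features = n_diff_features,
                 effect_log2fc = effect_log2fc, zero_prob = zero_prob,
                 zero_mode = zero_mode, dispersion = dispersion,
                 latent_sd = latent_sd, feature_mean_sd = feature_mean_sd,
                 seed = seed),
            class = "sim_config")
}

# baseline log-abundance location per layer: counts around exp(5),
# RPKM-like intensities around exp(2), metabolite intensities around exp(10)
layer_mu0 <- c(virome = 2, bacteria = 5, metabolite = 10)

apply_zeros <- function(x, zero_prob, zero_mode) {
  if (zero_prob <= 0) return(x)
  if (zero_mode == "independent") {
    x[stats::runif(length(x)) < zero_prob] <- 0
    return(x)
  }
  thr <- stats::quantile(x, zero_prob, names = FALSE, type = 1)
  x[x <= thr] <- 0
  x
}

#' Generate a synthetic multiomics dataset with known ground truth
#'
#' Latent-factor Gaussian copula: each block has a latent factor
#' \eqn{Z_b \sim N(0,1)} over samples; a block feature's latent value is
#' \eqn{a Z_b + \sqrt{1-a^2}\,\epsilon} with the loading \eqn{a} chosen so
#' the pairwise observed Spearman correlation hits \code{rho_within}.
#' Background features are independent noise. Per layer the latent values
#' are pushed through a marginal transform: bacteria become negative-
#' binomial counts with mean \code{exp(latent)}; virome and metabolite
#' layers become log-normal intensities. Differential features receive a
#' \code{effect_log2fc} group shift (alternating direction). Zeros are
#' injected afterwards according to \code{zero_mode}. Identical seeds give
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with \code{tables} (named list of [abundance_table()]s),
#'   \code{samples} (a [sample_table()] without symptom items yet) and
#'   \code{truth}: \code{block_membership} (named vector, 0 = background),
#'   \code{true_edges} (data.frame u, v of all within-block pairs),
#'   \code{diff_features} (data.frame feature_id, direction),
#'   \code{latent_factors} (samples x blocks matrix).
#' @export
generate_multiomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_case + config$n_control
  sample_ids <- sprintf("S%03d", seq_len(n))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  # loading so that latent pairwise Pearson a^2 maps to the Spearman target
  rho_pearson <- 2 * sin(pi * config$rho_within / 6)
  a <- sqrt(rho_pearson)
  Z <- matrix(stats::rnorm(n * config$n_modules), n, config$n_modules,
              dimnames = list(sample_ids, paste0("block", seq_len(config$n_modules))))
  layers <- names(config$n_features_per_layer)
  tables <- list(); memb_all <- integer(0); diff_all <- NULL
  for (lay in layers) {
    nf <- config$n_features_per_layer[[lay]]
    fid <- namespace_ids(sprintf("f%04d", seq_len(nf)), lay)
    memb <- integer(nf)
    n_block_feats <- config$n_modules * config$block_size
    memb[seq_len(n_block_feats)] <- rep(seq_len(config$n_modules),
                                        each = config$block_size)
    Zlay <- if (config$cross_layer) Z
    else matrix(stats::rnorm(n * config$n_modules), n, config$n_modules)
    mu_f <- stats::rnorm(nf, layer_mu0[[lay]], config$feature_mean_sd)
    eps <- matrix(stats::rnorm(nf * n), nf, n)
    y <- matrix(0, nf, n, dimnames = list(fid, sample_ids))
    for (i in seq_len(nf)) {
      y[i, ] <- if (memb[i] > 0) a * Zlay[, memb[i]] + sqrt(1 - a^2) * eps[i, ]
      else eps[i, ]
    }
    # group-differential features drawn from background
    bg <- which(memb == 0)
    di <- bg[seq_len(config$n_diff_features)]
    dir_up <- rep(c(TRUE, FALSE), length.out = length(di))
    shift <- log(2) * config$effect_log2fc
    for (j in seq_along(di)) {
      s <- if (dir_up[j]) shift else -shift
      y[di[j], group == "case"] <- y[di[j], group == "case"] + s / config$latent_sd
    }
    latent <- mu_f + config$latent_sd * y
    vals <- if (lay == "bacteria") {
      size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
      matrix(stats::rnbinom(length(latent), mu = exp(latent), size = size),
             nf, n, dimnames = dimnames(latent))
    } else {
      exp(latent)
    }
    vals <- t(apply(vals, 1, apply_zeros, zero_prob = config$zero_prob,
                    zero_mode = config$zero_mode))
    dimnames(vals) <- list(fid, sample_ids)
    tables[[lay]] <- abundance_table(vals, lay)
    # layer-private blocks get globally distinct ids so block membership
    # never implies cross-layer correlation that was not planted
    memb_store <- memb
    if (!config$cross_layer) {
      off <- (match(lay, layers) - 1L) * config$n_modules
      memb_store[memb_store > 0] <- memb_store[memb_store > 0] + off
    }
    memb_all <- c(memb_all, stats::setNames(memb_store, fid))
    if (length(di))
      diff_all <- rbind(diff_all, data.frame(
        feature_id = fid[di],
        direction = ifelse(dir_up, "case", "control"),
        stringsAsFactors = FALSE))
  }
  # true edges: all pairs sharing a block (cross-layer pairs only when
  # blocks span layers)
  edges <- NULL
  for (b in sort(unique(memb_all[memb_all > 0]))) {
    ids <- names(memb_all)[memb_all == b]
    if (length(ids) > 1) {
      pr <- t(utils::combn(sort(ids), 2))
      edges <- rbind(edges, data.frame(u = pr[, 1], v = pr[, 2],
                                       block = as.integer(b),
                                       stringsAsFactors = FALSE))
    }
  }
  truth <- list(block_membership = memb_all,
                true_edges = edges,
                diff_features = diff_all,
                latent_factors = Z)
  list(tables = tables,
       samples = sample_table(sample_ids, group),
       truth = truth)
}

#' Default symptom-item loadings on latent blocks
#'
#' Declares which questionnaire items load on which latent block: two GSS
#' items on block 1, three SDS items on block 2 and two SAS items on block
#' 3, all at the given loading. Remaining items are pure noise.
#'
#' @param loading common loading value (default 0.8).
#' @return data.frame with \code{item}, \code{block}, \code{loading}.
#' @export
default_item_loadings <- function(loading = 0.8) {
  data.frame(
    item = c("gss_1", "gss_2", "sds_01", "sds_02", "sds_03", "sas_01", "sas_02"),
    block = c(1, 1, 2, 2, 2, 3, 3),
    loading = loading, stringsAsFactors = FALSE)
}

#' Generate symptom questionnaire items coupled to latent blocks
#'
#' Produces per-sample ordinal item scores for the GSS (0-4 grid), SDS and
#' SAS (1-4 grid) by discretising \eqn{\lambda Z_b +
#' \sqrt{1-\lambda^2}\,\epsilon} at equiprobable normal quantiles. Items
#' listed in \code{item_loadings} load on the given latent block of
#' \code{truth}; all other declared items are independent noise. Loaded
#' items are the ground truth for symptom-omics edges.
#'
#' @param config a [sim_config()].
#' @param truth the \code{truth} element of [generate_multiomics()] output
#'   (supplies the latent factors).
#' @param item_loadings data.frame with \code{item}, \code{block},
#'   \code{loading} (default [default_item_loadings()]).
#' @param scale_defs scale definitions (default [default_scale_defs()]).
#' @param discretize if FALSE, raw continuous item scores are returned
#'   instead of ordinal grids (useful for rank-equivalence checks).
#' @return a [sample_table()] with group labels and symptom items.
#' @export
generate_symptoms <- function(config, truth,
                              item_loadings = default_item_loadings(),
                              scale_defs = default_scale_defs(),
                              discretize = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  Z <- truth$latent_factors
  n <- nrow(Z)
  set.seed(config$seed + 1L)
  if (any(item_loadings$block > ncol(Z)))
    stop("item loading refers to a non-existent block")
  if (any(abs(item_loadings$loading) > 1)) stop("|loading| must be <= 1")
  all_items <- unlist(lapply(scale_defs, `[[`, "items"), use.names = FALSE)
  unknown <- setdiff(item_loadings$item, all_items)
  if (length(unknown)) stop("loadings for undeclared items: ",
                            paste(unknown, collapse = ", "))
  items <- matrix(NA_real_, n, length(all_items),
                  dimnames = list(rownames(Z), all_items))
  for (it in all_items) {
    hit <- match(it, item_loadings$item)
    lat <- if (!is.na(hit)) {
      lam <- item_loadings$loading[hit]
      lam * Z[, item_loadings$block[hit]] + sqrt(1 - lam^2) * stats::rnorm(n)
    } else stats::rnorm(n)
    sc <- scale_defs[[which(vapply(scale_defs,
                                   function(d) it %in% d$items, TRUE))]]
    if (discretize) {
      lev <- seq(sc$range[1], sc$range[2])
      cuts <- stats::qnorm(seq(0, 1, length.out = length(lev) + 1))
      items[, it] <- lev[cut(lat, cuts, labels = FALSE, include.lowest = TRUE)]
    } else {
      items[, it] <- lat
    }
  }
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  sample_table(rownames(Z), group, as.data.frame(items),
               if (discretize) scale_defs else {
                 # raw scores are unbounded; widen declared ranges
                 lapply(scale_defs, function(d) { d$range <- c(-Inf, Inf); d })
               })
}

#' Write a simulated dataset to a directory of TSV files
#'
#' Serialises the generator output in the same formats the readers consume:
#' one abundance TSV per layer, a metadata TSV, a true-edge TSV and a JSON
#' echo of the configuration (requires \pkg{jsonlite}).
#'
#' @param sim output of [generate_multiomics()].
#' @param samples a [sample_table()] (e.g. from [generate_symptoms()]).
#' @param dir output directory (created if missing).
#' @param config the [sim_config()] used (echoed to JSON when \pkg{jsonlite}
#'   is available).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, samples, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lay in names(sim$tables))
    write_abundance(sim$tables[[lay]], file.path(dir, paste0(lay, ".tsv")))
  write_metadata(samples, file.path(dir, "metadata.tsv"))
  te <- sim$truth$true_edges
  lines <- c("u\tv\tblock",
             if (!is.null(te) && nrow(te))
               sprintf("%s\t%s\t%d", te$u, te$v, te$block))
  writeLines(lines, file.path(dir, "true_edges.tsv"))
  if (!is.null(config) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
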