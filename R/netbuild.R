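as_feature_matrix <- function(x) {
  if (inherits(x, "abundance_table")) {
    m <- x$values
    rownames(m) <- namespace_ids(rownames(m), x$layer)
    return(m)
  }
  if (inherits(x, "sample_table")) {
    if (is.null(x$symptom_items)) stop("sample_table has no symptom items")
    m <- t(as.matrix(x$symptom_items))
    rownames(m) <- namespace_ids(rownames(m), "symptom")
    colnames(m) <- x$sample_ids
    return(m)
  }
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected an abundance_table, sample_table or numeric matrix")
}

#' Pairwise Spearman correlation matrix with p and BH q
#'
#' Tie-corrected Spearman correlations for every pair of rows of \code{x}
#' (or between rows of \code{x} and rows of \code{y}), with p-values from
#' the t-distribution approximation on n - 2 degrees of freedom and
#' Benjamini-Hochberg q-values computed over all pairs tested in this call
#' (the diagonal and, in the symmetric case, the lower triangle are
#' excluded from the family). Constant rows yield undefined correlations;
#' their pairs are flagged (NA) and excluded from the BH family.
#'
#' @param x features x samples matrix, [abundance_table()] or
#'   [sample_table()] (symptom items).
#' @param y optional second input over the same, identically ordered
#'   samples; when given, correlations are between rows of \code{x} and rows
#'   of \code{y}.
#' @param exact_p if TRUE, p-values come from a seeded permutation null
#'   (add-one estimator over \code{n_perm} sample-order permutations)
#'   instead of the t approximation; useful at very small n where the t
#'   approximation is anticonservative.
#' @param n_perm,seed permutation count and seed for \code{exact_p}.
#' @return object of class \code{correlation_matrix}: list with \code{r},
#'   \code{p}, \code{q} matrices, \code{row_ids}, \code{col_ids},
#'   \code{symmetric}, \code{n}.
#' @export
spearman_matrix <- function(x, y = NULL, exact_p = FALSE, n_perm = 999,
                            seed = 1) {
  mx <- as_feature_matrix(x)
  my <- if (is.null(y)) NULL else as_feature_matrix(y)
  n <- ncol(mx)
  if (n < 4) stop("need >= 4 samples for rank correlation")
  if (!is.null(my)) {
    if (ncol(my) != n) stop("x and y must share the sample set")
    if (!is.null(colnames(mx)) && !is.null(colnames(my)) &&
        !identical(colnames(mx), colnames(my)))
      stop("x and y sample ids must be identically ordered")
  }
  rank_rows <- function(m) t(apply(m, 1, rank))
  rx <- rank_rows(mx)
  const_x <- apply(mx, 1, function(v) length(unique(v)) == 1)
  if (is.null(my)) {
    r <- suppressWarnings(stats::cor(t(rx)))
    const_y <- const_x
    symmetric <- TRUE
  } else {
    ry <- rank_rows(my)
    const_y <- apply(my, 1, function(v) length(unique(v)) == 1)
    r <- suppressWarnings(stats::cor(t(rx), t(ry)))
    symmetric <- FALSE
  }
  r[const_x, ] <- NA
  if (length(const_y)) r[, const_y] <- NA
  r <- pmin(pmax(r, -1), 1)
  if (exact_p) {
    # permutation null: permute the sample order of the second member of
    # every pair (a copy of x in the symmetric case); add-one estimator
    set.seed(seed)
    zx <- t(scale(t(rx)))
    zy <- if (is.null(my)) zx else t(scale(t(rank_rows(my))))
    exceed <- matrix(0, nrow(r), ncol(r))
    for (b in seq_len(n_perm)) {
      rp <- tcrossprod(zx, zy[, sample(n), drop = FALSE]) / (n - 1)
      exceed <- exceed + (abs(rp) >= abs(r) - 1e-12)
    }
    p <- (1 + exceed) / (1 + n_perm)
    p[is.na(r)] <- NA
  } else {
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p[abs(r) == 1] <- 0
  }
  tested <- if (symmetric) upper.tri(r) & !is.na(p) else !is.na(p)
  q <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  if (symmetric) {
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    diag(p) <- NA; diag(q) <- NA
  }
  structure(list(r = r, p = p, q = q, row_ids = rownames(r),
                 col_ids = colnames(r), symmetric = symmetric, n = n),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d x %d (%s), n = %d samples\n",
              length(x$row_ids), length(x$col_ids),
              if (x$symmetric) "symmetric" else "cross", x$n))
  invisible(x)
}

#' Long-form view of a correlation matrix
#' @param cm a \code{correlation_matrix}.
#' @return data.frame with columns \code{u}, \code{v}, \code{r}, \code{p},
#'   \code{q}, one row per tested pair.
#' @export
correlation_long <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  idx <- if (cm$symmetric) which(upper.tri(cm$r), arr.ind = TRUE)
  else as.matrix(expand.grid(seq_along(cm$row_ids), seq_along(cm$col_ids)))
  data.frame(u = cm$row_ids[idx[, 1]], v = cm$col_ids[idx[, 2]],
             r = cm$r[idx], p = cm$p[idx], q = cm$q[idx],
             stringsAsFactors = FALSE)
}

matrix_layers <- function(cm) {
  list(row = unique(id_layer(cm$row_ids)), col = unique(id_layer(cm$col_ids)))
}

#' Build a co-occurrence network from correlation matrices
#'
#' Thresholds one or more [spearman_matrix()] results into an undirected
#' network: an edge is kept iff \code{|r| > r_min} AND \code{p < p_max} AND
#' \code{q <= q_max} (defaults |r| > 0.8, p < 0.001, BH q <= 0.05).
#'
#' Modes mirror the three network families of the analysis:
#' \describe{
#'   \item{single}{one within-layer matrix; intra-layer edges.}
#'   \item{cross}{between-layer matrices only (virome-bacteria,
#'     virome-metabolite, bacteria-metabolite); contains no intra-layer
#'     edges by construction.}
#'   \item{symptom}{cross-layer matrices plus symptom x feature matrices;
#'     adds symptom nodes and symptom-feature edges onto the cross
#'     network.}
#' }
#' Isolated nodes are dropped.
#'
#' @param corrs a \code{correlation_matrix} or list of them, consistent with
#'   \code{mode}.
#' @param r_min,p_max,q_max edge thresholds.
#' @param mode \code{"single"}, \code{"cross"} or \code{"symptom"}.
#' @param annotations optional feature annotation data.frame (with
#'   \code{feature_id}) copied onto vertices.
#' @return an [omics_network()].
#' @export
build_network <- function(corrs, r_min = 0.8, p_max = 0.001, q_max = 0.05,
                          mode = c("single", "cross", "symptom"),
                          annotations = NULL) {
  mode <- match.arg(mode)
  if (inherits(corrs, "correlation_matrix")) corrs <- list(corrs)
  if (!length(corrs) || !all(vapply(corrs, inherits, TRUE, "correlation_matrix")))
    stop("`corrs` must be correlation_matrix objects")
  lay <- lapply(corrs, matrix_layers)
  is_intra <- vapply(corrs, function(cm) cm$symmetric, TRUE)
  has_sym <- vapply(lay, function(l) "symptom" %in% c(l$row, l$col), TRUE)
  if (mode == "single") {
    if (length(corrs) != 1 || !is_intra[1] || has_sym[1])
      stop("single mode expects exactly one within-layer correlation matrix")
  } else if (mode == "cross") {
    if (any(is_intra) || any(has_sym))
      stop("cross mode expects between-layer matrices only (no intra-layer, no symptom)")
  } else {
    if (any(is_intra))
      stop("symptom mode expects between-layer and symptom x feature matrices")
    if (!any(has_sym))
      stop("symptom mode requires at least one symptom x feature matrix")
  }
  edges <- do.call(rbind, lapply(corrs, function(cm) {
    long <- correlation_long(cm)
    keep <- !is.na(long$r) & abs(long$r) > r_min & long$p < p_max &
      !is.na(long$q) & long$q <= q_max
    long[keep, , drop = FALSE]
  }))
  if (is.null(edges))
    edges <- data.frame(u = character(), v = character(), r = numeric(),
                        p = numeric(), q = numeric())
  omics_network(edges, annotations = annotations)
}
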