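#' Shannon alpha diversity per sample
#'
#' \eqn{H = -\sum_i p_i \log p_i} over features with \eqn{p_i > 0}, where
#' \eqn{p_i} is the relative abundance of feature i in the sample. Natural
#' logarithm by default (nats).
#'
#' @param table an [abundance_table()].
#' @param base logarithm base; \code{exp(1)} (default) or e.g. 2.
#' @return named numeric vector, one entry per sample.
#' @export
shannon <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "abundance_table"))
  cs <- colSums(table$values)
  if (any(cs <= 0))
    stop("all-zero sample(s): ",
         paste(colnames(table$values)[cs <= 0], collapse = ", "))
  vegan::diversity(t(table$values), index = "shannon", base = base)
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, bounded in
#' [0, 1] for non-negative abundances.
#'
#' @param table an [abundance_table()] with >= 2 samples.
#' @return a \code{dist} object over samples.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (ncol(v) < 2) stop("need >= 2 samples")
  if (any(colSums(v) <= 0))
    stop("all-zero sample(s) make Bray-Curtis undefined: ",
         paste(colnames(v)[colSums(v) <= 0], collapse = ", "))
  vegan::vegdist(t(v), method = "bray")
}

#' Principal coordinates analysis (classical MDS)
#'
#' Classical scaling of the Gower-centred squared-distance matrix. Axes are
#' ordered by descending eigenvalue; coordinates are returned only for
#' positive-eigenvalue axes, and negative eigenvalues are reported so that
#' users can inspect how non-Euclidean the input is.
#'
#' @param d a \code{dist} or symmetric distance matrix.
#' @param k number of requested axes (default 2); truncated with a warning
#'   if fewer positive axes exist.
#' @return list with \code{coordinates} (samples x axes), \code{eigenvalues}
#'   (all, descending) and \code{relative_eig} (share of the positive part).
#' @export
pcoa <- function(d, k = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k > n - 1) stop("k must be <= n - 1")
  # cmdscale warns when < k axes are positive; axis truncation is handled
  # explicitly below
  sc <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sc$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > n_pos) {
    warning(sprintf("only %d positive axes available; truncating k from %d",
                    n_pos, k))
    k <- n_pos
  }
  coords <- sc$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords, eigenvalues = eig,
       relative_eig = pmax(eig, 0) / sum(pmax(eig, 0)))
}

permanova_f <- function(d2, idx_by_group, n, a) {
  # Anderson's pseudo-F from squared inter-point distances
  ssw <- 0
  for (idx in idx_by_group)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  sst <- sum(d2) / (2 * n)
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' PERMANOVA (Adonis-style) group test on a distance matrix
#'
#' Permutational multivariate analysis of variance using Anderson's
#' pseudo-F computed from within/between sums of squared distances. The
#' permutation p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}, so p = 0 is never
#' reported.
#'
#' @param d a \code{dist} or symmetric distance matrix over samples.
#' @param groups group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param n_perm number of label permutations (>= 99; default 999).
#' @param seed integer seed for the permutations.
#' @return list with \code{pseudo_F}, \code{R2}, \code{p}, \code{n_perm}.
#' @seealso \code{vegan::adonis2}, which implements the same test and is
#'   used as an independent cross-check in the package's test-suite.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(stats::as.dist(d))
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 samples; too small: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  if (n_perm < 99) stop("n_perm must be >= 99")
  d2 <- d^2
  a <- length(tab)
  split_idx <- split(seq_len(n), groups)
  f_obs <- permanova_f(d2, split_idx, n, a)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    g <- sample(groups)
    permanova_f(d2, split(seq_len(n), g), n, a)
  }, 0)
  sst <- sum(d2) / (2 * n)
  # SSA from F via F = (SSA/(a-1)) / ((SST-SSA)/(n-a))
  ssa <- f_obs * (a - 1) * sst / (n - a + f_obs * (a - 1))
  list(pseudo_F = f_obs, R2 = ssa / sst,
       p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm), n_perm = n_perm)
}

#' Fast two-group PERMANOVA for simulation studies
#'
#' Same statistic and p-value estimator as [permanova()], restricted to two
#' groups and vectorised over permutations, for use in null-calibration
#' simulations.
#'
#' @inheritParams permanova
#' @return list with \code{pseudo_F} and \code{p}.
#' @keywords internal
#' @export
permanova2 <- function(d, groups, n_perm = 99, seed = 1) {
  d2 <- as.matrix(stats::as.dist(d))^2
  n <- nrow(d2)
  u <- as.integer(groups == groups[1])
  n1 <- sum(u); n2 <- n - n1
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 samples")
  sst <- sum(d2) / (2 * n)
  fstat <- function(uu) {
    ssw <- sum((uu %*% d2) * uu) / (2 * n1) +
      sum(((1 - uu) %*% d2) * (1 - uu)) / (2 * n2)
    (sst - ssw) / (ssw / (n - 2))
  }
  f_obs <- fstat(u)
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample(u), integer(n))
  ssw1 <- colSums((d2 %*% P) * P) / (2 * n1)
  ssw2 <- colSums((d2 %*% (1 - P)) * (1 - P)) / (2 * n2)
  f_perm <- (sst - (ssw1 + ssw2)) / ((ssw1 + ssw2) / (n - 2))
  list(pseudo_F = f_obs, p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm))
}
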