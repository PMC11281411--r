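check_two_groups <- function(table, groups, min_n = 3) {
  groups <- as.character(groups)
  if (length(groups) != ncol(table$values))
    stop("one group label per sample required")
  tab <- table(groups)
  if (length(tab) != 2) stop("exactly two groups required")
  if (any(tab < min_n)) stop("each group needs >= ", min_n, " samples")
  groups
}

#' Per-feature Mann-Whitney U tests between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature. Exact
#' enumeration is used when both groups have <= 8 samples and the feature is
#' tie-free; otherwise the tie-corrected normal approximation with
#' continuity correction (which agrees with the exact test to within 0.01
#' at 10 samples per group). p-values are BH-adjusted across the feature
#' set. Constant features (all values equal) are assigned p = 1 and
#' flagged.
#'
#' @param table an [abundance_table()].
#' @param groups two-group label per sample (each group >= 3 samples).
#' @return data.frame with \code{feature_id}, \code{U}, \code{p}, \code{q},
#'   \code{constant}.
#' @export
rank_tests <- function(table, groups) {
  stopifnot(inherits(table, "abundance_table"))
  groups <- check_two_groups(table, groups)
  lev <- sort(unique(groups))
  v <- table$values
  res <- t(vapply(seq_len(nrow(v)), function(i) {
    x <- v[i, groups == lev[1]]; y <- v[i, groups == lev[2]]
    if (length(unique(c(x, y))) == 1) return(c(U = length(x) * length(y) / 2,
                                               p = 1, const = 1))
    use_exact <- length(x) <= 8 && length(y) <= 8 &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, exact = use_exact, correct = TRUE))
    c(U = unname(wt$statistic), p = wt$p.value, const = 0)
  }, c(U = 0, p = 0, const = 0)))
  data.frame(feature_id = rownames(v), U = res[, "U"], p = res[, "p"],
             q = stats::p.adjust(res[, "p"], method = "BH"),
             constant = res[, "const"] == 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' LDA effect sizes (two-class LEfSe-style scores)
#'
#' Simplified two-class effect-size procedure: abundances are rescaled to a
#' fixed per-sample total of 10^6 (so scores are on the scale of published
#' LEfSe scores); in each bootstrap round a subsample fraction of each class
#' is drawn and, per feature, a variance-regularised univariate linear
#' discriminant is fitted. Projecting the class means on a one-dimensional
#' discriminant axis reduces to the class-mean difference of the feature
#' itself, so the round's effect size is
#' \eqn{\log_{10}(\max(1, |\bar x_{case} - \bar x_{control}|))}. The
#' reported score is the mean over rounds. There is no subclass (within-
#' class Wilcoxon) stage because the two-group design has no subclasses;
#' this is a documented variant of LEfSe, not a clone.
#'
#' @param table an [abundance_table()].
#' @param groups two-group label per sample.
#' @param n_boot number of bootstrap rounds (>= 1; default 30).
#' @param subsample fraction of each class drawn per round, in (0, 1]
#'   (default 2/3).
#' @param seed integer seed.
#' @return named numeric vector of log10 LDA scores, one per feature.
#' @export
lda_effect_sizes <- function(table, groups, n_boot = 30, subsample = 2 / 3,
                             seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  groups <- check_two_groups(table, groups, min_n = 2)
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (subsample <= 0 || subsample > 1) stop("subsample must be in (0, 1]")
  v <- table$values
  cs <- colSums(v)
  if (any(cs <= 0)) stop("all-zero sample(s): ",
                         paste(colnames(v)[cs <= 0], collapse = ", "))
  v <- sweep(v, 2, cs, `/`) * 1e6
  lev <- sort(unique(groups))
  ia <- which(groups == lev[1]); ib <- which(groups == lev[2])
  # draw bootstrap members in sample-name order so the scores depend on
  # which samples are drawn, not on column position
  if (!is.null(colnames(v))) {
    ia <- ia[order(colnames(v)[ia])]
    ib <- ib[order(colnames(v)[ib])]
  }
  na <- max(2L, ceiling(subsample * length(ia)))
  nb <- max(2L, ceiling(subsample * length(ib)))
  set.seed(seed)
  scores <- matrix(NA_real_, nrow(v), n_boot)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    sa <- sample(ia, min(na, length(ia)))
    sb <- sample(ib, min(nb, length(ib)))
    if (length(sa) < 2 || length(sb) < 2) {
      skipped <- skipped + 1L
      warning("bootstrap round skipped: a class had < 2 samples")
      next
    }
    gap <- abs(rowMeans(v[, sa, drop = FALSE]) - rowMeans(v[, sb, drop = FALSE]))
    scores[, b] <- log10(pmax(1, gap))
  }
  if (skipped == n_boot) stop("all bootstrap rounds skipped")
  stats::setNames(rowMeans(scores, na.rm = TRUE), rownames(v))
}

#' Differentially abundant features (rank test + LDA score)
#'
#' Combines [rank_tests()] and [lda_effect_sizes()]: a feature is called
#' differential when its Mann-Whitney p-value is below \code{p_max} and its
#' LDA score exceeds \code{lda_min} (defaults: p < 0.05, LDA score > 2).
#' Enrichment direction is the group with the higher median abundance.
#'
#' @inheritParams lda_effect_sizes
#' @param p_max raw p-value cutoff (default 0.05).
#' @param lda_min log10 LDA score cutoff (default 2).
#' @return data.frame with one row per passing feature: \code{feature_id},
#'   \code{U}, \code{p}, \code{q}, \code{lda_score}, \code{direction}.
#' @export
differential_features <- function(table, groups, p_max = 0.05, lda_min = 2,
                                  n_boot = 30, subsample = 2 / 3, seed = 1) {
  rt <- rank_tests(table, groups)
  lda <- lda_effect_sizes(table, groups, n_boot, subsample, seed)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  v <- table$values
  med_a <- apply(v[, groups == lev[1], drop = FALSE], 1, stats::median)
  med_b <- apply(v[, groups == lev[2], drop = FALSE], 1, stats::median)
  out <- data.frame(rt[, c("feature_id", "U", "p", "q")],
                    lda_score = unname(lda[rt$feature_id]),
                    direction = ifelse(med_a >= med_b, lev[1], lev[2]),
                    stringsAsFactors = FALSE)
  out[out$p < p_max & out$lda_score > lda_min, , drop = FALSE]
}

#' Screen pairwise feature/symptom correlations
#'
#' All pairwise Spearman correlations between two feature sets (e.g. the
#' differential features of one layer against symptom scores or another
#' layer), retaining pairs with \code{|r| > r_min} and \code{p < p_max}
#' (defaults match the cross-omics heatmap thresholds |r| > 0.6, p < 0.05).
#'
#' @param x,y numeric matrices, features x samples, over the same samples
#'   (>= 4 shared samples); row names are feature ids.
#' @param r_min minimum absolute Spearman correlation (default 0.6).
#' @param p_max maximum raw p-value (default 0.05).
#' @return long-form data.frame with \code{u}, \code{v}, \code{r}, \code{p},
#'   \code{q} (BH over all tested pairs), one row per retained pair.
#' @export
correlation_screen <- function(x, y, r_min = 0.6, p_max = 0.05) {
  cm <- spearman_matrix(x, y)
  long <- correlation_long(cm)
  long[!is.na(long$r) & abs(long$r) > r_min & long$p < p_max, , drop = FALSE]
}
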