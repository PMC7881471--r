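# Three-stage dimensionality reduction, fitted on training data only:
#   1. two-sample Student t-test screen (p < alpha)
#   2. minimum-redundancy maximum-relevance (mRMR) ranking, mutual
#      information on 3-bin discretized features, MID (difference) criterion
#   3. recursive feature elimination with a linear SVM (squared-weight
#      scores), retained count chosen by inner cross-validation when "auto"

#' Configuration of the feature-selection cascade
#'
#' @param t_alpha Significance level of the t-test screen (default 0.05).
#' @param mrmr_keep Features retained after mRMR ranking (default 200,
#'   clipped to the number of t-test survivors).
#' @param mrmr_variant `"mid"` (relevance minus mean redundancy, default) or
#'   `"miq"` (relevance over mean redundancy).
#' @param rfe_keep Features retained after SVM-RFE: an integer, or `"auto"`
#'   to pick the best count from `rfe_keep_grid` by inner cross-validated
#'   accuracy of a linear SVM (ties to the smaller count).
#' @param rfe_keep_grid Candidate retained counts for `rfe_keep = "auto"`.
#' @param rfe_step Features eliminated per RFE iteration; `NULL` (default)
#'   removes 10% per iteration while more than 50 features remain, then 1.
#' @param rfe_cost Linear-SVM cost used inside RFE.
#' @param inner_folds Stratified folds for the `"auto"` inner CV.
#' @return A `selection_config` list.
#' @export
selection_config <- function(t_alpha = 0.05, mrmr_keep = 200,
                             mrmr_variant = c("mid", "miq"),
                             rfe_keep = "auto",
                             rfe_keep_grid = c(5, 10, 20, 50),
                             rfe_step = NULL, rfe_cost = 1,
                             inner_folds = 5) {
  mrmr_variant <- match.arg(mrmr_variant)
  if (t_alpha <= 0 || t_alpha >= 1) {
    abort("t_alpha must lie in (0, 1)", class = "hiernet_selection_error")
  }
  if (!identical(rfe_keep, "auto") &&
      (!is.numeric(rfe_keep) || rfe_keep < 1)) {
    abort("rfe_keep must be \"auto\" or a positive integer",
          class = "hiernet_selection_error")
  }
  if (is.numeric(rfe_keep) && mrmr_keep < rfe_keep) {
    abort("mrmr_keep must be >= rfe_keep", class = "hiernet_selection_error")
  }
  structure(list(t_alpha = t_alpha, mrmr_keep = mrmr_keep,
                 mrmr_variant = mrmr_variant, rfe_keep = rfe_keep,
                 rfe_keep_grid = sort(unique(rfe_keep_grid)),
                 rfe_step = rfe_step, rfe_cost = rfe_cost,
                 inner_folds = inner_folds),
            class = "selection_config")
}

check_xy <- function(x, y) {
  if (!is.matrix(x) || is.null(colnames(x))) {
    abort("features must be a column-named matrix",
          class = "hiernet_selection_error")
  }
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2 || any(table(y) < 1)) {
    abort("labels must contain two non-empty groups",
          class = "hiernet_selection_error")
  }
  y
}

#' Two-sample t-test feature screen
#'
#' Keeps features whose pooled-variance (Student) two-sided two-sample
#' t-test, computed per feature without multiple-testing correction, gives
#' p < `alpha`. Features with zero pooled within-group variance are assigned
#' p = 1 and never selected.
#'
#' @param x Training feature matrix (subjects x features, named columns).
#' @param y Two-level factor of training labels.
#' @param alpha Significance level.
#' @return List with `kept` (surviving feature names, in input column order)
#'   and `stats` (tibble of per-feature `statistic`, `p_value`, `kept`,
#'   `zero_variance`).
#' @export
ttest_filter <- function(x, y, alpha = 0.05) {
  y <- check_xy(x, y)
  g1 <- y == levels(y)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) {
    abort("each group needs >= 2 subjects for the t-test screen",
          class = "hiernet_selection_error")
  }
  x1 <- x[g1, , drop = FALSE]; x2 <- x[!g1, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  zero <- sp2 <= 0
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  stat <- ifelse(zero, NA_real_, (m1 - m2) / se)
  p <- ifelse(zero, 1, 2 * pt(-abs(stat), df = n1 + n2 - 2))
  kept <- !zero & p < alpha
  list(
    kept = colnames(x)[kept],
    stats = tibble::tibble(feature = colnames(x), statistic = unname(stat),
                           p_value = unname(p), kept = unname(kept),
                           zero_variance = unname(zero))
  )
}

# --- mutual information on discretized features -----------------------------

# 3-bin discretization at mean +/- 1 SD (constant features land in bin 2)
discretize_bins <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, sd)
  lo <- m - s; hi <- m + s
  b <- matrix(2L, nrow(x), ncol(x), dimnames = dimnames(x))
  b[sweep(x, 2, lo, `<`)] <- 1L
  b[sweep(x, 2, hi, `>`)] <- 3L
  b
}

mi_from_counts <- function(counts, n) {
  p <- counts / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (px[row(p)][nz] * py[col(p)][nz])))
}

# MI of every column of bin matrix `b` (values 1..3) with integer vector
# `z` taking values 1..kz
mi_cols <- function(b, z, kz) {
  n <- nrow(b)
  code <- b + 3L * (z - 1L)  # recycled over columns
  vapply(seq_len(ncol(b)), function(j) {
    counts <- matrix(tabulate(code[, j], nbins = 3L * kz), nrow = 3L)
    mi_from_counts(counts, n)
  }, numeric(1))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mRMR on mutual information over features discretized into three
#' bins at mean +/- 1 SD. The first pick maximizes relevance MI(feature;
#' label); each later pick maximizes relevance minus the mean MI with the
#' already-selected set (MID criterion; `variant = "miq"` uses the quotient
#' instead). Ties break by feature-name lexical order.
#'
#' @inheritParams ttest_filter
#' @param keep Number of features to retain (clipped, with a warning, to the
#'   number available).
#' @param variant `"mid"` or `"miq"`.
#' @return List with `kept` (the top-`keep` feature names in rank order) and
#'   `ranking` (tibble of `feature`, `step`, `score`, `relevance`).
#' @export
mrmr_rank <- function(x, y, keep, variant = c("mid", "miq")) {
  variant <- match.arg(variant)
  y <- check_xy(x, y)
  p <- ncol(x)
  if (keep > p) {
    warn(paste0("mrmr keep = ", keep, " exceeds the ", p,
                " available features; keeping all"))
    keep <- p
  }
  b <- discretize_bins(x)
  z <- as.integer(y)
  rel <- mi_cols(b, z, nlevels(y))
  names(rel) <- colnames(x)

  nm <- colnames(x)
  selected <- integer(0)
  red_sum <- numeric(p)
  steps <- tibble::tibble(feature = character(keep), step = seq_len(keep),
                          score = NA_real_, relevance = NA_real_)
  candidates <- seq_len(p)
  for (s in seq_len(keep)) {
    score <- if (s == 1) {
      rel[candidates]
    } else if (variant == "mid") {
      rel[candidates] - red_sum[candidates] / length(selected)
    } else {
      rel[candidates] / pmax(red_sum[candidates] / length(selected),
                             .Machine$double.eps)
    }
    ord <- order(-score, nm[candidates])
    pick <- candidates[ord[1]]
    steps$feature[s] <- nm[pick]
    steps$score[s] <- score[ord[1]]
    steps$relevance[s] <- rel[pick]
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
    if (length(candidates) > 0 && s < keep) {
      red_sum[candidates] <- red_sum[candidates] +
        mi_cols(b[, candidates, drop = FALSE] , b[, pick], 3L)
    }
  }
  list(kept = steps$feature, ranking = steps)
}

# linear-SVM feature scores: squared components of the primal weight vector
svm_weights2 <- function(x, y, cost) {
  fit <- tryCatch(
    e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE),
    error = function(e) {
      abort(paste0("linear SVM failed during RFE: ", conditionMessage(e)),
            class = "hiernet_selection_error")
    })
  w <- crossprod(fit$coefs, fit$SV)
  drop(w)^2
}

#' Recursive feature elimination with a linear SVM
#'
#' Repeatedly trains a linear maximum-margin classifier, scores features by
#' their squared weight, and removes the lowest-scoring features until
#' `keep` remain. Score ties break by feature-name lexical order (the
#' lexically earlier feature is eliminated first).
#'
#' @inheritParams ttest_filter
#' @param keep Number of features to retain.
#' @param step Features eliminated per iteration; `NULL` removes 10% while
#'   more than 50 remain, then 1 (never overshooting `keep`).
#' @param cost Linear-SVM cost.
#' @return List with `kept` (surviving feature names in input column order)
#'   and `elimination` (feature names in removal order, first removed first).
#' @export
svm_rfe <- function(x, y, keep, step = NULL, cost = 1) {
  y <- check_xy(x, y)
  if (keep > ncol(x)) {
    abort("keep exceeds the number of input features",
          class = "hiernet_selection_error")
  }
  surv <- colnames(x)
  eliminated <- character(0)
  while (length(surv) > keep) {
    sc <- svm_weights2(x[, surv, drop = FALSE], y, cost)
    p <- length(surv)
    nrem <- if (!is.null(step)) step else if (p > 50) max(1L, floor(0.1 * p)) else 1L
    nrem <- min(nrem, p - keep)
    ord <- order(sc, surv)  # lowest score first, ties lexical
    drop_now <- surv[ord[seq_len(nrem)]]
    eliminated <- c(eliminated, drop_now)
    surv <- setdiff(surv, drop_now)
  }
  list(kept = surv, elimination = eliminated)
}

#' Run the full selection cascade on a training set
#'
#' Composes the t-test screen, mRMR ranking and SVM-RFE in order; all three
#' stages see only the supplied (training) data. RFE runs on features
#' standardized to zero mean and unit variance of the training set. When
#' `rfe_keep = "auto"`, the retained count is chosen from `rfe_keep_grid` by
#' stratified inner cross-validated accuracy of a linear SVM along the RFE
#' elimination path.
#'
#' @inheritParams ttest_filter
#' @param config A [selection_config()].
#' @return List with `selected` (final feature names, input column order) and
#'   `trace` (per-stage survivor lists, t statistics, mRMR ranking, RFE
#'   elimination order, and the resolved `rfe_keep`).
#' @export
run_cascade <- function(x, y, config = selection_config()) {
  y <- check_xy(x, y)
  tt <- ttest_filter(x, y, config$t_alpha)
  if (length(tt$kept) == 0) {
    abort("no features survive the t-test screen; consider a larger t_alpha",
          class = "hiernet_selection_error")
  }
  x1 <- x[, tt$kept, drop = FALSE]
  mr <- mrmr_rank(x1, y, keep = min(config$mrmr_keep, ncol(x1)),
                  variant = config$mrmr_variant)
  x2 <- x[, intersect(colnames(x), mr$kept), drop = FALSE]
  xs <- scale(x2)

  k <- config$rfe_keep
  auto <- identical(k, "auto")
  if (auto) {
    k <- choose_rfe_keep(xs, y, config)
  }
  k <- min(k, ncol(xs))
  if (k == ncol(xs)) {
    rfe <- list(kept = colnames(xs), elimination = character(0))
  } else {
    rfe <- svm_rfe(xs, y, keep = k, step = config$rfe_step,
                   cost = config$rfe_cost)
  }
  selected <- intersect(colnames(x), rfe$kept)
  list(selected = selected,
       trace = list(ttest = tt$stats, mrmr = mr$ranking,
                    rfe_elimination = rfe$elimination,
                    rfe_keep = k, rfe_keep_auto = auto,
                    survivors = list(ttest = tt$kept, mrmr = mr$kept,
                                     rfe = selected)))
}

# pick the retained count along the RFE path by inner-CV linear-SVM accuracy
choose_rfe_keep <- function(xs, y, config) {
  grid <- config$rfe_keep_grid
  grid <- sort(unique(pmin(grid, ncol(xs))))
  if (length(grid) == 1) return(grid)
  kmin <- min(grid)
  path <- svm_rfe(xs, y, keep = kmin, step = config$rfe_step,
                  cost = config$rfe_cost)
  # reverse-elimination ranking: final survivors first
  ranking <- c(path$kept, rev(path$elimination))
  folds <- stratified_folds(y, config$inner_folds)
  acc <- vapply(grid, function(k) {
    feats <- ranking[seq_len(k)]
    correct <- 0L
    for (f in sort(unique(folds))) {
      tr <- folds != f
      fit <- e1071::svm(xs[tr, feats, drop = FALSE], y[tr],
                        kernel = "linear", cost = config$rfe_cost,
                        scale = FALSE)
      pred <- predict(fit, xs[!tr, feats, drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  grid[which.max(acc)]  # ties -> smaller count (grid is sorted)
}
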