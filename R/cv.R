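# Repeated stratified twofold nested cross-validation of the multi-kernel
# classifier. Per repetition the cohort is split into stratified halves; per
# fold the selection cascade and all hyperparameter choices (SVM cost, ROI
# kernel weight beta, RFE retained count) are fitted on the training half
# only, and the held-out half is predicted once.

#' Cross-validation configuration
#'
#' @param repetitions Repetitions of the outer split (default 100).
#' @param outer_folds Outer folds per repetition (default 2: random
#'   stratified halves, both used as test set once).
#' @param inner_folds Stratified folds of the inner hyperparameter loop.
#' @param cost_grid Candidate SVM cost values.
#' @param beta_grid Candidate ROI-kernel weights in `[0, 1]` for the inner
#'   loop; a single value fixes beta.
#' @param gamma_scale Multiplier on the per-block default RBF width
#'   `1 / n_features` (features are standardized, so feature variance is 1).
#' @param selection A [selection_config()] applied per block inside each
#'   training fold.
#' @param roi_block,net_block Names of the feature blocks entering the ROI
#'   and network kernels; set either to `NULL` for a single-kernel model
#'   (beta is then pinned to 1 or 0).
#' @param positive Positive-class label.
#' @return A `cv_config` list.
#' @export
cv_config <- function(repetitions = 100, outer_folds = 2, inner_folds = 5,
                      cost_grid = c(1, 10),
                      beta_grid = c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1),
                      gamma_scale = 1,
                      selection = selection_config(),
                      roi_block = "roi_L4", net_block = "net_all",
                      positive = "high") {
  if (any(beta_grid < 0 | beta_grid > 1)) {
    abort("beta_grid must lie in [0, 1]", class = "hiernet_cv_error")
  }
  if (is.null(roi_block) && is.null(net_block)) {
    abort("at least one of roi_block, net_block is required",
          class = "hiernet_cv_error")
  }
  structure(list(repetitions = as.integer(repetitions),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 cost_grid = cost_grid, beta_grid = beta_grid,
                 gamma_scale = gamma_scale, selection = selection,
                 roi_block = roi_block, net_block = net_block,
                 positive = positive),
            class = "cv_config")
}

#' Repeated nested cross-validation of the multi-kernel SVM
#'
#' For each repetition, draws a stratified split into `outer_folds` folds;
#' for each fold, runs the selection cascade per feature block on the
#' training portion, standardizes features on training statistics, builds
#' per-block RBF kernels, chooses SVM cost and kernel weight beta by inner
#' stratified cross-validation on the training portion, trains the fused
#' kernel SVM and predicts the held-out portion. Metrics are computed per
#' repetition from the pooled held-out predictions (each subject is tested
#' exactly once per repetition); per-feature selection counts are accumulated
#' over all repetition x fold fits.
#'
#' @param blocks A `feature_blocks` object from [assemble_blocks()].
#' @param config A [cv_config()].
#' @param seed Integer seed driving every split and inner fold.
#' @return A `cv_report`: list with `per_rep` (per-repetition metric tibble),
#'   `summary` (metric mean/sd), `frequencies` (per-block feature selection
#'   counts over all fits), `fits` (per-fit hyperparameters), `n_fits`,
#'   `config`, `manifest` and `seed`. See [tidy.cv_report()],
#'   [glance.cv_report()], [frequency_table()].
#' @export
nested_cv <- function(blocks, config = cv_config(), seed = NULL) {
  stopifnot(inherits(blocks, "feature_blocks"), inherits(config, "cv_config"))
  y <- blocks$labels
  if (nlevels(y) != 2 || min(table(y)) < 4) {
    abort("nested_cv needs two groups with >= 4 subjects each",
          class = "hiernet_cv_error")
  }
  active <- active_blocks(blocks, config)
  rep_seeds <- derive_seeds(seed, config$repetitions)

  per_rep <- vector("list", config$repetitions)
  fits <- list()
  freq <- lapply(active, function(b) integer(0))
  for (r in seq_len(config$repetitions)) {
    res <- with_seed(rep_seeds[[r]], run_repetition(blocks, config, active, y))
    per_rep[[r]] <- dplyr::bind_cols(tibble::tibble(repetition = r),
                                     res$metrics)
    fits[[r]] <- dplyr::bind_cols(tibble::tibble(repetition = r), res$fits)
    for (b in names(active)) {
      freq[[b]] <- merge_counts(freq[[b]], res$selected[[b]])
    }
  }
  per_rep <- dplyr::bind_rows(per_rep)
  summary <- tibble::tibble(
    metric = metric_names,
    mean = unname(vapply(metric_names, function(m) mean(per_rep[[m]]),
                         numeric(1))),
    sd = unname(vapply(metric_names, function(m) sd(per_rep[[m]]),
                       numeric(1)))
  )
  frequencies <- dplyr::bind_rows(lapply(names(active), function(b) {
    tibble::tibble(block = active[[b]],
                   feature = names(freq[[b]]),
                   frequency = as.integer(freq[[b]]))
  }))
  structure(list(per_rep = per_rep, summary = summary,
                 frequencies = frequencies,
                 fits = dplyr::bind_rows(fits),
                 n_fits = config$repetitions * config$outer_folds,
                 n_subjects = length(y), class_counts = table(y),
                 config = config, manifest = blocks$manifest, seed = seed),
            class = "cv_report")
}

active_blocks <- function(blocks, config) {
  active <- list()
  for (role in c("roi", "net")) {
    bn <- config[[paste0(role, "_block")]]
    if (!is.null(bn)) {
      if (is.null(blocks$blocks[[bn]])) {
        abort(paste0("feature block not found: ", bn),
              class = "hiernet_cv_error")
      }
      active[[role]] <- bn
    }
  }
  active
}

merge_counts <- function(counts, new_names) {
  tab <- table(new_names)
  all_names <- union(names(counts), names(tab))
  out <- setNames(integer(length(all_names)), all_names)
  out[names(counts)] <- counts
  out[names(tab)] <- out[names(tab)] + as.integer(tab)
  out
}

run_repetition <- function(blocks, config, active, y) {
  folds <- stratified_folds(y, config$outer_folds)
  n <- length(y)
  pred <- character(n)
  score <- numeric(n)
  fit_rows <- list()
  selected <- lapply(active, function(b) character(0))
  for (f in seq_len(config$outer_folds)) {
    test <- folds == f
    fit <- fit_fold(blocks, config, active, y, train = !test)
    kte <- mapply(function(prep, b) {
      rbf_kernel(prep$z_test, prep$gamma, prep$z_train)
    }, fit$prep, names(fit$prep), SIMPLIFY = FALSE)
    kfull <- fuse_block_kernels(kte, fit$beta)
    sv <- kernlab::SVindex(fit$model)
    pr <- kernlab::predict(fit$model,
                  kernlab::as.kernelMatrix(kfull[, sv, drop = FALSE]))
    dc <- kernlab::predict(fit$model,
                  kernlab::as.kernelMatrix(kfull[, sv, drop = FALSE]),
                  type = "decision")
    pred[test] <- as.character(pr)
    score[test] <- fit$orientation * drop(dc)
    for (b in names(active)) {
      selected[[b]] <- c(selected[[b]], fit$prep[[b]]$selected)
    }
    fit_rows[[f]] <- tibble::tibble(
      fold = f, cost = fit$cost, beta = fit$beta,
      n_roi = if ("roi" %in% names(active)) length(fit$prep$roi$selected) else NA_integer_,
      n_net = if ("net" %in% names(active)) length(fit$prep$net$selected) else NA_integer_,
      inner_accuracy = fit$inner_accuracy
    )
  }
  pos <- config$positive
  metrics <- compute_metrics(as.character(y), pred, score, positive = pos)
  list(metrics = metrics, fits = dplyr::bind_rows(fit_rows),
       selected = selected)
}

# test-portion predictions need the fold's trained state: per-block selected
# features, training standardization, gamma, plus the fitted kernel SVM.
# Hyperparameters (cost, beta, retained feature count) are chosen first by a
# leakage-free inner CV; the full cascade then runs once on the training
# portion with the chosen retained count.
fit_fold <- function(blocks, config, active, y, train) {
  ytr <- droplevels(y[train])
  xtr_full <- lapply(active, function(b) blocks$blocks[[b]][train, , drop = FALSE])
  pick <- inner_select(xtr_full, ytr, config)
  prep <- list()
  for (role in names(active)) {
    x <- blocks$blocks[[active[[role]]]]
    sel_cfg <- config$selection
    if (identical(sel_cfg$rfe_keep, "auto")) {
      sel_cfg$rfe_keep <- pick$keep[[role]]
    }
    casc <- run_cascade(xtr_full[[role]], ytr, sel_cfg)
    sel <- casc$selected
    xtr <- x[train, sel, drop = FALSE]
    mu <- colMeans(xtr)
    sg <- apply(xtr, 2, sd)
    sg[sg == 0] <- 1
    z_train <- sweep(sweep(xtr, 2, mu), 2, sg, `/`)
    z_test <- sweep(sweep(x[!train, sel, drop = FALSE], 2, mu), 2, sg, `/`)
    gamma <- config$gamma_scale / length(sel)
    prep[[role]] <- list(selected = sel, z_train = z_train, z_test = z_test,
                         gamma = gamma,
                         k_train = rbf_kernel(z_train, gamma))
  }
  ktr <- fuse_block_kernels(lapply(prep, `[[`, "k_train"), pick$beta)
  model <- kernlab::ksvm(kernlab::as.kernelMatrix(ktr), ytr, type = "C-svc",
                         C = pick$cost)
  # orient decision scores so larger = more positive-class-like
  sv <- kernlab::SVindex(model)
  dtr <- drop(kernlab::predict(model, kernlab::as.kernelMatrix(ktr[, sv, drop = FALSE]),
                      type = "decision"))
  ptr <- as.character(kernlab::predict(model,
                              kernlab::as.kernelMatrix(ktr[, sv, drop = FALSE])))
  is_pos <- ptr == config$positive
  orientation <- if (any(is_pos) && any(!is_pos) &&
                     mean(dtr[is_pos]) < mean(dtr[!is_pos])) -1 else 1
  list(prep = prep, model = model, cost = pick$cost, beta = pick$beta,
       inner_accuracy = pick$accuracy, orientation = orientation)
}

# grid over per-block retained counts, SVM cost and kernel weight
hyper_grid <- function(config, roles, keep_grids) {
  beta <- if (!"net" %in% roles) 1 else if (!"roi" %in% roles) 0 else config$beta_grid
  args <- lapply(keep_grids, identity)
  names(args) <- paste0("keep_", names(keep_grids))
  args$cost <- config$cost_grid
  args$beta <- beta
  expand.grid(args, KEEP.OUT.ATTRS = FALSE)
}

fuse_block_kernels <- function(ks, beta) {
  if (length(ks) == 2) fuse_kernels(ks$roi, ks$net, beta)
  else ks[[1]]
}

# Leakage-free stratified inner CV over the (retained count, cost, beta)
# grid on the training portion. Each inner fold re-fits a light selection
# surrogate — the top-k features by absolute two-sample t statistic on the
# inner-training portion, per block — so that inner validation subjects
# never inform the features they are scored on; the full cascade would be
# too costly to refit per inner fold and grid point, and the t ranking is
# its first, dominant stage. Accuracy ties are broken by the standardized
# class separation of the pooled validation decision values, then by grid
# order (smaller retained counts first).
inner_select <- function(xtr_full, ytr, config) {
  folds <- stratified_folds(ytr, config$inner_folds)
  base_grid <- config$selection$rfe_keep_grid
  if (!identical(config$selection$rfe_keep, "auto")) {
    base_grid <- config$selection$rfe_keep
  }
  keep_grids <- lapply(xtr_full, function(x) {
    sort(unique(pmin(base_grid, ncol(x))))
  })
  fold_ids <- sort(unique(folds))
  hi <- ytr == levels(ytr)[2]

  # kernel cache: per fold, per block, per retained count
  cache <- lapply(fold_ids, function(f) {
    tr <- folds != f
    yf <- droplevels(ytr[tr])
    if (nlevels(yf) < 2) return(NULL)
    km <- lapply(names(xtr_full), function(role) {
      x <- xtr_full[[role]]
      tstat <- abs(ttest_filter(x[tr, , drop = FALSE], yf,
                                alpha = 1)$stats$statistic)
      tstat[is.na(tstat)] <- 0
      ranked <- colnames(x)[order(-tstat, colnames(x))]
      ks <- keep_grids[[role]]
      lapply(setNames(ks, ks), function(k) {
        xk <- x[, ranked[seq_len(k)], drop = FALSE]
        mu <- colMeans(xk[tr, , drop = FALSE])
        sg <- apply(xk[tr, , drop = FALSE], 2, sd)
        sg[sg == 0] <- 1
        z <- sweep(sweep(xk, 2, mu), 2, sg, `/`)
        gamma <- config$gamma_scale / k
        list(tr = rbf_kernel(z[tr, , drop = FALSE], gamma),
             va = rbf_kernel(z[!tr, , drop = FALSE], gamma,
                             z[tr, , drop = FALSE]))
      })
    })
    names(km) <- names(xtr_full)
    km
  })

  # evaluate one (kernel-choice, cost, beta) point across the inner folds;
  # `roles` restricts to a single block during stage A
  eval_point <- function(get_k, cost, beta, roles = names(xtr_full)) {
    correct <- 0L
    dval <- numeric(length(ytr))
    for (i in seq_along(fold_ids)) {
      km <- cache[[i]]
      if (is.null(km)) next
      km <- km[roles]
      f <- fold_ids[i]
      tr <- folds != f
      yf <- droplevels(ytr[tr])
      ktr <- fuse_block_kernels(
        setNames(lapply(names(km), function(r) km[[r]][[get_k(r)]]$tr),
                 names(km)), beta)
      kva <- fuse_block_kernels(
        setNames(lapply(names(km), function(r) km[[r]][[get_k(r)]]$va),
                 names(km)), beta)
      m <- kernlab::ksvm(kernlab::as.kernelMatrix(ktr), yf, type = "C-svc",
                         C = cost)
      sv <- kernlab::SVindex(m)
      kv <- kernlab::as.kernelMatrix(kva[, sv, drop = FALSE])
      pr <- kernlab::predict(m, kv)
      correct <- correct + sum(as.character(pr) == as.character(ytr[!tr]))
      dval[!tr] <- drop(kernlab::predict(m, kv, type = "decision"))
    }
    s <- sd(dval)
    list(acc = correct / length(ytr),
         margin = if (s == 0) 0 else abs(mean(dval[hi]) - mean(dval[!hi])) / s)
  }

  # stage A: retained count per block, each block's kernel alone (cost held
  # at its first grid value; cost is tuned in stage B)
  keep <- integer(0)
  stage_a <- list()
  for (role in names(xtr_full)) {
    beta_solo <- if (role == "roi") 1 else 0
    ga <- expand.grid(keep = keep_grids[[role]], cost = config$cost_grid[1],
                      KEEP.OUT.ATTRS = FALSE)
    res <- lapply(seq_len(nrow(ga)), function(g) {
      eval_point(function(r) as.character(ga$keep[g]), ga$cost[g], beta_solo,
                 roles = role)
    })
    acc <- vapply(res, `[[`, numeric(1), "acc")
    mar <- vapply(res, `[[`, numeric(1), "margin")
    best <- order(-acc, -mar)[1]
    keep[role] <- as.integer(ga$keep[best])
    stage_a[[role]] <- list(cost = ga$cost[best], acc = acc[best])
  }

  # stage B: cost and beta on the fused kernel at the chosen counts
  if (length(xtr_full) == 2) {
    gb <- expand.grid(cost = config$cost_grid, beta = config$beta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  } else {
    role <- names(xtr_full)
    gb <- expand.grid(cost = config$cost_grid,
                      beta = if (role == "roi") 1 else 0,
                      KEEP.OUT.ATTRS = FALSE)
  }
  res <- lapply(seq_len(nrow(gb)), function(g) {
    eval_point(function(r) as.character(keep[[r]]), gb$cost[g], gb$beta[g])
  })
  acc <- vapply(res, `[[`, numeric(1), "acc")
  mar <- vapply(res, `[[`, numeric(1), "margin")
  best <- order(-acc, -mar)[1]
  list(keep = keep, cost = gb$cost[best], beta = gb$beta[best],
       accuracy = acc[best])
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$config$repetitions, "repetitions x",
      x$config$outer_folds, "folds;", x$n_subjects, "subjects (",
      paste(names(x$class_counts), x$class_counts, sep = "=", collapse = ", "),
      ")\n")
  s <- x$summary
  cat(paste0("  ", s$metric, " = ", sprintf("%.3f", s$mean), " +/- ",
             sprintf("%.3f", s$sd), collapse = "\n"), "\n")
  invisible(x)
}
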