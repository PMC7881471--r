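#' Classification performance across fixed kernel weights
#'
#' Runs the full nested cross-validation once per value of the ROI-kernel
#' weight beta, with beta pinned (removed from the inner hyperparameter
#' grid). Small beta weights the network kernel, large beta the ROI kernel;
#' the curve shows which feature family carries the discriminative signal.
#' The same seed (hence the same outer splits) is used at every beta so the
#' curve is comparable across the grid.
#'
#' @param blocks A `feature_blocks` object with both active blocks.
#' @param beta_grid Beta values to evaluate, each in `[0, 1]`.
#' @param config A [cv_config()]; its `beta_grid` is overridden point-wise.
#' @param seed Integer seed shared by all sweep points.
#' @return A `weight_sweep` tibble: one row per beta with the mean of each
#'   metric over repetitions plus `ACC_sd`.
#' @export
weight_sweep <- function(blocks, beta_grid = seq(0, 1, by = 0.05),
                         config = cv_config(), seed = NULL) {
  if (any(beta_grid < 0 | beta_grid > 1)) {
    abort("beta_grid must lie in [0, 1]", class = "hiernet_cv_error")
  }
  if (is.null(config$roi_block) || is.null(config$net_block)) {
    abort("weight_sweep needs both roi_block and net_block",
          class = "hiernet_cv_error")
  }
  rows <- lapply(beta_grid, function(b) {
    cfg <- config
    cfg$beta_grid <- b
    rep <- nested_cv(blocks, cfg, seed = seed)
    means <- setNames(rep$summary$mean, rep$summary$metric)
    dplyr::bind_cols(tibble::tibble(beta = b),
                     tibble::as_tibble(as.list(means)),
                     tibble::tibble(ACC_sd = rep$summary$sd[
                       rep$summary$metric == "ACC"]))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("weight_sweep", class(out))
  out
}

#' Comparison classifiers on the selected features
#'
#' Runs the same repeated stratified outer cross-validation protocol as
#' [nested_cv()], but trains conventional classifiers on the concatenated,
#' training-standardized features selected per block by the cascade:
#' RBF-kernel SVM, linear SVM, k-nearest neighbours, naive Bayes and a
#' decision tree.
#'
#' @param blocks A `feature_blocks` object.
#' @param config A [cv_config()]; `repetitions`, `outer_folds`, `selection`
#'   and the block choices are honoured.
#' @param classifiers Subset of `"svm_rbf"`, `"svm_linear"`, `"knn"`,
#'   `"naive_bayes"`, `"decision_tree"`.
#' @param knn_k Neighbours for the k-nearest-neighbour classifier.
#' @param seed Integer seed.
#' @return Tibble with one row per classifier: mean and sd of accuracy over
#'   repetitions.
#' @export
baseline_classifiers <- function(blocks, config = cv_config(),
                                 classifiers = c("svm_rbf", "svm_linear",
                                                 "knn", "naive_bayes",
                                                 "decision_tree"),
                                 knn_k = 5, seed = NULL) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  y <- blocks$labels
  if (nlevels(y) != 2 || min(table(y)) < 4) {
    abort("baseline_classifiers needs two groups with >= 4 subjects each",
          class = "hiernet_cv_error")
  }
  active <- active_blocks(blocks, config)
  rep_seeds <- derive_seeds(seed, config$repetitions)
  acc <- matrix(NA_real_, config$repetitions, length(classifiers),
                dimnames = list(NULL, classifiers))
  for (r in seq_len(config$repetitions)) {
    acc[r, ] <- with_seed(rep_seeds[[r]], {
      folds <- stratified_folds(y, config$outer_folds)
      hits <- setNames(numeric(length(classifiers)), classifiers)
      for (f in seq_len(config$outer_folds)) {
        test <- folds == f
        ytr <- droplevels(y[!test])
        zs <- lapply(names(active), function(role) {
          x <- blocks$blocks[[active[[role]]]]
          sel <- run_cascade(x[!test, , drop = FALSE], ytr,
                             config$selection)$selected
          xtr <- x[!test, sel, drop = FALSE]
          mu <- colMeans(xtr); sg <- apply(xtr, 2, sd); sg[sg == 0] <- 1
          list(tr = sweep(sweep(xtr, 2, mu), 2, sg, `/`),
               te = sweep(sweep(x[test, sel, drop = FALSE], 2, mu), 2, sg, `/`))
        })
        ztr <- do.call(cbind, lapply(zs, `[[`, "tr"))
        zte <- do.call(cbind, lapply(zs, `[[`, "te"))
        colnames(ztr) <- colnames(zte) <- paste0("f", seq_len(ncol(ztr)))
        for (cl in classifiers) {
          pr <- fit_baseline(cl, ztr, ytr, zte, knn_k)
          hits[cl] <- hits[cl] + sum(as.character(pr) == as.character(y[test]))
        }
      }
      hits / length(y)
    })
  }
  tibble::tibble(
    classifier = classifiers,
    accuracy = colMeans(acc),
    accuracy_sd = apply(acc, 2, sd)
  )
}

fit_baseline <- function(classifier, ztr, ytr, zte, knn_k) {
  switch(
    classifier,
    svm_rbf = predict(e1071::svm(ztr, ytr, kernel = "radial",
                                 gamma = 1 / ncol(ztr), scale = FALSE), zte),
    svm_linear = predict(e1071::svm(ztr, ytr, kernel = "linear",
                                    scale = FALSE), zte),
    knn = class::knn(ztr, zte, ytr, k = min(knn_k, nrow(ztr))),
    naive_bayes = predict(e1071::naiveBayes(ztr, ytr), zte),
    decision_tree = {
      df <- data.frame(ztr); df$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minsplit = 4,
                                                         cp = 0.01,
                                                         xval = 0))
      predict(fit, data.frame(zte), type = "class")
    },
    abort(paste0("unknown classifier: ", classifier),
          class = "hiernet_cv_error")
  )
}
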