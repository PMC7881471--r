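# shared fixtures and independent oracles

# 4-region toy hierarchy: two homologous pairs merging into one pair at
# layers 3 and 2 (layer sizes 1/2/2/4)
toy_atlas <- function() {
  new_atlas(tibble::tibble(
    layer4_index = 1:4,
    layer4_name = rep(c("Alpha", "Beta"), each = 2),
    hemisphere = rep(c("L", "R"), 2),
    layer3_index = c(1L, 2L, 1L, 2L),
    layer3_name = "Combined",
    layer2_index = c(1L, 2L, 1L, 2L),
    layer2_name = "Lobe"
  ))
}

# hand-buildable cohort on the toy atlas: measures supplied per subject as a
# 4-row data frame of the six ROI measures
toy_cohort <- function(subjects) {
  rows <- lapply(names(subjects), function(id) {
    m <- subjects[[id]]
    tibble::tibble(
      subject_id = id,
      label = attr(m, "label"),
      tiv = sum(m$gm_volume + m$wm_volume + m$csf_volume),
      mean_thickness = mean(m$thickness_mean),
      total_area = sum(m$surface_area),
      roi_index = seq_len(nrow(m)),
      gm_volume = m$gm_volume, wm_volume = m$wm_volume,
      csf_volume = m$csf_volume, thickness_mean = m$thickness_mean,
      thickness_sd = m$thickness_sd, surface_area = m$surface_area
    )
  })
  dplyr::bind_rows(rows)
}

toy_measures <- function(thk, thk_sd = rep(0.3, length(thk)), label = "high",
                         gm = rep(100, length(thk))) {
  out <- tibble::tibble(
    gm_volume = gm, wm_volume = rep(80, length(thk)),
    csf_volume = rep(30, length(thk)), thickness_mean = thk,
    thickness_sd = thk_sd, surface_area = rep(50, length(thk))
  )
  attr(out, "label") <- label
  out
}

# the acceptance-scale planted-effect experiment: 5 regional effects (d = 2,
# volume/area measures only) and 4 edge couplings on disjoint matched pairs
recovery_effects <- function() {
  list(
    roi = data.frame(roi = c(7, 46, 1, 48, 19),
                     measure = c("wm", "gm", "csf", "area", "wm"), d = 2),
    edge = data.frame(roi_i = c(15, 16, 27, 28),
                      roi_j = c(55, 56, 63, 64), coupling = 0.95),
    roi_features = c("roi07_wm", "roi46_gm", "roi01_csf", "roi48_area",
                     "roi19_wm"),
    edge_features = c("L4_e15_55", "L4_e16_56", "L4_e27_63", "L4_e28_64")
  )
}

# --- independent oracles ----------------------------------------------------

# entropy-based mutual information of two discrete vectors, written from the
# textbook definition via table()
oracle_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        mi <- mi + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
      }
    }
  }
  mi
}

oracle_bins <- function(v) {
  cut(v, c(-Inf, mean(v) - sd(v), mean(v) + sd(v), Inf), labels = FALSE)
}

# exhaustive greedy mRMR (MID): at every step scores every remaining
# candidate from scratch
oracle_mrmr <- function(x, y, keep) {
  bins <- apply(x, 2, oracle_bins)
  chosen <- character(0)
  candidates <- colnames(x)
  for (s in seq_len(keep)) {
    scores <- sapply(candidates, function(f) {
      rel <- oracle_mi(bins[, f], as.integer(y))
      red <- if (length(chosen) == 0) 0 else
        mean(sapply(chosen, function(g) oracle_mi(bins[, f], bins[, g])))
      rel - red
    })
    ord <- order(-scores, candidates)
    chosen <- c(chosen, candidates[ord[1]])
    candidates <- setdiff(candidates, chosen)
  }
  chosen
}

# step-by-step RFE oracle: refits the linear SVM each iteration and removes
# the single lowest squared-weight feature (ties lexical)
oracle_rfe_order <- function(x, y, keep) {
  surv <- colnames(x)
  removed <- character(0)
  while (length(surv) > keep) {
    fit <- e1071::svm(x[, surv, drop = FALSE], y, kernel = "linear",
                      scale = FALSE)
    w2 <- drop(crossprod(fit$coefs, fit$SV))^2
    drop_f <- surv[order(w2, surv)][1]
    removed <- c(removed, drop_f)
    surv <- setdiff(surv, drop_f)
  }
  list(kept = surv, elimination = removed)
}
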