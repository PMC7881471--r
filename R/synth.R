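# Synthetic two-group cohorts with planted regional and edge-level effects.
#
# Generative model, per subject s and bottom-layer ROI i:
#   thickness_mean[s,i] = h_s * (mu[i] + delta[s,i])      (mm)
#   thickness_sd[s,i]   = h_s * sw[i] * exp(N(0, 0.05))
#   volume/area[s,i,m]  = g_s * B[i,m] * exp(N(0, cv_m))
# with ROI profiles mu[i] ~ N(2.5, 0.25), sw[i] ~ N(0.30, 0.05) (floored),
# B[i,m] log-normal around tissue-typical magnitudes; g_s and h_s are
# per-subject multiplicative global size/thickness factors, removed again by
# normalization. delta[s,i] is the between-subject regional thickness
# deviation (SD tau = 0.15 mm).
#
# Planted effects (applied to the "high" group):
#   * ROI effect (roi, measure, d): shifts that measure by d standard
#     deviations of its between-subject noise (additive d*tau for thickness,
#     a d*cv log-shift for volumes/areas).
#   * Edge effect (roi_i, roi_j, coupling): the two ROIs' thickness
#     deviations are drawn with correlation `coupling` in the high group and
#     independently in the low group. Marginals are unchanged, so the signal
#     appears only in the joint distribution — i.e. in the similarity edge —
#     not in any single regional measure.

#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate a 34 + 34 two-group morphometry study: mean cortical
#' thickness around 2.5 mm with 0.25 mm regional spread, 0.30 mm within-ROI
#' dispersion and 0.15 mm between-subject regional variability; tissue
#' volumes and surface areas log-normal around typical regional magnitudes
#' with 10% between-subject noise and a 5% global size factor.
#'
#' @param n_per_group Subjects per group (>= 2); default 34.
#' @param roi_effects Data frame of planted regional effects with columns
#'   `roi` (layer-4 index), `measure` (one of `"gm"`, `"wm"`, `"csf"`,
#'   `"thk"`, `"area"`) and `d` (standardized effect size).
#' @param edge_effects Data frame of planted edge effects with columns
#'   `roi_i`, `roi_j` (layer-4 indices) and `coupling` (thickness-deviation
#'   correlation in (0, 1] for the high group).
#' @param baseline Named list overriding generator baselines:
#'   `thickness_mean`, `thickness_roi_sd`, `thickness_subject_sd`,
#'   `thickness_within_sd`, `thickness_within_roi_sd`, `gm_volume`,
#'   `wm_volume`, `csf_volume`, `surface_area` (per-ROI magnitudes),
#'   `volume_roi_cv`, `measure_cv`, `global_size_sd`, `global_thickness_sd`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group = 34, roi_effects = NULL,
                       edge_effects = NULL, baseline = list()) {
  if (n_per_group < 2) {
    abort("n_per_group must be >= 2", class = "hiernet_sim_error")
  }
  base <- list(
    thickness_mean = 2.5, thickness_roi_sd = 0.25,
    thickness_subject_sd = 0.15, thickness_within_sd = 0.30,
    thickness_within_roi_sd = 0.05,
    gm_volume = 8000, wm_volume = 6000, csf_volume = 2000,
    surface_area = 2500,
    volume_roi_cv = 0.30, measure_cv = 0.10,
    global_size_sd = 0.05, global_thickness_sd = 0.02
  )
  unknown <- setdiff(names(baseline), names(base))
  if (length(unknown) > 0) {
    abort(paste0("unknown baseline parameter(s): ",
                 paste(unknown, collapse = ", ")),
          class = "hiernet_sim_error")
  }
  base <- modifyList(base, baseline)
  roi_effects <- if (is.null(roi_effects)) {
    tibble::tibble(roi = integer(0), measure = character(0), d = numeric(0))
  } else tibble::as_tibble(roi_effects)
  edge_effects <- if (is.null(edge_effects)) {
    tibble::tibble(roi_i = integer(0), roi_j = integer(0),
                   coupling = numeric(0))
  } else tibble::as_tibble(edge_effects)
  if (nrow(roi_effects) > 0) {
    bad <- setdiff(roi_effects$measure, names(block_measures))
    if (length(bad) > 0) {
      abort(paste0("unknown measure in roi_effects: ", bad[1]),
            class = "hiernet_sim_error")
    }
    if (any(!is.finite(roi_effects$d))) {
      abort("roi effect sizes must be finite", class = "hiernet_sim_error")
    }
  }
  if (nrow(edge_effects) > 0 &&
      (any(!is.finite(edge_effects$coupling)) ||
       any(edge_effects$coupling <= 0) || any(edge_effects$coupling > 1))) {
    abort("edge couplings must lie in (0, 1]", class = "hiernet_sim_error")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 roi_effects = roi_effects, edge_effects = edge_effects,
                 baseline = base),
            class = "sim_config")
}

#' Simulate a two-group morphometry cohort
#'
#' Draws a cohort under the generative model described in [sim_config()],
#' applying planted regional and edge-level effects to the high-self-esteem
#' ("high") group. Subject globals (total intracranial volume, global mean
#' thickness, total surface area) are computed from the generated regional
#' values, so normalization is internally consistent.
#'
#' @param config A [sim_config()].
#' @param atlas A `roi_atlas` defining the bottom-layer ROI set.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A cohort tibble (see [read_cohort()] for the schema) with the
#'   planted effects recorded in attribute `ground_truth`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_per_group = 4), seed = 7)
#' dplyr::count(cohort, label) # 4 x 78 rows per group
#' @export
simulate_cohort <- function(config = sim_config(), atlas = load_atlas(),
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_cohort_impl(config, atlas))
}

simulate_cohort_impl <- function(config, atlas) {
  b <- config$baseline
  n4 <- nrow(atlas_layer(atlas, 4))
  n <- config$n_per_group
  ns <- 2L * n
  ids <- sprintf("S%03d", seq_len(ns))
  labels <- rep(c("high", "low"), each = n)

  bad_roi <- setdiff(c(config$roi_effects$roi, config$edge_effects$roi_i,
                       config$edge_effects$roi_j), seq_len(n4))
  if (length(bad_roi) > 0) {
    abort(paste0("planted effect names unknown ROI index ", bad_roi[1]),
          class = "hiernet_sim_error")
  }

  # ROI population profiles
  mu <- rnorm(n4, b$thickness_mean, b$thickness_roi_sd)
  mu <- pmax(mu, 0.5)
  # a planted edge pairs two regions of matched population thickness (the
  # regime where a similarity edge can be strong), whose subject-level
  # deviations are then coupled in the high group only
  if (nrow(config$edge_effects) > 0) {
    for (r in seq_len(nrow(config$edge_effects))) {
      mu[config$edge_effects$roi_j[r]] <- mu[config$edge_effects$roi_i[r]]
    }
  }
  sw <- pmax(rnorm(n4, b$thickness_within_sd, b$thickness_within_roi_sd), 0.05)
  vol_base <- sapply(c(b$gm_volume, b$wm_volume, b$csf_volume,
                       b$surface_area),
                     function(m) m * exp(rnorm(n4, 0, b$volume_roi_cv)))
  colnames(vol_base) <- c("gm", "wm", "csf", "area")

  g <- exp(rnorm(ns, 0, b$global_size_sd))
  h <- exp(rnorm(ns, 0, b$global_thickness_sd))

  # between-subject thickness deviations; planted edges correlate pairs of
  # ROI deviations in the high group only
  tau <- b$thickness_subject_sd
  corr <- diag(n4)
  if (nrow(config$edge_effects) > 0) {
    for (r in seq_len(nrow(config$edge_effects))) {
      i <- config$edge_effects$roi_i[r]
      j <- config$edge_effects$roi_j[r]
      rho <- config$edge_effects$coupling[r]
      corr[i, j] <- corr[j, i] <- rho
    }
  }
  ch <- tryCatch(chol(corr), error = function(e) {
    abort("edge_effects define a non-positive-definite coupling structure",
          class = "hiernet_sim_error")
  })
  delta <- matrix(0, ns, n4)
  is_high <- labels == "high"
  delta[is_high, ] <- (matrix(rnorm(n * n4), n, n4) %*% ch) * tau
  delta[!is_high, ] <- matrix(rnorm(n * n4, 0, tau), n, n4)

  thk <- sweep(matrix(mu, ns, n4, byrow = TRUE) + delta, 1, h, `*`)
  # planted regional thickness shifts
  re <- config$roi_effects
  for (r in seq_len(nrow(re))) {
    if (re$measure[r] == "thk") {
      thk[is_high, re$roi[r]] <- thk[is_high, re$roi[r]] +
        h[is_high] * re$d[r] * tau
    }
  }
  # positivity: bounded redraw of offending deviations
  for (tries in seq_len(20)) {
    bad <- which(thk <= 0)
    if (length(bad) == 0) break
    thk[bad] <- matrix(mu, ns, n4, byrow = TRUE)[bad] +
      rnorm(length(bad), 0, tau)
  }
  if (any(thk <= 0)) {
    abort("could not generate strictly positive thickness values; check baselines",
          class = "hiernet_sim_error")
  }

  thk_sd <- sweep(matrix(sw, ns, n4, byrow = TRUE) *
                    exp(matrix(rnorm(ns * n4, 0, 0.05), ns, n4)), 1, h, `*`)

  meas <- list()
  for (m in c("gm", "wm", "csf", "area")) {
    shift <- matrix(0, ns, n4)
    for (r in seq_len(nrow(re))) {
      if (re$measure[r] == m) {
        shift[is_high, re$roi[r]] <- re$d[r] * b$measure_cv
      }
    }
    meas[[m]] <- sweep(matrix(vol_base[, m], ns, n4, byrow = TRUE) *
                         exp(matrix(rnorm(ns * n4, 0, b$measure_cv), ns, n4) +
                               shift), 1, g, `*`)
  }

  tiv <- rowSums(meas$gm + meas$wm + meas$csf)
  mean_thk <- rowMeans(thk)
  tot_area <- rowSums(meas$area)

  cohort <- tibble::tibble(
    subject_id = rep(ids, each = n4),
    label = rep(labels, each = n4),
    tiv = rep(tiv, each = n4),
    mean_thickness = rep(mean_thk, each = n4),
    total_area = rep(tot_area, each = n4),
    roi_index = rep(seq_len(n4), times = ns),
    gm_volume = as.vector(t(meas$gm)),
    wm_volume = as.vector(t(meas$wm)),
    csf_volume = as.vector(t(meas$csf)),
    thickness_mean = as.vector(t(thk)),
    thickness_sd = as.vector(t(thk_sd)),
    surface_area = as.vector(t(meas$area))
  )
  attr(cohort, "ground_truth") <- list(roi_effects = config$roi_effects,
                                       edge_effects = config$edge_effects)
  cohort
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_per_group, "subjects/group;",
      nrow(x$roi_effects), "planted ROI effect(s),",
      nrow(x$edge_effects), "planted edge effect(s)\n")
  invisible(x)
}
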