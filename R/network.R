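# Per-layer similarity networks. The edge between ROIs i and j is a Gaussian
# kernel of the difference of their mean cortical thicknesses,
#   C(i,j) = exp(-(t_i - t_j)^2 / (2 (s_i^2 + s_j^2))),
# where s_i is the within-ROI thickness standard deviation. Coarser-layer
# ROIs inherit (t, s) as unweighted means over their constituent ROIs.

#' Gaussian thickness-similarity between two ROIs
#'
#' Computes `exp(-(t_i - t_j)^2 / (2 * (sigma_i^2 + sigma_j^2)))`. Values lie
#' in (0, 1]: 1 for identical mean thickness, decreasing in the thickness
#' difference. Depends only on the difference `t_i - t_j`, so a uniform shift
#' of all thickness means leaves every edge unchanged. Vectorized over its
#' arguments.
#'
#' @param t_i,t_j Mean cortical thickness of the two ROIs.
#' @param sigma_i,sigma_j Within-ROI thickness standard deviations (>= 0).
#' @return Similarity in (0, 1]. When both sigmas are zero the value is 1 if
#'   `t_i == t_j` and an error otherwise (the dispersion scale is degenerate).
#' @examples
#' edge_similarity(2.5, 0.3, 2.5, 0.4)          # 1
#' edge_similarity(2.8, 0.3, 2.2, 0.4)          # exp(-0.72)
#' @export
edge_similarity <- function(t_i, sigma_i, t_j, sigma_j) {
  if (any(sigma_i < 0) || any(sigma_j < 0)) {
    abort("thickness standard deviations must be non-negative",
          class = "hiernet_network_error")
  }
  denom <- sigma_i^2 + sigma_j^2
  d2 <- (t_i - t_j)^2
  bad <- denom == 0 & d2 > 0
  if (any(bad)) {
    abort("degenerate dispersion: sigma_i = sigma_j = 0 with t_i != t_j",
          class = "hiernet_network_error")
  }
  ifelse(denom == 0, 1, exp(-d2 / (2 * denom)))
}

#' Per-ROI thickness statistics at any layer
#'
#' At the bottom layer these are the measured per-ROI mean thickness and its
#' within-ROI standard deviation. At coarser layers a compound ROI's mean and
#' standard deviation are the unweighted averages of its constituent
#' bottom-layer ROIs' values (`sigma_method = "mean"`). A pooled alternative,
#' `sqrt(mean(sigma^2))`, is available via `sigma_method = "pooled"`.
#'
#' @inheritParams validate_cohort
#' @param layer Layer number in 1-4.
#' @param sigma_method How compound-ROI standard deviations are aggregated:
#'   `"mean"` (default) or `"pooled"`.
#' @return Tibble with `subject_id`, `index` (ROI index at `layer`), `t`
#'   (mean thickness) and `sigma`, ordered by subject then index.
#' @export
merge_thickness_stats <- function(cohort, atlas = load_atlas(), layer = 4,
                                  sigma_method = c("mean", "pooled")) {
  sigma_method <- match.arg(sigma_method)
  check_layer(atlas, layer)
  map <- atlas_merge_map(atlas, layer)
  df <- tibble::tibble(
    subject_id = cohort$subject_id,
    index = map[as.integer(cohort$roi_index)],
    t = cohort$thickness_mean,
    sigma = cohort$thickness_sd
  )
  agg <- if (sigma_method == "mean") {
    dplyr::summarise(dplyr::group_by(df, .data$subject_id, .data$index),
                     t = mean(.data$t), sigma = mean(.data$sigma),
                     .groups = "drop")
  } else {
    dplyr::summarise(dplyr::group_by(df, .data$subject_id, .data$index),
                     t = mean(.data$t), sigma = sqrt(mean(.data$sigma^2)),
                     .groups = "drop")
  }
  dplyr::arrange(agg, .data$subject_id, .data$index)
}

#' Build one subject's similarity network at a layer
#'
#' @inheritParams merge_thickness_stats
#' @param subject_id Which subject; may be omitted for a single-subject
#'   cohort.
#' @param normalize Normalize the cohort first (default); see
#'   [normalize_cohort()]. The network is invariant to the normalization of
#'   thickness (numerator and denominator of the kernel exponent scale
#'   together), so this only matters for consistency with downstream blocks.
#' @return A `layer_network`: a symmetric n x n matrix with unit diagonal and
#'   entries in (0, 1], with ROI names as dimnames and attribute `layer`.
#' @export
build_layer_network <- function(cohort, atlas = load_atlas(), layer = 4,
                                subject_id = NULL, normalize = TRUE,
                                sigma_method = c("mean", "pooled")) {
  sigma_method <- match.arg(sigma_method)
  if (normalize) cohort <- normalize_cohort(cohort, atlas)
  ids <- unique(cohort$subject_id)
  if (is.null(subject_id)) {
    if (length(ids) != 1) {
      abort("cohort has several subjects; supply subject_id",
            class = "hiernet_network_error")
    }
    subject_id <- ids
  }
  if (!subject_id %in% ids) {
    abort(paste0("unknown subject: ", subject_id), class = "hiernet_network_error")
  }
  stats <- merge_thickness_stats(cohort[cohort$subject_id == subject_id, ],
                                 atlas, layer, sigma_method)
  n <- nrow(stats)
  t <- stats$t
  s <- stats$sigma
  mat <- outer(seq_len(n), seq_len(n),
               function(i, j) edge_similarity(t[i], s[i], t[j], s[j]))
  diag(mat) <- 1
  rois <- atlas_layer(atlas, layer)
  lbl <- paste0(rois$name, ifelse(rois$hemisphere == "whole", "",
                                  paste0(" (", rois$hemisphere, ")")))
  dimnames(mat) <- list(lbl, lbl)
  structure(mat, layer = as.integer(layer), class = c("layer_network", "matrix", "array"))
}

#' Flatten a similarity network to its edge-feature vector
#'
#' Takes the strict upper triangle (i < j) in row-major order: pair (1,2),
#' (1,3), ..., (1,n), (2,3), ... Feature names encode the layer and ROI index
#' pair as `L<layer>_e<i>_<j>`.
#'
#' @param net A `layer_network` from [build_layer_network()].
#' @return Named numeric vector of length n(n-1)/2 (length 0 for the 1-ROI
#'   whole-brain layer).
#' @export
vectorize_network <- function(net) {
  if (!inherits(net, "layer_network")) {
    abort("net must be a layer_network", class = "hiernet_network_error")
  }
  n <- nrow(net)
  layer <- attr(net, "layer")
  pairs <- upper_pairs(n)
  vals <- net[cbind(pairs$i, pairs$j)]
  setNames(as.numeric(vals), edge_feature_names(layer, pairs))
}

# strict upper-triangle pairs in row-major order (i ascending, then j)
upper_pairs <- function(n) {
  if (n < 2) return(list(i = integer(0), j = integer(0)))
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n), use.names = FALSE)
  list(i = i, j = as.integer(j))
}

edge_feature_names <- function(layer, pairs) {
  if (length(pairs$i) == 0) return(character(0))
  sprintf("L%d_e%02d_%02d", layer, pairs$i, pairs$j)
}
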