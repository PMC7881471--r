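# Feature blocks: subjects x features matrices for classification.
#   roi_L4  — 78 ROIs x 5 normalized measures (GM/WM/CSF volume, mean
#             thickness, surface area) = 390 features
#   net_L4/net_L3/net_L2 — strict upper triangles of the per-layer similarity
#             networks (3003 / 630 / 91 edges)
#   net_all — concatenation over layers 4, 3, 2, 1 (the 1-ROI whole-brain
#             layer contributes no edges) = 3724 features

block_measures <- c(gm = "gm_volume", wm = "wm_volume", csf = "csf_volume",
                    thk = "thickness_mean", area = "surface_area")

measure_labels <- c(gm = "GM volume", wm = "WM volume", csf = "CSF volume",
                    thk = "Thickness", area = "Area")

#' Assemble per-subject feature blocks
#'
#' Normalizes the cohort, builds the per-layer similarity networks, and
#' returns the regional and network feature blocks as subjects x features
#' matrices with a deterministic, documented feature order: ROI features are
#' ordered by ROI index with the five measures (GM, WM, CSF volume, mean
#' thickness, surface area) nested inside; edge features follow the row-major
#' strict upper triangle of each layer's matrix, layers concatenated in the
#' order 4, 3, 2, 1.
#'
#' @inheritParams validate_cohort
#' @param blocks Which blocks to build (any of `"roi_L4"`, `"net_L4"`,
#'   `"net_L3"`, `"net_L2"`, `"net_all"`).
#' @param normalize Normalize measures by subject globals first (default).
#' @param sigma_method Compound-ROI dispersion rule; see
#'   [merge_thickness_stats()].
#' @param positive Label treated as the positive class.
#' @return A `feature_blocks` object: list with `blocks` (named list of
#'   matrices, rows = subjects in order of first appearance), `labels`
#'   (named factor), and `manifest` (tibble annotating every feature with its
#'   block, layer, ROI indices/names, hemispheres and measure).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_per_group = 4), seed = 1)
#' fb <- assemble_blocks(cohort)
#' vapply(fb$blocks, ncol, integer(1))
#' @export
assemble_blocks <- function(cohort, atlas = load_atlas(),
                            blocks = c("roi_L4", "net_L4", "net_L3",
                                       "net_L2", "net_all"),
                            normalize = TRUE,
                            sigma_method = c("mean", "pooled"),
                            positive = "high") {
  sigma_method <- match.arg(sigma_method)
  blocks <- match.arg(blocks, several.ok = TRUE)
  validate_cohort(cohort, atlas)
  if (normalize) cohort <- normalize_cohort(cohort, atlas)
  ids <- unique(cohort$subject_id)
  labels <- cohort_labels(cohort, positive = positive)[ids]

  need_layers <- integer(0)
  if (any(c("net_L4", "net_all") %in% blocks)) need_layers <- c(need_layers, 4L)
  if (any(c("net_L3", "net_all") %in% blocks)) need_layers <- c(need_layers, 3L)
  if (any(c("net_L2", "net_all") %in% blocks)) need_layers <- c(need_layers, 2L)

  edge <- if (length(need_layers) == 0) list() else {
    lapply(setNames(need_layers, paste0("L", need_layers)),
           function(l) edge_block(cohort, atlas, l, ids, sigma_method))
  }

  out <- list()
  manifest <- list()
  if ("roi_L4" %in% blocks) {
    rb <- roi_block(cohort, atlas, ids)
    out$roi_L4 <- rb$x
    manifest$roi_L4 <- dplyr::mutate(rb$manifest, block = "roi_L4")
  }
  for (l in c(4L, 3L, 2L)) {
    bn <- paste0("net_L", l)
    if (bn %in% blocks) {
      out[[bn]] <- edge[[paste0("L", l)]]$x
      manifest[[bn]] <- dplyr::mutate(edge[[paste0("L", l)]]$manifest,
                                      block = bn)
    }
  }
  if ("net_all" %in% blocks) {
    xs <- lapply(paste0("L", c(4L, 3L, 2L)), function(k) edge[[k]]$x)
    out$net_all <- do.call(cbind, xs)
    manifest$net_all <- dplyr::mutate(
      dplyr::bind_rows(lapply(paste0("L", c(4L, 3L, 2L)),
                              function(k) edge[[k]]$manifest)),
      block = "net_all")
  }
  manifest <- dplyr::relocate(dplyr::bind_rows(manifest), "block")
  structure(list(blocks = out, labels = labels, manifest = manifest),
            class = "feature_blocks")
}

roi_block <- function(cohort, atlas, ids) {
  rois <- atlas_layer(atlas, 4)
  n <- nrow(rois)
  ord <- order(match(cohort$subject_id, ids), cohort$roi_index)
  co <- cohort[ord, ]
  cols <- lapply(names(block_measures), function(m) {
    matrix(co[[block_measures[[m]]]], nrow = length(ids), ncol = n, byrow = TRUE)
  })
  # interleave: ROI-major, measure-minor
  x <- matrix(0, nrow = length(ids), ncol = n * length(block_measures))
  keys <- names(block_measures)
  fnames <- character(ncol(x))
  for (k in seq_along(keys)) {
    idx <- (seq_len(n) - 1) * length(keys) + k
    x[, idx] <- cols[[k]]
    fnames[idx] <- sprintf("roi%02d_%s", seq_len(n), keys[k])
  }
  colnames(x) <- fnames
  rownames(x) <- ids
  manifest <- tibble::tibble(
    feature = fnames,
    kind = "roi",
    layer = 4L,
    roi_i = rep(seq_len(n), each = length(keys)),
    roi_j = NA_integer_,
    roi_i_name = rep(rois$name, each = length(keys)),
    roi_i_hemi = rep(rois$hemisphere, each = length(keys)),
    roi_j_name = NA_character_,
    roi_j_hemi = NA_character_,
    measure = rep(unname(measure_labels[keys]), times = n)
  )
  list(x = x, manifest = manifest)
}

edge_block <- function(cohort, atlas, layer, ids, sigma_method) {
  stats <- merge_thickness_stats(cohort, atlas, layer, sigma_method)
  n <- nrow(atlas_layer(atlas, layer))
  ord <- order(match(stats$subject_id, ids), stats$index)
  stats <- stats[ord, ]
  tmat <- matrix(stats$t, nrow = length(ids), ncol = n, byrow = TRUE)
  smat <- matrix(stats$sigma, nrow = length(ids), ncol = n, byrow = TRUE)
  pairs <- upper_pairs(n)
  d2 <- (tmat[, pairs$i, drop = FALSE] - tmat[, pairs$j, drop = FALSE])^2
  denom <- smat[, pairs$i, drop = FALSE]^2 + smat[, pairs$j, drop = FALSE]^2
  if (any(denom == 0 & d2 > 0)) {
    abort("degenerate dispersion: sigma_i = sigma_j = 0 with t_i != t_j",
          class = "hiernet_network_error")
  }
  x <- ifelse(denom == 0, 1, exp(-d2 / (2 * denom)))
  x <- matrix(x, nrow = length(ids))
  colnames(x) <- edge_feature_names(layer, pairs)
  rownames(x) <- ids
  rois <- atlas_layer(atlas, layer)
  manifest <- tibble::tibble(
    feature = colnames(x),
    kind = "edge",
    layer = as.integer(layer),
    roi_i = pairs$i,
    roi_j = pairs$j,
    roi_i_name = rois$name[pairs$i],
    roi_i_hemi = rois$hemisphere[pairs$i],
    roi_j_name = rois$name[pairs$j],
    roi_j_hemi = rois$hemisphere[pairs$j],
    measure = "Similarity"
  )
  list(x = x, manifest = manifest)
}

#' @export
print.feature_blocks <- function(x, ...) {
  cat("<feature_blocks>", nrow(x$blocks[[1]]), "subjects;",
      paste(names(x$blocks), vapply(x$blocks, ncol, integer(1)),
            sep = ":", collapse = ", "), "\n")
  cat("  labels:", paste(levels(x$labels), table(x$labels),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Feature matrix of one block as a tibble
#'
#' @param blocks A `feature_blocks` object.
#' @param block Block name.
#' @return Tibble with `subject_id`, `label` and one column per feature.
#' @export
block_tibble <- function(blocks, block = "roi_L4") {
  stopifnot(inherits(blocks, "feature_blocks"))
  x <- blocks$blocks[[block]]
  if (is.null(x)) abort(paste0("no such block: ", block))
  dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(x),
                   label = as.character(blocks$labels[rownames(x)])),
    tibble::as_tibble(x))
}
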