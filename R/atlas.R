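#' Load a multi-resolution ROI hierarchy
#'
#' Reads a four-layer region-of-interest (ROI) hierarchy. The built-in
#' `"aal78"` atlas is the 78-region cortical subset of the Automated
#' Anatomical Labeling (AAL) parcellation (the 12 subcortical AAL regions
#' removed, remaining regions renumbered 1-78), merged upward into 36
#' anatomical surfaces (layer 3), 14 lobes (layer 2) and the whole brain
#' (layer 1). Odd indices are left-hemisphere, even indices right-hemisphere
#' homologues.
#'
#' The interchange format is a flat TSV with one row per bottom-layer ROI and
#' columns `layer4_index`, `layer4_name`, `hemisphere`, `layer3_index`,
#' `layer3_name`, `layer2_index`, `layer2_name`. Layer 1 is implicit: every
#' ROI belongs to the single whole-brain region.
#'
#' Note on the built-in table: the source parcellation lists the index pair
#' 17/18 under a single label "Rolandic operculum left"; the pair is encoded
#' here as left/right "Rolandic operculum" following the index convention, as
#' for every other homologous pair.
#'
#' @param source `"aal78"` for the built-in atlas, or a path to a hierarchy
#'   TSV in the interchange format.
#' @return A `roi_atlas` object: a list with `table` (the flat tibble),
#'   `layers` (per-layer ROI tibbles with `index`, `name`, `hemisphere`) and
#'   `merge` (per-layer integer maps from layer-4 index to that layer's
#'   index).
#' @examples
#' atlas <- load_atlas()
#' atlas_layer_sizes(atlas)
#' count_layer_edges(atlas, 4)
#' @export
load_atlas <- function(source = "aal78") {
  path <- if (identical(source, "aal78")) {
    system.file("extdata", "aal78_hierarchy.tsv", package = "hiernet",
                mustWork = TRUE)
  } else {
    if (!file.exists(source)) {
      abort(paste0("atlas file not found: ", source), class = "hiernet_atlas_error")
    }
    source
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  new_atlas(tab)
}

#' Construct and validate an ROI hierarchy from a flat table
#'
#' @param table A data frame in the hierarchy interchange format (see
#'   [load_atlas()]).
#' @return A validated `roi_atlas`.
#' @export
new_atlas <- function(table) {
  required <- c("layer4_index", "layer4_name", "hemisphere",
                "layer3_index", "layer3_name", "layer2_index", "layer2_name")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    abort(paste0("atlas table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "hiernet_atlas_error")
  }
  tab <- tibble::as_tibble(table)[required]
  tab <- dplyr::arrange(tab, .data$layer4_index)
  validate_atlas_table(tab)

  n4 <- nrow(tab)
  layers <- list(
    `1` = tibble::tibble(index = 1L, name = "Whole brain", hemisphere = "whole"),
    `2` = dplyr::distinct(dplyr::arrange(
      tibble::tibble(index = tab$layer2_index, name = tab$layer2_name,
                     hemisphere = tab$hemisphere), .data$index)),
    `3` = dplyr::distinct(dplyr::arrange(
      tibble::tibble(index = tab$layer3_index, name = tab$layer3_name,
                     hemisphere = tab$hemisphere), .data$index)),
    `4` = tibble::tibble(index = tab$layer4_index, name = tab$layer4_name,
                         hemisphere = tab$hemisphere)
  )
  merge <- list(
    `1` = rep(1L, n4),
    `2` = as.integer(tab$layer2_index),
    `3` = as.integer(tab$layer3_index),
    `4` = as.integer(tab$layer4_index)
  )
  structure(list(table = tab, layers = layers, merge = merge),
            class = "roi_atlas")
}

validate_atlas_table <- function(tab) {
  bad_hemi <- setdiff(unique(tab$hemisphere), c("L", "R"))
  if (length(bad_hemi) > 0) {
    abort(paste0("invalid hemisphere code(s): ", paste(bad_hemi, collapse = ", ")),
          class = "hiernet_atlas_error")
  }
  n4 <- nrow(tab)
  if (anyDuplicated(tab$layer4_index)) {
    dup <- tab$layer4_index[duplicated(tab$layer4_index)][1]
    abort(paste0("duplicate layer-4 ROI index: ", dup),
          class = "hiernet_atlas_error")
  }
  if (!identical(as.integer(tab$layer4_index), seq_len(n4))) {
    abort("layer-4 ROI indices must be contiguous from 1",
          class = "hiernet_atlas_error")
  }
  for (l in c("layer3", "layer2")) {
    idx <- tab[[paste0(l, "_index")]]
    nm <- tab[[paste0(l, "_name")]]
    if (anyNA(idx) || anyNA(nm)) {
      roi <- tab$layer4_index[which(is.na(idx) | is.na(nm))[1]]
      abort(paste0("missing ", l, " mapping for layer-4 ROI ", roi),
            class = "hiernet_atlas_error")
    }
    u <- sort(unique(as.integer(idx)))
    if (!identical(u, seq_along(u))) {
      abort(paste0(l, " indices are not surjective onto 1..",
                   length(u), " (gaps present)"),
            class = "hiernet_atlas_error")
    }
    # one name per index
    nn <- tapply(nm, idx, function(x) length(unique(x)))
    if (any(nn > 1)) {
      abort(paste0("inconsistent ", l, " name for index ",
                   names(nn)[which(nn > 1)[1]]),
            class = "hiernet_atlas_error")
    }
  }
  # layer-4 -> 2 must factor through layer-4 -> 3
  via3 <- tapply(tab$layer2_index, tab$layer3_index,
                 function(x) length(unique(x)))
  if (any(via3 > 1)) {
    abort(paste0("layer-3 ROI ", names(via3)[which(via3 > 1)[1]],
                 " maps to multiple layer-2 ROIs"),
          class = "hiernet_atlas_error")
  }
  invisible(tab)
}

#' Number of ROIs at each layer
#'
#' @param atlas A `roi_atlas`.
#' @return Named integer vector of ROI counts for layers 1-4.
#' @export
atlas_layer_sizes <- function(atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  vapply(atlas$layers, nrow, integer(1))
}

#' ROI table for one layer
#'
#' @param atlas A `roi_atlas`.
#' @param layer Layer number in 1-4 (1 = whole brain, 4 = finest).
#' @return Tibble with `index`, `name`, `hemisphere`.
#' @export
atlas_layer <- function(atlas, layer) {
  check_layer(atlas, layer)
  atlas$layers[[as.character(layer)]]
}

#' Map from bottom-layer ROIs to a coarser layer
#'
#' @inheritParams atlas_layer
#' @return Integer vector of length `n4` giving, for each layer-4 ROI, its ROI
#'   index at `layer`.
#' @export
atlas_merge_map <- function(atlas, layer) {
  check_layer(atlas, layer)
  atlas$merge[[as.character(layer)]]
}

#' Number of network edge features at a layer
#'
#' A layer with n ROIs contributes the n(n-1)/2 strict upper-triangular
#' entries of its similarity matrix as features.
#'
#' @inheritParams atlas_layer
#' @return Integer edge count.
#' @examples
#' count_layer_edges(load_atlas(), 4)  # 3003
#' @export
count_layer_edges <- function(atlas, layer) {
  check_layer(atlas, layer)
  n <- nrow(atlas$layers[[as.character(layer)]])
  as.integer(n * (n - 1) / 2)
}

check_layer <- function(atlas, layer) {
  stopifnot(inherits(atlas, "roi_atlas"))
  if (length(layer) != 1 || !layer %in% as.numeric(names(atlas$layers))) {
    abort(paste0("invalid layer: ", paste(layer, collapse = ",")),
          class = "hiernet_atlas_error")
  }
  invisible(layer)
}

#' Write an ROI hierarchy to the interchange TSV
#'
#' @param atlas A `roi_atlas`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "roi_atlas"))
  readr::write_tsv(atlas$table, path, progress = FALSE)
  invisible(path)
}

#' @export
print.roi_atlas <- function(x, ...) {
  sizes <- atlas_layer_sizes(x)
  cat("<roi_atlas> 4-layer hierarchy:",
      paste(rev(sizes), collapse = " -> "), "ROIs\n")
  cat("  layer-4 edge features:", count_layer_edges(x, 4), "\n")
  invisible(x)
}

#' @export
format.roi_atlas <- function(x, ...) {
  paste0("<roi_atlas: ", paste(rev(atlas_layer_sizes(x)), collapse = "/"), ">")
}
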