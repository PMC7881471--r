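#' Feature selection-frequency table
#'
#' Ranks features by how often they survived the full selection cascade over
#' all repetition x fold fits of a [nested_cv()] run — the stability ranking
#' of the discriminative regional and network features. Frequencies are
#' bounded by `repetitions * outer_folds`. Ties break by feature-name
#' lexical order. Features are annotated with their ROI name(s), hemisphere
#' and measure (or layer, for network edges) from the block manifest.
#'
#' @param report A `cv_report`.
#' @param block `"roi"` or `"net"`: which kernel's features to rank.
#' @param top_k Rows to return (the full table if larger than the number of
#'   ever-selected features).
#' @return Tibble with `rank`, `feature`, `frequency` and annotation columns
#'   (`layer`, `roi_i_name`, `roi_i_hemi`, `roi_j_name`, `roi_j_hemi`,
#'   `measure`).
#' @export
frequency_table <- function(report, block = c("net", "roi"), top_k = 15) {
  stopifnot(inherits(report, "cv_report"))
  block <- match.arg(block)
  bn <- report$config[[paste0(block, "_block")]]
  if (is.null(bn)) {
    abort(paste0("no ", block, " block in this report"),
          class = "hiernet_cv_error")
  }
  freq <- report$frequencies[report$frequencies$block == bn, ]
  freq <- freq[order(-freq$frequency, freq$feature), ]
  freq <- head(freq, top_k)
  ann <- report$manifest[report$manifest$block == bn,
                         c("feature", "layer", "roi_i_name", "roi_i_hemi",
                           "roi_j_name", "roi_j_hemi", "measure")]
  out <- dplyr::left_join(freq, ann, by = "feature")
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(tibble::as_tibble(out), "rank")
}
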