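#' Radial-basis-function kernel matrix
#'
#' `K[a, b] = exp(-gamma * ||x_a - x_b||^2)` between the rows of `x` (or
#' between rows of `x` and rows of `x2`). With `x2 = NULL` the result is
#' symmetric positive-semidefinite with unit diagonal.
#'
#' @param x Feature matrix (subjects x features), typically standardized on
#'   training statistics.
#' @param gamma Kernel width parameter (> 0); a common default is
#'   `1 / ncol(x)` on standardized features.
#' @param x2 Optional second feature matrix; the result is then
#'   `nrow(x) x nrow(x2)`.
#' @return Kernel matrix.
#' @export
rbf_kernel <- function(x, gamma, x2 = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(paste0("non-finite feature value at subject ",
                 rownames(x)[bad[1]] %||% bad[1], ", feature ",
                 colnames(x)[bad[2]] %||% bad[2]),
          class = "hiernet_kernel_error")
  }
  if (gamma < 0) abort("gamma must be non-negative", class = "hiernet_kernel_error")
  symmetric <- is.null(x2)
  x2 <- if (symmetric) x else as.matrix(x2)
  if (!all(is.finite(x2))) {
    abort("non-finite feature value in x2", class = "hiernet_kernel_error")
  }
  d2 <- outer(rowSums(x^2), rowSums(x2^2), `+`) - 2 * tcrossprod(x, x2)
  d2[d2 < 0] <- 0  # numerical noise
  k <- exp(-gamma * d2)
  if (symmetric) {
    k <- (k + t(k)) / 2
    diag(k) <- 1
  }
  k
}

#' Convex fusion of two block kernels
#'
#' `beta * k_roi + (1 - beta) * k_net`. A convex combination of
#' positive-semidefinite kernels is positive-semidefinite, so the fused
#' matrix is a valid SVM kernel. `beta = 1` reproduces the ROI kernel
#' exactly and `beta = 0` the network kernel.
#'
#' @param k_roi,k_net Kernel matrices of matching dimension (ROI-feature
#'   block and network-feature block).
#' @param beta Weight of the ROI kernel, in `[0, 1]`.
#' @return Fused kernel matrix.
#' @export
fuse_kernels <- function(k_roi, k_net, beta) {
  if (beta < 0 || beta > 1) {
    abort("beta must lie in [0, 1]", class = "hiernet_kernel_error")
  }
  if (!all(dim(k_roi) == dim(k_net))) {
    abort("kernel dimensions differ", class = "hiernet_kernel_error")
  }
  beta * k_roi + (1 - beta) * k_net
}
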