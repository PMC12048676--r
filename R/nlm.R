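#' Non-local means denoising of a single frame
#'
#' Classic patch-based NLM: each pixel is replaced by a weighted average of
#' pixels in a search window, with weights decaying in the mean squared
#' difference between the surrounding patches,
#' `w = exp(-d2 / h^2)`. Implemented by shifting the frame over all search
#' offsets and box-filtering the squared difference image, which is exact
#' and fast for the small patch sizes used here. A constant image is a
#' fixed point.
#'
#' @param frame numeric matrix.
#' @param patch_radius patch half-width in px (patch is
#'   `(2r+1) x (2r+1)`).
#' @param search_radius search window half-width in px.
#' @param h filter strength in intensity units; default `0.8 * sd(frame)`.
#' @return denoised matrix of the same shape.
#' @export
nlm_denoise <- function(frame, patch_radius = 1, search_radius = 5,
                        h = NULL) {
  if (!is.matrix(frame)) abort("`frame` must be a 2-D matrix.")
  if (is.null(h)) h <- 0.8 * sd(frame)
  if (!is.finite(h) || h <= 0) return(frame)  # constant frame: nothing to do
  nr <- nrow(frame); nc <- ncol(frame)
  pr <- as.integer(patch_radius)
  box <- matrix(1 / (2 * pr + 1)^2, 2 * pr + 1, 2 * pr + 1)
  acc <- frame              # centre pixel enters with weight 1
  wsum <- matrix(1, nr, nc)
  shift_mat <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  for (dr in -search_radius:search_radius) {
    for (dc in -search_radius:search_radius) {
      if (dr == 0 && dc == 0) next
      shifted <- shift_mat(frame, dr, dc)
      d2 <- conv2_same((frame - shifted)^2, box)
      w <- exp(-d2 / h^2)
      acc <- acc + w * shifted
      wsum <- wsum + w
    }
  }
  acc / wsum
}
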