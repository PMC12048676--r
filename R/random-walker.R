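#' Seeded random-walker segmentation of a frame
#'
#' Two-label random-walker (graph diffusion) labelling: pixels are nodes of
#' a 4-connected lattice with edge weights
#' `w_ij = exp(-beta * (g_i - g_j)^2)` on the `[0, 1]`-scaled image, and
#' each unlabeled pixel receives the probability that a random walker
#' started there reaches an "inside" seed before an "outside" seed — the
#' solution of the combinatorial Dirichlet problem on the graph Laplacian.
#' The sparse linear system is solved with Matrix.
#'
#' @param frame numeric matrix (any range; scaled internally).
#' @param seeds integer matrix of the same shape: 1 = inside seed,
#'   2 = outside seed, 0 = unlabeled.
#' @param beta edge-weight diffusion parameter (dimensionless); larger
#'   values make intensity steps harder to cross.
#' @return numeric matrix of inside-label probabilities in `[0, 1]` (seeds
#'   are exactly 1 or 0).
#' @export
random_walker <- function(frame, seeds, beta = 130) {
  stopifnot(is.matrix(frame), all(dim(seeds) == dim(frame)))
  if (!any(seeds == 1) || !any(seeds == 2)) {
    abort("`seeds` must contain both labels (1 = inside, 2 = outside).")
  }
  nr <- nrow(frame); nc <- ncol(frame)
  rng <- range(frame)
  g <- if (diff(rng) > 0) (frame - rng[1]) / diff(rng) else frame * 0
  n <- nr * nc
  idx <- matrix(seq_len(n), nr, nc)
  # vertical and horizontal lattice edges
  vi <- as.vector(idx[-nr, ]); vj <- as.vector(idx[-1, ])
  hi <- as.vector(idx[, -nc]); hj <- as.vector(idx[, -1])
  ei <- c(vi, hi); ej <- c(vj, hj)
  wgt <- exp(-beta * (g[ei] - g[ej])^2)
  # graph Laplacian L = D - W
  W <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = c(wgt, wgt),
                            dims = c(n, n))
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  lab <- as.vector(seeds)
  unl <- which(lab == 0L)
  prob <- as.numeric(lab == 1L)
  if (length(unl) > 0) {
    sed <- which(lab != 0L)
    b <- as.numeric(lab[sed] == 1L)
    rhs <- -L[unl, sed, drop = FALSE] %*% b
    x <- Matrix::solve(L[unl, unl], rhs)
    prob[unl] <- pmin(pmax(as.numeric(x), 0), 1)
  }
  matrix(prob, nr, nc)
}
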