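# Internal helpers shared across modules.

# Scalar checks ------------------------------------------------------------

check_number <- function(x, name, min = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (finite && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name))
  }
  if (strict && x <= min) {
    abort(sprintf("`%s` must be > %g.", name, min))
  }
  if (!strict && x < min) {
    abort(sprintf("`%s` must be >= %g.", name, min))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  check_number(x, name, min = 0)
  if (x > 1) abort(sprintf("`%s` must lie in [0, 1].", name))
  invisible(x)
}

# RNG ----------------------------------------------------------------------

# Evaluate `expr` under `seed` and restore the caller's RNG state so that
# simulations are reproducible without perturbing the global stream.
with_sim_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Image stacks ---------------------------------------------------------------

# A stack is a numeric array [rows, cols, frames] with `pixel_size` (um/px)
# and `frame_interval` (s) attributes. Pixel (r, c) has its centre at
# x = (c - 0.5) * pixel_size, y = (r - 0.5) * pixel_size; the origin is the
# top-left pixel corner, x rightward, y downward, matching spot coordinates.
image_stack <- function(data, pixel_size, frame_interval) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  check_number(pixel_size, "pixel_size", min = 0, strict = TRUE)
  check_number(frame_interval, "frame_interval", min = 0, strict = TRUE)
  structure(data, pixel_size = pixel_size, frame_interval = frame_interval,
            class = c("image_stack", class(data)))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %d x %d px, %d frame(s), %.4g um/px, %.4g s/frame\n",
              d[1], d[2], d[3], attr(x, "pixel_size"), attr(x, "frame_interval")))
  invisible(x)
}

stack_pixel_size <- function(stack) attr(stack, "pixel_size") %||% 1
stack_frame_interval <- function(stack) attr(stack, "frame_interval") %||% 1

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pixel-centre coordinate vectors (um) for a frame of given shape.
pixel_centers <- function(n, pixel_size) (seq_len(n) - 0.5) * pixel_size

#' Read / write multi-page TIFF stacks
#'
#' Thin wrappers around the tiff package that carry the pixel size and frame
#' interval metadata used throughout the package.
#'
#' @param path file path.
#' @param pixel_size pixel size in micrometres per pixel.
#' @param frame_interval time between frames in seconds.
#' @return `read_stack_tiff()` returns an image stack (array `[rows, cols,
#'   frames]` with metadata attributes); `write_stack_tiff()` invisibly
#'   returns `path`.
#' @export
read_stack_tiff <- function(path, pixel_size = 1, frame_interval = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Package 'tiff' is required to read TIFF stacks.")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  image_stack(arr, pixel_size, frame_interval)
}

#' @rdname read_stack_tiff
#' @param stack an image stack array.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Package 'tiff' is required to write TIFF stacks.")
  }
  mx <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i] / mx)
  tiff::writeTIFF(pages, path)
  invisible(path)
}
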