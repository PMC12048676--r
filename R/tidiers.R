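# broom-style tidiers for the package's fitted objects.

#' Tidy a mono-exponential fit
#'
#' @param x an `exp_fit` from [fit_monoexp()].
#' @param ... unused.
#' @return one row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(term = c("A", "k", "C"),
         estimate = c(x$A, x$k, x$C),
         std.error = c(NA_real_, x$se_k, NA_real_))
}

#' @rdname tidy.exp_fit
#' @return `glance()`: one-row model summary with `model`, `k`, `t_half`,
#'   `se_k`, `r.squared`, `degenerate`, `nobs`.
#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble(model = x$model, k = x$k, t_half = x$t_half, se_k = x$se_k,
         r.squared = x$r_squared, degenerate = x$degenerate, nobs = x$n)
}

#' Tidy a diffusion fit
#'
#' @param x a `diffusion_fit` from [fit_diffusion()].
#' @param ... unused.
#' @return one row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy diffusion_fit
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble(term = c("D", "intercept"),
         estimate = c(x$D, x$intercept),
         std.error = c(x$se_D, NA_real_))
}

#' @rdname tidy.diffusion_fit
#' @return `glance()`: one-row summary with `D`, `intercept`, `r.squared`,
#'   `n_points`.
#' @method glance diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(D = x$D, intercept = x$intercept, r.squared = x$r_squared,
         n_points = x$n_points)
}
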