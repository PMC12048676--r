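#' Dwell-time survival curve
#'
#' Fraction of uncensored dwell times at least as long as `t`, evaluated at
#' the observed dwell times (a right-continuous step function with
#' `S(min dwell) = 1` by the >= convention). Right-censored dwells — tracks
#' still on the membrane when the movie ends — are excluded from the
#' fraction and reported in `n_censored` so the user can bound the bias.
#'
#' @param dwells dwell times, s (> 0).
#' @param censored logical flags, same length (default: none censored).
#' @return tibble of class `survival_curve` with columns `t`, `survival`;
#'   attributes `n_total`, `n_censored`.
#' @export
survival_curve <- function(dwells, censored = NULL) {
  if (length(dwells) == 0) abort("`dwells` is empty.")
  if (any(dwells <= 0)) abort("Dwell times must be > 0.")
  if (is.null(censored)) censored <- rep(FALSE, length(dwells))
  stopifnot(length(censored) == length(dwells))
  obs <- dwells[!censored]
  if (length(obs) == 0) abort("All dwells are censored.")
  ts <- sort(unique(obs))
  surv <- vapply(ts, function(t) mean(obs >= t), numeric(1))
  out <- tibble(t = ts, survival = surv)
  attr(out, "n_total") <- length(dwells)
  attr(out, "n_censored") <- sum(censored)
  class(out) <- c("survival_curve", class(out))
  out
}

#' Mono-exponential decay / growth fit
#'
#' Nonlinear least squares for the one-phase models
#' `y = C + A exp(-k t)` (decay) and `y = C + A (1 - exp(-k t))` (growth)
#' used for FRET exchange traces, dwell-time survival curves, flow-out
#' dissociation, FRAP recovery and photoactivation disappearance.
#' Fitting uses Levenberg-Marquardt (minpack.lm). Unless supplied,
#' starting values are `C = min(y)` (decay) or `max(y)` (growth),
#' `A = diff(range(y))`, and `k` from a log-linear regression on the first
#' half of the baseline-subtracted data. Non-convergence raises an error;
#' a non-positive rate at the optimum is flagged degenerate.
#'
#' @param t time points, s (increasing).
#' @param y observations (same length, >= 4 points).
#' @param model `"decay"` or `"growth"`.
#' @param init optional named list with starting values `A`, `k`, `C`.
#' @param fix_offset fit with `C` fixed at 0 (natural for survival
#'   fractions, which decay to zero).
#' @param weights optional per-point weights (unweighted by default).
#' @return an object of class `exp_fit`: `model`, `A`, `k`, `C`, `t_half`
#'   (`= log(2) / k`), `se_k`, `r_squared`, `degenerate`, `n`.
#' @export
fit_monoexp <- function(t, y, model = c("decay", "growth"), init = NULL,
                        fix_offset = FALSE, weights = NULL) {
  model <- match.arg(model)
  stopifnot(length(t) == length(y))
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 4) abort("At least 4 finite points are required.")
  if (is.unsorted(t)) abort("`t` must be increasing.")
  if (diff(range(y)) == 0) {
    abort("Constant trace: mono-exponential fit is degenerate.")
  }
  if (is.null(init)) {
    C0 <- if (fix_offset) 0 else if (model == "decay") min(y) else max(y)
    A0 <- diff(range(y))
    # log-linear rate guess from the first half of baseline-subtracted data
    half <- seq_len(max(4, floor(length(t) / 2)))
    z <- if (model == "decay") y[half] - C0 else (C0 - y[half])
    pos <- z > 0 & t[half] >= 0
    k0 <- if (sum(pos) >= 2) {
      sl <- -coef(lm(log(z[pos]) ~ t[half][pos]))[2]
      if (is.finite(sl) && sl > 0) unname(sl) else 1 / max(t[t > 0], 1)
    } else 1 / max(t[t > 0], 1)
    if (model == "growth" && !fix_offset) C0 <- min(y)
    init <- list(A = A0, k = k0, C = C0)
  }
  predict_fn <- if (model == "decay") {
    function(p, tt) (if (fix_offset) 0 else p["C"]) + p["A"] * exp(-p["k"] * tt)
  } else {
    function(p, tt) (if (fix_offset) 0 else p["C"]) +
      p["A"] * (1 - exp(-p["k"] * tt))
  }
  w <- if (is.null(weights)) rep(1, length(y)) else sqrt(weights)
  resid_fn <- function(p) w * (y - predict_fn(p, t))
  start <- unlist(init[if (fix_offset) c("A", "k") else c("A", "k", "C")])
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (!fit$info %in% 1:4) {
    abort(paste0("Mono-exponential fit failed to converge: ", fit$message))
  }
  est <- coef(fit)
  k <- unname(est["k"])
  se_k <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                   error = function(e) NA_real_)
  res <- y - predict_fn(est, t)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  degenerate <- !is.finite(k) || k <= 0
  if (degenerate) {
    warn("Fitted rate is not positive; fit flagged degenerate.")
  }
  structure(list(model = model, A = unname(est["A"]), k = k,
                 C = if (fix_offset) 0 else unname(est["C"]),
                 t_half = if (degenerate) NA_real_ else log(2) / k,
                 se_k = se_k, r_squared = r2, degenerate = degenerate,
                 n = length(t)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit:%s> k = %.4g /s (se %.2g), t1/2 = %.4g s, A = %.4g, C = %.4g, R2 = %.4f%s\n",
    x$model, x$k, x$se_k, x$t_half, x$A, x$C, x$r_squared,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fit a mono-exponential decay to a survival curve
#'
#' Convenience wrapper: fits `S(t) = A exp(-k t)` (offset fixed at zero,
#' since survival fractions decay to zero) and returns the [fit_monoexp()]
#' object. The fitted `k` is the membrane dissociation rate; compare with
#' the maximum-likelihood estimate `1 / mean(dwell)`.
#'
#' @param curve a [survival_curve()].
#' @param ... passed to [fit_monoexp()].
#' @return an `exp_fit`.
#' @export
fit_survival <- function(curve, ...) {
  fit_monoexp(curve$t - min(curve$t), curve$survival, model = "decay",
              fix_offset = TRUE, ...)
}

#' Acceptor/donor FRET ratio trace
#'
#' Pointwise `acceptor / donor` intensity ratio; its exponential decay
#' reports nucleotide exchange or complex dissociation. Samples with
#' non-positive donor signal yield `NA` and are flagged with a warning.
#' Optionally normalizes to the mean ratio over a leading baseline window.
#'
#' @param donor,acceptor equal-length intensity vectors.
#' @param normalize_baseline number of leading samples whose mean ratio is
#'   scaled to 1 (0 = no normalization).
#' @return numeric ratio vector.
#' @export
fret_ratio_trace <- function(donor, acceptor, normalize_baseline = 0) {
  stopifnot(length(donor) == length(acceptor))
  bad <- !is.finite(donor) | donor <= 0
  if (any(bad)) warn(sprintf("%d sample(s) with non-positive donor flagged NA.",
                             sum(bad)))
  ratio <- ifelse(bad, NA_real_, acceptor / donor)
  if (normalize_baseline > 0) {
    base <- mean(ratio[seq_len(normalize_baseline)], na.rm = TRUE)
    if (!is.finite(base) || base == 0) abort("Baseline ratio is empty or zero.")
    ratio <- ratio / base
  }
  ratio
}

#' Ratio of half-times between two mono-exponential fits
#'
#' `t_half(in) / t_half(out)` with the standard error propagated from the
#' two rate uncertainties (`t_half = ln 2 / k`, so relative errors add in
#' quadrature). Used to quantify dwell-time prolongation inside
#' GEF-containing membrane areas relative to outside.
#'
#' @param fit_in,fit_out converged [fit_monoexp()] objects.
#' @return one-row tibble: `ratio`, `se`, `t_half_in`, `t_half_out`.
#' @export
dwell_half_time_ratio <- function(fit_in, fit_out) {
  stopifnot(inherits(fit_in, "exp_fit"), inherits(fit_out, "exp_fit"))
  if (fit_in$degenerate || fit_out$degenerate) {
    abort("Cannot form a half-time ratio from a degenerate fit.")
  }
  ratio <- fit_in$t_half / fit_out$t_half
  rel <- sqrt((fit_in$se_k / fit_in$k)^2 + (fit_out$se_k / fit_out$k)^2)
  tibble(ratio = ratio, se = ratio * rel,
         t_half_in = fit_in$t_half, t_half_out = fit_out$t_half)
}
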