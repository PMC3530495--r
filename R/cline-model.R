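#' Sigmoid cline model
#'
#' The cline in a 0-1 scaled trait along the transect axis is the hyperbolic
#' tangent sigmoid
#' \deqn{p(x) = p_{min} + (p_{max} - p_{min}) \frac{1}{2}\left[1 +
#'   \tanh\left(\frac{2 (x - c)}{w}\right)\right]}
#' where `c` is the cline center (the position of the steepest point, km),
#' `w` the cline width (km), and `p_min`, `p_max` the tail trait values. The
#' maximum slope is `(p_max - p_min) / w` at `x = c`, so for a 0-1 cline the
#' width is the inverse of the maximum slope. `sigma` is the residual scale
#' of the Gaussian site-mean error model used by [cline_log_likelihood()].
#'
#' @param c Center position on the transect x axis (km).
#' @param w Width (km), > 0.
#' @param p_min,p_max Tail trait values (west / east asymptotes).
#' @param sigma Residual scale, > 0.
#'
#' @return An object of class `cline_model`.
#' @export
#' @examples
#' m <- cline_model(c = 30, w = 5)
#' cline_expectation(30, m)  # 0.5 at the center
cline_model <- function(c, w, p_min = 0, p_max = 1, sigma = 0.05) {
  stopifnot(is.finite(c), is.finite(w), w > 0,
            is.finite(p_min), is.finite(p_max),
            is.finite(sigma), sigma > 0)
  structure(list(c = c, w = w, p_min = p_min, p_max = p_max, sigma = sigma),
            class = "cline_model")
}

#' @export
print.cline_model <- function(x, ...) {
  cat(sprintf("Sigmoid cline: center %.2f km, width %.2f km, tails [%.3f, %.3f], sigma %.4f\n",
              x$c, x$w, x$p_min, x$p_max, x$sigma))
  if (!is.null(attr(x, "logLik")))
    cat(sprintf("  log-likelihood: %.3f\n", attr(x, "logLik")))
  if (isTRUE(attr(x, "degenerate")))
    cat("  NOTE: degenerate fit (p_max ~ p_min); no cline in these data\n")
  invisible(x)
}

#' Expected trait value under a cline model
#'
#' @param x Numeric vector of transect positions (km).
#' @param model A [cline_model()].
#' @return Numeric vector of expected trait values.
#' @export
cline_expectation <- function(x, model) {
  stopifnot(inherits(model, "cline_model"))
  model$p_min + (model$p_max - model$p_min) *
    0.5 * (1 + tanh(2 * (x - model$c) / model$w))
}

.check_obs <- function(obs) {
  stopifnot(is.data.frame(obs), all(c("x_km", "value", "n") %in% names(obs)),
            nrow(obs) >= 1)
  if (any(!is.finite(obs$x_km)) || any(!is.finite(obs$value)))
    stop("non-finite site observations")
  if (any(obs$n < 1)) stop("site sample sizes must be >= 1")
  invisible(obs)
}

#' Gaussian log-likelihood of site observations under a cline model
#'
#' Site trait values are means of `n_i` specimens, so they are modeled as
#' Gaussian around the cline expectation with standard deviation
#' `sigma / sqrt(n_i)`:
#' \deqn{\log L = \sum_i \left[-\tfrac{1}{2}\log(2\pi\sigma^2/n_i)
#'   - \frac{n_i (v_i - p(x_i))^2}{2\sigma^2}\right]}
#' With `weighted = FALSE` all sites count equally (`n_i` replaced by 1).
#'
#' @param model A [cline_model()].
#' @param obs Site-observation data frame (`x_km`, `value`, `n`).
#' @param weighted Weight sites by their sample size (default TRUE).
#' @return Scalar log-likelihood.
#' @export
cline_log_likelihood <- function(model, obs, weighted = TRUE) {
  stopifnot(inherits(model, "cline_model"))
  .check_obs(obs)
  if (model$sigma <= 0) stop("sigma must be positive")
  n <- if (weighted) obs$n else rep(1, nrow(obs))
  r <- obs$value - cline_expectation(obs$x_km, model)
  sum(-0.5 * log(2 * pi * model$sigma^2 / n) - n * r^2 / (2 * model$sigma^2))
}
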