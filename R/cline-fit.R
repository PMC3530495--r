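#' Fitting configuration
#'
#' Settings for the maximum-likelihood cline search. The fit runs independent
#' Metropolis-Hastings chains used as a stochastic maximizer (best visited
#' state retained, never a posterior sample), followed by a deterministic
#' polish: tail values and the residual scale are concentrated out in closed
#' form (weighted least squares and the sigma MLE are exact under the Gaussian
#' site-mean model), leaving a low-dimensional optimization over center and
#' width. Results are deterministic given `seed`.
#'
#' @param iterations Metropolis iterations per chain (default 800; sensible
#'   values run from 500 to 1000 depending on the number of sites).
#' @param chains Number of independent chains (default 2).
#' @param seed Integer seed; every random draw in [fit_cline()] /
#'   [profile_center()] descends from it.
#' @param center_grid_step Grid step (km) for the center likelihood profile
#'   (default 0.5).
#' @param profile_iterations Metropolis iterations per profile grid point
#'   (default 100; the deterministic polish does most of the work).
#' @param grid_expand Fraction by which the profile grid extends beyond the
#'   data x-range on each side (default 0.1).
#' @param weighted Weight sites by sample size `n_i` in the likelihood
#'   (default TRUE); set FALSE for unweighted site means.
#' @param w_bounds Width bounds in km; `NULL` means `c(0.1, 2 * x-range)`.
#' @param p_bounds Bounds for the tail values `p_min`, `p_max`.
#' @param sigma_bounds Bounds for the residual scale.
#'
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(iterations = 800, chains = 2, seed = 1,
                       center_grid_step = 0.5, profile_iterations = 100,
                       grid_expand = 0.1, weighted = TRUE,
                       w_bounds = NULL, p_bounds = c(-0.5, 1.5),
                       sigma_bounds = c(1e-8, 1)) {
  stopifnot(iterations >= 1, chains >= 1, center_grid_step > 0,
            profile_iterations >= 0, grid_expand >= 0,
            length(p_bounds) == 2, p_bounds[1] < p_bounds[2],
            length(sigma_bounds) == 2, sigma_bounds[1] > 0,
            is.null(w_bounds) || (length(w_bounds) == 2 && w_bounds[1] > 0))
  structure(list(iterations = as.integer(iterations),
                 chains = as.integer(chains),
                 seed = as.integer(seed),
                 center_grid_step = center_grid_step,
                 profile_iterations = as.integer(profile_iterations),
                 grid_expand = grid_expand,
                 weighted = isTRUE(weighted),
                 w_bounds = w_bounds,
                 p_bounds = p_bounds,
                 sigma_bounds = sigma_bounds),
            class = "fit_config")
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

.effective_n <- function(obs, weighted) if (weighted) obs$n else rep(1, nrow(obs))

# Closed-form profile over (p_min, p_max, sigma) at fixed (c, w):
# the expectation is linear in the tails, p(x) = p_min (1 - s) + p_max s with
# s = (1 + tanh(2 (x - c) / w)) / 2, so weighted least squares is exact, and
# sigma^2 = sum(n r^2) / n_sites is the Gaussian MLE.
.concentrate <- function(c, w, obs, cfg) {
  n <- .effective_n(obs, cfg$weighted)
  s <- 0.5 * (1 + tanh(2 * (obs$x_km - c) / w))
  a <- 1 - s
  v <- obs$value
  # normal equations for (p_min, p_max)
  m11 <- sum(n * a * a); m12 <- sum(n * a * s); m22 <- sum(n * s * s)
  b1 <- sum(n * a * v);  b2 <- sum(n * s * v)
  det <- m11 * m22 - m12 * m12
  if (det > 1e-10 * max(m11 * m22, 1e-300)) {
    p_min <- (m22 * b1 - m12 * b2) / det
    p_max <- (m11 * b2 - m12 * b1) / det
  } else {
    # tails indistinguishable (all s nearly equal): flat fit
    p_min <- p_max <- sum(n * v) / sum(n)
  }
  p_min <- min(max(p_min, cfg$p_bounds[1]), cfg$p_bounds[2])
  p_max <- min(max(p_max, cfg$p_bounds[1]), cfg$p_bounds[2])
  r <- v - (p_min * a + p_max * s)
  sigma <- sqrt(sum(n * r^2) / nrow(obs))
  sigma <- min(max(sigma, cfg$sigma_bounds[1]), cfg$sigma_bounds[2])
  logl <- sum(-0.5 * log(2 * pi * sigma^2 / n) - n * r^2 / (2 * sigma^2))
  list(c = c, w = w, p_min = p_min, p_max = p_max, sigma = sigma, logl = logl)
}

# maximize the concentrated log-likelihood over w at fixed c
.max_over_w <- function(c, obs, cfg, w_starts) {
  wb <- cfg$w_bounds
  best <- NULL
  for (w0 in unique(pmin(pmax(w_starts, wb[1]), wb[2]))) {
    opt <- stats::nlminb(log(w0),
                         function(lw) -.concentrate(c, exp(lw), obs, cfg)$logl,
                         lower = log(wb[1]), upper = log(wb[2]))
    cand <- .concentrate(c, exp(opt$par), obs, cfg)
    if (is.null(best) || cand$logl > best$logl) best <- cand
  }
  best
}

.resolve_w_bounds <- function(obs, cfg) {
  if (!is.null(cfg$w_bounds)) return(cfg)
  xr <- diff(range(obs$x_km))
  cfg$w_bounds <- c(0.1, max(2 * xr, 1))
  cfg
}

#' Initial center estimate from a cubic spline
#'
#' Smooths the (x, value) curve with a cubic spline and returns the position
#' of the steepest region: the x at which the absolute spline slope, evaluated
#' on a dense grid across the data range, is maximal. If the maximal-slope
#' region is a plateau (e.g. perfectly linear data), its midpoint is returned.
#' Used to initialize the maximum-likelihood search.
#'
#' @param obs Site-observation data frame with at least 4 distinct `x_km`.
#' @param grid_n Number of dense-grid evaluation points (default 1001).
#' @return Initial center position `c0` in km.
#' @export
spline_center_init <- function(obs, grid_n = 1001) {
  .check_obs(obs)
  if (length(unique(obs$x_km)) < 4)
    stop("need at least 4 distinct x positions for spline initialization")
  o <- order(obs$x_km)
  x <- obs$x_km[o]; v <- obs$value[o]
  xg <- seq(min(x), max(x), length.out = grid_n)
  slope <- tryCatch({
    ss <- suppressWarnings(stats::smooth.spline(x, v))
    stats::predict(ss, xg, deriv = 1)$y
  }, error = function(e) {
    # too few points for a smoothing spline: interpolating natural spline
    ux <- unique(x)
    uv <- as.numeric(tapply(v, match(x, ux), mean))
    f <- stats::splinefun(ux, uv, method = "natural")
    f(xg, deriv = 1)
  })
  amax <- max(abs(slope))
  tol <- max(1e-8, 1e-6 * amax)
  at_max <- which(abs(slope) >= amax - tol)
  mean(range(xg[at_max]))
}

# one Metropolis-Hastings chain used as a stochastic maximizer over
# theta = (c, log w, p_min, p_max, log sigma); returns the best visited state
.mh_chain <- function(obs, cfg, start, iterations, fix_c = FALSE) {
  n <- .effective_n(obs, cfg$weighted)
  x <- obs$x_km; v <- obs$value
  wb <- cfg$w_bounds; pb <- cfg$p_bounds; sb <- cfg$sigma_bounds
  cb <- range(x) + c(-1, 1) * diff(range(x))

  logl_of <- function(th) {
    w <- exp(th[2]); sig <- exp(th[5])
    pred <- th[3] + (th[4] - th[3]) * 0.5 * (1 + tanh(2 * (x - th[1]) / w))
    r <- v - pred
    sum(-0.5 * log(2 * pi * sig^2 / n) - n * r^2 / (2 * sig^2))
  }
  in_bounds <- function(th)
    th[1] >= cb[1] && th[1] <= cb[2] &&
    th[2] >= log(wb[1]) && th[2] <= log(wb[2]) &&
    th[3] >= pb[1] && th[3] <= pb[2] &&
    th[4] >= pb[1] && th[4] <= pb[2] &&
    th[5] >= log(sb[1]) && th[5] <= log(sb[2])

  th <- start
  ll <- logl_of(th)
  best_th <- th; best_ll <- ll
  scales <- c(diff(range(x)) / 20, 0.3, 0.08, 0.08, 0.3)
  if (fix_c) scales[1] <- 0
  burn <- max(1L, as.integer(0.2 * iterations))
  acc_window <- 0L; win_len <- 25L
  for (i in seq_len(iterations)) {
    prop <- th + stats::rnorm(5) * scales
    if (in_bounds(prop)) {
      llp <- logl_of(prop)
      if (is.finite(llp) && llp - ll > log(stats::runif(1))) {
        th <- prop; ll <- llp; acc_window <- acc_window + 1L
        if (ll > best_ll) { best_ll <- ll; best_th <- th }
      }
    }
    # burn-in adaptation toward ~30% acceptance; post-burn scales are frozen
    if (i <= burn && i %% win_len == 0L) {
      rate <- acc_window / win_len
      scales <- scales * exp(rate - 0.3)
      if (fix_c) scales[1] <- 0
      acc_window <- 0L
    }
  }
  list(theta = best_th, logl = best_ll)
}

#' Fit a sigmoid cline by maximum likelihood
#'
#' Runs independent Metropolis-Hastings chains started around the cubic-spline
#' center estimate, retains the highest-likelihood visited state, then
#' polishes deterministically: Nelder-Mead over (center, log width) with the
#' tail values and residual scale concentrated out in closed form. The
#' returned log-likelihood is never below that of any visited state.
#' Deterministic given `config$seed`; the caller's RNG state is untouched.
#'
#' @param obs Site-observation data frame (`x_km`, `value`, `n`), at least 5
#'   rows (four curve parameters plus the residual scale).
#' @param config A [fit_config()].
#'
#' @return A [cline_model()] with attributes `logLik` (achieved
#'   log-likelihood), `degenerate` (TRUE when `p_max` is within 0.01 of
#'   `p_min`, i.e. no cline in the data) and `c0` (spline initial center).
#' @export
#' @examples
#' obs <- simulate_cline_observations(seq(10, 50, by = 10), n = 10,
#'                                    c = 30, w = 5, sigma = 0.02, seed = 1)
#' fit_cline(obs, fit_config(seed = 1))
fit_cline <- function(obs, config = fit_config()) {
  .check_obs(obs)
  stopifnot(inherits(config, "fit_config"))
  if (nrow(obs) < 5)
    stop("need at least 5 site observations to fit a cline")
  cfg <- .resolve_w_bounds(obs, config)

  c0 <- spline_center_init(obs)
  xr <- diff(range(obs$x_km))
  v <- obs$value
  p_lo <- min(max(stats::quantile(v, 0.1), cfg$p_bounds[1]), cfg$p_bounds[2])
  p_hi <- min(max(stats::quantile(v, 0.9), cfg$p_bounds[1]), cfg$p_bounds[2])
  sigma0 <- min(max(stats::sd(v) / 2, 10 * cfg$sigma_bounds[1]), cfg$sigma_bounds[2])

  best <- .with_seed(cfg$seed, {
    res <- NULL
    for (k in seq_len(cfg$chains)) {
      # chain 1 starts at the spline center; later chains jitter around it
      ck <- if (k == 1) c0 else c0 + stats::rnorm(1, 0, xr / 10)
      wk <- xr / (2 * k)
      start <- c(ck, log(min(max(wk, cfg$w_bounds[1]), cfg$w_bounds[2])),
                 p_lo, p_hi, log(sigma0))
      ch <- .mh_chain(obs, cfg, start, cfg$iterations)
      if (is.null(res) || ch$logl > res$logl) res <- ch
    }
    res
  })
  if (!is.finite(best$logl))
    stop("no finite-likelihood state found")

  # deterministic polish on (c, log w), tails and sigma concentrated out
  obj <- function(par) -.concentrate(par[1], exp(par[2]), obs, cfg)$logl
  start <- c(best$theta[1], best$theta[2])
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  sol <- .concentrate(opt$par[1], exp(opt$par[2]), obs, cfg)
  # the concentrated solution at the best visited (c, w) dominates that state
  fallback <- .concentrate(best$theta[1], exp(best$theta[2]), obs, cfg)
  if (fallback$logl > sol$logl) sol <- fallback

  model <- cline_model(c = sol$c, w = sol$w, p_min = sol$p_min,
                       p_max = sol$p_max, sigma = sol$sigma)
  attr(model, "logLik") <- sol$logl
  attr(model, "degenerate") <- abs(sol$p_max - sol$p_min) < 0.01
  attr(model, "c0") <- c0
  model
}

#' Center-position log-likelihood profile
#'
#' Holds the center fixed at each position of a regular grid and maximizes the
#' log-likelihood over width, tail values and residual scale — a short
#' Metropolis chain warm-started from the neighbouring grid point, followed by
#' the deterministic concentrated polish. The grid spans the data x-range
#' extended by `grid_expand` on each side, with the full fit's center inserted
#' so the profile maximum reproduces the fit's log-likelihood.
#'
#' @param obs Site-observation data frame.
#' @param config A [fit_config()].
#' @param fit Optional [fit_cline()] result to reuse (otherwise refitted
#'   internally).
#' @param grid Optional explicit vector of center positions (km), overriding
#'   the default grid; the fit center is inserted only if it falls inside the
#'   supplied range.
#'
#' @return A [cline_profile()] with the fitted model attached as attribute
#'   `fit`.
#' @export
profile_center <- function(obs, config = fit_config(), fit = NULL, grid = NULL) {
  .check_obs(obs)
  stopifnot(inherits(config, "fit_config"))
  cfg <- .resolve_w_bounds(obs, config)
  if (is.null(fit)) fit <- fit_cline(obs, config)
  fit_ll <- attr(fit, "logLik")

  if (is.null(grid)) {
    xr <- range(obs$x_km)
    pad <- cfg$grid_expand * diff(xr)
    grid <- seq(xr[1] - pad, xr[2] + pad, by = cfg$center_grid_step)
  }
  grid <- sort(unique(grid))
  if (fit$c >= min(grid) && fit$c <= max(grid))
    grid <- sort(unique(c(grid, fit$c)))

  ngrid <- length(grid)
  logl <- numeric(ngrid)
  w_at <- numeric(ngrid)
  # sweep outward from the grid point nearest the fitted center so each
  # point is warm-started from an already-profiled neighbour
  anchor <- which.min(abs(grid - fit$c))
  order_idx <- order(abs(seq_len(ngrid) - anchor))

  .with_seed(cfg$seed + 1L, {
    for (i in order_idx) {
      nb <- if (i == anchor) NULL else if (i < anchor) i + 1L else i - 1L
      w_warm <- if (is.null(nb)) fit$w else w_at[nb]
      starts <- c(w_warm, fit$w)
      if (cfg$profile_iterations > 0) {
        warm <- .concentrate(grid[i], w_warm, obs, cfg)
        th0 <- c(grid[i], log(w_warm), warm$p_min, warm$p_max,
                 log(max(warm$sigma, cfg$sigma_bounds[1] * 10)))
        ch <- .mh_chain(obs, cfg, th0, cfg$profile_iterations, fix_c = TRUE)
        starts <- c(starts, exp(ch$theta[2]))
      }
      sol <- .max_over_w(grid[i], obs, cfg, starts)
      logl[i] <- sol$logl
      w_at[i] <- sol$w
    }
  })

  # Adaptive refinement near the maximum: where the profile is sharp
  # relative to the grid step, piecewise-linear interpolation would
  # misplace the peak and the support-limit crossings (and bias composite
  # profiles downward). Bisect adjacent pairs within 8 log-likelihood units
  # of the maximum (covering the support limits and the region where a
  # composite peak with another profile can land) until neighbouring values
  # differ by < 0.05 or the local spacing falls below 1 m. The polish alone
  # (deterministic) evaluates the inserted points.
  refine_tol <- 0.05; min_step <- 1e-3; budget <- 800L
  for (pass in 1:50) {
    keep <- logl >= max(logl) - 8
    amax <- which.max(logl)
    new_c <- c()
    for (j in which(keep[-length(keep)] | keep[-1])) {
      gap <- grid[j + 1] - grid[j]
      if (gap <= min_step) next
      if (abs(logl[j + 1] - logl[j]) > refine_tol || j == amax || j + 1 == amax)
        new_c <- c(new_c, (grid[j] + grid[j + 1]) / 2)
    }
    if (length(new_c) == 0 || budget <= 0L) break
    new_c <- new_c[seq_len(min(length(new_c), budget))]
    budget <- budget - length(new_c)
    new_l <- numeric(length(new_c)); new_w <- numeric(length(new_c))
    for (k in seq_along(new_c)) {
      j <- findInterval(new_c[k], grid)
      sol <- .max_over_w(new_c[k], obs, cfg,
                         c(w_at[j], w_at[min(j + 1, length(grid))], fit$w))
      new_l[k] <- sol$logl; new_w[k] <- sol$w
    }
    o <- order(c(grid, new_c))
    grid <- c(grid, new_c)[o]
    logl <- c(logl, new_l)[o]
    w_at <- c(w_at, new_w)[o]
  }

  prof <- cline_profile(grid, logl)
  if (prof$lmax < fit_ll - 0.01)
    warning(sprintf("profile maximum %.3f below fit log-likelihood %.3f",
                    prof$lmax, fit_ll))
  attr(prof, "fit") <- fit
  prof
}

#' Likelihood-profile container
#'
#' Bundles a center grid with its profiled maximum log-likelihood values and
#' derived summaries: the maximum `lmax`, the maximum-likelihood center
#' `c_hat`, and 2-unit support limits.
#'
#' @param grid Ordered vector of center positions (km).
#' @param logl Profiled maximum log-likelihood at each grid position (finite).
#'
#' @return An object of class `cline_profile`: a list with elements `grid`,
#'   `logl`, `c_hat`, `lmax`, `support` (see [support_limits()]).
#' @export
cline_profile <- function(grid, logl) {
  stopifnot(is.numeric(grid), is.numeric(logl), length(grid) == length(logl),
            length(grid) >= 2, all(is.finite(grid)), all(is.finite(logl)))
  o <- order(grid)
  grid <- grid[o]; logl <- logl[o]
  if (any(duplicated(grid))) stop("duplicate grid positions")
  p <- structure(list(grid = grid, logl = logl,
                      c_hat = grid[which.max(logl)],
                      lmax = max(logl), support = NULL),
                 class = "cline_profile")
  p$support <- support_limits(p)
  p
}

#' @export
print.cline_profile <- function(x, ...) {
  s <- x$support
  cat(sprintf("Center likelihood profile: %d points on [%.1f, %.1f] km\n",
              length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  c_hat = %.2f km, Lmax = %.3f\n", x$c_hat, x$lmax))
  cat(sprintf("  2-unit support: [%.2f%s, %.2f%s] km\n",
              s$low, if (s$open_low) "*" else "",
              s$high, if (s$open_high) "*" else ""))
  if (s$open_low || s$open_high)
    cat("  (* open-ended at the grid boundary)\n")
  invisible(x)
}

#' Two-unit support limits of a likelihood profile
#'
#' The support interval is the outermost range of center positions whose
#' profiled log-likelihood stays within `drop` units (default 2, approximating
#' a 95% confidence interval) of the maximum. Crossing positions are linearly
#' interpolated between grid points; a side that never drops below the
#' threshold is reported at the grid boundary and flagged open.
#'
#' @param profile A [cline_profile()].
#' @param drop Log-likelihood drop defining the limits (default 2).
#'
#' @return A list with `low`, `high` (km) and logical flags `open_low`,
#'   `open_high`.
#' @export
support_limits <- function(profile, drop = 2) {
  stopifnot(inherits(profile, "cline_profile"), drop > 0)
  g <- profile$grid; ll <- profile$logl
  thr <- profile$lmax - drop
  inside <- ll >= thr
  i1 <- which(inside)[1]
  i2 <- rev(which(inside))[1]

  if (i1 == 1) {
    low <- g[1]; open_low <- TRUE
  } else {
    f <- (thr - ll[i1 - 1]) / (ll[i1] - ll[i1 - 1])
    low <- g[i1 - 1] + f * (g[i1] - g[i1 - 1]); open_low <- FALSE
  }
  if (i2 == length(g)) {
    high <- g[length(g)]; open_high <- TRUE
  } else {
    f <- (thr - ll[i2 + 1]) / (ll[i2] - ll[i2 + 1])
    high <- g[i2 + 1] - f * (g[i2 + 1] - g[i2]); open_high <- FALSE
  }
  list(low = low, high = high, open_low = open_low, open_high = open_high)
}
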