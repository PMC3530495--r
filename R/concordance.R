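#' Composite likelihood profile of two clines
#'
#' Sums two center-position log-likelihood profiles over the overlap of their
#' grids. Both profiles are linearly interpolated onto the union of their grid
#' points within the overlap (profiles are smooth near their maxima, so linear
#' interpolation is adequate), and the log-likelihoods are added pointwise.
#' The composite's maximum is the best log-likelihood attainable under a
#' shared center.
#'
#' @param a,b [cline_profile()] objects with overlapping grids.
#' @return A [cline_profile()] on the shared grid.
#' @export
composite_profile <- function(a, b) {
  stopifnot(inherits(a, "cline_profile"), inherits(b, "cline_profile"))
  lo <- max(min(a$grid), min(b$grid))
  hi <- min(max(a$grid), max(b$grid))
  if (lo >= hi) stop("profile grids do not overlap")
  g <- sort(unique(c(a$grid[a$grid >= lo & a$grid <= hi],
                     b$grid[b$grid >= lo & b$grid <= hi],
                     lo, hi)))
  la <- stats::approx(a$grid, a$logl, xout = g)$y
  lb <- stats::approx(b$grid, b$logl, xout = g)$y
  cline_profile(g, la + lb)
}

#' Likelihood-ratio test of cline coincidence
#'
#' Tests the null hypothesis that two clines share a common center position.
#' `LL_sum` is the sum of the two profiles' separate maxima (centers free);
#' `composite_max` is the maximum of their composite profile (centers forced
#' equal). The statistic \eqn{R = 2 (LL_\Sigma - \Sigma LL)} is referred to a
#' chi-squared distribution with 1 degree of freedom (two clines, one
#' constraint).
#'
#' @param a,b [cline_profile()] objects with overlapping grids.
#' @return An object of class `concordance_result`: a one-row data frame with
#'   `ll_sum_of_maxima`, `max_of_composite`, `r_stat`, `p_value`, `df`.
#' @export
#' @examples
#' g <- seq(-10, 10, 0.1)
#' pa <- cline_profile(g, -(g - 1)^2 / 2)
#' pb <- cline_profile(g, -(g + 1)^2 / 2)
#' lrt_coincidence(pa, pb)  # R = (1 - (-1))^2 / 2 = 2
lrt_coincidence <- function(a, b) {
  comp <- composite_profile(a, b)
  ll_sum <- a$lmax + b$lmax
  r <- 2 * (ll_sum - comp$lmax)
  if (r < -1e-9)
    stop("composite maximum exceeds the sum of maxima; inconsistent profiles")
  r <- max(r, 0)
  res <- data.frame(ll_sum_of_maxima = ll_sum,
                    max_of_composite = comp$lmax,
                    r_stat = r,
                    p_value = stats::pchisq(r, df = 1, lower.tail = FALSE),
                    df = 1L)
  class(res) <- c("concordance_result", class(res))
  res
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Cline coincidence LRT: R = %.3f (df = 1), P %s\n",
              x$r_stat, format_p(x$p_value)))
  invisible(as.data.frame(x))
}

#' Format a p-value for reporting
#'
#' Three decimals, with values below 0.001 printed as `<0.001`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Sequential Bonferroni (Holm step-down) significance flags
#'
#' Orders the p-values ascending and compares the k-th smallest to
#' `alpha / (m - k + 1)`, stopping at the first failure; every later test is
#' non-significant regardless of its p-value. Computed via Holm-adjusted
#' p-values (`stats::p.adjust`), which yield identical flags. Flags are
#' returned in input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param alpha Family-wise significance level (default 0.05).
#' @return Logical vector of significance flags, input order.
#' @export
#' @examples
#' sequential_bonferroni(c(0.01, 0.02, 0.04))  # all TRUE
#' sequential_bonferroni(c(0.03, 0.03, 0.03))  # all FALSE
sequential_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  # p-values of extreme statistics may underflow to exactly 0
  stopifnot(all(p_values >= 0), all(p_values <= 1), alpha > 0, alpha < 1)
  stats::p.adjust(p_values, method = "holm") <= alpha
}

#' Pairwise cline coincidence tests
#'
#' Runs [lrt_coincidence()] for every planned pair of profiles and applies
#' sequential Bonferroni correction *within each comparison group separately*
#' (e.g. morphology vs. morphology, habitat vs. habitat, morphology vs.
#' habitat) — corrections never pool across groups.
#'
#' @param profiles Named list of [cline_profile()] objects.
#' @param plan Data frame with columns `a`, `b` (profile names) and optional
#'   `group` (correction group label; default one group). Default plan: all
#'   pairs, one group.
#' @param alpha Significance level (default 0.05).
#'
#' @return An object of class `comparison_matrix`: list with `pairs` (data
#'   frame: a, b, group, r_stat, p_value, significant_raw,
#'   significant_holm) and `matrix` (square character matrix, R values above
#'   the diagonal, formatted p-values below).
#' @export
compare_all <- function(profiles, plan = NULL, alpha = 0.05) {
  stopifnot(is.list(profiles), length(profiles) >= 2,
            !is.null(names(profiles)), all(nzchar(names(profiles))))
  if (is.null(plan)) {
    cmb <- utils::combn(names(profiles), 2)
    plan <- data.frame(a = cmb[1, ], b = cmb[2, ], group = "all")
  }
  if (is.null(plan$group)) plan$group <- "all"
  unknown <- setdiff(unique(c(plan$a, plan$b)), names(profiles))
  if (length(unknown) > 0)
    stop("plan references unknown profiles: ", paste(unknown, collapse = ", "))

  rows <- lapply(seq_len(nrow(plan)), function(i) {
    res <- lrt_coincidence(profiles[[plan$a[i]]], profiles[[plan$b[i]]])
    data.frame(a = plan$a[i], b = plan$b[i], group = plan$group[i],
               r_stat = res$r_stat, p_value = res$p_value)
  })
  pairs <- do.call(rbind, rows)
  pairs$significant_raw <- pairs$p_value <= alpha
  pairs$significant_holm <- FALSE
  for (g in unique(pairs$group)) {
    idx <- pairs$group == g
    pairs$significant_holm[idx] <- sequential_bonferroni(pairs$p_value[idx], alpha)
  }

  labs <- names(profiles)
  m <- matrix("", length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_len(nrow(pairs))) {
    ia <- match(pairs$a[i], labs); ib <- match(pairs$b[i], labs)
    up <- c(min(ia, ib), max(ia, ib))   # R above the diagonal
    m[up[1], up[2]] <- sprintf("%.2f", pairs$r_stat[i])
    m[up[2], up[1]] <- paste0(format_p(pairs$p_value[i]),
                              if (pairs$significant_raw[i]) "*" else "",
                              if (pairs$significant_holm[i]) "†" else "")
  }
  diag(m) <- "-"
  structure(list(pairs = pairs, matrix = m, alpha = alpha),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat("Pairwise cline coincidence (R above diagonal, P below; * raw, † sequential Bonferroni)\n")
  print(x$matrix, quote = FALSE)
  invisible(x)
}
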