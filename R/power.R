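#' Power of the general-linear-model F test for a Cohen's f-squared effect
#'
#' Probability that the F statistic on `u` numerator and `v` denominator
#' degrees of freedom exceeds its central critical value at level `alpha`,
#' under the noncentral F distribution with noncentrality
#' `lambda = f2 * (u + v + 1)`.
#'
#' @param u Numerator degrees of freedom (number of tested/adjusted slopes).
#' @param v Denominator degrees of freedom.
#' @param f2 Cohen's f-squared effect size (> 0); 0.02/0.15/0.35 are the
#'   conventional small/medium/large values.
#' @param alpha Significance level.
#' @return Power in (0, 1).
#' @export
power_f2 <- function(u, v, f2, alpha) {
  stopifnot(u >= 1, v > 0, f2 > 0, alpha > 0, alpha < 1)
  lambda <- f2 * (u + v + 1)
  crit <- stats::qf(alpha, u, v, lower.tail = FALSE)
  stats::pf(crit, u, v, ncp = lambda, lower.tail = FALSE)
}

#' Required sample size for a linear-model effect
#'
#' Solves the noncentral-F power equation of [power_f2()] for the
#' continuous denominator degrees of freedom `v*` achieving the target
#' power, then converts to a sample size.
#'
#' Two conversion conventions are supported. The default, `"v_plus_1"`,
#' takes the denominator degrees of freedom as `n - 1` when converting to
#' a sample size, i.e. `n = ceiling(v* + 1)`: the degrees of freedom
#' spent on the `u` fitted slopes are not added back. It is the convention
#' under which the widely quoted sample size of 115 for a medium effect
#' (f2 = 0.15, u = 4, alpha = 0.01, power = 0.8) arises. The exact OLS
#' accounting `"u_plus_v_plus_1"` uses the residual degrees of freedom
#' `v = n - u - 1`, hence `n = ceiling(u + v* + 1)` (119 for the same
#' query). Within either convention the returned `n` is minimal: `n - 1`
#' fails the power condition.
#'
#' @param f2 Cohen's f-squared effect size (> 0).
#' @param u Numerator degrees of freedom.
#' @param alpha Significance level.
#' @param power Target power in (0, 1).
#' @param convention `"v_plus_1"` (default) or `"u_plus_v_plus_1"`, see
#'   Details.
#' @param v_max Search ceiling for the denominator df.
#' @return Integer sample size, with attributes `v` (the continuous
#'   solution) and `achieved_power`.
#' @examples
#' required_sample_size(f2 = 0.15, u = 4, alpha = 0.01, power = 0.80)  # 115
#' @export
required_sample_size <- function(f2, u, alpha, power,
                                 convention = c("v_plus_1", "u_plus_v_plus_1"),
                                 v_max = 1e6) {
  stopifnot(f2 > 0, u >= 1, alpha > 0, alpha < 1, power > 0, power < 1)
  convention <- match.arg(convention)
  g <- function(v) power_f2(u, v, f2, alpha) - power
  lo <- 1e-6
  if (g(v_max) < 0)
    stop("no solution: required denominator df exceeds ", v_max)
  v_star <- if (g(lo) >= 0) lo else
    stats::uniroot(g, c(lo, v_max), tol = 1e-9)$root
  n_cont <- if (convention == "v_plus_1") v_star + 1 else u + v_star + 1
  n <- as.integer(ceiling(n_cont - 1e-9))
  v_at_n <- if (convention == "v_plus_1") n - 1 else n - u - 1
  structure(n, v = v_star, achieved_power = power_f2(u, v_at_n, f2, alpha))
}
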