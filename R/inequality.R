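#' Weighted fractional rank (Lerman-Yitzhaki)
#'
#' Position of each record in the weighted wealth distribution: sort by
#' `x`, then give record *i* the cumulative normalized weight of all strictly
#' poorer records plus half the normalized weight of its own tied group. All
#' records tied on `x` share one rank. Ranks lie strictly inside (0, 1) and
#' their weighted mean is exactly 0.5.
#'
#' @param x Ranking variable (e.g. a wealth score); finite.
#' @param w Sampling weights, positive; default equal weights.
#' @return Numeric vector of ranks aligned with `x`.
#' @export
fractional_rank <- function(x, w = NULL) {
  n <- length(x)
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) {
    rlang::abort("x and w must have equal length", class = "ineq_config_error")
  }
  if (any(!is.finite(x))) {
    rlang::abort("ranking variable must be finite", class = "ineq_data_error")
  }
  if (any(!is.finite(w) | w <= 0)) {
    rlang::abort("weights must be finite and > 0", class = "ineq_data_error")
  }
  wn <- w / sum(w)
  # group mass per distinct value, midpoint rank per tied group
  grp <- match(x, sort(unique(x)))
  gw <- unname(vapply(split(wn, grp), sum, numeric(1)))
  cum <- cumsum(gw)
  r_group <- cum - gw / 2
  unname(r_group[grp])
}

#' Pair an outcome with weighted wealth ranks
#'
#' Bundles the ingredients every concentration-index computation needs: the
#' outcome, its weighted fractional ranks over the ranking variable,
#' normalized weights, the weighted outcome mean, and the attainable outcome
#' bounds (0/1 for binary outcomes, used by the Erreygers correction).
#'
#' @param y Outcome values (binary 0/1 or bounded real).
#' @param wealth Ranking variable (wealth score), finite.
#' @param w Sampling weights, positive; default equal.
#' @param bounds Length-2 numeric `c(lower, upper)` of attainable outcome
#'   values; defaults to `c(0, 1)` when `y` takes only values in {0, 1},
#'   otherwise `range(y)`.
#' @param cluster Optional cluster (PSU) identifiers for cluster-robust
#'   standard errors.
#' @return An object of class `ranked_outcome`.
#' @export
ranked_outcome <- function(y, wealth, w = NULL, bounds = NULL, cluster = NULL) {
  n <- length(y)
  if (length(wealth) != n) {
    rlang::abort("y and wealth must have equal length",
                 class = "ineq_config_error")
  }
  if (is.null(w)) w <- rep(1, n)
  if (anyNA(y)) {
    keep <- !is.na(y)
    y <- y[keep]; wealth <- wealth[keep]; w <- w[keep]
    if (!is.null(cluster)) cluster <- cluster[keep]
    n <- length(y)
  }
  if (n == 0L) rlang::abort("no non-missing outcomes", class = "ineq_data_error")
  y <- as.numeric(y)
  is_binary <- all(y %in% c(0, 1))
  if (is.null(bounds)) bounds <- if (is_binary) c(0, 1) else range(y)
  r <- fractional_rank(wealth, w)
  wn <- w / sum(w)
  structure(
    list(y = y, R = r, w = wn, mu = sum(wn * y), bounds = bounds,
         n = n, binary = is_binary, cluster = cluster),
    class = "ranked_outcome"
  )
}

# weighted covariance of y with the ranks, cov_w(y, R)
rank_covariance <- function(ranked) {
  rbar <- sum(ranked$w * ranked$R)
  sum(ranked$w * (ranked$y - ranked$mu) * (ranked$R - rbar))
}

#' Concentration index
#'
#' The standard (relative) concentration index
#' \deqn{CI = \frac{2}{\mu}\,\mathrm{cov}_w(y, R),}
#' twice the weighted covariance between the outcome and its weighted
#' fractional wealth rank, divided by the weighted outcome mean. Positive
#' values indicate concentration of the outcome among the wealthy
#' (pro-rich inequality); the index lies in \[-1, 1\].
#'
#' For a binary outcome with mean 1 the covariance is zero; the index is
#' returned as 0 with a degeneracy flag. A zero mean leaves the index
#' undefined and is an error.
#'
#' @param ranked A [ranked_outcome()].
#' @param se_method `"convenient_regression"` (heteroskedasticity-robust SE
#'   from the weighted convenient regression) or `"cluster_robust"` (same,
#'   clustered on the PSU identifiers carried by `ranked`).
#' @return A `concentration_result`: list with `index_type`, `value`, `se`,
#'   `n`, `mu`, `se_method`, `degenerate`.
#' @export
concentration_index <- function(ranked,
                                se_method = c("convenient_regression",
                                              "cluster_robust")) {
  se_method <- match.arg(se_method)
  if (ranked$mu == 0) {
    rlang::abort("concentration index undefined: outcome mean is 0",
                 class = "ineq_estimation_error")
  }
  degenerate <- ranked$binary && ranked$mu == 1
  value <- 2 * rank_covariance(ranked) / ranked$mu
  se <- index_standard_error(ranked, index_type = "CI", method = se_method)
  structure(
    list(index_type = "CI", value = value, se = se, n = ranked$n,
         mu = ranked$mu, se_method = se_method, degenerate = degenerate),
    class = "concentration_result"
  )
}

#' Erreygers concentration index
#'
#' Bounded-outcome correction of the concentration index,
#' \deqn{ECI = \frac{4\mu}{b_n - a_n}\,CI,}
#' where \eqn{(a_n, b_n)} are the attainable outcome bounds. For a binary
#' outcome this is \eqn{4\mu \cdot CI = 8\,\mathrm{cov}_w(y, R)}; unlike the
#' plain CI its attainable range does not shrink as the mean approaches 0 or
#' 1, which makes it the appropriate index for prevalence outcomes.
#'
#' @inheritParams concentration_index
#' @return A `concentration_result` with `index_type = "ECI"`.
#' @export
erreygers_index <- function(ranked,
                            se_method = c("convenient_regression",
                                          "cluster_robust")) {
  se_method <- match.arg(se_method)
  b <- ranked$bounds
  if (!(b[2] > b[1])) {
    rlang::abort("degenerate outcome bounds: upper must exceed lower",
                 class = "ineq_estimation_error")
  }
  value <- 8 * rank_covariance(ranked) / (b[2] - b[1])
  se <- index_standard_error(ranked, index_type = "ECI", method = se_method)
  structure(
    list(index_type = "ECI", value = value, se = se, n = ranked$n,
         mu = ranked$mu, se_method = se_method,
         degenerate = ranked$binary && ranked$mu %in% c(0, 1)),
    class = "concentration_result"
  )
}

#' @export
print.concentration_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (SE %.4f, %s), n = %d, mean = %.4f\n",
              x$index_type, x$value, x$se, x$se_method, x$n, x$mu))
  invisible(x)
}

#' Standard error of a concentration index
#'
#' Uses the convenient-regression representation: the weighted least-squares
#' slope of \eqn{2\sigma^2_R\, y_i/\mu} (CI scale) or
#' \eqn{8\sigma^2_R\, y_i/(b_n-a_n)} (Erreygers scale) on the fractional rank
#' equals the index, so its regression standard error estimates the index SE.
#' The variance is heteroskedasticity-robust (HC1), optionally clustered on
#' PSU identifiers.
#'
#' @param ranked A [ranked_outcome()].
#' @param index_type `"CI"` or `"ECI"`.
#' @param method `"convenient_regression"` or `"cluster_robust"` (requires
#'   cluster ids in `ranked`).
#' @return Non-negative numeric standard error.
#' @export
index_standard_error <- function(ranked, index_type = c("CI", "ECI"),
                                 method = c("convenient_regression",
                                            "cluster_robust")) {
  index_type <- match.arg(index_type)
  method <- match.arg(method)
  if (ranked$n < 2L || stats::var(ranked$y) == 0) return(0)
  rbar <- sum(ranked$w * ranked$R)
  s2r <- sum(ranked$w * (ranked$R - rbar)^2)
  lhs <- if (index_type == "CI") {
    2 * s2r * ranked$y / ranked$mu
  } else {
    8 * s2r * ranked$y / (ranked$bounds[2] - ranked$bounds[1])
  }
  fit <- stats::lm(lhs ~ ranked$R, weights = ranked$w)
  vc <- if (method == "cluster_robust") {
    if (is.null(ranked$cluster)) {
      rlang::abort("cluster_robust SE requested but no cluster ids supplied",
                   class = "ineq_config_error")
    }
    if (length(unique(ranked$cluster)) < 2L) {
      rlang::abort("cluster_robust SE requires at least 2 clusters",
                   class = "ineq_estimation_error")
    }
    sandwich::vcovCL(fit, cluster = ranked$cluster, type = "HC1")
  } else {
    sandwich::vcovHC(fit, type = "HC1")
  }
  sqrt(vc[2, 2])
}

#' Concentration curve
#'
#' Cumulative weighted outcome share against cumulative population share,
#' with records ordered by wealth (poorest first). A curve below the 45-degree
#' diagonal indicates pro-rich concentration. Endpoints (0,0) and (1,1) are
#' exact; both coordinates are non-decreasing for non-negative outcomes.
#'
#' @param ranked A [ranked_outcome()] with positive outcome mean.
#' @return Tibble with columns `pop_share` and `outcome_share`, one row per
#'   distinct rank plus the origin.
#' @export
concentration_curve <- function(ranked) {
  if (ranked$mu == 0) {
    rlang::abort("concentration curve undefined: outcome mean is 0",
                 class = "ineq_estimation_error")
  }
  ord <- order(ranked$R)
  w <- ranked$w[ord]
  yw <- (ranked$w * ranked$y)[ord]
  # merge tied-rank groups so tied records move together
  grp <- cumsum(!duplicated(ranked$R[ord]))
  pop <- unname(cumsum(vapply(split(w, grp), sum, numeric(1))))
  out <- unname(cumsum(vapply(split(yw, grp), sum, numeric(1)))) / ranked$mu
  k <- length(pop)
  pop[k] <- 1; out[k] <- 1
  tibble::tibble(pop_share = c(0, pop), outcome_share = c(0, out))
}

#' Area-based check of the concentration index
#'
#' Trapezoidal area under the record-level concentration curve; the identity
#' `CI = 1 - 2 * AUC` ties the curve to the index and is used as an internal
#' consistency check.
#'
#' @param curve Output of [concentration_curve()].
#' @return The area under the curve.
#' @export
curve_auc <- function(curve) {
  x <- curve$pop_share
  y <- curve$outcome_share
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
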