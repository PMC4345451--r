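# Profile-likelihood confidence intervals.
#
# A level-gamma interval for one parameter collects the values whose
# profile log-likelihood (nuisance parameters re-maximised) lies within
# qchisq(gamma, 1)/2 of the maximum (1.9207 units at 95%). Bounds are
# located by bracketing plus bisection; a lower bound clipped at a domain
# boundary (s = 0) is flagged rather than extrapolated.

#' Generic profile-likelihood interval of a scalar function
#'
#' Finds the two crossing points of `ll_fun` with
#' `ll_fun(mle) - qchisq(level, 1)/2` by outward bracketing from the
#' maximiser and root bisection. This is the root-finding core used by
#' [profile_ci()]; it can be applied to any (already profiled) scalar
#' log-likelihood.
#'
#' @param ll_fun Scalar function of the parameter (log-likelihood scale).
#' @param mle The maximiser of `ll_fun`.
#' @param level Confidence level (default 0.95).
#' @param lower_domain,upper_domain Domain limits of the parameter.
#' @param max_ll Value of `ll_fun(mle)` (computed if missing).
#' @param step Initial bracketing step (default `max(|mle|, 1)/4`).
#' @param max_expand Bracketing iterations before a bound is declared
#'   open (default 60, doubling the step each time).
#' @return List with `lower`, `upper`, `lower_at_boundary`,
#'   `upper_at_boundary` (domain clip flags), `lower_open`, `upper_open`
#'   (threshold never crossed inside the search range), `level`.
#' @export
profile_interval <- function(ll_fun, mle, level = 0.95,
                             lower_domain = -Inf, upper_domain = Inf,
                             max_ll = NULL, step = NULL, max_expand = 60L) {
  if (is.null(max_ll)) max_ll <- ll_fun(mle)
  thr <- qchisq(level, 1) / 2
  target <- max_ll - thr
  f <- function(x) ll_fun(x) - target    # positive inside the interval
  if (is.null(step)) step <- max(abs(mle), 1) / 4

  find_bound <- function(dir) {          # dir = -1 lower, +1 upper
    dom <- if (dir < 0) lower_domain else upper_domain
    s <- step
    x_in <- mle
    for (it in seq_len(max_expand)) {
      x_try <- mle + dir * s
      clipped <- FALSE
      if (dir < 0 && x_try < dom) { x_try <- dom; clipped <- TRUE }
      if (dir > 0 && x_try > dom) { x_try <- dom; clipped <- TRUE }
      fx <- f(x_try)
      if (is.finite(fx) && fx < 0) {
        root <- uniroot(f, lower = min(x_in, x_try), upper = max(x_in, x_try),
                        tol = max(1e-8, 1e-6 * max(abs(mle), 1)))$root
        return(list(bound = root, at_boundary = FALSE, open = FALSE))
      }
      if (clipped)                        # still inside the interval at the domain edge
        return(list(bound = dom, at_boundary = TRUE, open = FALSE))
      x_in <- x_try
      s <- s * 2
    }
    list(bound = mle + dir * s / 2, at_boundary = FALSE, open = TRUE)
  }
  lo <- find_bound(-1)
  hi <- find_bound(1)
  list(lower = lo$bound, upper = hi$bound,
       lower_at_boundary = lo$at_boundary, upper_at_boundary = hi$at_boundary,
       lower_open = lo$open, upper_open = hi$open, level = level)
}

#' Profile-likelihood confidence interval for a fitted model parameter
#'
#' Profiles one parameter of a converged [fit_model()] fit: at each
#' candidate value the remaining parameters are re-optimised (started
#' from the MLE), and the interval is the set of values within
#' `qchisq(level, 1)/2` log-likelihood units of the maximum. The
#' difference of two social rates (e.g. `s_inter - s_intra`) can be
#' profiled by passing `param = c("s_a", "s_b")`, which reparameterises
#' the model as `s_a = s_b + d` and profiles `d`.
#'
#' @param fit A converged `nbda_fit`.
#' @param param Parameter name, or a character(2) vector `c(a, b)` to
#'   profile the difference `a - b`.
#' @param level Confidence level (default 0.95).
#' @param max_expand Passed to [profile_interval()].
#' @return As [profile_interval()], plus `param` and `mle`. For
#'   non-negative rate parameters a lower bound of 0 is reported with
#'   `lower_at_boundary = TRUE` when the profile at 0 is still inside the
#'   interval.
#' @export
profile_ci <- function(fit, param, level = 0.95, max_expand = 60L) {
  stopifnot(inherits(fit, "nbda_fit"))
  if (!fit$converged) stop("profile CI requires a converged fit", call. = FALSE)
  nm <- theta_names(fit$layout, fit$spec)
  cache <- new.env(parent = emptyenv())
  if (length(param) == 2) {
    if (!all(param %in% nm)) stop("unknown parameter(s): ",
                                  paste(setdiff(param, nm), collapse = ", "), call. = FALSE)
    mle <- unname(fit$estimates[param[1]] - fit$estimates[param[2]])
    pll <- function(d) {
      key <- sprintf("%.12g", d)
      if (!is.null(cache[[key]])) return(cache[[key]])
      v <- -refit_with_fixed(fit, list(s_diff = list(a = param[1], b = param[2], value = d)))$value
      cache[[key]] <- v
      v
    }
    out <- profile_interval(pll, mle, level = level, max_ll = fit$loglik,
                            max_expand = max_expand)
    out$param <- paste(param[1], "-", param[2])
    out$mle <- mle
    return(out)
  }
  if (!param %in% nm) stop("unknown parameter '", param, "'", call. = FALSE)
  mle <- unname(fit$estimates[param])
  positive <- !grepl("^beta_", param)
  lower_domain <- if (positive) 0 else -Inf
  pll <- function(v) {
    key <- sprintf("%.12g", v)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fx <- list(v); names(fx) <- param
    val <- -refit_with_fixed(fit, fx)$value
    cache[[key]] <- val
    val
  }
  step <- if (abs(mle) > 1e-8) abs(mle) / 4 else max(fit$estimates["lambda0"], 0.25)
  out <- profile_interval(pll, mle, level = level, lower_domain = lower_domain,
                          max_ll = fit$loglik, step = step, max_expand = max_expand)
  out$param <- param
  out$mle <- mle
  out
}
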