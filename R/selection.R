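#' Corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`. The sample size `n` is
#' the total number of acquisition events across diffusions -- the
#' information units of the arrival-time likelihood.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size (total discovery events); must satisfy
#'   `n - k - 1 > 0`.
#' @return Scalar AICc.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0)
    stop("AICc undefined: need n - k - 1 > 0 (n = ", n, ", k = ", k, ")", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' Normalised relative likelihoods `w_m = exp(-Delta_m/2) / sum(...)`
#' with `Delta_m = AICc_m - min(AICc)`; the shift by the minimum keeps
#' the exponentials in range. Non-finite AICc values are excluded with a
#' warning and receive weight `NA`.
#'
#' @param aiccs Numeric vector of AICc values.
#' @return Numeric vector of weights summing to 1 over the finite entries.
#' @export
akaike_weights <- function(aiccs) {
  if (length(aiccs) < 1) stop("at least one model is required", call. = FALSE)
  ok <- is.finite(aiccs)
  if (!any(ok)) stop("no model with finite AICc", call. = FALSE)
  if (any(!ok)) warning(sum(!ok), " model(s) with non-finite AICc excluded from weights", call. = FALSE)
  w <- rep(NA_real_, length(aiccs))
  d <- aiccs[ok] - min(aiccs[ok])
  e <- exp(-d / 2)
  w[ok] <- e / sum(e)
  w
}

#' Model-averaged parameter estimate
#'
#' Averages a parameter over a fitted model set using Akaike weights.
#' Two conventions are reported: the conditional average renormalises the
#' weights over the models actually containing the parameter; the full
#' average treats the parameter as 0 in models that lack it (shrinking
#' poorly supported effects toward zero).
#'
#' @param set A `nbda_model_set_result` from [fit_model_set()].
#' @param param Parameter name (as in the fits' `estimates`).
#' @return List with `conditional`, `full`, and `weight_with_param` (the
#'   summed weight of models containing the parameter).
#' @export
model_average <- function(set, param) {
  stopifnot(inherits(set, "nbda_model_set_result"))
  w <- set$weights
  th <- vapply(set$fits, function(f) {
    if (param %in% names(f$estimates)) unname(f$estimates[param]) else NA_real_
  }, numeric(1))
  has <- !is.na(th) & !is.na(w)
  if (!any(!is.na(th))) stop("parameter '", param, "' appears in no model", call. = FALSE)
  wh <- sum(w[has])
  list(conditional = if (wh > 0) sum(w[has] * th[has]) / wh else NA_real_,
       full = sum(w[has] * th[has]),
       weight_with_param = wh)
}

#' Fit and compare a candidate model set
#'
#' Fits every spec, assembles the AICc table (ascending), computes Akaike
#' weights, sums them per transmission hypothesis, and reports
#' model-averaged estimates for every parameter appearing anywhere in the
#' set. Non-converged fits are excluded from the weights with a warning.
#'
#' @param diffusions List of [diffusion_data()].
#' @param stacks A [network_stack()] or named list by site.
#' @param cov Covariate table.
#' @param specs List of [model_spec()] (at least 2), e.g. from
#'   [nbda_model_set()].
#' @param seed Integer; per-model fitting seeds are derived from it.
#' @param n_starts Optimisation starts per model.
#' @return Object of class `nbda_model_set_result`: `fits`, `table`
#'   (label, hypothesis, k, loglik, aicc, delta, weight), `weights`,
#'   `hypothesis_support` (summed weights), `averages` (per-parameter
#'   conditional/full averages).
#' @export
fit_model_set <- function(diffusions, stacks, cov = NULL, specs, seed = 1L,
                          n_starts = mnbda_defaults()$n_starts) {
  if (length(specs) < 2) stop("a model set needs at least two candidate specs", call. = FALSE)
  fits <- vector("list", length(specs))
  for (m in seq_along(specs)) {
    fits[[m]] <- fit_model(diffusions, stacks, cov, specs[[m]],
                           seed = as.integer(seed) + 1000L * (m - 1L), n_starts = n_starts)
  }
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(conv)) stop("no candidate model converged", call. = FALSE)
  if (any(!conv))
    warning(sum(!conv), " non-converged model(s) excluded from Akaike weights: ",
            paste(vapply(fits[!conv], function(f) f$spec$label, character(1)), collapse = "; "),
            call. = FALSE)
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  aiccs[!conv] <- NA_real_
  w <- akaike_weights(aiccs)
  w[is.na(w)] <- 0

  layer_names <- if (inherits(stacks, "network_stack")) stacks$layer_names else stacks[[1]]$layer_names
  hyp <- vapply(seq_along(specs), function(m) hypothesis_class(specs[[m]], layer_names), character(1))
  support <- tapply(w, hyp, sum)
  tab <- data.frame(
    model = vapply(specs, `[[`, character(1), "label"),
    hypothesis = hyp,
    k = vapply(fits, `[[`, numeric(1), "n_params"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    weight = w,
    converged = conv,
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aicc), ]
  tab$delta <- tab$aicc - min(tab$aicc, na.rm = TRUE)
  rownames(tab) <- NULL

  params <- unique(unlist(lapply(fits, function(f) names(f$estimates))))
  res <- structure(list(fits = fits, weights = w, table = tab,
                        hypothesis_support = support, n_events = fits[[1]]$n_events),
                   class = "nbda_model_set_result")
  res$averages <- lapply(setNames(params, params), function(p) model_average(res, p))
  res
}

#' @export
print.nbda_model_set_result <- function(x, digits = 4, ...) {
  cat("<nbda_model_set_result>", length(x$fits), "models,", x$n_events, "events\n")
  tab <- x$table
  tab$loglik <- round(tab$loglik, 2); tab$aicc <- round(tab$aicc, 2)
  tab$delta <- round(tab$delta, 2); tab$weight <- round(tab$weight, digits)
  print(utils::head(tab[, c("model", "hypothesis", "k", "aicc", "delta", "weight")], 10))
  cat("hypothesis support (summed Akaike weights):\n")
  print(round(sort(unclass(x$hypothesis_support), decreasing = TRUE), digits))
  invisible(x)
}
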