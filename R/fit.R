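# Maximum-likelihood fitting of one candidate model.
#
# Positive parameters (lambda0, kappa, the free s_k) are optimised on the
# log scale so an unconstrained quasi-Newton method respects the domain;
# covariate effects beta are unconstrained. Box bounds of +/-30 on the
# transformed scale keep the search numerically sane (exp(30) ~ 1e13)
# while leaving the boundary s -> 0 reachable to optimizer tolerance.

theta_names <- function(layout, spec) {
  c("lambda0",
    if (spec$baseline == "weibull") "kappa",
    layout$s_names,
    if (!is.null(layout$beta_names)) layout$beta_names)
}

unpack_theta <- function(theta, layout, spec, n_beta) {
  i <- 1L
  lambda0 <- exp(theta[i]); i <- i + 1L
  kappa <- 1
  if (spec$baseline == "weibull") { kappa <- exp(theta[i]); i <- i + 1L }
  ns <- length(layout$s_names)
  s_free <- if (ns > 0) exp(theta[seq.int(i, length.out = ns)]) else numeric(0)
  i <- i + ns
  beta <- if (n_beta > 0) theta[seq.int(i, length.out = n_beta)] else numeric(0)
  list(lambda0 = lambda0, kappa = kappa, s_free = s_free, beta = beta)
}

#' Fit one diffusion model by maximum likelihood
#'
#' Maximises the total continuous time-of-acquisition log-likelihood over
#' the parameters the spec leaves free, using seeded multi-start
#' L-BFGS-B on log-transformed positive parameters. The best start is
#' retained; convergence requires a clean optimizer status plus a small
#' numerical gradient at the optimum (boundary coordinates exempt).
#'
#' @param diffusions List of [diffusion_data()] (or a single one).
#' @param stacks A [network_stack()] or named list of stacks by site.
#' @param cov Covariate table with an `id` column (may be `NULL` when the
#'   spec has no ILVs).
#' @param spec A [model_spec()].
#' @param seed Integer seed controlling the multi-start draws.
#' @param n_starts Number of optimisation starts (default 5).
#' @param control Extra `optim` control entries.
#' @return Object of class `nbda_fit`: `spec`, `estimates` (named, natural
#'   scale), `loglik`, `n_params`, `n_events` (total discoveries, the AICc
#'   sample size), `aicc`, `converged`, `diagnostics` (per-start table),
#'   plus internal context/layout needed by downstream operations.
#' @export
fit_model <- function(diffusions, stacks, cov = NULL, spec, seed = 1L,
                      n_starts = mnbda_defaults()$n_starts, control = list()) {
  ctxs <- nbda_contexts(diffusions, stacks, cov, spec)
  layout <- ctxs[[1]]$layout
  n_beta <- if (is.null(ctxs[[1]]$V)) 0L else ncol(ctxs[[1]]$V)
  beta_names <- if (n_beta > 0) paste0("beta_", colnames(ctxs[[1]]$V)) else character()
  layout$beta_names <- beta_names
  n_events <- sum(vapply(ctxs, `[[`, numeric(1), "n_events"))
  if (n_events < 1) stop("at least one acquisition event is required to fit", call. = FALSE)

  negll <- function(theta) {
    p <- unpack_theta(theta, layout, spec, n_beta)
    s_eff <- expand_s(layout, p$s_free)
    ll <- sum(vapply(ctxs, ll_context, numeric(1), lambda0 = p$lambda0,
                     kappa = p$kappa, s_eff = s_eff, beta = p$beta))
    if (!is.finite(ll)) 1e10 else -ll
  }

  # data-driven centre: events per unit total exposure
  exposure <- sum(vapply(ctxs, function(cx) sum(cx$R - cx$L), numeric(1)))
  l0_heur <- log(max(n_events / max(exposure, 1e-12), 1e-12))
  np <- 1L + (spec$baseline == "weibull") + length(layout$s_names) + n_beta

  starts <- vector("list", n_starts)
  set.seed(as.integer(seed))
  for (r in seq_len(n_starts)) {
    th <- c(l0_heur + if (r == 1) 0 else rnorm(1, 0, 1.5),
            if (spec$baseline == "weibull") { if (r == 1) 0 else rnorm(1, 0, 0.4) },
            if (length(layout$s_names) > 0) {
              if (r == 1) rep(0, length(layout$s_names)) else runif(length(layout$s_names), -2, 4)
            },
            if (n_beta > 0) { if (r == 1) rep(0, n_beta) else rnorm(n_beta, 0, 0.5) })
    starts[[r]] <- th
  }

  bounds <- 30
  runs <- lapply(starts, function(th) {
    tryCatch(
      optim(th, negll, method = "L-BFGS-B", lower = -bounds, upper = bounds,
            control = modifyList(list(maxit = 500L, factr = 1e8), control)),
      error = function(e) list(value = Inf, par = th, convergence = 99L, message = conditionMessage(e)))
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]

  grad_ok <- TRUE
  if (is.finite(best$value)) {
    h <- 1e-5
    at_bound <- abs(abs(best$par) - bounds) < 1e-6
    g <- vapply(seq_along(best$par), function(j) {
      if (at_bound[j]) return(0)
      e <- rep(0, length(best$par)); e[j] <- h
      (negll(best$par + e) - negll(best$par - e)) / (2 * h)
    }, numeric(1))
    grad_ok <- max(abs(g)) < 0.05 * max(1, abs(best$value))
  }
  converged <- is.finite(best$value) && best$convergence == 0L && grad_ok

  p <- unpack_theta(best$par, layout, spec, n_beta)
  estimates <- c(lambda0 = p$lambda0,
                 if (spec$baseline == "weibull") c(kappa = p$kappa),
                 setNames(p$s_free, layout$s_names),
                 setNames(p$beta, beta_names))
  aicc_val <- tryCatch(aicc(-best$value, np, n_events), error = function(e) {
    warning("AICc undefined: ", conditionMessage(e), call. = FALSE)
    NA_real_
  })
  structure(list(
    spec = spec, estimates = estimates, loglik = -best$value, aicc = aicc_val,
    n_params = np, n_events = n_events, converged = converged,
    diagnostics = data.frame(start = seq_len(n_starts), negll = vals,
                             status = vapply(runs, `[[`, numeric(1), "convergence")),
    theta = best$par, layout = layout, n_beta = n_beta,
    contexts = ctxs
  ), class = "nbda_fit")
}

#' @export
print.nbda_fit <- function(x, digits = 4, ...) {
  cat("<nbda_fit>", x$spec$label, "\n")
  cat(sprintf("  logLik %.4f | AICc %s | k = %d | events = %d | converged: %s\n",
              x$loglik, ifelse(is.na(x$aicc), "NA", sprintf("%.4f", x$aicc)),
              x$n_params, x$n_events, x$converged))
  print(signif(x$estimates, digits))
  invisible(x)
}

# Re-evaluate a fit's negative log-likelihood with some natural-scale
# parameters pinned; used by the profiler. fixed: named list on the
# natural scale; may also carry `s_diff = list(a, b, value)` pinning
# s_a - s_b = value with s_b free.
refit_with_fixed <- function(fit, fixed, start_theta = fit$theta) {
  spec <- fit$spec; layout <- fit$layout; ctxs <- fit$contexts; n_beta <- fit$n_beta
  nm <- theta_names(layout, spec)
  fix_plain <- fixed[setdiff(names(fixed), "s_diff")]
  fixed_idx <- match(names(fix_plain), nm)
  if (anyNA(fixed_idx)) stop("unknown parameter(s): ",
                             paste(names(fix_plain)[is.na(fixed_idx)], collapse = ", "), call. = FALSE)
  sdiff <- fixed$s_diff
  diff_idx_a <- diff_idx_b <- NA_integer_
  if (!is.null(sdiff)) {
    diff_idx_a <- match(sdiff$a, nm); diff_idx_b <- match(sdiff$b, nm)
    if (is.na(diff_idx_a) || is.na(diff_idx_b))
      stop("unknown s parameter in difference profile", call. = FALSE)
  }
  drop_idx <- c(fixed_idx, diff_idx_a)
  drop_idx <- drop_idx[!is.na(drop_idx)]
  free_idx <- setdiff(seq_along(nm), drop_idx)

  assemble <- function(eta) {
    th <- numeric(length(nm))
    th[free_idx] <- eta
    if (length(fixed_idx) > 0) {
      # positive parameters live on the log scale in theta
      th[fixed_idx] <- vapply(seq_along(fixed_idx), function(j) {
        v <- fix_plain[[j]]
        if (grepl("^beta_", names(fix_plain)[j])) v else log(max(v, 1e-300))
      }, numeric(1))
    }
    if (!is.null(sdiff)) {
      s_b <- exp(th[diff_idx_b])
      s_a <- s_b + sdiff$value
      th[diff_idx_a] <- log(max(s_a, 1e-300))
      if (s_a < 0) return(NULL)
    }
    th
  }
  negll_full <- function(theta) {
    p <- unpack_theta(theta, layout, spec, n_beta)
    s_eff <- expand_s(layout, p$s_free)
    ll <- sum(vapply(ctxs, ll_context, numeric(1), lambda0 = p$lambda0,
                     kappa = p$kappa, s_eff = s_eff, beta = p$beta))
    if (!is.finite(ll)) 1e10 else -ll
  }
  negll_eta <- function(eta) {
    th <- assemble(eta)
    if (is.null(th)) return(1e10)
    # keep s_a >= 0 feasible when profiling a negative difference
    if (!is.null(sdiff) && exp(th[diff_idx_b]) + sdiff$value < 0) return(1e10)
    negll_full(th)
  }
  eta0 <- start_theta[free_idx]
  if (!is.null(sdiff) && sdiff$value < 0) {
    # ensure the start satisfies s_b >= -value
    eta_b <- match(diff_idx_b, free_idx)
    eta0[eta_b] <- max(eta0[eta_b], log(-sdiff$value * 1.05 + 1e-12))
  }
  if (length(eta0) == 0) {
    th <- assemble(numeric(0))
    return(list(value = negll_full(th), par = numeric(0)))
  }
  optim(eta0, negll_eta, method = "L-BFGS-B", lower = -30, upper = 30,
        control = list(maxit = 400L, factr = 1e8))
}
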