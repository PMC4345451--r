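# Continuous time-of-acquisition diffusion likelihood.
#
# Rate of acquisition for a naive individual i at time t:
#   social term  S_i(t) = sum_k s_k * sum_j a[i,j,k] * z_j(t) * T[i,j]
#   covariates   A_i    = exp(sum_v beta_v * V[v,i])
#   additive       rate = lambda0(t) * (S_i(t) + A_i)
#   multiplicative rate = lambda0(t) * A_i * (S_i(t) + 1)
# with baseline lambda0(t) = lambda0 (constant) or lambda0*kappa*t^(kappa-1)
# (Weibull). Informed individuals have rate 0. Between arrivals the state
# z is constant, so the survival integral is available in closed form per
# segment: integral lambda0(t) dt over [t1, t2] = lambda0 * (t2^k - t1^k)
# with k = 1 for the constant baseline. Internally the constant baseline
# is the kappa = 1 case of the Weibull form.

#' Build the individual-level covariate design matrix
#'
#' Expands the requested covariate columns into a numeric design matrix
#' `V` for the exponential link `A_i = exp(V beta)`: character/factor
#' columns become treatment-coded indicators against their reference
#' level (first factor level, or alphabetically first), numeric columns
#' are optionally centred and scaled across all individuals.
#'
#' @param cov Data frame with an `id` column plus covariate columns.
#' @param ilv_names Columns to include.
#' @param standardize Centre/scale numeric columns (default `TRUE`).
#' @param ids Optional node ordering for the rows of the result.
#' @return Numeric matrix (individuals x effects) with id rownames, or
#'   `NULL` when `ilv_names` is empty.
#' @export
ilv_design <- function(cov, ilv_names, standardize = TRUE, ids = NULL) {
  if (length(ilv_names) == 0) return(NULL)
  if (is.null(cov) || !"id" %in% names(cov))
    stop("a covariate table with an `id` column is required for ILVs", call. = FALSE)
  missing <- setdiff(ilv_names, names(cov))
  if (length(missing) > 0)
    stop("covariate column(s) not found: ", paste(missing, collapse = ", "), call. = FALSE)
  df <- cov[, ilv_names, drop = FALSE]
  for (nm in ilv_names) {
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    if (is.numeric(df[[nm]]) && standardize) {
      s <- sd(df[[nm]])
      df[[nm]] <- (df[[nm]] - mean(df[[nm]])) / (if (is.na(s) || s == 0) 1 else s)
    }
  }
  V <- model.matrix(~ ., data = df)[, -1, drop = FALSE]
  rownames(V) <- as.character(cov$id)
  if (!is.null(ids)) {
    missing_id <- setdiff(ids, rownames(V))
    if (length(missing_id) > 0)
      stop("covariate table lacks individual(s): ", paste(missing_id, collapse = ", "), call. = FALSE)
    V <- V[ids, , drop = FALSE]
  }
  V
}

# Effective layers after applying the spec's constraint, plus the mapping
# from free s parameters to layers. Returns list(mats, layer_names,
# s_names, s_map) where s_map[k] indexes into s_names (0 = fixed at 0).
param_layout <- function(spec, stack) {
  ln <- stack$layer_names
  mats <- lapply(stack$layers, `[[`, "weights")
  switch(spec$constraint,
    free = list(mats = mats, layer_names = ln,
                s_names = paste0("s_", ln), s_map = seq_along(ln)),
    shared = list(mats = mats, layer_names = ln,
                  s_names = "s", s_map = rep(1L, length(ln))),
    zero_set = {
      bad <- setdiff(spec$zero_layers, ln)
      if (length(bad) > 0) stop("unknown layer(s) in zero_layers: ", paste(bad, collapse = ", "), call. = FALSE)
      keep <- !(ln %in% spec$zero_layers)
      list(mats = mats, layer_names = ln,
           s_names = paste0("s_", ln[keep]),
           s_map = ifelse(keep, cumsum(keep), 0L))
    },
    homogeneous = {
      n <- length(stack$node_ids)
      ones <- matrix(1, n, n, dimnames = list(stack$node_ids, stack$node_ids))
      diag(ones) <- 0
      list(mats = list(ones), layer_names = "homogeneous",
           s_names = "s_homogeneous", s_map = 1L)
    },
    asocial = list(mats = mats, layer_names = ln,
                   s_names = character(), s_map = rep(0L, length(ln))))
}

# Expand the free s vector (named by layout$s_names) into one coefficient
# per effective layer.
expand_s <- function(layout, s_free) {
  vapply(layout$s_map, function(m) if (m == 0L) 0 else s_free[m], numeric(1))
}

# Precompute everything about one diffusion that does not depend on the
# parameters: per-segment informed-neighbour connection sums, event
# connection sums (informers strictly before the event), and per-segment
# exposure bounds for the survival integral.
build_diffusion_context <- function(diff, stack, cov, spec, V = NULL) {
  ids <- stack$node_ids
  n <- length(ids)
  extra <- setdiff(c(names(diff$arrivals), diff$seeded), ids)
  if (length(extra) > 0)
    stop("arrival recorded for individual(s) not in the network: ",
         paste(extra, collapse = ", "), call. = FALSE)
  arr <- setNames(rep(Inf, n), ids)
  arr[names(diff$arrivals)] <- diff$arrivals
  # seeded demonstrators are informed from t = 0: they transmit in every
  # segment but are neither an event nor at risk
  if (length(diff$seeded) > 0) arr[diff$seeded] <- 0
  TM <- tie_matrix(diff, node_ids = ids, use_ties = spec$use_ties)
  layout <- param_layout(spec, stack)
  Wk <- lapply(layout$mats, function(A) A * TM)
  M <- length(Wk)

  arrived <- which(is.finite(arr) & arr > 0)
  ev_idx <- arrived[order(arr[arrived])]
  ev_t <- unname(arr[ev_idx])
  breaks <- sort(unique(ev_t))
  nseg <- length(breaks) + 1L
  lo <- c(0, breaks)
  hi <- c(breaks, diff$t_end)

  conn <- vector("list", M)
  conn_ev <- matrix(0, length(ev_idx), M)
  for (k in seq_len(M)) {
    Cm <- matrix(0, n, nseg)
    for (m in seq_len(nseg)) {
      informed <- which(arr <= lo[m] & is.finite(arr))
      if (length(informed) > 0)
        Cm[, m] <- rowSums(Wk[[k]][, informed, drop = FALSE])
    }
    conn[[k]] <- Cm
    for (e in seq_along(ev_idx)) {
      informers <- which(arr < ev_t[e])
      conn_ev[e, k] <- if (length(informers) > 0)
        sum(Wk[[k]][ev_idx[e], informers]) else 0
    }
  }

  tau <- pmin(arr, diff$t_end)          # end of each individual's exposure
  L <- matrix(lo, n, nseg, byrow = TRUE)
  R <- pmin(matrix(hi, n, nseg, byrow = TRUE), tau)
  R <- pmax(L, R)                        # zero-length once past censoring/arrival

  if (length(spec$ilv_names) > 0 && is.null(V))
    V <- ilv_design(cov, spec$ilv_names, spec$standardize_ilvs, ids = ids)
  list(n = n, ids = ids, nseg = nseg, M = M, layout = layout,
       conn = conn, conn_ev = conn_ev, ev_idx = ev_idx, ev_t = ev_t,
       L = L, R = R, n_events = length(ev_idx),
       tau = tau, t_end = diff$t_end,
       V = if (length(spec$ilv_names) > 0) V[ids, , drop = FALSE] else NULL,
       ilv_mode = spec$ilv_mode, trial_id = diff$trial_id, site = diff$site)
}

# Log-likelihood of one precomputed diffusion context.
ll_context <- function(ctx, lambda0, kappa, s_eff, beta) {
  A <- if (is.null(ctx$V)) rep(1, ctx$n) else as.vector(exp(ctx$V %*% beta))
  S <- matrix(0, ctx$n, ctx$nseg)
  for (k in seq_len(ctx$M)) if (s_eff[k] != 0) S <- S + s_eff[k] * ctx$conn[[k]]
  Cmat <- switch(ctx$ilv_mode,
                 additive = S + A,
                 multiplicative = A * (S + 1),
                 none = S + 1)
  if (kappa == 1) { G1 <- ctx$L; G2 <- ctx$R } else { G1 <- ctx$L^kappa; G2 <- ctx$R^kappa }
  cumhaz <- lambda0 * sum(Cmat * (G2 - G1))
  ev <- 0
  if (ctx$n_events > 0) {
    Sev <- as.vector(ctx$conn_ev %*% s_eff)
    Aev <- A[ctx$ev_idx]
    Cev <- switch(ctx$ilv_mode,
                  additive = Sev + Aev,
                  multiplicative = Aev * (Sev + 1),
                  none = Sev + 1)
    base <- if (kappa == 1) rep(log(lambda0), ctx$n_events)
            else log(lambda0 * kappa) + (kappa - 1) * log(ctx$ev_t)
    ev <- sum(base + log(Cev))
  }
  ev - cumhaz
}

check_params <- function(params, layout, baseline) {
  if (is.null(params$lambda0) || params$lambda0 <= 0)
    stop("lambda0 must be strictly positive", call. = FALSE)
  kappa <- if (baseline == "weibull") params$kappa else 1
  if (is.null(kappa) || kappa <= 0) stop("kappa must be strictly positive", call. = FALSE)
  s_free <- params$s
  if (length(layout$s_names) > 0) {
    if (is.null(s_free)) stop("social rate(s) `s` missing from params", call. = FALSE)
    if (!is.null(names(s_free)) && all(layout$s_names %in% names(s_free)))
      s_free <- s_free[layout$s_names]
    if (length(s_free) != length(layout$s_names))
      stop("expected ", length(layout$s_names), " social rate(s): ",
           paste(layout$s_names, collapse = ", "), call. = FALSE)
    if (any(s_free < 0)) stop("social transmission rates must be non-negative", call. = FALSE)
  } else s_free <- numeric(0)
  list(lambda0 = params$lambda0, kappa = kappa, s_free = unname(s_free),
       beta = if (is.null(params$beta)) numeric(0) else unname(unlist(params$beta)))
}

#' Acquisition rate of one individual
#'
#' Reference (scalar) evaluation of the model's hazard: the rate at which
#' a naive individual `i` acquires the information at time `t`, given the
#' set of already-informed individuals. Informed individuals have rate 0.
#'
#' @param i Individual id.
#' @param t Time (seconds, `> 0` for the Weibull baseline).
#' @param informed Character vector of informed individual ids at `t`.
#' @param stack A [network_stack()].
#' @param cov Covariate table (needed when the spec names ILVs).
#' @param spec A [model_spec()].
#' @param params List with `lambda0`, `s` (named or positional vector of
#'   the free social rates), optional `kappa`, optional `beta`.
#' @param ties Optional tie mask matrix over the stack's node set
#'   (defaults to all ones).
#' @return Non-negative scalar rate (per second).
#' @export
acquisition_rate <- function(i, t, informed, stack, cov = NULL, spec, params, ties = NULL) {
  if (!i %in% stack$node_ids) stop("individual '", i, "' not in the network", call. = FALSE)
  layout <- param_layout(spec, stack)
  p <- check_params(params, layout, spec$baseline)
  if (i %in% informed) return(0)
  s_eff <- expand_s(layout, p$s_free)
  if (is.null(ties)) {
    ties <- matrix(1, length(stack$node_ids), length(stack$node_ids),
                   dimnames = list(stack$node_ids, stack$node_ids))
  }
  informed <- intersect(informed, stack$node_ids)
  Ssoc <- 0
  for (k in seq_along(layout$mats)) {
    if (s_eff[k] != 0 && length(informed) > 0)
      Ssoc <- Ssoc + s_eff[k] * sum(layout$mats[[k]][i, informed] * ties[i, informed])
  }
  A <- 1
  if (length(spec$ilv_names) > 0) {
    V <- ilv_design(cov, spec$ilv_names, spec$standardize_ilvs, ids = stack$node_ids)
    A <- exp(sum(V[i, ] * p$beta))
  }
  base <- if (spec$baseline == "weibull") p$lambda0 * p$kappa * t^(p$kappa - 1) else p$lambda0
  fac <- switch(spec$ilv_mode,
                additive = Ssoc + A,
                multiplicative = A * (Ssoc + 1),
                none = Ssoc + 1)
  base * fac
}

#' Log-likelihood of one diffusion
#'
#' Closed-form piecewise evaluation of the continuous time-of-acquisition
#' likelihood: the sum over discovery events of the log hazard of the
#' acquirer (with the informed state taken as individuals arriving
#' strictly earlier), minus every individual's integrated hazard up to
#' its arrival or the censoring horizon. Rates are piecewise constant in
#' the informed state, so the integral is exact segment by segment.
#'
#' @param diff A [diffusion_data()].
#' @param stack A [network_stack()] over the trial's node set.
#' @param cov Covariate table (`id` column; needed when the spec has ILVs).
#' @param spec A [model_spec()].
#' @param params Parameter list as in [acquisition_rate()].
#' @return Scalar log-likelihood contribution.
#' @export
diffusion_loglik <- function(diff, stack, cov = NULL, spec, params) {
  layout <- param_layout(spec, stack)
  p <- check_params(params, layout, spec$baseline)
  ctx <- build_diffusion_context(diff, stack, cov, spec)
  ll_context(ctx, p$lambda0, p$kappa, expand_s(layout, p$s_free), p$beta)
}

#' Total log-likelihood over several diffusions
#'
#' Sums [diffusion_loglik()] over independent trials. Social rates and
#' covariate effects are shared across trials; each trial uses the network
#' stack of its site.
#'
#' @param diffusions List of [diffusion_data()] objects.
#' @param stacks A single [network_stack()] used for every trial, or a
#'   named list of stacks indexed by site.
#' @param cov Covariate table.
#' @param spec A [model_spec()].
#' @param params Parameter list as in [acquisition_rate()].
#' @return Scalar total log-likelihood.
#' @export
total_loglik <- function(diffusions, stacks, cov = NULL, spec, params) {
  ctxs <- nbda_contexts(diffusions, stacks, cov, spec)
  layout <- ctxs[[1]]$layout
  p <- check_params(params, layout, spec$baseline)
  s_eff <- expand_s(layout, p$s_free)
  sum(vapply(ctxs, ll_context, numeric(1), lambda0 = p$lambda0, kappa = p$kappa,
             s_eff = s_eff, beta = p$beta))
}

# Resolve the stack for a diffusion's site and build all contexts.
nbda_contexts <- function(diffusions, stacks, cov, spec) {
  if (inherits(diffusions, "diffusion_data")) diffusions <- list(diffusions)
  if (length(diffusions) == 0) stop("no diffusions supplied", call. = FALSE)
  single <- inherits(stacks, "network_stack")
  lapply(diffusions, function(d) {
    st <- if (single) stacks else stacks[[d$site]]
    if (is.null(st))
      stop("no network stack supplied for site '", d$site, "'", call. = FALSE)
    build_diffusion_context(d, st, cov, spec)
  })
}
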