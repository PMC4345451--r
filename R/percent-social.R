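#' Social/asocial decomposition of discovery events
#'
#' For every acquisition event, splits the acquirer's total rate at its
#' arrival time into the contribution of each network layer and the
#' asocial remainder: `p_k(e) = s_k * c_k(e) * factor / rate_total(e)`,
#' where `c_k(e)` is the tie-masked connection of the acquirer to
#' individuals informed strictly before the event, and the factor follows
#' the additive/multiplicative form of the fitted model (the baseline
#' `lambda0(t)` cancels). `p_asocial = 1 - sum_k p_k`. The estimated
#' fraction of discoveries due to social transmission is the mean of
#' `sum_k p_k` over events; the first discoverer of each diffusion has no
#' informed associates, so its event is asocial by construction.
#'
#' @param fit A converged `nbda_fit` from [fit_model()].
#' @param cov Optional covariate table with `id` and `species` columns;
#'   when present the decomposition is also reported per species of the
#'   acquirer.
#' @return Object of class `percent_social`: `percent_social` (overall,
#'   in percent), `by_layer` (percent per layer), `by_species` (percent
#'   social per acquirer species, if available), `events` (per-event
#'   data frame with trial, id, time, per-layer probabilities and
#'   `p_social`), `n_events`.
#' @export
percent_social <- function(fit, cov = NULL) {
  stopifnot(inherits(fit, "nbda_fit"))
  if (!fit$converged) stop("decomposition requires a converged fit", call. = FALSE)
  layout <- fit$layout
  s_free <- fit$estimates[layout$s_names]
  s_eff <- expand_s(layout, unname(s_free))
  beta <- if (fit$n_beta > 0) unname(fit$estimates[layout$beta_names]) else numeric(0)

  rows <- list()
  for (ctx in fit$contexts) {
    if (ctx$n_events == 0) next
    A <- if (is.null(ctx$V)) rep(1, ctx$n) else as.vector(exp(ctx$V %*% beta))
    Aev <- A[ctx$ev_idx]
    soc_k <- sweep(ctx$conn_ev, 2, s_eff, "*")        # events x layers
    Sev <- rowSums(soc_k)
    denom <- switch(ctx$ilv_mode,
                    additive = Sev + Aev,
                    multiplicative = Sev + 1,
                    none = Sev + 1)
    if (any(denom <= 0)) stop("event with zero total rate: invalid fitted parameters", call. = FALSE)
    P <- soc_k / denom
    df <- data.frame(trial = ctx$trial_id, id = ctx$ids[ctx$ev_idx], time = ctx$ev_t,
                     stringsAsFactors = FALSE)
    colnames(P) <- paste0("p_", layout$layer_names)
    df <- cbind(df, as.data.frame(P))
    df$p_social <- rowSums(P)
    rows[[length(rows) + 1]] <- df
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev) || nrow(ev) == 0) stop("no acquisition events to decompose", call. = FALSE)
  stopifnot(all(ev$p_social >= -1e-12 & ev$p_social <= 1 + 1e-12))

  by_species <- NULL
  if (!is.null(cov) && all(c("id", "species") %in% names(cov))) {
    sp <- setNames(as.character(cov$species), as.character(cov$id))
    ev$species <- sp[ev$id]
    by_species <- 100 * tapply(ev$p_social, ev$species, mean)
  }
  structure(list(
    percent_social = 100 * mean(ev$p_social),
    by_layer = 100 * colMeans(ev[, paste0("p_", layout$layer_names), drop = FALSE]),
    by_species = by_species,
    events = ev,
    n_events = nrow(ev)
  ), class = "percent_social")
}

#' @export
print.percent_social <- function(x, ...) {
  cat(sprintf("<percent_social> %.1f%% of %d discoveries attributed to social transmission\n",
              x$percent_social, x$n_events))
  for (nm in names(x$by_layer))
    cat(sprintf("  %s: %.1f%%\n", sub("^p_", "", nm), x$by_layer[nm]))
  if (!is.null(x$by_species)) {
    cat("  by acquirer species (%social):\n")
    for (nm in names(x$by_species)) cat(sprintf("    %s: %.1f%%\n", nm, x$by_species[nm]))
  }
  invisible(x)
}
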