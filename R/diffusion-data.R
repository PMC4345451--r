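#' Construct diffusion (arrival-time) data for one trial
#'
#' Records the first arrival of each discovering individual at a novel
#' resource within one diffusion trial. Individuals without an arrival are
#' right-censored at the trial horizon `t_end`: they contribute only
#' survival probability to the likelihood. Time starts at 0 by convention
#' and is measured in seconds.
#'
#' @param trial_id Character trial label.
#' @param arrivals Named numeric vector: `individual id -> arrival time`
#'   in `(0, t_end]`. Individuals absent from this vector never acquired.
#' @param t_end Censoring horizon in seconds (default 259200 s = 3 days).
#' @param site Site label; used to pick the site's network stack when
#'   several stacks are supplied to a fit.
#' @param tie_window Duration in seconds within which two discoveries are
#'   treated as a tie (likely co-discovery by a travelling group) and
#'   excluded from the social term; default 600 s (10 min).
#' @param seeded Character vector of ids informed at the start of the
#'   trial (trained demonstrators): part of the initial condition, so
#'   they contribute neither a discovery event nor survival exposure,
#'   but do transmit from time 0.
#' @return Object of class `diffusion_data`.
#' @export
diffusion_data <- function(trial_id, arrivals, t_end = mnbda_defaults()$t_end_s,
                           site = "site1", tie_window = mnbda_defaults()$tie_window_s,
                           seeded = character()) {
  arrivals <- unlist(arrivals)
  if (length(arrivals) > 0 && is.null(names(arrivals)))
    stop("`arrivals` must be named by individual id", call. = FALSE)
  if (anyDuplicated(names(arrivals)))
    stop("one arrival time per individual: duplicated id in `arrivals`", call. = FALSE)
  if (!is.numeric(t_end) || t_end < 0) stop("`t_end` must be non-negative", call. = FALSE)
  if (length(arrivals) > 0) {
    if (any(arrivals <= 0)) stop("arrival times must be strictly positive", call. = FALSE)
    if (any(arrivals > t_end))
      stop("arrival after the censoring horizon t_end in trial '", trial_id, "'", call. = FALSE)
  }
  if (!is.numeric(tie_window) || tie_window < 0)
    stop("`tie_window` must be non-negative", call. = FALSE)
  seeded <- as.character(seeded)
  if (length(intersect(seeded, names(arrivals))) > 0)
    stop("seeded individuals cannot also have an arrival time", call. = FALSE)
  structure(list(trial_id = as.character(trial_id), site = as.character(site),
                 arrivals = arrivals, t_end = as.numeric(t_end),
                 tie_window = as.numeric(tie_window), seeded = seeded),
            class = "diffusion_data")
}

#' @export
print.diffusion_data <- function(x, ...) {
  cat(sprintf("<diffusion_data> trial %s (site %s): %d arrivals, horizon %g s, tie window %g s\n",
              x$trial_id, x$site, length(x$arrivals), x$t_end, x$tie_window))
  invisible(x)
}

#' Tie matrix of near-simultaneous discoveries
#'
#' Two individuals that discovered the resource within `tie_window` of
#' each other are "tied" (`T[i, j] = 0`): their near-simultaneous arrival
#' is treated as a single co-discovery by a travelling group rather than
#' social transmission, and their mutual social terms are excluded from
#' the rate. All other pairs, including pairs with a censored member, get
#' `T[i, j] = 1`. Ties are pairwise, not transitively chained.
#'
#' @param diff A [diffusion_data()] object.
#' @param node_ids Character vector of the full node set (defaults to the
#'   arriving individuals only).
#' @param use_ties If `FALSE`, returns the all-ones matrix (tie masking
#'   disabled; used to gauge how conservative the mask is).
#' @return Symmetric 0/1 matrix over `node_ids` (diagonal 1; the diagonal
#'   is never evaluated because informed individuals have rate 0).
#' @export
tie_matrix <- function(diff, node_ids = names(diff$arrivals), use_ties = TRUE) {
  if (diff$tie_window < 0) stop("negative tie window", call. = FALSE)
  n <- length(node_ids)
  TM <- matrix(1, n, n, dimnames = list(node_ids, node_ids))
  if (!use_ties || length(diff$arrivals) < 2) return(TM)
  arr <- diff$arrivals[names(diff$arrivals) %in% node_ids]
  ids <- names(arr)
  gap <- abs(outer(arr, arr, "-"))
  tied <- gap <= diff$tie_window
  diag(tied) <- FALSE
  TM[ids, ids][tied] <- 0
  TM
}
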