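#' Construct an association network
#'
#' A symmetric, weighted association network over labelled individuals.
#' Edge weights are association strengths in `[0, 1]` (for networks built
#' with [compute_sri_network()] they are simple ratio indices, interpreted
#' as the proportion of sampling periods in which the dyad was seen
#' together). The diagonal is zero; `n_obs` carries the number of gathering
#' events each individual was detected in, the raw material for the
#' residency covariate.
#'
#' @param weights Square numeric matrix with individual ids as dimnames
#'   (or supplied via `node_ids`). Must be symmetric, zero-diagonal and in
#'   `[0, 1]`.
#' @param n_obs Optional named integer vector of per-individual observation
#'   counts; defaults to `NA` for all individuals.
#' @param node_ids Character vector of ids; defaults to `rownames(weights)`.
#' @return An object of class `association_network` with fields
#'   `node_ids`, `weights`, `n_obs`.
#' @export
association_network <- function(weights, n_obs = NULL, node_ids = rownames(weights)) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights) || !is.numeric(weights))
    stop("`weights` must be a square numeric matrix", call. = FALSE)
  if (is.null(node_ids))
    stop("`weights` must carry node ids as dimnames (or pass `node_ids`)", call. = FALSE)
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(weights) || anyDuplicated(node_ids))
    stop("node ids must be unique and match the matrix dimension", call. = FALSE)
  dimnames(weights) <- list(node_ids, node_ids)
  if (nrow(weights) > 0) {
    if (max(abs(weights - t(weights))) > 1e-8)
      stop("association weights must be symmetric", call. = FALSE)
    weights <- (weights + t(weights)) / 2
    if (any(diag(weights) != 0))
      stop("self-association (diagonal) must be exactly zero", call. = FALSE)
    if (any(weights < 0) || any(weights > 1))
      stop("association weights must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(n_obs)) {
    n_obs <- setNames(rep(NA_integer_, length(node_ids)), node_ids)
  } else {
    if (is.null(names(n_obs))) names(n_obs) <- node_ids
    if (!all(node_ids %in% names(n_obs)))
      stop("`n_obs` must be named by node id and cover every node", call. = FALSE)
    n_obs <- n_obs[node_ids]
    if (any(!is.na(n_obs) & n_obs < 0)) stop("`n_obs` must be non-negative", call. = FALSE)
  }
  structure(list(node_ids = node_ids, weights = weights, n_obs = n_obs),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  n <- length(x$node_ids)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<association_network> %d individuals, %d non-zero edges\n", n, ne))
  invisible(x)
}

#' Construct an observation stream
#'
#' Visit records from automated loggers: one row per detection of an
#' individual at a location within a fixed-width sampling time block
#' (15 s blocks by default in this system). Duplicate
#' (id, location, time_block) triples are collapsed.
#'
#' @param id,location Character vectors (recycled against each other).
#' @param time_block Non-negative integer index of the sampling window.
#' @return Object of class `observation_stream`: a data.frame with columns
#'   `id`, `location`, `time_block`, deduplicated.
#' @export
observation_stream <- function(id, location, time_block) {
  df <- data.frame(id = as.character(id), location = as.character(location),
                   time_block = as.integer(time_block), stringsAsFactors = FALSE)
  if (any(is.na(df$time_block)) || any(df$time_block < 0))
    stop("`time_block` must be a non-negative integer", call. = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("observation_stream", "data.frame")
  df
}

#' Detect gathering events from an observation stream
#'
#' A gathering event is the set of individuals co-detected at one location
#' in one sampling time block -- the unit of "seen together". Two
#' individuals belong to the same event if and only if they share both the
#' location and the time block.
#'
#' @param stream An [observation_stream()].
#' @return Object of class `gathering_events`: a list of events, each a
#'   list with `location_id`, `time_block`, `members` (character vector).
#' @export
detect_gathering_events <- function(stream) {
  if (!inherits(stream, "observation_stream")) stream <- observation_stream(stream$id, stream$location, stream$time_block)
  if (nrow(stream) == 0) stop("observation stream is empty: no records to group", call. = FALSE)
  key <- paste(stream$location, stream$time_block, sep = "\r")
  parts <- split(seq_len(nrow(stream)), key)
  events <- lapply(parts, function(ix) {
    list(location_id = stream$location[ix[1]],
         time_block = stream$time_block[ix[1]],
         members = unique(stream$id[ix]))
  })
  names(events) <- NULL
  structure(events, class = "gathering_events")
}

#' @export
print.gathering_events <- function(x, ...) {
  cat(sprintf("<gathering_events> %d events, %d individuals\n", length(x),
              length(unique(unlist(lapply(x, `[[`, "members"))))))
  invisible(x)
}

#' Simple-ratio-index association network from gathering events
#'
#' Dyadic association strength as the simple ratio index
#' `SRI = x / (x + yA + yB + yAB)`, counted over sampling blocks:
#' `x` blocks in which the pair shared a gathering event, `yA` / `yB`
#' blocks in which only one of the two was observed, and `yAB` blocks in
#' which both were observed but in different simultaneous events (same
#' block, different location). A weight of 0.5 therefore means the two
#' individuals were seen together in half of the observations of either;
#' 0 means never co-observed. Dyads whose denominator is zero (one
#' individual never observed) get weight 0, never `NaN`.
#'
#' @param events A `gathering_events` object from [detect_gathering_events()].
#' @return An [association_network()] with nodes in sorted id order and
#'   `n_obs` set to the number of events containing each individual.
#' @export
compute_sri_network <- function(events) {
  if (length(events) == 0) stop("no gathering events supplied", call. = FALSE)
  ids <- sort(unique(unlist(lapply(events, `[[`, "members"))))
  n <- length(ids)
  blocks <- sort(unique(vapply(events, `[[`, integer(1), "time_block")))
  # incidence over events and over blocks
  Em <- matrix(0L, n, length(events), dimnames = list(ids, NULL))
  Pb <- matrix(0L, n, length(blocks), dimnames = list(ids, as.character(blocks)))
  for (e in seq_along(events)) {
    m <- match(events[[e]]$members, ids)
    Em[m, e] <- 1L
    Pb[m, as.character(events[[e]]$time_block)] <- 1L
  }
  X <- Em %*% t(Em)          # events shared by the pair
  D <- Pb %*% t(Pb)          # blocks in which both were observed (anywhere)
  x <- pmin(X, D)            # blocks with a shared event
  blocks_i <- diag(D)
  denom <- outer(blocks_i, blocks_i, "+") - D   # blocks with at least one observed
  W <- ifelse(denom > 0, x / denom, 0)
  diag(W) <- 0
  association_network(W, n_obs = setNames(as.integer(diag(X)), ids), node_ids = ids)
}

#' Split an association network into same- and cross-category layers
#'
#' Partitions the edges of a network by a node attribute (typically
#' species): the first layer keeps edges between individuals sharing the
#' attribute value (e.g. conspecific associations), the second keeps edges
#' between individuals of different values (heterospecific associations).
#' The two layers sum element-wise to the input network.
#'
#' @param net An [association_network()].
#' @param attribute Named vector mapping every node id to a category.
#' @param layer_names Character(2) names for the same-/cross-category
#'   layers; default `c("intra", "inter")`.
#' @return A [network_stack()] of two layers sharing the input node order
#'   and `n_obs`.
#' @export
split_network_by_attribute <- function(net, attribute, layer_names = c("intra", "inter")) {
  stopifnot(inherits(net, "association_network"), length(layer_names) == 2)
  missing <- setdiff(net$node_ids, names(attribute))
  if (length(missing) > 0)
    stop("no attribute value for node(s): ", paste(missing, collapse = ", "), call. = FALSE)
  a <- as.character(attribute[net$node_ids])
  same <- outer(a, a, "==")
  intra <- net$weights * same
  inter <- net$weights * !same
  network_stack(
    list(association_network(intra, n_obs = net$n_obs, node_ids = net$node_ids),
         association_network(inter, n_obs = net$n_obs, node_ids = net$node_ids)),
    layer_names = layer_names)
}

#' Descriptive metrics of an association network
#'
#' @param net An [association_network()].
#' @param assortativity_mode `"binary"` (default) computes Newman degree
#'   assortativity on the binary degree of the thresholded (weight > 0)
#'   graph; `"weighted"` uses node strength (weighted degree) as the
#'   endpoint value. Both conventions are exposed because field reports of
#'   "assortment by degree" rarely state which was used.
#' @return List of class `network_metrics`:
#'   `n_nodes`; `mean_strength` (mean row sum of weights);
#'   `mean_weighted_degree` (mean row sum normalised by `n - 1`, the 0-1
#'   scale convention, stated in `conventions`); `mean_binary_degree`;
#'   `density` (binary edge density); `assortativity` (value, `mode`, and
#'   `assortativity_defined` flag -- `FALSE` instead of `NaN` when degree
#'   variance is zero); `eigenvector` (dominant-eigenvector centrality,
#'   max-normalised so the most central node scores 1).
#' @export
network_metrics <- function(net, assortativity_mode = c("binary", "weighted")) {
  stopifnot(inherits(net, "association_network"))
  assortativity_mode <- match.arg(assortativity_mode)
  W <- net$weights
  n <- nrow(W)
  strength <- rowSums(W)
  bindeg <- rowSums(W > 0)
  n_edges <- sum(W[upper.tri(W)] > 0)
  density <- if (n > 1) n_edges / (n * (n - 1) / 2) else 0
  g <- igraph::graph_from_adjacency_matrix(1 * (W > 0), mode = "undirected", diag = FALSE)
  assort <- if (n_edges == 0) NaN else if (assortativity_mode == "binary") {
    igraph::assortativity_degree(g)
  } else {
    igraph::assortativity(g, values = strength)
  }
  assort_defined <- is.finite(assort)
  ev <- if (all(W == 0)) {
    setNames(rep(0, n), net$node_ids)
  } else {
    e <- eigen(W, symmetric = TRUE)
    v <- abs(e$vectors[, which.max(e$values)])
    setNames(v / max(v), net$node_ids)
  }
  structure(list(
    n_nodes = n,
    mean_strength = if (n > 0) mean(strength) else 0,
    mean_weighted_degree = if (n > 1) mean(strength) / (n - 1) else 0,
    mean_binary_degree = if (n > 0) mean(bindeg) else 0,
    density = density,
    assortativity = if (assort_defined) assort else NA_real_,
    assortativity_defined = assort_defined,
    assortativity_mode = assortativity_mode,
    eigenvector = ev,
    conventions = c(mean_weighted_degree = "mean row-sum of weights divided by (n - 1)",
                    density = "share of unordered dyads with weight > 0")
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> n = %d | density %.3f | mean weighted degree %.3f (/(n-1)) | assortativity (%s) %s\n",
              x$n_nodes, x$density, x$mean_weighted_degree, x$assortativity_mode,
              if (x$assortativity_defined) sprintf("%.3f", x$assortativity) else "undefined"))
  invisible(x)
}
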