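#' Construct a multi-layer network stack
#'
#' A stack of `M >= 1` co-indexed association networks over one ordered
#' node set -- e.g. a conspecific layer and a heterospecific layer of the
#' same underlying association network. Layer `k` supplies the connection
#' strengths `a[i, j, k]` entering the social term of the diffusion model.
#'
#' @param layers List of [association_network()] objects sharing
#'   `node_ids` in identical order.
#' @param layer_names Character vector naming the layers (defaults to
#'   `layer1`, `layer2`, ...).
#' @return Object of class `network_stack` with fields `layers`,
#'   `layer_names`, `node_ids`.
#' @export
network_stack <- function(layers, layer_names = NULL) {
  if (!is.list(layers) || length(layers) < 1)
    stop("`layers` must be a non-empty list of association networks", call. = FALSE)
  if (!all(vapply(layers, inherits, logical(1), "association_network")))
    stop("every layer must be an association_network", call. = FALSE)
  ids <- layers[[1]]$node_ids
  for (k in seq_along(layers)) {
    if (!identical(layers[[k]]$node_ids, ids))
      stop("all layers must share the same node ids in the same order", call. = FALSE)
  }
  if (is.null(layer_names)) layer_names <- paste0("layer", seq_along(layers))
  if (length(layer_names) != length(layers) || anyDuplicated(layer_names))
    stop("`layer_names` must be unique and match the number of layers", call. = FALSE)
  structure(list(layers = layers, layer_names = as.character(layer_names), node_ids = ids),
            class = "network_stack")
}

#' @export
print.network_stack <- function(x, ...) {
  cat(sprintf("<network_stack> %d layer(s) [%s] over %d individuals\n",
              length(x$layers), paste(x$layer_names, collapse = ", "),
              length(x$node_ids)))
  invisible(x)
}

#' Number of layers in a stack
#' @param stack A [network_stack()].
#' @return Integer layer count.
#' @export
n_layers <- function(stack) length(stack$layers)
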