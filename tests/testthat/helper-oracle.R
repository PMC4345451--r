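# Shared fixtures and the independent likelihood oracle.

# Random symmetric association network on given ids.
rand_net <- function(ids, max_w = 0.5) {
  n <- length(ids)
  w <- matrix(runif(n * n) * max_w, n, n)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 0
  association_network(w, node_ids = ids)
}

# Random small diffusion instance over a 2-layer stack.
rand_instance <- function(n_max = 5, t_end = 100) {
  n <- sample(2:n_max, 1)
  ids <- paste0("i", seq_len(n))
  st <- network_stack(list(rand_net(ids), rand_net(ids)), c("intra", "inter"))
  k <- sample(seq_len(n), 1)
  arrv <- sort(runif(k, 1, t_end))
  names(arrv) <- sample(ids, k)
  d <- diffusion_data("t1", arrv, t_end = t_end,
                      tie_window = sample(c(0, 5, 20), 1))
  spec <- model_spec(sample(c("constant", "weibull"), 1), "none", "free",
                     use_ties = sample(c(TRUE, FALSE), 1))
  params <- list(lambda0 = runif(1, 0.001, 0.05), s = runif(2, 0, 3),
                 kappa = runif(1, 0.5, 2))
  list(diff = d, stack = st, spec = spec, params = params)
}

# Independent oracle: adaptive quadrature of the hazard over the same
# rate function (acquisition_rate evaluated pointwise), integrating
# piecewise between arrival times, plus the event log-hazard terms with
# the informed set taken strictly before each arrival.
oracle_loglik <- function(diff, stack, cov, spec, params) {
  ids <- stack$node_ids
  arr <- stats::setNames(rep(Inf, length(ids)), ids)
  arr[names(diff$arrivals)] <- diff$arrivals
  TM <- tie_matrix(diff, node_ids = ids, use_ties = spec$use_ties)
  rate_at <- function(i, u)
    acquisition_rate(i, u, names(arr)[arr < u], stack, cov, spec, params, ties = TM)
  breaks <- sort(unique(c(0, diff$arrivals, diff$t_end)))
  ll <- 0
  for (i in ids) {
    tau <- min(arr[i], diff$t_end)
    bs <- c(breaks[breaks < tau], tau)
    for (m in seq_len(length(bs) - 1)) {
      ll <- ll - stats::integrate(function(u) vapply(u, function(x) rate_at(i, x), 0),
                                  bs[m], bs[m + 1], rel.tol = 1e-11)$value
    }
    if (is.finite(arr[i])) ll <- ll + log(rate_at(i, arr[[i]]))
  }
  unname(ll)
}

# Tiny deterministic 3-node stack used across tests.
toy_stack <- function(w_ab = 0.5, w_ac = 0, w_bc = 0) {
  ids <- c("A", "B", "C")
  w1 <- matrix(0, 3, 3, dimnames = list(ids, ids))
  w1["A", "B"] <- w1["B", "A"] <- w_ab
  w1["A", "C"] <- w1["C", "A"] <- w_ac
  w1["B", "C"] <- w1["C", "B"] <- w_bc
  network_stack(list(association_network(w1, node_ids = ids)), "intra")
}
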