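# Tie masking, acquisition rates, and the closed-form piecewise
# log-likelihood against its independent quadrature oracle.

test_that("tie matrix masks pairs discovering within the window", {
  d <- diffusion_data("t", c(A = 100, B = 400), t_end = 1000, tie_window = 600)
  TM <- tie_matrix(d, node_ids = c("A", "B", "C"))
  expect_equal(TM["A", "B"], 0)
  expect_equal(TM["B", "A"], 0)
  expect_equal(TM["A", "C"], 1)

  d2 <- diffusion_data("t", c(A = 100, B = 800), t_end = 1000, tie_window = 600)
  expect_equal(tie_matrix(d2, node_ids = c("A", "B"))["A", "B"], 1)

  # masking disabled -> all ones
  TM3 <- tie_matrix(d, node_ids = c("A", "B", "C"), use_ties = FALSE)
  expect_true(all(TM3 == 1))

  expect_error(diffusion_data("t", c(A = 1), t_end = 10, tie_window = -5), "non-negative")
})

test_that("acquisition rate follows the additive hazard with tie masking", {
  st <- toy_stack(w_ab = 0.5)
  spec <- model_spec("constant", "none", "free")
  params <- list(lambda0 = 0.1, s = 2)

  # informed individuals have rate zero
  expect_equal(acquisition_rate("B", 10, informed = "B", st, NULL, spec, params), 0)
  # no social input: the asocial rate
  expect_equal(acquisition_rate("B", 10, informed = character(), st, NULL, spec,
                                list(lambda0 = 0.3, s = 0)), 0.3)
  # one informed conspecific at a = 0.5: 0.1 * (2*0.5 + 1) = 0.2
  expect_equal(acquisition_rate("B", 10, informed = "A", st, NULL, spec, params), 0.2)
  # same informer tie-masked: back to the asocial rate
  ties <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ties["A", "B"] <- ties["B", "A"] <- 0
  expect_equal(acquisition_rate("B", 10, informed = "A", st, NULL, spec, params,
                                ties = ties), 0.1)

  expect_error(acquisition_rate("B", 10, "A", st, NULL, spec, list(lambda0 = -1, s = 2)),
               "positive")
  expect_error(acquisition_rate("B", 10, "A", st, NULL, spec, list(lambda0 = 0.1, s = -2)),
               "non-negative")
})

test_that("degenerate diffusions have closed-form likelihoods", {
  st <- toy_stack(0)
  spec <- model_spec("constant", "none", "asocial")
  # nobody at risk: zero horizon, no arrivals
  d0 <- diffusion_data("t", numeric(), t_end = 0)
  expect_equal(diffusion_loglik(d0, st, NULL, spec, list(lambda0 = 0.2)), 0)
  # isolated individual arriving at t: exponential log-density, others censored
  ids <- "X"
  st1 <- network_stack(list(association_network(matrix(0, 1, 1, dimnames = list(ids, ids)))))
  d1 <- diffusion_data("t", c(X = 7), t_end = 7)
  expect_equal(diffusion_loglik(d1, st1, NULL, spec, list(lambda0 = 0.2)),
               log(0.2) - 0.2 * 7)
})

test_that("closed-form likelihood matches the quadrature oracle on random instances", {
  set.seed(2024)
  for (r in 1:12) {
    inst <- rand_instance()
    a <- diffusion_loglik(inst$diff, inst$stack, NULL, inst$spec, inst$params)
    b <- oracle_loglik(inst$diff, inst$stack, NULL, inst$spec, inst$params)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("total log-likelihood is additive and order-invariant", {
  set.seed(5)
  inst <- rand_instance()
  inst2 <- rand_instance()
  st <- inst$stack
  # re-use one stack: rebuild second diffusion on the same node set
  ids <- st$node_ids
  arr <- sort(runif(2, 1, 90)); names(arr) <- sample(ids, 2)
  d2 <- diffusion_data("t2", arr, t_end = 100)
  spec <- model_spec("constant", "none", "free")
  params <- list(lambda0 = 0.01, s = c(1, 2))
  single <- diffusion_loglik(inst$diff, st, NULL, spec, params)
  expect_equal(total_loglik(list(inst$diff), st, NULL, spec, params), single)
  expect_equal(total_loglik(list(inst$diff, inst$diff), st, NULL, spec, params), 2 * single)
  expect_identical(total_loglik(list(inst$diff, d2), st, NULL, spec, params),
                   total_loglik(list(d2, inst$diff), st, NULL, spec, params))
})

test_that("model reductions hold to numerical identity", {
  set.seed(77)
  inst <- rand_instance(n_max = 5)
  st <- inst$stack; d <- inst$diff
  ids <- st$node_ids

  # s = 0: pure survival with rate lambda0 (constant baseline)
  spec0 <- model_spec("constant", "none", "free")
  l0 <- 0.004
  ll <- diffusion_loglik(d, st, NULL, spec0, list(lambda0 = l0, s = c(0, 0)))
  tau <- pmin(stats::setNames(rep(d$t_end, length(ids)), ids), Inf)
  tau[names(d$arrivals)] <- d$arrivals
  closed <- length(d$arrivals) * log(l0) - l0 * sum(tau)
  expect_equal(ll, closed, tolerance = 1e-12)

  # Weibull with kappa = 1 equals the constant baseline
  specw <- model_spec("weibull", "none", "free")
  expect_equal(diffusion_loglik(d, st, NULL, specw, list(lambda0 = 0.01, kappa = 1, s = c(1, 2))),
               diffusion_loglik(d, st, NULL, spec0, list(lambda0 = 0.01, s = c(1, 2))),
               tolerance = 1e-12)

  # homogeneous constraint equals an explicit all-ones layer
  ones <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids)); diag(ones) <- 0
  st_ones <- network_stack(list(association_network(ones, node_ids = ids)), "hom")
  spec_hom <- model_spec("constant", "none", "homogeneous")
  spec_one <- model_spec("constant", "none", "free")
  expect_identical(diffusion_loglik(d, st, NULL, spec_hom, list(lambda0 = 0.01, s = 1.7)),
                   diffusion_loglik(d, st_ones, NULL, spec_one, list(lambda0 = 0.01, s = 1.7)))

  # duplicated identical layers: likelihood depends on s1 + s2 only
  stdup <- network_stack(list(st$layers[[1]], st$layers[[1]]), c("a", "b"))
  for (delta in c(0.3, 0.9)) {
    expect_equal(diffusion_loglik(d, stdup, NULL, spec0, list(lambda0 = 0.01, s = c(1.2, 0.9))),
                 diffusion_loglik(d, stdup, NULL, spec0,
                                  list(lambda0 = 0.01, s = c(1.2 + delta, 0.9 - delta))),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is non-increasing in the censoring horizon", {
  set.seed(99)
  inst <- rand_instance(t_end = 50)
  arr <- inst$diff$arrivals
  lls <- vapply(c(50, 80, 120, 200), function(te) {
    d <- diffusion_data("t", arr, t_end = te, tie_window = inst$diff$tie_window)
    diffusion_loglik(d, inst$stack, NULL, inst$spec, inst$params)
  }, numeric(1))
  expect_true(all(diff(lls) <= 1e-12))
})

test_that("data validation names the offending input", {
  st <- toy_stack(0.5)
  expect_error(diffusion_data("t", c(A = 5), t_end = 3), "horizon")
  d <- diffusion_data("t", c(Z = 5), t_end = 10)
  expect_error(diffusion_loglik(d, st, NULL, model_spec("constant", "none", "free"),
                                list(lambda0 = 0.1, s = 1)), "Z")
  expect_error(total_loglik(list(diffusion_data("t", c(A = 1), site = "nowhere")),
                            list(site1 = st), NULL, model_spec("constant", "none", "free"),
                            list(lambda0 = 0.1, s = 1)), "nowhere")
})
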