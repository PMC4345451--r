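# Information-criterion arithmetic, model weights and averaging, the
# profile-interval root finder, and maximum-likelihood behaviour.

test_that("AICc matches hand arithmetic and guards its domain", {
  expect_equal(aicc(-50, 2, 10), 100 + 4 + 12 / 7)
  expect_equal(aicc(-50, 0, 10), 100)                      # penalty vanishes
  # finite-sample correction always exceeds plain AIC
  for (n in c(5, 20, 100)) expect_gt(aicc(-10, 3, n), -2 * -10 + 2 * 3)
  expect_error(aicc(-50, 9, 10), "n - k - 1")
})

test_that("Akaike weights are stable, normalised and symmetric", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w[1], 1 / (1 + exp(-1)))
  expect_equal(w[2], exp(-1) / (1 + exp(-1)))
  set.seed(3)
  for (r in 1:5) expect_equal(sum(akaike_weights(runif(6, 200, 240))), 1)
  # huge AICc values do not overflow thanks to the max shift
  expect_equal(sum(akaike_weights(c(1e6, 1e6 + 2))), 1)
  expect_warning(w2 <- akaike_weights(c(10, Inf)), "excluded")
  expect_equal(w2, c(1, NA))
})

test_that("model averaging reports conditional and zero-filled variants", {
  fits <- list(
    structure(list(estimates = c(s = 10), converged = TRUE), class = "nbda_fit"),
    structure(list(estimates = c(lambda0 = 1), converged = TRUE), class = "nbda_fit"))
  set <- structure(list(fits = fits, weights = c(0.6, 0.4)),
                   class = "nbda_model_set_result")
  av <- model_average(set, "s")
  expect_equal(av$conditional, 10)
  expect_equal(av$full, 6)
  expect_equal(av$weight_with_param, 0.6)
  # parameter present everywhere with equal value: both averages equal it
  fits2 <- list(
    structure(list(estimates = c(s = 4)), class = "nbda_fit"),
    structure(list(estimates = c(s = 4)), class = "nbda_fit"))
  set2 <- structure(list(fits = fits2, weights = c(0.25, 0.75)),
                    class = "nbda_model_set_result")
  expect_equal(model_average(set2, "s")$conditional, 4)
  expect_equal(model_average(set2, "s")$full, 4)
  # concentrated weights reduce to the best model
  set3 <- structure(list(fits = fits, weights = c(1, 0)), class = "nbda_model_set_result")
  expect_equal(model_average(set3, "s")$full, 10)
  expect_error(model_average(set, "missing_param"), "no model")
})

test_that("profile_interval solves the quadratic case and keeps the MLE inside", {
  ll <- function(theta) -(theta - 2)^2
  ci <- profile_interval(ll, mle = 2)
  half <- sqrt(qchisq(0.95, 1) / 2)
  expect_equal(ci$lower, 2 - half, tolerance = 1e-6)
  expect_equal(ci$upper, 2 + half, tolerance = 1e-6)
  expect_true(ci$lower <= 2 && 2 <= ci$upper)
  expect_false(ci$lower_open || ci$upper_open)
  # domain clipping: maximum sits on the boundary
  ci0 <- profile_interval(function(x) -x^2 / 100, mle = 0, lower_domain = 0)
  expect_equal(ci0$lower, 0)
  expect_true(ci0$lower_at_boundary)
})

test_that("fit_model recovers rates and respects the duplicated-layer ridge", {
  cond <- study_conditions()
  sim <- simulate_network_stack(cond$n, seed = 501)
  d <- simulate_diffusions(sim$stack, params = list(lambda0 = cond$lambda0, s = cond$s),
                           n_diffusions = cond$n_diffusions, t_end = cond$t_end, seed = 502)
  spec <- model_spec("constant", "none", "free", use_ties = FALSE)
  fit <- fit_model(d, sim$stack, NULL, spec, seed = 11)
  expect_true(fit$converged)
  expect_named(fit$estimates, c("lambda0", "s_intra", "s_inter"))
  # order-of-magnitude sanity at a single replicate (tight recovery is a
  # multi-replicate property, asserted elsewhere)
  expect_gt(fit$estimates["s_intra"], 5)
  expect_lt(fit$estimates["s_intra"], 80)
  expect_equal(fit$aicc, aicc(fit$loglik, 3, fit$n_events))

  # duplicated identical layers: s1 + s2 matches the single-layer fit
  single <- network_stack(list(sim$stack$layers[[1]]), "only")
  dup <- network_stack(list(sim$stack$layers[[1]], sim$stack$layers[[1]]), c("a", "b"))
  f1 <- fit_model(d, single, NULL, spec, seed = 21)
  f2 <- fit_model(d, dup, NULL, spec, seed = 21)
  expect_equal(unname(f2$estimates["s_a"] + f2$estimates["s_b"]),
               unname(f1$estimates["s_only"]), tolerance = 1e-2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("fit_model is invariant to individual relabelling and trial order", {
  sim <- simulate_network_stack(12, seed = 31)
  d <- simulate_diffusions(sim$stack, params = list(lambda0 = 2e-6, s = c(15, 8)),
                           n_diffusions = 3, seed = 32)
  spec <- model_spec("constant", "none", "shared", use_ties = FALSE)
  f_ab <- fit_model(d, sim$stack, NULL, spec, seed = 5)
  f_ba <- fit_model(rev(d), sim$stack, NULL, spec, seed = 5)
  expect_equal(f_ab$loglik, f_ba$loglik, tolerance = 1e-6)

  perm <- sample(length(sim$stack$node_ids))
  relab <- setNames(paste0("new", seq_along(perm)), sim$stack$node_ids)
  st2 <- network_stack(lapply(sim$stack$layers, function(l) {
    w <- l$weights; dimnames(w) <- list(relab[rownames(w)], relab[colnames(w)])
    association_network(w)
  }), sim$stack$layer_names)
  d2 <- lapply(d, function(x) diffusion_data(x$trial_id,
                                             setNames(x$arrivals, relab[names(x$arrivals)]),
                                             t_end = x$t_end, site = x$site,
                                             tie_window = x$tie_window))
  f_rl <- fit_model(d2, st2, NULL, spec, seed = 5)
  expect_equal(f_ab$loglik, f_rl$loglik, tolerance = 1e-6)
  expect_equal(f_ab$estimates, f_rl$estimates, tolerance = 1e-4)
})

test_that("social rates shrink on asocially simulated data", {
  shat <- vapply(1:3, function(r) {
    sim <- simulate_network_stack(15, seed = 700 + r)
    d <- simulate_diffusions(sim$stack, params = list(lambda0 = 4e-6, s = c(0, 0)),
                             n_diffusions = 30, seed = 730 + r)
    fit <- fit_model(d, sim$stack, NULL,
                     model_spec("constant", "none", "shared", use_ties = FALSE),
                     seed = r, n_starts = 3)
    unname(fit$estimates["s"])
  }, numeric(1))
  expect_lt(median(shat), 0.5)
})

test_that("profile_ci covers the MLE, flags boundaries, and profiles differences", {
  cond <- study_conditions()
  sim <- simulate_network_stack(cond$n, seed = 901)
  d <- simulate_diffusions(sim$stack, params = list(lambda0 = cond$lambda0, s = cond$s),
                           n_diffusions = cond$n_diffusions, t_end = cond$t_end, seed = 902)
  spec <- model_spec("constant", "none", "free", use_ties = FALSE)
  fit <- fit_model(d, sim$stack, NULL, spec, seed = 3)
  ci <- profile_ci(fit, "s_intra")
  expect_true(ci$lower <= ci$mle && ci$mle <= ci$upper)
  expect_gt(ci$lower, 0)

  # difference of the two social rates via reparameterisation
  cid <- profile_ci(fit, c("s_intra", "s_inter"))
  expect_equal(cid$mle, unname(fit$estimates["s_intra"] - fit$estimates["s_inter"]))
  expect_true(cid$lower <= cid$mle && cid$mle <= cid$upper)

  # boundary flag when the likelihood is maximal near s = 0
  sim0 <- simulate_network_stack(12, seed = 911)
  d0 <- simulate_diffusions(sim0$stack, params = list(lambda0 = 4e-6, s = c(0, 0)),
                            n_diffusions = 12, seed = 912)
  fit0 <- fit_model(d0, sim0$stack, NULL,
                    model_spec("constant", "none", "shared", use_ties = FALSE), seed = 4)
  ci0 <- profile_ci(fit0, "s")
  expect_equal(ci0$lower, 0)
  expect_true(ci0$lower_at_boundary)
})

test_that("fit_model_set weighs duplicated specs equally and partitions support", {
  sim <- simulate_network_stack(12, seed = 41)
  d <- simulate_diffusions(sim$stack, params = list(lambda0 = 2e-6, s = c(15, 8)),
                           n_diffusions = 3, seed = 42)
  spec <- model_spec("constant", "none", "shared", use_ties = FALSE)
  sel <- fit_model_set(d, sim$stack, NULL, list(spec, spec), seed = 6, n_starts = 3)
  expect_equal(sel$weights, c(0.5, 0.5))
  expect_equal(sum(sel$hypothesis_support), 1)
  expect_equal(unname(sel$hypothesis_support["same_rate"]), 1)
})
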