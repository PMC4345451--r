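# mnbda — multi-network network-based diffusion analysis

`mnbda` estimates how information about a novel resource spreads
through an animal community along **several social network layers at
once**. It was built for the mixed-species setting — e.g. tit flocks in
which blue, great and marsh tits forage together — where the
association network splits into a conspecific layer and a
heterospecific layer, and the scientific question is whether
individuals learn the location of new food patches from members of
other species as well as their own.

The package covers the full workflow:

1. **Networks from co-observations.** Visit logs (individual,
   location, 15-s time block) become gathering events; dyadic
   association strengths are simple ratio indices
   `SRI = x / (x + yA + yB + yAB)` — the proportion of sampling periods
   in which the pair was seen together. Networks can be split by any
   node attribute into same-/cross-category layers and summarised
   (weighted degree, edge density, degree assortativity, eigenvector
   centrality).
2. **The diffusion model.** Continuous time-of-acquisition NBDA: a
   naive individual `i` discovers at hazard

   ```
   lambda_i(t) = lambda0(t) * ( sum_k s_k sum_j a[i,j,k] z_j(t) T[i,j] + A_i )
   ```

   with one social-transmission rate `s_k` per network layer, informed
   state `z_j(t)`, a tie mask `T[i,j]` that strips social credit from
   pairs discovering within 10 minutes of each other (travelling
   groups co-discovering), covariate factor
   `A_i = exp(beta' V_i)` (additive or multiplicative), and a constant
   or Weibull baseline `lambda0(t)`. The likelihood is evaluated in
   closed form piecewise between arrivals, with right-censoring at the
   trial horizon.
3. **Inference.** Seeded multi-start maximum likelihood; AICc
   multimodel comparison over the six transmission hypotheses
   (different per-layer rates, shared rate, one layer only,
   homogeneous, asocial); Akaike weights, hypothesis support and model
   averaging; profile-likelihood CIs (including for the difference
   `s_intra - s_inter`); and a per-event decomposition of discoveries
   into per-layer social and asocial fractions.
4. **Simulation.** An exact event-driven generator for diffusions from
   the same hazard model, plus a co-observation stream generator with
   known dyadic co-membership probabilities — every estimator in the
   package can be validated against data whose truth is known.

## Worked example

Simulate a species-assorted co-observation stream, build and split the
SRI network, simulate diffusions on it, and fit the two-layer model:

```r
library(mnbda)

obs <- simulate_observation_stream(20, species = c("blue", "great"), n_groups = 4,
                                   assortment = 0.6, n_periods = 400, seed = 2)
net <- compute_sri_network(detect_gathering_events(obs$stream))
stack <- split_network_by_attribute(net, obs$species)

d <- simulate_diffusions(stack, params = list(lambda0 = 6e-7, s = c(22.2, 12.5)),
                         n_diffusions = 8, seed = 3)
fit <- fit_model(d, stack, NULL,
                 model_spec("constant", "none", "free", use_ties = FALSE), seed = 1)
fit
#> <nbda_fit> free|constant|none|noties
#>   logLik -1828.7134 | AICc 3663.5817 | k = 3 | events = 159 | converged: TRUE
#>   lambda0   s_intra   s_inter
#> 7.874e-07 1.776e+01 1.073e+01

ci <- profile_ci(fit, "s_intra")
sprintf("s_intra 95%% profile CI: [%.1f, %.1f]", ci$lower, ci$upper)
#> "s_intra 95% profile CI: [9.1, 39.9]"

percent_social(fit, cov = data.frame(id = names(obs$species),
                                     species = unname(obs$species)))
#> <percent_social> 91.7% of 159 discoveries attributed to social transmission
#>   intra: 72.2%
#>   inter: 19.5%
#>   by acquirer species (%social):
#>     blue: 94.1%
#>     great: 89.3%
```

Reading the output: the fitted transmission rates (17.8 within
species, 10.7 between, against generating values 22.2 and 12.5 — a
single replicate of ~160 events carries this much sampling noise, and
the profile interval says so) are *per unit of association*, relative
to the asocial rate `lambda0`. The decomposition attributes 91.7% of
discovery events to transmission, 72.2 points of it along conspecific
edges. Comparing hypotheses is one call:

```r
sel <- fit_model_set(d, stack, NULL,
                     nbda_model_set(ilv_sets = list(character(0)),
                                    baselines = "constant", use_ties = FALSE),
                     seed = 9)
sel$hypothesis_support   # summed Akaike weights per transmission hypothesis
```

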