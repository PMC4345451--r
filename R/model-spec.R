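#' Specify one candidate diffusion model
#'
#' A `model_spec` pins down one member of the candidate set compared by
#' AICc: the baseline hazard form, how individual-level variables (ILVs)
#' enter, the constraint on the per-layer social-transmission rates, and
#' whether near-simultaneous discoveries are tie-masked.
#'
#' Layer constraints encode the competing transmission hypotheses:
#' \describe{
#'   \item{`free`}{one rate `s_k` per layer (e.g. `s_intra != s_inter`).}
#'   \item{`shared`}{a single rate `s` on every layer (`s_intra = s_inter`).}
#'   \item{`zero_set`}{the layers named in `zero_layers` are forced to
#'     `s = 0` (e.g. within-species transmission only).}
#'   \item{`homogeneous`}{the stack is replaced by a single all-ones
#'     network -- transmission without regard to observed associations.}
#'   \item{`asocial`}{all `s_k = 0`: discovery is individual only.}
#' }
#'
#' ILV modes: `additive` covariates scale only the asocial component
#' (`rate = lambda0(t) * (S_i + A_i)`, social transmission an independent
#' discovery channel); `multiplicative` covariates scale the whole rate
#' (`rate = lambda0(t) * A_i * (S_i + 1)`); `none` sets `A_i = 1`. The
#' covariate link is exponential, `A_i = exp(sum(beta * V_i))`, so effects
#' read as rate ratios.
#'
#' @param baseline `"constant"` (`lambda0(t) = lambda0`) or `"weibull"`
#'   (`lambda0(t) = lambda0 * kappa * t^(kappa - 1)`, allowing the asocial
#'   rate to rise or fall over a trial).
#' @param ilv_mode `"none"`, `"additive"` or `"multiplicative"`.
#' @param constraint One of `"free"`, `"shared"`, `"zero_set"`,
#'   `"homogeneous"`, `"asocial"`.
#' @param zero_layers Layer names forced to zero when
#'   `constraint = "zero_set"`.
#' @param ilv_names Covariate columns (of the covariate table) entering
#'   the model.
#' @param use_ties Mask mutual social terms of discoveries closer than
#'   the trial's tie window (default `TRUE`).
#' @param standardize_ilvs Centre/scale numeric covariates (default
#'   `TRUE`; categorical covariates become treatment-coded indicators).
#' @param label Optional model label (auto-generated otherwise).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(baseline = c("constant", "weibull"),
                       ilv_mode = c("none", "additive", "multiplicative"),
                       constraint = c("free", "shared", "zero_set", "homogeneous", "asocial"),
                       zero_layers = character(),
                       ilv_names = character(),
                       use_ties = TRUE,
                       standardize_ilvs = TRUE,
                       label = NULL) {
  baseline <- match.arg(baseline)
  ilv_mode <- match.arg(ilv_mode)
  constraint <- match.arg(constraint)
  if (constraint == "zero_set" && length(zero_layers) == 0)
    stop("constraint 'zero_set' needs at least one layer in `zero_layers`", call. = FALSE)
  if (constraint != "zero_set" && length(zero_layers) > 0)
    stop("`zero_layers` only applies to constraint 'zero_set'", call. = FALSE)
  if (ilv_mode == "none" && length(ilv_names) > 0)
    stop("`ilv_names` given but ilv_mode is 'none'", call. = FALSE)
  if (ilv_mode != "none" && length(ilv_names) == 0)
    stop("ilv_mode '", ilv_mode, "' needs `ilv_names`", call. = FALSE)
  if (is.null(label)) {
    label <- paste0(constraint,
                    if (length(zero_layers)) paste0("(-", paste(zero_layers, collapse = ","), ")"),
                    "|", baseline, "|", ilv_mode,
                    if (length(ilv_names)) paste0(":", paste(ilv_names, collapse = "+")),
                    if (!use_ties) "|noties")
  }
  structure(list(baseline = baseline, ilv_mode = ilv_mode, constraint = constraint,
                 zero_layers = as.character(zero_layers), ilv_names = as.character(ilv_names),
                 use_ties = isTRUE(use_ties), standardize_ilvs = isTRUE(standardize_ilvs),
                 label = label),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$label, "\n")
  invisible(x)
}

#' Classify a model spec into a transmission hypothesis
#'
#' Maps a spec onto the standard six-way hypothesis partition used when
#' summing Akaike weights: different per-layer rates, a shared rate,
#' single-layer-only transmission, homogeneous (all ties equal)
#' transmission, or no social transmission.
#'
#' @param spec A [model_spec()].
#' @param layer_names Layer names of the stack the spec is fitted to.
#' @return Character scalar, one of `"different_rates"`, `"same_rate"`,
#'   `"<layer>_only"`, `"homogeneous"`, `"asocial"`.
#' @export
hypothesis_class <- function(spec, layer_names = c("intra", "inter")) {
  switch(spec$constraint,
         free = "different_rates",
         shared = "same_rate",
         homogeneous = "homogeneous",
         asocial = "asocial",
         zero_set = {
           kept <- setdiff(layer_names, spec$zero_layers)
           if (length(kept) == 0) "asocial" else paste0(paste(kept, collapse = "+"), "_only")
         })
}

#' Build the combinatorial candidate model set
#'
#' Generates the full grid of candidate specs: the six transmission
#' hypotheses crossed with additive/multiplicative covariate entry,
#' constant/Weibull baselines, and a list of covariate subsets. Covariates
#' named in `always_ilvs` (typically the site indicator, which must be in
#' every model when trials ran at several sites) are appended to every
#' subset. The asocial hypothesis has no social rate, so its
#' additive/multiplicative variants coincide; it is emitted once per
#' baseline/covariate combination.
#'
#' @param layer_names Layer names of the target stack.
#' @param ilv_sets List of character vectors of covariate subsets (the
#'   empty subset is allowed; with `ilv_mode = "none"` when the combined
#'   set is empty).
#' @param always_ilvs Covariates appended to every subset.
#' @param baselines Subset of `c("constant", "weibull")`.
#' @param modes Subset of `c("additive", "multiplicative")`.
#' @param use_ties Passed to every spec.
#' @return List of [model_spec()] objects.
#' @export
nbda_model_set <- function(layer_names = c("intra", "inter"),
                           ilv_sets = list(character(0)),
                           always_ilvs = character(),
                           baselines = c("constant", "weibull"),
                           modes = c("additive", "multiplicative"),
                           use_ties = TRUE) {
  single_layer_only <- if (length(layer_names) >= 2) {
    lapply(layer_names, function(keep)
      list(constraint = "zero_set", zero = setdiff(layer_names, keep)))
  } else list()
  constraints <- c(list(list(constraint = "free", zero = character()),
                        list(constraint = "shared", zero = character())),
                   single_layer_only,
                   list(list(constraint = "homogeneous", zero = character()),
                        list(constraint = "asocial", zero = character())))
  specs <- list()
  for (bl in baselines) for (ilvs in ilv_sets) {
    ilvs <- union(as.character(ilvs), always_ilvs)
    mode_set <- if (length(ilvs) == 0) "none" else modes
    for (con in constraints) {
      emitted_modes <- if (con$constraint == "asocial") mode_set[1] else mode_set
      for (md in emitted_modes) {
        specs[[length(specs) + 1]] <- model_spec(
          baseline = bl, ilv_mode = md, constraint = con$constraint,
          zero_layers = con$zero, ilv_names = if (md == "none") character() else ilvs,
          use_ties = use_ties)
      }
    }
  }
  specs
}
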