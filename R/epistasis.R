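#' Fractional change of a bursting parameter
#'
#' The effect of a perturbation on one parameter is the ratio between the
#' bootstrap mean of that parameter in the perturbed and the reference
#' population; its uncertainty is propagated from the bootstrap s.d.s
#' assuming independence between conditions. For the active fraction, the
#' ratio of fractions is used with square-root-of-count errors instead.
#'
#' @param perturbed,reference `population_summary` objects.
#' @param parameter One of `"induction_time"`, `"burst_duration"`,
#'   `"inter_burst_time"`, `"burst_intensity"`, `"active_fraction"`.
#' @param perturbation,reference_label Optional labels.
#' @return Class `effect_estimate`: `parameter`, `f`, `sd`, labels.
#' @export
fractional_change <- function(perturbed, reference, parameter,
                              perturbation = perturbed$condition,
                              reference_label = reference$condition) {
  get <- function(s) {
    if (parameter == "active_fraction")
      return(c(s$active_fraction, s$active_fraction_sd))
    p <- s$parameters[[parameter]]
    if (is.null(p)) stopf("summary lacks parameter '%s'", parameter)
    c(p$mean, p$sd)
  }
  pv <- get(perturbed); rv <- get(reference)
  if (rv[1] == 0) stopf("reference mean for '%s' is 0", parameter)
  pr <- propagate_ratio(pv[1], pv[2], rv[1], rv[2])
  structure(list(parameter = parameter, f = unname(pr["value"]),
                 sd = unname(pr["sd"]), perturbation = perturbation,
                 reference = reference_label), class = "effect_estimate")
}

#' Expected effect of a double perturbation under independence
#'
#' For independent processes the expected fractional change of the double
#' perturbation is the product of the single-perturbation fractional changes,
#' `f_exp = f_A * f_B`, with
#' `sd_exp = f_exp * sqrt((sd_A/f_A)^2 + (sd_B/f_B)^2)` — the multiplicative
#' null of genetic-interaction analysis applied to bursting parameters.
#'
#' @param effect_A,effect_B `effect_estimate` objects for the same parameter
#'   and reference.
#' @return An `effect_estimate` for the expected double effect.
#' @export
expected_double <- function(effect_A, effect_B) {
  if (!identical(effect_A$parameter, effect_B$parameter))
    stopf("effects are for different parameters ('%s' vs '%s')",
          effect_A$parameter, effect_B$parameter)
  if (!identical(effect_A$reference, effect_B$reference))
    stopf("effects have different references ('%s' vs '%s')",
          effect_A$reference, effect_B$reference)
  if (effect_A$f <= 0 || effect_B$f <= 0) stopf("fractional changes must be > 0")
  f <- effect_A$f * effect_B$f
  sd <- f * sqrt((effect_A$sd / effect_A$f)^2 + (effect_B$sd / effect_B$f)^2)
  structure(list(parameter = effect_A$parameter, f = f, sd = sd,
                 perturbation = paste(effect_A$perturbation, effect_B$perturbation,
                                      sep = " x "),
                 reference = effect_A$reference), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("effect_estimate [%s] %s vs %s: f = %.3f +/- %.3f\n",
              x$parameter, x$perturbation, x$reference, x$f, x$sd))
  invisible(x)
}

#' Classify a double-perturbation effect against the multiplicative null
#'
#' The deviation `z = (f_obs - f_exp) / sqrt(sd_obs^2 + sd_exp^2)` is
#' compared with `z_cut`: larger than `z_cut` means the observed effect
#' exceeds the product of the singles (`synergistic` — redundant processes);
#' below `-z_cut` it falls short (`buffered` — same pathway or opposing
#' functions); otherwise the perturbations act independently
#' (`as-expected`).
#'
#' @param observed,expected `effect_estimate` objects (same parameter).
#' @param z_cut Classification cutoff on the z-score.
#' @return Class `epistasis_call`: `parameter`, `f_obs`, `f_exp`, `z`, `label`.
#' @export
classify_interaction <- function(observed, expected, z_cut = 2) {
  if (!identical(observed$parameter, expected$parameter))
    stopf("observed and expected effects are for different parameters")
  den <- sqrt(observed$sd^2 + expected$sd^2)
  z <- if (den == 0) {
    if (observed$f == expected$f) 0 else sign(observed$f - expected$f) * Inf
  } else (observed$f - expected$f) / den
  label <- if (z > z_cut) "synergistic" else if (z < -z_cut) "buffered" else "as-expected"
  structure(list(parameter = observed$parameter, f_obs = observed$f,
                 sd_obs = observed$sd, f_exp = expected$f, sd_exp = expected$sd,
                 z = z, z_cut = z_cut, label = label), class = "epistasis_call")
}

#' @export
print.epistasis_call <- function(x, ...) {
  cat(sprintf("epistasis_call [%s]: observed %.3f +/- %.3f vs expected %.3f +/- %.3f, z = %.2f -> %s\n",
              x$parameter, x$f_obs, x$sd_obs, x$f_exp, x$sd_exp, x$z, x$label))
  invisible(x)
}

#' Simulate one replicate study of a double perturbation
#'
#' Runs the full measurement path on four simulated conditions — reference,
#' single perturbations A and B (multiplying the mean inter-burst time by
#' `a` and `b`) and the double perturbation (factor `double_factor`) — and
#' classifies the double effect on the time between bursts against the
#' multiplicative null. The default study design uses long movies at sparse
#' sampling (960 min at 60-s frames): completed-interval means are biased by
#' roughly `-mean_off / movie_length` through length-biased censoring, a
#' concave distortion that breaks the multiplicative null when the movie is
#' short relative to the largest perturbed OFF time, so the movie is sized to
#' keep that distortion well below the sampling error of the fractional
#' changes.
#'
#' @param a,b Single-perturbation factors on the mean OFF time.
#' @param double_factor Factor of the double perturbation (`a * b` under
#'   independence; larger simulates synergy).
#' @param n_cells Cells per condition.
#' @param base Baseline [burst_sim_params()]; its `mean_off` is scaled.
#' @param n_boot Bootstrap repetitions per condition summary.
#' @param seed Integer seed.
#' @return The `epistasis_call` for the inter-burst time.
#' @export
simulate_epistasis_replicate <- function(a = 2, b = 1.5, double_factor = a * b,
                                         n_cells = 200,
                                         base = burst_sim_params(
                                           mean_on = 2, mean_off = 8,
                                           movie_length = 960, frame_interval = 60,
                                           active_prob = 1,
                                           mean_intensity = 1000, bg_sd = 20),
                                         n_boot = 1000, seed = 1L) {
  factors <- c(ref = 1, A = a, B = b, AB = double_factor)
  seeds <- derive_seeds(seed, length(factors) + 1L)
  summaries <- lapply(seq_along(factors), function(i) {
    p <- base
    p$mean_off <- base$mean_off * factors[[i]]
    p$seed <- seeds[i]
    sim <- simulate_traces(p, n_cells)
    recs <- burst_records(sim$traces, bg_width = base$bg_sd)
    summarize_population(recs, n_boot = n_boot, seed = seeds[i],
                         condition = names(factors)[i],
                         parameters = "inter_burst_time")
  })
  names(summaries) <- names(factors)
  fA <- fractional_change(summaries$A, summaries$ref, "inter_burst_time")
  fB <- fractional_change(summaries$B, summaries$ref, "inter_burst_time")
  fAB <- fractional_change(summaries$AB, summaries$ref, "inter_burst_time")
  classify_interaction(fAB, expected_double(fA, fB))
}

#' Resolve the reference condition for each perturbation
#'
#' By default each perturbed condition is referenced to the unperturbed
#' (e.g. DMSO-treated) condition of the same strain; explicit rules override
#' this, e.g. to express a histone-deletion effect relative to the
#' remodeler-depleted background rather than the fully unperturbed strain.
#'
#' @param conditions Data frame with columns `condition`, `strain`,
#'   `treatment`.
#' @param rules Named character vector: `rules[condition] = reference`.
#' @param baseline_treatment Treatment labelling the default baseline.
#' @return Named character vector mapping every non-baseline condition to its
#'   reference condition.
#' @export
relative_reference_resolve <- function(conditions, rules = NULL,
                                       baseline_treatment = "DMSO") {
  need <- c("condition", "strain", "treatment")
  if (!all(need %in% names(conditions)))
    stopf("'conditions' needs columns %s", paste(need, collapse = ", "))
  is_base <- conditions$treatment == baseline_treatment
  out <- character(0)
  for (i in which(!is_base)) {
    cond <- conditions$condition[i]
    if (!is.null(rules) && cond %in% names(rules)) {
      ref <- unname(rules[[cond]])
      if (!ref %in% conditions$condition)
        stopf("rule for '%s' points to unknown condition '%s'; candidates: %s",
              cond, ref, paste(conditions$condition, collapse = ", "))
    } else {
      j <- which(is_base & conditions$strain == conditions$strain[i])
      if (length(j) == 0)
        stopf("no baseline ('%s') condition for strain '%s' (condition '%s'); candidates: %s",
              baseline_treatment, conditions$strain[i], cond,
              paste(conditions$condition[is_base], collapse = ", "))
      ref <- conditions$condition[j[1]]
    }
    out[cond] <- ref
  }
  out
}
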