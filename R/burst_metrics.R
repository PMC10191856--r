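#' Lorentzian (Cauchy) width of a background sample
#'
#' Maximum-likelihood location-scale Cauchy fit. The Cauchy has no standard
#' deviation, so the fitted scale parameter gamma serves as the background
#' "s.d." used for thresholding; `mode = "sigma"` instead converts the fitted
#' half-width at half-maximum to the Gaussian sigma with the same HWHM
#' (`gamma / sqrt(2 log 2)`).
#'
#' @param samples Numeric vector of background intensities.
#' @param mode `"scale"` (default, return gamma) or `"sigma"`.
#' @return List: `width`, `location`, `scale`, `n`.
#' @export
fit_lorentzian_width <- function(samples, mode = c("scale", "sigma")) {
  mode <- match.arg(mode)
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2) stopf("need at least 2 samples")
  if (stats::sd(samples) == 0)
    return(list(width = 0, location = samples[1], scale = 0, n = n))
  nll <- function(p) -sum(stats::dcauchy(samples, p[1], exp(p[2]), log = TRUE))
  init <- c(stats::median(samples), log(max(stats::IQR(samples) / 2, 1e-6)))
  ## finite-difference steps can probe extreme log-scales; those NaN probes are
  ## harmless to the optimum (validated against MASS::fitdistr in the tests)
  fit <- suppressWarnings(stats::optim(init, nll, method = "BFGS"))
  gam <- exp(fit$par[2])
  width <- if (mode == "sigma") gam / sqrt(2 * log(2)) else gam
  list(width = width, location = fit$par[1], scale = gam, n = n)
}

#' Per-cell background width from points around the transcription site
#'
#' Pools intensities measured at four points (north/east/south/west) at a
#' fixed distance from the per-frame TS position, over all frames with a
#' position, and fits a Lorentzian to the pooled sample
#' (see [fit_lorentzian_width()]). Points falling outside the image are
#' skipped; with fewer than `min_samples` pooled values the global image s.d.
#' is used instead (with a warning).
#'
#' @param stack `image_stack` or (y, x, t) / (y, x, z, t) array.
#' @param trace An `intensity_trace` from [quantify_ts()].
#' @param ring_distance Distance of the four points from the TS, pixels.
#' @param min_samples Minimum pooled sample size before falling back.
#' @inheritParams fit_lorentzian_width
#' @return Background width, a.u. (attributes carry the full fit).
#' @export
estimate_background_sd <- function(stack, trace, ring_distance = 5,
                                   min_samples = 20, mode = c("scale", "sigma")) {
  mode <- match.arg(mode)
  dat <- stack_data(stack)
  proj <- max_project_z(dat)
  nf <- dim(proj)[3]
  vals <- c()
  for (k in seq_len(min(nf, length(trace$x)))) {
    x <- trace$x[k]; y <- trace$y[k]
    if (!is.finite(x) || !is.finite(y)) next
    pts <- rbind(c(y - ring_distance, x), c(y + ring_distance, x),
                 c(y, x - ring_distance), c(y, x + ring_distance))
    pts <- round(pts)
    ok <- pts[, 1] >= 1 & pts[, 1] <= nrow(proj) &
          pts[, 2] >= 1 & pts[, 2] <= ncol(proj)
    if (any(ok)) vals <- c(vals, proj[cbind(pts[ok, 1], pts[ok, 2], k)])
  }
  if (length(vals) < min_samples) {
    warnf("only %d background samples: using global image s.d.", length(vals))
    return(stats::sd(as.vector(proj)))
  }
  fit <- fit_lorentzian_width(vals, mode)
  structure(fit$width, fit = fit)
}

#' Binarize a transcription-site trace
#'
#' ON where intensity exceeds `threshold_factor x bg_width`, evaluated up to
#' the trace `end_frame`. Cleanup then (1) deletes ON runs lasting a single
#' frame and (2) merges ON runs separated by a single OFF frame — in that
#' order by default; the order changes results and is configurable.
#'
#' @param trace An `intensity_trace`, or a numeric intensity vector.
#' @param bg_width Background width, a.u. (see [estimate_background_sd()]).
#' @param threshold_factor Multiple of `bg_width` defining the ON threshold.
#' @param cleanup Apply the two cleanup rules?
#' @param cleanup_order `"delete_first"` (default) or `"merge_first"`.
#' @return Logical vector of class `binary_trace` (length = `end_frame` when
#'   the input is an `intensity_trace`), with a `frame_interval` attribute.
#' @export
binarize <- function(trace, bg_width, threshold_factor = 5, cleanup = TRUE,
                     cleanup_order = c("delete_first", "merge_first")) {
  cleanup_order <- match.arg(cleanup_order)
  if (bg_width < 0) stopf("'bg_width' must be >= 0")
  if (inherits(trace, "intensity_trace")) {
    v <- trace$intensity[seq_len(trace$end_frame)]
    fi <- trace$frame_interval
  } else {
    v <- as.numeric(trace)
    fi <- attr(trace, "frame_interval") %||% NA_real_
  }
  on <- v > threshold_factor * bg_width
  if (cleanup) {
    if (cleanup_order == "delete_first")
      on <- merge_single_gaps(delete_single_frame_bursts(on))
    else
      on <- delete_single_frame_bursts(merge_single_gaps(on))
  }
  structure(on, frame_interval = fi, class = "binary_trace")
}

delete_single_frame_bursts <- function(on) {
  r <- rle(as.logical(on))
  r$values[r$values & r$lengths == 1L] <- FALSE
  inverse.rle(r)
}

merge_single_gaps <- function(on) {
  r <- rle(as.logical(on))
  k <- length(r$values)
  if (k >= 3) {
    interior <- which(!r$values & r$lengths == 1L)
    interior <- interior[interior > 1 & interior < k]  # only gaps between bursts
    r$values[interior] <- TRUE
  }
  inverse.rle(r)
}

#' Extract per-cell burst parameters from a binarized trace
#'
#' Induction time is the time of the first ON frame (frame 1 sits at t = 0)
#' plus the acquisition dead time; burst durations are ON-run lengths times
#' the frame interval; inter-burst times are the OFF runs between consecutive
#' bursts; burst intensity is the mean raw intensity over all ON frames. A
#' burst still running at the trace endpoint is right-censored: counted in
#' `n_censored` and excluded from the duration list.
#'
#' @param binary A `binary_trace`.
#' @param trace The matching `intensity_trace` (or raw intensity vector).
#' @param t_acquisition_offset Dead time between stimulus and acquisition
#'   start, minutes.
#' @param cell_id Optional identifier.
#' @return Class `burst_record`: `cell_id`, `active`, `induction_time` (min),
#'   `burst_durations` (min), `inter_burst_times` (min), `burst_intensity`
#'   (a.u.), `n_censored`.
#' @export
extract_burst_record <- function(binary, trace, t_acquisition_offset = 0,
                                 cell_id = NA) {
  fi <- attr(binary, "frame_interval")
  if (!is.finite(fi)) stopf("binary trace lacks a frame_interval")
  dt_min <- fi / 60
  on <- as.logical(binary)
  raw <- if (inherits(trace, "intensity_trace")) trace$intensity else as.numeric(trace)
  if (is.na(cell_id) && inherits(trace, "intensity_trace")) cell_id <- trace$cell_id
  if (!any(on))
    return(structure(list(cell_id = cell_id, active = FALSE,
                          induction_time = NA_real_, burst_durations = numeric(0),
                          inter_burst_times = numeric(0),
                          burst_intensity = NA_real_, n_censored = 0L),
                     class = "burst_record"))
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_runs <- which(r$values)
  durations <- r$lengths[on_runs] * dt_min
  censored <- ends[on_runs] == length(on)
  gaps <- which(!r$values)
  gaps <- gaps[gaps > min(on_runs) & gaps < max(on_runs)]
  structure(list(
    cell_id = cell_id, active = TRUE,
    induction_time = (starts[on_runs[1]] - 1L) * dt_min + t_acquisition_offset,
    burst_durations = durations[!censored],
    inter_burst_times = r$lengths[gaps] * dt_min,
    burst_intensity = mean(raw[seq_along(on)][on]),
    n_censored = sum(censored)), class = "burst_record")
}

#' Binarize and extract burst records for every cell of a trace set
#'
#' Convenience wrapper: applies [binarize()] and [extract_burst_record()] to
#' each column of a simulated or measured `trace_set`.
#'
#' @param traces A `trace_set`.
#' @param bg_width Background width, a.u.
#' @param threshold_factor ON threshold in background-width units.
#' @param t_acquisition_offset Acquisition dead time, minutes.
#' @return List of `burst_record` objects.
#' @export
burst_records <- function(traces, bg_width, threshold_factor = 5,
                          t_acquisition_offset = 0) {
  if (!inherits(traces, "trace_set")) stopf("'traces' must be a trace_set")
  lapply(seq_len(traces$n_cells), function(i) {
    v <- structure(traces$intensity[, i], frame_interval = traces$frame_interval)
    b <- binarize(v, bg_width, threshold_factor)
    extract_burst_record(b, traces$intensity[, i], t_acquisition_offset,
                         cell_id = i)
  })
}

#' Summarize a population of burst records with bootstrap uncertainty
#'
#' Cells are the independent units: each bootstrap replicate resamples active
#' cells with replacement and recomputes the pooled mean of each parameter
#' (interval-level values follow their cell). Reported are the mean and s.d.
#' of the bootstrap means (1,000 repetitions by default). The active fraction
#' is reported from the counts, with square-root-of-count errors.
#'
#' @param records List of `burst_record` objects.
#' @param n_boot Bootstrap repetitions.
#' @param seed Integer seed.
#' @param condition Optional condition label.
#' @param parameters Which parameters to summarize.
#' @return Class `population_summary`: `condition`, `n_active`, `n_inactive`,
#'   `active_fraction` (+ `active_fraction_sd` from the count errors) and, per
#'   parameter, a list with `mean`, `sd`, `n` and the raw pooled `values`.
#' @export
summarize_population <- function(records, n_boot = 1000, seed = 1L, condition = NA,
                                 parameters = c("induction_time", "burst_duration",
                                                "inter_burst_time", "burst_intensity")) {
  parameters <- match.arg(parameters, several.ok = TRUE)
  active <- vapply(records, function(r) isTRUE(r$active), logical(1))
  n_act <- sum(active); n_inact <- sum(!active)
  recs <- records[active]
  p <- n_act / (n_act + n_inact)
  ## sqrt(n) errors on both counts, propagated to the fraction
  sd_p <- if (n_act + n_inact > 0)
    sqrt(n_inact^2 * n_act + n_act^2 * n_inact) / (n_act + n_inact)^2 else NA_real_
  out <- list(condition = condition, n_active = n_act, n_inactive = n_inact,
              active_fraction = p, active_fraction_sd = sd_p,
              n_boot = n_boot, parameters = list())
  field <- c(induction_time = "induction_time", burst_duration = "burst_durations",
             inter_burst_time = "inter_burst_times", burst_intensity = "burst_intensity")
  if (n_act > 0) {
    set.seed(seed)
    for (par in parameters) {
      vals_by_cell <- lapply(recs, function(r) {
        v <- r[[field[[par]]]]
        v[is.finite(v)]
      })
      S <- vapply(vals_by_cell, sum, numeric(1))
      C <- vapply(vals_by_cell, length, numeric(1))
      pooled <- unlist(vals_by_cell, use.names = FALSE)
      if (length(pooled) == 0) next
      idx <- matrix(sample.int(n_act, n_boot * n_act, replace = TRUE), n_boot)
      bs <- rowSums(matrix(S[idx], n_boot)) / rowSums(matrix(C[idx], n_boot))
      bs <- bs[is.finite(bs)]
      out$parameters[[par]] <- list(mean = mean(bs), sd = stats::sd(bs),
                                    n = length(pooled), values = pooled)
    }
  }
  structure(out, class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("population_summary%s: %d active / %d inactive (fraction %.3f +/- %.3f)\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$n_active, x$n_inactive, x$active_fraction, x$active_fraction_sd))
  for (nm in names(x$parameters)) {
    p <- x$parameters[[nm]]
    cat(sprintf("  %-18s %8.3f +/- %.3f (bootstrap, n = %d)\n", nm, p$mean, p$sd, p$n))
  }
  invisible(x)
}

#' Frame-discretization of ground-truth states
#'
#' Maps the true per-frame state series through the same run-length
#' bookkeeping and cleanup rules the measurement path applies, yielding the
#' discretization-corrected generative truth for burst duration, inter-burst
#' time and induction time. Exponential dwell means are biased upward by
#' single-frame-burst deletion at finite frame rate; comparing recovered
#' parameters to this corrected truth isolates the measurement error from the
#' (documented) discretization effect.
#'
#' @param truth A `ground_truth` from [simulate_traces()].
#' @param frame_interval Frame interval, seconds.
#' @return List of `burst_record` objects, one per cell.
#' @export
discretize_truth <- function(truth, frame_interval) {
  lapply(seq_len(ncol(truth$state)), function(i) {
    on <- structure(merge_single_gaps(delete_single_frame_bursts(truth$state[, i])),
                    frame_interval = frame_interval, class = "binary_trace")
    extract_burst_record(on, rep(0, length(on)), cell_id = i)
  })
}
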