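#' Detect and quantify smFISH spots in a 3D stack
#'
#' Local maxima above `threshold_factor x bg_sd` over the cell background are
#' quantified by iterative 3D Gaussian-mask photometry (amplitude and a
#' constant local background fit jointly, centre iterated to convergence).
#' Each spot is assigned to a cell and to the nuclear or cytoplasmic
#' compartment; cells without any detected spot are absent from the table
#' (they are excluded from analysis as unsegmentable/unpermeabilized).
#'
#' @param stack 3D array (y, x, z).
#' @param cell_mask Integer label matrix (2D; applied to all slices).
#' @param nucleus_mask Logical or integer matrix marking nuclear pixels.
#' @param bg_sd Background s.d., a.u.
#' @param psf_sigma_xy,psf_sigma_z PSF widths, pixels/slices.
#' @param threshold_factor Detection threshold in background s.d. units.
#' @return Data frame: `cell`, `compartment`, `intensity`, `x`, `y`, `z`.
#' @export
detect_spots_3d <- function(stack, cell_mask, nucleus_mask, bg_sd,
                            psf_sigma_xy = 1.3, psf_sigma_z = 1.0,
                            threshold_factor = 6) {
  if (length(dim(stack)) != 3) stopf("'stack' must be a 3D array")
  labs <- sort(unique(as.integer(cell_mask[cell_mask > 0])))
  if (length(labs) == 0)
    return(data.frame(cell = integer(0), compartment = character(0),
                      intensity = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  base <- stats::median(stack)
  thr <- base + threshold_factor * bg_sd
  cand <- which(stack > thr)
  out <- list()
  if (length(cand) > 0) {
    idx <- arrayInd(cand, dim(stack))
    ## keep only 26-neighbourhood local maxima
    is_max <- vapply(seq_len(nrow(idx)), function(i) {
      r <- idx[i, 1]; c <- idx[i, 2]; z <- idx[i, 3]
      nb <- stack[max(1, r - 1):min(dim(stack)[1], r + 1),
                  max(1, c - 1):min(dim(stack)[2], c + 1),
                  max(1, z - 1):min(dim(stack)[3], z + 1)]
      stack[r, c, z] >= max(nb)
    }, logical(1))
    idx <- idx[is_max, , drop = FALSE]
    for (i in seq_len(nrow(idx))) {
      lab <- cell_mask[idx[i, 1], idx[i, 2]]
      if (lab == 0) next
      fit <- gaussian_mask_fit_3d(stack, idx[i, 2], idx[i, 1], idx[i, 3],
                                  psf_sigma_xy, psf_sigma_z)
      if (!is.finite(fit$intensity)) next
      nuc <- nucleus_mask[round(fit$y), round(fit$x)] > 0
      out[[length(out) + 1]] <- data.frame(
        cell = as.integer(lab),
        compartment = if (nuc) "nuclear" else "cytoplasmic",
        intensity = fit$intensity, x = fit$x, y = fit$y, z = fit$z)
    }
  }
  if (length(out) == 0)
    return(data.frame(cell = integer(0), compartment = character(0),
                      intensity = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  do.call(rbind, out)
}

## 3D analogue of gaussian_mask_fit(): joint LS of amplitude + constant
## background over a separable pixel-integrated Gaussian window.
gaussian_mask_fit_3d <- function(arr, x0, y0, z0, sigma_xy = 1.3, sigma_z = 1.0) {
  rxy <- ceiling(3 * sigma_xy); rz <- ceiling(3 * sigma_z)
  x <- x0; y <- y0; z <- z0
  res <- list(intensity = NA_real_, x = x, y = y, z = z, converged = FALSE)
  for (it in seq_len(100)) {
    rows <- max(1, round(y) - rxy):min(dim(arr)[1], round(y) + rxy)
    cols <- max(1, round(x) - rxy):min(dim(arr)[2], round(x) + rxy)
    slcs <- max(1, round(z) - rz):min(dim(arr)[3], round(z) + rz)
    sub <- arr[rows, cols, slcs, drop = FALSE]
    py <- stats::pnorm(rows + 0.5, y, sigma_xy) - stats::pnorm(rows - 0.5, y, sigma_xy)
    px <- stats::pnorm(cols + 0.5, x, sigma_xy) - stats::pnorm(cols - 0.5, x, sigma_xy)
    pz <- stats::pnorm(slcs + 0.5, z, sigma_z) - stats::pnorm(slcs - 0.5, z, sigma_z)
    P <- outer(py %o% px, pz)
    n <- length(P)
    sP <- sum(P); sP2 <- sum(P^2); sI <- sum(sub); sPI <- sum(P * sub)
    det <- sP2 * n - sP^2
    if (abs(det) < .Machine$double.eps) return(res)
    N <- (sPI * n - sP * sI) / det
    b <- (sI * sP2 - sPI * sP) / det
    w <- P * (sub - b)
    sw <- sum(w)
    if (sw <= 0) return(list(intensity = N, x = x, y = y, z = z, converged = FALSE))
    co <- expand_grid_idx(rows, cols, slcs)
    xn <- sum(w * co$x) / sw; yn <- sum(w * co$y) / sw; zn <- sum(w * co$z) / sw
    moved <- sqrt((xn - x)^2 + (yn - y)^2 + (zn - z)^2)
    x <- xn; y <- yn; z <- zn
    res <- list(intensity = N, x = x, y = y, z = z, converged = moved < 0.01)
    if (moved < 0.01) break
  }
  res
}

expand_grid_idx <- function(rows, cols, slcs) {
  nr <- length(rows); nc <- length(cols); ns <- length(slcs)
  list(y = array(rep(rows, nc * ns), c(nr, nc, ns)),
       x = array(rep(rep(cols, each = nr), ns), c(nr, nc, ns)),
       z = array(rep(slcs, each = nr * nc), c(nr, nc, ns)))
}

#' Per-cell nascent transcription from an smFISH spot table
#'
#' One RNA-equivalent unit is the median intensity of all cytoplasmic spots
#' across the dataset. Per cell, the transcription site is the brightest
#' nuclear spot; its intensity divided by the unit gives the nascent RNA
#' count. Cells with fewer than `active_threshold` RNAs at the TS are
#' inactive; `active_threshold` or more, active.
#'
#' @param spots Data frame with `cell`, `compartment`
#'   (`"nuclear"`/`"cytoplasmic"`), `intensity` (e.g. from
#'   [detect_spots_3d()] or [simulate_smfish()]).
#' @param active_threshold Nascent-count activity threshold, RNAs.
#' @return Class `cell_table`: `cells` data frame (`cell`, `ts_intensity`,
#'   `nascent`, `active`), `unit`, `active_fraction`,
#'   `mean_nascent_active`.
#' @export
quantify_cells <- function(spots, active_threshold = 5) {
  cyto <- spots$intensity[spots$compartment == "cytoplasmic"]
  if (length(cyto) == 0) stopf("no cytoplasmic spots in the dataset")
  unit <- stats::median(cyto)
  cells <- sort(unique(spots$cell))
  ts <- vapply(cells, function(cl) {
    v <- spots$intensity[spots$cell == cl & spots$compartment == "nuclear"]
    if (length(v) == 0) 0 else max(v)
  }, numeric(1))
  nascent <- ts / unit
  active <- nascent >= active_threshold
  structure(list(
    cells = data.frame(cell = cells, ts_intensity = ts, nascent = nascent,
                       active = active),
    unit = unit,
    active_fraction = mean(active),
    mean_nascent_active = if (any(active)) mean(nascent[active]) else NA_real_),
    class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells, unit = %.1f a.u., active fraction = %.3f, mean nascent (active) = %.2f\n",
              nrow(x$cells), x$unit, x$active_fraction, x$mean_nascent_active))
  invisible(x)
}

#' Classify cell-cycle stage from total DAPI content
#'
#' A two-component Gaussian mixture is fit to the per-cell DAPI sums (the
#' 50-bin histogram is used for initialization; the mixture itself is fit on
#' the raw values). With component centres `c1 < c2` and s.d.s `sd1`, `sd2`,
#' cells in `[c1 - g1_window[1] sd1, c1 + g1_window[2] sd1]` are G1, cells in
#' `[c2 - g2_window[1] sd2, c2 + g2_window[2] sd2]` are G2, cells between the
#' two windows are S, and cells outside both extremes are unclassified. The
#' default asymmetric windows are `(1, 0.75)` and `(0.5, 1.5)`.
#'
#' @param dapi_sums Per-cell DAPI totals, a.u.
#' @param nbins Histogram bins for initialization.
#' @param g1_window,g2_window Window half-widths in s.d. units,
#'   `c(below, above)` the component centre.
#' @return Factor with levels G1, S, G2, unclassified; the mixture parameters
#'   are attached as the `"model"` attribute.
#' @importFrom mclust Mclust mclustBIC
#' @export
classify_cell_cycle <- function(dapi_sums, nbins = 50,
                                g1_window = c(1, 0.75), g2_window = c(0.5, 1.5)) {
  lv <- c("G1", "S", "G2", "unclassified")
  collapse <- function() {
    warnf("DAPI mixture collapsed: all cells unclassified")
    factor(rep("unclassified", length(dapi_sums)), levels = lv)
  }
  if (length(dapi_sums) < 4 || stats::sd(dapi_sums) == 0) return(collapse())
  h <- graphics::hist(dapi_sums, breaks = nbins, plot = FALSE)
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(dapi_sums, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(collapse())
  mns <- fit$parameters$mean
  sds <- sqrt(fit$parameters$variance$sigmasq)
  sds <- rep_len(sds, 2)
  o <- order(mns)
  c1 <- mns[o[1]]; c2 <- mns[o[2]]; sd1 <- sds[o[1]]; sd2 <- sds[o[2]]
  if ((c2 - c1) < 1e-2 * (c1 + c2) / 2) return(collapse())
  g1_lo <- c1 - g1_window[1] * sd1; g1_hi <- c1 + g1_window[2] * sd1
  g2_lo <- c2 - g2_window[1] * sd2; g2_hi <- c2 + g2_window[2] * sd2
  stage <- rep("unclassified", length(dapi_sums))
  stage[dapi_sums >= g1_lo & dapi_sums <= g1_hi] <- "G1"
  stage[dapi_sums >= g2_lo & dapi_sums <= g2_hi] <- "G2"
  stage[dapi_sums > g1_hi & dapi_sums < g2_lo] <- "S"
  structure(factor(stage, levels = lv),
            model = list(c1 = c1, c2 = c2, sd1 = sd1, sd2 = sd2,
                         g1_window = c(g1_lo, g1_hi), g2_window = c(g2_lo, g2_hi),
                         hist_breaks = h$breaks))
}

#' Combine smFISH replicates into a condition summary
#'
#' Per replicate, the active fraction and the mean nascent count of active
#' cells; across replicates, their mean and standard error of the mean.
#' Optionally stratified by cell-cycle stage (requires a `stage` column in
#' each replicate's `cells` data frame).
#'
#' @param tables List of `cell_table` objects (one per replicate).
#' @param stratify_by_stage Compute per-stage summaries too?
#' @return Data frame: `stage` (`"all"` or G1/S/G2), `n_replicates`,
#'   `active_fraction`, `active_fraction_sem`, `mean_nascent`,
#'   `mean_nascent_sem`, `sem_defined`.
#' @export
summarize_replicates <- function(tables, stratify_by_stage = FALSE) {
  sem <- function(v) if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  one <- function(stage) {
    af <- numeric(0); mn <- numeric(0)
    for (tb in tables) {
      cl <- tb$cells
      if (!identical(stage, "all")) {
        if (is.null(cl$stage)) stopf("stratified summary needs a 'stage' column")
        cl <- cl[cl$stage == stage, , drop = FALSE]
      }
      if (nrow(cl) == 0) next
      af <- c(af, mean(cl$active))
      mn <- c(mn, if (any(cl$active)) mean(cl$nascent[cl$active]) else NA_real_)
    }
    data.frame(stage = stage, n_replicates = length(af),
               active_fraction = mean(af), active_fraction_sem = sem(af),
               mean_nascent = mean(mn, na.rm = TRUE),
               mean_nascent_sem = sem(mn[is.finite(mn)]),
               sem_defined = length(af) >= 2)
  }
  stages <- "all"
  if (stratify_by_stage) stages <- c("all", "G1", "S", "G2")
  out <- do.call(rbind, lapply(stages, one))
  if (any(!out$sem_defined))
    warnf("fewer than 2 replicates: s.e.m. undefined")
  out
}
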