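#' Parameters of the two-state bursting simulator
#'
#' Bundles the generative parameters of the telegraph-with-delay model used by
#' [simulate_traces()]. A cell activates with probability `active_prob`; its
#' induction delay is the sum of `n_steps` sequential exponential activation
#' steps of rate `step_rate` (i.e. Gamma(`n_steps`, scale = 1/`step_rate`)),
#' optionally offset by `dead_time` (the lag between stimulus and the start of
#' acquisition). After induction the promoter alternates between exponential
#' ON periods (mean `mean_on`) and OFF periods (mean `mean_off`). While ON, the
#' transcription-site intensity is `mean_intensity` modulated by multiplicative
#' log-normal noise of coefficient of variation `intensity_cv` (heavy-tailed
#' burst intensities); every frame additionally carries Gaussian background of
#' mean `bg_mean` and s.d. `bg_sd`.
#'
#' @param n_steps Number of sequential rate-limiting activation steps.
#' @param step_rate Rate of each activation step, per minute.
#' @param mean_on,mean_off Mean ON (burst) and OFF (inter-burst) durations, minutes.
#' @param mean_intensity Mean transcription-site intensity while ON, a.u.
#' @param intensity_cv Coefficient of variation of the multiplicative intensity noise.
#' @param frame_interval Frame interval, seconds. Must divide the movie evenly.
#' @param movie_length Movie length, minutes.
#' @param active_prob Probability that a cell ever activates.
#' @param dead_time Offset added to every induction time, minutes.
#' @param bg_mean,bg_sd Gaussian background mean and s.d., a.u.
#' @param seed Integer seed; identical parameters and seed give identical output.
#' @return An object of class `burst_sim_params`.
#' @export
burst_sim_params <- function(n_steps = 3, step_rate = 0.5, mean_on = 2, mean_off = 8,
                             mean_intensity = 1000, intensity_cv = 0.2,
                             frame_interval = 15, movie_length = 60,
                             active_prob = 0.8, dead_time = 0,
                             bg_mean = 0, bg_sd = 0, seed = 1L) {
  check_positive(n_steps, "n_steps"); check_positive(step_rate, "step_rate")
  check_positive(mean_on, "mean_on"); check_positive(mean_off, "mean_off")
  check_positive(mean_intensity, "mean_intensity")
  check_nonneg(intensity_cv, "intensity_cv")
  check_positive(frame_interval, "frame_interval")
  check_positive(movie_length, "movie_length")
  check_nonneg(dead_time, "dead_time")
  check_nonneg(bg_sd, "bg_sd")
  if (active_prob < 0 || active_prob > 1) stopf("'active_prob' must be in [0, 1]")
  n_frames <- movie_length * 60 / frame_interval
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stopf("'frame_interval' (%g s) does not divide the movie (%g min) evenly",
          frame_interval, movie_length)
  structure(list(n_steps = n_steps, step_rate = step_rate, mean_on = mean_on,
                 mean_off = mean_off, mean_intensity = mean_intensity,
                 intensity_cv = intensity_cv, frame_interval = frame_interval,
                 movie_length = movie_length, active_prob = active_prob,
                 dead_time = dead_time, bg_mean = bg_mean, bg_sd = bg_sd,
                 seed = as.integer(seed), n_frames = as.integer(round(n_frames))),
            class = "burst_sim_params")
}

#' Simulate two-state bursting intensity traces with ground truth
#'
#' Draws, for each cell, an activation flag, a Gamma-distributed induction
#' delay and alternating exponential ON/OFF dwell times, then samples the true
#' promoter state on the frame grid (frame `k` sits at time `(k-1)` frame
#' intervals). Observed intensity per frame is
#' `state * mean_intensity * lognormal + Gaussian background`.
#'
#' @param params A [burst_sim_params()] object.
#' @param n_cells Number of cells to simulate.
#' @return A list with components
#'   * `traces`: class `trace_set` — `intensity` (frames x cells matrix),
#'     `spot_intensity` (background-free spot brightness), `frame_interval`
#'     (seconds), `time_min`, `params`;
#'   * `truth`: class `ground_truth` — per-cell `active`, `induction_time`
#'     (minutes, `NA` for inactive cells), `on_intervals` / `off_intervals`
#'     (lists of dwell times in minutes, truncated at the movie end),
#'     `last_interval_censored` and which state it belongs to, and the
#'     frames x cells logical `state` matrix.
#' @export
simulate_traces <- function(params, n_cells) {
  if (!inherits(params, "burst_sim_params")) stopf("'params' must be a burst_sim_params object")
  if (n_cells < 1) stopf("'n_cells' must be >= 1")
  n_cells <- as.integer(n_cells)
  dt_min <- params$frame_interval / 60
  nf <- params$n_frames
  t_min <- (seq_len(nf) - 1) * dt_min
  seeds <- derive_seeds(params$seed, n_cells)

  state <- matrix(FALSE, nf, n_cells)
  spot <- matrix(0, nf, n_cells)
  intensity <- matrix(0, nf, n_cells)
  active <- logical(n_cells)
  induction <- rep(NA_real_, n_cells)
  on_iv <- vector("list", n_cells)
  off_iv <- vector("list", n_cells)
  cens <- logical(n_cells)
  cens_state <- rep(NA_character_, n_cells)

  sdlog <- sqrt(log1p(params$intensity_cv^2))
  meanlog <- -sdlog^2 / 2   # unit-mean multiplicative noise

  for (i in seq_len(n_cells)) {
    set.seed(seeds[i])
    on_iv[[i]] <- numeric(0); off_iv[[i]] <- numeric(0)
    if (stats::runif(1) < params$active_prob) {
      active[i] <- TRUE
      t0 <- params$dead_time + stats::rgamma(1, shape = params$n_steps,
                                             rate = params$step_rate)
      induction[i] <- t0
      if (t0 < params$movie_length) {
        t_cur <- t0
        on <- TRUE
        while (t_cur < params$movie_length) {
          d <- stats::rexp(1, 1 / if (on) params$mean_on else params$mean_off)
          t_end <- t_cur + d
          trunc <- t_end > params$movie_length
          if (trunc) {
            t_end <- params$movie_length
            cens[i] <- TRUE
            cens_state[i] <- if (on) "on" else "off"
          }
          if (on) {
            on_iv[[i]] <- c(on_iv[[i]], t_end - t_cur)
            state[t_min >= t_cur & t_min < t_end, i] <- TRUE
          } else {
            off_iv[[i]] <- c(off_iv[[i]], t_end - t_cur)
          }
          t_cur <- t_end
          on <- !on
        }
      }
    }
    n_on <- sum(state[, i])
    s <- numeric(nf)
    if (n_on > 0)
      s[state[, i]] <- params$mean_intensity *
        stats::rlnorm(n_on, meanlog = meanlog, sdlog = sdlog)
    spot[, i] <- s
    intensity[, i] <- s + stats::rnorm(nf, params$bg_mean, params$bg_sd)
  }

  traces <- structure(list(intensity = intensity, spot_intensity = spot,
                           frame_interval = params$frame_interval,
                           time_min = t_min, n_cells = n_cells, params = params),
                      class = "trace_set")
  truth <- structure(list(active = active, induction_time = induction,
                          on_intervals = on_iv, off_intervals = off_iv,
                          last_interval_censored = cens,
                          censored_state = cens_state, state = state),
                     class = "ground_truth")
  list(traces = traces, truth = truth)
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d cells x %d frames (%.0f s interval, %.1f min)\n",
              x$n_cells, nrow(x$intensity), x$frame_interval,
              nrow(x$intensity) * x$frame_interval / 60))
  invisible(x)
}

#' Render a trace set as a synthetic time-lapse movie
#'
#' Lays cells out on a grid of square tiles and renders, per frame and ON
#' cell, one diffraction-limited spot: a pixel-integrated 2D Gaussian of
#' integrated intensity equal to the background-free trace value, at a fixed
#' per-cell position, plus i.i.d. Gaussian camera noise on a constant
#' baseline. With `n_z > 1` the spot is placed in the central slice and the
#' other slices contain only noise (widefield-style stacks are analysed on
#' the maximum projection anyway).
#'
#' @param traces A `trace_set` from [simulate_traces()].
#' @param psf_sigma PSF width, pixels.
#' @param cell_size Tile side, pixels; one cell per tile.
#' @param noise_sd Camera noise s.d., a.u.
#' @param bg_level Constant baseline added everywhere, a.u.
#' @param n_z Number of z slices.
#' @param jitter Max per-cell spot offset from the tile centre, pixels.
#' @param seed Seed for noise and spot placement.
#' @return Class `image_stack`: `data` (y, x, t) or (y, x, z, t) array,
#'   `frame_interval`, `masks` (integer label image, one label per cell) and
#'   `spot_xy` (true spot positions, one row per cell).
#' @export
render_movie <- function(traces, psf_sigma = 1.3, cell_size = 32, noise_sd = 1,
                         bg_level = 100, n_z = 1, jitter = 3, seed = 1L) {
  if (!inherits(traces, "trace_set")) stopf("'traces' must be a trace_set")
  check_positive(psf_sigma, "psf_sigma")
  if (cell_size < 8 * psf_sigma) stopf("cell tiles overlap the PSF: increase 'cell_size'")
  n_cells <- traces$n_cells
  nf <- nrow(traces$intensity)
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  ny <- nrow_grid * cell_size
  nx <- ncol_grid * cell_size

  set.seed(seed)
  masks <- matrix(0L, ny, nx)
  spot_xy <- matrix(NA_real_, n_cells, 2, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(n_cells)) {
    gr <- (i - 1) %/% ncol_grid
    gc <- (i - 1) %% ncol_grid
    rows <- gr * cell_size + seq_len(cell_size)
    cols <- gc * cell_size + seq_len(cell_size)
    masks[rows, cols] <- i
    spot_xy[i, ] <- c(gc * cell_size + cell_size / 2 + stats::runif(1, -jitter, jitter),
                      gr * cell_size + cell_size / 2 + stats::runif(1, -jitter, jitter))
  }

  mid_z <- ceiling(n_z / 2)
  dims <- if (n_z > 1) c(ny, nx, n_z, nf) else c(ny, nx, nf)
  data <- array(stats::rnorm(prod(dims), bg_level, noise_sd), dim = dims)
  for (k in seq_len(nf)) {
    frame <- matrix(0, ny, nx)
    for (i in seq_len(n_cells)) {
      I <- traces$spot_intensity[k, i]
      if (I > 0)
        frame <- add_gaussian_spot(frame, spot_xy[i, 1], spot_xy[i, 2], I, psf_sigma)
    }
    if (n_z > 1) data[, , mid_z, k] <- data[, , mid_z, k] + frame
    else data[, , k] <- data[, , k] + frame
  }
  data[data < 0] <- 0
  structure(list(data = data, frame_interval = traces$frame_interval,
                 masks = masks, spot_xy = spot_xy, psf_sigma = psf_sigma,
                 bg_level = bg_level, noise_sd = noise_sd),
            class = "image_stack")
}

## Add a pixel-integrated 2D Gaussian of integrated intensity I at (x0, y0).
## Pixel (r, c) covers [c-0.5, c+0.5] x [r-0.5, r+0.5].
add_gaussian_spot <- function(mat, x0, y0, I, sigma) {
  r <- ceiling(5 * sigma)
  rows <- max(1, round(y0) - r):min(nrow(mat), round(y0) + r)
  cols <- max(1, round(x0) - r):min(ncol(mat), round(x0) + r)
  py <- stats::pnorm(rows + 0.5, y0, sigma) - stats::pnorm(rows - 0.5, y0, sigma)
  px <- stats::pnorm(cols + 0.5, x0, sigma) - stats::pnorm(cols - 0.5, x0, sigma)
  mat[rows, cols] <- mat[rows, cols] + I * (py %o% px)
  mat
}

#' Simulate an smFISH cell table with known ground truth
#'
#' Per cell: cytoplasmic mRNA spots with a Poisson count and log-normal
#' intensities whose distribution median is one RNA-equivalent unit; one
#' nuclear transcription-site spot of intensity `nascent * unit`; and a total
#' DAPI signal drawn from a two-component Gaussian mixture (G1/G2 DNA
#' content) with the generative component recorded.
#'
#' @param n_cells Number of cells.
#' @param ts_nascent Nascent RNA counts at the transcription site: a numeric
#'   vector (recycled) or a `function(n)` returning counts.
#' @param cyto_counts Cytoplasmic RNA counts per cell: numeric vector or
#'   `function(n)`; default Poisson(30).
#' @param dapi_model List with `means`, `sds` and optional `weights` (two
#'   components each).
#' @param unit_intensity Intensity of one RNA, a.u.
#' @param cyto_cv Log-scale spread of cytoplasmic spot intensities.
#' @param seed Integer seed.
#' @return Class `smfish_sim`: `cells` data frame (`cell`, `dapi_sum`,
#'   `stage_true` = generative mixture component, `nascent_true`) and `spots`
#'   data frame (`cell`, `compartment`, `intensity`). `degenerate_mixture`
#'   flags equal DAPI component means.
#' @export
simulate_smfish <- function(n_cells, ts_nascent = function(n) stats::rpois(n, 8),
                            cyto_counts = function(n) stats::rpois(n, 30),
                            dapi_model = list(means = c(1e5, 2e5), sds = c(5e3, 5e3),
                                              weights = c(0.5, 0.5)),
                            unit_intensity = 1000, cyto_cv = 0.25, seed = 1L) {
  if (n_cells < 1) stopf("'n_cells' must be >= 1")
  set.seed(seed)
  nasc <- if (is.function(ts_nascent)) ts_nascent(n_cells) else rep_len(ts_nascent, n_cells)
  ncyt <- if (is.function(cyto_counts)) cyto_counts(n_cells) else rep_len(cyto_counts, n_cells)
  if (any(nasc < 0) || any(ncyt < 0)) stopf("spot counts must be non-negative")
  w <- dapi_model$weights %||% c(0.5, 0.5)
  degenerate <- abs(diff(dapi_model$means)) < 1e-9
  if (degenerate) warnf("degenerate DAPI mixture: equal component means")
  comp <- sample.int(2L, n_cells, replace = TRUE, prob = w)
  dapi <- stats::rnorm(n_cells, dapi_model$means[comp], dapi_model$sds[comp])

  sdlog <- sqrt(log1p(cyto_cv^2))
  spots <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cy <- if (ncyt[i] > 0)
      unit_intensity * exp(stats::rnorm(ncyt[i], 0, sdlog)) else numeric(0)
    spots[[i]] <- data.frame(
      cell = i,
      compartment = c("nuclear", rep("cytoplasmic", length(cy))),
      intensity = c(nasc[i] * unit_intensity, cy))
  }
  structure(list(
    cells = data.frame(cell = seq_len(n_cells), dapi_sum = dapi,
                       stage_true = comp, nascent_true = nasc),
    spots = do.call(rbind, spots),
    unit_intensity = unit_intensity,
    degenerate_mixture = degenerate), class = "smfish_sim")
}

#' Generative model for planted MNase-seq fragments
#'
#' @param chrom_sizes Named integer vector of chromosome lengths, bp.
#' @param nucleosomes Data frame with `chrom`, `center` (bp, 0-based) and
#'   `occupancy` (relative weight, >= 0), one row per planted nucleosome.
#' @param n_fragments Total fragments to draw.
#' @param frag_mean,frag_sd Fragment length distribution (Normal, bp),
#'   truncated to `[50, 300]`.
#' @param midpoint_sd Positional spread of fragment midpoints around the
#'   planted centre, bp.
#' @param seed Integer seed.
#' @return Class `nuc_sim_model`.
#' @export
nuc_sim_model <- function(chrom_sizes, nucleosomes, n_fragments = 10000,
                          frag_mean = 150, frag_sd = 15, midpoint_sd = 20,
                          seed = 1L) {
  if (is.null(names(chrom_sizes))) stopf("'chrom_sizes' must be named")
  if (!all(c("chrom", "center", "occupancy") %in% names(nucleosomes)))
    stopf("'nucleosomes' needs columns chrom, center, occupancy")
  if (!all(nucleosomes$chrom %in% names(chrom_sizes)))
    stopf("nucleosome on unknown chromosome")
  sz <- chrom_sizes[nucleosomes$chrom]
  if (any(nucleosomes$center < 0 | nucleosomes$center >= sz))
    stopf("nucleosome centre outside chromosome bounds")
  if (any(nucleosomes$occupancy < 0)) stopf("occupancies must be >= 0")
  if (sum(nucleosomes$occupancy) <= 0) stopf("total occupancy is zero")
  structure(list(chrom_sizes = chrom_sizes, nucleosomes = nucleosomes,
                 n_fragments = as.integer(n_fragments), frag_mean = frag_mean,
                 frag_sd = frag_sd, midpoint_sd = midpoint_sd,
                 seed = as.integer(seed)), class = "nuc_sim_model")
}

#' Simulate paired-end MNase fragments from planted nucleosomes
#'
#' Fragment midpoints are Normal around an occupancy-weighted planted centre;
#' lengths are Normal(`frag_mean`, `frag_sd`) rejected outside `[50, 300]`.
#' Fragments are clipped to chromosome bounds.
#'
#' @param model A [nuc_sim_model()].
#' @return Data frame `chrom`, `start`, `end` (bp, 0-based half-open).
#' @export
simulate_mnase <- function(model) {
  if (!inherits(model, "nuc_sim_model")) stopf("'model' must be a nuc_sim_model")
  set.seed(model$seed)
  nuc <- model$nucleosomes
  idx <- sample.int(nrow(nuc), model$n_fragments, replace = TRUE,
                    prob = nuc$occupancy)
  mid <- stats::rnorm(model$n_fragments, nuc$center[idx], model$midpoint_sd)
  len <- stats::rnorm(model$n_fragments, model$frag_mean, model$frag_sd)
  bad <- which(len < 50 | len > 300)
  while (length(bad) > 0) {
    len[bad] <- stats::rnorm(length(bad), model$frag_mean, model$frag_sd)
    bad <- bad[len[bad] < 50 | len[bad] > 300]
  }
  len <- round(len)
  start <- round(mid - len / 2)
  end <- start + len
  chrom <- nuc$chrom[idx]
  sz <- model$chrom_sizes[chrom]
  start <- pmax(start, 0)
  end <- pmin(end, sz)
  keep <- end > start
  data.frame(chrom = chrom[keep], start = as.integer(start[keep]),
             end = as.integer(end[keep]), row.names = NULL)
}

#' Planted promoter nucleosome architecture for simulations
#'
#' Convenience builder: `n_genes` genes spaced along one chromosome, each with
#' a -1 nucleosome, a +1 nucleosome (optionally shifted, e.g. to emulate
#' remodeler depletion) and a downstream array at 165-bp spacing. Alternating
#' genes are placed on the Watson/Crick strands and assigned TATA /
#' TATA-mismatch classes.
#'
#' @param n_genes Number of genes.
#' @param spacing Distance between consecutive TSSs, bp.
#' @param minus_one,plus_one -1 and +1 nucleosome offsets from the TSS, bp
#'   (TSS-oriented: downstream positive).
#' @param plus_one_shift Extra downstream-array and +1 shift, bp (applied to
#'   +1 and the gene-body array).
#' @param n_array Gene-body array nucleosomes beyond +1 (165-bp spacing); an
#'   upstream array of `n_upstream` nucleosomes beyond -1 fills the promoter
#'   flank so the TSS window sits in a continuous nucleosomal landscape, as
#'   on a real chromosome.
#' @param n_upstream Upstream array nucleosomes beyond -1.
#' @param ndr_jitter Per-gene spread added to the -1 offset so NDR widths vary, bp.
#' @param occupancy_minus Occupancy of the -1 nucleosome relative to +1.
#' @param seed Seed for the jitter.
#' @return List with `genes` (data frame: `gene`, `chrom`, `strand`, `tss`,
#'   `tata_start`, `class`), `nucleosomes` (for [nuc_sim_model()]) and
#'   `chrom_sizes`.
#' @export
promoter_architecture <- function(n_genes = 8, spacing = 6000, minus_one = -180,
                                  plus_one = 120, plus_one_shift = 0, n_array = 13,
                                  n_upstream = 14, ndr_jitter = 0,
                                  occupancy_minus = 1, seed = 1L) {
  set.seed(seed)
  chrom <- "chrSim"
  tss <- 3000 + spacing * (seq_len(n_genes) - 1)
  strand <- rep(c("+", "-"), length.out = n_genes)
  class <- rep(c("TATA", "TATA-mismatch"), length.out = n_genes)
  m1 <- minus_one - round(stats::runif(n_genes, 0, ndr_jitter))
  p1 <- plus_one + plus_one_shift
  sgn <- ifelse(strand == "+", 1, -1)
  genes <- data.frame(gene = sprintf("g%02d", seq_len(n_genes)), chrom = chrom,
                      strand = strand, tss = tss,
                      tata_start = tss + sgn * (m1 + 60),  # inside the NDR
                      class = class)
  nuc <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    off <- c(m1[i] - 165 * (n_upstream:1), m1[i], p1 + 165 * (0:n_array))
    occ <- c(rep(1, n_upstream), occupancy_minus, rep(1, n_array + 1))
    data.frame(chrom = chrom, center = tss[i] + sgn[i] * off, occupancy = occ,
               gene = genes$gene[i])
  }))
  nuc <- nuc[nuc$center >= 100 & nuc$center <= max(tss) + 3000 + spacing - 100, ]
  list(genes = genes, nucleosomes = nuc,
       chrom_sizes = c(chrSim = max(tss) + 3000 + spacing))
}
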