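#' Correct a time-lapse stack for xy stage drift
#'
#' Registers every frame to the first one using phase correlation on the
#' maximum-intensity projection (z is projected out first if present). The
#' default is translation-only registration — stage drift is translational —
#' estimated with sub-pixel precision by a parabolic fit around the
#' correlation peak; frames are then shifted by the rounded offset with the
#' frame median filling exposed edges.
#'
#' @param stack An `image_stack` (from [render_movie()] or [read_stack_tiff()])
#'   or a (y, x, t) array.
#' @return List: `stack` (registered, same class as input) and `offsets`, a
#'   frames x 2 matrix of estimated (dx, dy) displacements of each frame
#'   relative to the first.
#' @export
drift_correct <- function(stack) {
  dat <- stack_data(stack)
  proj <- max_project_z(dat)
  nf <- dim(proj)[3]
  if (nf < 2) stopf("drift correction needs at least 2 frames")
  ref <- proj[, , 1]
  offsets <- matrix(0, nf, 2, dimnames = list(NULL, c("dx", "dy")))
  fr <- stats::fft(ref)
  for (k in 2:nf) {
    frame <- proj[, , k]
    if (stats::sd(frame) == 0 || stats::sd(ref) == 0) {
      warnf("featureless frame %d: identity transform used", k)
      next
    }
    offsets[k, ] <- phase_correlate(fr, stats::fft(frame), dim(ref))
  }
  out <- dat
  for (k in 2:nf) {
    sh <- round(offsets[k, ])
    if (any(sh != 0)) {
      if (length(dim(dat)) == 4) {
        for (z in seq_len(dim(dat)[3]))
          out[, , z, k] <- translate_matrix(dat[, , z, k], -sh[1], -sh[2])
      } else {
        out[, , k] <- translate_matrix(dat[, , k], -sh[1], -sh[2])
      }
    }
  }
  res <- stack
  if (inherits(stack, "image_stack")) res$data <- out else res <- out
  list(stack = res, offsets = offsets)
}

## Displacement (dx, dy) such that frame(x) ~= ref(x - d).
phase_correlate <- function(fft_ref, fft_frame, dm) {
  cp <- fft_ref * Conj(fft_frame)
  m <- Mod(cp)
  m[m < .Machine$double.eps] <- 1
  r <- Re(stats::fft(cp / m, inverse = TRUE))
  pk <- arrayInd(which.max(r), dm)
  sub <- function(vals) {  # parabolic 3-point interpolation
    den <- vals[1] - 2 * vals[2] + vals[3]
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (vals[1] - vals[3]) / den
  }
  ny <- dm[1]; nx <- dm[2]
  iy <- pk[1]; ix <- pk[2]
  wy <- c((iy - 2) %% ny + 1, iy, iy %% ny + 1)
  wx <- c((ix - 2) %% nx + 1, ix, ix %% nx + 1)
  dy <- (iy - 1) + sub(r[wy, ix])
  dx <- (ix - 1) + sub(r[iy, wx])
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(-dx, -dy)
}

translate_matrix <- function(m, dx, dy) {
  fill <- stats::median(m)
  out <- matrix(fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dy
  src_c <- seq_len(ncol(m)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

stack_data <- function(stack) {
  if (inherits(stack, "image_stack")) stack$data
  else if (is.array(stack)) stack
  else stopf("expected an image_stack or array")
}

max_project_z <- function(dat) {
  if (length(dim(dat)) == 4) apply(dat, c(1, 2, 4), max) else dat
}

#' Segment cells by Otsu thresholding and watershedding
#'
#' Global Otsu threshold on the (time-averaged or single) reference image,
#' hole filling, then a distance-transform watershed to split touching cells;
#' objects smaller than `min_area` pixels are dropped and labels compacted.
#'
#' @param img 2D numeric matrix, e.g. a time-averaged maximum projection.
#' @param min_area Minimum object area, pixels.
#' @return Integer label matrix of class `cell_mask` (0 = background).
#' @export
segment_cells <- function(img, min_area = 100) {
  if (length(dim(img)) != 2) stopf("'img' must be a 2D matrix")
  rng <- range(img)
  if (diff(rng) == 0) {
    warnf("blank image: empty mask")
    return(structure(matrix(0L, nrow(img), ncol(img)), class = "cell_mask"))
  }
  nimg <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(nimg))
  bw <- nimg > thr
  if (!any(bw)) {
    warnf("empty foreground after Otsu threshold")
    return(structure(matrix(0L, nrow(img), ncol(img)), class = "cell_mask"))
  }
  bw <- EBImage::fillHull(EBImage::Image(bw))
  dm <- EBImage::distmap(bw)
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_area)
  relab <- integer(length(tab))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(img), ncol(img))
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  structure(out, class = "cell_mask")
}

#' Iterative Gaussian-mask photometry of one spot
#'
#' Fits the integrated intensity of a pixel-integrated 2D Gaussian of fixed
#' width `sigma` within a square window of half-width `ceiling(3 sigma)`
#' around the current centre. Amplitude and a constant local background are
#' solved jointly by linear least squares; the centre is then updated to the
#' signal-weighted Gaussian-mask centroid and the fit iterated to convergence
#' (centre change < 0.01 px, at most 100 iterations).
#'
#' @param img 2D matrix.
#' @param x0,y0 Starting centre (x = column, y = row, pixel units).
#' @param sigma PSF width, pixels.
#' @param iterate If `FALSE`, measure at the fixed centre without relocalizing
#'   (used for carried-over frames).
#' @return List: `intensity` (integrated, background-subtracted), `x`, `y`,
#'   `background`, `converged`, `iterations`.
#' @export
gaussian_mask_fit <- function(img, x0, y0, sigma = 1.3, iterate = TRUE) {
  r <- ceiling(3 * sigma)
  x <- x0; y <- y0
  res <- NULL
  max_it <- if (iterate) 100L else 1L
  for (it in seq_len(max_it)) {
    rows <- max(1, round(y) - r):min(nrow(img), round(y) + r)
    cols <- max(1, round(x) - r):min(ncol(img), round(x) + r)
    sub <- img[rows, cols, drop = FALSE]
    py <- stats::pnorm(rows + 0.5, y, sigma) - stats::pnorm(rows - 0.5, y, sigma)
    px <- stats::pnorm(cols + 0.5, x, sigma) - stats::pnorm(cols - 0.5, x, sigma)
    P <- py %o% px
    n <- length(P)
    sP <- sum(P); sP2 <- sum(P^2); sI <- sum(sub); sPI <- sum(P * sub)
    det <- sP2 * n - sP^2
    if (abs(det) < .Machine$double.eps) return(list(intensity = NA_real_, x = x, y = y,
                                                    background = NA_real_,
                                                    converged = FALSE, iterations = it))
    N <- (sPI * n - sP * sI) / det
    b <- (sI * sP2 - sPI * sP) / det
    w <- P * (sub - b)
    sw <- sum(w)
    if (sw <= 0) {
      res <- list(intensity = N, x = x, y = y, background = b,
                  converged = FALSE, iterations = it)
      break
    }
    xn <- sum(w * rep(cols, each = length(rows))) / sw
    yn <- sum(w * rep(rows, times = length(cols))) / sw
    moved <- sqrt((xn - x)^2 + (yn - y)^2)
    if (iterate) { x <- xn; y <- yn }
    res <- list(intensity = N, x = x, y = y, background = b,
                converged = !iterate || moved < 0.01, iterations = it)
    if (!iterate || moved < 0.01) break
  }
  res
}

#' Extract per-cell transcription-site intensity traces
#'
#' For every frame and cell, on the maximum z-projection of the registered
#' stack: (tier `primary`) the brightest pixel in the cell exceeding the cell
#' background by `6 x bg_sd` seeds an iterative Gaussian-mask fit; (tier
#' `fallback`) failing that, the search is repeated within `fallback_radius`
#' pixels of previously detected positions at a `4 x bg_sd` threshold; (tier
#' `carried-over`) failing that too, the intensity is measured at the last
#' known position. The trace endpoint `end_frame` is the last frame with a
#' primary or fallback detection (automatic stand-in for manual endpoint
#' curation; override via `end_frames`). Cells with no detection in any frame
#' are flagged `no_ts` and should be excluded downstream.
#'
#' @param stack Registered `image_stack` or (y, x, t) / (y, x, z, t) array.
#' @param masks `cell_mask` label matrix.
#' @param bg_sd Background s.d., a single value or one per cell.
#' @param psf_sigma PSF width for the Gaussian mask, pixels.
#' @param fallback_radius Search radius around previous detections, pixels.
#' @param end_frames Optional integer vector (one per cell) overriding the
#'   automatic endpoint, e.g. from a curation file.
#' @return List of `intensity_trace` objects: `cell_id`, `intensity`, `x`,
#'   `y`, `tier` (factor), `end_frame`, `no_ts`, `frame_interval`.
#' @export
quantify_ts <- function(stack, masks, bg_sd, psf_sigma = 1.3,
                        fallback_radius = 5, end_frames = NULL) {
  dat <- stack_data(stack)
  proj <- max_project_z(dat)
  nf <- dim(proj)[3]
  labs <- sort(unique(as.integer(masks[masks > 0])))
  n_cells <- length(labs)
  bg_sd <- rep_len(bg_sd, n_cells)
  fi <- if (inherits(stack, "image_stack")) stack$frame_interval else NA_real_

  cell_idx <- lapply(labs, function(l) which(unclass(masks) == l))
  cell_rc <- lapply(cell_idx, function(ix) arrayInd(ix, dim(masks)))

  traces <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    ix <- cell_idx[[ci]]
    rc <- cell_rc[[ci]]
    intensity <- rep(NA_real_, nf)
    xs <- rep(NA_real_, nf); ys <- rep(NA_real_, nf)
    tier <- rep(NA_character_, nf)
    last_pos <- NULL
    for (k in seq_len(nf)) {
      frame <- proj[, , k]
      vals <- frame[ix]
      base <- stats::median(vals)
      best <- which.max(vals)       # ties: which.max takes the first index,
      peak <- vals[best]            # i.e. lowest (row, col) in column order
      pos <- rc[best, ]
      hit <- NULL
      if (peak - base > 6 * bg_sd[ci]) {
        hit <- gaussian_mask_fit(frame, pos[2], pos[1], psf_sigma)
        tier[k] <- "primary"
      } else if (!is.null(last_pos)) {
        near <- abs(rc[, 1] - last_pos[2]) <= fallback_radius &
                abs(rc[, 2] - last_pos[1]) <= fallback_radius
        if (any(near)) {
          vn <- vals[near]
          bn <- which.max(vn)
          if (vn[bn] - base > 4 * bg_sd[ci]) {
            p2 <- rc[near, , drop = FALSE][bn, ]
            hit <- gaussian_mask_fit(frame, p2[2], p2[1], psf_sigma)
            tier[k] <- "fallback"
          }
        }
      }
      if (is.null(hit) && !is.null(last_pos)) {
        hit <- gaussian_mask_fit(frame, last_pos[1], last_pos[2], psf_sigma,
                                 iterate = FALSE)
        tier[k] <- "carried-over"
      }
      if (!is.null(hit)) {
        intensity[k] <- hit$intensity
        xs[k] <- hit$x; ys[k] <- hit$y
        if (tier[k] %in% c("primary", "fallback")) last_pos <- c(hit$x, hit$y)
      }
    }
    detected <- which(tier %in% c("primary", "fallback"))
    no_ts <- length(detected) == 0
    end_frame <- if (no_ts) 0L else max(detected)
    if (!is.null(end_frames)) end_frame <- as.integer(end_frames[ci])
    intensity[is.na(intensity)] <- 0
    traces[[ci]] <- structure(list(
      cell_id = labs[ci], intensity = intensity, x = xs, y = ys,
      tier = factor(tier, levels = c("primary", "fallback", "carried-over")),
      end_frame = end_frame, no_ts = no_ts, frame_interval = fi),
      class = "intensity_trace")
  }
  traces
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("intensity_trace cell %s: %d frames, end_frame %d%s\n",
              x$cell_id, length(x$intensity), x$end_frame,
              if (x$no_ts) " [no TS]" else ""))
  invisible(x)
}
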