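#' Write intensity traces to CSV
#'
#' Long format: one row per cell and frame with columns `cell_id`, `frame`,
#' `time_s`, `intensity`, `tier`, `x`, `y` (frame 1 at `time_s` 0).
#'
#' @param traces List of `intensity_trace` objects, or a `trace_set`.
#' @param path Output file.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "trace_set")) {
    nf <- nrow(traces$intensity)
    df <- do.call(rbind, lapply(seq_len(traces$n_cells), function(i)
      data.frame(cell_id = i, frame = seq_len(nf),
                 time_s = (seq_len(nf) - 1) * traces$frame_interval,
                 intensity = traces$intensity[, i], tier = NA, x = NA, y = NA)))
  } else {
    df <- do.call(rbind, lapply(traces, function(tr)
      data.frame(cell_id = tr$cell_id, frame = seq_along(tr$intensity),
                 time_s = (seq_along(tr$intensity) - 1) * tr$frame_interval,
                 intensity = tr$intensity, tier = as.character(tr$tier),
                 x = tr$x, y = tr$y)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read intensity traces from CSV
#'
#' @param path CSV written by [write_traces_csv()].
#' @return List of `intensity_trace` objects.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  fi <- if (nrow(df) >= 2) diff(sort(unique(df$time_s)))[1] else NA_real_
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$frame), ]
    tier <- factor(d$tier, levels = c("primary", "fallback", "carried-over"))
    detected <- which(tier %in% c("primary", "fallback"))
    structure(list(cell_id = d$cell_id[1], intensity = d$intensity,
                   x = d$x, y = d$y, tier = tier,
                   end_frame = if (length(detected)) max(detected) else 0L,
                   no_ts = length(detected) == 0,
                   frame_interval = fi), class = "intensity_trace")
  })
}

#' Write / read an image stack as multi-page 32-bit float TIFF
#'
#' Pages are frames; z-stacks are flattened as z-within-t pages and restored
#' from the `n_z` argument on reading. On disk, intensities are stored divided
#' by a fixed scale of 2^16 (float TIFF is defined on [0, 1]); values above
#' 2^16 a.u. would clip and raise an error.
#'
#' @param stack `image_stack` or (y, x, t) / (y, x, z, t) array.
#' @param path TIFF file.
#' @export
write_stack_tiff <- function(stack, path) {
  dat <- stack_data(stack)
  dm <- dim(dat)
  pages <- if (length(dm) == 4)
    lapply(seq_len(dm[3] * dm[4]), function(i) {
      z <- (i - 1) %% dm[3] + 1; t <- (i - 1) %/% dm[3] + 1
      dat[, , z, t]
    })
  else lapply(seq_len(dm[3]), function(t) dat[, , t])
  if (max(dat) >= 65536 || min(dat) < 0)
    stopf("stack intensities must be in [0, 65536) for TIFF export")
  tiff::writeTIFF(lapply(pages, function(p) p / 65536), path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param frame_interval Frame interval, seconds (metadata for the returned
#'   stack).
#' @param n_z Number of z slices per frame.
#' @export
read_stack_tiff <- function(path, frame_interval = NA_real_, n_z = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(unlist(pages), dim = c(ny, nx, length(pages))) * 65536
  if (n_z > 1) {
    nf <- length(pages) / n_z
    arr <- array(arr, dim = c(ny, nx, n_z, nf))
  }
  structure(list(data = arr, frame_interval = frame_interval),
            class = "image_stack")
}

#' Read / write fragment intervals as BED3(+length)
#'
#' Plain 0-based half-open BED: `chrom`, `start`, `end`; a fourth `length`
#' column is written for convenience and ignored on reading.
#'
#' @param fragments Data frame with `chrom`, `start`, `end`.
#' @param path File path.
#' @export
write_fragments_bed <- function(fragments, path) {
  utils::write.table(data.frame(fragments$chrom, fragments$start, fragments$end,
                                fragments$end - fragments$start),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  df <- df[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  df
}

#' Write a normalized coverage track as bedGraph
#'
#' @param coverage A `coverage_track`.
#' @param path Output file.
#' @param which `"norm"` or `"raw"`.
#' @export
write_bedgraph <- function(coverage, path, which = c("norm", "raw")) {
  which <- match.arg(which)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(coverage[[which]])) {
    v <- coverage[[which]][[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      utils::write.table(data.frame(ch, starts[keep], ends[keep], r$values[keep]),
                         con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth A `ground_truth` from [simulate_traces()].
#' @param path JSON file.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    active = truth$active, induction_time = truth$induction_time,
    on_intervals = truth$on_intervals, off_intervals = truth$off_intervals,
    last_interval_censored = truth$last_interval_censored,
    censored_state = truth$censored_state), path, digits = NA, null = "null")
  invisible(path)
}
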