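#' Filter MNase fragments to mono-nucleosome lengths
#'
#' Retains fragments whose length (end - start) lies between 95 and 225 bp
#' inclusive.
#'
#' @param fragments Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param min_len,max_len Inclusive length bounds, bp.
#' @return The retained fragments.
#' @export
filter_fragments <- function(fragments, min_len = 95, max_len = 225) {
  len <- fragments$end - fragments$start
  fragments[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Base-resolution fragment coverage, normalized per chromosome
#'
#' Each fragment increments every base of its span `[start, end)` (one count
#' per read pair); per chromosome, the track is also normalized to total sum
#' 1 so that coverage is comparable across sequencing depths. Fragments
#' extending beyond the chromosome are clipped with a warning.
#'
#' @param fragments Data frame with `chrom`, `start`, `end`.
#' @param chrom_sizes Named vector of chromosome lengths, bp.
#' @return Class `coverage_track`: `raw` and `norm` lists of per-chromosome
#'   vectors (index `i` is base `i - 1`), plus `chrom_sizes`.
#' @export
make_coverage <- function(fragments, chrom_sizes) {
  if (is.null(names(chrom_sizes))) stopf("'chrom_sizes' must be named")
  unknown <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(unknown) > 0) stopf("fragments on unknown chromosome(s): %s",
                                 paste(unknown, collapse = ", "))
  raw <- lapply(names(chrom_sizes), function(ch) numeric(chrom_sizes[[ch]]))
  names(raw) <- names(chrom_sizes)
  clipped <- FALSE
  for (ch in unique(fragments$chrom)) {
    fr <- fragments[fragments$chrom == ch, ]
    L <- chrom_sizes[[ch]]
    s <- fr$start; e <- fr$end
    if (any(s < 0 | e > L)) {
      clipped <- TRUE
      s <- pmax(s, 0); e <- pmin(e, L)
    }
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    ## difference array: +1 at start, -1 at end, cumulative sum
    d <- numeric(L + 1)
    ts <- table(s); te <- table(e)
    d[as.integer(names(ts)) + 1L] <- d[as.integer(names(ts)) + 1L] + as.numeric(ts)
    d[as.integer(names(te)) + 1L] <- d[as.integer(names(te)) + 1L] - as.numeric(te)
    raw[[ch]] <- cumsum(d)[seq_len(L)]
  }
  if (clipped) warnf("fragments extending beyond chromosome bounds were clipped")
  norm <- lapply(raw, function(v) { s <- sum(v); if (s > 0) v / s else v })
  structure(list(raw = raw, norm = norm, chrom_sizes = chrom_sizes),
            class = "coverage_track")
}

## Gaussian smoothing with a 40-bp effective window by default: the "window"
## is read as the kernel FWHM, sigma = fwhm / sqrt(8 log 2). Set sigma
## directly for the raw-sigma interpretation.
#' Gaussian-smooth a coverage vector
#'
#' @param x Numeric vector.
#' @param fwhm Full width at half maximum of the kernel, bp.
#' @param sigma Kernel sigma, bp; overrides `fwhm` when given.
#' @return Smoothed vector of the same length (edge-renormalized kernel).
#' @export
smooth_gaussian <- function(x, fwhm = 40, sigma = NULL) {
  if (is.null(sigma)) sigma <- fwhm / sqrt(8 * log(2))
  half <- ceiling(4 * sigma)
  k <- stats::dnorm(-half:half, 0, sigma)
  n <- length(x)
  num <- stats::convolve(c(rep(0, half), x, rep(0, half)), k, type = "filter")
  den <- stats::convolve(c(rep(0, half), rep(1, n), rep(0, half)), k, type = "filter")
  num / den
}

## TSS-oriented coverage window: positions tss + rel on the Watson strand,
## tss - rel on the Crick strand, rel in -window..window. Bases outside the
## chromosome are NA.
extract_window <- function(track_vec, tss, strand, window) {
  rel <- -window:window
  pos <- if (strand == "-") tss - rel else tss + rel
  ok <- pos >= 0 & pos < length(track_vec)
  out <- rep(NA_real_, length(rel))
  out[ok] <- track_vec[pos[ok] + 1L]
  out
}

## Local maxima with a minimum prominence and minimum separation.
find_peaks <- function(x, min_prominence = 0, min_sep = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  ## plateau-safe local maxima via run-length encoding
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  cand <- integer(0)
  for (i in seq_len(k)) {
    left <- if (i == 1) -Inf else r$values[i - 1]
    right <- if (i == k) -Inf else r$values[i + 1]
    if (r$values[i] > left && r$values[i] > right)
      cand <- c(cand, (starts[i] + ends[i]) %/% 2L)
  }
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(p) {
    v <- x[p]
    lmin <- v; i <- p
    while (i > 1 && x[i] <= v) { lmin <- min(lmin, x[i]); i <- i - 1 }
    if (x[i] <= v) lmin <- min(lmin, x[i])   # reached the edge without a higher peak
    rmin <- v; i <- p
    while (i < n && x[i] <= v) { rmin <- min(rmin, x[i]); i <- i + 1 }
    if (x[i] <= v) rmin <- min(rmin, x[i])
    v - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1 || min_sep <= 1) return(sort(keep))
  ## greedy separation: keep higher peaks first
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (p in ord) if (all(abs(p - sel) >= min_sep)) sel <- c(sel, p)
  sort(sel)
}

#' Call -1/+1 promoter nucleosomes from pooled reference coverage
#'
#' Per gene: the prenormalization coverage in a `2 x window` bp region around
#' the TSS is extracted from every reference track, flipped for Crick-strand
#' genes, summed, and smoothed with a Gaussian filter (40-bp window). The
#' global minimum of the smoothed profile marks the nucleosome-depleted
#' region; nucleosome peaks are called as local maxima with prominence at
#' least `min_prominence_frac` of the window maximum and pairwise separation
#' `min_sep`. The -1 nucleosome is the last peak before the minimum and the
#' +1 nucleosome the first peak after it. Genes with fewer than two peaks, or
#' whose -1 or +1 lies more than `max_tss_dist` bp from the TSS, are
#' excluded (reason recorded), as are genes without coverage.
#'
#' @param coverage_sets A `coverage_track` or list of them (reference pool).
#' @param genes Data frame: `gene`, `chrom`, `strand`, `tss` (bp, 0-based).
#' @param window Half-window around the TSS, bp.
#' @param fwhm Gaussian smoothing window (FWHM), bp.
#' @param min_prominence_frac Peak prominence threshold, fraction of the
#'   window maximum.
#' @param min_sep Minimum peak separation, bp.
#' @param max_tss_dist Exclusion distance from the TSS, bp.
#' @return Class `nucleosome_calls` (data frame): `gene`, `minus_one`,
#'   `plus_one` (bp relative to the TSS, downstream positive), `ndr_width`,
#'   `excluded`, `reason`.
#' @export
call_plus_one <- function(coverage_sets, genes, window = 2000, fwhm = 40,
                          min_prominence_frac = 0.05, min_sep = 100,
                          max_tss_dist = 1000) {
  if (inherits(coverage_sets, "coverage_track")) coverage_sets <- list(coverage_sets)
  rel <- -window:window
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    out <- data.frame(gene = g$gene, minus_one = NA_real_, plus_one = NA_real_,
                      ndr_width = NA_real_, excluded = TRUE, reason = "")
    win <- NULL
    for (cv in coverage_sets) {
      v <- cv$raw[[g$chrom]]
      if (is.null(v)) next
      w <- extract_window(v, g$tss, g$strand, window)
      win <- if (is.null(win)) w else win + w
    }
    if (is.null(win) || all(is.na(win)) || sum(win, na.rm = TRUE) == 0) {
      out$reason <- "no-data"
      return(out)
    }
    truncated <- anyNA(win)
    win[is.na(win)] <- 0
    sm <- smooth_gaussian(win, fwhm = fwhm)
    mn <- which.min(sm)
    pk <- find_peaks(sm, min_prominence = min_prominence_frac * max(sm),
                     min_sep = min_sep)
    if (length(pk) < 2) { out$reason <- "fewer-than-two-peaks"; return(out) }
    before <- pk[pk < mn]; after <- pk[pk > mn]
    if (length(before) == 0 || length(after) == 0) {
      out$reason <- "fewer-than-two-peaks"
      return(out)
    }
    m1 <- rel[max(before)]; p1 <- rel[min(after)]
    if (abs(m1) > max_tss_dist || abs(p1) > max_tss_dist) {
      out$reason <- sprintf(">%d bp", max_tss_dist)
      return(out)
    }
    out$minus_one <- m1; out$plus_one <- p1
    out$ndr_width <- p1 - m1
    out$excluded <- FALSE
    out$reason <- if (truncated) "window-truncated" else ""
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("nucleosome_calls", "data.frame")
  res
}

## Genomic position of a TSS-relative offset.
genomic_pos <- function(tss, strand, rel) if (strand == "-") tss - rel else tss + rel

#' Metagene coverage profile aligned at the +1 nucleosome
#'
#' Averages the normalized, strand-oriented coverage of all included genes in
#' a 2,000-bp window centred on each gene's reference +1 nucleosome position.
#'
#' @param coverage A `coverage_track`.
#' @param calls `nucleosome_calls` giving the reference +1 per gene.
#' @param genes The gene table used for the calls.
#' @param window Half-window, bp (profile length `2 * window + 1`).
#' @return Numeric profile with attribute `n_genes`; positions run from
#'   `-window` to `window` relative to the +1 nucleosome.
#' @export
metagene_profile <- function(coverage, calls, genes, window = 1000) {
  inc <- calls[!calls$excluded, ]
  if (nrow(inc) == 0) stopf("no included genes for the metagene profile")
  acc <- numeric(2 * window + 1)
  n <- 0
  for (i in seq_len(nrow(inc))) {
    g <- genes[genes$gene == inc$gene[i], ]
    center <- genomic_pos(g$tss, g$strand, inc$plus_one[i])
    w <- extract_window(coverage$norm[[g$chrom]], center, g$strand, window)
    w[is.na(w)] <- 0
    acc <- acc + w
    n <- n + 1
  }
  structure(acc / n, n_genes = n, positions = -window:window)
}

#' Gene-by-position log2 fold-change matrix, sorted by NDR width
#'
#' For every included gene, `log2((depleted + eps) / (mean control + eps))`
#' over the window centred on the reference +1 nucleosome, computed on the
#' normalized tracks; rows are ordered by ascending NDR width so that
#' remodeler-dependent NDR filling appears as a coherent band.
#'
#' @param depleted A `coverage_track` (depletion condition).
#' @param control_replicates List of `coverage_track`s (unperturbed
#'   replicates; averaged).
#' @param calls,genes Reference calls and gene table.
#' @param window Half-window, bp.
#' @param eps Pseudo-count on the normalized scale; default is the uniform
#'   per-base value of the normalized track (1 / chromosome length) divided by
#'   the window length, i.e. small against any real coverage.
#' @return Matrix (genes x positions) with NDR widths as the `ndr_width`
#'   attribute; rownames are gene names.
#' @export
log2fc_matrix <- function(depleted, control_replicates, calls, genes,
                          window = 1000, eps = NULL) {
  if (inherits(control_replicates, "coverage_track"))
    control_replicates <- list(control_replicates)
  inc <- calls[!calls$excluded, ]
  inc <- inc[order(inc$ndr_width), ]
  mat <- matrix(NA_real_, nrow(inc), 2 * window + 1,
                dimnames = list(inc$gene, -window:window))
  for (i in seq_len(nrow(inc))) {
    g <- genes[genes$gene == inc$gene[i], ]
    center <- genomic_pos(g$tss, g$strand, inc$plus_one[i])
    eps_i <- eps %||% (1 / (length(depleted$norm[[g$chrom]]) * (2 * window + 1)))
    dep <- extract_window(depleted$norm[[g$chrom]], center, g$strand, window)
    ctl <- rowMeans(vapply(control_replicates, function(cv)
      extract_window(cv$norm[[g$chrom]], center, g$strand, window),
      numeric(2 * window + 1)))
    mat[i, ] <- log2((dep + eps_i) / (ctl + eps_i))
  }
  attr(mat, "ndr_width") <- inc$ndr_width
  mat
}

#' Shift of the +1 nucleosome upon depletion
#'
#' Per gene called in both conditions, the difference between the +1 position
#' in the depleted condition and in the unperturbed reference, in
#' TSS-oriented coordinates (negative values move the +1 toward the
#' NDR/TSS). Medians are reported per promoter class (TATA vs
#' TATA-mismatch).
#'
#' @param depleted_calls,reference_calls `nucleosome_calls` for the two
#'   conditions.
#' @param genes Gene table with a `class` column.
#' @return List: `shifts` data frame (`gene`, `class`, `shift`) and `medians`
#'   (named by class).
#' @export
plus_one_shift <- function(depleted_calls, reference_calls, genes) {
  dep <- depleted_calls[!depleted_calls$excluded, c("gene", "plus_one")]
  ref <- reference_calls[!reference_calls$excluded, c("gene", "plus_one")]
  m <- merge(dep, ref, by = "gene", suffixes = c("_dep", "_ref"))
  m <- merge(m, genes[, c("gene", "class")], by = "gene")
  shifts <- data.frame(gene = m$gene, class = m$class,
                       shift = m$plus_one_dep - m$plus_one_ref)
  medians <- tapply(shifts$shift, shifts$class, stats::median)
  list(shifts = shifts, medians = medians)
}

#' Normalized coverage over the 8-bp TATA (or TATA-mismatch) window
#'
#' @param coverage A `coverage_track`.
#' @param genes Gene table with `tata_start` (bp, 0-based; genes with `NA`
#'   are skipped) and `chrom`.
#' @param width Window width, bp.
#' @return Named numeric vector of per-gene window sums (normalized scale).
#' @export
tata_window_coverage <- function(coverage, genes, width = 8) {
  keep <- !is.na(genes$tata_start)
  g <- genes[keep, ]
  out <- vapply(seq_len(nrow(g)), function(i) {
    v <- coverage$norm[[g$chrom[i]]]
    idx <- g$tata_start[i] + seq_len(width) - 1L  # bases [tata_start, tata_start + width)
    idx <- idx[idx >= 0 & idx < length(v)]
    sum(v[idx + 1L])
  }, numeric(1))
  names(out) <- g$gene
  out
}
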