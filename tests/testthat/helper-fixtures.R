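# Shared fixtures, built in code at test time.

# Noiseless image with one pixel-integrated Gaussian spot.
spot_image <- function(I = 1000, x0 = 20.3, y0 = 21.7, sigma = 1.3,
                       size = 41, bg = 10) {
  burstepi:::add_gaussian_spot(matrix(bg, size, size), x0, y0, I, sigma)
}

# Two-disk segmentation fixture; centers as a list of c(row, col).
disk_image <- function(centers, radius = 15, size = 100, value = 100) {
  img <- matrix(0, size, size)
  for (ctr in centers) {
    for (r in seq_len(size)) {
      cc <- which((r - ctr[1])^2 + (seq_len(size) - ctr[2])^2 < radius^2)
      img[r, cc] <- value
    }
  }
  img
}

# Logical vector -> binary_trace.
as_binary <- function(on, frame_interval = 15) {
  structure(as.logical(on), frame_interval = frame_interval,
            class = "binary_trace")
}

# Small planted promoter landscape with matched reference/depleted coverage.
mnase_fixture <- function(n_genes = 8, frags_per_gene = 10000, shift = 40,
                          ndr_jitter = 120, seed = 2) {
  arch <- promoter_architecture(n_genes = n_genes, ndr_jitter = ndr_jitter,
                                seed = seed)
  arch_dep <- promoter_architecture(n_genes = n_genes, ndr_jitter = ndr_jitter,
                                    plus_one_shift = shift, seed = seed)
  cov_ref <- make_coverage(
    filter_fragments(simulate_mnase(nuc_sim_model(
      arch$chrom_sizes, arch$nucleosomes,
      n_fragments = n_genes * frags_per_gene, seed = seed + 100))),
    arch$chrom_sizes)
  cov_dep <- make_coverage(
    filter_fragments(simulate_mnase(nuc_sim_model(
      arch$chrom_sizes, arch_dep$nucleosomes,
      n_fragments = n_genes * frags_per_gene, seed = seed + 200))),
    arch$chrom_sizes)
  list(arch = arch, cov_ref = cov_ref, cov_dep = cov_dep)
}

# Exact two-sided Fisher p by enumeration over the hypergeometric support.
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  p_obs <- pr[k == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
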