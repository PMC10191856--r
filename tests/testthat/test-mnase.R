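test_that("fragment filter keeps the inclusive 95-225 bp set", {
  fr <- data.frame(chrom = "c", start = 0, end = c(94, 95, 150, 225, 226))
  kept <- filter_fragments(fr)
  expect_equal(kept$end, c(95, 150, 225))
  expect_equal(nrow(filter_fragments(fr[0, ])), 0)
  # generator fixture with all 80-bp fragments is removed entirely
  mod <- nuc_sim_model(c(chrT = 2000),
                       data.frame(chrom = "chrT", center = 1000, occupancy = 1),
                       n_fragments = 500, frag_mean = 80, frag_sd = 0.01, seed = 1)
  expect_equal(nrow(filter_fragments(simulate_mnase(mod))), 0)
})

test_that("coverage counts full fragment spans and normalizes per chromosome", {
  cov <- make_coverage(data.frame(chrom = "c1", start = 10, end = 25),
                       c(c1 = 100))
  expect_equal(cov$norm$c1[11:25], rep(1 / 15, 15))
  expect_equal(sum(cov$norm$c1[-(11:25)]), 0)
  expect_equal(cov$raw$c1[11], 1)
  # duplicated fragments leave the normalized track unchanged
  cov2 <- make_coverage(data.frame(chrom = "c1", start = c(10, 10),
                                   end = c(25, 25)), c(c1 = 100))
  expect_equal(cov2$norm$c1, cov$norm$c1)
  # chromosomes normalize independently to sum 1
  cov3 <- make_coverage(data.frame(chrom = c("c1", "c2", "c2"),
                                   start = c(5, 10, 40), end = c(30, 20, 90)),
                        c(c1 = 100, c2 = 200))
  expect_lt(abs(sum(cov3$norm$c1) - 1), 1e-9)
  expect_lt(abs(sum(cov3$norm$c2) - 1), 1e-9)
  expect_warning(make_coverage(data.frame(chrom = "c1", start = 90, end = 120),
                               c(c1 = 100)), "clipped")
})

test_that("peak finding respects prominence and separation", {
  x <- dnorm(1:400, 100, 30) + 0.6 * dnorm(1:400, 300, 30)
  pk <- burstepi:::find_peaks(x, min_prominence = 0.05 * max(x), min_sep = 100)
  expect_equal(length(pk), 2)
  expect_lt(abs(pk[1] - 100), 3)
  expect_lt(abs(pk[2] - 300), 3)
  # a shallow ripple below the prominence floor is not a peak
  y <- x; y[200] <- y[200] + 1e-5
  expect_equal(length(burstepi:::find_peaks(y, min_prominence = 0.05 * max(y),
                                            min_sep = 100)), 2)
})

test_that("planted promoter geometry is recovered within 10 bp", {
  fx <- mnase_fixture(n_genes = 6, ndr_jitter = 0, seed = 3)
  calls <- call_plus_one(fx$cov_ref, fx$arch$genes)
  expect_false(any(calls$excluded))
  expect_true(all(abs(calls$plus_one - 120) <= 10))
  expect_true(all(abs(calls$minus_one - (-180)) <= 10))
  expect_true(all(abs(calls$ndr_width - 300) <= 15))
})

test_that("strand mirroring leaves TSS-oriented calls unchanged", {
  fx <- mnase_fixture(n_genes = 6, ndr_jitter = 60, seed = 4)
  genes <- fx$arch$genes
  calls <- call_plus_one(fx$cov_ref, genes)
  # mirror every gene onto the Crick strand with mirrored coverage
  L <- fx$arch$chrom_sizes[["chrSim"]]
  mirrored <- fx$cov_ref
  mirrored$raw$chrSim <- rev(mirrored$raw$chrSim)
  mirrored$norm$chrSim <- rev(mirrored$norm$chrSim)
  genes_m <- genes
  genes_m$tss <- L - 1 - genes$tss
  genes_m$strand <- ifelse(genes$strand == "+", "-", "+")
  calls_m <- call_plus_one(mirrored, genes_m)
  expect_equal(calls_m$plus_one, calls$plus_one)
  expect_equal(calls_m$minus_one, calls$minus_one)
})

test_that("exclusion rules fire for sparse or distant architectures", {
  # single isolated peak: fewer than two peaks in the window
  mod <- nuc_sim_model(c(chrT = 6000),
                       data.frame(chrom = "chrT", center = 3000, occupancy = 1),
                       n_fragments = 5000, seed = 5)
  cov <- make_coverage(filter_fragments(simulate_mnase(mod)), c(chrT = 6000))
  genes <- data.frame(gene = "g1", chrom = "chrT", strand = "+", tss = 3000,
                      tata_start = 2900, class = "TATA")
  calls <- call_plus_one(cov, genes)
  expect_true(calls$excluded)
  expect_equal(calls$reason, "fewer-than-two-peaks")
  # +1 planted beyond 1000 bp from the TSS (very wide NDR inside full arrays)
  arch_far <- promoter_architecture(n_genes = 1, minus_one = -200,
                                    plus_one = 1200, seed = 6)
  mod2 <- nuc_sim_model(arch_far$chrom_sizes, arch_far$nucleosomes,
                        n_fragments = 30000, seed = 6)
  cov2 <- make_coverage(filter_fragments(simulate_mnase(mod2)),
                        arch_far$chrom_sizes)
  calls2 <- call_plus_one(cov2, arch_far$genes)
  expect_true(calls2$excluded)
  expect_equal(calls2$reason, ">1000 bp")
  # a gene with no coverage at all
  genes_nc <- data.frame(gene = "g2", chrom = "chrT", strand = "+", tss = 3000,
                         tata_start = NA, class = "unknown")
  empty <- make_coverage(data.frame(chrom = "chrT", start = 1, end = 2)[0, ],
                         c(chrT = 6000))
  expect_equal(call_plus_one(empty, genes_nc)$reason, "no-data")
})

test_that("metagene profiles align included genes at the +1 nucleosome", {
  fx <- mnase_fixture(n_genes = 6, ndr_jitter = 0, seed = 7)
  calls <- call_plus_one(fx$cov_ref, fx$arch$genes)
  mg <- metagene_profile(fx$cov_ref, calls, fx$arch$genes, window = 400)
  pos <- attr(mg, "positions")
  # a local maximum sits at the alignment centre and the NDR trough upstream
  expect_lt(abs(pos[which.max(mg[pos >= -80 & pos <= 80]) + sum(pos < -80)]), 16)
  expect_lt(min(mg[pos < -100 & pos > -250]), 0.5 * max(mg))
  # single gene: profile equals that gene's own window
  one <- calls[1, ]
  mg1 <- metagene_profile(fx$cov_ref, one, fx$arch$genes, window = 200)
  expect_equal(attr(mg1, "n_genes"), 1)
  # excluded genes contribute nothing
  calls_x <- calls; calls_x$excluded[2:6] <- TRUE
  mg2 <- metagene_profile(fx$cov_ref, calls_x, fx$arch$genes, window = 200)
  expect_equal(as.numeric(mg2), as.numeric(mg1))
  expect_error(metagene_profile(fx$cov_ref, calls[calls$excluded, ],
                                fx$arch$genes), "no included genes")
})

test_that("log2 fold-change matrices are zero for identical conditions and sorted", {
  fx <- mnase_fixture(n_genes = 6, ndr_jitter = 120, seed = 8)
  calls <- call_plus_one(fx$cov_ref, fx$arch$genes)
  m0 <- log2fc_matrix(fx$cov_ref, list(fx$cov_ref), calls, fx$arch$genes,
                      window = 300)
  expect_true(all(abs(m0) < 1e-12))
  # doubled coverage: ratios of normalized tracks stay 1 (depth-invariant)
  dbl <- fx$cov_ref
  dbl$norm <- lapply(dbl$norm, function(v) v)  # normalized scale already depth-free
  expect_equal(attr(m0, "ndr_width"), sort(attr(m0, "ndr_width")))
  # a genuinely doubled normalized track gives log2 FC of 1
  fake <- fx$cov_ref
  fake$norm$chrSim <- fake$norm$chrSim * 2
  m1 <- log2fc_matrix(fake, list(fx$cov_ref), calls, fx$arch$genes, window = 300)
  # covered bases read log2(2) = 1; only zero-coverage bases are damped to 0
  expect_lt(abs(median(m1) - 1), 0.05)
  expect_true(all(m1 >= 0 & m1 <= 1.001))
})

test_that("+1 shifts and TATA-window coverage read out planted remodeling", {
  fx <- mnase_fixture(n_genes = 8, frags_per_gene = 10000, shift = 40,
                      ndr_jitter = 120, seed = 2)
  calls_ref <- call_plus_one(fx$cov_ref, fx$arch$genes)
  calls_dep <- call_plus_one(fx$cov_dep, fx$arch$genes)
  sh <- plus_one_shift(calls_dep, calls_ref, fx$arch$genes)
  expect_true(all(abs(sh$shifts$shift - 40) <= 15))
  expect_true(all(abs(sh$medians - 40) <= 10))
  # identical conditions: all shifts zero
  sh0 <- plus_one_shift(calls_ref, calls_ref, fx$arch$genes)
  expect_true(all(sh0$shifts$shift == 0))
  # genes excluded in one condition drop out of the shift set
  calls_x <- calls_dep; calls_x$excluded[1] <- TRUE
  shx <- plus_one_shift(calls_x, calls_ref, fx$arch$genes)
  expect_false(fx$arch$genes$gene[1] %in% shx$shifts$gene)
  # uniform coverage sums to 8 x the per-base value over the TATA window
  covu <- make_coverage(data.frame(chrom = "chrSim", start = 0,
                                   end = fx$arch$chrom_sizes[["chrSim"]]),
                        fx$arch$chrom_sizes)
  tw <- tata_window_coverage(covu, fx$arch$genes)
  expect_equal(unname(tw), rep(8 / fx$arch$chrom_sizes[["chrSim"]], 8),
               tolerance = 1e-12)
})
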