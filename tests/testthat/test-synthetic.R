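group_cols <- c("G80", "G100", "G120", "G140", "G168")

test_that("fragment placement follows the retained-edge geometry", {
  sym <- state_mixture(unwrap_state("core", 147, 1e-6, "symmetric", 1))
  set.seed(1)
  fr <- sample_fragments(rep(1000L, 5), sym)
  expect_true(all((fr$start + fr$end) %/% 2L == 1000L))
  expect_true(all(fr$end - fr$start == 147L))
  # L = 60, left edge retained: span [927, 987), center 957 (43 bp left of dyad)
  left <- state_mixture(unwrap_state("l", 60, 1e-6, "left_retained", 1))
  fr_l <- sample_fragments(1000L, left)
  expect_equal(fr_l$start, 927L)
  expect_equal(fr_l$end, 987L)
  expect_equal((fr_l$start + fr_l$end) %/% 2L, 957L)
  # right edge retained mirrors: span [1013, 1073), center 1043
  right <- state_mixture(unwrap_state("r", 60, 1e-6, "right_retained", 1))
  fr_r <- sample_fragments(1000L, right)
  expect_equal(fr_r$start, 1013L)
  expect_equal(fr_r$end, 1073L)
  expect_equal((fr_r$start + fr_r$end) %/% 2L, 1043L)
})

test_that("equal left/right retained weights give symmetric center offsets", {
  mix <- state_mixture(
    unwrap_state("l", 60, 8, "left_retained", 0.5),
    unwrap_state("r", 60, 8, "right_retained", 0.5)
  )
  set.seed(2)
  fr <- sample_fragments(rep(5000L, 1e4), mix)
  offs <- (fr$start + fr$end) %/% 2L - 5000L
  nz <- offs[offs != 0]
  bt <- stats::binom.test(sum(nz > 0), length(nz), 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_histone_sample(mixture_canonical_longmn(), 1, seed = 3)
  b <- simulate_histone_sample(mixture_canonical_longmn(), 1, seed = 3)
  expect_identical(a, b)
  l1 <- simulate_tss_landscape(n_genes = 30, seed = 4, frags_plus1 = 50,
                               frags_other = 20)
  l2 <- simulate_tss_landscape(n_genes = 30, seed = 4, frags_plus1 = 50,
                               frags_other = 20)
  expect_identical(l1, l2)
  c1 <- simulate_cbs_landscape(n_cbs = 10, seed = 5, frags_per_nuc = 40)
  c2 <- simulate_cbs_landscape(n_cbs = 10, seed = 5, frags_per_nuc = 40)
  expect_identical(c1, c2)
})

test_that("empirical mode fractions converge to the planted weights", {
  n <- 1e5
  fs <- simulate_histone_sample(mixture_canonical_longmn(), n, seed = 6)
  lens <- fs$fragments$length
  planted <- c(`147` = 0.45, `127` = 0.20, `105` = 0.15, `91` = 0.12, `69` = 0.08)
  modes <- as.integer(names(planted))
  nearest <- modes[max.col(-abs(outer(lens, modes, "-")))]
  for (m in names(planted)) {
    got <- mean(nearest == as.integer(m))
    se <- sqrt(planted[[m]] * (1 - planted[[m]]) / n)
    # 3 binomial SEs plus the small mass each mode loses across the
    # nearest-mode boundaries (sd 3 vs gaps >= 14 bp)
    expect_lt(abs(got - planted[[m]]), 3 * se + 0.004)
  }
})

test_that("the variant-histone mixture is dominated by 30-80 bp fragments", {
  fs <- simulate_histone_sample(mixture_h2az_longmn(), 2e5, seed = 7)
  lens <- fs$fragments$length
  expect_gt(mean(lens >= 30 & lens <= 80), 0.5)
})

test_that("invalid mixtures are rejected", {
  expect_error(state_mixture(unwrap_state("a", 100, 5, "symmetric", 0.7)), "sum")
  expect_error(unwrap_state("a", 10, 5, "symmetric", 1), "length_mode")
  expect_error(unwrap_state("a", 100, 0, "symmetric", 1), "length_sd")
})

test_that("promoter landscapes respect strand and plant per-class weights", {
  land <- simulate_tss_landscape(n_genes = 60, seed = 8, frags_plus1 = 500,
                                 frags_other = 0, n_other_nucs = 0)
  tr <- land$truth
  d <- (tr$plus1_dyad - tr$tss) * ifelse(tr$strand == "-", -1L, 1L)
  expect_true(all(d >= 50 & d <= 200))
  # for a planted class-A gene, G80 has the largest window ratio
  centers <- reference_points(tr$chrom, tr$plus1_dyad, kind = "NUC_CENTER",
                              name = tr$gene_id)
  tab <- window_group_ratios(land$fragments, windows_around(centers, 100))
  rm_ <- ratio_matrix(tab)
  for (cl in c("A", "C", "E")) {
    genes <- tr$gene_id[tr$cluster == cl]
    dominant <- names(which.max(colMeans(rm_[rownames(rm_) %in% genes, , drop = FALSE])))
    expect_equal(dominant, group_cols[match(cl, c("A", "B", "C", "D", "E"))])
  }
  expect_error(simulate_tss_landscape(n_genes = 5, seed = 1), "n_genes")
})

test_that("expression tiers tilt weights in opposite directions for G80 and G168", {
  land <- simulate_tss_landscape(n_genes = 300, seed = 9, frags_plus1 = 50,
                                 frags_other = 0, n_other_nucs = 0,
                                 cluster_boost = 0)
  tr <- land$truth
  expect_lt(mean(tr$w_G80[tr$tier == "high"]), mean(tr$w_G80[tr$tier == "low"]))
  expect_gt(mean(tr$w_G168[tr$tier == "high"]), mean(tr$w_G168[tr$tier == "low"]))
})

test_that("CBS landscapes plant footprints and flanking dyads as declared", {
  land <- simulate_cbs_landscape(n_cbs = 40, seed = 10, frags_per_nuc = 100,
                                 footprint_weight = 0)
  f <- land$fragments$fragments
  near_center <- outer(f$center, land$truth$center, function(a, b) abs(a - b) <= 20)
  short <- f$length >= 30 & f$length <= 55
  expect_equal(sum(short & rowSums(near_center) > 0), 0L)
  # with footprints, short fragments pile up at the center
  land2 <- simulate_cbs_landscape(n_cbs = 40, seed = 10, frags_per_nuc = 100,
                                  footprint_weight = 0.15)
  f2 <- land2$fragments$fragments
  near2 <- outer(f2$center, land2$truth$center, function(a, b) abs(a - b) <= 20)
  short2 <- f2$length >= 30 & f2$length <= 55
  expect_gt(sum(short2 & rowSums(near2) > 0), 0L)
  # truth lists the two first flanking dyads at the declared distance
  d <- land$params$ndr_halfwidth + 73L
  expect_equal(land$truth$flank_dyad_left, land$truth$center - d)
  expect_equal(land$truth$flank_dyad_right, land$truth$center + d)
})

test_that("knockdown pairs share structure and shift mass to long fragments", {
  p0 <- simulate_knockdown("tss", shift = 0, seed = 11, n_genes = 40,
                           frags_plus1 = 60, frags_other = 20)
  expect_identical(p0$wt, p0$kd)
  shift <- 0.2
  pair <- simulate_knockdown("tss", shift = shift, seed = 11, n_genes = 200,
                             frags_plus1 = 200, frags_other = 50)
  expect_identical(pair$wt$tss, pair$kd$tss)
  expect_identical(pair$wt$truth$plus1_dyad, pair$kd$truth$plus1_dyad)
  lw <- pair$wt$fragments$fragments$length
  lk <- pair$kd$fragments$fragments$length
  gain <- mean(lk >= 120 & lk <= 168) - mean(lw >= 120 & lw <= 168)
  se <- sqrt(0.5 * 0.5 * (1 / length(lw) + 1 / length(lk)))
  # transferred mass, allowing binomial error plus normal-tail leakage
  # of the group length distributions across the 120-bp boundary
  expect_lt(abs(gain - shift), 3 * se + 0.02)
  expect_error(simulate_knockdown("tss", shift = 0.95, seed = 1, n_genes = 20,
                                  frags_plus1 = 20, frags_other = 0),
               "shift")
})
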