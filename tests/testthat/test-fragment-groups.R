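test_that("group boundaries are inclusive and partition 30-168 exactly", {
  scheme <- fragment_group_scheme()
  expect_equal(as.character(assign_group(c(80, 81, 141), scheme)),
               c("G80", "G100", "G168"))
  expect_equal(as.character(assign_group(168, scheme)), "G168")
  expect_true(all(is.na(assign_group(c(29, 169), scheme))))
  # exhaustive scan: every in-range length maps to exactly one group
  g <- assign_group(30:168, scheme)
  expect_false(anyNA(g))
  expect_equal(as.vector(table(g)), c(51L, 20L, 20L, 20L, 28L))
})

test_that("the stricter 35-bp lower bound is available", {
  scheme35 <- fragment_group_scheme(min_small = 35)
  expect_true(is.na(assign_group(34, scheme35)))
  expect_equal(as.character(assign_group(35, scheme35)), "G80")
})

test_that("window ratios match a hand count and sum to one", {
  lens <- c(rep(40, 4), rep(90, 2), 110, rep(130, 2), 150)
  start <- 1000L - lens %/% 2L  # all centered at 1000
  fs <- fragment_set("chrS", start, start + lens, label = "toy")
  win <- data.frame(chrom = "chrS", start = 900L, end = 1100L, name = "w1")
  tab <- window_group_ratios(fs, win, min_fragments = 5)
  expect_equal(unname(unlist(tab[1, paste0("ratio_", c("G80", "G100", "G120", "G140", "G168"))])),
               c(0.4, 0.2, 0.1, 0.2, 0.1))
  expect_equal(tab$total, 10L)
  expect_true(tab$pass)
  # a 200-bp fragment centered in the window is outside the scheme
  fs2 <- fragment_set("chrS", c(start, 900L), c(start + lens, 1100L), label = "toy")
  tab2 <- window_group_ratios(fs2, win, min_fragments = 5)
  expect_equal(tab2$total, 10L)
  expect_equal(sum(tab2[1, paste0("ratio_", c("G80", "G100", "G120", "G140", "G168"))]), 1)
})

test_that("window membership is by fragment center, half-open", {
  # length-56 fragments (G80); centers at start + 28
  fs <- fragment_set("chrS", c(72L, 71L, 172L), c(128L, 127L, 228L), label = "edge")
  # centers: 100, 99, 200; window [100, 200) -> only center 100 inside
  win <- data.frame(chrom = "chrS", start = 100L, end = 200L, name = "w")
  tab <- window_group_ratios(fs, win, min_fragments = 1)
  expect_equal(tab$total, 1L)
})

test_that("per-window group counts conserve the in-range total (brute force)", {
  fs <- random_fragment_set(600, seed = 11, len_min = 20, len_max = 190)
  set.seed(12)
  centers <- reference_points("chrS", sample.int(9e4, 20) + 1000L,
                              kind = "NUC_CENTER")
  wins <- windows_around(centers, 100)
  tab <- window_group_ratios(fs, wins, min_fragments = 1)
  f <- fs$fragments
  for (i in seq_len(nrow(wins))) {
    inwin <- f$center >= wins$start[i] & f$center < wins$end[i] &
      f$length >= 30 & f$length <= 168
    expect_equal(tab$total[i], sum(inwin))
    expect_equal(sum(tab[i, paste0("count_", c("G80", "G100", "G120", "G140", "G168"))]),
                 sum(inwin))
  }
  ok <- tab$total > 0
  sums <- rowSums(tab[ok, paste0("ratio_", c("G80", "G100", "G120", "G140", "G168"))])
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("+1 selection applies the 50-200 bp strand-aware rule", {
  tss <- reference_points("chrS", 1000L, "+", kind = "TSS", name = "g1")
  centers <- reference_points("chrS", c(1030L, 1100L), kind = "NUC_CENTER")
  sel <- select_plus1(centers, tss)
  expect_equal(sel$plus1, 1100L)  # 1030 is outside [1050, 1200]
  tss_m <- reference_points("chrS", 1000L, "-", kind = "TSS", name = "g2")
  sel_m <- select_plus1(reference_points("chrS", 900L, kind = "NUC_CENTER"), tss_m)
  expect_equal(sel_m$plus1, 900L)  # downstream = decreasing coordinate
  # nearest wins; genes without candidates are omitted
  tss2 <- reference_points("chrS", c(1000L, 5000L), c("+", "+"), kind = "TSS",
                           name = c("g1", "g2"))
  centers2 <- reference_points("chrS", c(1060L, 1190L), kind = "NUC_CENTER")
  expect_message(sel2 <- select_plus1(centers2, tss2), "1 of 2")
  expect_equal(nrow(sel2), 1L)
  expect_equal(sel2$plus1, 1060L)
})

test_that("mirroring coordinates and flipping strands mirrors +1 selection", {
  set.seed(21)
  M <- 2e5L
  tss <- reference_points("chrS", sort(sample.int(1e5, 30)) + 10000L,
                          sample(c("+", "-"), 30, TRUE), kind = "TSS",
                          name = sprintf("g%02d", 1:30))
  centers <- reference_points("chrS", sample.int(12e4, 200) + 5000L,
                              kind = "NUC_CENTER")
  sel <- suppressMessages(select_plus1(centers, tss))
  tss_m <- tss
  tss_m$pos <- M - tss$pos
  tss_m$strand <- ifelse(tss$strand == "+", "-", "+")
  centers_m <- centers
  centers_m$pos <- M - centers$pos
  sel_m <- suppressMessages(select_plus1(centers_m, tss_m))
  sel_m <- sel_m[match(sel$gene, sel_m$gene), ]
  expect_equal(sel_m$plus1, M - sel$plus1)
  expect_equal(sel_m$distance, sel$distance)
})

test_that("group tracks are RPM-scaled and sum to the combined track", {
  fs <- fragment_set("chrS", 100L, 160L, label = "one")  # length 60 -> G80
  tr <- group_tracks(fs)
  expect_equal(tr$G80$value, 1e6)
  expect_equal(tr$G80$start, 130L %/% 10L * 10L)
  expect_equal(nrow(tr$G168), 0L)
  fs2 <- random_fragment_set(500, seed = 3)
  tr2 <- group_tracks(fs2)
  pool <- do.call(rbind, tr2[c("G80", "G100", "G120", "G140", "G168")])
  summed <- stats::aggregate(value ~ chrom + start + end, pool, sum)
  summed <- summed[order(summed$start), ]
  comb <- tr2$combined[order(tr2$combined$start), ]
  expect_equal(summed$start, comb$start)
  expect_equal(summed$value, comb$value)
})

test_that("interval overlap classification covers boundary cases", {
  a <- data.frame(chrom = "chr1", start = c(0L, 500L), end = c(100L, 600L))
  ident <- interval_overlap(a, a)
  expect_equal(unname(ident$counts), c(0L, 0L, 4L))
  b <- data.frame(chrom = "chr1", start = 1000L, end = 1100L)
  disj <- interval_overlap(a, b)
  expect_equal(unname(disj$counts["shared"]), 0L)
  expect_equal(unname(disj$counts["a_specific"]), 2L)
  # 1-bp overlap counts as shared
  c1 <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  c2 <- data.frame(chrom = "chr1", start = 99L, end = 200L)
  expect_equal(unname(interval_overlap(c1, c2)$counts["shared"]), 2L)
  # touching half-open intervals do not overlap
  c3 <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  expect_equal(unname(interval_overlap(c1, c3)$counts["shared"]), 0L)
})
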