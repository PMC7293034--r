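group_cols <- c("G80", "G100", "G120", "G140", "G168")

toy_ratio_table <- function(m) {
  # wrap a ratio matrix as a minimal GroupRatioTable
  tab <- data.frame(window = rownames(m) %||% paste0("w", seq_len(nrow(m))),
                    stringsAsFactors = FALSE)
  for (g in colnames(m)) tab[[paste0("ratio_", g)]] <- m[, g]
  tab$total <- rep(100L, nrow(m))
  tab$pass <- TRUE
  attr(tab, "scheme") <- fragment_group_scheme()
  class(tab) <- c("GroupRatioTable", "data.frame")
  tab
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("median/MAD scaling matches hand computations", {
  m <- cbind(G80 = c(1, 2, 3, 4, 5), G100 = c(5, 10, 20, 40, 80),
             G120 = 1:5, G140 = 1:5, G168 = 1:5)
  s1 <- scale_ratios(m, constant = 1)
  expect_equal(unname(s1[, "G80"]), c(-2, -1, 0, 1, 2))
  s2 <- scale_ratios(m, constant = 1.4826)
  expect_equal(unname(s2[, "G80"]), c(-2, -1, 0, 1, 2) / 1.4826)
  # per column the median of scaled entries is 0
  expect_true(all(abs(apply(s2, 2, median)) < 1e-9))
  # rank order within each column is preserved
  expect_equal(order(s2[, "G100"]), order(m[, "G100"]))
})

test_that("zero-MAD columns pass through as zeros with a warning", {
  m <- cbind(G80 = c(1, 2, 3, 4), G100 = rep(0.2, 4), G120 = c(1, 1, 1, 9),
             G140 = 1:4, G168 = 1:4)
  expect_warning(s <- scale_ratios(m), "G100")
  expect_true(all(s[, "G100"] == 0))
  expect_false(all(s[, "G80"] == 0))
})

test_that("hierarchical clustering recovers the optimal 2-partition of 6 points", {
  set.seed(31)
  m <- rbind(matrix(rnorm(9, 0, 0.1), 3, 3), matrix(rnorm(9, 10, 0.1), 3, 3))
  rownames(m) <- paste0("p", 1:6)
  r <- hcluster(m, k = 2)
  oracle <- brute_best_2partition(m)
  got <- canonical_partition(r$assignment)
  want <- canonical_partition(ifelse(oracle, 1L, 2L), rownames(m))
  expect_equal(got, want)
})

test_that("k = rows gives singletons; row order does not change the partition", {
  set.seed(32)
  m <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("w", 1:8), group_cols))
  r <- hcluster(m, k = 8)
  expect_equal(as.vector(table(r$assignment)), rep(1L, 8))
  r5 <- hcluster(m, k = 3)
  perm <- sample(nrow(m))
  r5p <- hcluster(m[perm, ], k = 3)
  expect_equal(canonical_partition(r5$assignment), canonical_partition(r5p$assignment))
  expect_error(hcluster(m, k = 9), "9 clusters")
})

test_that("A-E labels go to the cluster dominating each group", {
  # 5 tight blobs, each maximal in one distinct column (identity case)
  set.seed(33)
  m <- do.call(rbind, lapply(1:5, function(g) {
    b <- matrix(rnorm(50, 0, 0.05), 10, 5)
    b[, g] <- b[, g] + 5
    b
  }))
  colnames(m) <- group_cols
  rownames(m) <- paste0("w", 1:50)
  r <- label_clusters(hcluster(m, k = 5), m)
  # rows 1-10 are the G80 blob -> label A, etc.
  expect_equal(unname(r$label_by_row[c(1, 11, 21, 31, 41)]),
               c("A", "B", "C", "D", "E"))
  expect_equal(sort(unname(r$labels)), c("A", "B", "C", "D", "E"))
})

test_that("a degenerate labelling (ties across clusters) errors", {
  m <- matrix(0, 10, 5, dimnames = list(paste0("w", 1:10), group_cols))
  fake <- structure(list(assignment = stats::setNames(rep(1:5, each = 2),
                                                      rownames(m)),
                         k = 5L),
                    class = "ClusterResult")
  expect_error(label_clusters(fake, m), "degenerate")
  expect_error(label_clusters(structure(list(assignment = 1:4, k = 4L),
                                        class = "ClusterResult"), m),
               "k = 5")
})

test_that("Spearman correlation handles monotone, tied and short inputs", {
  m <- cbind(G80 = seq(0.1, 1, length.out = 12), G100 = rep(0.1, 12),
             G120 = runif(12), G140 = runif(12), G168 = seq(1, 0.1, length.out = 12))
  rownames(m) <- paste0("g", 1:12)
  tab <- toy_ratio_table(m)
  expr <- data.frame(gene_id = paste0("g", 1:12), expression = seq(2, 24, by = 2))
  rep_ <- suppressWarnings(correlate_ratios_expression(tab, expr))
  expect_equal(rep_$rho[rep_$group == "G80"], 1)
  expect_equal(rep_$rho[rep_$group == "G168"], -1)
  expect_true(is.na(rep_$rho[rep_$group == "G100"]))
  expect_true(all(rep_$n == 12))
  short <- toy_ratio_table(m[1:5, ])
  expect_error(correlate_ratios_expression(short, expr), ">= 10")
})

test_that("planted expression links give the expected correlation signs", {
  land <- simulate_tss_landscape(n_genes = 600, seed = 34, frags_plus1 = 200,
                                 frags_other = 0, n_other_nucs = 0)
  centers <- reference_points(land$truth$chrom, land$truth$plus1_dyad,
                              kind = "NUC_CENTER", name = land$truth$gene_id)
  tab <- window_group_ratios(land$fragments, windows_around(centers, 100))
  rep_ <- correlate_ratios_expression(tab, land$expression)
  expect_lt(rep_$rho[rep_$group == "G80"], 0)
  expect_lt(rep_$p[rep_$group == "G80"], 0.01)
  expect_gt(rep_$rho[rep_$group == "G168"], 0)
  expect_lt(rep_$p[rep_$group == "G168"], 0.01)
})
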