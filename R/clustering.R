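#' Robust median/MAD scaling of group ratios
#'
#' Centers each fragment-group column of the ratio matrix by its median
#' and scales it by its median absolute deviation times a consistency
#' constant `c` (default 1.4826, the usual normal-consistency factor;
#' `c = 1` gives the raw MAD). Columns with zero MAD cannot be scaled
#' and pass through as all-zeros with a warning, preserving the
#' information in the remaining columns.
#'
#' Scaling is monotone within each column, so within-column rank order
#' is preserved exactly.
#'
#' @param table a `GroupRatioTable` (passing windows are used) or a
#'   numeric ratio matrix.
#' @param constant MAD consistency constant `c`.
#' @return numeric matrix (class `ScaledRatioMatrix`) of scaled ratios,
#'   same rows/columns as the input ratio matrix.
#' @export
scale_ratios <- function(table, constant = 1.4826) {
  m <- if (inherits(table, "GroupRatioTable")) ratio_matrix(table) else as.matrix(table)
  if (nrow(m) < 2L) stop("scaling requires at least 2 rows")
  zero_mad <- character(0)
  for (j in seq_len(ncol(m))) {
    med <- stats::median(m[, j])
    mad_raw <- stats::median(abs(m[, j] - med))
    if (mad_raw == 0) {
      m[, j] <- 0
      zero_mad <- c(zero_mad, colnames(m)[j])
    } else {
      m[, j] <- (m[, j] - med) / (mad_raw * constant)
    }
  }
  if (length(zero_mad)) {
    warning(sprintf("zero MAD in column(s) %s; passed through as zeros",
                    paste(zero_mad, collapse = ", ")))
  }
  structure(m, class = c("ScaledRatioMatrix", class(m)), constant = constant)
}

#' Hierarchical clustering of scaled unwrapping ratios
#'
#' Agglomerative clustering (via [stats::hclust()]) of the rows of a
#' scaled ratio matrix, cut into `k` clusters. Defaults: complete
#' linkage, Euclidean distance; both configurable. Deterministic for a
#' given input (ties broken by merge order inside `hclust`).
#'
#' @param m scaled ratio matrix ([scale_ratios()]).
#' @param k number of clusters (>= 1, <= rows).
#' @param linkage agglomeration method passed to `hclust`.
#' @param metric distance method passed to [stats::dist()].
#' @return object of class `ClusterResult`: list with `assignment`
#'   (named integer vector of cluster ids per row), `tree` (the hclust
#'   object), `k`, and `labels` (NULL until [label_clusters()]).
#' @export
hcluster <- function(m, k = 5L, linkage = "complete", metric = "euclidean") {
  m <- unclass(m)
  if (nrow(m) < k) stop(sprintf("cannot cut %d rows into %d clusters", nrow(m), k))
  d <- stats::dist(m, method = metric)
  tree <- stats::hclust(d, method = linkage)
  assignment <- stats::cutree(tree, k = k)
  names(assignment) <- rownames(m)
  structure(
    list(assignment = assignment, tree = tree, k = as.integer(k), labels = NULL),
    class = "ClusterResult"
  )
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d rows in %d clusters\n", length(x$assignment), x$k))
  tab <- table(x$assignment)
  for (i in names(tab)) {
    lab <- if (!is.null(x$labels)) sprintf(" (%s)", x$labels[[i]]) else ""
    cat(sprintf("  cluster %s%s: %d rows\n", i, lab, tab[[i]]))
  }
  invisible(x)
}

# All permutations of 1..n (n small; 120 for n = 5).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Label five clusters A-E by their dominant fragment group
#'
#' Each unwrapping-state class is named after the fragment group it
#' over-represents: A for G80 (30-80 bp), B for G100, C for G120, D for
#' G140, E for G168. Formally, the cluster x group matrix of median
#' scaled ratios is matched one-to-one (maximum-weight bipartite
#' matching, solved exactly over all 5! assignments) so labels are
#' unique. A degenerate matching (two assignments with equal total
#' weight) is an error.
#'
#' @param r a `ClusterResult` with `k = 5`.
#' @param m the scaled ratio matrix the clustering was computed from.
#' @return `r` with `labels` filled in: named character vector mapping
#'   cluster id to letter, plus `label_by_row` mapping each row.
#' @export
label_clusters <- function(r, m) {
  stopifnot(inherits(r, "ClusterResult"))
  m <- unclass(m)
  if (r$k != 5L) stop("A-E labelling requires k = 5")
  if (ncol(m) != 5L) stop("expected 5 fragment-group columns")
  med <- t(vapply(seq_len(r$k), function(cl) {
    apply(m[r$assignment == cl, , drop = FALSE], 2L, stats::median)
  }, numeric(5L)))
  # med[cluster, group]; maximize sum over groups of med[perm[g], g]
  perms <- all_perms(5L)
  scores <- apply(perms, 1L, function(p) sum(med[cbind(p, 1:5)]))
  best <- which.max(scores)
  o <- order(scores, decreasing = TRUE)
  if (length(o) > 1L && scores[o[1L]] - scores[o[2L]] < 1e-12) {
    tied <- perms[o[2L], ] != perms[best, ]
    stop(sprintf("degenerate cluster labelling: tied assignment for group(s) %s",
                 paste(colnames(m)[tied], collapse = ", ")))
  }
  letters5 <- c("A", "B", "C", "D", "E")
  labels <- character(5L)
  labels[perms[best, ]] <- letters5
  names(labels) <- as.character(seq_len(5L))
  r$labels <- labels
  r$label_by_row <- labels[as.character(r$assignment)]
  names(r$label_by_row) <- names(r$assignment)
  r
}

#' Correlate fragment-group ratios with gene expression
#'
#' Spearman rank correlation (average ranks for ties) between each
#' group's per-window ratio and the matched gene's expression value.
#' Two-sided p-values use the t-approximation for n > 30 and the exact
#' null distribution of the rank statistic for n <= 30 (falling back to
#' the approximation when ties preclude the exact method). A group whose
#' ratios are all tied has no defined correlation and is reported as
#' `NA` with a warning.
#'
#' @param table a `GroupRatioTable` whose window ids are gene ids.
#' @param expr expression data.frame with `gene_id` and `expression`.
#' @return data.frame (class `CorrelationReport`) with columns `group`,
#'   `rho`, `p`, `n`.
#' @export
correlate_ratios_expression <- function(table, expr) {
  stopifnot(inherits(table, "GroupRatioTable"), is.data.frame(expr))
  scheme <- attr(table, "scheme")
  t <- table[table$pass, , drop = FALSE]
  i <- match(t$window, expr$gene_id)
  ok <- !is.na(i)
  t <- t[ok, , drop = FALSE]
  y <- expr$expression[i[ok]]
  n <- nrow(t)
  if (n < 10L) stop(sprintf("only %d matched window-expression pairs (need >= 10)", n))
  rows <- lapply(scheme$labels, function(g) {
    x <- t[[paste0("ratio_", g)]]
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
      warning(sprintf("all values tied for group %s; correlation undefined", g))
      return(data.frame(group = g, rho = NA_real_, p = NA_real_, n = n))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = n <= 30L)
    )
    data.frame(group = g, rho = unname(ct$estimate), p = ct$p.value, n = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("CorrelationReport", "data.frame")
  out
}
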