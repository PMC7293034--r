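#' Compute a strand-oriented V-plot matrix
#'
#' A V-plot is the two-dimensional density of fragment centers around a
#' set of reference points: rows are fragment lengths, columns are the
#' offset of the fragment center from the reference point at 1-bp
#' resolution. Offsets are strand-oriented: for a `-` strand reference
#' the offset is negated, so positive offsets always point downstream.
#' A fragment near several reference points contributes to each (every
#' reference is an independent anchor).
#'
#' With `norm = "CPB"` counts are scaled to centers of fragments per
#' billion read pairs: `CPB = raw * 1e9 / total_pairs`, where
#' `total_pairs` is the library size of the FragmentSet (all retained
#' pairs, not only in-window pairs).
#'
#' @param frags a `FragmentSet`.
#' @param refs reference points data.frame ([reference_points()]).
#' @param W window half-width in bp (columns run -W..+W).
#' @param len_range inclusive fragment length bounds (rows), within
#'   `[1, 1000]`.
#' @param norm `"CPB"` or `"raw"`.
#' @return object of class `VPlotMatrix`: list with `values`
#'   (length x offset matrix, dimnames are lengths and offsets), `norm`,
#'   `total_pairs`, `n_refpoints`, `W`, `len_range`.
#' @export
compute_vplot <- function(frags, refs, W = 2000L, len_range = c(30L, 200L),
                          norm = c("CPB", "raw")) {
  norm <- match.arg(norm)
  stopifnot(inherits(frags, "FragmentSet"), is.data.frame(refs))
  if (nrow(refs) == 0L) stop("no reference points supplied")
  W <- as.integer(W)
  if (W < 1L) stop("W must be >= 1")
  if (len_range[1L] < 1L || len_range[2L] > 1000L || len_range[1L] > len_range[2L]) {
    stop("len_range must be increasing and within [1, 1000]")
  }
  if (norm == "CPB" && frags$total_pairs == 0L) {
    stop("CPB normalization requires total_pairs > 0")
  }
  nL <- len_range[2L] - len_range[1L] + 1L
  nO <- 2L * W + 1L
  vals <- matrix(0, nL, nO,
                 dimnames = list(seq.int(len_range[1L], len_range[2L]),
                                 seq.int(-W, W)))
  f <- frags$fragments
  f <- f[f$length >= len_range[1L] & f$length <= len_range[2L], , drop = FALSE]
  for (ch in intersect(unique(refs$chrom), unique(f$chrom))) {
    fc <- f[f$chrom == ch, , drop = FALSE]
    rc <- refs[refs$chrom == ch, , drop = FALSE]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(fc$center, width = 1L),
      IRanges::IRanges(rc$pos - W, rc$pos + W)
    )
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    if (length(qi) == 0L) next
    off <- fc$center[qi] - rc$pos[si]
    off <- ifelse(rc$strand[si] == "-", -off, off)
    lin <- (off + W) * nL + (fc$length[qi] - len_range[1L] + 1L)
    vals <- vals + matrix(tabulate(lin, nbins = nL * nO), nL, nO)
  }
  if (norm == "CPB") vals <- vals * 1e9 / frags$total_pairs
  structure(
    list(values = vals, norm = norm, total_pairs = frags$total_pairs,
         n_refpoints = nrow(refs), W = W,
         len_range = as.integer(len_range)),
    class = "VPlotMatrix"
  )
}

#' @export
print.VPlotMatrix <- function(x, ...) {
  cat(sprintf("VPlotMatrix (%s): lengths %d-%d bp x offsets -%d..+%d, %d reference points\n",
              x$norm, x$len_range[1L], x$len_range[2L], x$W, x$W, x$n_refpoints))
  cat(sprintf("  total signal: %.4g\n", sum(x$values)))
  invisible(x)
}

#' Aggregate a V-plot into fragment-group meta-profiles
#'
#' Sums the V-plot rows belonging to each fragment length group, giving
#' one signal-vs-offset vector per group (the per-group read density
#' around the reference points).
#'
#' @param v a `VPlotMatrix`.
#' @param scheme a [fragment_group_scheme()]; every group range must lie
#'   within the V-plot's length range.
#' @return object of class `MetaProfile`: list with `profiles` (group x
#'   offset matrix), `norm`, `W`, `n_refpoints`.
#' @export
aggregate_groups <- function(v, scheme = fragment_group_scheme()) {
  stopifnot(inherits(v, "VPlotMatrix"), inherits(scheme, "FragmentGroupScheme"))
  if (scheme$min < v$len_range[1L] || scheme$max > v$len_range[2L]) {
    stop("group scheme extends outside the V-plot length range")
  }
  lens <- as.integer(rownames(v$values))
  prof <- t(vapply(scheme$labels, function(g) {
    b <- scheme$bounds[[g]]
    rows <- lens >= b[1L] & lens <= b[2L]
    colSums(v$values[rows, , drop = FALSE])
  }, numeric(ncol(v$values))))
  rownames(prof) <- scheme$labels
  colnames(prof) <- colnames(v$values)
  structure(
    list(profiles = prof, norm = v$norm, W = v$W, n_refpoints = v$n_refpoints),
    class = "MetaProfile"
  )
}

#' Difference V-plot between two conditions
#'
#' Elementwise subtraction of two CPB-normalized V-plots of identical
#' shape (same length range and window): each cell of the treatment
#' matrix minus the cell with the same offset and fragment length in the
#' control matrix. Positive values mark signal gained in the treatment
#' (e.g. after a knockdown), negative values signal lost.
#'
#' @param treat,ctrl `VPlotMatrix` objects, both `norm = "CPB"`, same
#'   shape.
#' @return object of class `DiffVPlot` with the difference in `values`.
#' @export
difference_vplot <- function(treat, ctrl) {
  stopifnot(inherits(treat, "VPlotMatrix"), inherits(ctrl, "VPlotMatrix"))
  if (treat$norm != "CPB" || ctrl$norm != "CPB") {
    stop("difference V-plots require CPB normalization on both inputs")
  }
  if (treat$W != ctrl$W || !identical(treat$len_range, ctrl$len_range)) {
    stop("V-plot shapes differ (window or length range mismatch)")
  }
  structure(
    list(values = treat$values - ctrl$values, norm = "CPB_difference",
         W = treat$W, len_range = treat$len_range),
    class = "DiffVPlot"
  )
}
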