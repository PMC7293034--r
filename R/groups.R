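#' Windows around reference points
#'
#' Builds half-open windows `[pos - halfwidth, pos + halfwidth)` around
#' reference points (e.g. the 200-bp region of a nucleosome center with
#' `halfwidth = 100`, or summit +/- 500 for 1-kb peak regions).
#'
#' @param points reference points data.frame.
#' @param halfwidth half-width in bp.
#' @return data.frame with columns chrom, start, end, name.
#' @export
windows_around <- function(points, halfwidth = 100L) {
  halfwidth <- as.integer(halfwidth)
  data.frame(
    chrom = points$chrom,
    start = points$pos - halfwidth,
    end = points$pos + halfwidth,
    name = points$name,
    stringsAsFactors = FALSE
  )
}

#' Per-window fragment group counts and ratios
#'
#' A fragment belongs to a window iff its center lies in the half-open
#' window interval. Only fragments whose length falls in the scheme's
#' range contribute; per window, `ratio_g = count_g / total`. Windows
#' with fewer than `min_fragments` in-range fragments are flagged
#' (`pass = FALSE`) so downstream scaling/clustering can exclude them;
#' ratios for zero-total windows are `NA`.
#'
#' @param frags a `FragmentSet`.
#' @param windows data.frame with chrom, start, end, name (see
#'   [windows_around()]).
#' @param scheme a [fragment_group_scheme()].
#' @param min_fragments minimum in-range fragments for `pass = TRUE`.
#' @return a `GroupRatioTable`: data.frame with the window columns,
#'   `count_<group>` and `ratio_<group>` per group, `total`, `pass`; the
#'   scheme is attached as attribute `"scheme"`.
#' @export
window_group_ratios <- function(frags, windows, scheme = fragment_group_scheme(),
                                min_fragments = 20L) {
  stopifnot(inherits(frags, "FragmentSet"), is.data.frame(windows))
  if (nrow(windows) == 0L) stop("no windows supplied")
  f <- frags$fragments
  grp <- assign_group(f$length, scheme)
  sel <- !is.na(grp)
  f <- f[sel, , drop = FALSE]
  grp <- grp[sel]
  nw <- nrow(windows)
  counts <- matrix(0L, nw, length(scheme$labels),
                   dimnames = list(NULL, scheme$labels))
  for (ch in intersect(unique(windows$chrom), unique(f$chrom))) {
    wi <- which(windows$chrom == ch)
    fi <- which(f$chrom == ch)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(f$center[fi], width = 1L),
      IRanges::IRanges(windows$start[wi], windows$end[wi] - 1L)
    )
    if (length(ov) == 0L) next
    tab <- table(
      factor(wi[S4Vectors::subjectHits(ov)], levels = seq_len(nw)),
      grp[fi[S4Vectors::queryHits(ov)]]
    )
    counts <- counts + as.matrix(unclass(tab))
  }
  total <- rowSums(counts)
  ratios <- counts / ifelse(total > 0L, total, NA_real_)
  out <- data.frame(
    window = windows$name, chrom = windows$chrom,
    start = windows$start, end = windows$end,
    stringsAsFactors = FALSE
  )
  for (g in scheme$labels) out[[paste0("count_", g)]] <- counts[, g]
  out$total <- total
  for (g in scheme$labels) out[[paste0("ratio_", g)]] <- ratios[, g]
  out$pass <- total >= min_fragments
  attr(out, "scheme") <- scheme
  class(out) <- c("GroupRatioTable", "data.frame")
  out
}

#' Extract the ratio matrix of passing windows
#'
#' @param table a `GroupRatioTable`.
#' @param pass_only drop windows flagged `pass = FALSE` (default).
#' @return numeric matrix, rows = windows (named by window id), columns =
#'   group labels.
#' @export
ratio_matrix <- function(table, pass_only = TRUE) {
  stopifnot(inherits(table, "GroupRatioTable"))
  scheme <- attr(table, "scheme")
  t <- if (pass_only) table[table$pass, , drop = FALSE] else table
  m <- as.matrix(t[, paste0("ratio_", scheme$labels), drop = FALSE])
  colnames(m) <- scheme$labels
  rownames(m) <- t$window
  m
}

#' Select +1 nucleosomes downstream of TSSs
#'
#' For each TSS, candidate nucleosome centers lie 50-200 bp downstream
#' (strand-aware: `[p + 50, p + 200]` for `+` TSSs, `[p - 200, p - 50]`
#' for `-` TSSs, bounds configurable). Among candidates the center
#' nearest the TSS wins; exact distance ties go to the smaller
#' coordinate. Genes with no candidate are omitted (a message reports
#' how many).
#'
#' @param centers nucleosome-center reference points.
#' @param tss TSS reference points (stranded).
#' @param min_dist,max_dist downstream distance bounds in bp.
#' @return data.frame with columns `gene`, `chrom`, `tss`, `strand`,
#'   `plus1` (selected center position), `distance`.
#' @export
select_plus1 <- function(centers, tss, min_dist = 50L, max_dist = 200L) {
  stopifnot(is.data.frame(centers), is.data.frame(tss))
  down <- ifelse(tss$strand == "-", -1L, 1L)
  lo <- ifelse(down > 0L, tss$pos + min_dist, tss$pos - max_dist)
  hi <- ifelse(down > 0L, tss$pos + max_dist, tss$pos - min_dist)
  res <- vector("list", nrow(tss))
  for (ch in intersect(unique(tss$chrom), unique(centers$chrom))) {
    ti <- which(tss$chrom == ch)
    ci <- which(centers$chrom == ch)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(lo[ti], hi[ti]),
      IRanges::IRanges(centers$pos[ci], width = 1L)
    )
    if (length(ov) == 0L) next
    qh <- S4Vectors::queryHits(ov)
    cpos <- centers$pos[ci[S4Vectors::subjectHits(ov)]]
    for (q in unique(qh)) {
      i <- ti[q]
      cand <- cpos[qh == q]
      d <- abs(cand - tss$pos[i])
      best <- cand[d == min(d)]
      pick <- min(best)  # tie -> smaller coordinate
      res[[i]] <- data.frame(
        gene = tss$name[i], chrom = ch, tss = tss$pos[i],
        strand = tss$strand[i], plus1 = pick,
        distance = abs(pick - tss$pos[i]), stringsAsFactors = FALSE
      )
    }
  }
  found <- !vapply(res, is.null, logical(1))
  if (any(!found)) {
    message(sprintf("select_plus1: %d of %d genes had no nucleosome center in range",
                    sum(!found), nrow(tss)))
  }
  if (!any(found)) {
    return(data.frame(gene = character(0), chrom = character(0), tss = integer(0),
                      strand = character(0), plus1 = integer(0), distance = integer(0)))
  }
  do.call(rbind, res[found])
}

#' Per-group RPM genome tracks
#'
#' Bins fragment centers into fixed-width bins (default 10 bp) per
#' chromosome and scales to reads per million using the library total
#' (`total_pairs`). One track per fragment group plus a `combined` track
#' of all in-scheme fragments; the group tracks sum exactly to the
#' combined track.
#'
#' @param frags a `FragmentSet`.
#' @param scheme a [fragment_group_scheme()].
#' @param binsize bin width in bp.
#' @return named list of track data.frames (chrom, start, end, value),
#'   one per group label plus `"combined"`. Only non-empty bins are
#'   returned.
#' @export
group_tracks <- function(frags, scheme = fragment_group_scheme(), binsize = 10L) {
  stopifnot(inherits(frags, "FragmentSet"))
  binsize <- as.integer(binsize)
  if (frags$total_pairs == 0L) {
    empty <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), value = numeric(0))
    out <- c(stats::setNames(rep(list(empty), length(scheme$labels)), scheme$labels),
             list(combined = empty))
    return(out)
  }
  f <- frags$fragments
  grp <- assign_group(f$length, scheme)
  sel <- !is.na(grp)
  f <- f[sel, , drop = FALSE]
  grp <- factor(grp[sel], levels = scheme$labels)
  one_track <- function(rows) {
    if (!length(rows)) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), value = numeric(0)))
    }
    sub <- f[rows, , drop = FALSE]
    bin <- sub$center %/% binsize
    agg <- stats::aggregate(list(n = rep(1L, nrow(sub))),
                            by = list(chrom = sub$chrom, bin = bin), FUN = sum)
    agg <- agg[order(agg$chrom, agg$bin), , drop = FALSE]
    data.frame(
      chrom = agg$chrom,
      start = agg$bin * binsize,
      end = (agg$bin + 1L) * binsize,
      value = agg$n * 1e6 / frags$total_pairs,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- lapply(scheme$labels, function(g) one_track(which(grp == g)))
  names(out) <- scheme$labels
  out$combined <- one_track(seq_len(nrow(f)))
  out
}

#' Classify overlaps between two interval sets
#'
#' An interval is "shared" iff it overlaps any interval of the other set
#' by at least 1 bp; otherwise it is specific to its own set. This is
#' the Venn-style classification used to compare peak sets.
#'
#' @param a,b data.frames with chrom, start, end (0-based half-open).
#' @return list with `a_shared`/`b_shared` (logical vectors per input
#'   row) and `counts` (named: `a_specific`, `b_specific`, `shared`,
#'   where `shared` counts intervals from both sets).
#' @export
interval_overlap <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  hit <- function(x, y) {
    out <- logical(nrow(x))
    for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
      xi <- which(x$chrom == ch)
      yi <- which(y$chrom == ch)
      n <- IRanges::countOverlaps(
        IRanges::IRanges(x$start[xi], x$end[xi] - 1L),
        IRanges::IRanges(y$start[yi], y$end[yi] - 1L)
      )
      out[xi] <- n > 0L
    }
    out
  }
  a_shared <- hit(a, b)
  b_shared <- hit(b, a)
  list(
    a_shared = a_shared,
    b_shared = b_shared,
    counts = c(
      a_specific = sum(!a_shared),
      b_specific = sum(!b_shared),
      shared = sum(a_shared) + sum(b_shared)
    )
  )
}
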