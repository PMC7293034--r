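#' Five-way fragment length group scheme
#'
#' Subnucleosomal fragments are partitioned into five inclusive length
#' ranges reflecting progressive nucleosome unwrapping: G80 (30-80 bp,
#' strongly unwrapped / tetrasome-scale protection), G100 (81-100),
#' G120 (101-120), G140 (121-140, hexasome-scale) and G168 (141-168,
#' intact core particle). Ranges are disjoint, contiguous and ascending;
#' every length in `[min_small, 168]` maps to exactly one group.
#'
#' The lower bound of the smallest group is configurable (`min_small`):
#' 30 bp is the default, 35 bp is a common stricter alternative that
#' drops the shortest protections.
#'
#' @param min_small lower bound (bp) of the smallest group.
#' @return object of class `FragmentGroupScheme`.
#' @export
fragment_group_scheme <- function(min_small = 30L) {
  min_small <- as.integer(min_small)
  if (min_small < 1L || min_small > 80L) stop("min_small must be in [1, 80]")
  bounds <- list(
    G80 = c(min_small, 80L),
    G100 = c(81L, 100L),
    G120 = c(101L, 120L),
    G140 = c(121L, 140L),
    G168 = c(141L, 168L)
  )
  lo <- vapply(bounds, `[`, integer(1), 1L)
  hi <- vapply(bounds, `[`, integer(1), 2L)
  if (any(lo > hi) || any(lo[-1] != hi[-length(hi)] + 1L)) {
    stop("group ranges must be disjoint, contiguous and ascending")
  }
  structure(
    list(bounds = bounds, labels = names(bounds), min = lo[[1L]], max = hi[[length(hi)]]),
    class = "FragmentGroupScheme"
  )
}

#' @export
print.FragmentGroupScheme <- function(x, ...) {
  cat("FragmentGroupScheme:\n")
  for (g in x$labels) {
    cat(sprintf("  %s: %d-%d bp\n", g, x$bounds[[g]][1L], x$bounds[[g]][2L]))
  }
  invisible(x)
}

#' Assign fragment lengths to groups
#'
#' @param length integer vector of fragment lengths (bp), all >= 1.
#' @param scheme a [fragment_group_scheme()].
#' @return factor with the scheme's group labels as levels; `NA` for
#'   lengths outside the scheme's range.
#' @examples
#' assign_group(c(80, 81, 141, 168, 169, 29))
#' @export
assign_group <- function(length, scheme = fragment_group_scheme()) {
  stopifnot(inherits(scheme, "FragmentGroupScheme"))
  if (any(length < 1L)) stop("fragment lengths must be >= 1")
  out <- rep(NA_character_, length(length))
  for (g in scheme$labels) {
    b <- scheme$bounds[[g]]
    out[length >= b[1L] & length <= b[2L]] <- g
  }
  factor(out, levels = scheme$labels)
}
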