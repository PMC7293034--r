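#' Construct a FragmentSet
#'
#' A `FragmentSet` holds the sequenced chromatin particles of one sample
#' (one antibody / digestion condition / genotype) as genomic intervals in
#' 0-based half-open BED convention. Fragment `length` and `center` are
#' derived columns: `length = end - start` and `center = floor((start +
#' end) / 2)`, so the center of an even-length fragment is the left of the
#' two middle coordinates. These derived values are used consistently for
#' V-plots, genome tracks and window membership.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start coordinates.
#' @param end integer vector, 0-based exclusive end coordinates; must
#'   satisfy `end > start` elementwise.
#' @param label non-empty free-text source tag (e.g. antibody and
#'   digestion condition).
#' @return An object of class `FragmentSet`: a list with elements
#'   `fragments` (data.frame with columns chrom, start, end, length,
#'   center), `total_pairs` (number of fragments) and `label`.
#' @examples
#' fs <- fragment_set("chr1", 100L, 250L, label = "toy")
#' fs$fragments$length  # 150
#' fs$fragments$center  # 175
#' @export
fragment_set <- function(chrom, start, end, label = "sample") {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("'label' must be a non-empty string")
  }
  n <- length(start)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n) {
    stop("chrom, start and end must have equal lengths")
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (n > 0L && any(end <= start)) {
    bad <- which(end <= start)[1L]
    stop(sprintf("fragment %d has end <= start (%d <= %d)", bad, end[bad], start[bad]))
  }
  frags <- data.frame(
    chrom = as.character(chrom),
    start = start,
    end = end,
    length = end - start,
    center = (start + end) %/% 2L,
    stringsAsFactors = FALSE
  )
  structure(
    list(fragments = frags, total_pairs = n, label = label),
    class = "FragmentSet"
  )
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet '%s': %d fragments\n", x$label, x$total_pairs))
  if (x$total_pairs > 0L) {
    cat(sprintf(
      "  chromosomes: %s\n  length range: %d-%d bp (median %d)\n",
      paste(unique(x$fragments$chrom), collapse = ", "),
      min(x$fragments$length), max(x$fragments$length),
      as.integer(stats::median(x$fragments$length))
    ))
  }
  invisible(x)
}

#' Number of fragments in a FragmentSet
#' @param x a `FragmentSet`.
#' @return integer count (equal to `x$total_pairs`).
#' @export
n_fragments <- function(x) {
  stopifnot(inherits(x, "FragmentSet"))
  x$total_pairs
}

#' Combine FragmentSets
#'
#' Concatenates the fragments of several sets into one; `total_pairs` is
#' the sum. Used e.g. to pool technical replicates.
#'
#' @param ... `FragmentSet` objects.
#' @param label label for the combined set.
#' @return a `FragmentSet`.
#' @export
combine_fragment_sets <- function(..., label = "combined") {
  sets <- list(...)
  stopifnot(length(sets) > 0L, all(vapply(sets, inherits, logical(1), "FragmentSet")))
  frags <- do.call(rbind, lapply(sets, function(s) s$fragments[, c("chrom", "start", "end")]))
  fragment_set(frags$chrom, frags$start, frags$end, label = label)
}

#' Build reference points in memory
#'
#' Reference points anchor V-plots and window analyses: transcription
#' start sites (TSS), CTCF binding sites (CBS), nucleosome centers or
#' peak summits. TSS and CBS must carry a strand; nucleosome centers are
#' "+" by convention.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based anchor coordinates.
#' @param strand `"+"` or `"-"` per point (recycled).
#' @param kind one of `"TSS"`, `"CBS"`, `"NUC_CENTER"`, `"PEAK_SUMMIT"`.
#' @param name identifiers (default `pt1`, `pt2`, ...).
#' @return data.frame with columns chrom, pos, strand, kind, name.
#' @export
reference_points <- function(chrom, pos, strand = "+",
                             kind = c("TSS", "CBS", "NUC_CENTER", "PEAK_SUMMIT"),
                             name = NULL) {
  kind <- match.arg(kind)
  n <- length(pos)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (is.null(name)) name <- paste0("pt", seq_len(max(n, 0L)))
  pos <- as.integer(pos)
  if (n > 0L && any(pos < 0L)) stop("reference point positions must be >= 0")
  if (kind %in% c("TSS", "CBS") && n > 0L && !all(strand %in% c("+", "-"))) {
    stop(sprintf("strand must be '+' or '-' for kind %s", kind))
  }
  if (kind == "NUC_CENTER") strand <- rep("+", n)
  data.frame(
    chrom = as.character(chrom), pos = pos, strand = as.character(strand),
    kind = rep(kind, length.out = n), name = as.character(name),
    stringsAsFactors = FALSE
  )
}
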