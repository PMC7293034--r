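#' CTCF core consensus motif (14-mer, IUPAC)
#'
#' The directional CTCF binding consensus 5'-CCACNAGGTGGCAG-3' used to
#' orient and center CTCF binding sites. Its reverse complement is
#' CTGCCACCTNGTGG.
#' @export
CTCF_CONSENSUS <- "CCACNAGGTGGCAG"

#' Scan a sequence for the CTCF consensus
#'
#' Reports every position where the 14-mer consensus matches on the
#' forward strand, or where its reverse complement matches (a minus
#' strand site). The consensus N matches any base; an N in the scanned
#' sequence matches nothing (candidate matches covering a sequence N are
#' discarded). Overlapping hits are all reported. The site center is
#' fixed at `start + 7` (0-based).
#'
#' @param seq DNA sequence: character string or `Biostrings::DNAString`,
#'   alphabet ACGTN (case-insensitive).
#' @param offset genomic 0-based coordinate of the first base of `seq`;
#'   reported coordinates are `offset`-shifted.
#' @param consensus the IUPAC consensus to scan for.
#' @return data.frame of class `MotifHits` with columns `start`
#'   (0-based), `end` (exclusive), `strand`, `center`, ordered by start
#'   (then `+` before `-`).
#' @examples
#' scan_consensus("CCACTAGGTGGCAG")   # one + hit centered at 7
#' scan_consensus("CTGCCACCTAGTGG")   # one - hit centered at 7
#' @export
scan_consensus <- function(seq, offset = 0L, consensus = CTCF_CONSENSUS) {
  if (is.character(seq)) {
    seq <- toupper(seq)
    if (grepl("[^ACGTN]", seq)) stop("invalid characters in sequence (expected A/C/G/T/N)")
    seq <- Biostrings::DNAString(seq)
  }
  stopifnot(methods::is(seq, "DNAString"))
  pat <- Biostrings::DNAString(consensus)
  hits_one <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, seq, fixed = FALSE)
    if (length(m) == 0L) {
      return(data.frame(start = integer(0), end = integer(0),
                        strand = character(0), center = integer(0)))
    }
    matched <- as.character(m)
    keep <- !grepl("N", matched, fixed = TRUE)
    s0 <- offset + BiocGenerics::start(m)[keep] - 1L
    data.frame(
      start = s0, end = s0 + nchar(consensus),
      strand = rep(strand, sum(keep)), center = s0 + 7L,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    hits_one(pat, "+"),
    hits_one(Biostrings::reverseComplement(pat), "-")
  )
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MotifHits", "data.frame")
  out
}

#' Orient CTCF binding sites on the consensus motif
#'
#' For each peak interval, scans the underlying genome sequence for the
#' consensus; if at least one hit is found, the hit whose center is
#' nearest the peak midpoint is taken (ties: `+` strand first, then the
#' smaller coordinate), and a strand-aware CBS reference point is
#' emitted at the motif center. Peaks without a hit are dropped and
#' counted (attribute `n_dropped`, plus a message).
#'
#' @param peaks data.frame with chrom, start, end and optionally name.
#' @param genome a named `Biostrings::DNAStringSet` or path to a FASTA
#'   file (names are truncated at the first whitespace).
#' @param consensus the IUPAC consensus.
#' @return CBS reference points data.frame (chrom, pos, strand, kind,
#'   name) with attribute `n_dropped`.
#' @export
orient_cbs <- function(peaks, genome, consensus = CTCF_CONSENSUS) {
  stopifnot(is.data.frame(peaks))
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.null(peaks$name)) peaks$name <- paste0("peak", seq_len(nrow(peaks)))
  res <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    if (!ch %in% names(genome)) stop(sprintf("chromosome %s not in genome", ch))
    chlen <- length(genome[[ch]])
    s <- max(peaks$start[i], 0L)
    e <- min(peaks$end[i], chlen)
    if (e - s < nchar(consensus)) next
    hits <- scan_consensus(Biostrings::subseq(genome[[ch]], s + 1L, e),
                           offset = s, consensus = consensus)
    if (nrow(hits) == 0L) next
    mid <- (peaks$start[i] + peaks$end[i]) %/% 2L
    d <- abs(hits$center - mid)
    hits <- hits[d == min(d), , drop = FALSE]
    hits <- hits[order(hits$strand, hits$center), , drop = FALSE]  # "+" < "-"
    res[[i]] <- data.frame(
      chrom = ch, pos = hits$center[1L], strand = hits$strand[1L],
      kind = "CBS", name = peaks$name[i], stringsAsFactors = FALSE
    )
  }
  found <- !vapply(res, is.null, logical(1))
  n_dropped <- sum(!found)
  if (n_dropped > 0L) {
    message(sprintf("orient_cbs: %d of %d peaks had no consensus hit", n_dropped, nrow(peaks)))
  }
  out <- if (any(found)) {
    do.call(rbind, res[found])
  } else {
    reference_points(character(0), integer(0), character(0), kind = "CBS",
                     name = character(0))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
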