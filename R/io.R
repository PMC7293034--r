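#' Read aligned fragments from BED or BEDPE
#'
#' Reads paired-end fragments from a 3+ column fragment BED (one row per
#' fragment) or a 10-column BEDPE (one row per read pair; the fragment is
#' the outer span of the two mates). Coordinates are 0-based half-open.
#' Inputs are assumed to be already filtered for mapping quality upstream
#' (the usual contract is mapq > 10 at alignment time); this reader does
#' not deduplicate and does not require deduplicated input.
#'
#' Ingestion is lossless by default (`min_len`/`max_len` of 1/1000);
#' analysis-level length bounds are applied later by the individual
#' analyses.
#'
#' @param path path to a BED/BEDPE file. Lines starting with `#`,
#'   `track` or `browser` are skipped.
#' @param min_len,max_len retain only fragments with
#'   `min_len <= length <= max_len`.
#' @param format `"auto"` (default), `"bed"` or `"bedpe"`. Auto-detection
#'   treats files whose rows have >= 10 fields with numeric fields 5 and 6
#'   as BEDPE.
#' @param label sample label; defaults to the file name.
#' @return a [fragment_set()] with fragments in file order.
#' @export
read_fragments <- function(path, min_len = 1L, max_len = 1000L,
                           format = c("auto", "bed", "bedpe"),
                           label = basename(path)) {
  format <- match.arg(format)
  if (min_len > max_len) stop("min_len must be <= max_len")
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(fragment_set(character(0), integer(0), integer(0), label = label))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)

  num_field <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(fields, function(f) {
      if (length(f) >= k) f[[k]] else NA_character_
    }, character(1))))
    v
  }

  if (format == "auto") {
    f5 <- num_field(5L)
    f6 <- num_field(6L)
    format <- if (all(nf >= 10L) && !anyNA(f5) && !anyNA(f6)) "bedpe" else "bed"
  }

  fail <- function(i, why) {
    stop(sprintf("%s: line %d: %s", path, idx[i], why), call. = FALSE)
  }

  if (format == "bed") {
    if (any(nf < 3L)) fail(which(nf < 3L)[1L], "expected at least 3 columns")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start <- num_field(2L)
    end <- num_field(3L)
    if (anyNA(start) || anyNA(end)) {
      fail(which(is.na(start) | is.na(end))[1L], "non-numeric start/end")
    }
  } else {
    if (any(nf < 10L)) fail(which(nf < 10L)[1L], "expected at least 10 BEDPE columns")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    chrom2 <- vapply(fields, `[[`, character(1), 4L)
    s1 <- num_field(2L); e1 <- num_field(3L)
    s2 <- num_field(5L); e2 <- num_field(6L)
    if (anyNA(s1) || anyNA(e1) || anyNA(s2) || anyNA(e2)) {
      fail(which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2))[1L],
           "non-numeric mate coordinates")
    }
    if (any(chrom != chrom2)) {
      fail(which(chrom != chrom2)[1L], "mates on different chromosomes")
    }
    start <- pmin(s1, s2)
    end <- pmax(e1, e2)
  }

  if (any(end <= start)) fail(which(end <= start)[1L], "end <= start")

  len <- end - start
  sel <- len >= min_len & len <= max_len
  fragment_set(chrom[sel], start[sel], end[sel], label = label)
}

#' Write a FragmentSet as 3-column BED
#' @param x a `FragmentSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(x, path) {
  stopifnot(inherits(x, "FragmentSet"))
  f <- x$fragments
  writeLines(sprintf("%s\t%d\t%d", f$chrom, f$start, f$end), path)
  invisible(path)
}

#' Read reference points from BED6
#'
#' Single-bp records (`end == start + 1`) anchor at `start`; wider
#' intervals anchor at their midpoint `floor((start + end) / 2)`. TSS and
#' CBS records must have a `+`/`-` strand; nucleosome centers are forced
#' to `+` by convention.
#'
#' @param path BED6 file path.
#' @param kind one of `"TSS"`, `"CBS"`, `"NUC_CENTER"`, `"PEAK_SUMMIT"`.
#' @return data.frame as from [reference_points()].
#' @export
read_reference_points <- function(path, kind = c("TSS", "CBS", "NUC_CENTER", "PEAK_SUMMIT")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  if (!any(keep)) {
    return(reference_points(character(0), integer(0), character(0), kind = kind,
                            name = character(0)))
  }
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (any(lengths(fields) < 6L)) {
    stop(sprintf("%s: expected BED6 (6 columns)", path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- as.integer(vapply(fields, `[[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[[`, character(1), 3L))
  name <- vapply(fields, `[[`, character(1), 4L)
  strand <- vapply(fields, `[[`, character(1), 6L)
  if (kind %in% c("TSS", "CBS") && !all(strand %in% c("+", "-"))) {
    stop(sprintf("%s: %s records require a '+'/'-' strand in column 6", path, kind))
  }
  pos <- ifelse(end - start == 1L, start, (start + end) %/% 2L)
  reference_points(chrom, pos, strand, kind = kind, name = name)
}

#' Write reference points as BED6
#' @param refs data.frame from [reference_points()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_points <- function(refs, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     refs$chrom, refs$pos, refs$pos + 1L, refs$name, refs$strand),
             path)
  invisible(path)
}

#' Write a binned genome track as bedGraph
#'
#' The track is expected in fixed-width bins (default 10 bp; the last bin
#' of a chromosome may be shorter), sorted and non-overlapping within each
#' chromosome. Zero-valued bins are omitted. Values are written with four
#' decimal places; one track per file, with a `track type=bedGraph`
#' header.
#'
#' @param track data.frame with columns chrom, start, end, value.
#' @param path output path.
#' @param name track name for the header line.
#' @param binsize expected bin width in bp.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name = "track", binsize = 10L) {
  stopifnot(is.data.frame(track), all(c("chrom", "start", "end", "value") %in% names(track)))
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, ]
    if (is.unsorted(t$start, strictly = TRUE) || any(t$start[-1] < t$end[-nrow(t)])) {
      stop(sprintf("bins on %s are unsorted or overlapping", ch))
    }
    w <- t$end - t$start
    if (nrow(t) > 1L && any(w[-nrow(t)] != binsize)) {
      stop(sprintf("bins on %s are not fixed %d-bp width", ch, binsize))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  t <- track[track$value != 0, , drop = FALSE]
  if (nrow(t) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%.4f", t$chrom, t$start, t$end, t$value), con)
  }
  invisible(path)
}

#' Write / read a labelled numeric matrix as TSV
#'
#' Row labels (fragment lengths, window ids) go in the first column; the
#' header carries the column labels (offsets, group names). The pair
#' round-trips losslessly (`read_matrix_tsv(write_matrix_tsv(m))`
#' reproduces `m`, up to full double precision).
#'
#' @param m numeric matrix with dimnames, or a `VPlotMatrix` (its
#'   `values` are written).
#' @param path output path.
#' @param row_label header for the row-label column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, row_label = "row") {
  if (inherits(m, "VPlotMatrix") || inherits(m, "DiffVPlot")) m <- m$values
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(row_label, colnames(m)), collapse = "\t"), con)
  if (nrow(m) > 0L) {
    body <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
            collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- rn
  m
}

#' Read / write a gene expression table
#'
#' Tab-separated with header: `gene_id`, `chrom`, `tss` (0-based
#' coordinate), `strand`, `expression` (non-negative, FPKM-like), and
#' optionally `tier` (low/medium/high).
#'
#' @param path TSV path.
#' @return data.frame of expression records.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand", "expression")
  if (!all(need %in% names(d))) {
    stop(sprintf("%s: expression table requires columns %s", path,
                 paste(need, collapse = ", ")))
  }
  if (any(d$expression < 0)) stop("expression values must be non-negative")
  d
}

#' @rdname read_expression
#' @param expr expression data.frame.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
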