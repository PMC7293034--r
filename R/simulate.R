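#' Define a nucleosome unwrapping state
#'
#' An unwrapping state is a component of the fragment-length mixture a
#' nucleosome emits under MNase digestion: a protected-length mode, its
#' spread, and a placement geometry. Placements: `symmetric` fragments
#' are centered on the dyad (intact cores and footprint-like
#' protections); `left_retained` fragments keep the left edge of the
#' 147-bp core, spanning `[dyad - 73, dyad - 73 + L)`; `right_retained`
#' fragments keep the right edge, spanning `[dyad + 73 - L, dyad + 73)`;
#' `footprint` fragments are centered on the reference (used for small
#' factor-protected fragments at CTCF site centers).
#'
#' @param name state label.
#' @param length_mode mean protected fragment length (bp), in [20, 200].
#' @param length_sd standard deviation of the length (bp), > 0.
#' @param placement one of `"symmetric"`, `"left_retained"`,
#'   `"right_retained"`, `"footprint"`.
#' @param weight mixing proportion (weights of a mixture sum to 1).
#' @return list of class `UnwrapState`.
#' @export
unwrap_state <- function(name, length_mode, length_sd, placement = "symmetric",
                         weight = 1) {
  placement <- match.arg(placement,
                         c("symmetric", "left_retained", "right_retained", "footprint"))
  if (length_mode < 20 || length_mode > 200) stop("length_mode must be in [20, 200]")
  if (length_sd <= 0) stop("length_sd must be > 0")
  if (weight < 0) stop("weight must be >= 0")
  structure(
    list(name = name, length_mode = length_mode, length_sd = length_sd,
         placement = placement, weight = weight),
    class = "UnwrapState"
  )
}

#' Assemble and validate a state mixture
#' @param ... `UnwrapState` objects whose weights sum to 1 (tolerance
#'   1e-9).
#' @return list of class `UnwrapMixture`.
#' @export
state_mixture <- function(...) {
  states <- list(...)
  if (length(states) == 1L && !inherits(states[[1L]], "UnwrapState")) {
    states <- states[[1L]]
  }
  if (!length(states) || !all(vapply(states, inherits, logical(1), "UnwrapState"))) {
    stop("a mixture is built from UnwrapState objects")
  }
  w <- vapply(states, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("mixture weights sum to %.12f, not 1", sum(w)))
  }
  structure(states, class = "UnwrapMixture")
}

# Split a state into equal-weight left/right retained pair (one-sided
# unwrapping has no preferred side on average).
split_sides <- function(name, mode, sd, weight) {
  list(
    unwrap_state(paste0(name, "_L"), mode, sd, "left_retained", weight / 2),
    unwrap_state(paste0(name, "_R"), mode, sd, "right_retained", weight / 2)
  )
}

#' Default canonical-histone mixture (deep digestion)
#'
#' Five modes: the intact core at 147 bp (symmetric) plus partially
#' unwrapped protections at 127, 105, 91 and 69 bp (one-sided, split
#' equally between left- and right-retained), sd 3 bp throughout.
#' Weights 0.45/0.20/0.15/0.12/0.08 (free parameters; the modes are the
#' observable the mixture is designed around).
#'
#' @return an `UnwrapMixture`.
#' @export
mixture_canonical_longmn <- function() {
  state_mixture(c(
    list(unwrap_state("core147", 147, 3, "symmetric", 0.45)),
    split_sides("unwrap127", 127, 3, 0.20),
    split_sides("unwrap105", 105, 3, 0.15),
    split_sides("unwrap91", 91, 3, 0.12),
    split_sides("unwrap69", 69, 3, 0.08)
  ))
}

#' Default H2A.Z-variant mixture (deep digestion)
#'
#' Dominated by strongly unwrapped 30-80 bp protection (a broad mode at
#' 55 bp, weight 0.6) with far lower weight on larger fragments,
#' emulating a variant histone enriched in unwrapping states.
#'
#' @return an `UnwrapMixture`.
#' @export
mixture_h2az_longmn <- function() {
  state_mixture(c(
    split_sides("unwrap55", 55, 10, 0.60),
    split_sides("unwrap91", 91, 4, 0.10),
    split_sides("unwrap105", 105, 4, 0.10),
    split_sides("unwrap127", 127, 4, 0.10),
    list(unwrap_state("core147", 147, 3, "symmetric", 0.10))
  ))
}

#' Sample fragments from dyads and a state mixture
#'
#' For each dyad, draws a state from the mixture, a length
#' `L ~ round(Normal(length_mode, length_sd))` clipped to [20, 200], and
#' places the fragment per the state's geometry (see [unwrap_state()]).
#' Gaussian dyad jitter (rounded) is applied before placement. Uses the
#' current RNG state; seed management belongs to the callers.
#'
#' @param dyads integer vector of dyad positions (each >= 100).
#' @param mixture an `UnwrapMixture`.
#' @param jitter_sd dyad jitter sd in bp (0 = none).
#' @return data.frame with columns start, end (0-based half-open).
#' @export
sample_fragments <- function(dyads, mixture, jitter_sd = 0) {
  stopifnot(inherits(mixture, "UnwrapMixture"))
  n <- length(dyads)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  if (any(dyads < 100L)) stop("dyads must be >= 100")
  w <- vapply(mixture, `[[`, numeric(1), "weight")
  modes <- vapply(mixture, `[[`, numeric(1), "length_mode")
  sds <- vapply(mixture, `[[`, numeric(1), "length_sd")
  plc <- vapply(mixture, `[[`, character(1), "placement")
  s <- sample.int(length(mixture), n, replace = TRUE, prob = w)
  L <- as.integer(pmin(pmax(round(stats::rnorm(n, modes[s], sds[s])), 20L), 200L))
  d <- as.integer(dyads)
  if (jitter_sd > 0) d <- d + as.integer(round(stats::rnorm(n, 0, jitter_sd)))
  start <- integer(n)
  p <- plc[s]
  sym <- p %in% c("symmetric", "footprint")
  start[sym] <- d[sym] - L[sym] %/% 2L
  lft <- p == "left_retained"
  start[lft] <- d[lft] - 73L
  rgt <- p == "right_retained"
  start[rgt] <- d[rgt] + 73L - L[rgt]
  data.frame(start = start, end = start + L)
}

#' Simulate one histone sample as an i.i.d. mixture draw
#'
#' Draws `n` fragments from a state mixture at dyads scattered uniformly
#' on a synthetic chromosome. This emulates the bulk fragment-length
#' behaviour of one ChIPed sample without any positional structure;
#' use the landscape simulators for promoter/CTCF-site geometry.
#'
#' @param mixture an `UnwrapMixture`.
#' @param n number of fragments (>= 1).
#' @param seed optional RNG seed (sets the global RNG).
#' @param chrom chromosome name.
#' @param chrom_length synthetic chromosome length in bp.
#' @param label sample label.
#' @return a `FragmentSet`.
#' @export
simulate_histone_sample <- function(mixture, n, seed = NULL, chrom = "chrS",
                                    chrom_length = 5e6, label = "synthetic") {
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dyads <- sample.int(as.integer(chrom_length) - 500L, n, replace = TRUE) + 250L
  fr <- sample_fragments(dyads, mixture)
  fragment_set(chrom, fr$start, fr$end, label = label)
}

# Move `shift` probability mass from the short-fragment groups
# (mode < 120 bp) to the long-fragment groups (>= 120 bp), removing it
# proportionally from the donors and adding proportionally to the
# recipients. Models a condition (e.g. a variant-histone knockdown)
# where nucleosomes become less unwrapped.
shift_weights_to_long <- function(w, shift, modes) {
  if (shift == 0) return(w)
  if (shift < 0) stop("shift must be >= 0")
  donor <- modes < 120
  recip <- !donor
  if (!any(donor) || !any(recip)) stop("weight shift needs both short and long states")
  ws <- sum(w[donor])
  if (shift > ws + 1e-12) stop(sprintf("cannot shift %.3f from total short mass %.3f", shift, ws))
  w[donor] <- w[donor] * (1 - shift / ws)
  w[recip] <- w[recip] + shift * w[recip] / sum(w[recip])
  if (abs(sum(w) - 1) > 1e-9 || any(w < -1e-12)) stop("invalid post-shift mixture")
  pmax(w, 0)
}
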