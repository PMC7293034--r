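#' Default run configuration
#'
#' A nested list of every tunable the pipeline exposes, with defaults
#' materialized. A config file ([load_config()]) or CLI flags override
#' entries; unknown keys are rejected so typos fail loudly.
#'
#' @return nested list of class `RunConfig`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    outdir = "nucwrap_out",
    log_level = "info",
    paths = list(
      fragments = NULL, fragments_control = NULL, references = NULL,
      tss = NULL, centers = NULL, fasta = NULL, expression = NULL,
      peaks_a = NULL, peaks_b = NULL, ratios = NULL
    ),
    scheme = list(min_small = 30L),
    flp = list(min_len = 0L, max_len = 200L, smooth_halfwidth = 2L,
               min_prominence = 0.05),
    vplot = list(window = 2000L, len_min = 30L, len_max = 200L, norm = "CPB"),
    groups = list(halfwidth = 100L, min_fragments = 20L),
    plus1 = list(min_dist = 50L, max_dist = 200L),
    cluster = list(k = 5L, linkage = "complete", metric = "euclidean",
                   mad_constant = 1.4826),
    tracks = list(binsize = 10L),
    simulate = list(landscape = "tss", n_genes = 2000L, n_cbs = 200L,
                    shift = 0, footprint_weight = 0.1)
  ), class = "RunConfig")
}

# Recursively overlay `over` onto `base`, rejecting keys absent from the
# defaults. `where` tracks the nesting for error messages.
merge_config <- function(base, over, where = "") {
  errs <- character(0)
  for (k in names(over)) {
    path <- if (nzchar(where)) paste0(where, ".", k) else k
    if (!k %in% names(base)) {
      errs <- c(errs, sprintf("unknown config key '%s'", path))
      next
    }
    if (is.list(base[[k]]) && is.list(over[[k]])) {
      res <- merge_config(base[[k]], over[[k]], path)
      base[[k]] <- res$config
      errs <- c(errs, res$errors)
    } else {
      base[[k]] <- over[[k]]
    }
  }
  list(config = base, errors = errs)
}

validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(config$seed) && config$seed == as.integer(config$seed),
      "seed must be an integer")
  chk(config$flp$min_len <= config$flp$max_len, "flp: min_len > max_len")
  chk(config$vplot$len_min <= config$vplot$len_max, "vplot: len_min > len_max")
  chk(config$vplot$window >= 1, "vplot: window must be >= 1")
  chk(config$vplot$norm %in% c("CPB", "raw"), "vplot: norm must be CPB or raw")
  chk(config$cluster$k >= 1, "cluster: k must be >= 1")
  chk(config$scheme$min_small >= 1 && config$scheme$min_small <= 80,
      "scheme: min_small must be in [1, 80]")
  chk(config$simulate$landscape %in% c("tss", "cbs", "histone"),
      "simulate: landscape must be tss, cbs or histone")
  chk(config$groups$halfwidth >= 1, "groups: halfwidth must be >= 1")
  # scheme sanity through the constructor (overlapping/invalid ranges)
  tryCatch(fragment_group_scheme(config$scheme$min_small),
           error = function(e) errs <<- c(errs, paste0("scheme: ", conditionMessage(e))))
  errs
}

#' Load and validate a run configuration
#'
#' Reads a YAML config file (if given), overlays it on the defaults,
#' then overlays explicit `overrides` (e.g. parsed CLI flags). All
#' validation problems are reported together in one error.
#'
#' @param path optional YAML file path.
#' @param overrides optional nested list of overrides (highest
#'   precedence).
#' @return validated `RunConfig`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  config <- default_config()
  errs <- character(0)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    res <- merge_config(config, user)
    config <- res$config
    errs <- c(errs, res$errors)
  }
  if (length(overrides)) {
    res <- merge_config(config, overrides)
    config <- res$config
    errs <- c(errs, res$errors)
  }
  errs <- c(errs, validate_config(config))
  if (length(errs)) {
    stop(paste(c("invalid configuration:", paste0("  - ", errs)), collapse = "\n"),
         call. = FALSE)
  }
  class(config) <- "RunConfig"
  config
}

# JSON run manifest written next to each subcommand's outputs. No
# timestamp: identical config + seed must give byte-identical output
# trees.
write_manifest <- function(outdir, subcommand, config, outputs) {
  manifest <- list(
    tool = "nucwrap",
    version = as.character(utils::packageVersion("nucwrap")),
    subcommand = subcommand,
    seed = config$seed,
    config = unclass(config),
    outputs = outputs
  )
  path <- file.path(outdir, paste0("manifest_", subcommand, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

log_msg <- function(config, level, fmt, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] >= levels[[config$log_level %||% "info"]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
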