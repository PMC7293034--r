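#' Run a pipeline subcommand
#'
#' Dispatches one named analysis stage on a validated configuration and
#' writes its outputs (plus a JSON run manifest) under
#' `config$outdir`. This is the programmatic core of the command-line
#' interface; each stage is a thin wrapper over the exported analysis
#' functions. Outputs are deterministic under a fixed `config$seed`.
#'
#' Subcommands: `simulate`, `flp`, `vplot`, `diffvplot`, `metaprofile`,
#' `groups`, `plus1`, `cluster`, `orient-cbs`, `tracks`, `overlap`.
#'
#' @param name subcommand name.
#' @param config a `RunConfig` from [load_config()].
#' @return invisible named list of output file paths.
#' @export
run_subcommand <- function(name, config) {
  name <- match.arg(name, c("simulate", "flp", "vplot", "diffvplot", "metaprofile",
                            "groups", "plus1", "cluster", "orient-cbs", "tracks",
                            "overlap"))
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  need <- function(key) {
    p <- config$paths[[key]]
    if (is.null(p)) stop(sprintf("subcommand '%s' requires paths.%s", name, key),
                         call. = FALSE)
    p
  }
  scheme <- fragment_group_scheme(config$scheme$min_small)
  outputs <- switch(
    name,
    simulate = {
      s <- config$simulate
      if (s$landscape == "tss") {
        land <- simulate_tss_landscape(n_genes = s$n_genes, seed = config$seed,
                                       kd_shift = s$shift)
        paths <- list(
          fragments = file.path(config$outdir, "fragments.bed"),
          tss = file.path(config$outdir, "tss.bed"),
          centers = file.path(config$outdir, "centers.bed"),
          expression = file.path(config$outdir, "expression.tsv"),
          truth = file.path(config$outdir, "truth.tsv")
        )
        write_fragments(land$fragments, paths$fragments)
        write_reference_points(land$tss, paths$tss)
        write_reference_points(
          reference_points(land$truth$chrom, land$truth$plus1_dyad,
                           kind = "NUC_CENTER", name = land$truth$gene_id),
          paths$centers
        )
        write_expression(land$expression, paths$expression)
        utils::write.table(land$truth, paths$truth, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths
      } else if (s$landscape == "cbs") {
        land <- simulate_cbs_landscape(n_cbs = s$n_cbs, seed = config$seed,
                                       footprint_weight = s$footprint_weight,
                                       kd_shift = s$shift)
        paths <- list(
          fragments = file.path(config$outdir, "fragments.bed"),
          cbs = file.path(config$outdir, "cbs.bed"),
          peaks = file.path(config$outdir, "peaks.bed"),
          fasta = file.path(config$outdir, "genome.fa"),
          truth = file.path(config$outdir, "truth.tsv")
        )
        write_fragments(land$fragments, paths$fragments)
        write_reference_points(land$cbs, paths$cbs)
        writeLines(sprintf("%s\t%d\t%d\t%s", land$peaks$chrom, land$peaks$start,
                           land$peaks$end, land$peaks$name), paths$peaks)
        Biostrings::writeXStringSet(land$genome, paths$fasta)
        utils::write.table(land$truth, paths$truth, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths
      } else {
        fs <- simulate_histone_sample(mixture_canonical_longmn(),
                                      n = s$n_genes * 100L, seed = config$seed)
        paths <- list(fragments = file.path(config$outdir, "fragments.bed"))
        write_fragments(fs, paths$fragments)
        paths
      }
    },
    flp = {
      fs <- read_fragments(need("fragments"))
      p <- compute_flp(fs, config$flp$min_len, config$flp$max_len)
      pk <- find_peaks(p, config$flp$smooth_halfwidth, config$flp$min_prominence)
      paths <- list(flp = file.path(config$outdir, "flp.tsv"),
                    peaks = file.path(config$outdir, "flp_peaks.tsv"))
      write_flp(p, paths$flp)
      utils::write.table(pk, paths$peaks, sep = "\t", quote = FALSE, row.names = FALSE)
      paths
    },
    vplot = {
      fs <- read_fragments(need("fragments"))
      refs <- read_reference_points(need("references"), kind = "TSS")
      v <- compute_vplot(fs, refs, W = config$vplot$window,
                         len_range = c(config$vplot$len_min, config$vplot$len_max),
                         norm = config$vplot$norm)
      paths <- list(vplot = file.path(config$outdir, "vplot.tsv"))
      write_matrix_tsv(v, paths$vplot, row_label = "length")
      paths
    },
    diffvplot = {
      fs_t <- read_fragments(need("fragments"))
      fs_c <- read_fragments(need("fragments_control"))
      refs <- read_reference_points(need("references"), kind = "TSS")
      lr <- c(config$vplot$len_min, config$vplot$len_max)
      dv <- difference_vplot(
        compute_vplot(fs_t, refs, W = config$vplot$window, len_range = lr, norm = "CPB"),
        compute_vplot(fs_c, refs, W = config$vplot$window, len_range = lr, norm = "CPB")
      )
      paths <- list(diffvplot = file.path(config$outdir, "diffvplot.tsv"))
      write_matrix_tsv(dv, paths$diffvplot, row_label = "length")
      paths
    },
    metaprofile = {
      fs <- read_fragments(need("fragments"))
      refs <- read_reference_points(need("references"), kind = "TSS")
      v <- compute_vplot(fs, refs, W = config$vplot$window,
                         len_range = c(config$vplot$len_min, config$vplot$len_max),
                         norm = config$vplot$norm)
      mp <- aggregate_groups(v, scheme)
      paths <- list(metaprofile = file.path(config$outdir, "metaprofile.tsv"))
      write_matrix_tsv(mp$profiles, paths$metaprofile, row_label = "group")
      paths
    },
    groups = {
      fs <- read_fragments(need("fragments"))
      centers <- read_reference_points(need("centers"), kind = "NUC_CENTER")
      wins <- windows_around(centers, config$groups$halfwidth)
      tab <- window_group_ratios(fs, wins, scheme, config$groups$min_fragments)
      paths <- list(ratios = file.path(config$outdir, "group_ratios.tsv"))
      utils::write.table(as.data.frame(tab), paths$ratios, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths
    },
    plus1 = {
      centers <- read_reference_points(need("centers"), kind = "NUC_CENTER")
      tss <- read_reference_points(need("tss"), kind = "TSS")
      sel <- select_plus1(centers, tss, config$plus1$min_dist, config$plus1$max_dist)
      paths <- list(plus1 = file.path(config$outdir, "plus1.tsv"))
      utils::write.table(sel, paths$plus1, sep = "\t", quote = FALSE, row.names = FALSE)
      paths
    },
    cluster = {
      tab <- utils::read.delim(need("ratios"), stringsAsFactors = FALSE)
      attr(tab, "scheme") <- scheme
      class(tab) <- c("GroupRatioTable", "data.frame")
      m <- scale_ratios(tab, config$cluster$mad_constant)
      r <- hcluster(m, k = config$cluster$k, linkage = config$cluster$linkage,
                    metric = config$cluster$metric)
      if (config$cluster$k == 5L) r <- label_clusters(r, m)
      assign_df <- data.frame(window = names(r$assignment),
                              cluster = unname(r$assignment),
                              label = if (!is.null(r$labels)) unname(r$label_by_row)
                                      else NA_character_)
      paths <- list(assignments = file.path(config$outdir, "cluster_assignments.tsv"))
      utils::write.table(assign_df, paths$assignments, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      if (!is.null(config$paths$expression)) {
        expr <- read_expression(config$paths$expression)
        rep_ <- correlate_ratios_expression(tab, expr)
        paths$correlations <- file.path(config$outdir, "expression_correlations.tsv")
        utils::write.table(as.data.frame(rep_), paths$correlations, sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      paths
    },
    `orient-cbs` = {
      peaks <- utils::read.delim(need("peaks_a"), header = FALSE,
                                 stringsAsFactors = FALSE)
      names(peaks)[1:3] <- c("chrom", "start", "end")
      if (ncol(peaks) >= 4L) names(peaks)[4L] <- "name"
      cbs <- orient_cbs(peaks, need("fasta"))
      paths <- list(cbs = file.path(config$outdir, "cbs_oriented.bed"))
      write_reference_points(cbs, paths$cbs)
      paths
    },
    tracks = {
      fs <- read_fragments(need("fragments"))
      tr <- group_tracks(fs, scheme, config$tracks$binsize)
      paths <- lapply(names(tr), function(g) {
        p <- file.path(config$outdir, sprintf("track_%s.bedgraph", g))
        write_bedgraph(tr[[g]], p, name = g, binsize = config$tracks$binsize)
        p
      })
      names(paths) <- paste0("track_", names(tr))
      paths
    },
    overlap = {
      rd <- function(p) {
        d <- utils::read.delim(p, header = FALSE, stringsAsFactors = FALSE)
        names(d)[1:3] <- c("chrom", "start", "end")
        d
      }
      ov <- interval_overlap(rd(need("peaks_a")), rd(need("peaks_b")))
      paths <- list(overlap = file.path(config$outdir, "overlap.json"))
      jsonlite::write_json(as.list(ov$counts), paths$overlap, auto_unbox = TRUE)
      paths
    }
  )
  write_manifest(config$outdir, name, config, outputs)
  log_msg(config, "info", "subcommand '%s' wrote %d output file(s) to %s",
          name, length(outputs), config$outdir)
  invisible(outputs)
}
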