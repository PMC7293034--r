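# Length/placement parameters of the state each fragment group is drawn
# from in the landscape simulators. "sided" states retain one edge of
# the 147-bp core (left/right with equal probability); the intact-core
# group is symmetric about the dyad.
landscape_group_states <- function() {
  data.frame(
    group = c("G80", "G100", "G120", "G140", "G168"),
    mode = c(60, 91, 110, 130, 150),
    sd = c(8, 4, 5, 5, 5),
    sided = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Draw fragments at given dyads with per-fragment group weights.
# weights: matrix n x 5 (rows aligned with dyads) or a single row.
draw_group_fragments <- function(dyads, weights, jitter_sd = 10,
                                 sided_placement = TRUE) {
  st <- landscape_group_states()
  n <- length(dyads)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0), group = character(0)))
  if (is.null(dim(weights))) weights <- matrix(weights, n, 5L, byrow = TRUE)
  cw <- weights %*% upper.tri(diag(5L), diag = TRUE)  # row-wise cumsum
  u <- stats::runif(n) * cw[, 5L]
  grp <- rep(1L, n)
  for (j in 1:4) grp <- grp + (u > cw[, j])
  L <- as.integer(pmin(pmax(round(stats::rnorm(n, st$mode[grp], st$sd[grp])), 20L), 200L))
  d <- as.integer(dyads)
  if (jitter_sd > 0) d <- d + as.integer(round(stats::rnorm(n, 0, jitter_sd)))
  start <- d - L %/% 2L
  if (sided_placement) {
    sided <- st$sided[grp]
    left <- sided & stats::runif(n) < 0.5
    right <- sided & !left
    start[left] <- d[left] - 73L
    start[right] <- d[right] + 73L - L[right]
  }
  data.frame(start = start, end = start + L, group = st$group[grp],
             stringsAsFactors = FALSE)
}

#' Simulate a promoter (TSS) landscape with planted unwrapping classes
#'
#' Generates a synthetic chromosome of phased nucleosome arrays at
#' `n_genes` promoters with known ground truth. Each gene has: a TSS
#' with random strand; a +1 nucleosome dyad placed 50-200 bp downstream
#' (strand-aware); downstream nucleosomes at multiples of `nuc_spacing`;
#' a -1 nucleosome upstream of a nucleosome-depleted region (NDR) that
#' emits no nucleosomal fragments (optionally a small proportion of
#' "fragile" short fragments); an expression value and tier
#' (low/medium/high, planted in equal numbers); and a planted
#' unwrapping class A-E that over-weights the corresponding fragment
#' group at the +1 nucleosome.
#'
#' Per-gene +1 group weights are built as: base weights, plus
#' `cluster_boost` on the planted class's group, plus an expression-tier
#' tilt that moves `expr_shift` mass per tier step from the 30-80 bp
#' group to the 121-168 bp groups (so strong unwrapping anti-correlates
#' with expression), renormalized and then perturbed by a Dirichlet draw
#' with concentration `dirichlet_conc` (per-nucleosome biological
#' variability). `kd_shift` moves mass from sub-120-bp groups to the
#' 120+ groups after all of the above (a knockdown-like condition;
#' see [simulate_knockdown()]).
#'
#' Two RNG streams make condition pairs comparable: the landscape
#' structure (positions, strands, classes, tiers, expression, weights)
#' is drawn under `seed`, fragments under `seed + 1`, so two runs
#' differing only in `kd_shift` share identical reference points and
#' truth.
#'
#' @param n_genes number of genes (>= 10).
#' @param seed RNG seed.
#' @param gene_spacing bp between consecutive TSSs.
#' @param plus1_offset_range downstream distance range of the +1 dyad.
#' @param nuc_spacing nucleosome repeat length (bp).
#' @param ndr_halfwidth NDR half-width upstream of the TSS (bp).
#' @param dyad_jitter_sd per-fragment dyad jitter sd (bp).
#' @param frags_plus1 fragments emitted per +1 nucleosome.
#' @param frags_other fragments per non-+1 nucleosome slot.
#' @param n_other_nucs downstream slots (+2, +3, ...) per gene.
#' @param cluster_boost weight boost of the planted class's group.
#' @param dirichlet_conc Dirichlet concentration of per-gene weights.
#' @param base_weights named base group weights (sum 1).
#' @param expr_shift per-tier-step weight transfer from G80 to G140/G168.
#' @param fragile_weight proportion of NDR "fragile" short fragments
#'   relative to the +1 fragment count (default 0 = none).
#' @param kd_shift knockdown-like weight transfer to the long groups.
#' @param chrom chromosome name.
#' @param label FragmentSet label.
#' @return list with `fragments` (FragmentSet), `tss` (reference
#'   points), `expression` (data.frame gene_id/chrom/tss/strand/
#'   expression/tier), `truth` (per-gene data.frame: cluster, tier,
#'   plus1_dyad, planted weights), `params`.
#' @export
simulate_tss_landscape <- function(n_genes = 2000L, seed = NULL,
                                   gene_spacing = 5000L,
                                   plus1_offset_range = c(50L, 200L),
                                   nuc_spacing = 180L,
                                   ndr_halfwidth = 150L,
                                   dyad_jitter_sd = 10,
                                   frags_plus1 = 400L,
                                   frags_other = 100L,
                                   n_other_nucs = 3L,
                                   cluster_boost = 0.5,
                                   dirichlet_conc = 50,
                                   base_weights = c(G80 = 0.40, G100 = 0.15,
                                                    G120 = 0.15, G140 = 0.15,
                                                    G168 = 0.15),
                                   expr_shift = 0.05,
                                   fragile_weight = 0,
                                   kd_shift = 0,
                                   chrom = "chrS",
                                   label = "synthetic_tss") {
  n_genes <- as.integer(n_genes)
  if (n_genes < 10L) stop("n_genes must be >= 10 (too small for clustering)")
  if (abs(sum(base_weights) - 1) > 1e-9) stop("base_weights must sum to 1")
  st <- landscape_group_states()

  ## -- structure stream ------------------------------------------------
  if (!is.null(seed)) set.seed(seed)
  tss_pos <- 2000L + (seq_len(n_genes) - 1L) * as.integer(gene_spacing)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  dir <- ifelse(strand == "-", -1L, 1L)
  cluster <- sample(rep(c("A", "B", "C", "D", "E"), length.out = n_genes))
  tier <- sample(rep(c("low", "medium", "high"), length.out = n_genes))
  tier_idx <- match(tier, c("low", "medium", "high"))
  meanlog <- c(0, 2, 4)[tier_idx]
  expression <- exp(stats::rnorm(n_genes, meanlog, 0.5))
  offs <- sample(seq.int(plus1_offset_range[1L], plus1_offset_range[2L]),
                 n_genes, replace = TRUE)
  plus1_dyad <- tss_pos + dir * offs

  w <- matrix(base_weights, n_genes, 5L, byrow = TRUE,
              dimnames = list(NULL, st$group))
  w[cbind(seq_len(n_genes), match(cluster, c("A", "B", "C", "D", "E")))] <-
    w[cbind(seq_len(n_genes), match(cluster, c("A", "B", "C", "D", "E")))] + cluster_boost
  delta <- expr_shift * (tier_idx - 2L)
  w[, "G80"] <- w[, "G80"] - delta
  w[, "G140"] <- w[, "G140"] + delta / 2
  w[, "G168"] <- w[, "G168"] + delta / 2
  w <- w / rowSums(w)
  if (dirichlet_conc > 0) {
    g <- matrix(stats::rgamma(n_genes * 5L, shape = dirichlet_conc * w), n_genes, 5L)
    w <- g / rowSums(g)
    colnames(w) <- st$group
  }
  if (kd_shift > 0) {
    w <- t(apply(w, 1L, shift_weights_to_long, shift = kd_shift, modes = st$mode))
    colnames(w) <- st$group
  }

  ## -- fragment stream -------------------------------------------------
  set.seed(if (is.null(seed)) sample.int(2^30, 1L) else seed + 1L)
  gene_of <- rep(seq_len(n_genes), each = frags_plus1)
  fr_plus1 <- draw_group_fragments(plus1_dyad[gene_of], w[gene_of, , drop = FALSE],
                                   jitter_sd = dyad_jitter_sd)
  other <- list()
  base_w <- if (kd_shift > 0) {
    shift_weights_to_long(base_weights, kd_shift, st$mode)
  } else {
    base_weights
  }
  slot_dyads <- function(k) {
    if (k == -1L) plus1_dyad - dir * (as.integer(ndr_halfwidth) + 73L + offs)
    else plus1_dyad + dir * (k - 1L) * as.integer(nuc_spacing)
  }
  for (k in c(if (n_other_nucs >= 1L) seq.int(2L, n_other_nucs + 1L) else integer(0), -1L)) {
    dy <- slot_dyads(k)
    g <- rep(seq_len(n_genes), each = frags_other)
    other[[length(other) + 1L]] <-
      draw_group_fragments(dy[g], matrix(base_w, length(g), 5L, byrow = TRUE),
                           jitter_sd = dyad_jitter_sd)
  }
  frs <- rbind(fr_plus1, do.call(rbind, other))
  if (fragile_weight > 0) {
    n_fragile <- as.integer(round(fragile_weight * frags_plus1 * n_genes))
    gi <- sample.int(n_genes, n_fragile, replace = TRUE)
    ndr_center <- tss_pos[gi] - dir[gi] * (as.integer(ndr_halfwidth) %/% 2L)
    L <- as.integer(pmin(pmax(round(stats::rnorm(n_fragile, 45, 8)), 20L), 200L))
    s <- ndr_center - L %/% 2L
    frs <- rbind(frs, data.frame(start = s, end = s + L, group = "fragile"))
  }
  fragments <- fragment_set(chrom, frs$start, frs$end, label = label)

  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  tss <- reference_points(chrom, tss_pos, strand, kind = "TSS", name = gene_id)
  expr <- data.frame(gene_id = gene_id, chrom = chrom, tss = tss_pos,
                     strand = strand, expression = expression, tier = tier,
                     stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_id, chrom = chrom, tss = tss_pos,
                      strand = strand, plus1_dyad = plus1_dyad,
                      cluster = cluster, tier = tier, expression = expression,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, stats::setNames(as.data.frame(w), paste0("w_", st$group)))
  list(fragments = fragments, tss = tss, expression = expr, truth = truth,
       params = list(n_genes = n_genes, seed = seed, nuc_spacing = nuc_spacing,
                     ndr_halfwidth = ndr_halfwidth, cluster_boost = cluster_boost,
                     dirichlet_conc = dirichlet_conc, expr_shift = expr_shift,
                     kd_shift = kd_shift, frags_plus1 = frags_plus1))
}

#' Simulate a CTCF-binding-site landscape
#'
#' Generates a synthetic chromosome with `n_cbs` CTCF binding sites:
#' the 14-mer consensus (N drawn uniformly) is embedded at each site
#' center on a random strand in the emitted genome sequence; phased
#' nucleosomes flank each site at `+/- (ndr_halfwidth + 73 + k *
#' nuc_spacing)`; flanking nucleosomes emit fragments per
#' `flank_weights` with one-sided (edge-retained) placement of
#' subnucleosomal fragments, so short-fragment centers are bimodal
#' around each flanking dyad (`flanking_placement = "symmetric"`
#' removes the one-sidedness, an ablation control); short footprint
#' fragments (30-55 bp) are centered on the site with overall
#' proportion `footprint_weight`.
#'
#' Structure is drawn under `seed`, fragments under `seed + 1` (see
#' [simulate_tss_landscape()]).
#'
#' @param n_cbs number of CTCF sites.
#' @param seed RNG seed.
#' @param cbs_spacing bp between consecutive sites.
#' @param ndr_halfwidth half-width of the depleted region at the site.
#' @param nuc_spacing nucleosome repeat length (bp).
#' @param n_flank_nucs phased nucleosomes per side.
#' @param dyad_jitter_sd per-fragment dyad jitter sd (bp).
#' @param frags_per_nuc fragments per flanking nucleosome.
#' @param footprint_weight proportion of site-center footprint
#'   fragments among all emitted fragments, in [0, 1).
#' @param flank_weights group weights of flanking nucleosomes (sum 1).
#' @param flanking_placement `"retained"` (bimodal short fragments) or
#'   `"symmetric"`.
#' @param kd_shift knockdown-like weight transfer to the long groups.
#' @param chrom chromosome name.
#' @param label FragmentSet label.
#' @return list with `fragments` (FragmentSet), `cbs` (truth-oriented
#'   CBS reference points), `peaks` (site-spanning intervals for
#'   [orient_cbs()]), `genome` (DNAStringSet), `truth` (per-site
#'   data.frame incl. first flanking dyads), `params`.
#' @export
simulate_cbs_landscape <- function(n_cbs = 200L, seed = NULL,
                                   cbs_spacing = 4000L,
                                   ndr_halfwidth = 120L,
                                   nuc_spacing = 180L,
                                   n_flank_nucs = 2L,
                                   dyad_jitter_sd = 8,
                                   frags_per_nuc = 300L,
                                   footprint_weight = 0.1,
                                   flank_weights = c(G80 = 0.50, G100 = 0.125,
                                                     G120 = 0.125, G140 = 0.125,
                                                     G168 = 0.125),
                                   flanking_placement = c("retained", "symmetric"),
                                   kd_shift = 0,
                                   chrom = "chrS",
                                   label = "synthetic_cbs") {
  flanking_placement <- match.arg(flanking_placement)
  n_cbs <- as.integer(n_cbs)
  if (footprint_weight < 0 || footprint_weight >= 1) {
    stop("footprint_weight must be in [0, 1)")
  }
  if (abs(sum(flank_weights) - 1) > 1e-9) stop("flank_weights must sum to 1")
  st <- landscape_group_states()

  ## -- structure stream ------------------------------------------------
  if (!is.null(seed)) set.seed(seed)
  centers <- 2000L + (seq_len(n_cbs) - 1L) * as.integer(cbs_spacing)
  strand <- sample(c("+", "-"), n_cbs, replace = TRUE)
  chrom_len <- max(centers) + 2000L
  bases <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  motif <- strsplit(CTCF_CONSENSUS, "")[[1L]]
  for (i in seq_len(n_cbs)) {
    m <- motif
    m[m == "N"] <- sample(c("A", "C", "G", "T"), 1L)
    if (strand[i] == "-") {
      m <- rev(c(A = "T", C = "G", G = "C", T = "A")[m])
    }
    bases[(centers[i] - 7L + 1L):(centers[i] + 6L + 1L)] <- m
  }
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- chrom

  first_dist <- as.integer(ndr_halfwidth) + 73L
  flank_dists <- first_dist + (seq_len(n_flank_nucs) - 1L) * as.integer(nuc_spacing)

  fw <- if (kd_shift > 0) {
    shift_weights_to_long(flank_weights, kd_shift, st$mode)
  } else {
    flank_weights
  }

  ## -- fragment stream -------------------------------------------------
  set.seed(if (is.null(seed)) sample.int(2^30, 1L) else seed + 1L)
  frs <- list()
  for (k in seq_len(n_flank_nucs)) {
    for (side in c(-1L, 1L)) {
      dy <- centers + side * flank_dists[k]
      g <- rep(seq_len(n_cbs), each = frags_per_nuc)
      frs[[length(frs) + 1L]] <- draw_group_fragments(
        dy[g], matrix(fw, length(g), 5L, byrow = TRUE),
        jitter_sd = dyad_jitter_sd,
        sided_placement = flanking_placement == "retained"
      )
    }
  }
  n_nuc_frags <- 2L * n_flank_nucs * frags_per_nuc * n_cbs
  if (footprint_weight > 0) {
    n_fp <- as.integer(round(n_nuc_frags * footprint_weight / (1 - footprint_weight)))
    ci <- sample.int(n_cbs, n_fp, replace = TRUE)
    L <- as.integer(pmin(pmax(round(stats::rnorm(n_fp, 42, 6)), 30L), 55L))
    d <- centers[ci] + as.integer(round(stats::rnorm(n_fp, 0, 5)))
    s <- d - L %/% 2L
    frs[[length(frs) + 1L]] <- data.frame(start = s, end = s + L, group = "footprint")
  }
  frs <- do.call(rbind, frs)
  fragments <- fragment_set(chrom, frs$start, frs$end, label = label)

  site_id <- sprintf("cbs%03d", seq_len(n_cbs))
  cbs <- reference_points(chrom, centers, strand, kind = "CBS", name = site_id)
  peaks <- data.frame(chrom = chrom, start = centers - 50L, end = centers + 50L,
                      name = site_id, stringsAsFactors = FALSE)
  truth <- data.frame(name = site_id, chrom = chrom, center = centers,
                      strand = strand,
                      flank_dyad_left = centers - first_dist,
                      flank_dyad_right = centers + first_dist,
                      stringsAsFactors = FALSE)
  list(fragments = fragments, cbs = cbs, peaks = peaks, genome = genome,
       truth = truth,
       params = list(n_cbs = n_cbs, seed = seed, ndr_halfwidth = ndr_halfwidth,
                     nuc_spacing = nuc_spacing, n_flank_nucs = n_flank_nucs,
                     footprint_weight = footprint_weight,
                     flanking_placement = flanking_placement,
                     kd_shift = kd_shift))
}

#' Simulate a matched wild-type / knockdown condition pair
#'
#' Runs a landscape simulator twice with identical structure (same seed,
#' same reference points and truth) differing only in a transfer of
#' `shift` probability mass from the short-fragment groups (length mode
#' < 120 bp) to the long-fragment groups (>= 120 bp) in the knockdown
#' condition -- the signature of reduced nucleosome unwrapping after
#' depletion of an unwrapping-promoting factor. `shift = 0` reproduces
#' the wild type exactly.
#'
#' @param landscape `"tss"` or `"cbs"`.
#' @param shift weight transfer in [0, total short-group mass].
#' @param seed RNG seed (shared by both conditions).
#' @param ... passed to the landscape simulator.
#' @return list with elements `wt` and `kd`, each a landscape result.
#' @export
simulate_knockdown <- function(landscape = c("tss", "cbs"), shift = 0.2,
                               seed = NULL, ...) {
  landscape <- match.arg(landscape)
  sim <- switch(landscape, tss = simulate_tss_landscape, cbs = simulate_cbs_landscape)
  list(
    wt = sim(seed = seed, kd_shift = 0, ...),
    kd = sim(seed = seed, kd_shift = shift, ...)
  )
}
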