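#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generator.  The defaults
#' encode the study conditions the analysis stages are built to recover: a
#' multi-chromosome yeast-like gene layout, 79% of convergent transcript
#' pairs with overlapping 3' UTRs, axis occupancy centred 150 bp
#' downstream of transcript 3' ends, a 2.5-fold small-chromosome bias
#' (flattened to 1.25-fold in `hop1_delta` mode), centromere-flanking
#' doublets at +-270 bp (axis proteins) or +-345 bp (cohesin), a fourfold
#' centromere boost in `hop1_delta` mode, and 51-bp single-end reads from
#' ~200-bp fragments.
#'
#' @param chromosome_lengths chromosome lengths in bp; the `n_small`
#'   shortest carry the small-chromosome bias.
#' @param orf_meanlog,orf_sdlog,orf_min log-normal ORF length draw (bp).
#' @param gap_meanlog,gap_sdlog,gap_min log-normal intergenic gap draw (bp).
#' @param p_plus probability a gene is laid on the `+` strand.
#' @param overlap_fraction probability a convergent pair's transcripts
#'   overlap (default 0.79).
#' @param overlap_shape,overlap_scale,overlap_min gamma draw of the
#'   overlap extent (bp) for overlapping pairs.
#' @param utr5_mean,utr3_mean mean default UTR extensions (bp) where no
#'   convergent-overlap rule applies.
#' @param rpkm_meanlog,rpkm_sdlog log-normal RPKM distribution.
#' @param offset_mean,offset_sd normal draw of the site offset downstream
#'   of transcript 3' ends (bp; default mean 150).
#' @param tandem_mass_factor site mass multiplier for tandem-pair sites,
#'   in `[0, 1]`.
#' @param background_fraction fraction of ChIP reads drawn uniformly.
#' @param n_reads reads per sample; `read_length` read geometry (bp).
#' @param fragment_mean,fragment_sd normal fragment-length draw (bp),
#'   truncated at `read_length`.
#' @param small_chrom_factor per-bp occupancy of the `n_small` shortest
#'   chromosomes relative to the rest (default 2.5);
#'   `hop1_small_chrom_factor` replaces it in `hop1_delta` mode (1.25).
#' @param n_small number of small chromosomes carrying the bias.
#' @param cen_flank_axis,cen_flank_cohesin centromere flank-site distances
#'   (bp); which one is used follows `protein`.
#' @param protein `"axis"` (Red1/Hop1-like, 270 bp) or `"cohesin"`
#'   (Rec8-like, 345 bp).
#' @param centromere_boost centromere site mass multiplier in
#'   `hop1_delta` mode (default 4).
#' @param rec8_cen_factor centromere site mass multiplier in `rec8_delta`
#'   mode (default 0.2).
#' @param cen_mass_factor baseline centromere site mass, in units of the
#'   mean convergent site mass.
#' @param cen_pocket width (bp) of the transcript-free pocket holding the
#'   centromere.
#' @param rec8_smooth_window,rec8_exponent coding-density smoothing window
#'   (bp) and cluster exponent for `rec8_delta` occupancy.
#' @param density_exclude_cen half-width (bp) of the centromere exclusion
#'   used when defining per-chromosome density targets.
#' @param mode `"wild_type"`, `"rec8_delta"` or `"hop1_delta"`.
#' @param seed integer seed governing all generator randomness (split
#'   per stage, see Details).
#' @details A single seed drives the whole generator.  Each stage draws
#'   from its own stream via `(seed * 1009 + stage * 9973) mod (2^31 - 1)`
#'   with stage codes genome = 1, expression = 2, occupancy = 3, reads = 4,
#'   so regenerating one stage never perturbs another.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(
    chromosome_lengths = c(120e3, 130e3, 140e3, 300e3, 310e3, 320e3,
                           330e3, 340e3),
    orf_meanlog = log(1200), orf_sdlog = 0.45, orf_min = 150,
    gap_meanlog = log(400), gap_sdlog = 0.6, gap_min = 60,
    p_plus = 0.5,
    overlap_fraction = 0.79,
    overlap_shape = 1.5, overlap_scale = 120, overlap_min = 10,
    utr5_mean = 75, utr3_mean = 100,
    rpkm_meanlog = log(20), rpkm_sdlog = 1.1,
    offset_mean = 150, offset_sd = 50,
    tandem_mass_factor = 0.25,
    background_fraction = 0.2,
    n_reads = 5e5, read_length = 51,
    fragment_mean = 200, fragment_sd = 20,
    small_chrom_factor = 2.5, n_small = 3,
    hop1_small_chrom_factor = 1.25,
    cen_flank_axis = 270, cen_flank_cohesin = 345,
    protein = c("axis", "cohesin"),
    centromere_boost = 4, rec8_cen_factor = 0.2, cen_mass_factor = 3,
    cen_pocket = 500,
    rec8_smooth_window = 2000, rec8_exponent = 2,
    density_exclude_cen = 25e3,
    mode = c("wild_type", "rec8_delta", "hop1_delta"),
    seed = 1) {
  cfg <- list(chromosome_lengths = chromosome_lengths,
              orf_meanlog = orf_meanlog, orf_sdlog = orf_sdlog,
              orf_min = orf_min, gap_meanlog = gap_meanlog,
              gap_sdlog = gap_sdlog, gap_min = gap_min, p_plus = p_plus,
              overlap_fraction = overlap_fraction,
              overlap_shape = overlap_shape, overlap_scale = overlap_scale,
              overlap_min = overlap_min, utr5_mean = utr5_mean,
              utr3_mean = utr3_mean, rpkm_meanlog = rpkm_meanlog,
              rpkm_sdlog = rpkm_sdlog, offset_mean = offset_mean,
              offset_sd = offset_sd,
              tandem_mass_factor = tandem_mass_factor,
              background_fraction = background_fraction,
              n_reads = n_reads, read_length = read_length,
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              small_chrom_factor = small_chrom_factor, n_small = n_small,
              hop1_small_chrom_factor = hop1_small_chrom_factor,
              cen_flank_axis = cen_flank_axis,
              cen_flank_cohesin = cen_flank_cohesin,
              protein = match.arg(protein),
              centromere_boost = centromere_boost,
              rec8_cen_factor = rec8_cen_factor,
              cen_mass_factor = cen_mass_factor, cen_pocket = cen_pocket,
              rec8_smooth_window = rec8_smooth_window,
              rec8_exponent = rec8_exponent,
              density_exclude_cen = density_exclude_cen,
              mode = match.arg(mode), seed = seed)
  probs <- c(cfg$p_plus, cfg$overlap_fraction, cfg$background_fraction,
             cfg$tandem_mass_factor)
  if (any(probs < 0 | probs > 1))
    stop("probabilities/factors must lie in [0, 1]")
  pos <- c(cfg$chromosome_lengths, cfg$orf_min, cfg$gap_min, cfg$n_reads,
           cfg$read_length, cfg$fragment_mean, cfg$small_chrom_factor,
           cfg$cen_pocket)
  if (any(pos <= 0)) stop("lengths, counts and factors must be positive")
  if (cfg$offset_mean < 0 || cfg$offset_sd < 0)
    stop("offset_mean and offset_sd must be non-negative")
  if (cfg$n_small < 0 || length(cfg$chromosome_lengths) <= cfg$n_small)
    stop("need more chromosomes than n_small (n_small = 0 disables the ",
         "bias)")
  class(cfg) <- "simulation_config"
  cfg
}

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 9973) %% 2147483647)
}

#' Simulate a genome annotation
#'
#' Tiles each chromosome with non-overlapping ORFs separated by random
#' gaps, assigns strands, reserves a transcript-free pocket holding the
#' centromere near mid-chromosome, and derives transcripts whose 3' UTRs
#' overlap across convergent pairs with the configured probability.  The
#' two genes immediately flanking the pocket are laid divergently so that
#' no transcript (and no convergent-pair geometry) crosses the pocket.
#'
#' @param config a [simulation_config()].
#' @return a [genome_annotation()] with transcripts and centromeres.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, 1))
  n_chr <- length(config$chromosome_lengths)
  chrom_names <- sprintf("chr%02d", seq_len(n_chr))
  genes_all <- list()
  cen_mid <- numeric(n_chr)
  for (ci in seq_len(n_chr)) {
    len <- config$chromosome_lengths[ci]
    pc <- floor(len * stats::runif(1, 0.4, 0.6))
    pocket <- c(pc - floor(config$cen_pocket / 2),
                pc + ceiling(config$cen_pocket / 2))
    cen_mid[ci] <- pc
    starts <- ends <- numeric(0)
    pos <- 0
    repeat {
      g <- max(config$gap_min,
               round(stats::rlnorm(1, config$gap_meanlog, config$gap_sdlog)))
      L <- max(config$orf_min,
               round(stats::rlnorm(1, config$orf_meanlog, config$orf_sdlog)))
      s <- pos + g; e <- s + L
      if (e > len - 100) break
      if (s < pocket[2] && e > pocket[1]) { pos <- pocket[2]; next }
      starts <- c(starts, s); ends <- c(ends, e)
      pos <- e
    }
    n <- length(starts)
    if (n < 2)
      stop("infeasible layout: fewer than 2 genes on ", chrom_names[ci])
    strand <- ifelse(stats::runif(n) < config$p_plus, "+", "-")
    # divergent junction around the centromere pocket: 5' ends face it
    before <- which(ends <= pocket[1])
    after <- which(starts >= pocket[2])
    if (length(before)) strand[max(before)] <- "-"
    if (length(after)) strand[min(after)] <- "+"
    genes_all[[ci]] <- data.frame(
      id = sprintf("g%02d_%04d", ci, seq_len(n)),
      chrom = chrom_names[ci], start = starts, end = ends,
      strand = strand, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes_all)

  # default UTR extensions on the left/right coordinate side of each ORF
  n <- nrow(genes)
  u5 <- pmax(20, round(stats::rnorm(n, config$utr5_mean,
                                    config$utr5_mean / 3)))
  u3 <- pmax(20, round(stats::rnorm(n, config$utr3_mean,
                                    config$utr3_mean / 3)))
  left_ext <- ifelse(genes$strand == "+", u5, u3)
  right_ext <- ifelse(genes$strand == "+", u3, u5)

  # convergent pairs: redraw the two facing 3' UTRs to hit the target
  # overlap distribution
  for (ci in seq_len(n_chr)) {
    idx <- which(genes$chrom == chrom_names[ci])
    if (length(idx) < 2) next
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      if (genes$strand[i] != "+" || genes$strand[j] != "-") next
      g <- genes$start[j] - genes$end[i]
      if (stats::runif(1) < config$overlap_fraction) {
        v <- config$overlap_min +
          round(stats::rgamma(1, shape = config$overlap_shape,
                              scale = config$overlap_scale))
      } else {
        v <- -round(stats::runif(1, 0.2, 0.8) * max(g, 1))
      }
      tot <- max(g + v, 0)
      uL <- round(stats::runif(1, 0.3, 0.7) * tot)
      right_ext[i] <- uL
      left_ext[j] <- tot - uL
    }
  }

  len_of <- stats::setNames(config$chromosome_lengths, chrom_names)
  tx_start <- pmax(0, genes$start - left_ext)
  tx_end <- pmin(len_of[genes$chrom], genes$end + right_ext)
  # keep the centromere pocket transcript-free
  for (ci in seq_len(n_chr)) {
    pocket <- c(cen_mid[ci] - floor(config$cen_pocket / 2),
                cen_mid[ci] + ceiling(config$cen_pocket / 2))
    on_chr <- genes$chrom == chrom_names[ci]
    left_of <- on_chr & genes$end <= pocket[1]
    right_of <- on_chr & genes$start >= pocket[2]
    tx_end[left_of] <- pmin(tx_end[left_of], pocket[1])
    tx_start[right_of] <- pmax(tx_start[right_of], pocket[2])
  }
  transcripts <- data.frame(gene_id = genes$id, tx_start = tx_start,
                            tx_end = tx_end, stringsAsFactors = FALSE)
  genome_annotation(
    data.frame(name = chrom_names, length = config$chromosome_lengths,
               cen_mid = cen_mid, stringsAsFactors = FALSE),
    genes, transcripts)
}

#' Simulate per-gene expression (RPKM)
#'
#' @param annotation a [genome_annotation()].
#' @param config a [simulation_config()] (log-normal RPKM parameters).
#' @return named numeric vector of RPKM values, one per gene.
#' @export
simulate_expression <- function(annotation, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, 2))
  stats::setNames(stats::rlnorm(nrow(annotation$genes),
                                config$rpkm_meanlog, config$rpkm_sdlog),
                  annotation$genes$id)
}

retained_length <- function(len, cen, half) {
  if (is.na(cen)) return(len)
  len - (min(len, cen + half) - max(0, cen - half))
}

site_in_retained <- function(pos, len, cen, half) {
  if (is.na(cen)) return(rep(TRUE, length(pos)))
  pos < max(0, cen - half) | pos >= min(len, cen + half)
}

# Scale gene-derived site masses per chromosome so that the per-bp density
# over the centromere-excluded region equals `factor` x the rest-group
# density on the n_small shortest chromosomes, and is uniform elsewhere.
chromosome_scale_factors <- function(sites, annotation, factor, config) {
  chroms <- annotation$chromosomes
  half <- config$density_exclude_cen
  small <- chroms$name[order(chroms$length)][seq_len(config$n_small)]
  dens <- numeric(nrow(chroms))
  lret <- numeric(nrow(chroms))
  for (i in seq_len(nrow(chroms))) {
    cn <- chroms$name[i]
    keep <- sites$chrom == cn &
      site_in_retained(sites$position, chroms$length[i], chroms$cen_mid[i],
                       half)
    lret[i] <- retained_length(chroms$length[i], chroms$cen_mid[i], half)
    m <- sum(sites$mass[keep])
    if (m <= 0)
      stop("no gene-derived signal on chromosome ", cn)
    dens[i] <- m / lret[i]
  }
  base <- mean(dens[!chroms$name %in% small])
  target <- ifelse(chroms$name %in% small, base * factor, base)
  stats::setNames(target / dens, chroms$name)
}

#' Build ground-truth occupancy under the cohesin-sliding model
#'
#' Encodes the transcription-driven positioning model: RNA polymerase,
#' unable to pass through chromatin-bound cohesin, pushes it downstream of
#' each transcribed gene, so occupancy accumulates just past transcript 3'
#' ends.  For each convergent pair with overlapping transcripts
#' (`tx_overlap > 0`) two sites are placed at `e_L + offset` and
#' `e_R - offset` (offsets drawn `Normal(offset_mean, offset_sd)`,
#' truncated at 0), with masses proportional to the pushing gene's RPKM,
#' so the truth separation is `tx_overlap + 2 * offset_mean` when
#' `offset_sd = 0`.  Convergent pairs without overlap collapse to a single
#' full-mass site at the transcript-end midpoint.  Tandem pairs get one
#' site downstream of the upstream gene's 3' end with mass scaled by
#' `tandem_mass_factor`; divergent pairs get none.  Gene-derived masses
#' are then rescaled per chromosome so the `n_small` shortest chromosomes
#' carry `small_chrom_factor` (wild type) or `hop1_small_chrom_factor`
#' (`hop1_delta`) times the per-bp mass of the rest, measured outside the
#' +-`density_exclude_cen` centromere windows.  Finally, centromere-flank
#' sites are added at `cen_mid` +- 270 bp (axis) or 345 bp (cohesin), with
#' mass boosted `centromere_boost`-fold in `hop1_delta` mode.
#'
#' @param annotation a [genome_annotation()] with transcripts.
#' @param expression named RPKM vector covering every paired gene.
#' @param config a [simulation_config()]; `mode` must be `wild_type` or
#'   `hop1_delta` (see [build_occupancy_rec8_delta()] for `rec8_delta`).
#' @return object of class `occupancy_model`: list with `track` (per-bp
#'   expected occupancy), `sites` (registry: chrom, position, mass,
#'   source), `mode`, and `config`.
#' @export
build_occupancy <- function(annotation, expression, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "simulation_config"))
  if (config$mode == "rec8_delta")
    stop("use build_occupancy_rec8_delta() for rec8_delta mode")
  set.seed(stage_seed(config$seed, 3))
  pairs <- suppressWarnings(classify_gene_pairs(annotation))
  paired <- unique(c(pairs$left_gene, pairs$right_gene))
  missing <- setdiff(paired, names(expression))
  if (length(missing))
    stop("missing expression for paired gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  len_of <- chrom_lengths(annotation)

  sites <- list()
  conv <- pairs[pairs$orientation == "convergent" &
                !is.na(pairs$tx_overlap), , drop = FALSE]
  if (nrow(conv)) {
    rL <- unname(expression[conv$left_gene])
    rR <- unname(expression[conv$right_gene])
    oL <- pmax(0, round(stats::rnorm(nrow(conv), config$offset_mean,
                                     config$offset_sd)))
    oR <- pmax(0, round(stats::rnorm(nrow(conv), config$offset_mean,
                                     config$offset_sd)))
    two <- conv$tx_overlap > 0
    if (any(two)) {
      sites$conv_L <- data.frame(
        chrom = conv$chrom[two],
        position = conv$tx_end_left[two] + oL[two],
        mass = rL[two], source = "convergent_end",
        stringsAsFactors = FALSE)
      sites$conv_R <- data.frame(
        chrom = conv$chrom[two],
        position = conv$tx_start_right[two] - oR[two],
        mass = rR[two], source = "convergent_end",
        stringsAsFactors = FALSE)
    }
    if (any(!two)) {
      sites$conv_merge <- data.frame(
        chrom = conv$chrom[!two],
        position = conv$tx_mid[!two],
        mass = rL[!two] + rR[!two], source = "convergent_end",
        stringsAsFactors = FALSE)
    }
  }
  tand <- pairs[pairs$orientation == "tandem", , drop = FALSE]
  if (nrow(tand) && config$tandem_mass_factor > 0 &&
      !is.null(annotation$transcripts)) {
    tx <- annotation$transcripts
    txs <- stats::setNames(tx$tx_start, tx$gene_id)
    txe <- stats::setNames(tx$tx_end, tx$gene_id)
    gstr <- stats::setNames(annotation$genes$strand, annotation$genes$id)
    up_plus <- gstr[tand$left_gene] == "+"
    o <- pmax(0, round(stats::rnorm(nrow(tand), config$offset_mean,
                                    config$offset_sd)))
    pos <- ifelse(up_plus, unname(txe[tand$left_gene]) + o,
                  unname(txs[tand$right_gene]) - o)
    pusher <- ifelse(up_plus, tand$left_gene, tand$right_gene)
    sites$tandem <- data.frame(
      chrom = tand$chrom, position = pos,
      mass = config$tandem_mass_factor * unname(expression[pusher]),
      source = "tandem_end", stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)
  if (is.null(sites) || !nrow(sites))
    stop("annotation yields no occupancy sites")
  sites$position <- pmin(pmax(sites$position, 0), len_of[sites$chrom] - 1)

  factor <- if (config$mode == "hop1_delta") config$hop1_small_chrom_factor
            else config$small_chrom_factor
  sc <- chromosome_scale_factors(sites, annotation, factor, config)
  sites$mass <- sites$mass * unname(sc[sites$chrom])

  cen <- annotation$chromosomes
  if (any(!is.na(cen$cen_mid))) {
    flank <- if (config$protein == "axis") config$cen_flank_axis
             else config$cen_flank_cohesin
    # baseline centromere mass is anchored to the unbiased (rest-group)
    # chromosomes, whose scaling is identical in every mode, so the
    # hop1-delta boost is a clean factor relative to wild type
    small <- cen$name[order(cen$length)][seq_len(config$n_small)]
    conv_mass <- sites$mass[sites$source == "convergent_end" &
                            !sites$chrom %in% small]
    cm <- config$cen_mass_factor * mean(conv_mass)
    cm <- cm * switch(config$mode, wild_type = 1,
                      hop1_delta = config$centromere_boost)
    has <- !is.na(cen$cen_mid)
    cen_sites <- data.frame(
      chrom = rep(cen$name[has], each = 2L),
      position = as.vector(rbind(cen$cen_mid[has] - flank,
                                 cen$cen_mid[has] + flank)),
      mass = cm, source = "centromere_flank", stringsAsFactors = FALSE)
    cen_sites$position <- pmin(pmax(cen_sites$position, 0),
                               len_of[cen_sites$chrom] - 1)
    sites <- rbind(sites, cen_sites)
  }
  rownames(sites) <- NULL

  values <- lapply(len_of, numeric)
  for (cn in unique(sites$chrom)) {
    sel <- sites$chrom == cn
    agg <- rowsum(sites$mass[sel], sites$position[sel])
    values[[cn]][as.numeric(rownames(agg)) + 1] <- agg[, 1]
  }
  structure(list(track = coverage_track(values, label = "truth_occupancy"),
                 sites = sites, mode = config$mode, config = config),
            class = "occupancy_model")
}

#' Build rec8-delta ground-truth occupancy
#'
#' Without cohesin, axis-protein binding is no longer positioned by
#' transcript ends; it instead tracks the local coding density of the
#' genome, forming clusters over gene-dense regions.  Occupancy is the
#' 0/1 coding indicator smoothed with a boxcar window
#' (`rec8_smooth_window`, default 2 kb) and raised to `rec8_exponent`
#' (default 2); the small-chromosome scaling is retained and centromere
#' flank sites are attenuated by `rec8_cen_factor`.
#'
#' @param annotation a [genome_annotation()].
#' @param config a [simulation_config()] with `mode = "rec8_delta"`.
#' @return an `occupancy_model` (see [build_occupancy()]).
#' @export
build_occupancy_rec8_delta <- function(annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, 3))
  len_of <- chrom_lengths(annotation)
  chroms <- annotation$chromosomes
  half <- config$density_exclude_cen
  values <- lapply(len_of, numeric)
  for (i in seq_len(nrow(chroms))) {
    cn <- chroms$name[i]
    ind <- numeric(chroms$length[i])
    g <- annotation$genes[annotation$genes$chrom == cn, , drop = FALSE]
    for (k in seq_len(nrow(g))) ind[(g$start[k] + 1):g$end[k]] <- 1
    values[[cn]] <- boxcar_smooth(ind, config$rec8_smooth_window) ^
      config$rec8_exponent
  }
  # per-chromosome scaling to the biased density targets
  small <- chroms$name[order(chroms$length)][seq_len(config$n_small)]
  dens <- lret <- numeric(nrow(chroms))
  for (i in seq_len(nrow(chroms))) {
    cn <- chroms$name[i]
    keep <- site_in_retained(seq_along(values[[cn]]) - 1, chroms$length[i],
                             chroms$cen_mid[i], half)
    lret[i] <- retained_length(chroms$length[i], chroms$cen_mid[i], half)
    dens[i] <- sum(values[[cn]][keep]) / lret[i]
    if (dens[i] <= 0) stop("no coding signal on chromosome ", cn)
  }
  base <- mean(dens[!chroms$name %in% small])
  target <- ifelse(chroms$name %in% small,
                   base * config$small_chrom_factor, base)
  for (i in seq_len(nrow(chroms)))
    values[[chroms$name[i]]] <- values[[chroms$name[i]]] *
      (target[i] / dens[i])

  sites <- data.frame(chrom = chroms$name,
                      position = floor(chroms$length / 2),
                      mass = vapply(chroms$name,
                                    function(cn) sum(values[[cn]]), 0),
                      source = "coding_body", stringsAsFactors = FALSE)
  if (any(!is.na(chroms$cen_mid))) {
    flank <- if (config$protein == "axis") config$cen_flank_axis
             else config$cen_flank_cohesin
    cm <- config$cen_mass_factor * (sum(sites$mass) /
                                    nrow(annotation$genes)) *
      config$rec8_cen_factor
    has <- !is.na(chroms$cen_mid)
    cen_sites <- data.frame(
      chrom = rep(chroms$name[has], each = 2L),
      position = as.vector(rbind(chroms$cen_mid[has] - flank,
                                 chroms$cen_mid[has] + flank)),
      mass = cm, source = "centromere_flank", stringsAsFactors = FALSE)
    cen_sites$position <- pmin(pmax(cen_sites$position, 0),
                               len_of[cen_sites$chrom] - 1)
    for (k in seq_len(nrow(cen_sites))) {
      cn <- cen_sites$chrom[k]
      values[[cn]][cen_sites$position[k] + 1] <-
        values[[cn]][cen_sites$position[k] + 1] + cm
    }
    sites <- rbind(sites, cen_sites)
  }
  rownames(sites) <- NULL
  structure(list(track = coverage_track(values,
                                        label = "truth_occupancy_rec8"),
                 sites = sites, mode = "rec8_delta", config = config),
            class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat("occupancy_model (", x$mode, "): ", nrow(x$sites), " sites, total mass ",
      format(sum(x$sites$mass)), "\n", sep = "")
  invisible(x)
}

sample_midpoints <- function(track, n, len_of) {
  mass <- vapply(track, sum, 0)
  counts <- as.vector(stats::rmultinom(1, n, mass / sum(mass)))
  chrom <- rep(names(track), counts)
  mid <- unlist(lapply(seq_along(track), function(i) {
    if (counts[i] == 0) return(numeric(0))
    sample.int(length(track[[i]]), counts[i], replace = TRUE,
               prob = track[[i]]) - 1
  }), use.names = FALSE)
  list(chrom = chrom, mid = mid)
}

uniform_midpoints <- function(len_of, n) {
  counts <- as.vector(stats::rmultinom(1, n, len_of / sum(len_of)))
  chrom <- rep(names(len_of), counts)
  mid <- unlist(lapply(seq_along(len_of), function(i) {
    if (counts[i] == 0) return(numeric(0))
    sample.int(len_of[i], counts[i], replace = TRUE) - 1
  }), use.names = FALSE)
  list(chrom = chrom, mid = mid)
}

reads_from_midpoints <- function(mp, len_of, config) {
  n <- length(mp$mid)
  L <- pmax(config$read_length,
            round(stats::rnorm(n, config$fragment_mean,
                               config$fragment_sd)))
  maxs <- len_of[mp$chrom] - L
  fs <- pmin(pmax(mp$mid - floor(L / 2), 0), pmax(maxs, 0))
  fe <- fs + L
  plus <- stats::runif(n) < 0.5
  start <- ifelse(plus, fs, fe - config$read_length)
  read_set(mp$chrom, start, start + config$read_length,
           ifelse(plus, "+", "-"), chrom_lengths = len_of)
}

#' Simulate ChIP, input and untagged read sets
#'
#' ChIP fragment midpoints are drawn from the mixture
#' `(1 - background_fraction) * occupancy + background_fraction * uniform`;
#' fragment lengths are `Normal(fragment_mean, fragment_sd)` truncated at
#' `read_length`, and a single `read_length`-bp read is emitted from a
#' uniformly chosen fragment end with the matching strand.  Input and
#' untagged samples are drawn uniformly.  All randomness is governed by
#' the configuration seed.
#'
#' @param occupancy an `occupancy_model` (or a bare [coverage_track()]).
#' @param config a [simulation_config()].
#' @param n_reads reads per sample (default `config$n_reads`).  Pass a
#'   depth calibrated to total occupancy mass when comparing absolute
#'   signal across modes (as cross-experiment background scaling permits
#'   on real data).
#' @return list of [read_set()]s: `chip`, `input`, `untagged`.
#' @export
simulate_reads <- function(occupancy, config, n_reads = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  track <- if (inherits(occupancy, "occupancy_model")) occupancy$track
           else occupancy
  stopifnot(inherits(track, "coverage_track"))
  set.seed(stage_seed(config$seed, 4))
  n_reads <- n_reads %||% config$n_reads
  len_of <- track_lengths(track)
  n_bg <- round(n_reads * config$background_fraction)
  n_sig <- n_reads - n_bg
  total_mass <- sum(vapply(track, sum, 0))
  if (total_mass <= 0 && n_sig > 0)
    stop("empty occupancy with background_fraction < 1")
  sig <- if (n_sig > 0) sample_midpoints(track, n_sig, len_of)
         else list(chrom = character(0), mid = numeric(0))
  bg <- uniform_midpoints(len_of, n_bg)
  chip_mp <- list(chrom = c(sig$chrom, bg$chrom), mid = c(sig$mid, bg$mid))
  chip <- reads_from_midpoints(chip_mp, len_of, config)
  input <- reads_from_midpoints(uniform_midpoints(len_of, n_reads),
                                len_of, config)
  untagged <- reads_from_midpoints(uniform_midpoints(len_of, n_reads),
                                   len_of, config)
  list(chip = chip, input = input, untagged = untagged)
}

#' Insert a transcription unit into an intergenic region
#'
#' Emulates integrating an active marker gene between two adjacent genes:
#' the new ORF is centred in the intergenic region in the chosen
#' orientation, converting one flanking junction to convergent and the
#' other to tandem (relative to a convergent host pair).
#'
#' @param annotation a [genome_annotation()] with transcripts.
#' @param left_gene id of the gene immediately left of the target
#'   intergenic region (its right-hand neighbour defines the other side).
#' @param orientation `"forward"` (`+`) or `"reverse"` (`-`).
#' @param orf_length,utr5,utr3 geometry of the inserted unit (bp).
#' @param id id of the inserted gene.
#' @return modified [genome_annotation()].  Supply an RPKM for `id`
#'   before rebuilding occupancy.
#' @export
scenario_insertion <- function(annotation, left_gene,
                               orientation = c("forward", "reverse"),
                               orf_length = 600, utr5 = 50, utr3 = 100,
                               id = "insertion") {
  orientation <- match.arg(orientation)
  stopifnot(inherits(annotation, "genome_annotation"))
  genes <- annotation$genes
  i <- match(left_gene, genes$id)
  if (is.na(i)) stop("unknown gene: ", left_gene)
  same <- which(genes$chrom == genes$chrom[i])
  k <- match(i, same)
  if (k == length(same)) stop(left_gene, " has no right-hand neighbour")
  j <- same[k + 1L]
  gap_lo <- genes$end[i]; gap_hi <- genes$start[j]
  if (gap_hi - gap_lo < orf_length + 2)
    stop("intergenic region too small for the insertion")
  s <- floor((gap_lo + gap_hi - orf_length) / 2)
  e <- s + orf_length
  strand <- if (orientation == "forward") "+" else "-"
  new_gene <- data.frame(id = id, chrom = genes$chrom[i], start = s,
                         end = e, strand = strand, stringsAsFactors = FALSE)
  lext <- if (strand == "+") utr5 else utr3
  rext <- if (strand == "+") utr3 else utr5
  len <- chrom_lengths(annotation)[genes$chrom[i]]
  new_tx <- data.frame(gene_id = id, tx_start = max(0, s - lext),
                       tx_end = min(len, e + rext), stringsAsFactors = FALSE)
  genome_annotation(annotation$chromosomes, rbind(genes, new_gene),
                    rbind(annotation$transcripts, new_tx))
}

#' Multiply one gene's expression (promoter induction scenario)
#'
#' @param expression named RPKM vector.
#' @param gene_id gene to induce.
#' @param fold multiplier (>= 0); 1 is the identity.
#' @return modified expression vector.
#' @export
scenario_induction <- function(expression, gene_id, fold) {
  if (!gene_id %in% names(expression)) stop("unknown gene: ", gene_id)
  if (fold < 0) stop("fold must be non-negative")
  expression[gene_id] <- expression[gene_id] * fold
  expression
}
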