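#' Read a gene expression table
#'
#' @param path TSV with header columns `gene_id` and `rpkm`.
#' @return named numeric vector of RPKM values.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "rpkm") %in% names(df)))
  if (any(df$rpkm < 0)) stop("negative RPKM values")
  stats::setNames(df$rpkm, df$gene_id)
}

#' Write a gene expression table
#'
#' @param expression named numeric RPKM vector.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  utils::write.table(
    data.frame(gene_id = names(expression),
               rpkm = unname(expression)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotation as GFF3 (+ chrom.sizes and centromere BED)
#'
#' @param annotation a [genome_annotation()].
#' @param gff_path output GFF3 (gene + mRNA features).
#' @param chrom_sizes_path optional two-column sizes file.
#' @param centromere_path optional BED3 of 1-bp centromere midpoints.
#' @return `gff_path`, invisibly.
#' @export
write_annotation <- function(annotation, gff_path,
                             chrom_sizes_path = NULL,
                             centromere_path = NULL) {
  g <- annotation$genes
  gr_gene <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1, end = g$end),
    strand = g$strand)
  gr_gene$type <- "gene"
  gr_gene$ID <- g$id
  gr_gene$Parent <- S4Vectors::unname(IRanges::CharacterList(
    rep(list(character(0)), nrow(g))))
  gr <- gr_gene
  if (!is.null(annotation$transcripts)) {
    tx <- annotation$transcripts
    m <- match(tx$gene_id, g$id)
    gr_tx <- GenomicRanges::GRanges(
      seqnames = g$chrom[m],
      ranges = IRanges::IRanges(start = tx$tx_start + 1, end = tx$tx_end),
      strand = g$strand[m])
    gr_tx$type <- "mRNA"
    gr_tx$ID <- paste0(tx$gene_id, "_mRNA")
    gr_tx$Parent <- IRanges::CharacterList(as.list(tx$gene_id))
    gr <- c(gr_gene, gr_tx)
  }
  len <- chrom_lengths(annotation)
  GenomeInfoDb::seqlengths(gr) <-
    len[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, gff_path, format = "gff3")
  if (!is.null(chrom_sizes_path))
    writeLines(sprintf("%s\t%d", names(len), as.integer(len)),
               chrom_sizes_path)
  if (!is.null(centromere_path)) {
    cc <- annotation$chromosomes
    cc <- cc[!is.na(cc$cen_mid), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d", cc$name, as.integer(cc$cen_mid),
                       as.integer(cc$cen_mid + 1)), centromere_path)
  }
  invisible(gff_path)
}

#' Export peaks as BED6+ (summit and category columns appended)
#'
#' @param peaks a `peak_set`.
#' @param path output file.
#' @param categories optional per-peak categories.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, categories = NULL) {
  if (is.null(categories)) categories <- rep(".", nrow(peaks))
  lines <- sprintf("%s\t%d\t%d\tpeak_%d\t%.4f\t.\t%d\t%s",
                   peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end), seq_len(nrow(peaks)),
                   peaks$score, as.integer(peaks$summit), categories)
  writeLines(lines, path)
  invisible(path)
}

write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> extend -> pileup -> normalize ->
#' background-subtract -> peak call -> profile, writing every stage
#' output plus a machine-readable JSON summary.  Fully deterministic
#' given the configuration seed.
#'
#' @param config either a [simulation_config()] (simulation mode) or a
#'   list of paths with elements `gff`, `chrom_sizes`, `chip`, `input`
#'   and optionally `centromeres`, `untagged`, `expression`, plus `seed`
#'   (real-data mode).
#' @param out_dir output directory (created if needed).
#' @param final_length read extension length (bp, default 200).
#' @return the summary list, invisibly; files are written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, final_length = 200) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  simulated <- inherits(config, "simulation_config")
  occupancy <- NULL
  if (simulated) {
    annotation <- simulate_genome(config)
    expression <- simulate_expression(annotation, config)
    occupancy <- if (config$mode == "rec8_delta")
      build_occupancy_rec8_delta(annotation, config)
    else build_occupancy(annotation, expression, config)
    reads <- simulate_reads(occupancy, config)
    seed <- config$seed
  } else {
    needed <- c("gff", "chrom_sizes", "chip", "input")
    paths <- unlist(config[intersect(names(config),
                                     c(needed, "centromeres", "untagged",
                                       "expression"))])
    missing <- setdiff(needed, names(config))
    if (length(missing))
      stop("missing input path(s): ", paste(missing, collapse = ", "))
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
    annotation <- load_annotation(config$gff, config$chrom_sizes,
                                  config$centromeres)
    len <- chrom_lengths(annotation)
    reads <- list(chip = read_reads(config$chip, len),
                  input = read_reads(config$input, len))
    if (!is.null(config$untagged))
      reads$untagged <- read_reads(config$untagged, len)
    expression <- if (!is.null(config$expression))
      read_expression(config$expression) else NULL
    seed <- config$seed %||% 0
  }
  len <- chrom_lengths(annotation)
  pairs <- suppressWarnings(classify_gene_pairs(annotation, expression))

  chip_cov <- pileup(extend_reads(reads$chip, final_length, len),
                     label = "chip")
  input_cov <- pileup(extend_reads(reads$input, final_length, len),
                      label = "input")
  norm <- median_normalize_subtract(chip_cov, input_cov)
  control_cov <- if (!is.null(reads$untagged))
    pileup(extend_reads(reads$untagged, final_length, len)) else input_cov
  bg <- background_scale_subtract(chip_cov, control_cov)
  peaks <- call_peaks(bg$track)
  classification <- classify_peaks(peaks, annotation)

  meta <- metagene_profile(bg$track, annotation)
  mid_conv <- midpoint_profile(bg$track, pairs, orientation = "convergent")
  mid_tand <- midpoint_profile(bg$track, pairs, orientation = "tandem",
                               annotation = annotation)
  has_tx <- !is.null(annotation$transcripts) &&
    any(pairs$orientation == "convergent" & !is.na(pairs$tx_overlap))
  end_prof <- if (has_tx) end_aligned_profile(bg$track, pairs) else NULL
  ranked <- if (has_tx) overlap_ranked_matrix(bg$track, pairs, smooth = 51)
            else NULL
  quant <- if (has_tx && !is.null(expression))
    delta_rpkm_quantile_profiles(bg$track, pairs, expression) else NULL
  has_cen <- any(!is.na(annotation$chromosomes$cen_mid))
  dens <- if (has_cen) chromosome_density(bg$track, annotation,
                                          n_small = min(3, nrow(
                                            annotation$chromosomes) - 1))
          else NULL
  cen_prof <- if (has_cen) centromere_profile(bg$track, annotation,
                                              smooth = 21) else NULL

  write_track(norm, file.path(out_dir, "normalized.bedGraph"))
  write_track(bg$track, file.path(out_dir, "subtracted.bedGraph"))
  write_peaks(peaks, file.path(out_dir, "peaks.bed"),
              classification$categories)
  write_profile_tsv(meta, file.path(out_dir, "metagene.tsv"))
  write_profile_tsv(mid_conv, file.path(out_dir,
                                        "midpoint_convergent.tsv"))
  write_profile_tsv(mid_tand, file.path(out_dir, "midpoint_tandem.tsv"))
  if (!is.null(end_prof))
    write_profile_tsv(end_prof, file.path(out_dir, "end_aligned.tsv"))
  if (!is.null(ranked))
    write_profile_tsv(ranked$meta, file.path(out_dir, "separation.tsv"))
  if (simulated) {
    write_annotation(annotation, file.path(out_dir, "genome.gff3"),
                     file.path(out_dir, "chrom.sizes"),
                     file.path(out_dir, "centromeres.bed"))
    write_expression(expression, file.path(out_dir, "expression.tsv"))
    write_track(occupancy$track,
                file.path(out_dir, "truth_occupancy.bedGraph"))
    write_profile_tsv(occupancy$sites,
                      file.path(out_dir, "truth_sites.tsv"))
  }

  summary <- list(
    seed = seed,
    simulated = simulated,
    parameters = list(final_length = final_length,
                      peak_window = 300, peak_p_threshold = 1e-15,
                      peak_merge_gap = 200, peak_min_width = 100),
    n_genes = nrow(annotation$genes),
    n_pairs = nrow(pairs),
    n_convergent = sum(pairs$orientation == "convergent"),
    n_reads = nrow(reads$chip),
    background_factor = bg$factor,
    n_peaks = nrow(peaks),
    median_peak_width = unname(peak_widths(peaks)$median),
    peak_fractions = as.list(classification$fractions))
  if (!is.null(end_prof))
    summary$end_profile_argmax <- profile_peak_offset(end_prof)
  if (!is.null(ranked)) {
    rm2 <- ranked$meta[ranked$meta$tx_overlap > 0 &
                       ranked$meta$separation > 0, , drop = FALSE]
    if (nrow(rm2) >= 3) {
      fit <- stats::lm(separation ~ tx_overlap, data = rm2)
      summary$separation_slope <- unname(stats::coef(fit)[2])
      summary$separation_intercept <- unname(stats::coef(fit)[1])
    }
  }
  if (!is.null(quant)) summary$quantile_skew <- quant$skew
  if (!is.null(dens)) summary$chromosome_density_ratio <- dens$ratio_small
  if (!is.null(cen_prof))
    summary$centromere_flank_distance <- cen_prof$flank_peak_distance
  if (simulated && !is.null(occupancy)) {
    big <- occupancy$sites[occupancy$sites$mass >=
                           5 * mean(occupancy$sites$mass), , drop = FALSE]
    if (nrow(big) && nrow(peaks)) {
      inside <- vapply(seq_len(nrow(big)), function(k) {
        p <- peaks[peaks$chrom == big$chrom[k], , drop = FALSE]
        any(p$start <= big$position[k] & big$position[k] < p$end)
      }, logical(1))
      summary$truth_sites_recovered <- mean(inside)
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Generate a small bundled test dataset
#'
#' Writes a complete miniature dataset (3 chromosomes under 100 kb,
#' around 60 genes, 5e4 reads per sample) through the standard writers,
#' regenerable bit-exactly from the seed.
#'
#' @param dir output directory.
#' @param seed generator seed.
#' @return named list of file paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- fixture_config(seed)
  annotation <- simulate_genome(config)
  expression <- simulate_expression(annotation, config)
  occupancy <- build_occupancy(annotation, expression, config)
  reads <- simulate_reads(occupancy, config)
  paths <- list(
    gff = file.path(dir, "genome.gff3"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    centromeres = file.path(dir, "centromeres.bed"),
    expression = file.path(dir, "expression.tsv"),
    chip = file.path(dir, "chip.bed"),
    input = file.path(dir, "input.bed"),
    untagged = file.path(dir, "untagged.bed"),
    truth_occupancy = file.path(dir, "truth_occupancy.bedGraph"),
    truth_sites = file.path(dir, "truth_sites.tsv"))
  write_annotation(annotation, paths$gff, paths$chrom_sizes,
                   paths$centromeres)
  write_expression(expression, paths$expression)
  write_reads(reads$chip, paths$chip)
  write_reads(reads$input, paths$input)
  write_reads(reads$untagged, paths$untagged)
  write_track(occupancy$track, paths$truth_occupancy)
  write_profile_tsv(occupancy$sites, paths$truth_sites)
  invisible(paths)
}

#' Fixture-scale simulation configuration
#'
#' @param seed generator seed.
#' @return a [simulation_config()] for a 3-chromosome miniature genome.
#' @export
fixture_config <- function(seed = 1) {
  simulation_config(
    chromosome_lengths = c(70e3, 85e3, 100e3),
    gap_meanlog = log(2500), gap_sdlog = 0.6,
    n_small = 1, n_reads = 5e4,
    density_exclude_cen = 10e3,
    seed = seed)
}
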