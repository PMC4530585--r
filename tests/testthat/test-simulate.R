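# fast shared fixtures for the simulator tests
small_cfg <- function(...) {
  args <- list(chromosome_lengths = c(60e3, 70e3, 80e3, 90e3),
               n_small = 1, density_exclude_cen = 5e3, n_reads = 2e4)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

test_that("identical seeds reproduce the genome; different seeds differ", {
  cfg <- small_cfg(seed = 5)
  a1 <- simulate_genome(cfg)
  a2 <- simulate_genome(cfg)
  expect_identical(a1, a2)
  a3 <- simulate_genome(small_cfg(seed = 6))
  expect_false(identical(a1$genes, a3$genes))
})

test_that("configured overlap fraction is honoured at the extremes", {
  conv_overlaps <- function(cfg) {
    ann <- simulate_genome(cfg)
    pairs <- suppressWarnings(classify_gene_pairs(ann))
    pairs$tx_overlap[pairs$orientation == "convergent" &
                     !is.na(pairs$tx_overlap)]
  }
  v0 <- conv_overlaps(small_cfg(seed = 2, overlap_fraction = 0))
  expect_true(all(v0 <= 0))
  # binomial check at n >= 500 pairs, tolerance 3 s.e.
  cfg1 <- simulation_config(
    chromosome_lengths = rep(3e5, 8), n_reads = 1e4,
    overlap_fraction = 1, seed = 3)
  v1 <- conv_overlaps(cfg1)
  expect_gt(length(v1), 100)
  expect_true(all(v1 > 0))
  cfg79 <- simulation_config(
    chromosome_lengths = rep(6e5, 9), n_reads = 1e4, seed = 4)
  v79 <- conv_overlaps(cfg79)
  expect_gt(length(v79), 500)
  p_hat <- mean(v79 > 0)
  se <- sqrt(0.79 * 0.21 / length(v79))
  expect_lt(abs(p_hat - 0.79), 3 * se)
})

test_that("occupancy site geometry follows the sliding model", {
  # one convergent pair, overlap 200, equal RPKM, offset_sd 0
  genes <- data.frame(id = c("gA", "gB"), chrom = "chrA",
                      start = c(1000, 2000), end = c(1600, 2600),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  tx <- data.frame(gene_id = c("gA", "gB"),
                   tx_start = c(950, 1700), tx_end = c(1900, 2650),
                   stringsAsFactors = FALSE)   # e_L 1900, e_R 1700: +200
  chroms <- data.frame(name = c("chrA", "chrB"),
                       length = c(10e3, 5e3), cen_mid = NA,
                       stringsAsFactors = FALSE)
  g2 <- data.frame(id = c("gC", "gD"), chrom = "chrB",
                   start = c(500, 1500), end = c(1100, 2100),
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  t2 <- data.frame(gene_id = c("gC", "gD"),
                   tx_start = c(450, 1180), tx_end = c(1280, 2150),
                   stringsAsFactors = FALSE)
  ann <- genome_annotation(chroms, rbind(genes, g2), rbind(tx, t2))
  cfg <- simulation_config(offset_sd = 0, n_small = 1,
                           density_exclude_cen = 0, seed = 1)
  expr <- c(gA = 10, gB = 10, gC = 8, gD = 2)
  occ <- build_occupancy(ann, expr, cfg)
  sA <- occ$sites[occ$sites$chrom == "chrA", ]
  expect_equal(sort(sA$position), c(1550, 2050))   # e_R-150, e_L+150
  expect_equal(diff(sort(sA$position)), 200 + 2 * 150)
  expect_equal(sA$mass[1], sA$mass[2])
  # 4:1 RPKM ratio puts 4/5 of pair mass on the forward-pushed site
  sB <- occ$sites[occ$sites$chrom == "chrB", ]
  mass_L <- sB$mass[sB$position == 1280 + 150]
  expect_equal(mass_L / sum(sB$mass), 4 / 5)
  # missing expression errors
  expect_error(build_occupancy(ann, expr[-1], cfg), "missing expression")
})

test_that("non-overlapping convergent pairs collapse to a midpoint site", {
  genes <- data.frame(id = c("gA", "gB"), chrom = "chrA",
                      start = c(1000, 2200), end = c(1600, 2800),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  tx <- data.frame(gene_id = c("gA", "gB"),
                   tx_start = c(950, 2100), tx_end = c(1700, 2850),
                   stringsAsFactors = FALSE)  # gap 400 >= 2 * 150
  ann <- toy_annotation(genes, chrom_len = 10e3, transcripts = tx)
  cfg <- simulation_config(offset_sd = 0, n_small = 0,
                           density_exclude_cen = 0, seed = 1)
  occ <- build_occupancy(ann, c(gA = 6, gB = 4), cfg)
  s <- occ$sites[occ$sites$source == "convergent_end", ]
  expect_equal(nrow(s), 1)
  expect_equal(s$position, floor((1700 + 2100) / 2))
  # full pair mass on the merged site (up to chromosome rescaling)
  expect_equal(s$mass / sum(occ$sites$mass[occ$sites$source !=
                                           "centromere_flank"]), 1)
})

test_that("occupancy mass is conserved and the chromosome bias is exact", {
  cfg <- small_cfg(seed = 8)
  ann <- simulate_genome(cfg)
  expr <- simulate_expression(ann, cfg)
  occ <- build_occupancy(ann, expr, cfg)
  track_mass <- sum(vapply(occ$track, sum, 0))
  expect_equal(track_mass, sum(occ$sites$mass), tolerance = 1e-9)
  d <- chromosome_density(occ$track, ann, exclude_cen_flank = 5e3,
                          n_small = 1)
  expect_equal(d$ratio_small, 2.5, tolerance = 0.01)
  # hop1-delta flattens the bias
  cfg_h <- small_cfg(seed = 8, mode = "hop1_delta")
  occ_h <- build_occupancy(ann, expr, cfg_h)
  d_h <- chromosome_density(occ_h$track, ann, exclude_cen_flank = 5e3,
                            n_small = 1)
  expect_equal(d_h$ratio_small, 1.25, tolerance = 0.01)
})

test_that("truth-site separation law holds exactly at offset_sd 0", {
  cfg <- small_cfg(seed = 12, offset_sd = 0)
  ann <- simulate_genome(cfg)
  expr <- simulate_expression(ann, cfg)
  occ <- build_occupancy(ann, expr, cfg)
  pairs <- suppressWarnings(classify_gene_pairs(ann))
  conv <- pairs[pairs$orientation == "convergent" &
                !is.na(pairs$tx_overlap) & pairs$tx_overlap > 0, ]
  sites <- occ$sites[occ$sites$source == "convergent_end", ]
  for (k in seq_len(nrow(conv))) {
    s <- sites[sites$chrom == conv$chrom[k] &
               sites$position %in% c(conv$tx_end_left[k] + 150,
                                     conv$tx_start_right[k] - 150), ]
    expect_equal(diff(range(s$position)), conv$tx_overlap[k] + 300)
  }
})

test_that("rec8-delta occupancy tracks coding density", {
  cfg <- small_cfg(seed = 9, mode = "rec8_delta")
  ann <- simulate_genome(cfg)
  occ <- build_occupancy_rec8_delta(ann, cfg)
  # fully intergenic region has (near-)zero occupancy far from genes
  expect_true(all(vapply(occ$track, min, 0) >= 0))
  # per-gene signal per bp rises with ORF length (rank correlation > 0)
  gl <- gene_length_binned_density(occ$track, ann, group_size = 25)
  expect_gt(cor(gl$groups$mean_length, gl$groups$mean_density,
                method = "spearman"), 0)
  # longer ORF monotonicity: stretching one ORF adds occupancy over it
  g <- ann$genes
  cn <- g$chrom[1]
  g2 <- g
  g2$end[1] <- g2$end[1] + 400
  ann2 <- genome_annotation(ann$chromosomes, g2, NULL)
  span <- (g$start[1] + 1):g$end[1]
  raw1 <- sum(coding_density_track(ann, 2000)[[cn]][span])
  raw2 <- sum(coding_density_track(ann2, 2000)[[cn]][span])
  expect_gte(raw2, raw1)
})

test_that("read simulation is seed-deterministic and mixes background", {
  cfg <- small_cfg(seed = 4)
  ann <- simulate_genome(cfg)
  expr <- simulate_expression(ann, cfg)
  occ <- build_occupancy(ann, expr, cfg)
  r1 <- simulate_reads(occ, cfg)
  r2 <- simulate_reads(occ, cfg)
  expect_identical(r1, r2)
  p1 <- tempfile(); p2 <- tempfile()
  write_reads(r1$chip, p1); write_reads(r2$chip, p2)
  expect_identical(readLines(p1), readLines(p2))
  r3 <- simulate_reads(occ, small_cfg(seed = 44))
  expect_false(identical(r1$chip, r3$chip))
  # all mass at one site, no background: every fragment midpoint there
  one <- coverage_track(list(chrA = c(numeric(5000), 1,
                                      numeric(60e3 - 5001))))
  cfg0 <- small_cfg(seed = 4, background_fraction = 0,
                    fragment_sd = 0, n_reads = 500)
  rs <- simulate_reads(one, cfg0)
  mids <- ifelse(rs$chip$strand == "+", rs$chip$start + 100,
                 rs$chip$end - 100)
  expect_true(all(mids == 5000))
  expect_error(simulate_reads(coverage_track(list(chrA = numeric(100))),
                              cfg0), "empty occupancy")
})

test_that("uniform background yields uniform coverage (chi-square GOF)", {
  cfg <- simulation_config(chromosome_lengths = 100e3, n_small = 0,
                           background_fraction = 1, n_reads = 1e5,
                           seed = 17)
  # n_small irrelevant here; bypass validation complaints
  trk <- coverage_track(list(chr1 = rep(1, 100e3)))
  rs <- simulate_reads(trk, cfg)
  mids <- ifelse(rs$chip$strand == "+",
                 rs$chip$start + 25, rs$chip$end - 25)
  h <- table(cut(mids, seq(0, 100e3, by = 1000), right = FALSE))
  p <- suppressWarnings(chisq.test(as.numeric(h))$p.value)
  expect_gt(p, 0.01)
})

test_that("insertion scenario rewires the junctions as bookkeeping says", {
  genes <- data.frame(id = c("gA", "gB"), chrom = "chrA",
                      start = c(1000, 4000), end = c(1600, 4600),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  tx <- data.frame(gene_id = c("gA", "gB"),
                   tx_start = c(950, 3900), tx_end = c(1700, 4650),
                   stringsAsFactors = FALSE)
  ann <- toy_annotation(genes, chrom_len = 10e3, transcripts = tx)
  fwd <- scenario_insertion(ann, "gA", "forward")
  pf <- classify_gene_pairs(fwd)
  expect_equal(sort(pf$orientation), c("convergent", "tandem"))
  expect_equal(pf$orientation[pf$left_gene == "gA"], "tandem")
  rev <- scenario_insertion(ann, "gA", "reverse")
  pr <- classify_gene_pairs(rev)
  expect_equal(pr$orientation[pr$left_gene == "gA"], "convergent")
  expect_equal(pr$orientation[pr$left_gene == "insertion"], "tandem")
  # with tandem_mass_factor 0 only the convergent junction gets a site
  cfg <- simulation_config(offset_sd = 0, tandem_mass_factor = 0,
                           n_small = 0, density_exclude_cen = 0,
                           seed = 1)
  occ <- build_occupancy(fwd, c(gA = 5, gB = 5, insertion = 5), cfg)
  s <- occ$sites
  expect_true(all(s$source == "convergent_end"))
  expect_true(all(s$position > fwd$genes$end[fwd$genes$id ==
                                             "insertion"] - 400))
})

test_that("promoter induction shifts site mass shares monotonically", {
  expr <- c(gA = 10, gB = 10)
  expect_identical(scenario_induction(expr, "gA", 1), expr)
  e10 <- scenario_induction(expr, "gA", 10)
  expect_equal(unname(e10["gA"] / sum(e10)), 10 / 11)
  shares <- sapply(c(1, 2, 5, 10, 50), function(f) {
    e <- scenario_induction(expr, "gA", f)
    e["gA"] / sum(e)
  })
  expect_true(all(diff(shares) > 0))
  expect_error(scenario_induction(expr, "gZ", 2), "unknown gene")
})
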