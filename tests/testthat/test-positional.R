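# toy genome shared by the oracle-equality tests
toy10 <- random_toy_genome(101, n_genes = 10, n_chrom = 2)
toy_track <- random_track(toy10, 202)
toy_pairs <- suppressWarnings(classify_gene_pairs(toy10))

test_that("metagene profile equals the brute-force oracle and is
           conservative on uniform tracks", {
  prof <- metagene_profile(toy_track, toy10, body_bins = 100, flank = 200)
  oracle <- bf_metagene(toy_track, toy10$genes, 100, 200)
  expect_lt(max(abs(prof$mean - oracle)), 1e-9)
  flat <- coverage_track(lapply(chrom_lengths(toy10),
                                function(L) rep(3.5, L)))
  pf <- metagene_profile(flat, toy10, body_bins = 100, flank = 200)
  expect_true(all(abs(pf$mean - 3.5) < 1e-12))
  # spike at every stop codon peaks at the 3' boundary of the profile
  spikes <- lapply(chrom_lengths(toy10), numeric)
  for (i in seq_len(nrow(toy10$genes))) {
    g <- toy10$genes[i, ]
    p <- if (g$strand == "+") g$end else g$start - 1
    spikes[[g$chrom]][p + 1] <- 100
  }
  sp <- metagene_profile(coverage_track(spikes), toy10,
                         body_bins = 100, flank = 200)
  expect_equal(which.max(sp$mean) - 1, 200 + 100)
})

test_that("midpoint and end-aligned profiles equal the aligned oracle", {
  conv <- toy_pairs[toy_pairs$orientation == "convergent", ]
  mp <- midpoint_profile(toy_track, toy_pairs, half_width = 150)
  or <- bf_aligned_profile(toy_track, conv$chrom, conv$midpoint, NULL, 150)
  expect_lt(max(abs(mp$mean - or$mean), na.rm = TRUE), 1e-9)
  tand <- toy_pairs[toy_pairs$orientation == "tandem", ]
  gstr <- setNames(toy10$genes$strand, toy10$genes$id)
  mt <- midpoint_profile(toy_track, toy_pairs, half_width = 150,
                         orientation = "tandem", annotation = toy10)
  ot <- bf_aligned_profile(toy_track, tand$chrom, tand$midpoint,
                           unname(gstr[tand$left_gene]), 150)
  expect_lt(max(abs(mt$mean - ot$mean), na.rm = TRUE), 1e-9)
  ep <- end_aligned_profile(toy_track, toy_pairs, half_width = 150)
  ends_chrom <- rep(conv$chrom, 2)
  ends_pos <- c(conv$tx_end_left, conv$tx_start_right)
  ends_str <- rep(c("+", "-"), each = nrow(conv))
  oe <- bf_aligned_profile(toy_track, ends_chrom, ends_pos, ends_str, 150)
  expect_lt(max(abs(ep$mean - oe$mean), na.rm = TRUE), 1e-9)
  # uniform track flatness
  flat <- coverage_track(lapply(chrom_lengths(toy10),
                                function(L) rep(1.25, L)))
  ef <- end_aligned_profile(flat, toy_pairs, half_width = 150)
  expect_true(all(abs(ef$mean - 1.25) < 1e-12))
  # mirror symmetry: reflecting the genome and track leaves the
  # end-aligned profile unchanged
  L <- chrom_lengths(toy10)
  mirrored <- coverage_track(lapply(toy_track, rev))
  ends_m <- data.frame(chrom = ends_chrom,
                       pos = L[ends_chrom] - 1 - ends_pos,
                       strand = ifelse(ends_str == "+", "-", "+"),
                       stringsAsFactors = FALSE)
  em <- end_aligned_profile(mirrored, ends = ends_m, half_width = 150)
  expect_equal(em$mean, ep$mean)
})

test_that("overlap-ranked matrix rows equal direct window extraction", {
  rk <- overlap_ranked_matrix(toy_track, toy_pairs, half_width = 150)
  expect_true(all(diff(rk$meta$tx_overlap) <= 0))
  for (r in seq_len(nrow(rk$meta))) {
    ctr <- rk$meta$center[r]
    v <- toy_track[[rk$meta$chrom[r]]]
    idx <- (ctr - 150):(ctr + 150)
    expect_equal(unname(rk$matrix[r, ]), v[idx + 1])
  }
})

test_that("doublet separation detects planted spike pairs", {
  v <- numeric(2001)
  v[1001 - 200] <- 5; v[1001 + 250] <- 4
  genes <- data.frame(id = c("gA", "gB"), chrom = "c1",
                      start = c(100, 1600), end = c(500, 1900),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  tx <- data.frame(gene_id = c("gA", "gB"), tx_start = c(90, 1050),
                   tx_end = c(950, 1950), stringsAsFactors = FALSE)
  ann <- toy_annotation(genes, chrom_len = 2001, transcripts = tx, chrom = "c1")
  pr <- classify_gene_pairs(ann)     # tx_mid = floor((950+1050)/2) = 1000
  rk <- overlap_ranked_matrix(coverage_track(list(c1 = v)), pr,
                              half_width = 500)
  expect_equal(rk$meta$separation, 450)
  # unimodal row reports 0
  v2 <- numeric(2001); v2[1001] <- 5
  rk2 <- overlap_ranked_matrix(coverage_track(list(c1 = v2)), pr,
                               half_width = 500)
  expect_equal(rk2$meta$separation, 0)
})

test_that("expression strata use strict percentile rules", {
  expr <- setNames(rep(7, nrow(toy10$genes)), toy10$genes$id)
  st <- expression_strata_profiles(toy_track, toy_pairs, expr)
  # all-equal expression leaves every stratum empty (ties excluded)
  expect_equal(st[["50"]]$n_high + st[["50"]]$n_low, 0)
  expect_equal(st[["25"]]$n_high + st[["25"]]$n_low, 0)
  set.seed(9)
  expr2 <- setNames(rlnorm(nrow(toy10$genes), 3, 1), toy10$genes$id)
  st2 <- expression_strata_profiles(toy_track, toy_pairs, expr2)
  conv <- toy_pairs[toy_pairs$orientation == "convergent", ]
  hi_thr <- quantile(expr2, 0.5, names = FALSE)
  n_hi <- sum(expr2[conv$left_gene] > hi_thr &
              expr2[conv$right_gene] > hi_thr)
  expect_equal(st2[["50"]]$n_high, unname(n_hi))
  expect_equal(st2[["50"]]$n_high + st2[["50"]]$n_low <= nrow(conv), TRUE)
})

test_that("delta-RPKM quantiles are balanced and skew is signed correctly", {
  set.seed(11)
  expr <- setNames(rlnorm(nrow(toy10$genes), 3, 1), toy10$genes$id)
  q <- delta_rpkm_quantile_profiles(toy_track, toy_pairs, expr,
                                    n_quantiles = 3, half_width = 150)
  expect_true(max(q$n) - min(q$n) <= 1)
  expect_true(all(diff(q$delta_mean) > 0))
  # a hand-built asymmetric window: all signal right of centre
  genes <- data.frame(id = c("gA", "gB"), chrom = "c1",
                      start = c(100, 1600), end = c(500, 1900),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  tx <- data.frame(gene_id = c("gA", "gB"), tx_start = c(90, 1050),
                   tx_end = c(950, 1950), stringsAsFactors = FALSE)
  ann <- toy_annotation(genes, chrom_len = 2001, transcripts = tx, chrom = "c1")
  pr <- classify_gene_pairs(ann)
  v <- numeric(2001); v[1301] <- 10      # +300 offset from tx_mid 1000
  qq <- delta_rpkm_quantile_profiles(
    coverage_track(list(c1 = v)), pr, c(gA = 9, gB = 1),
    n_quantiles = 1, half_width = 500)
  expect_equal(qq$skew, 1)
})

test_that("chromosome density excludes centromere windows and scales", {
  ann <- random_toy_genome(55, n_genes = 8, n_chrom = 4)
  flat <- coverage_track(lapply(chrom_lengths(ann),
                                function(L) rep(2, L)))
  d <- chromosome_density(flat, ann, exclude_cen_flank = 1000,
                          n_small = 2)
  expect_true(all(abs(d$per_chromosome$density - 2) < 1e-12))
  expect_equal(d$ratio_small, 1)
  # mass inside the excluded window has no effect
  spiked <- lapply(flat, identity)
  for (i in seq_len(nrow(ann$chromosomes))) {
    cen <- ann$chromosomes$cen_mid[i]
    spiked[[i]][(cen - 300):(cen + 300) + 1] <- 1e6
  }
  d2 <- chromosome_density(coverage_track(spiked), ann,
                           exclude_cen_flank = 1000, n_small = 2)
  expect_equal(d2$per_chromosome$density, d$per_chromosome$density)
})

test_that("coding density matches a brute-force boxcar", {
  genes <- data.frame(id = "g1", chrom = "c1", start = 2000, end = 3000,
                      strand = "+", stringsAsFactors = FALSE)
  ann <- toy_annotation(genes, chrom_len = 6000, chrom = "c1")
  cd <- coding_density_track(ann, smooth_window = 2000)
  expect_true(all(cd$c1 >= 0 & cd$c1 <= 1))
  # centre of the 1-kb ORF under a 2-kb window: plateau at 0.5
  expect_equal(cd$c1[2501], 1000 / 2001, tolerance = 1e-12)
  # brute-force mean over the window at a few positions
  ind <- numeric(6000); ind[2001:3000] <- 1
  for (p in c(1500, 2500, 3100, 4200))   # interior positions
    expect_equal(cd$c1[p], mean(ind[(p - 1000):(p + 1000)]),
                 tolerance = 1e-12)
  # all-coding chromosome is 1 everywhere
  all_ann <- toy_annotation(
    data.frame(id = "g", chrom = "c1", start = 0, end = 6000,
               strand = "+", stringsAsFactors = FALSE),
    chrom_len = 6000, chrom = "c1")
  expect_true(all(coding_density_track(all_ann, 2000)$c1 == 1))
})

test_that("track correlation is exact for self and negation", {
  ann <- random_toy_genome(66, n_genes = 6, n_chrom = 1)
  trk <- random_track(ann, 77)
  expect_equal(track_correlation(trk, trk, step = 10), 1)
  neg <- coverage_track(lapply(trk, function(v) -v))
  expect_equal(track_correlation(trk, neg, step = 10), -1)
})

test_that("gene-length groups chunk correctly and flatten on uniform", {
  ann <- random_toy_genome(88, n_genes = 10, n_chrom = 2)
  flat <- coverage_track(lapply(chrom_lengths(ann),
                                function(L) rep(4, L)))
  gl <- gene_length_binned_density(flat, ann, group_size = 3)
  expect_equal(nrow(gl$groups),
               ceiling(nrow(ann$genes) / 3))
  expect_true(all(abs(gl$groups$mean_density - 4) < 1e-12))
})

test_that("centromere profile equals the aligned oracle and flags
           unimodal signals", {
  ann <- random_toy_genome(99, n_genes = 6, n_chrom = 3)
  trk <- random_track(ann, 100)
  cp <- centromere_profile(trk, ann, half_width = 200)
  cen <- ann$chromosomes
  or <- bf_aligned_profile(trk, cen$name, cen$cen_mid, NULL, 200)
  expect_lt(max(abs(cp$profile$mean - or$mean), na.rm = TRUE), 1e-9)
  # planted doublet at +-120
  v <- lapply(chrom_lengths(ann), numeric)
  for (i in seq_len(nrow(cen))) {
    v[[cen$name[i]]][cen$cen_mid[i] + 1 - 120] <- 5
    v[[cen$name[i]]][cen$cen_mid[i] + 1 + 120] <- 5
  }
  cp2 <- centromere_profile(coverage_track(v), ann, half_width = 300)
  expect_equal(cp2$flank_peak_distance, 120)
  expect_false(cp2$unimodal)
  # single central site: unimodal, distance 0
  v3 <- lapply(chrom_lengths(ann), numeric)
  for (i in seq_len(nrow(cen))) {
    sp <- cen$cen_mid[i] + 1 + c(-1, 0, 1, 2)
    v3[[cen$name[i]]][sp] <- c(3, 5, 5, 3)
  }
  cp3 <- centromere_profile(coverage_track(v3), ann, half_width = 300)
  expect_true(cp3$unimodal)
  expect_equal(cp3$flank_peak_distance, 0)
})
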