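#' Centered boxcar smoothing with reflected edges
#'
#' @param v numeric vector.
#' @param window window size in bp; values < 2 return `v` unchanged.  The
#'   effective window is the odd size `2 * floor(window / 2) + 1`.
#' @return smoothed vector of the same length.
#' @export
boxcar_smooth <- function(v, window) {
  if (is.null(window) || window < 2) return(v)
  h <- floor(window / 2)
  n <- length(v)
  if (n == 1) return(v)
  pad <- c(v[pmin(h, n - 1):1 + 1], v, v[n - (1:pmin(h, n - 1))])
  extra <- h - pmin(h, n - 1)
  if (extra > 0)  # very short vectors: repeat-reflect
    pad <- c(rep(v[1], extra), pad, rep(v[n], extra))
  cs <- c(0, cumsum(pad))
  (cs[(1:n) + 2 * h + 1] - cs[1:n]) / (2 * h + 1)
}

#' Average track signal around anchor positions
#'
#' Shared engine of the profile operations: per offset in
#' `-half_width..half_width`, the mean of `track[pos + offset]` over all
#' anchors (mirrored for `-`-strand anchors so positive offsets always
#' point downstream).  Positions falling off chromosome ends are excluded
#' per offset (varying denominators, no zero-padding).
#'
#' @param track a [coverage_track()].
#' @param chrom,pos anchor chromosomes and 0-based positions.
#' @param strand optional anchor strands (`-` mirrors the window).
#' @param half_width profile half-width (bp).
#' @return data.frame `offset`, `mean`, `n`, `se`.
#' @export
aligned_profile <- function(track, chrom, pos, strand = NULL,
                            half_width = 1000) {
  offs <- -half_width:half_width
  m <- length(offs)
  sums <- sq <- cnt <- numeric(m)
  for (i in seq_along(pos)) {
    v <- track[[chrom[i]]]
    if (is.null(v)) stop("anchor on unknown chromosome: ", chrom[i])
    idx <- if (!is.null(strand) && strand[i] == "-") pos[i] - offs
           else pos[i] + offs
    ok <- idx >= 0 & idx < length(v)
    val <- v[idx[ok] + 1]
    sums[ok] <- sums[ok] + val
    sq[ok] <- sq[ok] + val^2
    cnt[ok] <- cnt[ok] + 1
  }
  mean <- ifelse(cnt > 0, sums / cnt, NA_real_)
  var <- ifelse(cnt > 1, (sq - cnt * mean^2) / (cnt - 1), NA_real_)
  data.frame(offset = offs, mean = mean, n = cnt,
             se = sqrt(pmax(var, 0) / pmax(cnt, 1)))
}

profile_rows <- function(track, chrom, pos, strand = NULL,
                         half_width = 500) {
  offs <- -half_width:half_width
  mat <- matrix(NA_real_, nrow = length(pos), ncol = length(offs))
  for (i in seq_along(pos)) {
    v <- track[[chrom[i]]]
    idx <- if (!is.null(strand) && strand[i] == "-") pos[i] - offs
           else pos[i] + offs
    ok <- idx >= 0 & idx < length(v)
    mat[i, ok] <- v[idx[ok] + 1]
  }
  colnames(mat) <- offs
  mat
}

#' Metagene profile over rescaled gene bodies
#'
#' Every ORF is linearly rescaled to `body_bins` bins (per-bin mean of
#' the covered base pairs); `flank` bp upstream of the start codon and
#' downstream of the stop codon are taken at native resolution.  Minus
#' strand genes are reversed before averaging, and each gene contributes
#' with equal weight.  Flank positions beyond chromosome ends contribute
#' only to the offsets they cover.
#'
#' @param track a [coverage_track()].
#' @param annotation a [genome_annotation()] (or a `genes` data.frame).
#' @param body_bins number of gene-body bins (default 1000).
#' @param flank flank width in bp (default 500).
#' @return data.frame `position` (0-based along the profile of length
#'   `2 * flank + body_bins`), `mean`, `n`.
#' @export
metagene_profile <- function(track, annotation, body_bins = 1000,
                             flank = 500) {
  genes <- if (inherits(annotation, "genome_annotation"))
    annotation$genes else annotation
  m <- 2 * flank + body_bins
  sums <- cnt <- numeric(m)
  for (i in seq_len(nrow(genes))) {
    v <- track[[genes$chrom[i]]]
    L <- genes$end[i] - genes$start[i]
    len <- length(v)
    cs <- c(0, cumsum(v[(genes$start[i] + 1):genes$end[i]]))
    b <- seq_len(body_bins)
    lo <- floor((b - 1) * L / body_bins)
    hi <- pmax(floor(b * L / body_bins), lo + 1)
    hi <- pmin(hi, L)
    lo <- pmin(lo, hi - 1)
    body <- (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
    up_idx <- (genes$start[i] - flank):(genes$start[i] - 1)
    dn_idx <- genes$end[i]:(genes$end[i] + flank - 1)
    up <- ifelse(up_idx >= 0 & up_idx < len, v[pmax(up_idx, 0) + 1],
                 NA_real_)
    dn <- ifelse(dn_idx >= 0 & dn_idx < len, v[pmin(dn_idx, len - 1) + 1],
                 NA_real_)
    prof <- if (genes$strand[i] == "+") c(up, body, dn)
            else rev(c(up, body, dn))
    ok <- !is.na(prof)
    sums[ok] <- sums[ok] + prof[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  data.frame(position = seq_len(m) - 1,
             mean = ifelse(cnt > 0, sums / cnt, NA_real_), n = cnt)
}

#' Average profile around intergenic midpoints
#'
#' Windows are centred on the ORF-frame intergenic midpoints of gene
#' pairs and oriented so the left gene transcribes rightward (for tandem
#' pairs: the shared direction of transcription).
#'
#' @param track a [coverage_track()].
#' @param pairs a `gene_pairs` data.frame (see [classify_gene_pairs()]).
#' @param half_width window half-width (bp, default 500: a 1-kb window).
#' @param orientation which pair class to average
#'   (`"convergent"`/`"tandem"`/`"divergent"`).
#' @param annotation required for tandem pairs (strand lookup).
#' @return data.frame `offset`, `mean`, `n`, `se`.
#' @export
midpoint_profile <- function(track, pairs, half_width = 500,
                             orientation = "convergent",
                             annotation = NULL) {
  sel <- pairs[pairs$orientation == orientation, , drop = FALSE]
  strand <- rep("+", nrow(sel))
  if (orientation == "tandem") {
    if (is.null(annotation))
      stop("annotation needed to orient tandem pairs")
    gstr <- stats::setNames(annotation$genes$strand, annotation$genes$id)
    strand <- unname(gstr[sel$left_gene])
  }
  aligned_profile(track, sel$chrom, sel$midpoint, strand, half_width)
}

#' Average profile aligned at transcript 3' ends
#'
#' Signal is averaged over all convergent transcript 3' ends as a
#' function of distance from the end, with `-` strand ends mirrored so
#' that positive offsets always point downstream of transcription.
#'
#' @param track a [coverage_track()].
#' @param pairs convergent `gene_pairs` rows with transcript columns; or
#'   pass `ends` directly.
#' @param half_width profile half-width (bp, default 1000).
#' @param ends optional data.frame `chrom`, `pos`, `strand` of 3' ends
#'   overriding `pairs`.
#' @return data.frame `offset` (downstream positive), `mean`, `n`, `se`.
#' @export
end_aligned_profile <- function(track, pairs = NULL, half_width = 1000,
                                ends = NULL) {
  if (is.null(ends)) {
    conv <- pairs[pairs$orientation == "convergent" &
                  !is.na(pairs$tx_overlap), , drop = FALSE]
    ends <- data.frame(
      chrom = rep(conv$chrom, 2),
      pos = c(conv$tx_end_left, conv$tx_start_right),
      strand = rep(c("+", "-"), each = nrow(conv)),
      stringsAsFactors = FALSE)
  }
  aligned_profile(track, ends$chrom, ends$pos, ends$strand, half_width)
}

#' Locate the peak of a mean profile
#'
#' Returns the offset of the profile maximum as the centroid of the
#' contiguous near-maximal region (values within `frac` of the maximum)
#' after optional smoothing.  For flat-topped peaks — the shape left by
#' fixed-length read extension of point sources — this estimates the
#' plateau centre rather than a noise-driven corner of the plateau.
#'
#' @param profile data.frame with `offset` and `mean` columns (as
#'   returned by the profile operations).
#' @param smooth boxcar window (bp) applied before locating the peak.
#' @param frac plateau threshold as a fraction of the maximum.
#' @return peak offset in bp (possibly fractional).
#' @export
profile_peak_offset <- function(profile, smooth = 21, frac = 0.9) {
  v <- boxcar_smooth(profile$mean, smooth)
  v[is.na(v)] <- -Inf
  profile$offset[1] - 1 + plateau_center(v, which.max(v), frac)
}

run_local_maxima <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k == 1) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_max <- logical(k)
  for (j in seq_len(k)) {
    left_ok <- j > 1 && r$values[j] > r$values[j - 1]
    right_ok <- j < k && r$values[j] > r$values[j + 1]
    is_max[j] <- (j == 1 || left_ok) && (j == k || right_ok) &&
      (j > 1 && j < k)   # interior runs only
  }
  starts[is_max]          # leftmost position of each maximal plateau
}

# centroid of the contiguous region around index i where v >= frac * v[i];
# locates the centre of a flat-topped (plateau) peak, and reduces to i for
# a sharp spike
plateau_center <- function(v, i, frac = 0.9) {
  thr <- frac * v[i]
  l <- i; r <- i
  while (l > 1 && v[l - 1] >= thr) l <- l - 1
  while (r < length(v) && v[r + 1] >= thr) r <- r + 1
  mean(l:r)
}

peak_pair_separation <- function(row, smooth = 1, min_separation = 1,
                                 frac = 0.9) {
  v <- boxcar_smooth(row, smooth)
  v[is.na(v)] <- 0
  mx <- run_local_maxima(v)
  if (length(mx) < 2) return(0)
  p1 <- mx[which.max(v[mx])]
  cand <- mx[abs(mx - p1) >= min_separation & mx != p1]
  if (!length(cand)) return(0)
  p2 <- cand[which.max(v[cand])]
  abs(plateau_center(v, p2, frac) - plateau_center(v, p1, frac))
}

#' Overlap-ranked profile matrix at convergent pairs
#'
#' Convergent gene pairs are ranked by the extent of their 3' transcript
#' overlap and the track is sampled in windows centred at the midpoints
#' between the two transcript ends.  For each row the separation between
#' the two highest interior local maxima is reported (0 when unimodal):
#' under the sliding model this separation follows
#' `tx_overlap + 2 * offset_mean` for overlapping pairs.
#'
#' @param track a [coverage_track()].
#' @param pairs `gene_pairs` with transcript columns.
#' @param half_width window half-width (bp, default 500).
#' @param smooth optional boxcar window (bp) applied per row before the
#'   maxima search (useful on read-level tracks; default none).
#' @param min_separation smallest admissible distance (bp) between the
#'   two maxima of a doublet; closer secondary maxima are treated as
#'   ripples of the primary peak (useful on read-level tracks).
#' @return list with `matrix` (rows = pairs ranked by decreasing
#'   overlap, columns = offsets) and `meta` (data.frame: left_gene,
#'   right_gene, chrom, tx_overlap, rank, center, separation).  Peak
#'   positions are plateau centroids, so flat-topped peaks produced by
#'   fixed-length read extension are located at their centres.
#' @export
overlap_ranked_matrix <- function(track, pairs, half_width = 500,
                                  smooth = 1, min_separation = 1) {
  conv <- pairs[pairs$orientation == "convergent" &
                !is.na(pairs$tx_overlap), , drop = FALSE]
  if (!nrow(conv)) stop("no convergent pairs with transcript overlap")
  conv <- conv[order(-conv$tx_overlap), , drop = FALSE]
  mat <- profile_rows(track, conv$chrom, conv$tx_mid,
                      half_width = half_width)
  sep <- apply(mat, 1, peak_pair_separation, smooth = smooth,
               min_separation = min_separation)
  meta <- data.frame(left_gene = conv$left_gene,
                     right_gene = conv$right_gene, chrom = conv$chrom,
                     tx_overlap = conv$tx_overlap,
                     rank = seq_len(nrow(conv)), center = conv$tx_mid,
                     separation = sep, stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  list(matrix = mat, meta = meta)
}

#' Expression-stratified midpoint profiles
#'
#' Convergent pairs are kept in the "high" stratum when both genes exceed
#' the `(100 - cutoff)` expression percentile, and in the "low" stratum
#' when both fall below the `cutoff` percentile (strict inequalities;
#' ties excluded).  Percentiles are taken over the whole expression
#' table.
#'
#' @param track a [coverage_track()].
#' @param pairs `gene_pairs`.
#' @param expression named RPKM vector.
#' @param cutoffs percentile cutoffs (default `c(50, 25)`).
#' @param half_width window half-width (bp).
#' @return named list (one element per cutoff, e.g. `"50"`), each with
#'   `high` and `low` profile data.frames and `n_high`/`n_low`.
#' @export
expression_strata_profiles <- function(track, pairs, expression,
                                       cutoffs = c(50, 25),
                                       half_width = 500) {
  conv <- pairs[pairs$orientation == "convergent", , drop = FALSE]
  rl <- unname(expression[conv$left_gene])
  rr <- unname(expression[conv$right_gene])
  out <- list()
  for (ct in cutoffs) {
    hi_thr <- stats::quantile(expression, 1 - ct / 100, names = FALSE)
    lo_thr <- stats::quantile(expression, ct / 100, names = FALSE)
    hi <- !is.na(rl) & !is.na(rr) & rl > hi_thr & rr > hi_thr
    lo <- !is.na(rl) & !is.na(rr) & rl < lo_thr & rr < lo_thr
    out[[as.character(ct)]] <- list(
      high = aligned_profile(track, conv$chrom[hi], conv$midpoint[hi],
                             half_width = half_width),
      low = aligned_profile(track, conv$chrom[lo], conv$midpoint[lo],
                            half_width = half_width),
      n_high = sum(hi), n_low = sum(lo))
  }
  out
}

#' Delta-RPKM quantile profiles and skew
#'
#' Convergent pairs are ranked by `dRPKM = RPKM(forward) - RPKM(reverse)`
#' (forward = the `+` strand, left gene) and split into `n_quantiles`
#' equal-size groups (quantile 1 = most negative dRPKM; sizes differ by
#' at most one, ties broken by stable pair order).  Windows are centred
#' at the transcript-end midpoints with the forward gene on the left; the
#' skew statistic of a profile is
#' `(sum(signal at offsets > 0) - sum(at < 0)) / sum(total)`, positive
#' when signal sits downstream of the forward gene (i.e. on the weakly
#' transcribed gene's side when dRPKM > 0).
#'
#' @param track a [coverage_track()].
#' @param pairs `gene_pairs` with transcript columns.
#' @param expression named RPKM vector.
#' @param n_quantiles number of quantile groups (default 6).
#' @param half_width window half-width (bp).
#' @return list with `profiles` (matrix: quantile x offset), `skew`
#'   (per-quantile skew of the mean profile), `pair_skew` (data.frame
#'   with per-pair skew, quantile and dRPKM), `delta_mean` and `n` per
#'   quantile.
#' @export
delta_rpkm_quantile_profiles <- function(track, pairs, expression,
                                         n_quantiles = 6,
                                         half_width = 500) {
  conv <- pairs[pairs$orientation == "convergent" &
                !is.na(pairs$tx_mid), , drop = FALSE]
  delta <- unname(expression[conv$left_gene] -
                  expression[conv$right_gene])
  ok <- !is.na(delta)
  conv <- conv[ok, , drop = FALSE]
  delta <- delta[ok]
  ord <- order(delta)           # stable; quantile 1 = most negative
  conv <- conv[ord, , drop = FALSE]
  delta <- delta[ord]
  n <- nrow(conv)
  q <- ceiling(seq_len(n) * n_quantiles / n)
  mat <- profile_rows(track, conv$chrom, conv$tx_mid,
                      half_width = half_width)
  offs <- -half_width:half_width
  skew_of <- function(p) {
    tot <- sum(p, na.rm = TRUE)
    if (tot == 0) return(NA_real_)
    (sum(p[offs > 0], na.rm = TRUE) - sum(p[offs < 0], na.rm = TRUE)) / tot
  }
  profiles <- matrix(NA_real_, n_quantiles, length(offs),
                     dimnames = list(NULL, offs))
  skew <- delta_mean <- numeric(n_quantiles)
  cnt <- integer(n_quantiles)
  for (k in seq_len(n_quantiles)) {
    rows <- mat[q == k, , drop = FALSE]
    profiles[k, ] <- colMeans(rows, na.rm = TRUE)
    skew[k] <- skew_of(profiles[k, ])
    delta_mean[k] <- mean(delta[q == k])
    cnt[k] <- sum(q == k)
  }
  pair_skew <- data.frame(left_gene = conv$left_gene,
                          right_gene = conv$right_gene,
                          delta = delta, quantile = q,
                          skew = apply(mat, 1, skew_of))
  list(profiles = profiles, skew = skew, pair_skew = pair_skew,
       delta_mean = delta_mean, n = cnt)
}

#' Per-chromosome signal density and size relation
#'
#' Sums the track over each chromosome, excluding
#' +-`exclude_cen_flank` bp around the centromere (to avoid the strong
#' centromere-proximal enrichment), and divides by the retained length.
#' Reports the mean and +-2 SD across chromosomes and the per-bp density
#' ratio of the `n_small` shortest chromosomes over the rest.
#'
#' @param track a [coverage_track()].
#' @param annotation a [genome_annotation()]; centromeres must be set
#'   when `exclude_cen_flank > 0`.
#' @param exclude_cen_flank exclusion half-width (bp, default 25 kb).
#' @param n_small size of the short-chromosome group (default 3).
#' @return list with `per_chromosome` (data.frame: chrom, length,
#'   density), `mean`, `sd`, `ratio_small` (density of the shortest
#'   `n_small` over the rest).
#' @export
chromosome_density <- function(track, annotation,
                               exclude_cen_flank = 25e3, n_small = 3) {
  stopifnot(inherits(annotation, "genome_annotation"))
  chroms <- annotation$chromosomes
  if (exclude_cen_flank > 0 && all(is.na(chroms$cen_mid)))
    stop("centromeres unset; cannot apply the centromere exclusion")
  dens <- sig <- lret <- numeric(nrow(chroms))
  for (i in seq_len(nrow(chroms))) {
    v <- track[[chroms$name[i]]]
    cen <- chroms$cen_mid[i]
    if (exclude_cen_flank > 0 && !is.na(cen)) {
      a <- max(0, cen - exclude_cen_flank)
      b <- min(length(v), cen + exclude_cen_flank)
      sig[i] <- sum(v) - sum(v[(a + 1):b])
      lret[i] <- length(v) - (b - a)
    } else {
      sig[i] <- sum(v)
      lret[i] <- length(v)
    }
    dens[i] <- sig[i] / lret[i]
  }
  per <- data.frame(chrom = chroms$name, length = chroms$length,
                    density = dens, stringsAsFactors = FALSE)
  small <- order(chroms$length)[seq_len(min(n_small, nrow(chroms)))]
  ratio <- (sum(sig[small]) / sum(lret[small])) /
    (sum(sig[-small]) / sum(lret[-small]))
  list(per_chromosome = per, mean = mean(dens), sd = stats::sd(dens),
       ratio_small = ratio)
}

#' Coding-density track
#'
#' The 0/1 coding indicator (1 inside any ORF) smoothed with a centred
#' boxcar window.
#'
#' @param annotation a [genome_annotation()].
#' @param smooth_window boxcar window in bp (10 kb for chromosome-scale
#'   views, 2 kb for per-locus views).
#' @return a [coverage_track()] with values in `[0, 1]`.
#' @export
coding_density_track <- function(annotation, smooth_window = 10e3) {
  len_of <- chrom_lengths(annotation)
  values <- lapply(names(len_of), function(cn) {
    ind <- numeric(len_of[[cn]])
    g <- annotation$genes[annotation$genes$chrom == cn, , drop = FALSE]
    for (k in seq_len(nrow(g))) ind[(g$start[k] + 1):g$end[k]] <- 1
    boxcar_smooth(ind, smooth_window)
  })
  names(values) <- names(len_of)
  coverage_track(values, label = "coding_density")
}

#' Smoothed Pearson correlation of two tracks
#'
#' @param track_a,track_b [coverage_track()]s on the same chromosomes.
#' @param smooth_a,smooth_b boxcar windows in bp (0/1 = no smoothing).
#' @param step sampling step in bp.
#' @return Pearson correlation coefficient.
#' @export
track_correlation <- function(track_a, track_b, smooth_a = 0,
                              smooth_b = 0, step = 50) {
  stopifnot(identical(names(track_a), names(track_b)))
  xa <- xb <- list()
  for (cn in names(track_a)) {
    a <- boxcar_smooth(track_a[[cn]], smooth_a)
    b <- boxcar_smooth(track_b[[cn]], smooth_b)
    idx <- seq(1, length(a), by = step)
    xa[[cn]] <- a[idx]; xb[[cn]] <- b[idx]
  }
  stats::cor(unlist(xa, use.names = FALSE),
             unlist(xb, use.names = FALSE))
}

#' Signal per bp in gene-length bins
#'
#' Genes are sorted by ORF length and chunked into groups of
#' `group_size`; per gene the track sum over the ORF divided by ORF
#' length is averaged within each group.
#'
#' @param track a [coverage_track()].
#' @param annotation a [genome_annotation()].
#' @param group_size genes per group (default 100).
#' @return list with `groups` (data.frame: group, mean_length,
#'   mean_density, n) and `r` (Pearson correlation of the group means).
#' @export
gene_length_binned_density <- function(track, annotation,
                                       group_size = 100) {
  genes <- annotation$genes
  L <- genes$end - genes$start
  dens <- vapply(seq_len(nrow(genes)), function(i)
    sum(track[[genes$chrom[i]]][(genes$start[i] + 1):genes$end[i]]) / L[i],
    numeric(1))
  ord <- order(L)
  grp <- ceiling(seq_along(ord) / group_size)
  groups <- data.frame(
    group = seq_len(max(grp)),
    mean_length = as.numeric(tapply(L[ord], grp, mean)),
    mean_density = as.numeric(tapply(dens[ord], grp, mean)),
    n = as.integer(table(grp)))
  r <- if (nrow(groups) > 2 && stats::sd(groups$mean_density) > 0)
    stats::cor(groups$mean_length, groups$mean_density) else NA_real_
  list(groups = groups, r = r)
}

#' Centromere-aligned average profile and flank-peak distance
#'
#' Averages the track around all centromere midpoints and locates the
#' flanking doublet: the maxima of the mean profile are found separately
#' in the negative and positive offset ranges (as plateau centroids, so
#' the flat-topped peaks left by fixed-length read extension are located
#' at their centres) and their mean absolute offset is the flank-peak
#' distance.  When both maxima fall within 50 bp of the centre the
#' profile is flagged unimodal and the distance reported as 0.
#'
#' @param track a [coverage_track()].
#' @param annotation a [genome_annotation()] with centromeres.
#' @param half_width profile half-width (bp, default 1000).
#' @param smooth optional boxcar window (bp) applied to the mean profile
#'   before locating the maxima.
#' @return list with `profile` (data.frame offset/mean/n/se),
#'   `flank_peak_distance` (bp), `flank_offsets` (the two signed
#'   offsets), `flank_heights`, `flank_prominence` (heights above the
#'   profile minimum over the central +-100 bp, the cenH3 core devoid of
#'   signal — the scale on which peak amplitudes compare across strains)
#'   and `unimodal`.
#' @export
centromere_profile <- function(track, annotation, half_width = 1000,
                               smooth = 1) {
  stopifnot(inherits(annotation, "genome_annotation"))
  cen <- annotation$chromosomes[!is.na(annotation$chromosomes$cen_mid), ,
                                drop = FALSE]
  if (!nrow(cen)) stop("centromeres unset in this annotation")
  prof <- aligned_profile(track, cen$name, cen$cen_mid,
                          half_width = half_width)
  v <- boxcar_smooth(prof$mean, smooth)
  neg <- prof$offset < 0
  pos <- prof$offset > 0
  o_neg <- prof$offset[neg][1] - 1 +
    plateau_center(v[neg], which.max(v[neg]))
  o_pos <- prof$offset[pos][1] - 1 +
    plateau_center(v[pos], which.max(v[pos]))
  unimodal <- abs(o_neg) < 50 && abs(o_pos) < 50
  heights <- c(v[neg][which.max(v[neg])], v[pos][which.max(v[pos])])
  core <- min(v[abs(prof$offset) <= 100])
  list(profile = prof,
       flank_peak_distance = if (unimodal) 0
                             else mean(c(abs(o_neg), abs(o_pos))),
       flank_offsets = c(o_neg, o_pos),
       flank_heights = heights,
       flank_prominence = heights - core,
       unimodal = unimodal)
}
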