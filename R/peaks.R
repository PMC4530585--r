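#' Call enriched peaks with a Poisson local-lambda scan
#'
#' Sliding-window counts (window sum of the non-negative track) are
#' tested against `Poisson(lambda_local)`, where `lambda_local` is the
#' larger of the genome-wide mean and the mean over a `local_bg`-bp
#' surround, times the window size.  A window starting at `s` is
#' significant when `P(X >= ceiling(count)) <= p_threshold`.  Significant
#' window footprints are unioned, runs separated by at most `merge_gap`
#' bp are merged, intervals narrower than `min_width` are dropped, and
#' the summit is the leftmost position attaining the maximum track value
#' inside each interval.
#'
#' @param track non-negative [coverage_track()].
#' @param window sliding-window width in bp (default 300).
#' @param p_threshold Poisson upper-tail significance cutoff
#'   (default 1e-15).
#' @param merge_gap merge intervals separated by at most this many bp.
#' @param min_width minimum retained interval width (bp).
#' @param local_bg width (bp) of the local background surround
#'   (default 10 kb).
#' @return data.frame of class `peak_set`: `chrom`, `start`, `end`,
#'   `summit`, `score` (-log10 p), `width`.  An all-zero track yields
#'   zero rows.
#' @export
call_peaks <- function(track, window = 300, p_threshold = 1e-15,
                       merge_gap = 200, min_width = 100, local_bg = 10e3) {
  stopifnot(inherits(track, "coverage_track"))
  if (any(vapply(track, function(v) any(v < 0), logical(1))))
    stop("call_peaks requires a non-negative track")
  genome_mean <- sum(vapply(track, sum, 0)) / sum(track_lengths(track))
  out <- list()
  for (cn in names(track)) {
    v <- track[[cn]]
    L <- length(v)
    if (L < window) next
    cs <- c(0, cumsum(v))
    s <- 0:(L - window)                       # 0-based window starts
    wsum <- cs[s + window + 1] - cs[s + 1]
    centre <- s + floor(window / 2)
    a <- pmax(0, centre - floor(local_bg / 2))
    b <- pmin(L, centre + ceiling(local_bg / 2))
    local_mean <- (cs[b + 1] - cs[a + 1]) / (b - a)
    lambda <- pmax(genome_mean, local_mean) * window
    pv <- stats::ppois(ceiling(wsum) - 1, lambda, lower.tail = FALSE)
    sig <- pv <= p_threshold
    if (!any(sig)) next
    r <- rle(sig)
    re <- cumsum(r$lengths)
    rs <- re - r$lengths + 1L
    runs <- which(r$values)
    ivs <- cbind(start = s[rs[runs]], end = s[re[runs]] + window)
    # merge runs separated by <= merge_gap
    merged <- list()
    cur <- ivs[1, ]
    for (k in seq_len(nrow(ivs))[-1]) {
      if (ivs[k, 1] - cur[2] <= merge_gap) {
        cur[2] <- ivs[k, 2]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- ivs[k, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
    for (iv in merged) {
      if (iv[2] - iv[1] < min_width) next
      seg <- v[(iv[1] + 1):iv[2]]
      summit <- iv[1] + which.max(seg) - 1L
      in_iv <- s >= iv[1] & s <= iv[2] - window & sig
      score <- -log10(max(min(pv[in_iv]), 1e-320))
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = unname(iv[1]), end = unname(iv[2]),
        summit = unname(summit), score = score,
        width = unname(iv[2] - iv[1]), stringsAsFactors = FALSE)
    }
  }
  peaks <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               summit = numeric(), score = numeric(), width = numeric(),
               stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  class(peaks) <- c("peak_set", "data.frame")
  peaks
}

#' Summarise peak width distribution
#'
#' @param peaks a `peak_set`.
#' @param breaks histogram break points in bp (right-open bins; the last
#'   bin absorbs anything wider).
#' @return list with `counts` (named per bin), `quartiles`
#'   (25/50/75%), `median` and `n`; all empty/NA for an empty peak set.
#' @export
peak_widths <- function(peaks, breaks = seq(0, 5000, by = 250)) {
  if (!nrow(peaks))
    return(list(counts = integer(0), quartiles = c(`25%` = NA_real_,
                `50%` = NA_real_, `75%` = NA_real_),
                median = NA_real_, n = 0L))
  b <- c(breaks, Inf)
  cuts <- cut(peaks$width, b, right = FALSE)
  q <- stats::quantile(peaks$width, c(0.25, 0.5, 0.75))
  list(counts = table(cuts), quartiles = q, median = unname(q[2]),
       n = nrow(peaks))
}

ranges_0based <- function(start, end) {
  keep <- end > start
  IRanges::IRanges(start = start[keep] + 1, end = end[keep])
}

#' Classify peaks against gene features
#'
#' Each summit's +-`flank` bp window is intersected, in fixed priority
#' order, with: convergent intergenic regions, divergent intergenic
#' regions, 3' regions (250 bp on either side of a stop codon), 5'
#' regions (500 bp upstream of a start codon); anything else is
#' `intragenic/other`.  The categories partition the peak set.
#'
#' @param peaks a `peak_set` with summits.
#' @param annotation a [genome_annotation()].
#' @param flank half-width of the summit window (bp, default 250).
#' @param five_prime 5' region extent upstream of start codons (bp).
#' @param three_prime 3' region half-width around stop codons (bp).
#' @return list with `categories` (character per peak) and `fractions`
#'   (named, sums to 1 over a non-empty peak set).
#' @export
classify_peaks <- function(peaks, annotation, flank = 250,
                           five_prime = 500, three_prime = 250) {
  stopifnot(inherits(annotation, "genome_annotation"))
  pairs <- suppressWarnings(classify_gene_pairs(annotation))
  genes <- annotation$genes
  cats <- c("convergent", "divergent", "3'", "5'", "intragenic/other")
  result <- rep(cats[5], nrow(peaks))
  stop_pos <- ifelse(genes$strand == "+", genes$end, genes$start)
  start_pos <- ifelse(genes$strand == "+", genes$start, genes$end)
  for (cn in unique(peaks$chrom)) {
    psel <- which(peaks$chrom == cn)
    win <- IRanges::IRanges(start = peaks$summit[psel] - flank + 1,
                            end = peaks$summit[psel] + flank + 1)
    pc <- pairs[pairs$chrom == cn, , drop = FALSE]
    gc <- genes$chrom == cn
    conv <- pc[pc$orientation == "convergent", , drop = FALSE]
    divr <- pc[pc$orientation == "divergent", , drop = FALSE]
    feat <- list(
      ranges_0based(conv$intergenic_start, conv$intergenic_end),
      ranges_0based(divr$intergenic_start, divr$intergenic_end),
      ranges_0based(stop_pos[gc] - three_prime, stop_pos[gc] + three_prime),
      ranges_0based(ifelse(genes$strand[gc] == "+",
                           start_pos[gc] - five_prime, start_pos[gc]),
                    ifelse(genes$strand[gc] == "+", start_pos[gc],
                           start_pos[gc] + five_prime)))
    assigned <- rep(FALSE, length(psel))
    for (fi in seq_along(feat)) {
      if (!length(feat[[fi]])) next
      hit <- IRanges::overlapsAny(win, feat[[fi]])
      take <- hit & !assigned
      result[psel[take]] <- cats[fi]
      assigned <- assigned | hit
    }
  }
  fr <- table(factor(result, levels = cats))
  fractions <- if (nrow(peaks)) as.numeric(fr) / nrow(peaks)
               else rep(NA_real_, length(cats))
  names(fractions) <- cats
  list(categories = result, fractions = fractions)
}

#' Average track signal around peak summits
#'
#' @param track a [coverage_track()].
#' @param summits data.frame with `chrom` and `pos` (0-based summit
#'   positions), or a `peak_set` (its `summit` column is used).
#' @param half_width profile half-width in bp.
#' @return data.frame `offset`, `mean`, `n` (positions beyond chromosome
#'   ends are excluded per offset).
#' @export
summit_aligned_profile <- function(track, summits, half_width = 2000) {
  if (inherits(summits, "peak_set"))
    summits <- data.frame(chrom = summits$chrom, pos = summits$summit,
                          stringsAsFactors = FALSE)
  aligned_profile(track, summits$chrom, summits$pos,
                  strand = NULL, half_width = half_width)
}
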