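#' Extend reads toward their 3' ends
#'
#' Each read is lengthened in its strand direction to `final_length` bp
#' (the fixed fragment-size convention is 200 bp): `+` reads become
#' `[start, start + final_length)`, `-` reads `[end - final_length, end)`,
#' clipped at chromosome bounds.  Reads already at least `final_length`
#' long are left unchanged (extension never truncates).
#'
#' @param reads a [read_set()] with attached chromosome lengths.
#' @param final_length target length in bp (must be >= the read length).
#' @param chrom_lengths optional named lengths (default: the read set's).
#' @return extended [read_set()].
#' @export
extend_reads <- function(reads, final_length = 200, chrom_lengths = NULL) {
  chrom_lengths <- chrom_lengths %||% attr(reads, "chrom_lengths")
  if (is.null(chrom_lengths)) stop("chrom_lengths required for clipping")
  rl <- reads$end - reads$start
  if (length(rl) && final_length < min(rl))
    stop("final_length shorter than a read (", min(rl), " bp)")
  keep <- rl >= final_length
  start <- ifelse(reads$strand == "+", reads$start,
                  reads$end - final_length)
  end <- ifelse(reads$strand == "+", reads$start + final_length, reads$end)
  start[keep] <- reads$start[keep]
  end[keep] <- reads$end[keep]
  start <- pmax(start, 0)
  end <- pmin(end, unname(chrom_lengths[reads$chrom]))
  read_set(reads$chrom, start, end, reads$strand, chrom_lengths)
}

strand_cross_correlation <- function(pc, mc, shifts) {
  n <- length(pc)
  vapply(shifts, function(s) {
    if (s >= n) return(0)
    sum(pc[1:(n - s)] * mc[(1 + s):n])
  }, numeric(1))
}

#' Estimate the local optimal extension size
#'
#' Fragment-size estimation by strand cross-correlation: within each
#' 10-kb window the density of `+`-read start positions is cross-correlated
#' with the density of `-`-read start positions over a 1-bp shift grid;
#' the window's extension estimate is `read_length + argmax(shift)`.  A
#' pooled genome-wide cross-correlation gives the global estimate.  When
#' the pooled correlation carries no reproducible peak (split-half argmax
#' disagreement > 25 bp, as for strand-independent uniform reads), the
#' estimator falls back to `fallback` with `used_fallback = TRUE`.
#'
#' @param reads a [read_set()] (un-extended).
#' @param window window size in bp (default 10 kb).
#' @param max_extension largest admissible extension (bp).
#' @param min_reads minimum reads per strand for a window estimate.
#' @param fallback genome-wide fallback extension (bp, default 200).
#' @return list with `windows` (data.frame: chrom, start, extension),
#'   `mean_extension` (genome-wide pooled estimate, bp) and
#'   `used_fallback` (logical).
#' @export
estimate_local_extension <- function(reads, window = 10e3,
                                     max_extension = 500, min_reads = 50,
                                     fallback = 200) {
  if (!nrow(reads)) stop("no reads")
  chrom_lengths <- attr(reads, "chrom_lengths")
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(reads$end, reads$chrom, max)
  read_length <- round(stats::median(reads$end - reads$start))
  shifts <- 0:(max_extension - read_length)
  pooled <- numeric(length(shifts))
  pooled_odd <- numeric(length(shifts))
  pooled_even <- numeric(length(shifts))
  win_rows <- list()
  ri <- 0L
  for (cn in names(chrom_lengths)) {
    r <- reads[reads$chrom == cn, , drop = FALSE]
    if (!nrow(r)) next
    len <- chrom_lengths[[cn]]
    for (ws in seq(0, len - 1, by = window)) {
      we <- min(ws + window, len)
      sel <- r$start >= ws & r$start < we
      if (!any(sel)) next
      rw <- r[sel, , drop = FALSE]
      plus <- rw$strand == "+"
      pc <- mc <- numeric(we - ws)
      pcs <- table(rw$start[plus] - ws + 1)
      mcs <- table(rw$start[!plus] - ws + 1)
      pc[as.integer(names(pcs))] <- as.numeric(pcs)
      mc[as.integer(names(mcs))] <- as.numeric(mcs)
      cc <- strand_cross_correlation(pc, mc, shifts)
      pooled <- pooled + cc
      # split halves by read parity for the degeneracy check
      idx <- which(sel)
      odd <- idx %% 2 == 1
      po <- mo <- pe <- me <- numeric(we - ws)
      fill <- function(v, starts) {
        t <- table(starts - ws + 1)
        v[as.integer(names(t))] <- as.numeric(t)
        v
      }
      po <- fill(po, rw$start[plus & odd[seq_len(nrow(rw))]])
      mo <- fill(mo, rw$start[!plus & odd[seq_len(nrow(rw))]])
      pe <- fill(pe, rw$start[plus & !odd[seq_len(nrow(rw))]])
      me <- fill(me, rw$start[!plus & !odd[seq_len(nrow(rw))]])
      pooled_odd <- pooled_odd + strand_cross_correlation(po, mo, shifts)
      pooled_even <- pooled_even + strand_cross_correlation(pe, me, shifts)
      if (sum(plus) >= min_reads && sum(!plus) >= min_reads) {
        ri <- ri + 1L
        win_rows[[ri]] <- data.frame(
          chrom = cn, start = ws,
          extension = read_length + shifts[which.max(boxcar_smooth(cc, 5))],
          stringsAsFactors = FALSE)
      }
    }
  }
  sm <- boxcar_smooth(pooled, 5)
  a_all <- shifts[which.max(sm)]
  a_odd <- shifts[which.max(boxcar_smooth(pooled_odd, 5))]
  a_even <- shifts[which.max(boxcar_smooth(pooled_even, 5))]
  used_fallback <- abs(a_odd - a_even) > 25 || sum(pooled) == 0
  if (used_fallback) {
    message("no reproducible strand cross-correlation peak; ",
            "falling back to ", fallback, " bp extension")
    mean_extension <- fallback
  } else {
    mean_extension <- read_length + a_all
  }
  windows <- if (ri) do.call(rbind, win_rows) else
    data.frame(chrom = character(), start = numeric(),
               extension = numeric(), stringsAsFactors = FALSE)
  list(windows = windows, mean_extension = mean_extension,
       read_length = read_length, used_fallback = used_fallback)
}

#' Median normalization with input subtraction
#'
#' Every base position of the ChIP track is divided by the genome-wide
#' median coverage of the ChIP sample; the input track is divided by its
#' own median the same way, and the scaled input is subtracted from the
#' scaled ChIP at each position.
#'
#' @param chip_track,input_track [coverage_track()]s on the same
#'   chromosomes.
#' @return normalized [coverage_track()] (may contain negative values).
#' @export
median_normalize_subtract <- function(chip_track, input_track) {
  stopifnot(inherits(chip_track, "coverage_track"),
            inherits(input_track, "coverage_track"),
            identical(names(chip_track), names(input_track)))
  med_chip <- stats::median(unlist(chip_track, use.names = FALSE))
  med_input <- stats::median(unlist(input_track, use.names = FALSE))
  if (med_chip == 0) stop("zero genome-wide median in the ChIP track")
  if (med_input == 0) stop("zero genome-wide median in the input track")
  out <- lapply(names(chip_track), function(cn)
    chip_track[[cn]] / med_chip - input_track[[cn]] / med_input)
  names(out) <- names(chip_track)
  coverage_track(out, label = "median_normalized")
}

bin_sums <- function(track, bin) {
  unlist(lapply(track, function(v) {
    idx <- ceiling(seq_along(v) / bin)
    as.numeric(rowsum(v, idx))
  }), use.names = FALSE)
}

#' Background-ratio scaling and subtraction
#'
#' A one-step background estimator in the spirit of NCIS: both tracks are
#' binned, bins whose ChIP count falls below the genome-wide bin median
#' define the background set, and the scaling factor is the median
#' ChIP/control ratio over those bins.  The scaled control is subtracted
#' from the ChIP track.
#'
#' @param chip_track,control_track [coverage_track()]s (control = input
#'   or untagged).
#' @param bin bin size in bp (default 1 kb).
#' @param floor_at_zero clip negative values to 0 (peak-calling
#'   convention); set `FALSE` to export faithful residuals.
#' @return list with `track` (subtracted [coverage_track()]) and
#'   `factor` (estimated background ratio).
#' @export
background_scale_subtract <- function(chip_track, control_track,
                                      bin = 1000, floor_at_zero = TRUE) {
  stopifnot(inherits(chip_track, "coverage_track"),
            inherits(control_track, "coverage_track"),
            identical(names(chip_track), names(control_track)))
  cb <- bin_sums(chip_track, bin)
  kb <- bin_sums(control_track, bin)
  med <- stats::median(cb)
  bg <- cb < med & kb > 0
  if (!any(bg)) stop("no background bins below the genome-wide bin median")
  factor <- stats::median(cb[bg] / kb[bg])
  out <- lapply(names(chip_track), function(cn) {
    v <- chip_track[[cn]] - factor * control_track[[cn]]
    if (floor_at_zero) pmax(v, 0) else v
  })
  names(out) <- names(chip_track)
  list(track = coverage_track(out, label = "background_subtracted"),
       factor = factor)
}

#' qPCR fold enrichment from Ct values
#'
#' Two-step ChIP-qPCR arithmetic: the percentage of ChIP relative to input
#' is computed for the target and for an internal control locus from Ct
#' differences with dilution correction (amplification efficiency fixed
#' at 2), and the fold enrichment is the ratio of the two percentages.
#' With the default 1:20 ChIP and 1:2000 input dilutions,
#' percent input = `100 * (dil_chip / dil_input) * 2^(Ct_input - Ct_chip)`.
#'
#' @param ct_chip,ct_input target-locus Ct values in the ChIP and input
#'   reactions.
#' @param ct_chip_ctrl,ct_input_ctrl control-locus Ct values.
#' @param dil_chip,dil_input dilution factors (defaults 20 and 2000).
#' @return fold enrichment (numeric); percent-input values for target and
#'   control are attached as attributes `percent_target` and
#'   `percent_control`.
#' @export
qpcr_enrichment <- function(ct_chip, ct_input, ct_chip_ctrl, ct_input_ctrl,
                            dil_chip = 20, dil_input = 2000) {
  pct <- function(cc, ci)
    100 * (dil_chip / dil_input) * 2 ^ (ci - cc)
  pt <- pct(ct_chip, ct_input)
  pc <- pct(ct_chip_ctrl, ct_input_ctrl)
  structure(pt / pc, percent_target = pt, percent_control = pc)
}
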