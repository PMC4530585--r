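scan_gan_strand <- function(chars, min_units) {
  n <- length(chars)
  if (n < 3) return(data.frame(start = integer(0), end = integer(0),
                               n_units = integer(0)))
  valid <- chars[1:(n - 2)] == "G" & chars[2:(n - 1)] == "A" &
    chars[3:n] %in% c("A", "C", "G", "T")
  out <- list()
  for (f in 0:2) {
    idx <- seq(f + 1, n - 2, by = 3)
    if (!length(idx) || idx[1] > length(valid)) next
    idx <- idx[idx <= length(valid)]
    r <- rle(valid[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hits <- which(r$values & r$lengths >= min_units)
    if (length(hits))
      out[[length(out) + 1L]] <- data.frame(
        start = idx[starts[hits]] - 1L,
        end = idx[starts[hits]] - 1L + 3L * r$lengths[hits],
        n_units = r$lengths[hits])
  }
  if (!length(out)) return(data.frame(start = integer(0),
                                      end = integer(0),
                                      n_units = integer(0)))
  do.call(rbind, out)
}

#' Scan sequences for GAN-repeat runs
#'
#' Finds maximal in-frame runs of the 3-bp unit `GA[ACGT]` of at least
#' `min_units` consecutive triplets.  `N` never matches.  The reverse
#' strand is scanned on the reverse complement and reported in forward
#' coordinates; out-of-frame runs are reported independently per frame
#' (maximality is per frame).
#'
#' @param sequences named character vector of sequences over
#'   `{A,C,G,T,N}`, or a [Biostrings::DNAStringSet].
#' @param min_units minimum run length in triplets (default 3).
#' @param both_strands also scan the reverse complement.
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open,
#'   `end - start = 3 * n_units`), `n_units`, `strand`.
#' @export
scan_gan <- function(sequences, min_units = 3, both_strands = TRUE) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences),
                                 names(sequences))
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  out <- list()
  for (cn in names(sequences)) {
    s <- toupper(sequences[[cn]])
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (any(!chars %in% c("A", "C", "G", "T", "N")))
      stop("invalid alphabet in sequence ", cn)
    fwd <- scan_gan_strand(chars, min_units)
    if (nrow(fwd))
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = fwd$start, end = fwd$end,
        n_units = fwd$n_units, strand = "+", stringsAsFactors = FALSE)
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
      rchars <- strsplit(rc, "", fixed = TRUE)[[1]]
      rev <- scan_gan_strand(rchars, min_units)
      if (nrow(rev)) {
        n <- length(chars)
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, start = n - rev$end, end = n - rev$start,
          n_units = rev$n_units, strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_units = integer(), strand = character(),
               stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, res$end, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Motif occurrence probability around summits
#'
#' The probability at offset d is the fraction of summits for which at
#' least one motif match covers `summit + d` (coverage-based, both
#' strands pooled).
#'
#' @param matches data.frame from [scan_gan()].
#' @param summits data.frame `chrom`, `pos` (or a `peak_set`).
#' @param half_width profile half-width in bp (default 500).
#' @param chrom_lengths optional named lengths; defaults to the extent of
#'   the matches/summits themselves.
#' @return data.frame `offset`, `probability`, `n` (summits with the
#'   offset position in range).
#' @export
motif_summit_profile <- function(matches, summits, half_width = 500,
                                 chrom_lengths = NULL) {
  if (inherits(summits, "peak_set"))
    summits <- data.frame(chrom = summits$chrom, pos = summits$summit,
                          stringsAsFactors = FALSE)
  if (is.null(chrom_lengths)) {
    all_chr <- union(unique(matches$chrom), unique(summits$chrom))
    chrom_lengths <- vapply(all_chr, function(cn)
      max(c(matches$end[matches$chrom == cn],
            summits$pos[summits$chrom == cn] + half_width + 1, 1)),
      numeric(1))
  }
  cov <- lapply(names(chrom_lengths), function(cn) {
    v <- logical(chrom_lengths[[cn]])
    m <- matches[matches$chrom == cn, , drop = FALSE]
    for (k in seq_len(nrow(m))) v[(m$start[k] + 1):m$end[k]] <- TRUE
    v
  })
  names(cov) <- names(chrom_lengths)
  offs <- -half_width:half_width
  hits <- cnt <- numeric(length(offs))
  for (i in seq_len(nrow(summits))) {
    v <- cov[[summits$chrom[i]]]
    idx <- summits$pos[i] + offs
    ok <- idx >= 0 & idx < length(v)
    hits[ok] <- hits[ok] + v[idx[ok] + 1]
    cnt[ok] <- cnt[ok] + 1
  }
  data.frame(offset = offs,
             probability = ifelse(cnt > 0, hits / cnt, NA_real_),
             n = cnt)
}

#' Fraction of peaks containing a motif match
#'
#' @param peaks a `peak_set`.
#' @param matches data.frame from [scan_gan()].
#' @param flank half-width around the summit (bp, default 500).
#' @return fraction of peaks whose `summit +- flank` window intersects at
#'   least one match.
#' @export
peak_motif_fraction <- function(peaks, matches, flank = 500) {
  if (!nrow(peaks)) return(NA_real_)
  hit <- logical(nrow(peaks))
  for (cn in unique(peaks$chrom)) {
    psel <- which(peaks$chrom == cn)
    m <- matches[matches$chrom == cn, , drop = FALSE]
    if (!nrow(m)) next
    win <- IRanges::IRanges(start = peaks$summit[psel] - flank + 1,
                            end = peaks$summit[psel] + flank + 1)
    mr <- IRanges::IRanges(start = m$start + 1, end = m$end)
    hit[psel] <- IRanges::overlapsAny(win, mr)
  }
  mean(hit)
}
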