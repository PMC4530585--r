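# Toy-genome builders and independently coded brute-force oracles used to
# verify the vectorized implementations.

toy_annotation <- function(genes, chrom_len = 2000, cen_mid = NA,
                           transcripts = NULL, chrom = "chrA") {
  chroms <- data.frame(name = chrom, length = chrom_len, cen_mid = cen_mid,
                       stringsAsFactors = FALSE)
  genome_annotation(chroms, genes, transcripts)
}

# a small random multi-gene genome with transcripts, for property tests
random_toy_genome <- function(seed, n_genes = 10, n_chrom = 2,
                              chrom_len = 20000) {
  set.seed(seed)
  genes <- list(); txs <- list()
  for (ci in seq_len(n_chrom)) {
    cn <- paste0("chr", ci)
    n <- ceiling(n_genes / n_chrom)
    pos <- 600
    for (k in seq_len(n)) {
      L <- sample(300:900, 1)
      gap <- sample(150:600, 1)
      s <- pos + gap; e <- s + L
      if (e > chrom_len - 600) break
      id <- paste0(cn, "_g", k)
      genes[[id]] <- data.frame(id = id, chrom = cn, start = s, end = e,
                                strand = sample(c("+", "-"), 1),
                                stringsAsFactors = FALSE)
      u1 <- sample(20:120, 1); u2 <- sample(20:120, 1)
      txs[[id]] <- data.frame(gene_id = id, tx_start = max(0, s - u1),
                              tx_end = min(chrom_len, e + u2),
                              stringsAsFactors = FALSE)
      pos <- e
    }
  }
  chroms <- data.frame(name = paste0("chr", seq_len(n_chrom)),
                       length = chrom_len,
                       cen_mid = round(chrom_len * 0.7),
                       stringsAsFactors = FALSE)
  genome_annotation(chroms, do.call(rbind, genes), do.call(rbind, txs))
}

random_track <- function(annotation, seed) {
  set.seed(seed)
  coverage_track(lapply(chrom_lengths(annotation),
                        function(L) runif(L, 0, 5)))
}

# ---- brute-force peak-caller oracle: explicit per-position loops ----
bf_call_peaks <- function(v, genome_mean, window = 300,
                          p_threshold = 1e-15, merge_gap = 200,
                          min_width = 100, local_bg = 10000) {
  L <- length(v)
  if (L < window) return(matrix(numeric(0), ncol = 2))
  sig <- logical(L - window + 1)
  for (s0 in 0:(L - window)) {
    ws <- sum(v[(s0 + 1):(s0 + window)])
    c0 <- s0 + floor(window / 2)
    a <- max(0, c0 - floor(local_bg / 2))
    b <- min(L, c0 + ceiling(local_bg / 2))
    lam <- max(genome_mean, mean(v[(a + 1):b])) * window
    sig[s0 + 1] <- ppois(ceiling(ws) - 1, lam, lower.tail = FALSE) <=
      p_threshold
  }
  ivs <- list()
  i <- 1
  while (i <= length(sig)) {
    if (sig[i]) {
      j <- i
      while (j < length(sig) && sig[j + 1]) j <- j + 1
      ivs[[length(ivs) + 1]] <- c(i - 1, j - 1 + window)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(ivs)) return(matrix(numeric(0), ncol = 2))
  merged <- list(ivs[[1]])
  for (iv in ivs[-1]) {
    last <- merged[[length(merged)]]
    if (iv[1] - last[2] <= merge_gap)
      merged[[length(merged)]] <- c(last[1], iv[2])
    else merged[[length(merged) + 1]] <- iv
  }
  keep <- Filter(function(iv) iv[2] - iv[1] >= min_width, merged)
  if (!length(keep)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, keep)
}

# ---- brute-force profile oracles: one anchor at a time, scalar loops ----
bf_aligned_profile <- function(track, chrom, pos, strand = NULL, hw) {
  offs <- -hw:hw
  means <- sapply(offs, function(o) {
    vals <- c()
    for (i in seq_along(pos)) {
      p <- if (!is.null(strand) && strand[i] == "-") pos[i] - o
           else pos[i] + o
      v <- track[[chrom[i]]]
      if (p >= 0 && p < length(v)) vals <- c(vals, v[p + 1])
    }
    if (length(vals)) mean(vals) else NA_real_
  })
  data.frame(offset = offs, mean = means)
}

bf_metagene <- function(track, genes, body_bins, flank) {
  profiles <- matrix(NA_real_, nrow(genes), 2 * flank + body_bins)
  for (i in seq_len(nrow(genes))) {
    v <- track[[genes$chrom[i]]]
    s <- genes$start[i]; e <- genes$end[i]; L <- e - s
    body <- sapply(seq_len(body_bins), function(b) {
      lo <- floor((b - 1) * L / body_bins)
      hi <- max(floor(b * L / body_bins), lo + 1)
      hi <- min(hi, L); lo <- min(lo, hi - 1)
      mean(v[(s + lo + 1):(s + hi)])
    })
    up <- sapply((s - flank):(s - 1), function(p)
      if (p >= 0 && p < length(v)) v[p + 1] else NA_real_)
    dn <- sapply(e:(e + flank - 1), function(p)
      if (p >= 0 && p < length(v)) v[p + 1] else NA_real_)
    prof <- c(up, body, dn)
    if (genes$strand[i] == "-") prof <- rev(prof)
    profiles[i, ] <- prof
  }
  colMeans(profiles, na.rm = TRUE)
}

# ---- regex-based GAN oracle: anchored match at every position, kept
# only where the preceding in-frame triplet does not extend the run ----
bf_scan_gan <- function(seq, min_units, both_strands = TRUE) {
  scan1 <- function(s, strand, n) {
    out <- list()
    if (n < 3) return(NULL)
    for (p in 0:(n - 3)) {                    # 0-based candidate start
      m <- regexpr("^(GA[ACGT])+", substring(s, p + 1))
      if (m == -1) next
      units <- attr(m, "match.length") / 3
      if (units < min_units) next
      if (p >= 3 && grepl("^GA[ACGT]", substring(s, p - 2)))
        next                                  # not run-maximal in frame
      st <- p; en <- p + 3 * units
      if (strand == "-") { tmp <- st; st <- n - en; en <- n - tmp }
      out[[length(out) + 1]] <- data.frame(start = st, end = en,
                                           n_units = units,
                                           strand = strand,
                                           stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  n <- nchar(seq)
  res <- list(scan1(seq, "+", n))
  if (both_strands) {
    rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]),
                                         collapse = ""))
    res[[2]] <- scan1(rc, "-", n)
  }
  res <- do.call(rbind, Filter(Negate(is.null), res))
  if (is.null(res))
    return(data.frame(start = integer(0), end = integer(0),
                      n_units = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

write_toy_gff <- function(annotation, dir = tempdir()) {
  gff <- file.path(dir, paste0("toy-", as.integer(runif(1, 1, 1e8)),
                               ".gff3"))
  sizes <- sub("\\.gff3$", ".sizes", gff)
  cens <- sub("\\.gff3$", ".cen.bed", gff)
  write_annotation(annotation, gff, sizes, cens)
  list(gff = gff, sizes = sizes, cens = cens)
}
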