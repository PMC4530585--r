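#' Construct a per-bp coverage track
#'
#' A coverage track is the currency of every analysis stage: one finite
#' numeric value per base pair per chromosome.
#'
#' @param values named list of numeric vectors, one per chromosome; the
#'   vector length is the chromosome length.
#' @param label optional character label (sample name / normalization
#'   state), carried through as an attribute.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(values, label = NULL) {
  stopifnot(is.list(values), !is.null(names(values)),
            all(nzchar(names(values))))
  for (cn in names(values)) {
    v <- values[[cn]]
    if (!is.numeric(v) || length(v) < 1L)
      stop("track for ", cn, " must be a non-empty numeric vector")
    if (!all(is.finite(v)))
      stop("non-finite values in track for ", cn)
  }
  structure(values, class = "coverage_track", label = label)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track", if (!is.null(attr(x, "label")))
    paste0("[", attr(x, "label"), "]") else "", ":",
    length(x), "chromosomes,", sum(vapply(x, length, 0)), "bp\n")
  invisible(x)
}

track_lengths <- function(track) vapply(track, length, numeric(1))

#' Construct a read set
#'
#' @param chrom,start,end,strand parallel vectors of aligned-read
#'   intervals, 0-based half-open, strand in `+`/`-`.
#' @param chrom_lengths named numeric vector of chromosome lengths; when
#'   given, reads are validated against it and the lengths travel with the
#'   object (attribute `chrom_lengths`).
#' @return data.frame of class `read_set`.
#' @export
read_set <- function(chrom, start, end, strand, chrom_lengths = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(!df$strand %in% c("+", "-"))) stop("read strand must be + or -")
    if (any(df$start < 0)) stop("negative read coordinate")
    if (any(df$start >= df$end)) stop("read must satisfy start < end")
    if (!is.null(chrom_lengths)) {
      unknown <- setdiff(df$chrom, names(chrom_lengths))
      if (length(unknown))
        stop("read on unknown chromosome: ", paste(unknown, collapse = ", "))
      if (any(df$end > chrom_lengths[df$chrom]))
        stop("read extends past chromosome end")
    }
  }
  attr(df, "chrom_lengths") <- chrom_lengths
  class(df) <- c("read_set", "data.frame")
  df
}

#' Read aligned reads from BED6 or SAM
#'
#' BED is parsed directly so that malformed lines can be reported with
#' their line numbers; SAM is converted through [Rsamtools::asBam()].
#' Only chromosome, start, end and strand are extracted.
#'
#' @param path input file (`.sam` switches to SAM parsing, anything else
#'   is treated as BED6).
#' @param chrom_lengths optional named lengths for validation/clipping
#'   context downstream.
#' @param format `"auto"`, `"bed"` or `"sam"`.
#' @return a [read_set()].
#' @export
read_reads <- function(path, chrom_lengths = NULL,
                       format = c("auto", "bed", "sam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "qwidth", "strand"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
    keep <- !is.na(rec$pos)
    return(read_set(as.character(rec$rname[keep]), rec$pos[keep] - 1,
                    rec$pos[keep] - 1 + rec$qwidth[keep],
                    as.character(rec$strand[keep]), chrom_lengths))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(read_set(character(), numeric(), numeric(), character(),
                    chrom_lengths))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("malformed BED6 line(s) (fewer than 6 fields): line ",
         paste(utils::head(which(nf < 6), 5), collapse = ", "))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  strand <- vapply(fields, `[[`, "", 6L)
  bad <- is.na(start) | is.na(end) | !strand %in% c("+", "-")
  if (any(bad))
    stop("malformed BED6 line(s): line ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  if (any(start < 0))
    stop("negative coordinate: line ",
         paste(utils::head(which(start < 0), 5), collapse = ", "))
  read_set(chrom, start, end, strand, chrom_lengths)
}

#' Write a read set as BED6
#'
#' @param reads a [read_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  lines <- sprintf("%s\t%d\t%d\t.\t0\t%s", reads$chrom,
                   as.integer(reads$start), as.integer(reads$end),
                   reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Zero runs are omitted; values are written with 17 significant digits so
#' that a write/read round-trip is value-exact.
#'
#' @param track a [coverage_track()].
#' @param path output bedGraph file.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cn in names(track)) {
    r <- rle(track[[cn]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.17g", cn,
                       as.integer(starts[keep]), as.integer(ends[keep]),
                       r$values[keep]), con)
  }
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (no track header lines).
#' @param chrom_lengths named numeric vector giving the full chromosome
#'   complement; positions not covered by any interval are 0.
#' @param label optional label for the resulting track.
#' @return a [coverage_track()].
#' @export
read_track <- function(path, chrom_lengths, label = NULL) {
  stopifnot(!is.null(names(chrom_lengths)))
  values <- lapply(chrom_lengths, numeric)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 4))
      stop("malformed bedGraph line(s): line ",
           paste(utils::head(which(nf < 4), 5), collapse = ", "))
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    val <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    bad <- is.na(start) | is.na(end) | is.na(val) | start < 0 | start >= end
    if (any(bad))
      stop("malformed bedGraph line(s): line ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    unknown <- setdiff(chrom, names(chrom_lengths))
    if (length(unknown))
      stop("bedGraph interval on unknown chromosome: ",
           paste(unknown, collapse = ", "))
    if (any(end > chrom_lengths[chrom]))
      stop("bedGraph interval past chromosome end")
    for (i in seq_along(chrom))
      values[[chrom[i]]][(start[i] + 1):end[i]] <- val[i]
  }
  coverage_track(values, label = label)
}

#' Per-bp pileup of a read set
#'
#' The value at position p is the number of reads covering p, computed
#' with [GenomicRanges::coverage()].
#'
#' @param reads a [read_set()].
#' @param chrom_lengths named lengths; defaults to the read set's own
#'   `chrom_lengths` attribute.
#' @param label optional track label.
#' @return a [coverage_track()]; the track sum equals the summed read
#'   lengths.
#' @export
pileup <- function(reads, chrom_lengths = NULL, label = NULL) {
  chrom_lengths <- chrom_lengths %||% attr(reads, "chrom_lengths")
  if (is.null(chrom_lengths))
    stop("chrom_lengths required (none attached to the read set)")
  gr <- GenomicRanges::GRanges(
    seqnames = factor(reads$chrom, levels = names(chrom_lengths)),
    ranges = IRanges::IRanges(start = reads$start + 1, end = reads$end),
    seqlengths = chrom_lengths)
  cov <- GenomicRanges::coverage(gr)
  coverage_track(lapply(as.list(cov), as.numeric), label = label)
}
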