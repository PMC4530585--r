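#' @importFrom utils read.table write.table head tail
#' @importFrom stats median ppois rnorm rlnorm rgamma runif rbinom cor
#'   quantile sd lm coef complete.cases setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a genome annotation
#'
#' Bundles chromosomes, ORFs and (optionally) transcripts into a single
#' validated object.  All coordinates are 0-based, half-open; GFF input is
#' converted at the parser boundary (see [load_annotation()]).
#'
#' @param chromosomes data.frame with columns `name`, `length` and
#'   optionally `cen_mid` (centromere midpoint in bp, `NA` when unknown).
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`); ORF coordinates, 0-based half-open.
#' @param transcripts optional data.frame with columns `gene_id`,
#'   `tx_start`, `tx_end`; each transcript must contain its ORF.
#' @return object of class `genome_annotation`: a list with elements
#'   `chromosomes`, `genes` (sorted by chromosome then start) and
#'   `transcripts` (or `NULL`).
#' @export
genome_annotation <- function(chromosomes, genes, transcripts = NULL) {
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  if (is.null(chromosomes$cen_mid)) chromosomes$cen_mid <- NA_real_
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be positive")
  cen <- chromosomes$cen_mid
  bad <- !is.na(cen) & (cen < 0 | cen >= chromosomes$length)
  if (any(bad))
    stop("centromere midpoint outside chromosome: ",
         paste(chromosomes$name[bad], collapse = ", "))

  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "start", "end", "strand") %in% names(genes)))
  genes$id <- as.character(genes$id)
  genes$chrom <- as.character(genes$chrom)
  if (anyDuplicated(genes$id))
    stop("duplicated gene ids: ",
         paste(unique(genes$id[duplicated(genes$id)]), collapse = ", "))
  unknown <- setdiff(genes$chrom, chromosomes$name)
  if (length(unknown))
    stop("gene on unknown chromosome: ", paste(unknown, collapse = ", "))
  if (any(genes$start < 0) || any(genes$start >= genes$end))
    stop("gene ORF must satisfy 0 <= start < end")
  len_of <- stats::setNames(chromosomes$length, chromosomes$name)
  if (any(genes$end > len_of[genes$chrom]))
    stop("gene ORF extends past chromosome end: ",
         paste(genes$id[genes$end > len_of[genes$chrom]], collapse = ", "))
  dup <- duplicated(genes[c("chrom", "start", "end")])
  if (any(dup))
    warning(sum(dup), " gene(s) with duplicated ORF coordinates kept")
  ord <- order(match(genes$chrom, chromosomes$name), genes$start, -genes$end)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL

  if (!is.null(transcripts)) {
    transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "tx_start", "tx_end") %in% names(transcripts)))
    transcripts$gene_id <- as.character(transcripts$gene_id)
    m <- match(transcripts$gene_id, genes$id)
    if (anyNA(m))
      stop("transcript for unknown gene: ",
           paste(transcripts$gene_id[is.na(m)], collapse = ", "))
    if (any(transcripts$tx_start > genes$start[m]) ||
        any(transcripts$tx_end < genes$end[m]))
      stop("transcript does not contain its ORF")
    if (any(transcripts$tx_start < 0) ||
        any(transcripts$tx_end > len_of[genes$chrom[m]]))
      stop("transcript outside chromosome bounds")
    transcripts <- transcripts[order(m), , drop = FALSE]
    rownames(transcripts) <- NULL
  }
  structure(list(chromosomes = chromosomes, genes = genes,
                 transcripts = transcripts),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$genes), "genes,",
      if (is.null(x$transcripts)) "no transcripts"
      else paste(nrow(x$transcripts), "transcripts"), "\n")
  invisible(x)
}

#' Chromosome lengths of an annotation
#'
#' @param annotation a `genome_annotation`.
#' @return named numeric vector of chromosome lengths (bp).
#' @export
chrom_lengths <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  stats::setNames(annotation$chromosomes$length, annotation$chromosomes$name)
}

#' Load a genome annotation from standard files
#'
#' Reads gene (and optional mRNA) features from a GFF3 file, chromosome
#' sizes from two-column text and centromere positions from three-column
#' BED.  GFF coordinates (1-based, closed) are converted to the package's
#' internal 0-based half-open convention here and nowhere else.
#'
#' @param gff_path GFF3 file with `gene` features (ID attribute used as the
#'   gene id) and optionally `mRNA` features carrying a `Parent` attribute.
#' @param chrom_sizes_path two-column whitespace-separated text:
#'   chromosome name, length.
#' @param centromere_path optional BED3 of centromere intervals; the
#'   midpoint of each interval is stored.  An empty/absent file leaves all
#'   centromeres unset (centromere-dependent operations then refuse to run).
#' @return a [genome_annotation()].
#' @export
load_annotation <- function(gff_path, chrom_sizes_path,
                            centromere_path = NULL) {
  sizes <- utils::read.table(chrom_sizes_path, header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("name", "length"))
  chromosomes <- data.frame(name = as.character(sizes$name),
                            length = as.numeric(sizes$length),
                            cen_mid = NA_real_,
                            stringsAsFactors = FALSE)

  if (!is.null(centromere_path) && file.exists(centromere_path) &&
      file.size(centromere_path) > 0) {
    cen <- utils::read.table(centromere_path, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(cen) < 3) stop("centromere BED needs >= 3 columns")
    m <- match(as.character(cen[[1]]), chromosomes$name)
    if (anyNA(m))
      stop("centromere on unknown chromosome: ",
           paste(cen[[1]][is.na(m)], collapse = ", "))
    chromosomes$cen_mid[m] <- floor((as.numeric(cen[[2]]) +
                                     as.numeric(cen[[3]])) / 2)
  }

  gff <- rtracklayer::import(gff_path)
  type <- as.character(gff$type)
  gg <- gff[type == "gene"]
  if (!length(gg)) stop("no gene features in ", gff_path)
  ids <- gg$ID %||% gg$Name
  if (is.null(ids) || anyNA(ids)) stop("gene features lack ID attributes")
  genes <- data.frame(id = as.character(ids),
                      chrom = as.character(GenomicRanges::seqnames(gg)),
                      start = GenomicRanges::start(gg) - 1L,
                      end = GenomicRanges::end(gg),
                      strand = as.character(GenomicRanges::strand(gg)),
                      stringsAsFactors = FALSE)
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene features must be stranded")

  transcripts <- NULL
  mm <- gff[type %in% c("mRNA", "transcript")]
  if (length(mm)) {
    parent <- vapply(as.list(mm$Parent), function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
    transcripts <- data.frame(gene_id = parent,
                              tx_start = GenomicRanges::start(mm) - 1L,
                              tx_end = GenomicRanges::end(mm),
                              stringsAsFactors = FALSE)
    transcripts <- transcripts[!is.na(transcripts$gene_id), , drop = FALSE]
    if (!nrow(transcripts)) transcripts <- NULL
  }
  genome_annotation(chromosomes, genes, transcripts)
}

#' Classify adjacent gene pairs
#'
#' Walks each chromosome's genes in coordinate order and classifies every
#' adjacent pair as convergent (`+` then `-`), tandem (same strand) or
#' divergent (`-` then `+`).  The intergenic region is taken between the
#' facing ORF boundaries; its midpoint is the floor of the boundary mean.
#' Nested ORFs (fully contained in an earlier gene) are skipped with a
#' warning, since pair orientation is undefined for them.
#'
#' For convergent pairs with known transcripts the signed 3' transcript
#' overlap is attached (`tx_overlap > 0` means overlapping 3' UTRs), along
#' with the transcript-end midpoint `tx_mid` used by transcript-frame
#' analyses.  When `expression` is supplied, convergent pairs also carry
#' `expression_delta` = RPKM(forward `+` gene) - RPKM(reverse `-` gene).
#'
#' @param annotation a [genome_annotation()].
#' @param expression optional named numeric vector of RPKM per gene id.
#' @return data.frame of class `gene_pairs` with one row per adjacent pair:
#'   `chrom`, `left_gene`, `right_gene`, `orientation`, `intergenic_start`,
#'   `intergenic_end`, `midpoint`, and for convergent pairs `tx_end_left`,
#'   `tx_start_right`, `tx_overlap`, `tx_mid`, `expression_delta`.
#' @export
classify_gene_pairs <- function(annotation, expression = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  genes <- annotation$genes
  tx <- annotation$transcripts
  tx_start <- tx_end <- NULL
  if (!is.null(tx)) {
    tx_start <- stats::setNames(tx$tx_start, tx$gene_id)
    tx_end <- stats::setNames(tx$tx_end, tx$gene_id)
  }
  out <- list()
  n_nested <- 0L
  for (cn in annotation$chromosomes$name) {
    g <- genes[genes$chrom == cn, , drop = FALSE]
    if (nrow(g) < 1L) next
    # genes are sorted by (start, -end); a gene whose end does not exceed
    # the running maximum of previous ends is nested inside an earlier gene
    if (nrow(g) > 1L) {
      run_max <- cummax(g$end)
      nested <- c(FALSE, g$end[-1L] <= run_max[-nrow(g)])
    } else nested <- FALSE
    n_nested <- n_nested + sum(nested)
    g <- g[!nested, , drop = FALSE]
    if (nrow(g) < 2L) next
    i <- seq_len(nrow(g) - 1L)
    sl <- g$strand[i]; sr <- g$strand[i + 1L]
    orientation <- ifelse(sl == "+" & sr == "-", "convergent",
                   ifelse(sl == "-" & sr == "+", "divergent", "tandem"))
    is_ <- g$end[i]; ie <- g$start[i + 1L]
    df <- data.frame(chrom = cn,
                     left_gene = g$id[i], right_gene = g$id[i + 1L],
                     orientation = orientation,
                     intergenic_start = is_, intergenic_end = ie,
                     midpoint = floor((is_ + ie) / 2),
                     stringsAsFactors = FALSE)
    df$tx_end_left <- NA_real_
    df$tx_start_right <- NA_real_
    df$tx_overlap <- NA_real_
    df$tx_mid <- NA_real_
    conv <- df$orientation == "convergent"
    if (!is.null(tx) && any(conv)) {
      el <- tx_end[df$left_gene[conv]]
      er <- tx_start[df$right_gene[conv]]
      df$tx_end_left[conv] <- el
      df$tx_start_right[conv] <- er
      df$tx_overlap[conv] <- el - er
      df$tx_mid[conv] <- floor((el + er) / 2)
    }
    df$expression_delta <- NA_real_
    if (!is.null(expression) && any(conv)) {
      df$expression_delta[conv] <-
        unname(expression[df$left_gene[conv]] -
               expression[df$right_gene[conv]])
    }
    out[[cn]] <- df
  }
  if (n_nested > 0L)
    warning(n_nested, " nested ORF(s) skipped during gene pairing")
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), left_gene = character(),
               right_gene = character(), orientation = character(),
               intergenic_start = numeric(), intergenic_end = numeric(),
               midpoint = numeric(), tx_end_left = numeric(),
               tx_start_right = numeric(), tx_overlap = numeric(),
               tx_mid = numeric(), expression_delta = numeric(),
               stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  class(pairs) <- c("gene_pairs", "data.frame")
  pairs
}

#' Signed 3' transcript overlap of convergent pairs
#'
#' For a convergent pair the returned value is the 3' end of the left
#' (`+`) transcript minus the 3' end of the right (`-`) transcript, i.e.
#' positive when the 3' UTRs overlap and negative when a gap separates
#' them.
#'
#' @param pairs `gene_pairs` rows; all must be convergent.
#' @param annotation a [genome_annotation()] with transcripts.
#' @return numeric vector of signed overlaps (bp).
#' @export
transcript_overlap <- function(pairs, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (is.null(annotation$transcripts))
    stop("annotation carries no transcripts")
  if (any(pairs$orientation != "convergent"))
    stop("transcript overlap is defined for convergent pairs only")
  tx <- annotation$transcripts
  tx_start <- stats::setNames(tx$tx_start, tx$gene_id)
  tx_end <- stats::setNames(tx$tx_end, tx$gene_id)
  unname(tx_end[pairs$left_gene] - tx_start[pairs$right_gene])
}
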