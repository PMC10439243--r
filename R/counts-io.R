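# Counts ingestion and aggregation onto the interval grid.

#' Read a per-amplicon / per-interval counts table
#'
#' Reads a BED4-like TSV (`chrom`, `start`, `end`, `count`; header optional,
#' gzip transparent). Rows with identical coordinates are summed with a
#' warning; malformed rows are rejected with their line numbers.
#'
#' @param path path to the counts TSV (optionally .gz).
#' @param sampleId sample identifier; defaults to the file basename.
#' @return A \linkS4class{SampleCounts}.
#' @export
readCountsTable <- function(path, sampleId = NULL) {
  if (is.null(sampleId))
    sampleId <- sub("\\.(tsv|bed|txt)(\\.gz)?$", "", basename(path))
  first <- readLines(con <- gzfile(path, "rt"), n = 1); close(con)
  f1 <- strsplit(first, "\t")[[1]]
  hasHeader <- length(f1) >= 4 && is.na(suppressWarnings(as.numeric(f1[2])))
  df <- read.table(gzfile(path), header = hasHeader, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 4)
    stop("counts file must have >= 4 columns (chrom, start, end, count)")
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "count")
  lineNo <- seq_len(nrow(df)) + as.integer(hasHeader)
  bad <- !is.finite(df$count) | df$count < 0 |
    !is.finite(df$start) | !is.finite(df$end) | df$end <= df$start
  if (any(bad))
    stop("malformed counts row(s) at line(s): ",
         paste(head(lineNo[bad], 10), collapse = ", "),
         " (negative count, non-numeric field, or end <= start)")
  key <- paste(df$chrom, df$start, df$end)
  if (anyDuplicated(key)) {
    warning("duplicate coordinates in ", basename(path), "; counts summed")
    df <- aggregate(count ~ chrom + start + end, data = df, FUN = sum)
  }
  gr <- GRanges(df$chrom, IRanges(start = df$start + 1, end = df$end))
  mcols(gr)$count <- df$count
  obj <- new("SampleCounts", sampleId = sampleId, records = gr)
  validObject(obj)
  obj
}

#' Construct SampleCounts from a data.frame
#'
#' @param df data.frame with columns chrom, start, end, count (0-based
#'   half-open coordinates).
#' @param sampleId sample identifier.
#' @return A \linkS4class{SampleCounts}.
#' @export
sampleCountsFromFrame <- function(df, sampleId = "sample") {
  gr <- GRanges(df$chrom, IRanges(start = df$start + 1, end = df$end))
  mcols(gr)$count <- df$count
  obj <- new("SampleCounts", sampleId = sampleId, records = gr)
  validObject(obj)
  obj
}

#' Aggregate amplicon counts onto the interval grid
#'
#' Each record's count is added to the single grid bin containing its
#' midpoint (records straddling a bin edge are never double-counted, so
#' count mass is conserved exactly). Records whose midpoint falls outside
#' every bin are dropped and tallied.
#'
#' @param sc a \linkS4class{SampleCounts}.
#' @param grid an \linkS4class{IntervalGrid} built from the same layout.
#' @return An \linkS4class{IntervalVector}.
#' @export
binCounts <- function(sc, grid) {
  stopifnot(is(sc, "SampleCounts"), is(grid, "IntervalGrid"))
  r <- sc@records
  mid <- floor((start(r) - 1 + end(r)) / 2)   # 0-based midpoint
  pts <- GRanges(seqnames(r), IRanges(start = mid + 1, width = 1))
  # records on chromosomes absent from the grid are expected: they are
  # dropped and tallied, so the seqlevel mismatch warning is noise here
  hits <- suppressWarnings(findOverlaps(pts, grid@bins))
  counts <- numeric(length(grid@bins))
  cnt <- mcols(r)$count
  agg <- tapply(cnt[queryHits(hits)], subjectHits(hits), sum)
  counts[as.integer(names(agg))] <- as.numeric(agg)
  dropped <- sum(cnt) - sum(counts)
  new("IntervalVector", sampleId = sc@sampleId, counts = counts,
      grid = grid, dropped = dropped)
}

#' Construct an IntervalVector from a plain count vector
#'
#' @param counts numeric vector, one count per grid bin.
#' @param grid an \linkS4class{IntervalGrid}.
#' @param sampleId sample identifier.
#' @return An \linkS4class{IntervalVector}.
#' @export
intervalVector <- function(counts, grid, sampleId = "sample") {
  obj <- new("IntervalVector", sampleId = sampleId,
             counts = as.numeric(counts), grid = grid, dropped = 0)
  validObject(obj)
  obj
}

#' Write an IntervalVector as a BED4-like counts TSV
#'
#' @param v an \linkS4class{IntervalVector}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeIntervalVector <- function(v, path) {
  b <- v@grid@bins
  df <- data.frame(chrom = as.character(seqnames(b)),
                   start = start(b) - 1, end = end(b), count = v@counts)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
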