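# Genome model: layouts, scored arms, the interval grid and focal windows.
# All internal coordinates are 0-based half-open (BED convention).

#' Load a genome layout from a TSV file
#'
#' Reads a tab-separated layout with columns `name`, `length`,
#' `cen_start`, `cen_end`, `acrocentric` describing each autosome and its
#' centromere gap. Coordinates must be 0-based half-open; files written in
#' 1-based display coordinates can be ingested with `oneBased = TRUE`,
#' which shifts the centromere start down by one.
#'
#' @param path path to the layout TSV.
#' @param oneBased logical; set TRUE when the file uses 1-based inclusive
#'   coordinates.
#' @return A validated \linkS4class{GenomeLayout}.
#' @examples
#' layout <- hg19Layout()
#' layout
#' @export
loadGenomeLayout <- function(path, oneBased = FALSE) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "length", "cen_start", "cen_end", "acrocentric")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("layout file is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("layout field 'name': duplicate chromosome '",
         df$name[duplicated(df$name)][1], "'")
  cenStart <- as.numeric(df$cen_start) - if (oneBased) 1 else 0
  layout <- new("GenomeLayout",
                chrom = as.character(df$name),
                length = as.numeric(df$length),
                cenStart = cenStart,
                cenEnd = as.numeric(df$cen_end),
                acrocentric = as.logical(df$acrocentric))
  validObject(layout)
  layout
}

#' Bundled hg19 autosome layout
#'
#' The 22 autosomes of hg19 with UCSC gap-track centromere coordinates; the
#' five acrocentric chromosomes (13, 14, 15, 21, 22) are flagged so that
#' their p arms are excluded from scoring.
#'
#' @return A \linkS4class{GenomeLayout} with 22 chromosomes.
#' @export
hg19Layout <- function() {
  loadGenomeLayout(system.file("extdata", "hg19_autosomes.tsv",
                               package = "realcsf", mustWork = TRUE))
}

#' Enumerate the scored (non-acrocentric) chromosome arms
#'
#' One arm per non-acrocentric autosomal arm: the p arm is
#' `[0, cen_start)`, the q arm `[cen_end, length)`; acrocentric p arms are
#' dropped. Order is deterministic: chromosomes in layout order, p before q.
#' The bundled hg19 layout yields the 39 scored arms.
#'
#' @param layout a \linkS4class{GenomeLayout}.
#' @return A `GRanges` named by arm label ("1p", "1q", ...) with metadata
#'   column `arm`.
#' @examples
#' length(scoredArms(hg19Layout()))  # 39
#' @export
scoredArms <- function(layout) {
  stopifnot(is(layout, "GenomeLayout"))
  chroms <- character(0); starts <- numeric(0); ends <- numeric(0)
  labels <- character(0)
  for (i in seq_along(layout@chrom)) {
    base <- sub("^chr", "", layout@chrom[i])
    if (!layout@acrocentric[i]) {
      chroms <- c(chroms, layout@chrom[i])
      starts <- c(starts, 0)
      ends <- c(ends, layout@cenStart[i])
      labels <- c(labels, paste0(base, "p"))
    }
    chroms <- c(chroms, layout@chrom[i])
    starts <- c(starts, layout@cenEnd[i])
    ends <- c(ends, layout@length[i])
    labels <- c(labels, paste0(base, "q"))
  }
  gr <- GRanges(chroms, IRanges(start = starts + 1, end = ends))
  names(gr) <- labels
  mcols(gr)$arm <- labels
  gr
}

#' Build the fixed-width autosomal interval grid
#'
#' Tiles each chromosome from position 0 in half-open bins of `width` bp;
#' the trailing partial bin is dropped so that all bins share the same
#' expected variance. Bins overlapping the centromere gap are kept in the
#' grid but excluded from arm assignment ("centromeric"); bins on
#' acrocentric p arms are excluded as "acrocentric_p".
#'
#' @param layout a \linkS4class{GenomeLayout}.
#' @param width bin width in bp (default 500 kb).
#' @return An \linkS4class{IntervalGrid}.
#' @examples
#' grid <- buildIntervalGrid(hg19Layout())
#' grid
#' @export
buildIntervalGrid <- function(layout, width = 5e5) {
  stopifnot(is(layout, "GenomeLayout"))
  if (length(width) != 1 || !is.finite(width) || width <= 0)
    stop("width must be a positive number of bp")
  chroms <- character(0); starts <- numeric(0)
  arm <- character(0); reason <- character(0)
  for (i in seq_along(layout@chrom)) {
    nb <- floor(layout@length[i] / width)
    if (nb < 1) next
    s <- (seq_len(nb) - 1) * width
    e <- s + width
    base <- sub("^chr", "", layout@chrom[i])
    a <- rep(NA_character_, nb)
    r <- rep("", nb)
    isP <- e <= layout@cenStart[i]
    isQ <- s >= layout@cenEnd[i]
    a[isP] <- paste0(base, "p")
    a[isQ] <- paste0(base, "q")
    r[!isP & !isQ] <- "centromeric"
    if (layout@acrocentric[i]) {
      r[isP] <- "acrocentric_p"
      a[isP] <- NA_character_
    }
    chroms <- c(chroms, rep(layout@chrom[i], nb))
    starts <- c(starts, s)
    arm <- c(arm, a)
    reason <- c(reason, r)
  }
  bins <- GRanges(chroms, IRanges(start = starts + 1, width = width))
  mcols(bins)$arm <- arm
  mcols(bins)$scored <- !is.na(arm)
  mcols(bins)$excludedReason <- reason
  new("IntervalGrid", bins = bins, width = width, layout = layout)
}

#' Arm labels of an interval grid
#'
#' @param grid an \linkS4class{IntervalGrid}.
#' @return Character vector of scored arm labels in canonical order.
#' @export
gridArmLabels <- function(grid) {
  stopifnot(is(grid, "IntervalGrid"))
  names(scoredArms(grid@layout))
}

#' Indices of grid bins assigned to one arm
#'
#' @param grid an \linkS4class{IntervalGrid}.
#' @param arm arm label such as `"7p"`.
#' @return Integer vector of bin indices.
#' @export
armBinIndices <- function(grid, arm) {
  stopifnot(is(grid, "IntervalGrid"))
  which(!is.na(mcols(grid@bins)$arm) & mcols(grid@bins)$arm == arm)
}

#' Define a focal window around a gene
#'
#' The window is the gene span extended by `flank` bp on each side, clipped
#' to the chromosome, with member intervals the grid bins overlapping it.
#'
#' @param gene gene symbol.
#' @param chrom chromosome name (must exist in the grid's layout).
#' @param start,end gene coordinates (bp, 0-based half-open).
#' @param grid an \linkS4class{IntervalGrid}.
#' @param flank bp added on each side (default 1 Mb).
#' @return A \linkS4class{FocalWindow}.
#' @examples
#' grid <- buildIntervalGrid(hg19Layout())
#' makeFocalWindow("TOY", "chr2", 2e6, 2.1e6, grid)
#' @export
makeFocalWindow <- function(gene, chrom, start, end, grid, flank = 1e6) {
  stopifnot(is(grid, "IntervalGrid"))
  if (flank < 0) stop("flank must be >= 0")
  li <- match(chrom, grid@layout@chrom)
  if (is.na(li))
    stop("gene chromosome '", chrom, "' not in layout")
  if (end <= start) stop("gene end must exceed start")
  ws <- max(0, start - flank)
  we <- min(grid@layout@length[li], end + flank)
  q <- GRanges(chrom, IRanges(start = ws + 1, end = we))
  hits <- findOverlaps(q, grid@bins)
  new("FocalWindow", gene = gene, chrom = chrom, start = ws, end = we,
      members = sort(subjectHits(hits)))
}

#' Default focal oncogene windows
#'
#' The four bundled oncogene windows used for focal amplification calling
#' (hg19 coordinates): MDM4 (1q32.1, 1.5 Mb), EGFR (7p11.2, 1.5 Mb),
#' CDK4 (12q14.1, 3.5 Mb) and ERBB2/HER2 (17q12, 2.5 Mb). The bundled
#' coordinates are complete windows (gene plus context), so no extra flank
#' is applied. Windows whose chromosome is absent from the grid's layout
#' (e.g. toy layouts) are silently skipped.
#'
#' @param grid an \linkS4class{IntervalGrid}.
#' @param bedPath optional BED4 file (chrom, start, end, gene) overriding
#'   the bundled window set.
#' @return Named list of \linkS4class{FocalWindow} objects.
#' @export
defaultFocalWindows <- function(grid, bedPath = NULL) {
  stopifnot(is(grid, "IntervalGrid"))
  if (is.null(bedPath))
    bedPath <- system.file("extdata", "focal_windows_hg19.bed",
                           package = "realcsf", mustWork = TRUE)
  bed <- read.table(bedPath, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "gene"))
  out <- list()
  for (i in seq_len(nrow(bed))) {
    if (!bed$chrom[i] %in% grid@layout@chrom) next
    out[[bed$gene[i]]] <- makeFocalWindow(bed$gene[i], bed$chrom[i],
                                          bed$start[i], bed$end[i],
                                          grid, flank = 0)
  }
  out
}

#' Export the grid as BED4 with arm labels
#'
#' @param grid an \linkS4class{IntervalGrid}.
#' @param path output path; excluded bins get their reason code as label.
#' @return Invisibly, the path.
#' @export
writeGridBed <- function(grid, path) {
  stopifnot(is(grid, "IntervalGrid"))
  b <- grid@bins
  lab <- ifelse(is.na(mcols(b)$arm), mcols(b)$excludedReason, mcols(b)$arm)
  df <- data.frame(chrom = as.character(seqnames(b)),
                   start = start(b) - 1, end = end(b), name = lab)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
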