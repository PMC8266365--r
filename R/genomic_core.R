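#' @importFrom GenomicRanges GRanges seqnames start end width reduce coverage
#' @importFrom IRanges IRanges slice
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom methods is
#' @importFrom stats lowess approx qnorm pnorm pt qt pchisq phyper p.adjust
#'   rnbinom rnorm runif rexp rbinom wilcox.test ks.test chisq.test
#'   setNames median quantile sd var
#' @importFrom utils read.table write.table
NULL

## ---------------------------------------------------------------------------
## Region containers
##
## Regions are plain GRanges. A labelled set of regions ("region set") is a
## GRanges with a `label` attribute in metadata(), built by region_set().
## Coordinates inside R are 1-based closed (GRanges convention); all files on
## disk are 0-based half-open BED.
## ---------------------------------------------------------------------------

#' Build a labelled region set
#'
#' Wraps a `GRanges` (or a data frame with `chrom`, `start`, `end` in 0-based
#' half-open coordinates) as a sorted region set carrying a class label such
#' as `"adult_biased"` or `"fetal_biased"`.
#'
#' @param x A `GRanges`, or a data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param label Character label for the set (e.g. `"adult_biased"`,
#'   `"fetal_biased"`, `"young_biased"`, `"old_biased"`, `"unaltered"`,
#'   `"background"`, or any custom string).
#' @return A sorted `GRanges` with a `label` attribute.
#' @export
region_set <- function(x, label = "custom") {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    if (any(x$start >= x$end)) stop("malformed coordinates: start >= end")
    x <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
  }
  stopifnot(methods::is(x, "GRanges"))
  if (any(GenomicRanges::width(x) < 1L)) stop("malformed coordinates: empty interval")
  x <- GenomicRanges::sort(x)
  attr(x, "label") <- label
  x
}

#' Label of a region set
#' @param x A `GRanges` built by [region_set()].
#' @return The label string, or `"custom"` when absent.
#' @export
set_label <- function(x) {
  lb <- attr(x, "label")
  if (is.null(lb)) "custom" else lb
}

#' Merge intervals into a minimal disjoint set
#'
#' Unions overlapping and book-ended (adjacent in half-open coordinates)
#' intervals so that total base-pair content is minimal.
#'
#' @param x A `GRanges` or region-set data frame (see [region_set()]).
#' @return A reduced, sorted `GRanges` preserving the set label.
#' @export
merge_regions <- function(x) {
  lb <- if (methods::is(x, "GRanges")) attr(x, "label") else NULL
  gr <- if (methods::is(x, "GRanges")) x else region_set(x)
  out <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  attr(out, "label") <- if (is.null(lb)) set_label(gr) else lb
  out
}

#' Total base pairs covered by a region set
#'
#' @param x A `GRanges`. Overlapping intervals are counted once.
#' @return Integer number of base pairs.
#' @export
total_bp <- function(x) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(x))))
}

#' Shared base pairs between two region sets
#'
#' @param a,b `GRanges` objects. Symmetric.
#' @return Number of base pairs covered by both sets.
#' @export
overlap_bp <- function(a, b) {
  ov <- GenomicRanges::intersect(GenomicRanges::reduce(a),
                                 GenomicRanges::reduce(b),
                                 ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(ov)))
}

#' Length- and chromosome-preserving randomizations of a region set
#'
#' Each randomization keeps every interval's length and chromosome and draws
#' its start uniformly over all positions where it fits, optionally rejecting
#' placements overlapping an exclusion mask. This is the randomized ("grey")
#' background used by the per-bp enrichment tests.
#'
#' @param x `GRanges` to randomize.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param n Number of randomized sets to draw.
#' @param exclude Optional `GRanges` exclusion mask; placements overlapping it
#'   are rejected and redrawn (up to `max_tries` rounds).
#' @param seed Optional integer seed for reproducible draws.
#' @param max_tries Rejection-sampling rounds before giving up on the mask.
#' @return A list of `n` `GRanges` objects.
#' @export
shuffle_regions <- function(x, chrom_sizes, n, exclude = NULL, seed = NULL,
                            max_tries = 1000L) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  chr <- as.character(GenomicRanges::seqnames(x))
  w <- GenomicRanges::width(x)
  if (!all(chr %in% names(chrom_sizes)))
    stop("chromosome missing from chrom_sizes")
  L <- chrom_sizes[chr]
  if (any(w > L)) stop("interval longer than its chromosome")
  nslots <- L - w + 1  # uniform over 0 .. L - w in 0-based starts
  draw_once <- function() {
    st <- floor(runif(length(w)) * nslots)  # 0-based starts
    gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(st + 1, st + w))
    if (!is.null(exclude) && length(exclude)) {
      bad <- IRanges::overlapsAny(gr, exclude, ignore.strand = TRUE)
      tries <- 0L
      while (any(bad)) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("could not place intervals outside exclusion mask")
        st2 <- floor(runif(sum(bad)) * nslots[bad])
        gr[bad] <- GenomicRanges::GRanges(chr[bad],
                                          IRanges::IRanges(st2 + 1, st2 + w[bad]))
        bad <- IRanges::overlapsAny(gr, exclude, ignore.strand = TRUE)
      }
    }
    GenomicRanges::sort(gr)
  }
  replicate(n, draw_once(), simplify = FALSE)
}

#' Flag points lying within a window of a region set
#'
#' A point is "nearby" a set when it falls inside an interval extended by
#' `window` bp on both sides. This single proximity rule is applied wherever
#' the pipeline asks for variants "within or nearby" regions.
#'
#' @param chrom Character vector of point chromosomes.
#' @param pos Numeric vector of 0-based point positions.
#' @param regions `GRanges` region set.
#' @param window Non-negative flank in bp (default 10000).
#' @return Logical vector, one flag per point.
#' @export
near_region_flags <- function(chrom, pos, regions, window = 10000) {
  if (window < 0) stop("negative window")
  stopifnot(length(chrom) == length(pos))
  if (!length(pos)) return(logical(0))
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
  ext <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::resize(regions, GenomicRanges::width(regions) + 2 * window,
                          fix = "center")))
  suppressWarnings(IRanges::overlapsAny(pts, ext, ignore.strand = TRUE))
}

#' Assign each point its nearest region-set label
#'
#' Given a named list of region sets, flags each point with the label of the
#' closest set within `window` bp (ties broken by list order); points near no
#' set get `fallback`.
#'
#' @param chrom,pos Point coordinates (0-based positions).
#' @param region_sets Named list of `GRanges`.
#' @param window Proximity window in bp.
#' @param fallback Label for points near no set.
#' @return Character vector of labels.
#' @export
nearest_set_label <- function(chrom, pos, region_sets, window = 10000,
                              fallback = "none") {
  stopifnot(length(names(region_sets)) == length(region_sets))
  n <- length(pos)
  dmat <- matrix(Inf, n, length(region_sets))
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
  for (j in seq_along(region_sets)) {
    hit <- suppressWarnings(
      GenomicRanges::distanceToNearest(pts, region_sets[[j]],
                                       ignore.strand = TRUE))
    dmat[S4Vectors::queryHits(hit), j] <- S4Vectors::mcols(hit)$distance
  }
  lab <- rep(fallback, n)
  best <- apply(dmat, 1, which.min)
  bestd <- dmat[cbind(seq_len(n), best)]
  ok <- is.finite(bestd) & bestd <= window
  lab[ok] <- names(region_sets)[best[ok]]
  lab
}

## ---------------------------------------------------------------------------
## File dialects: BED (0-based half-open, tab-separated, no header),
## chrom.sizes (two-column TSV).
## ---------------------------------------------------------------------------

#' Read a BED3/BED6 file into a GRanges
#'
#' @param path File path. Tab-separated, no header, 0-based half-open.
#' @param label Optional set label attached to the result.
#' @return `GRanges`; columns 4 and 5, when present, become `name` and
#'   `score` metadata.
#' @export
read_bed <- function(path, label = "custom") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  gr <- GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- as.character(df[[4]])
  if (ncol(df) >= 5) S4Vectors::mcols(gr)$score <- as.numeric(df[[5]])
  gr <- GenomicRanges::sort(gr)
  attr(gr, "label") <- label
  gr
}

#' Write a GRanges as BED
#'
#' @param gr `GRanges` to write.
#' @param path Output path.
#' @param header Optional comment lines (written prefixed with `#`).
#' @export
write_bed <- function(gr, path, header = NULL) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) {
    df$name <- mc$name
    if (!is.null(mc$score)) df$score <- mc$score
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a two-column chrom.sizes file
#' @param path TSV with chromosome name and length.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' Write a chrom.sizes file
#' @param sizes Named numeric vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.numeric(sizes)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Whole-genome region set from chromosome sizes
#' @param chrom_sizes Named numeric vector.
#' @return `GRanges` covering every chromosome end to end.
#' @export
genome_regions <- function(chrom_sizes) {
  GenomicRanges::GRanges(names(chrom_sizes),
                         IRanges::IRanges(1, as.numeric(chrom_sizes)))
}
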