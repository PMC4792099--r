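#' Genomic interval utilities
#'
#' All coordinates inside the package are 0-based half-open: an interval
#' (start, end) covers bases start, start+1, ..., end-1 and has length
#' end - start. Published tab-separated files (patient CNV tables,
#' DGV-dialect control tables, syndrome catalogues) are read as 1-based
#' inclusive and converted on the way in; BED output is written 0-based
#' half-open, tables 1-based inclusive. Half-open arithmetic makes overlap
#' and intersection tests off-by-one-proof.
#'
#' @param chrom chromosome name (e.g. "1", "X"); compared as a string.
#' @param start 0-based inclusive start (bp).
#' @param end exclusive end (bp); must satisfy \code{start < end}.
#' @return \code{genomic_interval} returns a named list of class
#'   \code{"genomic_interval"}.
#' @examples
#' gi <- genomic_interval("1", 99, 200)   # printed coordinates 100..200
#' interval_length(gi)                    # 101 bp
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param x a \code{genomic_interval}
#' @export
interval_length <- function(x) x$end - x$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval %s:%s-%s (%s bp)>\n", x$chrom,
              format(x$start + 1, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(interval_length(x), scientific = FALSE)))
  invisible(x)
}

# Vectorised half-open overlap test (same chromosome assumed by the caller).
intervals_intersect <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

#' Minimal common intersection of intervals
#'
#' The intersection of a set of intervals on one chromosome is
#' (max start, min end) when that span is non-empty. This is the "minimal
#' common region" used to turn a qualified patient clique into a candidate
#' locus: the largest genomic span covered by every assigned CNV.
#'
#' @param chrom chromosome name shared by all intervals (vector allowed; all
#'   entries must be equal).
#' @param start,end numeric vectors of 0-based half-open coordinates.
#' @return a \code{genomic_interval}, or \code{NULL} when the intervals have
#'   no common base pair.
#' @examples
#' common_intersection("1", c(100, 150, 200), c(250, 300, 280))  # 200..250
#' @export
common_intersection <- function(chrom, start, end) {
  chrom <- unique(as.character(chrom))
  if (length(chrom) != 1L)
    stop("common_intersection: intervals on mixed chromosomes: ",
         paste(chrom, collapse = ", "))
  s <- max(start); e <- min(end)
  if (s >= e) return(NULL)
  genomic_interval(chrom, s, e)
}

# File coordinates (1-based inclusive) <-> internal (0-based half-open).
to_internal_start <- function(start1) start1 - 1
to_external_start <- function(start0) start0 + 1
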