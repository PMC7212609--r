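# Interval arithmetic on 0-based half-open (BED) coordinates.
# Every genomic table in the package carries `chrom`, `start`, `end` columns in
# this convention; IRanges/GenomicRanges (1-based closed) are used internally
# for overlap machinery, converting at the boundary.

#' Validate a genomic interval table
#'
#' Checks the core invariants of 0-based half-open intervals: non-empty
#' chromosome names, `start >= 0`, `end > start`.
#'
#' @param x A data frame with `chrom`, `start`, `end` columns.
#' @param what Label used in error messages.
#' @return `x` invisibly, as a tibble.
#' @export
validate_intervals <- function(x, what = "interval table") {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s lacks column(s): %s", what, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(sprintf("%s: chrom must be non-empty", what))
  }
  if (any(x$start < 0)) abort(sprintf("%s: start must be >= 0", what))
  if (any(x$end <= x$start)) abort(sprintf("%s: end must be > start", what))
  invisible(x)
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x, start = "start", end = "end", chrom = "chrom") {
  GenomicRanges::GRanges(
    seqnames = x[[chrom]],
    ranges = IRanges::IRanges(start = x[[start]] + 1L, end = x[[end]])
  )
}

granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Base-pair overlap between two interval sets, row-wise
#'
#' Computes `max(0, min(end) - max(start))` for paired rows of `a` and `b`
#' (length-1 inputs are recycled); intervals on different chromosomes overlap
#' by 0. Symmetric in its arguments.
#'
#' @param a,b Data frames with `chrom`, `start`, `end`.
#' @return Integer vector of overlap widths in bp.
#' @examples
#' overlap_bp(
#'   tibble::tibble(chrom = "chr1", start = 100, end = 200),
#'   tibble::tibble(chrom = "chr1", start = 150, end = 300)
#' )
#' @export
overlap_bp <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), ]
  if (nrow(a) != nrow(b)) abort("overlap_bp: row counts must match (or be 1)")
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  as.integer(ov * (a$chrom == b$chrom))
}

#' Merge intervals within a gap threshold
#'
#' Transitively merges intervals whose gap is `<= max_gap` bp (inclusive, so
#' `max_gap = 0` merges touching and overlapping intervals). The result is
#' sorted and disjoint; each output interval spans the min-start/max-end of
#' its members.
#'
#' @param x Data frame with `chrom`, `start`, `end`.
#' @param max_gap Maximum gap in bp that still merges (inclusive), `>= 0`.
#' @return Tibble of merged intervals sorted by chromosome and start.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  if (max_gap < 0) abort("max_gap must be >= 0")
  x <- validate_intervals(x, "merge_intervals input")
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = max_gap + 1)
  out <- granges_to_tbl(GenomicRanges::sort(gr))
  arrange(out, chrom, start)
}

# Overlap join: all pairs (i in x, j in y) on the same chromosome with >= 1 bp
# overlap; returns indices plus overlap width. Internal workhorse.
overlap_pairs <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(tibble(x_idx = integer(), y_idx = integer(), overlap = integer()))
  }
  gx <- as_granges(x); gy <- as_granges(y)
  hits <- GenomicRanges::findOverlaps(gx, gy)
  xi <- S4Vectors::queryHits(hits); yi <- S4Vectors::subjectHits(hits)
  ov <- pmin(x$end[xi], y$end[yi]) - pmax(x$start[xi], y$start[yi])
  tibble(x_idx = xi, y_idx = yi, overlap = as.integer(ov))
}

# Minimal union-find for connected-component construction.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

#' Percentage of a count ratio, rounded half-up
#'
#' `100 * numerator / denominator` rounded half-up to `decimals` places, the
#' convention used for all reported class fractions (e.g. a TSS-proximal
#' share of 1921/6748 prints as 28).
#'
#' @param numerator_count,denominator_count Non-negative counts; the
#'   denominator must be positive.
#' @param decimals Decimal places to keep.
#' @return A single numeric percentage.
#' @examples
#' class_fraction(119, 146, 1) # 81.5
#' @export
class_fraction <- function(numerator_count, denominator_count, decimals = 0) {
  if (length(denominator_count) != 1 || is.na(denominator_count) ||
      denominator_count <= 0) {
    abort("class_fraction: denominator must be a single positive count")
  }
  pct <- 100 * numerator_count / denominator_count
  floor(pct * 10^decimals + 0.5) / 10^decimals
}
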