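# Readers and writers for the plain-text formats the pipeline exchanges:
# BED (3-6 col) for peaks/sites/domains, BEDPE (7+ col, col 7 = PET count)
# for loops, and headered TSVs for TSS and expression tables. Coordinates are
# kept verbatim as 0-based half-open; use `one_based = TRUE` to convert
# 1-based inputs on read.

split_data_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) &
    !grepl("^#", lines) &
    !grepl("^(track|browser)\\b", lines)
  list(lines = lines[keep], lineno = which(keep))
}

parse_int <- function(x, path, lineno, field) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) | suppressWarnings(as.numeric(x)) != out)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: non-integer %s '%s'",
                  path, lineno[bad[1]], field, x[bad[1]]))
  }
  out
}

#' Read a BED file of peaks
#'
#' Parses a tab-separated BED file (>= 3 columns) into a peak table. Column 4
#' (name) and column 5 (score) are optional; the score is mapped to `signal`
#' (default 0). Comment, `track` and `browser` lines are skipped. Malformed
#' lines (non-integer coordinates, `end <= start`) raise an error naming the
#' offending line.
#'
#' @param path Path to a BED file.
#' @param one_based If `TRUE`, input coordinates are 1-based closed and are
#'   converted to the internal 0-based half-open convention.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `signal`.
#' @export
read_bed <- function(path, one_based = FALSE) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  dat <- split_data_lines(path)
  if (length(dat$lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), signal = double()))
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    abort(sprintf("%s: line %d: expected >= 3 tab-separated columns",
                  path, dat$lineno[which(ncols < 3)[1]]))
  }
  col <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_, character(1))
  start <- parse_int(col(2), path, dat$lineno, "start")
  end <- parse_int(col(3), path, dat$lineno, "end")
  if (one_based) start <- start - 1L
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: invalid interval [%d, %d)",
                  path, dat$lineno[bad[1]], start[bad[1]], end[bad[1]]))
  }
  name <- col(4)
  score <- suppressWarnings(as.numeric(col(5)))
  score[is.na(score)] <- 0
  if (any(score < 0)) {
    abort(sprintf("%s: line %d: negative signal", path,
                  dat$lineno[which(score < 0)[1]]))
  }
  tibble(chrom = col(1), start = start, end = end, name = name, signal = score)
}

#' Write a peak table as BED
#'
#' @param x Peak tibble (`chrom`, `start`, `end`, optional `name`, `signal`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_tibble(x)
  out <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) if_else(is.na(x$name), ".", as.character(x$name)) else ".",
    score = if ("signal" %in% names(x)) x$signal else 0
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BEDPE file of loops
#'
#' Parses a tab-separated BEDPE file with at least 7 columns
#' (`chrom1 start1 end1 chrom2 start2 end2 pet_count`). Intra-chromosomal
#' records are returned with anchors in sorted genomic order (anchor 1 left of
#' anchor 2, swapped when needed). Inter-chromosomal records are set aside in
#' the `"interchromosomal"` attribute and their count reported.
#'
#' @inheritParams read_bed
#' @return Tibble of intra-chromosomal loops with `chrom`, `start1`, `end1`,
#'   `start2`, `end2`, `pet_count`; discarded inter-chromosomal records are in
#'   `attr(, "interchromosomal")`.
#' @export
read_bedpe <- function(path, one_based = FALSE) {
  if (!file.exists(path)) abort(sprintf("BEDPE file not found: %s", path))
  dat <- split_data_lines(path)
  empty <- tibble(chrom = character(), start1 = integer(), end1 = integer(),
                  start2 = integer(), end2 = integer(), pet_count = integer())
  if (length(dat$lines) == 0) {
    attr(empty, "interchromosomal") <- empty[0, ]
    return(empty)
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 7)) {
    abort(sprintf("%s: line %d: expected >= 7 tab-separated columns",
                  path, dat$lineno[which(ncols < 7)[1]]))
  }
  col <- function(k) vapply(fields, `[[`, character(1), k)
  start1 <- parse_int(col(2), path, dat$lineno, "start1")
  end1 <- parse_int(col(3), path, dat$lineno, "end1")
  start2 <- parse_int(col(5), path, dat$lineno, "start2")
  end2 <- parse_int(col(6), path, dat$lineno, "end2")
  pet <- parse_int(col(7), path, dat$lineno, "pet_count")
  if (one_based) { start1 <- start1 - 1L; start2 <- start2 - 1L }
  bad <- which(end1 <= start1 | end2 <= start2 | start1 < 0 | start2 < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: invalid anchor interval", path, dat$lineno[bad[1]]))
  }
  if (any(pet < 1)) {
    abort(sprintf("%s: line %d: pet_count must be >= 1", path,
                  dat$lineno[which(pet < 1)[1]]))
  }
  loops <- tibble(chrom1 = col(1), start1 = start1, end1 = end1,
                  chrom2 = col(4), start2 = start2, end2 = end2,
                  pet_count = pet)
  intra <- loops$chrom1 == loops$chrom2
  inter <- loops[!intra, ]
  loops <- loops[intra, ]
  swap <- loops$start1 > loops$start2 |
    (loops$start1 == loops$start2 & loops$end1 > loops$end2)
  tmp_s <- loops$start1[swap]; tmp_e <- loops$end1[swap]
  loops$start1[swap] <- loops$start2[swap]; loops$end1[swap] <- loops$end2[swap]
  loops$start2[swap] <- tmp_s; loops$end2[swap] <- tmp_e
  out <- tibble(chrom = loops$chrom1, start1 = loops$start1, end1 = loops$end1,
                start2 = loops$start2, end2 = loops$end2,
                pet_count = loops$pet_count)
  if (nrow(inter) > 0) {
    inform(sprintf("read_bedpe: discarded %d inter-chromosomal record(s)", nrow(inter)))
  }
  attr(out, "interchromosomal") <- inter
  out
}

#' Write a loop table as BEDPE
#'
#' @param x Loop tibble (`chrom`, `start1`, `end1`, `start2`, `end2`,
#'   `pet_count`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path) {
  x <- as_tibble(x)
  out <- tibble(chrom1 = x$chrom, start1 = x$start1, end1 = x$end1,
                chrom2 = x$chrom, start2 = x$start2, end2 = x$end2,
                pet_count = x$pet_count)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `position`, `strand`
#' (`position` is the 0-based TSS coordinate).
#'
#' @param path Path to the TSV.
#' @return Tibble with one row per gene.
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) abort(sprintf("TSS table not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         gene_id = readr::col_character(),
                         chrom = readr::col_character(),
                         position = readr::col_integer(),
                         strand = readr::col_character()
                       ))
  if (any(!x$strand %in% c("+", "-"))) abort("TSS strand must be '+' or '-'")
  if (any(x$position < 0)) abort("TSS position must be >= 0")
  x
}

#' Derive TSS records from gene-body intervals
#'
#' The TSS is the `start` of a `+`-strand gene body and `end - 1` of a
#' `-`-strand gene body (0-based).
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @return TSS tibble (`gene_id`, `chrom`, `position`, `strand`).
#' @export
tss_from_genes <- function(genes) {
  genes <- validate_intervals(as_tibble(genes), "gene table")
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    position = as.integer(if_else(genes$strand == "+", genes$start, genes$end - 1L)),
    strand = genes$strand
  )
}

#' Read an expression matrix
#'
#' Tab-separated with header: a `gene_id` column plus one numeric RPKM column
#' per condition/timepoint label.
#'
#' @param path Path to the TSV.
#' @return Tibble, genes in rows.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("expression table not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"gene_id" %in% names(x)) abort("expression table needs a gene_id column")
  num <- setdiff(names(x), "gene_id")
  if (any(vapply(x[num], function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    abort("expression values must be >= 0")
  }
  x
}
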