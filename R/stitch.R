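# Stitch-domain detection: overlay fusion-factor chromatin domains on the
# CCD scaffold and find domains whose span crosses the boundary between
# adjacent CCDs, entering both deeply enough to genuinely bridge them. Such
# "stitch" domains weave neighbouring CCDs into larger stitched CCDs.

#' Detect stitch domains bridging adjacent CCDs
#'
#' A factor domain is a stitch when it overlaps at least two CCDs, each by at
#' least `min_anchor_overlap` bp; all qualifying CCDs form the bridged set
#' and must be consecutive in genomic order (asserted). Factor domains
#' overlapping at most one CCD deeply enough are labelled `INTRA` if they
#' touch any CCD at all and `INTERGENIC` otherwise.
#'
#' @param factor_domains Domain tibble for the intruding factor.
#' @param ccds Scaffold CCD tibble; must be disjoint within each chromosome.
#' @param min_anchor_overlap Minimum penetration into each bridged CCD (bp).
#'   The default 10 kb exceeds a typical anchor width, so a stitch must
#'   genuinely enter both CCDs.
#' @return One row per factor domain: its coordinates and `domain_id`, the
#'   `label` (`STITCH`/`INTRA`/`INTERGENIC`), `n_ccds_overlapped` (any bp),
#'   `n_bridged`, comma-separated `bridged_ccds` and `overlap_bp_per_ccd`,
#'   and for stitches the `stitched_start`/`stitched_end` span (union of the
#'   factor domain and its bridged CCDs).
#' @export
find_stitch_domains <- function(factor_domains, ccds, min_anchor_overlap = 10000) {
  factor_domains <- as_tibble(factor_domains)
  ccds <- arrange(as_tibble(ccds), chrom, start)
  validate_intervals(ccds, "CCD table")
  for (chr in unique(ccds$chrom)) {
    d <- ccds[ccds$chrom == chr, ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      abort("CCDs must be disjoint within a chromosome")
    }
  }
  if (!"domain_id" %in% names(ccds)) {
    ccds <- mutate(ccds, domain_id = sprintf("%s_CCD%04d", chrom,
                                             stats::ave(start, chrom, FUN = seq_along)))
  }
  ccds <- ccds |> group_by(chrom) |> mutate(._ord = row_number()) |> ungroup()
  n <- nrow(factor_domains)
  out <- tibble(
    domain_id = if ("domain_id" %in% names(factor_domains)) factor_domains$domain_id
                else sprintf("FD%04d", seq_len(n)),
    chrom = factor_domains$chrom,
    start = factor_domains$start,
    end = factor_domains$end,
    label = rep("INTERGENIC", n),
    n_ccds_overlapped = 0L,
    n_bridged = 0L,
    bridged_ccds = NA_character_,
    overlap_bp_per_ccd = NA_character_,
    stitched_start = NA_integer_,
    stitched_end = NA_integer_
  )
  if (n == 0) return(out)
  pairs <- overlap_pairs(factor_domains, ccds)
  if (nrow(pairs) > 0) {
    hit_counts <- table(factor(pairs$x_idx, levels = seq_len(n)))
    out$n_ccds_overlapped <- as.integer(hit_counts)
    out$label[out$n_ccds_overlapped > 0] <- "INTRA"
    qual <- pairs[pairs$overlap >= min_anchor_overlap, ]
    if (nrow(qual) > 0) {
      for (i in unique(qual$x_idx)) {
        q <- qual[qual$x_idx == i, ]
        q <- q[order(ccds$._ord[q$y_idx]), ]
        if (nrow(q) < 2) next
        ords <- ccds$._ord[q$y_idx]
        if (!all(diff(ords) == 1)) {
          abort(sprintf(
            "stitch assertion failed: bridged CCDs of %s are not consecutive",
            out$domain_id[i]))
        }
        out$label[i] <- "STITCH"
        out$n_bridged[i] <- nrow(q)
        out$bridged_ccds[i] <- paste(ccds$domain_id[q$y_idx], collapse = ",")
        out$overlap_bp_per_ccd[i] <- paste(q$overlap, collapse = ",")
        out$stitched_start[i] <- min(out$start[i], ccds$start[q$y_idx])
        out$stitched_end[i] <- max(out$end[i], ccds$end[q$y_idx])
      }
    }
  }
  out
}

#' Merge stitch calls into maximal stitched-CCD spans
#'
#' Stitch calls that share a bridged CCD are chained together (union-find
#' over the shared-CCD relation); each chain yields one stitched-CCD span
#' covering all member stitch spans.
#'
#' @param stitches Output of [find_stitch_domains()] (non-stitch rows are
#'   ignored).
#' @return Domain tibble of kind `STITCHED_CCD` with the member stitch ids
#'   and the number of distinct CCDs woven together.
#' @export
stitched_ccd_spans <- function(stitches) {
  st <- filter(as_tibble(stitches), label == "STITCH")
  if (nrow(st) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  domain_id = character(), kind = character(),
                  n_ccds = integer(), member_stitches = character()))
  }
  ccd_lists <- strsplit(st$bridged_ccds, ",", fixed = TRUE)
  parent <- uf_new(nrow(st))
  seen <- list()
  for (i in seq_len(nrow(st))) {
    for (ccd in ccd_lists[[i]]) {
      if (!is.null(seen[[ccd]])) parent <- uf_union(parent, seen[[ccd]], i)
      seen[[ccd]] <- i
    }
  }
  st$._comp <- uf_components(parent)
  st |>
    group_by(._comp) |>
    summarise(chrom = first(chrom),
              start = min(stitched_start),
              end = max(stitched_end),
              n_ccds = length(unique(unlist(strsplit(bridged_ccds, ",")))),
              member_stitches = paste(domain_id, collapse = ","),
              .groups = "drop") |>
    arrange(chrom, start) |>
    mutate(domain_id = sprintf("%s_SCCD%04d", chrom,
                               stats::ave(start, chrom, FUN = seq_along)),
           kind = "STITCHED_CCD") |>
    select(chrom, start, end, domain_id, kind, n_ccds, member_stitches)
}

#' Compare chromatin-contact load of stitch vs non-stitch domains
#'
#' Assigns each loop to the factor domain whose interval contains its whole
#' span, totals PETs per domain, and compares the stitch and non-stitch
#' distributions with a one-sided Wilcoxon rank-sum test (alternative:
#' stitches carry more contacts).
#'
#' @param stitch_calls Output of [find_stitch_domains()].
#' @param loops Fusion-factor loop tibble.
#' @return List with `per_domain` (domain id, label, `n_loops`,
#'   `total_pets`) and `test` (one-row tibble: group sizes, rank-sum
#'   statistic, p-value).
#' @export
stitch_contact_load <- function(stitch_calls, loops) {
  calls <- as_tibble(stitch_calls)
  loops <- as_tibble(loops)
  per <- calls |> select(domain_id, chrom, start, end, label)
  per$n_loops <- 0L
  per$total_pets <- 0L
  if (nrow(loops) > 0 && nrow(per) > 0) {
    spans <- tibble(chrom = loops$chrom, start = loops$start1, end = loops$end2)
    pairs <- overlap_pairs(per, spans)
    pairs <- pairs[spans$start[pairs$y_idx] >= per$start[pairs$x_idx] &
                     spans$end[pairs$y_idx] <= per$end[pairs$x_idx], ]
    if (nrow(pairs) > 0) {
      agg <- pairs |>
        group_by(x_idx) |>
        summarise(n_loops = n(),
                  total_pets = sum(loops$pet_count[y_idx]), .groups = "drop")
      per$n_loops[agg$x_idx] <- agg$n_loops
      per$total_pets[agg$x_idx] <- as.integer(agg$total_pets)
    }
  }
  is_stitch <- per$label == "STITCH"
  test <- tibble(n_stitch = sum(is_stitch), n_other = sum(!is_stitch),
                 statistic = NA_real_, p_value = NA_real_)
  if (test$n_stitch > 0 && test$n_other > 0) {
    wt <- suppressWarnings(wilcox.test(per$total_pets[is_stitch],
                                       per$total_pets[!is_stitch],
                                       alternative = "greater"))
    test$statistic <- unname(wt$statistic)
    test$p_value <- wt$p.value
  }
  list(per_domain = per, test = test)
}
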