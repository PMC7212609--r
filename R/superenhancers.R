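# ROSE-style super-enhancer calling from acetylation (H3K9K14ac) peaks:
# TSS-proximal peaks are excluded, survivors are stitched within 12.5 kb,
# stitched regions are ranked by aggregate signal, and the super-enhancer
# cutoff is the slope-1 tangent point of the scaled rank curve. Catalogs can
# be compared across conditions and linked to genes through RNAPII loops.

#' Stitch enhancer peaks into candidate regions
#'
#' Removes peaks whose centre lies within `tss_exclusion` bp of a TSS, then
#' merges survivors with `max_gap = stitch_distance`. Each region carries the
#' sum of its constituent peak signals.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `signal`).
#' @param tss TSS tibble.
#' @param stitch_distance Merge gap in bp (ROSE default 12.5 kb).
#' @param tss_exclusion Promoter exclusion half-window in bp (ROSE default
#'   2 kb).
#' @return Tibble of stitched regions with `region_id`, `n_constituents`,
#'   `total_signal`; the number of TSS-excluded peaks is in
#'   `attr(, "n_excluded")`.
#' @export
stitch_enhancers <- function(peaks, tss, stitch_distance = 12500,
                             tss_exclusion = 2000) {
  if (stitch_distance < 0) abort("stitch_distance must be >= 0")
  peaks <- as_tibble(peaks)
  tss <- as_tibble(tss)
  keep <- rep(TRUE, nrow(peaks))
  if (nrow(peaks) > 0 && nrow(tss) > 0) {
    centre <- floor((peaks$start + peaks$end) / 2)
    for (chr in unique(peaks$chrom)) {
      pi <- which(peaks$chrom == chr)
      tpos <- tss$position[tss$chrom == chr]
      if (length(tpos) == 0) next
      mind <- vapply(centre[pi], function(cc) min(abs(tpos - cc)), numeric(1))
      keep[pi] <- mind > tss_exclusion
    }
  }
  surv <- peaks[keep, ]
  if (nrow(surv) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  region_id = character(), n_constituents = integer(),
                  total_signal = double())
    attr(out, "n_excluded") <- sum(!keep)
    return(out)
  }
  regions <- merge_intervals(surv, max_gap = stitch_distance)
  pairs <- overlap_pairs(regions, surv)
  agg <- pairs |>
    group_by(x_idx) |>
    summarise(n_constituents = n(),
              total_signal = sum(surv$signal[y_idx]), .groups = "drop")
  regions$n_constituents <- 0L
  regions$total_signal <- 0
  regions$n_constituents[agg$x_idx] <- agg$n_constituents
  regions$total_signal[agg$x_idx] <- agg$total_signal
  regions <- mutate(regions, region_id = sprintf("%s_E%04d", chrom,
                                                 stats::ave(start, chrom, FUN = seq_along)))
  attr(regions, "n_excluded") <- sum(!keep)
  regions
}

#' Rank stitched regions and call super-enhancers
#'
#' Regions are sorted by increasing `total_signal`; rank (x) and signal (y)
#' are scaled to `[0, 1]` and the cutoff is the signal at the slope-1
#' tangent point of the curve, found discretely as the point minimising
#' `y - x` (ties broken toward the higher-signal point, i.e. fewer, more
#' conservative calls). Regions with signal strictly above the cutoff are
#' super-enhancers; a flat curve (all signals equal, slope below 1
#' everywhere) calls none.
#'
#' @param regions Output of [stitch_enhancers()] (needs >= 3 rows).
#' @return `regions` with `rank` (1 = highest signal) and `is_super`; the
#'   cutoff signal is in `attr(, "cutoff")` (`Inf` when no region
#'   qualifies).
#' @export
rank_and_cut <- function(regions) {
  regions <- as_tibble(regions)
  n <- nrow(regions)
  if (n < 3) abort("CURVE_TOO_SHORT: need >= 3 regions to place a cutoff")
  s_sorted <- sort(regions$total_signal)
  if (s_sorted[n] == s_sorted[1]) {
    cutoff <- Inf
  } else {
    x <- seq(0, 1, length.out = n)
    y <- (s_sorted - s_sorted[1]) / (s_sorted[n] - s_sorted[1])
    d <- y - x
    i_star <- max(which(d == min(d)))
    cutoff <- s_sorted[i_star]
  }
  regions$rank <- as.integer(rank(-regions$total_signal, ties.method = "first"))
  regions$is_super <- regions$total_signal > cutoff
  attr(regions, "cutoff") <- cutoff
  regions
}

#' Call super-enhancers from enhancer peaks
#'
#' Runs [stitch_enhancers()] then [rank_and_cut()] and wraps the result in a
#' catalog object with `tidy()`, `glance()` and `autoplot()` methods.
#'
#' @inheritParams stitch_enhancers
#' @param condition Optional condition label stored on the catalog.
#' @return An object of class `ls_se`.
#' @export
call_super_enhancers <- function(peaks, tss, stitch_distance = 12500,
                                 tss_exclusion = 2000, condition = NA_character_) {
  regions <- stitch_enhancers(peaks, tss, stitch_distance, tss_exclusion)
  n_excluded <- attr(regions, "n_excluded")
  regions <- rank_and_cut(regions)
  structure(list(regions = regions,
                 cutoff = attr(regions, "cutoff"),
                 condition = condition,
                 params = list(stitch_distance = stitch_distance,
                               tss_exclusion = tss_exclusion,
                               n_excluded_peaks = n_excluded)),
            class = "ls_se")
}

#' @export
print.ls_se <- function(x, ...) {
  cat(sprintf("<ls_se> %d stitched regions, %d super-enhancers (cutoff %.3g)%s\n",
              nrow(x$regions), sum(x$regions$is_super), x$cutoff,
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]")))
  invisible(x)
}

#' @rdname call_super_enhancers
#' @param x An `ls_se` object.
#' @param ... Unused.
#' @export
tidy.ls_se <- function(x, ...) as_tibble(x$regions)

#' @rdname call_super_enhancers
#' @export
glance.ls_se <- function(x, ...) {
  tibble(n_regions = nrow(x$regions),
         n_super = sum(x$regions$is_super),
         cutoff_signal = x$cutoff,
         n_excluded_peaks = x$params$n_excluded_peaks,
         condition = x$condition)
}

se_regions <- function(x) {
  if (inherits(x, "ls_se")) filter(x$regions, is_super) else as_tibble(x)
}

#' Compare super-enhancer catalogs between two conditions
#'
#' Matches SEs by reciprocal overlap (`min(ov/len_a, ov/len_b) >= threshold`,
#' best partner per SE). An SE of catalog `a` is *common* when matched and,
#' if `fold_drop` is set, its partner retains at least `1/fold_drop` of its
#' signal; matched SEs whose signal collapsed by more than `fold_drop` count
#' as lost alongside the positionally unmatched ones. Unmatched SEs of `b`
#' are gained.
#'
#' @param ses_a,ses_b SE tibbles (or `ls_se` objects; only `is_super` rows
#'   are compared).
#' @param reciprocal_overlap Matching threshold in (0, 1].
#' @param fold_drop Signal-collapse fold counting a matched SE as lost;
#'   `NULL` for purely positional matching.
#' @return List of tibbles `common`, `lost_in_b`, `gained_in_b`;
#'   `nrow(common) + nrow(lost_in_b) == nrow(a)`.
#' @export
differential_se <- function(ses_a, ses_b, reciprocal_overlap = 0.5,
                            fold_drop = 2) {
  if (reciprocal_overlap <= 0 || reciprocal_overlap > 1) {
    abort("reciprocal_overlap must be in (0, 1]")
  }
  a <- se_regions(ses_a); b <- se_regions(ses_b)
  a$._len <- a$end - a$start; b$._len <- b$end - b$start
  matched_a <- rep(FALSE, nrow(a)); partner_signal <- rep(NA_real_, nrow(a))
  matched_b <- rep(FALSE, nrow(b))
  pairs <- overlap_pairs(a, b)
  if (nrow(pairs) > 0) {
    pairs$recip <- pmin(pairs$overlap / a$._len[pairs$x_idx],
                        pairs$overlap / b$._len[pairs$y_idx])
    pairs <- pairs[pairs$recip >= reciprocal_overlap, ]
    if (nrow(pairs) > 0) {
      matched_b[unique(pairs$y_idx)] <- TRUE
      best <- pairs |> arrange(x_idx, desc(recip), y_idx) |>
        distinct(x_idx, .keep_all = TRUE)
      matched_a[best$x_idx] <- TRUE
      if ("total_signal" %in% names(b)) {
        partner_signal[best$x_idx] <- b$total_signal[best$y_idx]
      }
    }
  }
  common <- matched_a
  if (!is.null(fold_drop) && "total_signal" %in% names(a)) {
    collapsed <- matched_a & !is.na(partner_signal) &
      partner_signal < a$total_signal / fold_drop
    common <- matched_a & !collapsed
  }
  list(common = select(a[common, ], -._len),
       lost_in_b = select(a[!common, ], -._len),
       gained_in_b = select(b[!matched_b, ], -._len))
}

#' Link super-enhancers to genes through loop connectivity
#'
#' Gene `g` is linked to SE `s` when some loop has one anchor overlapping
#' `s` (>= 1 bp) and the other anchor within `window` bp of `g`'s TSS.
#' Linkage is single-hop only.
#'
#' @param ses SE tibble or `ls_se` object (only super rows are linked).
#' @param loops RNAPII loop tibble.
#' @param tss TSS tibble.
#' @param window Promoter window around the TSS in bp.
#' @return Tibble of links (`region_id`, `gene_id`, `n_loops` supporting).
#' @export
link_se_to_genes <- function(ses, loops, tss, window = 2500) {
  se <- se_regions(ses)
  loops <- as_tibble(loops); tss <- as_tibble(tss)
  empty <- tibble(region_id = character(), gene_id = character(),
                  n_loops = integer())
  if (nrow(se) == 0 || nrow(loops) == 0 || nrow(tss) == 0) return(empty)
  if (!"region_id" %in% names(se)) se$region_id <- sprintf("SE%04d", seq_len(nrow(se)))
  anchor_hits <- function(anchors) overlap_pairs(anchors, se)
  tss_hits <- function(anchors) {
    tw <- tibble(chrom = tss$chrom,
                 start = pmax(0L, tss$position - as.integer(window)),
                 end = tss$position + as.integer(window) + 1L)
    overlap_pairs(anchors, tw)
  }
  a1 <- rename(select(loops, chrom, start1, end1), start = start1, end = end1)
  a2 <- rename(select(loops, chrom, start2, end2), start = start2, end = end2)
  link_dir <- function(se_side, tss_side) {
    sh <- anchor_hits(se_side); th <- tss_hits(tss_side)
    inner_join(sh, th, by = "x_idx", suffix = c("_se", "_tss"),
               relationship = "many-to-many")
  }
  links <- bind_rows(link_dir(a1, a2), link_dir(a2, a1))
  if (nrow(links) == 0) return(empty)
  links |>
    mutate(region_id = se$region_id[y_idx_se], gene_id = tss$gene_id[y_idx_tss]) |>
    group_by(region_id, gene_id) |>
    summarise(n_loops = length(unique(x_idx)), .groups = "drop")
}

#' Flag super-enhancers overlapped by fusion-side binding
#'
#' @param ses SE tibble or `ls_se` object.
#' @param sites Classified site tibble; fusion-side means `SHARED` or
#'   `FUSION_SPECIFIC`.
#' @return SE tibble with a logical `fusion_bound` column.
#' @export
se_fusion_overlap <- function(ses, sites) {
  se <- se_regions(ses)
  sites <- filter(as_tibble(sites),
                  site_class %in% c("SHARED", "FUSION_SPECIFIC"))
  se$fusion_bound <- FALSE
  if (nrow(se) > 0 && nrow(sites) > 0) {
    se$fusion_bound[unique(overlap_pairs(se, sites)$x_idx)] <- TRUE
  }
  se
}
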