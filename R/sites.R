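# Reproducible binding-site calling and classification across the three
# ChIA-PET anchor-peak datasets: the factor (RARa) in the uninduced condition,
# the factor after induction, and the PML antibody after induction (which in
# the induced cells reports the PML-RARa fusion). A site supported by at
# least two of the three datasets is considered reliable; the support pattern
# then determines whether the locus is factor-specific, shared, or
# fusion-specific.

SITE_CLASSES <- c("FACTOR_SPECIFIC", "SHARED", "FUSION_SPECIFIC", "UNSUPPORTED")

#' Call reproducible binding sites from three peak datasets
#'
#' Merges the union of all peaks (gap `<= merge_gap` merges) and marks each
#' merged region as supported by a dataset when at least one of that
#' dataset's peaks overlaps it by >= 1 bp. Regions supported by fewer than
#' `min_support` datasets are dropped.
#'
#' @param peaks_rara_ctrl,peaks_rara_ind,peaks_pml_ind Peak tibbles
#'   (`chrom`, `start`, `end`, ...) for the factor in the control condition,
#'   the factor after induction, and PML after induction.
#' @param min_support Minimum number of supporting datasets (1-3); the
#'   default 2 keeps sites seen in at least two independent libraries.
#' @param merge_gap Gap (bp, inclusive) within which peaks merge into one
#'   candidate region.
#' @return Tibble of sites sorted by coordinate with logical support columns
#'   `rara_ctrl`, `rara_ind`, `pml_ind`, the support sum `n_support`, and a
#'   `site_id`.
#' @export
call_reproducible_sites <- function(peaks_rara_ctrl, peaks_rara_ind,
                                    peaks_pml_ind, min_support = 2,
                                    merge_gap = 0) {
  if (!min_support %in% 1:3) abort("min_support must be 1, 2 or 3")
  sets <- list(rara_ctrl = as_tibble(peaks_rara_ctrl),
               rara_ind = as_tibble(peaks_rara_ind),
               pml_ind = as_tibble(peaks_pml_ind))
  all_peaks <- bind_rows(lapply(sets, function(p) {
    if (nrow(p) == 0) tibble(chrom = character(), start = integer(), end = integer())
    else select(p, chrom, start, end)
  }))
  if (nrow(all_peaks) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  rara_ctrl = logical(), rara_ind = logical(),
                  pml_ind = logical(), n_support = integer(),
                  site_id = character()))
  }
  merged <- merge_intervals(all_peaks, max_gap = merge_gap)
  support <- lapply(sets, function(p) {
    if (nrow(p) == 0) return(rep(FALSE, nrow(merged)))
    seq_len(nrow(merged)) %in% overlap_pairs(merged, p)$x_idx
  })
  out <- merged
  out$rara_ctrl <- support$rara_ctrl
  out$rara_ind <- support$rara_ind
  out$pml_ind <- support$pml_ind
  out$n_support <- out$rara_ctrl + out$rara_ind + out$pml_ind
  out <- filter(arrange(out, chrom, start), n_support >= min_support)
  out$site_id <- sprintf("site_%05d", seq_len(nrow(out)))
  out
}

#' Classify a 3-dataset support pattern
#'
#' Vectorised pure function from the support triple to the site class:
#' (T,T,F) is `FACTOR_SPECIFIC` (seen by the factor antibody in both
#' conditions, never by PML); (T,T,T) and (T,F,T) are `SHARED` (factor
#' evidence in the control condition plus fusion evidence after induction,
#' consistent with co-occupancy or competition at the locus); (F,T,T) is
#' `FUSION_SPECIFIC` (appears only after induction); any pattern with fewer
#' than two supporting datasets is `UNSUPPORTED`.
#'
#' @param rara_ctrl,rara_ind,pml_ind Logical vectors.
#' @param tft_as_shared If `FALSE`, the (T,F,T) pattern is classed
#'   `FUSION_SPECIFIC` instead of `SHARED` (treating loss of induced factor
#'   evidence as a complete take-over by the fusion).
#' @return Character vector of site classes.
#' @export
classify_support <- function(rara_ctrl, rara_ind, pml_ind, tft_as_shared = TRUE) {
  n <- rara_ctrl + rara_ind + pml_ind
  out <- rep("UNSUPPORTED", length(n))
  out[n >= 2 & rara_ctrl & !pml_ind] <- "FACTOR_SPECIFIC"
  out[n >= 2 & !rara_ctrl & pml_ind] <- "FUSION_SPECIFIC"
  out[rara_ctrl & pml_ind] <- "SHARED"
  if (!tft_as_shared) out[rara_ctrl & !rara_ind & pml_ind] <- "FUSION_SPECIFIC"
  out
}

#' Fill in site classes from support columns
#'
#' @param sites Site tibble from [call_reproducible_sites()].
#' @inheritParams classify_support
#' @return `sites` with a `site_class` column.
#' @export
classify_sites <- function(sites, tft_as_shared = TRUE) {
  sites <- as_tibble(sites)
  mutate(sites, site_class = classify_support(rara_ctrl, rara_ind, pml_ind,
                                              tft_as_shared = tft_as_shared))
}

#' Catalog sizes implied by the site classes
#'
#' The factor-side catalog is `FACTOR_SPECIFIC + SHARED` (everything with
#' factor evidence in the control condition); the fusion-side catalog is
#' `SHARED + FUSION_SPECIFIC` (everything with PML evidence after
#' induction).
#'
#' @param sites Classified site tibble.
#' @return One-row tibble with the per-class counts and the two catalog
#'   sizes.
#' @export
catalog_sizes <- function(sites) {
  cls <- sites$site_class
  tibble(
    n_factor_specific = sum(cls == "FACTOR_SPECIFIC"),
    n_shared = sum(cls == "SHARED"),
    n_fusion_specific = sum(cls == "FUSION_SPECIFIC"),
    factor_side = sum(cls %in% c("FACTOR_SPECIFIC", "SHARED")),
    fusion_side = sum(cls %in% c("SHARED", "FUSION_SPECIFIC"))
  )
}

# distance from a point TSS to a 0-based half-open interval; 0 inside,
# otherwise base pairs to the nearest contained base.
tss_distance <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos >= end, pos - end + 1L, 0L))
}

#' Annotate sites with TSS proximity
#'
#' A site is TSS-proximal when its interval extended by `window` bp on both
#' sides contains at least one TSS (so a TSS exactly `window` bp beyond the
#' last base is proximal, one base further is distal). The nearest gene and
#' its unsigned distance are recorded.
#'
#' @param sites Site tibble.
#' @param tss TSS tibble (`gene_id`, `chrom`, `position`).
#' @param window Proximity window in bp (> 0); the default 2500 is a common
#'   promoter-window choice.
#' @return `sites` with `tss_proximal`, `nearest_gene`, `distance_to_tss`.
#' @export
annotate_tss_proximity <- function(sites, tss, window = 2500) {
  if (window <= 0) abort("window must be > 0")
  sites <- as_tibble(sites)
  tss <- as_tibble(tss)
  n <- nrow(sites)
  sites$tss_proximal <- rep(FALSE, n)
  sites$nearest_gene <- rep(NA_character_, n)
  sites$distance_to_tss <- rep(NA_integer_, n)
  if (nrow(tss) == 0) {
    warn("annotate_tss_proximity: empty TSS table; all sites marked distal")
    return(sites)
  }
  for (chr in unique(sites$chrom)) {
    si <- which(sites$chrom == chr)
    tchr <- tss[tss$chrom == chr, ]
    if (nrow(tchr) == 0) next
    d <- outer(seq_along(si), seq_len(nrow(tchr)), function(i, j) {
      tss_distance(tchr$position[j], sites$start[si][i], sites$end[si][i])
    })
    best <- max.col(-d, ties.method = "first")
    dist <- d[cbind(seq_along(si), best)]
    sites$distance_to_tss[si] <- as.integer(dist)
    sites$nearest_gene[si] <- tchr$gene_id[best]
    sites$tss_proximal[si] <- dist <= window
  }
  sites
}

#' Summarise class counts and TSS-proximal fractions
#'
#' @param sites Classified, TSS-annotated site tibble.
#' @return Tibble with one row per site class: `n`, `n_proximal`, and the
#'   proximal percentage (half-up, 0 decimals).
#' @export
site_class_summary <- function(sites) {
  sites |>
    group_by(site_class) |>
    summarise(n = n(),
              n_proximal = sum(tss_proximal, na.rm = TRUE),
              .groups = "drop") |>
    mutate(pct_proximal = purrr::map2_dbl(
      n_proximal, n, function(k, m) if (m > 0) class_fraction(k, m) else NA_real_))
}
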