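# Expression time-course analysis: fold changes on pseudocount-guarded RPKM,
# classification of genes as repressed under fusion-protein induction and
# rescued after ATRA-mediated degradation of the fusion, and selection of
# candidate direct-target genes (promoters hit by both a reduced-occupancy
# locus and a fusion-side binding site).

RESPONSE_CLASSES <- c("REPRESSED_RESCUED", "REPRESSED_ONLY", "UNCHANGED", "OTHER")

#' Baseline-over-treated fold change with pseudocount
#'
#' `(baseline + pseudocount) / (treated + pseudocount)`; values above 1 mean
#' repression under treatment.
#'
#' @param baseline_rpkm,treated_rpkm Non-negative RPKM values (vectorised).
#' @param pseudocount Guard against division by zero at silent genes
#'   (default 0.1 RPKM).
#' @return Numeric fold change(s).
#' @export
fold_change <- function(baseline_rpkm, treated_rpkm, pseudocount = 0.1) {
  if (any(baseline_rpkm < 0) || any(treated_rpkm < 0)) {
    abort("RPKM values must be >= 0")
  }
  (baseline_rpkm + pseudocount) / (treated_rpkm + pseudocount)
}

#' RPKM from raw counts
#'
#' `count * 1e9 / (length_bp * depth)`. Provided as a utility; the pipeline
#' accepts precomputed RPKM tables.
#'
#' @param count Read count(s).
#' @param length_bp Transcript length(s) in bp (> 0).
#' @param depth Mapped-read depth (> 0).
#' @return Numeric RPKM.
#' @export
rpkm <- function(count, length_bp, depth) {
  if (any(length_bp <= 0) || any(depth <= 0)) abort("length and depth must be > 0")
  count * 1e9 / (length_bp * depth)
}

#' Classify gene time courses as repressed/rescued
#'
#' A gene is *repressed* when at some induction timepoint the baseline-over-
#' timepoint fold change reaches `repression_fold` (i.e. at least a
#' `repression_fold`-fold drop). A repressed gene is *rescued* when its
#' maximum rescue-timepoint RPKM re-bounds to at least `rescue_fold` times
#' its minimum induction RPKM. Genes that are not repressed are `UNCHANGED`
#' unless they rise by `repression_fold` or more at some induction
#' timepoint, in which case they are `OTHER`.
#'
#' @param expr Expression tibble: `gene_id` plus one RPKM column per label.
#' @param baseline Name of the baseline column.
#' @param induction Names of the induction timepoint columns.
#' @param rescue Names of the rescue timepoint columns.
#' @param repression_fold Fold-down threshold (default 2).
#' @param rescue_fold Re-bound multiple of the induction minimum
#'   (default 1.5).
#' @param pseudocount Passed to [fold_change()].
#' @return Tibble: `gene_id`, `baseline_rpkm`, `min_induction_rpkm`,
#'   `max_rescue_rpkm`, `repression_foldchange`, `response_class`.
#' @export
classify_response <- function(expr, baseline, induction, rescue,
                              repression_fold = 2.0, rescue_fold = 1.5,
                              pseudocount = 0.1) {
  expr <- as_tibble(expr)
  labels <- c(baseline, induction, rescue)
  missing_labels <- setdiff(labels, names(expr))
  if (length(missing_labels) > 0) {
    abort(sprintf("expression table lacks column(s): %s",
                  paste(missing_labels, collapse = ", ")))
  }
  base <- expr[[baseline]]
  ind <- as.matrix(expr[induction])
  res <- as.matrix(expr[rescue])
  min_ind <- apply(ind, 1, min)
  max_res <- apply(res, 1, max)
  down_fold <- fold_change(base, min_ind, pseudocount)
  rise_fold <- fold_change(apply(ind, 1, max), base, pseudocount)
  repressed <- down_fold >= repression_fold
  rescued <- repressed & (max_res >= rescue_fold * min_ind)
  cls <- rep("UNCHANGED", nrow(expr))
  cls[rise_fold >= repression_fold] <- "OTHER"
  cls[repressed] <- "REPRESSED_ONLY"
  cls[rescued] <- "REPRESSED_RESCUED"
  tibble(gene_id = expr$gene_id,
         baseline_rpkm = base,
         min_induction_rpkm = min_ind,
         max_rescue_rpkm = max_res,
         repression_foldchange = down_fold,
         response_class = cls)
}

#' Summarise repression and rescue rates
#'
#' @param classified Output of [classify_response()].
#' @return One-row tibble: `n_genes`, `n_repressed` (both repressed
#'   classes), `n_rescued`, and `rescue_pct` =
#'   `class_fraction(n_rescued, n_repressed, 1)` (`NA` if nothing is
#'   repressed).
#' @export
rescue_summary <- function(classified) {
  classified <- as_tibble(classified)
  if (nrow(classified) == 0) abort("need >= 1 classified series")
  n_rep <- sum(classified$response_class %in%
                 c("REPRESSED_RESCUED", "REPRESSED_ONLY"))
  n_res <- sum(classified$response_class == "REPRESSED_RESCUED")
  tibble(n_genes = nrow(classified),
         n_repressed = n_rep,
         n_rescued = n_res,
         rescue_pct = if (n_rep > 0) class_fraction(n_res, n_rep, 1) else NA_real_)
}

#' Select candidate direct-target genes
#'
#' Genes whose promoter window (TSS +/- `window`) overlaps both a locus
#' called reduced in the occupancy analysis and a fusion-side binding site
#' (`SHARED` or `FUSION_SPECIFIC`).
#'
#' @param sites Classified site tibble (with coordinates).
#' @param records Occupancy records carrying `reduced` and either
#'   coordinates or a `site_id` joining back to `sites`.
#' @param tss TSS tibble.
#' @param window Promoter half-window in bp.
#' @return Tibble of selected genes (`gene_id`, `n_reduced_loci`,
#'   `n_fusion_sites`).
#' @export
select_target_genes <- function(sites, records, tss, window = 2500) {
  sites <- as_tibble(sites); records <- as_tibble(records); tss <- as_tibble(tss)
  if (!all(c("chrom", "start", "end") %in% names(records))) {
    records <- left_join(records, select(sites, site_id, chrom, start, end),
                         by = "site_id")
  }
  reduced <- filter(records, reduced)
  fusion <- filter(sites, site_class %in% c("SHARED", "FUSION_SPECIFIC"))
  empty <- tibble(gene_id = character(), n_reduced_loci = integer(),
                  n_fusion_sites = integer())
  if (nrow(tss) == 0 || nrow(reduced) == 0 || nrow(fusion) == 0) return(empty)
  prom <- tibble(chrom = tss$chrom,
                 start = pmax(0L, tss$position - as.integer(window)),
                 end = tss$position + as.integer(window) + 1L)
  hit_red <- overlap_pairs(prom, reduced)
  hit_fus <- overlap_pairs(prom, fusion)
  both <- intersect(unique(hit_red$x_idx), unique(hit_fus$x_idx))
  if (length(both) == 0) return(empty)
  tibble(gene_id = tss$gene_id[both],
         n_reduced_loci = as.integer(table(factor(hit_red$x_idx, levels = both))),
         n_fusion_sites = as.integer(table(factor(hit_fus$x_idx, levels = both)))) |>
    arrange(gene_id)
}
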