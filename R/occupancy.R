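# Differential protein-occupancy testing at classified anchor loci between
# two conditions. Tag counts from two unreplicated libraries are compared
# with a conditional binomial test: given the total n = c_ctrl + c_trt, the
# treated count is Binomial(n, p0) under the null of equal underlying rates,
# with p0 the treated share of sequencing depth. This is exact at low counts
# and depth-aware (the two-library Poisson comparison in disguise).

#' Depth-normalise a tag count
#'
#' Tags per million: `count * 1e6 / library_depth`.
#'
#' @param count Tag count(s), >= 0.
#' @param library_depth Library depth (> 0).
#' @return Numeric vector.
#' @export
normalize_depth <- function(count, library_depth) {
  if (any(library_depth <= 0)) abort("library_depth must be > 0")
  count * 1e6 / library_depth
}

#' Test per-site occupancy reduction between two conditions
#'
#' One-sided conditional binomial test for reduction: with
#' `n = count_control + count_treated` and
#' `p0 = depth_treated / (depth_control + depth_treated)`, the p-value is
#' `P(X <= count_treated)` for `X ~ Binomial(n, p0)`. The log2 fold change is
#' computed on depth-normalised counts with a +0.5 pseudocount on each raw
#' count. Sites with both counts zero are flagged not testable.
#'
#' @param records Tibble with `count_control` and `count_treated` columns
#'   (extra columns such as `site_id`, `site_class` are carried through).
#' @param depth_control,depth_treated Library depths (> 0).
#' @param pseudocount Pseudocount added to each raw count for the fold
#'   change only.
#' @return `records` plus `norm_control`, `norm_treated`, `log2_fold`,
#'   `p_value`, `testable`.
#' @export
test_site_reduction <- function(records, depth_control, depth_treated,
                                pseudocount = 0.5) {
  records <- as_tibble(records)
  if (any(records$count_control < 0) || any(records$count_treated < 0)) {
    abort("counts must be >= 0")
  }
  if (depth_control <= 0 || depth_treated <= 0) abort("depths must be > 0")
  n <- records$count_control + records$count_treated
  p0 <- depth_treated / (depth_control + depth_treated)
  testable <- n > 0
  p <- rep(NA_real_, nrow(records))
  p[testable] <- pbinom(records$count_treated[testable], n[testable], p0)
  mutate(records,
         norm_control = normalize_depth(count_control, depth_control),
         norm_treated = normalize_depth(count_treated, depth_treated),
         log2_fold = log2(normalize_depth(count_treated + pseudocount, depth_treated) /
                            normalize_depth(count_control + pseudocount, depth_control)),
         p_value = p,
         testable = testable)
}

#' Call significantly reduced sites with BH control
#'
#' Benjamini-Hochberg q-values across all testable records; a site is
#' `reduced` when `q_value <= alpha` and the fold change is at least
#' `min_fold` down (`log2_fold <= -log2(min_fold)`).
#'
#' @param records Output of [test_site_reduction()].
#' @param alpha FDR level.
#' @param min_fold Minimum fold reduction required alongside significance.
#' @return `records` plus `q_value` and `reduced`.
#' @export
call_reduced <- function(records, alpha = 0.05, min_fold = 2.0) {
  records <- as_tibble(records)
  if (!any(records$testable)) abort("no testable records")
  q <- rep(NA_real_, nrow(records))
  q[records$testable] <- p.adjust(records$p_value[records$testable], method = "BH")
  mutate(records,
         q_value = q,
         reduced = testable & q_value <= alpha & log2_fold <= -log2(min_fold))
}

#' Differential occupancy analysis of a two-condition count table
#'
#' Convenience wrapper running [test_site_reduction()] and [call_reduced()],
#' returning a fitted-analysis object with `tidy()`, `glance()` and
#' `autoplot()` methods.
#'
#' @inheritParams test_site_reduction
#' @inheritParams call_reduced
#' @return An object of class `ls_diffocc`.
#' @export
occupancy_analysis <- function(records, depth_control, depth_treated,
                               alpha = 0.05, min_fold = 2.0,
                               pseudocount = 0.5) {
  rec <- test_site_reduction(records, depth_control, depth_treated, pseudocount)
  rec <- call_reduced(rec, alpha = alpha, min_fold = min_fold)
  structure(list(records = rec,
                 params = list(depth_control = depth_control,
                               depth_treated = depth_treated,
                               alpha = alpha, min_fold = min_fold,
                               pseudocount = pseudocount)),
            class = "ls_diffocc")
}

#' @export
print.ls_diffocc <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ls_diffocc> %d sites (%d testable), %d reduced at q <= %g & fold >= %g\n",
    g$n_sites, g$n_tested, g$n_reduced, x$params$alpha, x$params$min_fold))
  invisible(x)
}

#' @rdname occupancy_analysis
#' @param x An `ls_diffocc` object.
#' @param ... Unused.
#' @export
tidy.ls_diffocc <- function(x, ...) x$records

#' @rdname occupancy_analysis
#' @export
glance.ls_diffocc <- function(x, ...) {
  tibble(n_sites = nrow(x$records),
         n_tested = sum(x$records$testable),
         n_reduced = sum(x$records$reduced, na.rm = TRUE),
         alpha = x$params$alpha,
         min_fold = x$params$min_fold)
}

# site classes -> the three occupancy strata reported per scatter panel:
# fusion-side loci (fusion-specific or shared), factor-only loci, the rest.
occupancy_stratum <- function(site_class) {
  dplyr::case_when(
    site_class %in% c("FUSION_SPECIFIC", "SHARED") ~ "fusion",
    site_class == "FACTOR_SPECIFIC" ~ "factor",
    TRUE ~ "other"
  )
}

#' Stratify reduction calls by site class
#'
#' Reports, for fusion-side sites (fusion-specific or shared), factor-only
#' sites, and all other loci: the number of records, the number called
#' reduced, and the reduced percentage (half-up, 0 decimals; `NA` for empty
#' strata).
#'
#' @param records Output of [call_reduced()] (or `tidy()` of an
#'   `ls_diffocc`), carrying a `site_class` column.
#' @return Tibble with one row per stratum.
#' @export
stratify_by_class <- function(records) {
  records <- as_tibble(records)
  if (!"site_class" %in% names(records)) abort("records must carry site_class")
  records |>
    mutate(stratum = factor(occupancy_stratum(site_class),
                            levels = c("fusion", "factor", "other"))) |>
    group_by(stratum, .drop = FALSE) |>
    summarise(n = n(), n_reduced = sum(reduced, na.rm = TRUE),
              .groups = "drop") |>
    mutate(pct_reduced = purrr::map2_dbl(
      n_reduced, n, function(k, m) if (m > 0) class_fraction(k, m) else NA_real_))
}
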