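# Stage orchestration: each stage reads its inputs from a run directory,
# writes its outputs plus a run manifest (command, parameter snapshot, input
# checksums, seed, package version, record counts), and never mutates its
# inputs. All stages are deterministic given the same inputs and seed.

PIPELINE_STAGES <- c("simulate", "sites", "loops", "domains", "stitch",
                     "diffocc", "se", "expression")

default_pipeline_params <- function() {
  list(
    sites = list(min_support = 2, merge_gap = 0, tss_window = 2500),
    loops = list(min_pet = 4),
    domains = list(min_loops = 2, boundary_gap = 0),
    stitch = list(min_anchor_overlap = 10000),
    diffocc = list(alpha = 0.05, min_fold = 2.0),
    se = list(stitch_distance = 12500, tss_exclusion = 2000,
              reciprocal_overlap = 0.5, fold_drop = 2, link_window = 2500),
    expression = list(repression_fold = 2.0, rescue_fold = 1.5,
                      pseudocount = 0.1, target_window = 2500)
  )
}

write_manifest <- function(stage_dir, stage, params, inputs, counts, seed) {
  manifest <- list(
    command = stage,
    params = params,
    inputs = lapply(inputs, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    counts = counts,
    seed = seed,
    tool_version = as.character(utils::packageVersion("loopstitch")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_dir <- function(outdir, stage) {
  d <- file.path(outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

need_input <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing input file: %s", path))
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write the synthetic dataset), `sites` (reproducible
#' site calling/classification/TSS annotation), `loops` (PET filtering and
#' loop classification), `domains` (CCDs and factor domains from loop
#' connectivity), `stitch` (stitch calls, stitched-CCD spans, contact
#' load), `diffocc` (differential occupancy), `se` (super-enhancer calling,
#' differential catalog, gene linkage), `expression` (repression/rescue
#' classification and target-gene selection), or `all`. Each stage writes
#' its outputs and a `manifest.json` under `<outdir>/<stage>/`. Simulated
#' inputs are read from `<outdir>/simulate/`.
#'
#' @param stage Stage name.
#' @param outdir Run directory.
#' @param config [sim_config()] object used by the `simulate` stage (its
#'   seed is recorded in every manifest).
#' @param params Nested list of per-stage parameters; defaults from the
#'   module defaults. Unknown keys raise an error.
#' @param one_based Treat BED/BEDPE inputs as 1-based on read.
#' @param verbose Emit per-stage record counts.
#' @return Invisibly, a list of the stage's main results.
#' @export
run_stage <- function(stage, outdir, config = sim_config(), params = list(),
                      one_based = FALSE, verbose = FALSE) {
  if (!stage %in% c(PIPELINE_STAGES, "all")) {
    abort(sprintf("unknown stage '%s'; valid stages: %s", stage,
                  paste(c(PIPELINE_STAGES, "all"), collapse = ", ")))
  }
  defaults <- default_pipeline_params()
  for (s in names(params)) {
    if (!s %in% names(defaults)) {
      abort(sprintf("unknown parameter group '%s'; valid groups: %s", s,
                    paste(names(defaults), collapse = ", ")))
    }
    bad <- setdiff(names(params[[s]]), names(defaults[[s]]))
    if (length(bad) > 0) {
      abort(sprintf("unknown key(s) %s in group '%s'; valid keys: %s",
                    paste(bad, collapse = ", "), s,
                    paste(names(defaults[[s]]), collapse = ", ")))
    }
    defaults[[s]][names(params[[s]])] <- params[[s]]
  }
  pp <- defaults
  if (stage == "all") {
    res <- lapply(PIPELINE_STAGES, run_stage, outdir = outdir, config = config,
                  params = params, one_based = one_based, verbose = verbose)
    names(res) <- PIPELINE_STAGES
    return(invisible(res))
  }
  sim <- file.path(outdir, "simulate")
  say <- function(fmt, ...) if (verbose) inform(sprintf(paste0("[", stage, "] ", fmt), ...))
  out <- stage_dir(outdir, stage)

  if (stage == "simulate") {
    res <- simulate_dataset(config, sim)
    write_manifest(out, stage, list(seed = config$seed), character(0),
                   list(n_files = length(list.files(sim))), config$seed)
    say("wrote %d files", length(list.files(sim)))
    return(invisible(res))
  }

  if (stage == "sites") {
    ins <- vapply(c("peaks_rara_ctrl.bed", "peaks_rara_ind.bed",
                    "peaks_pml_ind.bed", "tss.tsv"),
                  function(f) need_input(file.path(sim, f)), character(1))
    pk <- lapply(ins[1:3], read_bed, one_based = one_based)
    tss <- read_tss(ins[4])
    sites <- call_reproducible_sites(pk[[1]], pk[[2]], pk[[3]],
                                     min_support = pp$sites$min_support,
                                     merge_gap = pp$sites$merge_gap) |>
      classify_sites() |>
      annotate_tss_proximity(tss, window = pp$sites$tss_window)
    readr::write_tsv(sites, file.path(out, "sites.tsv"))
    write_bed(mutate(sites, name = site_class, signal = n_support),
              file.path(out, "sites.bed"))
    readr::write_tsv(site_class_summary(sites), file.path(out, "site_class_summary.tsv"))
    write_manifest(out, stage, pp$sites, ins,
                   list(n_peaks_in = sum(vapply(pk, nrow, integer(1))),
                        n_sites_out = nrow(sites)), config$seed)
    say("%d sites from %d peaks", nrow(sites), sum(vapply(pk, nrow, integer(1))))
    return(invisible(sites))
  }

  if (stage == "loops") {
    ins <- c(need_input(file.path(sim, "fusion_loops.bedpe")),
             need_input(file.path(outdir, "sites", "sites.tsv")))
    loops <- read_bedpe(ins[1], one_based = one_based)
    sites <- readr::read_tsv(ins[2], show_col_types = FALSE)
    hi <- filter_loops(loops, min_pet = pp$loops$min_pet)
    hi <- classify_loops(hi, sites)
    readr::write_tsv(hi, file.path(out, "loops_classified.tsv"))
    readr::write_tsv(loop_class_tally(hi), file.path(out, "loop_class_tally.tsv"))
    write_manifest(out, stage, pp$loops, ins,
                   list(n_loops_in = nrow(loops), n_loops_out = nrow(hi)),
                   config$seed)
    say("%d/%d loops pass min_pet=%d", nrow(hi), nrow(loops), pp$loops$min_pet)
    return(invisible(hi))
  }

  if (stage == "domains") {
    ins <- c(need_input(file.path(sim, "ctcf_loops.bedpe")),
             need_input(file.path(sim, "fusion_loops.bedpe")))
    ctcf <- filter_loops(read_bedpe(ins[1], one_based = one_based),
                         min_pet = pp$loops$min_pet)
    fus <- filter_loops(read_bedpe(ins[2], one_based = one_based),
                        min_pet = pp$loops$min_pet)
    ccds <- build_domains(ctcf, min_loops = pp$domains$min_loops,
                          boundary_gap = pp$domains$boundary_gap,
                          kind = "CCD", factor = "CTCF")
    fdom <- build_domains(fus, min_loops = pp$domains$min_loops,
                          boundary_gap = pp$domains$boundary_gap,
                          kind = "FACTOR_DOMAIN", factor = "fusion")
    write_bed(mutate(ccds, name = domain_id, signal = n_loops),
              file.path(out, "ccds.bed"))
    write_bed(mutate(fdom, name = domain_id, signal = n_loops),
              file.path(out, "factor_domains.bed"))
    chrom_sizes <- setNames(rep(config$chrom_length, config$n_chroms),
                            sim_chroms(config))
    summary_tbl <- bind_rows(
      mutate(domain_coverage(ccds, chrom_sizes), set = "CCD"),
      mutate(domain_coverage(fdom, chrom_sizes), set = "FACTOR_DOMAIN"))
    readr::write_tsv(summary_tbl, file.path(out, "domain_summary.tsv"))
    write_manifest(out, stage, pp$domains, ins,
                   list(n_ccds = nrow(ccds), n_factor_domains = nrow(fdom)),
                   config$seed)
    say("%d CCDs, %d factor domains", nrow(ccds), nrow(fdom))
    return(invisible(list(ccds = ccds, factor_domains = fdom)))
  }

  if (stage == "stitch") {
    ins <- c(need_input(file.path(outdir, "domains", "ccds.bed")),
             need_input(file.path(outdir, "domains", "factor_domains.bed")),
             need_input(file.path(sim, "fusion_loops.bedpe")))
    ccds <- read_bed(ins[1]) |> rename(domain_id = name)
    fdom <- read_bed(ins[2]) |> rename(domain_id = name)
    loops <- filter_loops(read_bedpe(ins[3], one_based = one_based),
                          min_pet = pp$loops$min_pet)
    calls <- find_stitch_domains(fdom, ccds,
                                 min_anchor_overlap = pp$stitch$min_anchor_overlap)
    spans <- stitched_ccd_spans(calls)
    load <- stitch_contact_load(calls, loops)
    readr::write_tsv(calls, file.path(out, "stitch_calls.tsv"))
    write_bed(mutate(spans, name = domain_id, signal = n_ccds),
              file.path(out, "stitched_ccds.bed"))
    readr::write_tsv(load$per_domain, file.path(out, "contact_load.tsv"))
    readr::write_tsv(load$test, file.path(out, "contact_load_test.tsv"))
    write_manifest(out, stage, pp$stitch, ins,
                   list(n_factor_domains = nrow(calls),
                        n_stitches = sum(calls$label == "STITCH"),
                        n_stitched_ccds = nrow(spans)), config$seed)
    say("%d stitches of %d factor domains", sum(calls$label == "STITCH"), nrow(calls))
    return(invisible(list(calls = calls, spans = spans, load = load)))
  }

  if (stage == "diffocc") {
    ins <- need_input(file.path(sim, "occupancy_counts.tsv"))
    counts <- readr::read_tsv(ins, show_col_types = FALSE)
    depths <- jsonlite::read_json(need_input(file.path(sim, "truth.json")))$occupancy$depths
    fit <- occupancy_analysis(counts,
                              depth_control = depths$control,
                              depth_treated = depths$treated,
                              alpha = pp$diffocc$alpha,
                              min_fold = pp$diffocc$min_fold)
    readr::write_tsv(tidy(fit), file.path(out, "occupancy_records.tsv"))
    readr::write_tsv(stratify_by_class(tidy(fit)),
                     file.path(out, "occupancy_strata.tsv"))
    write_manifest(out, stage, pp$diffocc, ins,
                   as.list(glance(fit)[c("n_sites", "n_tested", "n_reduced")]),
                   config$seed)
    say("%d reduced of %d sites", glance(fit)$n_reduced, glance(fit)$n_sites)
    return(invisible(fit))
  }

  if (stage == "se") {
    ins <- vapply(c("acetyl_peaks_ctrl.bed", "acetyl_peaks_ind.bed", "tss.tsv",
                    "rnapii_loops.bedpe"),
                  function(f) need_input(file.path(sim, f)), character(1))
    tss <- read_tss(ins[3])
    se_ctrl <- call_super_enhancers(read_bed(ins[1], one_based = one_based), tss,
                                    stitch_distance = pp$se$stitch_distance,
                                    tss_exclusion = pp$se$tss_exclusion,
                                    condition = "control")
    se_ind <- call_super_enhancers(read_bed(ins[2], one_based = one_based), tss,
                                   stitch_distance = pp$se$stitch_distance,
                                   tss_exclusion = pp$se$tss_exclusion,
                                   condition = "induced")
    diff <- differential_se(se_ctrl, se_ind,
                            reciprocal_overlap = pp$se$reciprocal_overlap,
                            fold_drop = pp$se$fold_drop)
    loops <- read_bedpe(ins[4], one_based = one_based)
    links <- link_se_to_genes(se_ctrl, loops, tss, window = pp$se$link_window)
    readr::write_tsv(tidy(se_ctrl), file.path(out, "se_control.tsv"))
    readr::write_tsv(tidy(se_ind), file.path(out, "se_induced.tsv"))
    venn <- tibble(set = c("common", "lost_in_induced", "gained_in_induced"),
                   n = c(nrow(diff$common), nrow(diff$lost_in_b),
                         nrow(diff$gained_in_b)))
    readr::write_tsv(venn, file.path(out, "se_differential.tsv"))
    readr::write_tsv(links, file.path(out, "se_gene_links.tsv"))
    write_manifest(out, stage, pp$se,
                   ins, list(n_se_control = sum(tidy(se_ctrl)$is_super),
                             n_se_induced = sum(tidy(se_ind)$is_super),
                             n_lost = nrow(diff$lost_in_b),
                             n_links = nrow(links)), config$seed)
    say("%d SEs control, %d induced, %d lost",
        sum(tidy(se_ctrl)$is_super), sum(tidy(se_ind)$is_super),
        nrow(diff$lost_in_b))
    return(invisible(list(control = se_ctrl, induced = se_ind,
                          differential = diff, links = links)))
  }

  if (stage == "expression") {
    ins <- c(need_input(file.path(sim, "expression.tsv")),
             need_input(file.path(outdir, "sites", "sites.tsv")),
             need_input(file.path(outdir, "diffocc", "occupancy_records.tsv")),
             need_input(file.path(sim, "tss.tsv")))
    expr <- read_expression(ins[1])
    sites <- readr::read_tsv(ins[2], show_col_types = FALSE)
    records <- readr::read_tsv(ins[3], show_col_types = FALSE)
    tss <- read_tss(ins[4])
    classified <- classify_response(expr,
                                    baseline = config$baseline_label,
                                    induction = config$induction_labels,
                                    rescue = config$rescue_labels,
                                    repression_fold = pp$expression$repression_fold,
                                    rescue_fold = pp$expression$rescue_fold,
                                    pseudocount = pp$expression$pseudocount)
    summary_tbl <- rescue_summary(classified)
    targets <- select_target_genes(sites, records, tss,
                                   window = pp$expression$target_window)
    readr::write_tsv(classified, file.path(out, "response_classes.tsv"))
    readr::write_tsv(summary_tbl, file.path(out, "rescue_summary.tsv"))
    readr::write_tsv(targets, file.path(out, "target_genes.tsv"))
    write_manifest(out, stage, pp$expression, ins,
                   list(n_genes = nrow(classified),
                        n_repressed = summary_tbl$n_repressed,
                        n_rescued = summary_tbl$n_rescued,
                        n_targets = nrow(targets)), config$seed)
    say("%d repressed, %d rescued of %d genes",
        summary_tbl$n_repressed, summary_tbl$n_rescued, nrow(classified))
    return(invisible(list(classified = classified, summary = summary_tbl,
                          targets = targets)))
  }
}

#' Run the whole pipeline on a synthetic dataset
#'
#' Equivalent to `run_stage("all", ...)`: simulates a dataset and runs
#' every analysis stage over it, writing one output directory (with
#' manifest) per stage.
#'
#' @inheritParams run_stage
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(outdir, config = sim_config(), params = list(),
                         verbose = FALSE) {
  run_stage("all", outdir = outdir, config = config, params = params,
            verbose = verbose)
}
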