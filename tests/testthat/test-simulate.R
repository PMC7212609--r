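# The generator is first-class code: these tests check its planted ground
# truth is recovered by the analysis stages and that everything is
# deterministic under a fixed seed.

small_cfg <- function(...) {
  sim_config(seed = 123, n_chroms = 1, n_ccds_per_chrom = 3,
             n_factor_domains = 3, n_stitch_domains = 1,
             n_sites_factor = 30, n_sites_shared = 30, n_sites_fusion = 30,
             n_genes = 60, n_enhancer_peaks = 60, ...)
}

test_that("generators are byte-deterministic under a fixed seed", {
  c1 <- sim_config(seed = 7, n_chroms = 1, n_genes = 50)
  c2 <- sim_config(seed = 7, n_chroms = 1, n_genes = 50)
  expect_identical(generate_scaffold(c1), generate_scaffold(c2))
  expect_identical(generate_tss(c1), generate_tss(c2))
  expect_identical(generate_expression(c1), generate_expression(c2))
  c3 <- sim_config(seed = 8, n_chroms = 1, n_genes = 50)
  expect_false(identical(generate_scaffold(c1), generate_scaffold(c3)))
})

test_that("unknown configuration keys are rejected with the valid set", {
  expect_error(sim_config(seed = 1, not_a_key = 5), "unknown config key")
})

test_that("scaffold CCDs are recovered exactly by domain construction", {
  cfg <- small_cfg()
  sc <- generate_scaffold(cfg)
  dom <- build_domains(sc$loops, min_loops = 2)
  expect_equal(nrow(dom), 3)
  expect_equal(dom$start, sc$ccds$start)
  expect_equal(dom$end, sc$ccds$end)

  # one loop per CCD cannot reach the component threshold
  cfg1 <- small_cfg(loops_per_ccd = 1)
  sc1 <- generate_scaffold(cfg1)
  expect_equal(nrow(build_domains(sc1$loops, min_loops = 2)), 0)
})

test_that("planted site classes are fully recovered without dropout", {
  cfg <- small_cfg(dropout = 0)
  sc <- generate_scaffold(cfg)
  fl <- generate_fusion_layer(cfg, sc)
  sites <- call_reproducible_sites(fl$peaks$rara_ctrl, fl$peaks$rara_ind,
                                   fl$peaks$pml_ind) |> classify_sites()
  expect_equal(nrow(sites), 90)
  truth <- dplyr::arrange(fl$sites_truth, chrom, start)
  expect_equal(sites$site_class, truth$true_class)
})

test_that("dropout on one dataset migrates classes as the support algebra predicts", {
  cfg <- sim_config(seed = 11, n_chroms = 1, n_ccds_per_chrom = 3,
                    n_factor_domains = 3, n_stitch_domains = 1,
                    n_sites_factor = 0, n_sites_shared = 300, n_sites_fusion = 0,
                    dropout = c(0, 0, 0.5))
  sc <- generate_scaffold(cfg)
  fl <- generate_fusion_layer(cfg, sc)
  sites <- call_reproducible_sites(fl$peaks$rara_ctrl, fl$peaks$rara_ind,
                                   fl$peaks$pml_ind) |> classify_sites()
  # shared (T,T,T) sites lose PML evidence half the time -> FACTOR_SPECIFIC
  n_factor <- sum(sites$site_class == "FACTOR_SPECIFIC")
  expect_lt(abs(n_factor / 300 - 0.5), 3 * sqrt(0.25 / 300))
  expect_equal(nrow(sites), 300)  # two supports always remain
})

test_that("planted stitch domains are recovered exactly from the fusion loops", {
  cfg <- sim_config(seed = 5)
  sc <- generate_scaffold(cfg)
  fl <- generate_fusion_layer(cfg, sc)
  fdom <- build_domains(fl$loops, min_loops = 2, kind = "FACTOR_DOMAIN")
  expect_equal(nrow(fdom), cfg$n_factor_domains)
  calls <- find_stitch_domains(fdom, sc$ccds, min_anchor_overlap = 1e4)
  expect_equal(sum(calls$label == "STITCH"), cfg$n_stitch_domains)
  expect_equal(sum(calls$label == "INTRA"),
               cfg$n_factor_domains - cfg$n_stitch_domains)
  # recovered stitch spans coincide with the planted ones
  planted <- dplyr::filter(fl$domains_truth, planted_kind == "STITCH")
  called <- dplyr::filter(calls, label == "STITCH")
  expect_equal(dplyr::arrange(called, chrom, start)$start, planted$start)
  # stitches carry the planted PET excess
  load <- stitch_contact_load(calls, fl$loops)
  expect_lt(load$test$p_value, 0.05)
})

test_that("occupancy generation plants the reduced subset at fusion-side sites", {
  cfg <- sim_config(seed = 9, tag_dispersion = 1e-4)
  sc <- generate_scaffold(cfg)
  fl <- generate_fusion_layer(cfg, sc)
  occ <- generate_occupancy(cfg, fl$sites_truth)
  expect_equal(length(occ$reduced_truth),
               round(0.2 * sum(fl$sites_truth$true_class %in%
                                 c("SHARED", "FUSION_SPECIFIC"))))
  fit <- occupancy_analysis(occ$counts, occ$depths["control"],
                            occ$depths["treated"])
  rec <- tidy(fit)
  # near-Poisson counts: planted 4-fold reductions detected, strata recover
  # the planted rates within binomial error
  expect_gte(mean(rec$reduced[rec$site_id %in% occ$reduced_truth]), 0.9)
  strata <- stratify_by_class(rec)
  fusion_rate <- strata$n_reduced[strata$stratum == "fusion"] /
    strata$n[strata$stratum == "fusion"]
  expect_lt(abs(fusion_rate - 0.2), 3 * sqrt(0.2 * 0.8 / 350))
  expect_lt(strata$n_reduced[strata$stratum == "factor"] /
              strata$n[strata$stratum == "factor"], 0.05)

  # a null generator stays null through BH
  cfg0 <- sim_config(seed = 10, reduced_fraction = 0, tag_dispersion = 1e-4)
  occ0 <- generate_occupancy(cfg0, fl$sites_truth)
  fit0 <- occupancy_analysis(occ0$counts, occ0$depths["control"],
                             occ0$depths["treated"])
  expect_lte(glance(fit0)$n_reduced, 3)
})

test_that("planted SE clusters are called exactly and collapse when lost", {
  cfg <- sim_config(seed = 15)
  tss <- generate_tss(cfg)
  enh <- generate_enhancer_landscape(cfg, tss)
  se_c <- call_super_enhancers(enh$peaks_control, tss)
  expect_equal(sum(tidy(se_c)$is_super), cfg$se_outlier_count)
  # called SE regions coincide with the planted cluster spans
  called <- dplyr::arrange(dplyr::filter(tidy(se_c), is_super), chrom, start)
  planted <- dplyr::arrange(enh$se_truth, chrom, start)
  expect_equal(called$start, planted$start)
  expect_equal(called$end, planted$end)

  se_i <- call_super_enhancers(enh$peaks_treated, tss)
  expect_equal(sum(tidy(se_i)$is_super),
               cfg$se_outlier_count - cfg$se_lost_count)
  diff <- differential_se(se_c, se_i)
  expect_equal(nrow(diff$lost_in_b), cfg$se_lost_count)

  # linkage truth: each cluster connects to its planted gene
  links <- link_se_to_genes(se_c, enh$rnapii_loops, tss)
  got <- dplyr::left_join(called, links,
                          by = c("region_id" = "region_id"))
  expect_setequal(paste(got$start, got$gene_id),
                  paste(planted$start, planted$linked_gene))
})

test_that("planted expression classes yield the planted rescue rate", {
  cfg <- sim_config(seed = 25, expr_noise_sdlog = 0)
  ex <- generate_expression(cfg)
  classified <- classify_response(ex$expression, baseline = "t0",
                                  induction = cfg$induction_labels,
                                  rescue = cfg$rescue_labels)
  s <- rescue_summary(classified)
  expect_equal(s$n_repressed, 146)
  expect_equal(s$n_rescued, 119)
  expect_equal(s$rescue_pct, 81.5)
  expect_setequal(classified$gene_id[classified$response_class ==
                                       "REPRESSED_RESCUED"],
                  ex$truth$rescued)

  # full planted rescue
  cfg1 <- sim_config(seed = 26, rescue_fraction = 1, expr_noise_sdlog = 0,
                     n_genes = 200)
  ex1 <- generate_expression(cfg1)
  s1 <- rescue_summary(classify_response(ex1$expression, "t0",
                                         cfg1$induction_labels,
                                         cfg1$rescue_labels))
  expect_equal(s1$rescue_pct, 100)
})
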