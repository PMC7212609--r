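# Seeded synthetic-data generator with planted ground truth for every
# pipeline stage. The generator emulates the structure of the study data on
# a toy genome: a CTCF loop scaffold forming separated contact domains,
# a fusion-factor layer of binding sites (three partially overlapping
# datasets) and chromatin domains of which a chosen number stitch adjacent
# CCDs, two-condition tag counts with a planted reduced subset at
# fusion-side sites, a hockey-stick enhancer landscape with planted
# super-enhancer clusters (some collapsing after induction), and gene time
# courses with planted repressed/rescued classes. All randomness flows from
# one root seed; identical seed and configuration give identical output.

#' Synthetic-dataset configuration
#'
#' Returns the default configuration, optionally overridden by named
#' arguments. Defaults describe a toy genome of 2 chromosomes x 20 Mb with
#' 12 CCDs per chromosome, 12 fusion-factor domains of which 5 stitch
#' adjacent CCDs, 550 binding sites (200 factor-specific, 150 shared, 200
#' fusion-specific) with a 1% per-dataset dropout, negative-binomial tag
#' counts (mean 100, size 10) with a 4-fold reduction planted at 20% of
#' fusion-side sites, 205 enhancer regions of which 5 are 100x-signal
#' super-enhancer clusters (3 collapsing after induction), and 1000 genes of
#' which 146 are repressed under induction and 119 of those rescued.
#'
#' @param seed Root seed (integer).
#' @param ... Named overrides of any configuration field.
#' @return A list of class `ls_sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome
    n_chroms = 2, chrom_length = 2e7,
    # CTCF scaffold
    n_ccds_per_chrom = 12, ccd_size_range = c(3e5, 9e5), ccd_gap_min = 5e4,
    loops_per_ccd = 6, anchor_width = 1000,
    pet_floor = 4, pet_mu = 4, pet_dispersion = 0.1,
    # fusion layer: domains
    n_factor_domains = 12, n_stitch_domains = 5,
    stitch_overlap = 5e4, factor_domain_margin = 2e4,
    loops_per_factor_domain = 4, stitch_pet_ratio = 3,
    # fusion layer: binding sites (dropout recycles to one rate per dataset)
    n_sites_factor = 200, n_sites_shared = 150, n_sites_fusion = 200,
    peak_width = 400, peak_jitter = 50, dropout = 0.01,
    # occupancy
    mean_tag_count = 100, tag_dispersion = 0.1,
    reduced_fraction = 0.2, reduction_fold = 4, library_depth = 1e7,
    # enhancer landscape
    n_enhancer_peaks = 200, se_outlier_count = 5, se_peaks_per_cluster = 5,
    se_signal_ratio = 100, se_lost_count = 3,
    enhancer_meanlog = log(20), enhancer_sdlog = 0.5, se_noise_sdlog = 0.1,
    enhancer_peak_width = 800, se_peak_spacing = 4000,
    # expression
    n_genes = 1000, repressed_fraction = 0.146, rescue_fraction = 119 / 146,
    rpkm_meanlog = log(8), rpkm_sdlog = 1, expr_noise_sdlog = 0.1,
    induction_divisors = c(1.5, 2.5, 4, 4),
    baseline_label = "t0",
    induction_labels = c("zn_4h", "zn_6h", "zn_12h", "zn_24h"),
    rescue_labels = c("atra_24h", "atra_48h")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s; valid keys: %s",
                  paste(unknown, collapse = ", "),
                  paste(names(cfg), collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$dropout >= 0, cfg$dropout <= 1,
            cfg$reduced_fraction >= 0, cfg$reduced_fraction <= 1,
            cfg$rescue_fraction >= 0, cfg$rescue_fraction <= 1)
  # independent per-stage substreams derived once from the root seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  cfg$stage_seeds <- sample.int(2^31 - 2, 8)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(cfg, class = "ls_sim_config")
}

#' @export
print.ls_sim_config <- function(x, ...) {
  cat(sprintf("<ls_sim_config> seed %d: %d x %.0f Mb, %d CCDs, %d fusion domains (%d stitches), %d sites, %d genes\n",
              x$seed, x$n_chroms, x$chrom_length / 1e6,
              x$n_chroms * x$n_ccds_per_chrom, x$n_factor_domains,
              x$n_stitch_domains,
              x$n_sites_factor + x$n_sites_shared + x$n_sites_fusion,
              x$n_genes))
  invisible(x)
}

sim_chroms <- function(config) sprintf("chr%d", seq_len(config$n_chroms))

sim_pets <- function(n, config, mu = config$pet_mu) {
  config$pet_floor + rnbinom(n, mu = mu, size = 1 / config$pet_dispersion)
}

# chained loops inside [s, e): spans [q_i, q_{i+2}) over an even grid, so
# consecutive spans overlap and their union covers the whole interval
chained_loops <- function(chrom, s, e, n_loops, config, mu = config$pet_mu) {
  aw <- config$anchor_width
  q <- round(seq(s, e, length.out = n_loops + 2))
  tibble(chrom = chrom,
         start1 = as.integer(q[seq_len(n_loops)]),
         end1 = as.integer(q[seq_len(n_loops)] + aw),
         start2 = as.integer(q[seq_len(n_loops) + 2] - aw),
         end2 = as.integer(q[seq_len(n_loops) + 2]),
         pet_count = as.integer(sim_pets(n_loops, config, mu)))
}

#' Generate the CTCF scaffold: CCDs and their loops
#'
#' Places disjoint CCDs separated by loop-free gaps of at least
#' `ccd_gap_min` bp and samples chained, overlapping loop spans inside each
#' so that every CCD is one connected component.
#'
#' @param config An [sim_config()] object.
#' @return List with `ccds` (truth domain tibble) and `loops` (CTCF loop
#'   tibble).
#' @export
generate_scaffold <- function(config) {
  set.seed(config$stage_seeds[1])
  ccds <- list(); loops <- list()
  for (chr in sim_chroms(config)) {
    n <- config$n_ccds_per_chrom
    sizes <- round(runif(n, config$ccd_size_range[1], config$ccd_size_range[2]))
    slack <- config$chrom_length - sum(sizes) - (n + 1) * config$ccd_gap_min
    if (slack < 0) abort("infeasible CCD packing: reduce counts or sizes")
    w <- runif(n + 1)
    gaps <- config$ccd_gap_min + floor(slack * w / sum(w))
    starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, sizes[-n]))
    ends <- starts + sizes
    ccds[[chr]] <- tibble(chrom = chr, start = as.integer(starts),
                          end = as.integer(ends))
    loops[[chr]] <- purrr::map2(starts, ends, function(s, e) {
      chained_loops(chr, s, e, config$loops_per_ccd, config)
    }) |> bind_rows()
  }
  ccds <- bind_rows(ccds) |>
    mutate(domain_id = sprintf("%s_CCD%04d", chrom,
                               stats::ave(start, chrom, FUN = seq_along)),
           kind = "CCD")
  list(ccds = ccds, loops = bind_rows(loops))
}

#' Generate the fusion-factor layer: sites, domains, loops
#'
#' Plants binding sites of the three classes as jittered peaks in the three
#' datasets with per-dataset dropout, and plants fusion chromatin domains:
#' `n_stitch_domains` bridging two adjacent CCDs by `stitch_overlap` bp each
#' side, the remainder strictly inside CCDs away from boundaries. Stitch
#' domains carry `stitch_pet_ratio`-fold higher PET counts.
#'
#' @param config An [sim_config()] object.
#' @param scaffold Output of [generate_scaffold()].
#' @return List with `peaks` (named list of three peak tibbles), `loops`
#'   (fusion loops), `sites_truth`, `domains_truth`.
#' @export
generate_fusion_layer <- function(config, scaffold) {
  set.seed(config$stage_seeds[2])
  ccds <- scaffold$ccds
  # --- binding sites ---------------------------------------------------
  n_sites <- c(FACTOR_SPECIFIC = config$n_sites_factor,
               SHARED = config$n_sites_shared,
               FUSION_SPECIFIC = config$n_sites_fusion)
  total <- sum(n_sites)
  chroms <- sim_chroms(config)
  per_chrom <- diff(round(seq(0, total, length.out = length(chroms) + 1)))
  pos <- purrr::map2(chroms, per_chrom, function(chr, k) {
    grid <- seq(1e4, config$chrom_length - 1e4, by = 3000)
    tibble(chrom = chr, start = as.integer(sort(sample(grid, k))))
  }) |> bind_rows()
  pos$end <- pos$start + as.integer(config$peak_width)
  pos$true_class <- sample(rep(names(n_sites), n_sites))
  pos$site_uid <- sprintf("planted_%04d", seq_len(nrow(pos)))
  pattern <- list(FACTOR_SPECIFIC = c(TRUE, TRUE, FALSE),
                  SHARED = c(TRUE, TRUE, TRUE),
                  FUSION_SPECIFIC = c(FALSE, TRUE, TRUE))
  datasets <- c("rara_ctrl", "rara_ind", "pml_ind")
  drp <- rep(config$dropout, length.out = 3)
  peaks <- lapply(seq_along(datasets), function(k) {
    present <- vapply(pos$true_class, function(cl) pattern[[cl]][k], logical(1))
    present <- present & (runif(nrow(pos)) >= drp[k])
    jit <- as.integer(round(runif(nrow(pos), -config$peak_jitter, config$peak_jitter)))
    tibble(chrom = pos$chrom,
           start = pmax(0L, pos$start + jit),
           end = pos$end + jit,
           name = pos$site_uid,
           signal = round(rlnorm(nrow(pos), log(30), 0.3), 3))[present, ]
  })
  names(peaks) <- datasets
  # --- fusion domains --------------------------------------------------
  boundaries <- ccds |>
    group_by(chrom) |>
    mutate(next_start = dplyr::lead(start), next_end = dplyr::lead(end),
           next_id = dplyr::lead(domain_id), ._ord = row_number()) |>
    ungroup() |>
    filter(!is.na(next_start))
  if (config$n_stitch_domains > nrow(boundaries)) {
    abort("more stitch domains requested than adjacent-CCD boundaries")
  }
  # non-adjacent boundary picks so no CCD is shared between two stitches
  picked <- integer(0)
  avail <- seq_len(nrow(boundaries))
  bkey <- paste(boundaries$chrom, boundaries$._ord)
  while (length(picked) < config$n_stitch_domains) {
    if (length(avail) == 0) abort("cannot place stitches without sharing CCDs")
    p <- if (length(avail) == 1) avail else sample(avail, 1)
    picked <- c(picked, p)
    drop <- abs(boundaries$._ord - boundaries$._ord[p]) <= 1 &
      boundaries$chrom == boundaries$chrom[p]
    avail <- setdiff(avail, which(drop))
  }
  st <- boundaries[sort(picked), ]
  stitch_domains <- tibble(
    chrom = st$chrom,
    start = as.integer(st$end - config$stitch_overlap),
    end = as.integer(st$next_start + config$stitch_overlap),
    planted_kind = "STITCH",
    bridged = paste(st$domain_id, st$next_id, sep = ",")
  )
  used_ccds <- unique(unlist(strsplit(stitch_domains$bridged, ",")))
  n_intra <- config$n_factor_domains - config$n_stitch_domains
  free <- filter(ccds, !domain_id %in% used_ccds)
  used <- filter(ccds, domain_id %in% used_ccds)
  if (n_intra > nrow(free) + nrow(used)) {
    abort("not enough CCDs to host the intra factor domains")
  }
  # prefer CCDs not touched by a stitch; when a bridged CCD must host an
  # intra domain, widen its margin past the stitch footprint so planted
  # domains never overlap
  n_free <- min(n_intra, nrow(free))
  host <- free[sort(sample(nrow(free), n_free)), ]
  if (n_intra > n_free) {
    host <- bind_rows(host, used[sort(sample(nrow(used), n_intra - n_free)), ])
  }
  m <- config$factor_domain_margin +
    ifelse(host$domain_id %in% used_ccds, config$stitch_overlap, 0)
  intra_w <- pmin(1.5e5, (host$end - host$start) - 2 * m - 1e4)
  if (n_intra > 0 && any(intra_w < 1e4)) {
    abort("CCDs too small to host intra factor domains at these margins")
  }
  intra_start <- host$start + m +
    floor(runif(n_intra) * ((host$end - host$start) - 2 * m - intra_w))
  intra_domains <- tibble(chrom = host$chrom,
                          start = as.integer(intra_start),
                          end = as.integer(intra_start + intra_w),
                          planted_kind = "INTRA",
                          bridged = NA_character_)
  domains_truth <- bind_rows(stitch_domains, intra_domains) |>
    arrange(chrom, start) |>
    mutate(planted_id = sprintf("planted_fd_%02d", row_number()))
  fusion_loops <- purrr::pmap(
    list(domains_truth$chrom, domains_truth$start, domains_truth$end,
         domains_truth$planted_kind),
    function(chr, s, e, kind) {
      mu <- if (kind == "STITCH") config$pet_mu * config$stitch_pet_ratio else config$pet_mu
      chained_loops(chr, s, e, config$loops_per_factor_domain, config, mu = mu)
    }) |> bind_rows()
  list(peaks = peaks, loops = fusion_loops,
       sites_truth = pos, domains_truth = domains_truth)
}

#' Generate two-condition occupancy tag counts
#'
#' Control counts are negative binomial with mean `mean_tag_count`; treated
#' counts share the rate except for a planted subset of fusion-side sites
#' (`reduced_fraction` of them) whose rate drops by `reduction_fold`.
#'
#' @param config An [sim_config()] object.
#' @param sites Site tibble carrying `site_id` and a class column
#'   (`site_class` or `true_class`).
#' @return List with `counts` (site_id, coordinates, class, two counts),
#'   `depths` (named), and `reduced_truth` (site ids).
#' @export
generate_occupancy <- function(config, sites) {
  set.seed(config$stage_seeds[3])
  sites <- as_tibble(sites)
  cls <- if ("site_class" %in% names(sites)) sites$site_class else sites$true_class
  id <- if ("site_id" %in% names(sites)) sites$site_id else sites$site_uid
  n <- nrow(sites)
  fusion_idx <- which(cls %in% c("SHARED", "FUSION_SPECIFIC"))
  n_reduced <- round(length(fusion_idx) * config$reduced_fraction)
  reduced_idx <- sort(sample(fusion_idx, n_reduced))
  size <- 1 / config$tag_dispersion
  mu_trt <- rep(config$mean_tag_count, n)
  mu_trt[reduced_idx] <- config$mean_tag_count / config$reduction_fold
  counts <- tibble(site_id = id,
                   chrom = sites$chrom, start = sites$start, end = sites$end,
                   site_class = cls,
                   count_control = rnbinom(n, mu = config$mean_tag_count, size = size),
                   count_treated = rnbinom(n, mu = mu_trt, size = size))
  list(counts = counts,
       depths = c(control = config$library_depth, treated = config$library_depth),
       reduced_truth = id[reduced_idx])
}

#' Generate the enhancer landscape and SE-linking loops
#'
#' Background acetylation peaks sit on well-separated positions with
#' lognormal signal; `se_outlier_count` planted clusters of
#' `se_peaks_per_cluster` nearby high-signal peaks (within the stitch
#' distance) form the super-enhancers at `se_signal_ratio` times the
#' background median. A second (induced) condition keeps the background and
#' collapses the first `se_lost_count` clusters to background signal. Each
#' planted cluster is connected to one distinct gene's TSS by RNAPII loops.
#'
#' @param config An [sim_config()] object.
#' @param tss TSS tibble (peaks are placed clear of the exclusion window).
#' @return List with `peaks_control`, `peaks_treated`, `rnapii_loops`, and
#'   `se_truth` (cluster spans, lost flags, linked genes).
#' @export
generate_enhancer_landscape <- function(config, tss) {
  set.seed(config$stage_seeds[4])
  chroms <- sim_chroms(config)
  half_cluster <- (config$se_peaks_per_cluster - 1) / 2 * config$se_peak_spacing
  candidates <- bind_rows(lapply(chroms, function(chr) {
    tibble(chrom = chr,
           pos = seq(1e5, config$chrom_length - 1e5, by = 5e4))
  }))
  # keep candidate centres clear of TSS exclusion windows (with margin for
  # peak width and cluster extent)
  clear <- rep(TRUE, nrow(candidates))
  margin <- 2000 + config$enhancer_peak_width + half_cluster
  for (chr in chroms) {
    ci <- which(candidates$chrom == chr)
    tpos <- tss$position[tss$chrom == chr]
    if (length(tpos) == 0) next
    mind <- vapply(candidates$pos[ci], function(p) min(abs(tpos - p)), numeric(1))
    clear[ci] <- mind > margin
  }
  candidates <- candidates[clear, ]
  need <- config$n_enhancer_peaks + config$se_outlier_count
  if (nrow(candidates) < need) abort("not enough clear positions for enhancer peaks")
  take <- candidates[sort(sample(nrow(candidates), need)), ]
  cl_idx <- sort(sample(nrow(take), config$se_outlier_count))
  clusters <- take[cl_idx, ]
  bg <- take[-cl_idx, ]
  w <- config$enhancer_peak_width
  bg_peaks <- function() {
    tibble(chrom = bg$chrom,
           start = as.integer(bg$pos - w / 2), end = as.integer(bg$pos + w / 2),
           name = sprintf("bg_%03d", seq_len(nrow(bg))),
           signal = round(rlnorm(nrow(bg), config$enhancer_meanlog,
                                 config$enhancer_sdlog), 3))
  }
  cluster_peaks <- function(lost) {
    purrr::pmap(list(clusters$chrom, clusters$pos, seq_len(nrow(clusters))),
                function(chr, p, k) {
      offs <- (seq_len(config$se_peaks_per_cluster) -
                 (config$se_peaks_per_cluster + 1) / 2) * config$se_peak_spacing
      strength <- if (lost[k]) {
        rlnorm(length(offs), config$enhancer_meanlog, config$enhancer_sdlog)
      } else {
        config$se_signal_ratio * exp(config$enhancer_meanlog) *
          rlnorm(length(offs), 0, config$se_noise_sdlog)
      }
      tibble(chrom = chr,
             start = as.integer(p + offs - w / 2),
             end = as.integer(p + offs + w / 2),
             name = sprintf("se_cluster_%02d", k),
             signal = round(strength, 3))
    }) |> bind_rows()
  }
  lost <- seq_len(nrow(clusters)) <= config$se_lost_count
  peaks_control <- bind_rows(bg_peaks(), cluster_peaks(lost = rep(FALSE, nrow(clusters))))
  peaks_treated <- bind_rows(bg_peaks(), cluster_peaks(lost = lost))
  # RNAPII loops from each cluster to a distinct gene TSS
  genes <- tss[sample(nrow(tss), nrow(clusters)), ]
  rnapii <- purrr::pmap(list(clusters$chrom, clusters$pos, seq_len(nrow(clusters))),
                        function(chr, p, k) {
    g <- genes[k, ]
    if (g$chrom != chr) {
      g <- tss[tss$chrom == chr, ][sample(sum(tss$chrom == chr), 1), ]
      genes$gene_id[k] <<- g$gene_id
    }
    a1 <- sort(c(p - 500, g$position - 500))
    tibble(chrom = chr,
           start1 = as.integer(a1[1]), end1 = as.integer(a1[1] + 1000L),
           start2 = as.integer(a1[2]), end2 = as.integer(a1[2] + 1000L),
           pet_count = as.integer(sim_pets(1, config)))
  }) |> bind_rows()
  se_truth <- tibble(chrom = clusters$chrom,
                     start = as.integer(clusters$pos - half_cluster - w / 2),
                     end = as.integer(clusters$pos + half_cluster + w / 2),
                     cluster_id = sprintf("se_cluster_%02d", seq_len(nrow(clusters))),
                     lost_after_induction = lost,
                     linked_gene = genes$gene_id)
  list(peaks_control = peaks_control, peaks_treated = peaks_treated,
       rnapii_loops = rnapii, se_truth = se_truth)
}

#' Generate a TSS annotation table
#'
#' @param config An [sim_config()] object.
#' @return TSS tibble with `n_genes` genes spread over the toy genome.
#' @export
generate_tss <- function(config) {
  set.seed(config$stage_seeds[5])
  chroms <- sim_chroms(config)
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = length(chroms) + 1)))
  out <- purrr::map2(chroms, per_chrom, function(chr, k) {
    grid <- seq(2e4, config$chrom_length - 2e4, by = 1.5e4)
    tibble(chrom = chr, position = as.integer(sort(sample(grid, k))),
           strand = sample(c("+", "-"), k, replace = TRUE))
  }) |> bind_rows()
  mutate(out, gene_id = sprintf("G%04d", row_number())) |>
    select(gene_id, chrom, position, strand)
}

#' Generate expression time courses with planted repression/rescue
#'
#' Baseline RPKM is lognormal. Planted repressed genes fall along
#' `induction_divisors` (reaching at least a 2-fold drop); of those, a
#' planted subset re-bounds at the rescue timepoints while the rest stay
#' down. All values carry multiplicative lognormal noise.
#'
#' @param config An [sim_config()] object.
#' @param tss Optional TSS tibble supplying gene ids (generated if absent).
#' @return List with `expression` (wide tibble) and `truth` (repressed and
#'   rescued gene ids).
#' @export
generate_expression <- function(config, tss = NULL) {
  set.seed(config$stage_seeds[6])
  n <- config$n_genes
  gene_id <- if (!is.null(tss)) tss$gene_id else sprintf("G%04d", seq_len(n))
  n_rep <- round(n * config$repressed_fraction)
  n_res <- round(n_rep * config$rescue_fraction)
  rep_idx <- sort(sample(n, n_rep))
  res_idx <- rep_idx[sort(sample(n_rep, n_res))]
  base <- rlnorm(n, config$rpkm_meanlog, config$rpkm_sdlog)
  # repression is planted on expressed genes only: a silent gene cannot show
  # a measurable fold-down
  base[rep_idx] <- pmax(base[rep_idx], 1)
  noise <- function(k = n) rlnorm(k, 0, config$expr_noise_sdlog)
  expr <- tibble(gene_id = gene_id)
  expr[[config$baseline_label]] <- round(base * noise(), 4)
  for (j in seq_along(config$induction_labels)) {
    v <- base * noise()
    v[rep_idx] <- base[rep_idx] / config$induction_divisors[j] * noise(n_rep)
    expr[[config$induction_labels[j]]] <- round(v, 4)
  }
  floor_div <- max(config$induction_divisors)
  for (lab in config$rescue_labels) {
    v <- base * noise()
    stay_down <- setdiff(rep_idx, res_idx)
    v[stay_down] <- base[stay_down] / floor_div * noise(length(stay_down))
    v[res_idx] <- base[res_idx] * 0.9 * noise(n_res)
    expr[[lab]] <- round(v, 4)
  }
  list(expression = expr,
       truth = list(repressed = gene_id[rep_idx], rescued = gene_id[res_idx]))
}

#' Write a complete synthetic dataset with truth file
#'
#' Runs every generator in a fixed order and writes BED/BEDPE/TSV inputs
#' plus a machine-readable `truth.json` to `outdir`. Identical seed and
#' configuration give byte-identical files.
#'
#' @param config An [sim_config()] object.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(config = sim_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  scaffold <- generate_scaffold(config)
  tss <- generate_tss(config)
  fusion <- generate_fusion_layer(config, scaffold)
  occ <- generate_occupancy(config, fusion$sites_truth)
  enh <- generate_enhancer_landscape(config, tss)
  expr <- generate_expression(config, tss)

  p <- function(f) file.path(outdir, f)
  write_bedpe(scaffold$loops, p("ctcf_loops.bedpe"))
  write_bed(scaffold$ccds, p("ccds_truth.bed"))
  write_bedpe(fusion$loops, p("fusion_loops.bedpe"))
  write_bed(fusion$peaks$rara_ctrl, p("peaks_rara_ctrl.bed"))
  write_bed(fusion$peaks$rara_ind, p("peaks_rara_ind.bed"))
  write_bed(fusion$peaks$pml_ind, p("peaks_pml_ind.bed"))
  readr::write_tsv(tss, p("tss.tsv"))
  readr::write_tsv(occ$counts, p("occupancy_counts.tsv"))
  write_bed(enh$peaks_control, p("acetyl_peaks_ctrl.bed"))
  write_bed(enh$peaks_treated, p("acetyl_peaks_ind.bed"))
  write_bedpe(enh$rnapii_loops, p("rnapii_loops.bedpe"))
  readr::write_tsv(expr$expression, p("expression.tsv"))

  truth <- list(
    config = unclass(config)[setdiff(names(config), "stage_seeds")],
    scaffold = list(n_ccds = nrow(scaffold$ccds),
                    ccds = scaffold$ccds),
    sites = fusion$sites_truth,
    domains = fusion$domains_truth,
    occupancy = list(depths = as.list(occ$depths),
                     reduced_sites = occ$reduced_truth),
    enhancers = enh$se_truth,
    expression = expr$truth
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(scaffold = scaffold, tss = tss, fusion = fusion,
                 occupancy = occ, enhancers = enh, expression = expr,
                 truth = truth))
}
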