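no_tss <- tibble::tibble(gene_id = character(), chrom = character(),
                         position = integer(), strand = character())

peak_row <- function(chrom, start, end, signal, name = NA_character_) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), name = name, signal = signal)
}

test_that("enhancer stitching merges within 12.5 kb and excludes TSS-proximal peaks", {
  pk <- dplyr::bind_rows(peak_row("chr1", 0, 1000, 5),
                         peak_row("chr1", 11000, 12000, 7))
  expect_equal(nrow(stitch_enhancers(pk, no_tss)), 1)  # 10 kb gap
  pk2 <- dplyr::bind_rows(peak_row("chr1", 0, 1000, 5),
                          peak_row("chr1", 21000, 22000, 7))
  expect_equal(nrow(stitch_enhancers(pk2, no_tss)), 2)  # 20 kb gap

  tss <- tibble::tibble(gene_id = "g", chrom = "chr1", position = 1200L,
                        strand = "+")
  st <- stitch_enhancers(pk2, tss)  # first peak centre 500, within 2 kb of TSS
  expect_equal(nrow(st), 1)
  expect_equal(attr(st, "n_excluded"), 1L)
  expect_equal(st$total_signal, 7)
})

test_that("stitching conserves surviving peak signal and matches the merge oracle", {
  for (seed in 1:10) {
    set.seed(700 + seed)
    pk <- rand_intervals(40, max_pos = 200000, max_len = 2000)
    pk$signal <- round(runif(40, 1, 30), 2)
    tss <- tibble::tibble(gene_id = sprintf("g%d", 1:8),
                          chrom = sample(c("chr1", "chr2"), 8, replace = TRUE),
                          position = sample.int(200000, 8), strand = "+")
    st <- stitch_enhancers(pk, tss, stitch_distance = 12500, tss_exclusion = 2000)
    centre <- floor((pk$start + pk$end) / 2)
    survives <- vapply(seq_len(nrow(pk)), function(i) {
      tp <- tss$position[tss$chrom == pk$chrom[i]]
      length(tp) == 0 || min(abs(tp - centre[i])) > 2000
    }, logical(1))
    expect_equal(sum(st$total_signal), sum(pk$signal[survives]))
    want <- oracle_merge(pk[survives, ], max_gap = 12500)
    expect_equal(as.data.frame(st[c("chrom", "start", "end")]),
                 as.data.frame(want[c("chrom", "start", "end")]),
                 ignore_attr = TRUE)
  }
})

test_that("the rank curve cutoff separates planted outliers and calls none on flat input", {
  flat <- tibble::tibble(chrom = "chr1", start = seq(0, 9e5, 1e5),
                         end = seq(0, 9e5, 1e5) + 1000, total_signal = rep(3, 10))
  expect_equal(sum(rank_and_cut(flat)$is_super), 0)

  hockey <- tibble::tibble(chrom = "chr1",
                           start = seq(0, by = 1e5, length.out = 100),
                           end = seq(0, by = 1e5, length.out = 100) + 1000,
                           total_signal = c(rep(1.0, 95), rep(100.0, 5)))
  rc <- rank_and_cut(hockey)
  expect_equal(sum(rc$is_super), 5)
  expect_equal(attr(rc, "cutoff"), 1.0)
  expect_true(all(rc$total_signal[rc$is_super] == 100))
  expect_setequal(rc$rank[rc$is_super], 1:5)

  expect_error(rank_and_cut(flat[1:2, ]), "CURVE_TOO_SHORT")
  # determinism
  expect_identical(rank_and_cut(hockey), rank_and_cut(hockey))
})

test_that("the cutoff point is the discrete slope-1 tangent of the scaled curve", {
  for (seed in 1:10) {
    set.seed(800 + seed)
    n <- 60
    sig <- sort(rlnorm(n, 2, 1))
    reg <- tibble::tibble(chrom = "chr1", start = seq_len(n) * 1000L,
                          end = seq_len(n) * 1000L + 500L, total_signal = sig)
    rc <- rank_and_cut(reg)
    # independent scan: the cutpoint maximises distance below the diagonal
    x <- seq(0, 1, length.out = n)
    y <- (sig - sig[1]) / (sig[n] - sig[1])
    i_star <- max(which(y - x == min(y - x)))
    expect_equal(attr(rc, "cutoff"), sig[i_star])
    # upper set: no non-SE exceeds any SE
    if (any(rc$is_super)) {
      expect_lt(max(rc$total_signal[!rc$is_super]),
                min(rc$total_signal[rc$is_super]) + 1e-12)
    }
  }
})

test_that("differential SE comparison partitions catalogs", {
  ses <- tibble::tibble(chrom = "chr1",
                        start = c(0L, 50000L), end = c(20000L, 80000L),
                        region_id = c("a1", "a2"), total_signal = c(100, 200),
                        is_super = TRUE)
  same <- differential_se(ses, ses)
  expect_equal(nrow(same$common), 2)
  expect_equal(nrow(same$lost_in_b) + nrow(same$gained_in_b), 0)

  other <- dplyr::mutate(ses, start = start + 500000L, end = end + 500000L)
  disj <- differential_se(ses, other)
  expect_equal(nrow(disj$lost_in_b), 2)
  expect_equal(nrow(disj$gained_in_b), 2)

  # positional match but collapsed signal counts as lost by default
  dimmed <- dplyr::mutate(ses, total_signal = total_signal / 10)
  dim_cmp <- differential_se(ses, dimmed)
  expect_equal(nrow(dim_cmp$common), 0)
  expect_equal(nrow(dim_cmp$lost_in_b), 2)
  expect_equal(nrow(differential_se(ses, dimmed, fold_drop = NULL)$common), 2)
})

test_that("positional SE matching equals the all-pairs reciprocal-overlap oracle", {
  for (seed in 1:15) {
    set.seed(900 + seed)
    a <- rand_intervals(12, max_pos = 60000, max_len = 8000)
    b <- rand_intervals(12, max_pos = 60000, max_len = 8000)
    a$region_id <- sprintf("a%d", 1:12); b$region_id <- sprintf("b%d", 1:12)
    got <- differential_se(a, b, reciprocal_overlap = 0.5, fold_drop = NULL)
    matched_a <- vapply(seq_len(nrow(a)), function(i) {
      any(vapply(seq_len(nrow(b)), function(j) {
        ov <- iv_overlap(a$chrom[i], a$start[i], a$end[i],
                         b$chrom[j], b$start[j], b$end[j])
        min(ov / (a$end[i] - a$start[i]), ov / (b$end[j] - b$start[j])) >= 0.5
      }, logical(1)))
    }, logical(1))
    expect_setequal(got$common$region_id, a$region_id[matched_a])
    expect_equal(nrow(got$common) + nrow(got$lost_in_b), nrow(a))
  }
})

test_that("SE-gene linkage requires one anchor on the SE and one at a promoter", {
  ses <- tibble::tibble(chrom = "chr1", start = 0L, end = 20000L,
                        region_id = "se1", total_signal = 50, is_super = TRUE)
  tss <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                        position = c(100000L, 500000L), strand = "+")
  loops <- tibble::tibble(chrom = "chr1",
                          start1 = c(5000L, 5000L), end1 = c(6000L, 6000L),
                          start2 = c(99500L, 300000L), end2 = c(100500L, 301000L),
                          pet_count = c(5L, 5L))
  links <- link_se_to_genes(ses, loops, tss, window = 2500)
  expect_equal(nrow(links), 1)
  expect_equal(links$gene_id, "gA")  # second loop touches the SE but no promoter
})

test_that("SE-gene links match the brute-force triple loop on random input", {
  for (seed in 1:15) {
    set.seed(1000 + seed)
    ses <- rand_intervals(6, max_pos = 50000, max_len = 6000)
    ses$region_id <- sprintf("se%d", 1:6)
    ses$is_super <- TRUE
    loops <- rand_loops(20, max_pos = 50000)
    tss <- tibble::tibble(gene_id = sprintf("g%02d", 1:8),
                          chrom = sample(c("chr1", "chr2"), 8, replace = TRUE),
                          position = sample.int(50000, 8), strand = "+")
    w <- sample(c(500, 2500), 1)
    got <- link_se_to_genes(ses, loops, tss, window = w)
    got_keys <- sort(paste(match(got$region_id, ses$region_id),
                           match(got$gene_id, tss$gene_id), sep = ":"))
    expect_equal(got_keys, oracle_se_links(ses, loops, tss, w))
  }
})

test_that("fusion-site overlap flags SEs touched by fusion-side binding", {
  ses <- tibble::tibble(chrom = "chr1", start = c(0L, 50000L),
                        end = c(20000L, 70000L), region_id = c("s1", "s2"),
                        total_signal = 10, is_super = TRUE)
  sites <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1400L,
                          site_class = "FUSION_SPECIFIC")
  got <- se_fusion_overlap(ses, sites)
  expect_equal(got$fusion_bound, c(TRUE, FALSE))
  none <- se_fusion_overlap(ses, sites[0, ])
  expect_false(any(none$fusion_bound))
  # factor-only sites never flag
  factor_only <- dplyr::mutate(sites, site_class = "FACTOR_SPECIFIC")
  expect_false(any(se_fusion_overlap(ses, factor_only)$fusion_bound))
})
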