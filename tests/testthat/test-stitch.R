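make_ccds <- function(starts, ends, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(ends),
                 domain_id = sprintf("%s_CCD%04d", chrom, seq_along(starts)))
}

test_that("stitch calls distinguish bridging, intra and intergenic domains", {
  ccds <- make_ccds(c(0, 1.2e6), c(1e6, 2e6))
  fd <- tibble::tibble(chrom = "chr1",
                       start = c(2e5, 9.5e5, 1.05e6),
                       end = c(4e5, 1.25e6, 1.15e6),
                       domain_id = c("fd1", "fd2", "fd3"))
  got <- find_stitch_domains(fd, ccds, min_anchor_overlap = 1e4)
  expect_equal(got$label, c("INTRA", "STITCH", "INTERGENIC"))
  expect_equal(got$n_bridged[2], 2L)
  expect_equal(got$overlap_bp_per_ccd[2], "50000,50000")
  expect_equal(got$stitched_start[2], 0L)
  expect_equal(got$stitched_end[2], 2e6)

  # overlapping CCDs are rejected
  bad <- make_ccds(c(0, 5e5), c(1e6, 2e6))
  expect_error(find_stitch_domains(fd, bad), "disjoint")
})

test_that("a deep overlap into only one CCD is not a stitch", {
  ccds <- make_ccds(c(0, 1.2e6), c(1e6, 2e6))
  fd <- tibble::tibble(chrom = "chr1", start = 9.5e5, end = 1.205e6,
                       domain_id = "fd")
  got <- find_stitch_domains(fd, ccds, min_anchor_overlap = 1e4)
  expect_equal(got$label, "INTRA")  # 50 kb into CCD1 but only 5 kb into CCD2
})

test_that("stitch calls match the all-pairs overlap oracle on random domains", {
  for (seed in 1:20) {
    set.seed(500 + seed)
    starts <- sort(sample.int(55, 10)) * 2000L
    ccds <- make_ccds(starts, starts + 1500L)
    fd <- rand_intervals(30, chroms = "chr1", max_pos = 110000, max_len = 5000)
    got <- find_stitch_domains(fd, ccds, min_anchor_overlap = 1)
    want <- oracle_stitch(fd, ccds, min_ov = 1)
    expect_equal(got$label, want)
  }
})

test_that("bridged CCDs are consecutive in genomic order", {
  set.seed(9)
  starts <- seq(0, 9e5, by = 1e5)
  ccds <- make_ccds(starts, starts + 8e4)
  fd <- rand_intervals(25, chroms = "chr1", max_pos = 9e5, max_len = 4e5)
  got <- find_stitch_domains(fd, ccds, min_anchor_overlap = 1e3)
  for (b in got$bridged_ccds[got$label == "STITCH"]) {
    ids <- as.integer(sub(".*CCD", "", strsplit(b, ",")[[1]]))
    expect_equal(ids, seq(min(ids), max(ids)))
  }
  # a middle CCD too small to reach the overlap threshold breaks the
  # consecutive-bridging assertion
  tiny_mid <- make_ccds(c(0, 1.1e6, 1.2e6), c(1e6, 1.105e6, 2.2e6))
  wide <- tibble::tibble(chrom = "chr1", start = 9e5, end = 1.4e6,
                         domain_id = "fd")
  expect_error(find_stitch_domains(wide, tiny_mid, min_anchor_overlap = 1e4),
               "consecutive")
})

test_that("stitched-CCD spans merge stitches sharing a CCD", {
  ccds <- make_ccds(c(0, 1.2e6, 2.4e6), c(1e6, 2.2e6, 3.4e6))
  fd <- tibble::tibble(chrom = "chr1",
                       start = c(9.5e5, 2.15e6),
                       end = c(1.25e6, 2.45e6),
                       domain_id = c("fd1", "fd2"))
  st <- find_stitch_domains(fd, ccds, min_anchor_overlap = 1e4)
  sp <- stitched_ccd_spans(st)
  expect_equal(nrow(sp), 1)  # chained through the shared middle CCD
  expect_equal(c(sp$start, sp$end), c(0, 3.4e6))
  expect_equal(sp$n_ccds, 3L)

  solo <- stitched_ccd_spans(st[1, ])
  expect_equal(c(solo$start, solo$end), c(0, 2.2e6))
})

test_that("stitched spans equal an independent shared-CCD closure on random stitches", {
  for (seed in 1:10) {
    set.seed(600 + seed)
    n_ccd <- 12
    starts <- seq(0, by = 1.1e6, length.out = n_ccd)
    ccds <- make_ccds(starts, starts + 1e6)
    k <- sample(3:6, 1)
    bnd <- sort(sample(n_ccd - 1, k))
    fd <- tibble::tibble(chrom = "chr1",
                         start = as.integer(ccds$end[bnd] - 5e4),
                         end = as.integer(ccds$start[bnd + 1] + 5e4),
                         domain_id = sprintf("fd%d", seq_len(k)))
    st <- find_stitch_domains(fd, ccds, min_anchor_overlap = 1e4)
    sp <- stitched_ccd_spans(st)
    # closure oracle: boundaries i and j chain iff consecutive picks share a CCD
    groups <- cumsum(c(1, diff(bnd) > 1))
    expect_equal(nrow(sp), length(unique(groups)))
    for (g in unique(groups)) {
      b <- bnd[groups == g]
      expect_true(any(sp$start == ccds$start[min(b)] &
                        sp$end == ccds$end[max(b) + 1]))
    }
  }
})

test_that("contact load totals PETs per domain and detects planted excess", {
  calls <- tibble::tibble(domain_id = c("a", "b"), chrom = "chr1",
                          start = c(0L, 5000L), end = c(2000L, 8000L),
                          label = c("STITCH", "INTRA"))
  loops <- tibble::tibble(chrom = "chr1",
                          start1 = c(100L, 500L, 5100L), end1 = c(200L, 600L, 5200L),
                          start2 = c(1500L, 1800L, 9000L), end2 = c(1600L, 1900L, 9100L),
                          pet_count = c(4L, 6L, 5L))
  load <- stitch_contact_load(calls, loops)
  expect_equal(load$per_domain$total_pets, c(10L, 0L))  # third loop leaves domain b

  # planted 3x PET excess in stitches is detected at n = 20 per group
  set.seed(77)
  n <- 20
  starts <- seq(0, by = 2e4, length.out = 2 * n)
  calls2 <- tibble::tibble(domain_id = sprintf("d%02d", seq_len(2 * n)),
                           chrom = "chr1", start = as.integer(starts),
                           end = as.integer(starts + 1.5e4),
                           label = rep(c("STITCH", "INTRA"), each = n))
  mu <- ifelse(calls2$label == "STITCH", 30, 10)
  loops2 <- tibble::tibble(chrom = "chr1",
                           start1 = calls2$start + 100L, end1 = calls2$start + 300L,
                           start2 = calls2$end - 300L, end2 = calls2$end - 100L,
                           pet_count = rpois(2 * n, mu) + 1L)
  load2 <- stitch_contact_load(calls2, loops2)
  expect_lt(load2$test$p_value, 0.05)
})
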