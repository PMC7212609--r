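# Brute-force oracles and random-instance generators used across the suite.
# Every oracle is an independent O(n^2)/O(n^3) re-derivation of the result,
# sharing no code path with the implementation it checks.

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                           max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE)
  )
}

rand_loops <- function(n, chroms = c("chr1", "chr2"), max_pos = 20000,
                       anchor = 200) {
  a <- sample.int(max_pos, n, replace = TRUE) - 1L
  gap <- sample.int(max_pos / 2, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start1 = a, end1 = a + anchor,
    start2 = a + gap, end2 = a + gap + anchor,
    pet_count = sample.int(12, n, replace = TRUE)
  )
}

# transitive-closure interval merge: repeatedly fuse any pair whose gap is
# <= max_gap until no pair fuses
oracle_merge <- function(x, max_gap = 0) {
  rows <- lapply(seq_len(nrow(x)), function(i) x[i, c("chrom", "start", "end")])
  repeat {
    fused <- FALSE
    for (i in seq_along(rows)) {
      if (fused) break
      for (j in seq_along(rows)) {
        if (i >= j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom == b$chrom &&
            max(a$start, b$start) - min(a$end, b$end) <= max_gap) {
          rows[[i]] <- tibble::tibble(chrom = a$chrom,
                                      start = min(a$start, b$start),
                                      end = max(a$end, b$end))
          rows[[j]] <- NULL
          fused <- TRUE
          break
        }
      }
    }
    if (!fused) break
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, chrom, start)
}

iv_overlap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0L)
  max(0L, min(e1, e2) - max(s1, s2))
}

# enumerate merged regions, then re-test each against every peak of every
# dataset for >= 1 bp overlap
oracle_sites <- function(pk_a, pk_b, pk_c, min_support = 2, merge_gap = 0) {
  all <- dplyr::bind_rows(pk_a[c("chrom", "start", "end")],
                          pk_b[c("chrom", "start", "end")],
                          pk_c[c("chrom", "start", "end")])
  merged <- oracle_merge(all, merge_gap)
  sup <- function(region, peaks) {
    any(vapply(seq_len(nrow(peaks)), function(j) {
      iv_overlap(region$chrom, region$start, region$end,
                 peaks$chrom[j], peaks$start[j], peaks$end[j]) >= 1
    }, logical(1)))
  }
  merged$rara_ctrl <- vapply(seq_len(nrow(merged)),
                             function(i) sup(merged[i, ], pk_a), logical(1))
  merged$rara_ind <- vapply(seq_len(nrow(merged)),
                            function(i) sup(merged[i, ], pk_b), logical(1))
  merged$pml_ind <- vapply(seq_len(nrow(merged)),
                           function(i) sup(merged[i, ], pk_c), logical(1))
  merged$n_support <- merged$rara_ctrl + merged$rara_ind + merged$pml_ind
  merged[merged$n_support >= min_support, ]
}

# connected components over the loop-span overlap graph by repeated
# label propagation (O(n^3) worst case)
oracle_domains <- function(loops, min_loops = 2, boundary_gap = 0) {
  n <- nrow(loops)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || comp[i] == comp[j]) next
      ov <- iv_overlap(loops$chrom[i], loops$start1[i], loops$end2[i],
                       loops$chrom[j], loops$start1[j], loops$end2[j])
      if (ov > boundary_gap) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  doms <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    if (length(idx) < min_loops) return(NULL)
    tibble::tibble(chrom = loops$chrom[idx[1]],
                   start = min(loops$start1[idx]),
                   end = max(loops$end2[idx]),
                   n_loops = length(idx),
                   total_pets = sum(loops$pet_count[idx]))
  })
  dplyr::arrange(dplyr::bind_rows(doms), chrom, start)
}

# all-pairs stitch classification
oracle_stitch <- function(fd, ccds, min_ov) {
  vapply(seq_len(nrow(fd)), function(i) {
    ovs <- vapply(seq_len(nrow(ccds)), function(j) {
      iv_overlap(fd$chrom[i], fd$start[i], fd$end[i],
                 ccds$chrom[j], ccds$start[j], ccds$end[j])
    }, numeric(1))
    if (sum(ovs >= min_ov) >= 2) "STITCH"
    else if (any(ovs >= 1)) "INTRA"
    else "INTERGENIC"
  }, character(1))
}

# exact lower binomial tail by direct summation on log scale
oracle_binom_tail <- function(k, n, p) {
  i <- 0:k
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# triple loop over (SE, loop, gene)
oracle_se_links <- function(ses, loops, tss, window) {
  out <- list()
  for (s in seq_len(nrow(ses))) for (l in seq_len(nrow(loops))) {
    for (g in seq_len(nrow(tss))) {
      if (tss$chrom[g] != loops$chrom[l]) next
      near_tss <- function(st, en) {
        d <- if (tss$position[g] < st) st - tss$position[g]
        else if (tss$position[g] >= en) tss$position[g] - en + 1
        else 0
        d <= window
      }
      on_se <- function(st, en) {
        iv_overlap(ses$chrom[s], ses$start[s], ses$end[s],
                   loops$chrom[l], st, en) >= 1
      }
      hit <- (on_se(loops$start1[l], loops$end1[l]) &&
                near_tss(loops$start2[l], loops$end2[l])) ||
        (on_se(loops$start2[l], loops$end2[l]) &&
           near_tss(loops$start1[l], loops$end1[l]))
      if (hit) out[[length(out) + 1]] <- c(s, g)
    }
  }
  if (length(out) == 0) return(character(0))
  sort(unique(vapply(out, function(p) paste(p, collapse = ":"), character(1))))
}
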