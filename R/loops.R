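# Loop filtering, loop classification by anchor site class, and contact-
# domain construction from loop-span connectivity. A domain is the genomic
# span of a connected component of loops, where two loops are connected when
# their spans (anchor-start to anchor-end footprints) overlap; applied to
# CTCF loop clusters this yields CTCF contact domains (CCDs), and applied to
# the fusion-factor loops it yields the fusion chromatin domains overlaid on
# that scaffold.

CLASS_PRIORITY <- c(FUSION_SPECIFIC = 4, SHARED = 3, FACTOR_SPECIFIC = 2,
                    UNSUPPORTED = 1, NONE = 0)

#' Keep loops with at least `min_pet` supporting tags
#'
#' @param loops Loop tibble with `pet_count`.
#' @param min_pet Minimum PET count (>= 1).
#' @return Filtered tibble, input order preserved.
#' @export
filter_loops <- function(loops, min_pet = 4) {
  if (min_pet < 1) abort("min_pet must be >= 1")
  filter(as_tibble(loops), pet_count >= min_pet)
}

#' Extend both anchors of each loop
#'
#' Convenience approximation of anchor-extension clustering: pads each anchor
#' by `ext` bp on both sides (clipped at 0).
#'
#' @param loops Loop tibble.
#' @param ext Extension in bp.
#' @return Loop tibble with padded anchors.
#' @export
extend_anchors <- function(loops, ext = 250) {
  mutate(as_tibble(loops),
         start1 = pmax(0L, start1 - as.integer(ext)),
         end1 = end1 + as.integer(ext),
         start2 = pmax(0L, start2 - as.integer(ext)),
         end2 = end2 + as.integer(ext))
}

# class of the site under each anchor: largest overlap wins, ties go to the
# higher-priority class (fusion > shared > factor), then to the first site.
anchor_class <- function(anchors, sites) {
  cls <- rep("NONE", nrow(anchors))
  if (nrow(sites) == 0 || nrow(anchors) == 0) return(cls)
  pairs <- overlap_pairs(anchors, sites)
  if (nrow(pairs) == 0) return(cls)
  pairs$class <- sites$site_class[pairs$y_idx]
  pairs$prio <- CLASS_PRIORITY[pairs$class]
  best <- pairs |>
    arrange(x_idx, desc(overlap), desc(prio), y_idx) |>
    distinct(x_idx, .keep_all = TRUE)
  cls[best$x_idx] <- best$class
  cls
}

#' Classify loops by the site classes at their anchors
#'
#' Each anchor takes the class of the binding site it overlaps by >= 1 bp
#' (largest overlap wins; ties resolved toward the higher-priority class:
#' fusion-specific > shared > factor-specific). Anchors touching no site get
#' `NONE`. The loop class is the unordered pair, reported with the higher-
#' priority class first.
#'
#' @param loops Loop tibble.
#' @param sites Classified site tibble.
#' @return `loops` with `anchor1_class`, `anchor2_class`, `loop_class`.
#' @export
classify_loops <- function(loops, sites) {
  loops <- as_tibble(loops)
  sites <- as_tibble(sites)
  if (!"site_class" %in% names(sites)) abort("sites must be classified first")
  a1 <- anchor_class(rename(loops, start = start1, end = end1), sites)
  a2 <- anchor_class(rename(loops, start = start2, end = end2), sites)
  hi <- if_else(CLASS_PRIORITY[a1] >= CLASS_PRIORITY[a2], a1, a2)
  lo <- if_else(CLASS_PRIORITY[a1] >= CLASS_PRIORITY[a2], a2, a1)
  mutate(loops, anchor1_class = a1, anchor2_class = a2,
         loop_class = paste(hi, lo, sep = "|"))
}

#' Tally loops per unordered anchor-class pair
#'
#' @param loops Classified loop tibble.
#' @return Tibble of `loop_class` counts, descending.
#' @export
loop_class_tally <- function(loops) {
  count(as_tibble(loops), loop_class, sort = TRUE)
}

#' Build contact domains from loop-span connectivity
#'
#' Treats each loop's genomic span `[start1, end2)` as a node and connects
#' two loops when their spans overlap by more than `boundary_gap` bp.
#' Each connected component with at least `min_loops` loops becomes one
#' domain spanning the min-start/max-end of its member spans; smaller
#' components are set aside as singleton loop records in the
#' `"singletons"` attribute. With `boundary_gap = 0`, domains of one factor
#' are provably disjoint (an overlap between two component spans would imply
#' an edge between them), and this is asserted.
#'
#' @param loops Intra-chromosomal loop tibble.
#' @param min_loops Minimum component size for a domain.
#' @param boundary_gap Spans must overlap by more than this many bp to be
#'   connected.
#' @param kind Domain kind label (`"CCD"`, `"FACTOR_DOMAIN"`, ...).
#' @param factor Optional factor name recorded on each domain.
#' @return Domain tibble (`chrom`, `start`, `end`, `domain_id`, `n_loops`,
#'   `total_pets`, `kind`, `factor`), sorted by coordinate.
#' @export
build_domains <- function(loops, min_loops = 2, boundary_gap = 0,
                          kind = "CCD", factor = NA_character_) {
  loops <- as_tibble(loops)
  if (nrow(loops) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  domain_id = character(), n_loops = integer(),
                  total_pets = integer(), kind = character(), factor = character())
    attr(out, "singletons") <- loops
    return(out)
  }
  spans <- tibble(chrom = loops$chrom, start = loops$start1, end = loops$end2)
  validate_intervals(spans, "loop spans")
  comp <- integer(nrow(loops))
  offset <- 0L
  for (chr in unique(spans$chrom)) {
    idx <- which(spans$chrom == chr)
    s <- spans$start[idx]; e <- spans$end[idx]
    ord <- order(s, e)
    parent <- uf_new(length(idx))
    # Sweep in start order keeping open components with their running max
    # end. For sorted i <= j, spans overlap by > gap iff
    # min(e_i, e_j) - s_j > gap, i.e. both e_i - s_j > gap and j's own width
    # exceeds gap; a component connects to j iff its max end does.
    active <- integer(0)
    active_end <- numeric(0)
    for (j in ord) {
      joins <- active_end - s[j] > boundary_gap
      if (e[j] - s[j] > boundary_gap && any(joins)) {
        for (a in active[joins]) parent <- uf_union(parent, a, j)
        active <- c(active[!joins], j)
        active_end <- c(active_end[!joins], max(e[j], active_end[joins]))
      } else {
        # components whose max end is within gap of s_j can never connect
        # to any later (larger-start) span either
        still <- active_end - s[j] > boundary_gap
        active <- c(active[still], j)
        active_end <- c(active_end[still], e[j])
      }
    }
    cc <- uf_components(parent)
    comp[idx] <- cc + offset
    offset <- offset + max(cc)
  }
  loops$._comp <- comp
  agg <- loops |>
    group_by(._comp) |>
    summarise(chrom = first(chrom), start = min(start1), end = max(end2),
              n_loops = n(), total_pets = sum(pet_count), .groups = "drop")
  domains <- agg |>
    filter(n_loops >= min_loops) |>
    arrange(chrom, start) |>
    mutate(domain_id = sprintf("%s_%s%04d", chrom, substr(kind, 1, 1), row_number()),
           kind = kind, factor = factor) |>
    select(chrom, start, end, domain_id, n_loops, total_pets, kind, factor)
  singles <- loops |>
    filter(!._comp %in% agg$._comp[agg$n_loops >= min_loops]) |>
    select(-._comp)
  if (boundary_gap == 0 && nrow(domains) > 1) {
    by_chr <- split(domains, domains$chrom)
    ok <- all(vapply(by_chr, function(d) {
      d <- arrange(d, start)
      nrow(d) < 2 || all(d$start[-1] >= d$end[-nrow(d)])
    }, logical(1)))
    if (!ok) abort("internal error: overlapping domains from distinct components")
  }
  attr(domains, "singletons") <- singles
  domains
}

#' Genome coverage and size statistics of a domain set
#'
#' @param domains Domain tibble.
#' @param chrom_sizes Named numeric vector (or tibble with `chrom`, `length`)
#'   of chromosome lengths covering every domain chromosome.
#' @return One-row tibble: `n_domains`, `total_bp` (of the merged domain
#'   footprint), `genome_bp`, `fraction`, `mean_size`, `median_size`.
#' @export
domain_coverage <- function(domains, chrom_sizes) {
  domains <- as_tibble(domains)
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  }
  genome_bp <- sum(chrom_sizes)
  if (nrow(domains) == 0) {
    return(tibble(n_domains = 0L, total_bp = 0, genome_bp = genome_bp,
                  fraction = 0, mean_size = NA_real_, median_size = NA_real_))
  }
  missing_chr <- setdiff(domains$chrom, names(chrom_sizes))
  if (length(missing_chr) > 0) {
    abort(sprintf("chrom_sizes lacks: %s", paste(missing_chr, collapse = ", ")))
  }
  if (any(domains$end > chrom_sizes[domains$chrom])) {
    abort("domain extends beyond its chromosome length")
  }
  merged <- merge_intervals(domains, max_gap = 0)
  sizes <- domains$end - domains$start
  tibble(n_domains = nrow(domains),
         total_bp = sum(merged$end - merged$start),
         genome_bp = genome_bp,
         fraction = sum(merged$end - merged$start) / genome_bp,
         mean_size = mean(sizes), median_size = median(sizes))
}
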