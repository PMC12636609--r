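#' Count subject intervals overlapping each query interval
#'
#' Half-open overlap test (`a.start < b.end && b.start < a.end`) requiring at
#' least `min_bp` shared bases; strand is ignored. Chromosomes absent from
#' the subject simply yield zero counts. Counting is delegated to
#' `GenomicRanges::countOverlaps()`.
#'
#' @param query,subject Interval tibbles (see [genomic_intervals()]).
#' @param min_bp Minimum overlap in bp (>= 1).
#' @return The `query` tibble with an added integer column `n_overlaps`.
#' @export
count_overlaps <- function(query, subject, min_bp = 1) {
  if (min_bp < 1) abort("min_bp must be >= 1")
  validate_intervals(query, "query")
  validate_intervals(subject, "subject")
  query <- as_tibble(query)
  if (nrow(query) == 0) {
    query$n_overlaps <- integer()
    return(query)
  }
  if (nrow(subject) == 0) {
    query$n_overlaps <- 0L
    return(query)
  }
  gq <- intervals_to_granges(query)
  gs <- intervals_to_granges(subject)
  suppressWarnings(
    query$n_overlaps <- GenomicRanges::countOverlaps(
      gq, gs, minoverlap = min_bp, ignore.strand = TRUE)
  )
  query
}

#' Stratify rG4 regions into tertiles of G4 probability
#'
#' Regions are ranked ascending by their stability score (`g4_probability`,
#' the fraction of reads with reverse-transcription stops) with stable tie
#' order, then cut into three groups whose sizes differ by at most one
#' (any extras go to the lower strata): lowest scores are `"low"`, highest
#' `"high"`.
#'
#' @param regions Tibble with a numeric `g4_probability` column in `[0, 1]`;
#'   at least 3 rows.
#' @return `regions` with an added factor column `stratum`
#'   (`low < medium < high`), input row order preserved.
#' @export
stratify_by_probability <- function(regions) {
  if (!"g4_probability" %in% names(regions)) {
    abort("regions must have a 'g4_probability' column")
  }
  n <- nrow(regions)
  if (n < 3) abort("need at least 3 regions to stratify")
  p <- regions$g4_probability
  if (any(is.na(p) | p < 0 | p > 1)) abort("g4_probability must lie in [0, 1]")
  ord <- order(p, seq_len(n))          # stable: ties keep input order
  n_low <- ceiling(n / 3)
  n_med <- ceiling((n - n_low) / 2)
  lab <- character(n)
  lab[ord[seq_len(n_low)]] <- "low"
  lab[ord[n_low + seq_len(n_med)]] <- "medium"
  lab[ord[(n_low + n_med + 1):n]] <- "high"
  regions$stratum <- factor(lab, levels = c("low", "medium", "high"))
  regions
}

#' Soluble/droplet phase enrichment per rG4 region
#'
#' For each region, counts overlapping intervals in the soluble and droplet
#' FUS interactomes, labels phase exclusivity, and computes the enrichment
#' score — the ratio of a region's occurrence in the soluble interactome to
#' its occurrence in the droplet interactome — for regions shared between
#' the two phases (`NA` otherwise).
#'
#' @param regions Region tibble (interval columns; extra columns such as
#'   `g4_probability`/`stratum` are carried through).
#' @param soluble,droplet Interval tibbles for the two interactomes.
#' @param min_bp Minimum overlap in bp.
#' @return `regions` plus columns `region_id`, `count_soluble`,
#'   `count_droplet`, `exclusivity` (factor: `soluble_only`, `droplet_only`,
#'   `shared`, `neither`) and `enrichment`.
#' @export
phase_enrichment <- function(regions, soluble, droplet, min_bp = 1) {
  out <- as_tibble(regions)
  out$region_id <- if ("name" %in% names(out) && !anyNA(out$name)) {
    out$name
  } else {
    sprintf("region_%04d", seq_len(nrow(out)))
  }
  out$count_soluble <- count_overlaps(regions, soluble, min_bp)$n_overlaps
  out$count_droplet <- count_overlaps(regions, droplet, min_bp)$n_overlaps
  s <- out$count_soluble > 0
  d <- out$count_droplet > 0
  out$exclusivity <- factor(
    dplyr::case_when(s & !d ~ "soluble_only",
                     !s & d ~ "droplet_only",
                     s & d ~ "shared",
                     TRUE ~ "neither"),
    levels = c("soluble_only", "droplet_only", "shared", "neither"))
  out$enrichment <- ifelse(s & d, out$count_soluble / out$count_droplet,
                           NA_real_)
  out
}

#' Rank candidate regions by soluble-phase enrichment
#'
#' Soluble-exclusive regions come first (the strongest possible soluble
#' bias), followed by shared regions in decreasing enrichment order; ties
#' broken by region id. Droplet-only and non-overlapping regions are
#' dropped.
#'
#' @param records Output of [phase_enrichment()].
#' @param strata_filter Keep only this stratum before ranking (default
#'   `"high"`); `NULL`, or records without a `stratum` column, keep all.
#' @return Ranked tibble of candidate records with a `rank` column.
#' @export
select_candidates <- function(records, strata_filter = "high") {
  x <- as_tibble(records)
  if (!is.null(strata_filter) && "stratum" %in% names(x)) {
    x <- dplyr::filter(x, .data$stratum %in% strata_filter)
  }
  excl <- dplyr::arrange(
    dplyr::filter(x, .data$exclusivity == "soluble_only"), .data$region_id)
  shared <- dplyr::arrange(
    dplyr::filter(x, .data$exclusivity == "shared"),
    dplyr::desc(.data$enrichment), .data$region_id)
  out <- dplyr::bind_rows(excl, shared)
  out$rank <- seq_len(nrow(out))
  out
}

#' Randomly re-place intervals within a genome
#'
#' Each interval is shuffled independently (bedtools-shuffle semantics):
#' the target chromosome is drawn with probability proportional to its
#' length among chromosomes long enough to hold the interval, and the start
#' is uniform on `[0, chrom_length - interval_length]`. Interval lengths
#' are preserved; shuffled intervals may overlap each other.
#'
#' @param intervals Interval tibble.
#' @param genome Genome table (see [genome_table()]).
#' @param seed Optional integer seed; when given the placement is
#'   deterministic and the caller's RNG state is untouched.
#' @return A tibble of re-placed intervals (names/scores/strand carried).
#' @export
shuffle_intervals <- function(intervals, genome, seed = NULL) {
  validate_intervals(intervals)
  run <- function() shuffle_intervals_impl(intervals, genome)
  if (is.null(seed)) run() else withr::with_seed(scramble_seed(seed), run())
}

# union of intervals per chromosome as sorted disjoint (start, end) blocks
merge_interval_blocks <- function(iv) {
  lapply(split(seq_len(nrow(iv)), iv$chrom), function(ix) {
    o <- ix[order(iv$start[ix])]
    s <- iv$start[o]; e <- iv$end[o]
    cme <- cummax(e)
    gid <- cumsum(c(TRUE, s[-1] > cme[-length(cme)]))
    list(start = as.numeric(tapply(s, gid, min)),
         end = as.numeric(tapply(cme, gid, max)))
  })
}

# number of query intervals sharing >= 1 bp with any merged block
n_overlapping_any <- function(query, merged) {
  tot <- 0L
  for (ch in unique(query$chrom)) {
    m <- merged[[ch]]
    if (is.null(m)) next
    sel <- query$chrom == ch
    qs <- query$start[sel]; qe <- query$end[sel]
    idx <- findInterval(qs, m$start)       # last block starting <= qs
    hit_here <- idx >= 1 & m$end[pmax(idx, 1)] > qs
    nb <- length(m$start)
    hit_next <- idx < nb & m$start[pmin(idx + 1, nb)] < qe
    tot <- tot + sum(hit_here | hit_next)
  }
  tot
}

# Lehmer step decouples the shuffle RNG stream from any generator stream
# seeded with the same integer: replaying the data-generating draws during
# shuffling would place null intervals on top of the originals and bias the
# null upward. Deterministic per seed.
scramble_seed <- function(seed) {
  as.integer((as.double(seed) * 48271) %% 2147483647)
}

shuffle_intervals_impl <- function(intervals, genome) {
  n <- nrow(intervals)
  if (n == 0) return(intervals)
  len <- intervals$end - intervals$start
  if (any(len > max(genome$length))) {
    abort("an interval is longer than every chromosome")
  }
  if (all(len <= min(genome$length))) {
    # every chromosome can hold every interval: fully vectorised draw
    j <- if (nrow(genome) == 1) rep(1L, n) else {
      sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
    }
  } else {
    j <- vapply(len, function(L) {
      ok <- which(genome$length >= L)
      if (length(ok) == 1) ok else sample(ok, 1, prob = genome$length[ok])
    }, integer(1))
  }
  # uniform integer start in [0, L - len]
  start_out <- floor(runif(n) * (genome$length[j] - len + 1))
  out <- intervals
  out$chrom <- genome$chrom[j]
  out$start <- start_out
  out$end <- start_out + len
  out
}

#' Permutation test for interval-set overlap enrichment
#'
#' The observed statistic is the number of `set_a` intervals overlapping at
#' least one `set_b` interval (>= 1 bp). The null distribution is built by
#' re-placing one of the sets uniformly within the genome `n_shuffles`
#' times ([shuffle_intervals()]) and recomputing the statistic. The
#' empirical p-value for the enrichment tail uses the pseudocount form
#' `(1 + #[null >= observed]) / (n_shuffles + 1)`, so it is never zero.
#'
#' @param set_a,set_b Non-empty interval tibbles.
#' @param genome Genome table.
#' @param n_shuffles Number of permutations (default 100).
#' @param direction Which set to shuffle: `"a"` or `"b"`.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `rg4_permtest` with fields `observed`,
#'   `null_counts`, `n_shuffles`, `empirical_p`, `direction`, `n_a`, `n_b`.
#' @export
permutation_test <- function(set_a, set_b, genome, n_shuffles = 100,
                             direction = c("a", "b"), seed = NULL) {
  direction <- match.arg(direction)
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    abort("both interval sets must be non-empty")
  }
  if (n_shuffles < 1) abort("n_shuffles must be >= 1")
  observed <- sum(count_overlaps(set_a, set_b)$n_overlaps > 0)
  # hot loop: the any-overlap statistic runs on merged sorted blocks
  # (S4 range objects per shuffle would dominate the runtime); equivalence
  # with the GenomicRanges route is pinned by a test
  b_merged <- merge_interval_blocks(set_b)
  run <- function() {
    vapply(seq_len(n_shuffles), function(i) {
      if (direction == "a") {
        sh <- shuffle_intervals_impl(set_a, genome)
        n_overlapping_any(sh, b_merged)
      } else {
        sh <- shuffle_intervals_impl(set_b, genome)
        n_overlapping_any(set_a, merge_interval_blocks(sh))
      }
    }, numeric(1))
  }
  null_counts <- if (is.null(seed)) run()
                 else withr::with_seed(scramble_seed(seed), run())
  structure(list(
    observed = observed,
    null_counts = null_counts,
    n_shuffles = n_shuffles,
    empirical_p = (1 + sum(null_counts >= observed)) / (n_shuffles + 1),
    direction = direction,
    n_a = nrow(set_a), n_b = nrow(set_b)
  ), class = "rg4_permtest")
}

#' @export
print.rg4_permtest <- function(x, ...) {
  cat("Interval-overlap permutation test\n")
  cat(sprintf("  observed overlapping intervals: %d of %d in set A\n",
              x$observed, x$n_a))
  cat(sprintf("  null: %d shuffles of set %s, mean %.2f, max %d\n",
              x$n_shuffles, toupper(x$direction), mean(x$null_counts),
              max(x$null_counts)))
  cat(sprintf("  empirical p (enrichment tail): %.4g\n", x$empirical_p))
  invisible(x)
}

#' @rdname permutation_test
#' @param x An `rg4_permtest` object.
#' @param ... Unused.
#' @method tidy rg4_permtest
#' @export
tidy.rg4_permtest <- function(x, ...) {
  tibble(shuffle = seq_len(x$n_shuffles), null_count = x$null_counts)
}

#' @rdname permutation_test
#' @method glance rg4_permtest
#' @export
glance.rg4_permtest <- function(x, ...) {
  tibble(observed = x$observed, n_shuffles = x$n_shuffles,
         null_mean = mean(x$null_counts), null_max = max(x$null_counts),
         empirical_p = x$empirical_p, direction = x$direction)
}

#' @rdname permutation_test
#' @param object An `rg4_permtest` object.
#' @method autoplot rg4_permtest
#' @export
autoplot.rg4_permtest <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "overlapping intervals (null shuffles)", y = "shuffles",
                  title = sprintf("observed = %d, empirical p = %.3g",
                                  object$observed, object$empirical_p))
}
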