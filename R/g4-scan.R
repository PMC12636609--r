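#' Scan parameters for QGRS-style G-quadruplex motif detection
#'
#' Defaults mirror the standard QGRS-mapper settings used for short RNA
#' inhibitor panels: maximum motif span 30 nt, minimum G-group size 2, loop
#' lengths 0-36 nt.
#'
#' @param max_length Maximum total motif span in nt (>= `4 * min_group`).
#' @param min_group Minimum G-run (tetrad) length, >= 2.
#' @param loop_min,loop_max Loop length bounds, `0 <= loop_min <= loop_max`.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(max_length = 30, min_group = 2,
                        loop_min = 0, loop_max = 36) {
  if (min_group < 2) abort("min_group must be >= 2")
  if (loop_min < 0 || loop_min > loop_max) {
    abort("need 0 <= loop_min <= loop_max")
  }
  if (max_length < 4 * min_group) abort("max_length must be >= 4 * min_group")
  structure(list(max_length = max_length, min_group = min_group,
                 loop_min = loop_min, loop_max = loop_max),
            class = "scan_params")
}

#' Find all quadruplex-forming G-rich motif placements in one sequence
#'
#' Exhaustively enumerates every placement of four equal-length G-runs of
#' `g >= min_group` separated by three loops within `[loop_min, loop_max]`
#' whose total span does not exceed `max_length`. A G-run longer than `g`
#' yields candidates at every register; overlapping candidates are all
#' reported (presence/absence is the consumed signal downstream).
#'
#' @param sequence A single RNA sequence string (ACGU; T accepted).
#' @param params A [scan_params()] object.
#' @return A tibble with columns `start` (0-based), `g`, `l1`, `l2`, `l3`,
#'   `length`, `score`, sorted by `(start, -score)`. Zero rows when no
#'   motif fits.
#' @export
#' @examples
#' find_candidates(strrep("GGGGCC", 4))
find_candidates <- function(sequence, params = scan_params()) {
  stopifnot(length(sequence) == 1)
  seq_chr <- chartr("tT", "uU", toupper(as.character(sequence)))
  is_g <- strsplit(seq_chr, "")[[1]] == "G"
  n <- length(is_g)
  p <- params
  empty <- tibble(start = integer(), g = integer(), l1 = integer(),
                  l2 = integer(), l3 = integer(), length = integer(),
                  score = double())
  if (n < 4 * p$min_group) return(empty)

  # run_len[i] = length of the G-run starting at i (0 if not G)
  run_len <- integer(n)
  acc <- 0L
  for (i in n:1) {
    acc <- if (is_g[i]) acc + 1L else 0L
    run_len[i] <- acc
  }

  g_max <- p$max_length %/% 4L
  out <- vector("list", 0)
  for (g in seq.int(p$min_group, max(p$min_group, g_max))) {
    if (4L * g > p$max_length) break
    starts1 <- which(run_len >= g)
    if (length(starts1) == 0) next
    for (s1 in starts1) {
      span_max <- min(n, s1 + p$max_length - 1L)
      # run-2 start range such that runs 3 and 4 can still fit in the span
      lo2 <- s1 + g + p$loop_min
      hi2 <- min(s1 + g + p$loop_max, span_max - 3L * g + 1L)
      if (lo2 > hi2) next
      for (s2 in lo2:hi2) {
        if (run_len[s2] < g) next
        lo3 <- s2 + g + p$loop_min
        hi3 <- min(s2 + g + p$loop_max, span_max - 2L * g + 1L)
        if (lo3 > hi3) next
        for (s3 in lo3:hi3) {
          if (run_len[s3] < g) next
          lo4 <- s3 + g + p$loop_min
          hi4 <- min(s3 + g + p$loop_max, span_max - g + 1L)
          if (lo4 > hi4) next
          for (s4 in lo4:hi4) {
            if (run_len[s4] < g) next
            L <- s4 + g - s1
            out[[length(out) + 1L]] <- c(s1 - 1L, g,
                                         s2 - (s1 + g), s3 - (s2 + g),
                                         s4 - (s3 + g), L)
          }
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  m <- do.call(rbind, out)
  cand <- tibble(start = m[, 1], g = m[, 2], l1 = m[, 3], l2 = m[, 4],
                 l3 = m[, 5], length = m[, 6])
  cand <- dplyr::distinct(cand)
  cand$score <- score_candidate(cand, params = p)
  dplyr::arrange(cand, .data$start, dplyr::desc(.data$score))
}

#' Score a G-quadruplex candidate
#'
#' Surrogate G-score implementing the standard ordering principles: more
#' stacked tetrads, shorter total span, and more equal loops score higher:
#' `10 * (g - min_group) + (max_length - L) - (max(loops) - min(loops))`.
#'
#' @param cand A candidate tibble (columns `g`, `l1`, `l2`, `l3`, `length`)
#'   as returned by [find_candidates()].
#' @param params The [scan_params()] the candidates were produced under.
#' @return Numeric score vector.
#' @export
score_candidate <- function(cand, params = scan_params()) {
  p <- params
  loops <- cbind(cand$l1, cand$l2, cand$l3)
  bad <- cand$g < p$min_group | cand$length > p$max_length |
    apply(loops, 1, min) < p$loop_min | apply(loops, 1, max) > p$loop_max |
    cand$length != 4 * cand$g + cand$l1 + cand$l2 + cand$l3
  if (any(bad)) abort("candidate violates scan constraints")
  10 * (cand$g - p$min_group) + (p$max_length - cand$length) -
    (apply(loops, 1, max) - apply(loops, 1, min))
}

#' Classify a sequence panel for rG4-forming potential
#'
#' Runs [find_candidates()] on each record; a sequence is rG4-positive when
#' at least one motif placement exists. The best candidate per sequence is
#' the highest-scoring one, ties broken by smallest start.
#'
#' @param records Tibble with columns `name`, `sequence`.
#' @param params A [scan_params()] object.
#' @return A tibble with columns `name`, `has_rg4`, and the best candidate's
#'   `start`, `g`, `l1`, `l2`, `l3`, `length`, `score` (`NA` when negative).
#' @export
classify_panel <- function(records, params = scan_params()) {
  if (nrow(records) == 0) {
    return(tibble(name = character(), has_rg4 = logical(), start = integer(),
                  g = integer(), l1 = integer(), l2 = integer(),
                  l3 = integer(), length = integer(), score = double()))
  }
  purrr::map2_dfr(records$name, records$sequence, function(nm, sq) {
    cand <- find_candidates(sq, params)
    if (nrow(cand) == 0) {
      tibble(name = nm, has_rg4 = FALSE, start = NA_integer_, g = NA_integer_,
             l1 = NA_integer_, l2 = NA_integer_, l3 = NA_integer_,
             length = NA_integer_, score = NA_real_)
    } else {
      best <- dplyr::slice(dplyr::arrange(cand, dplyr::desc(.data$score),
                                          .data$start), 1)
      dplyr::bind_cols(tibble(name = nm, has_rg4 = TRUE), best)
    }
  })
}
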