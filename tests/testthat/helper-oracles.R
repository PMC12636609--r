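# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: plain loops and direct arithmetic only.

# O(n*m) pairwise half-open overlap counter
brute_force_overlap_counts <- function(query, subject, min_bp = 1) {
  vapply(seq_len(nrow(query)), function(i) {
    q <- query[i, ]
    sum(vapply(seq_len(nrow(subject)), function(j) {
      s <- subject[j, ]
      if (q$chrom != s$chrom) return(FALSE)
      ov <- min(q$end, s$end) - max(q$start, s$start)
      ov >= min_bp
    }, logical(1)))
  }, numeric(1))
}

# naive quadruple-nested enumeration of G4 motif placements
brute_force_g4 <- function(sequence, max_length = 30, min_group = 2,
                           loop_min = 0, loop_max = 36) {
  ch <- strsplit(toupper(chartr("t", "u", sequence)), "")[[1]]
  n <- length(ch)
  is_run <- function(s, g) all(ch[s:(s + g - 1)] == "G")
  out <- list()
  for (g in min_group:max(min_group, max_length %/% 4)) {
    if (4 * g > max_length) next
    for (s1 in 1:max(1, n - 4 * g + 1)) {
      if (s1 + g - 1 > n || !is_run(s1, g)) next
      for (l1 in loop_min:loop_max) {
        if (4 * g + l1 + 2 * loop_min > max_length) break  # ascending loops
        for (l2 in loop_min:loop_max) {
          if (4 * g + l1 + l2 + loop_min > max_length) break
          for (l3 in loop_min:loop_max) {
            L <- 4 * g + l1 + l2 + l3
            if (L > max_length) break
            if (s1 + L - 1 > n) next
            s2 <- s1 + g + l1; s3 <- s2 + g + l2; s4 <- s3 + g + l3
            if (is_run(s2, g) && is_run(s3, g) && is_run(s4, g)) {
              out[[length(out) + 1]] <- c(s1 - 1, g, l1, l2, l3, L)
            }
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), g = integer(), l1 = integer(),
                      l2 = integer(), l3 = integer(), length = integer()))
  }
  m <- unique(do.call(rbind, out))
  data.frame(start = m[, 1], g = m[, 2], l1 = m[, 3], l2 = m[, 4],
             l3 = m[, 5], length = m[, 6])
}

random_intervals <- function(n, genome, max_len = 200) {
  j <- sample(nrow(genome), n, replace = TRUE)
  len <- sample(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (genome$length[j] - len))
  genomic_intervals(genome$chrom[j], start, start + len,
                    name = sprintf("iv%03d", seq_len(n)),
                    score = runif(n),
                    strand = sample(c("+", "-", "."), n, replace = TRUE))
}

test_genome <- function() genome_table(c("chrA", "chrB"), c(2e5, 3e5))
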