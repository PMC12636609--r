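#' Construct a table of genomic intervals
#'
#' Intervals follow the BED convention: 0-based, half-open `[start, end)`.
#' This is the unit of all enrichment arithmetic in the package.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer-like vector, 0-based inclusive start (bp).
#' @param end Integer-like vector, exclusive end (bp); must satisfy
#'   `0 <= start < end`.
#' @param name Optional identifiers (recycled `NA` if missing).
#' @param score Optional numeric scores.
#' @param strand One of `"+"`, `"-"`, `"."` per interval; strand is carried
#'   through IO but ignored by all overlap arithmetic.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
#' @examples
#' genomic_intervals("chr1", 10, 40, name = "r1", score = 0.9)
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = ".") {
  tb <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand)
  )
  validate_intervals(tb)
  tb
}

validate_intervals <- function(x, what = "intervals") {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s must have columns %s", what,
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) {
    abort(sprintf("%s: chrom must be non-empty", what))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf("%s: need 0 <= start < end (first offending row %d)",
                  what, bad[1]))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    abort(sprintf("%s: strand must be one of '+', '-', '.'", what))
  }
  invisible(x)
}

#' Read a BED file of genomic intervals
#'
#' Tolerant BED3-BED6 reader: fields may be separated by tabs or runs of
#' spaces; `track`, `browser` and `#` comment lines are skipped. Coordinates
#' are kept in the native BED convention (0-based, half-open).
#'
#' @param path Path to a BED file.
#' @return A tibble of intervals (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !(grepl("^\\s*$", lines) |
              grepl("^(track|browser)\\b", lines) |
              grepl("^#", lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(genomic_intervals(character(), numeric(), numeric()))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED parse error at line %d: fewer than 3 columns",
                  idx[which(nf < 3)[1]]))
  }
  get_col <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, character(1))
  }
  chrom <- get_col(1, NA_character_)
  start <- suppressWarnings(as.numeric(get_col(2, NA_character_)))
  end <- suppressWarnings(as.numeric(get_col(3, NA_character_)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("BED parse error at line %d: malformed coordinate", idx[bad[1]]))
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad) > 0) {
    abort(sprintf("BED parse error at line %d: need 0 <= start < end", idx[bad[1]]))
  }
  name <- get_col(4, NA_character_)
  score_chr <- get_col(5, NA_character_)
  score <- suppressWarnings(as.numeric(score_chr))
  bad <- which(!is.na(score_chr) & is.na(score))
  if (length(bad) > 0) {
    abort(sprintf("BED parse error at line %d: malformed score", idx[bad[1]]))
  }
  strand <- get_col(6, ".")
  strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "."
  genomic_intervals(chrom, start, end, name, score, strand)
}

#' Write intervals to a BED file
#'
#' Writes canonical tab-delimited BED6 in the input row order. `NA` name and
#' score become `"."` and `0`.
#'
#' @param intervals Tibble of intervals (see [genomic_intervals()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(intervals)) intervals$name else NA_character_
  score <- if ("score" %in% names(intervals)) intervals$score else NA_real_
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                   intervals$chrom,
                   format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   ifelse(is.na(name), ".", name),
                   ifelse(is.na(score), "0", sprintf("%.15g", score)),
                   ifelse(is.na(strand), ".", strand))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a genome table of chromosome sizes
#'
#' Expects UCSC `chrom.sizes` format: two tab-delimited columns, chromosome
#' name and length in bp.
#'
#' @param path Path to a chrom.sizes file.
#' @return A tibble with columns `chrom`, `length`.
#' @export
read_genome <- function(path) {
  tb <- readr::read_tsv(path, col_names = c("chrom", "length"),
                        col_types = "cd", progress = FALSE)
  genome_table(tb$chrom, tb$length)
}

#' Construct a genome table
#'
#' @param chrom Unique chromosome names.
#' @param length Chromosome lengths in bp (> 0).
#' @return A tibble with columns `chrom`, `length`.
#' @export
genome_table <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) abort("genome table: chromosome names must be unique")
  if (any(length <= 0)) abort("genome table: lengths must be > 0")
  tibble(chrom = chrom, length = length)
}

#' Read RNA sequences from FASTA or two-column TSV
#'
#' Sequences are uppercased and DNA `T` is mapped to RNA `U`; any character
#' outside `ACGUT` is an error. TSV input must carry a header row with
#' columns `name` and `sequence`.
#'
#' @param path Path to a FASTA file (first non-blank character `>`) or TSV.
#' @return A tibble with columns `name`, `sequence`.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) > 0 && grepl("^>", first)) {
    ss <- Biostrings::readBStringSet(path)
    tb <- tibble(name = names(ss), sequence = as.character(ss))
  } else {
    tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    if (!all(c("name", "sequence") %in% names(tb))) {
      abort("sequence TSV must have columns 'name' and 'sequence'")
    }
    tb <- tb[, c("name", "sequence")]
  }
  sequence_records(tb$name, tb$sequence)
}

#' Construct RNA sequence records
#'
#' @param name Record identifiers.
#' @param sequence RNA (or DNA, `T` mapped to `U`) sequences.
#' @return A tibble with columns `name`, `sequence` (uppercase ACGU).
#' @export
sequence_records <- function(name, sequence) {
  sequence <- chartr("tT", "uU", as.character(sequence))
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence)) || any(is.na(sequence))) {
    abort("sequences must be non-empty")
  }
  bad <- grepl("[^ACGU]", sequence)
  if (any(bad)) {
    abort(sprintf("sequence '%s' contains characters outside ACGU/T",
                  as.character(name)[which(bad)[1]]))
  }
  tibble(name = as.character(name), sequence = sequence)
}

#' Write sequence records as FASTA
#'
#' @param records Tibble with columns `name`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path) {
  ss <- Biostrings::BStringSet(setNames(records$sequence, records$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a long-format curve table
#'
#' Reads a TSV or CSV (by extension) with at least columns `series`, `x`,
#' `y`; any extra metadata columns are preserved. Rows are sorted by
#' `(series, x)`; a duplicated `(series, x)` pair is an error, as is a
#' non-numeric `x` or `y`.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` file.
#' @return A tibble sorted by `(series, x)`.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  tb <- reader(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  if (!all(c("series", "x", "y") %in% names(tb))) {
    abort("curve table must have columns 'series', 'x', 'y'")
  }
  as_curve_table(tb)
}

#' Validate and sort a curve table
#'
#' @param tb A data frame with columns `series`, `x`, `y`.
#' @return A tibble sorted by `(series, x)` with numeric `x`, `y`.
#' @export
as_curve_table <- function(tb) {
  tb <- as_tibble(tb)
  xn <- suppressWarnings(as.numeric(tb$x))
  yn <- suppressWarnings(as.numeric(tb$y))
  bad <- which((is.na(xn) & !is.na(tb$x)) | (is.na(yn) & !is.na(tb$y)))
  if (length(bad) > 0) {
    abort(sprintf("curve table: non-numeric x or y at row %d", bad[1]))
  }
  tb$x <- xn
  tb$y <- yn
  tb <- dplyr::arrange(tb, .data$series, .data$x)
  dup <- duplicated(tb[, c("series", "x")])
  if (any(dup)) {
    abort(sprintf("curve table: duplicated (series, x) pair at sorted row %d",
                  which(dup)[1]))
  }
  tb
}

#' Write a curve table as TSV
#'
#' @param tb Curve table (see [read_curves()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(tb, path) {
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

# GRanges bridge: BED convention (0-based half-open) -> 1-based closed.
intervals_to_granges <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = "*"
  )
}
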