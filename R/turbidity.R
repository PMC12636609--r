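#' Preprocess turbidity traces for an inhibition assay
#'
#' Per trial: (1) the pointwise mean of the buffer-blank traces is
#' subtracted from every trace; (2) every trace is divided by the maximum
#' absorbance of that trial's single zero-RNA control, so the control peaks
#' at exactly 1. Traces are matched by the `time` column, which must be
#' shared across series within a trial.
#'
#' @param traces Tibble with columns `series`, `time` (min), `a395`, `role`
#'   (one of `"sample"`, `"buffer_blank"`, `"zero_rna_control"`), and
#'   optionally `trial`; extra metadata columns are preserved.
#' @return The tibble with `a395` blank-subtracted and control-normalized
#'   (buffer-blank rows are dropped).
#' @export
preprocess_inhibition <- function(traces) {
  traces <- as_tibble(traces)
  req <- c("series", "time", "a395", "role")
  if (!all(req %in% names(traces))) {
    abort(sprintf("traces need columns %s", paste(req, collapse = ", ")))
  }
  if (!"trial" %in% names(traces)) traces$trial <- 1L
  out <- dplyr::group_modify(dplyr::group_by(traces, .data$trial),
                             function(df, key) {
    blanks <- dplyr::filter(df, .data$role == "buffer_blank")
    if (nrow(blanks) == 0) abort("each trial needs >= 1 buffer_blank trace")
    ctrl_series <- unique(df$series[df$role == "zero_rna_control"])
    if (length(ctrl_series) != 1) {
      abort("each trial needs exactly one zero_rna_control series")
    }
    buf <- dplyr::summarise(dplyr::group_by(blanks, .data$time),
                            buf_mean = mean(.data$a395), .groups = "drop")
    df <- dplyr::filter(df, .data$role != "buffer_blank")
    df <- dplyr::left_join(df, buf, by = "time")
    if (anyNA(df$buf_mean)) {
      abort("buffer blank does not cover all time points")
    }
    df$a395 <- df$a395 - df$buf_mean
    df$buf_mean <- NULL
    ctrl_max <- max(df$a395[df$series == ctrl_series])
    if (ctrl_max <= 0) abort("zero-RNA control maximum is <= 0")
    df$a395 <- df$a395 / ctrl_max
    df
  })
  dplyr::ungroup(out)
}

#' Normalize a reversal-assay trace to its pre-RNA absorbance
#'
#' Divides the whole trace by the mean of the last `k_pre` points collected
#' before RNA addition, so the signal immediately before addition is ~1 and
#' post-addition values read as a relative response to the RNA.
#'
#' @param trace Tibble for a single series with columns `time`, `a395`.
#' @param rna_add_time Time of RNA addition (min); must leave at least
#'   `k_pre` points before it.
#' @param k_pre Number of pre-addition points averaged (default 5, robust
#'   to single-point noise).
#' @return The trace with normalized `a395` and an added `rna_add_time`
#'   column.
#' @export
preprocess_reversal <- function(trace, rna_add_time, k_pre = 5) {
  trace <- as_tibble(trace)
  if (!all(c("time", "a395") %in% names(trace))) {
    abort("trace needs columns time, a395")
  }
  pre <- which(trace$time < rna_add_time)
  if (length(pre) < k_pre) {
    abort(sprintf("need >= %d points before rna_add_time", k_pre))
  }
  anchor <- mean(trace$a395[utils::tail(pre, k_pre)])
  if (anchor <= 0) abort("pre-RNA mean absorbance is <= 0")
  trace$a395 <- trace$a395 / anchor
  trace$rna_add_time <- rna_add_time
  trace
}

#' Area under a turbidity trace
#'
#' Trapezoidal integral of `a395` over `[t0, t1]` on the native time grid;
#' window endpoints falling between samples are linearly interpolated.
#' When a control AUC is supplied, the normalized AUC (fraction of the
#' matched zero-RNA control) is reported as well.
#'
#' @param trace Tibble with columns `time`, `a395`.
#' @param t0,t1 Integration window (min), within the trace span.
#' @param control_auc Optional raw AUC of the matched zero-RNA control.
#' @return One-row tibble with `raw_auc`, `normalized_auc`, `t0`, `t1`.
#' @export
trace_auc <- function(trace, t0 = min(trace$time), t1 = max(trace$time),
                      control_auc = NULL) {
  trace <- dplyr::arrange(as_tibble(trace), .data$time)
  if (t0 >= t1) abort("need t0 < t1")
  if (t0 < min(trace$time) - 1e-9 || t1 > max(trace$time) + 1e-9) {
    abort("integration window outside trace span")
  }
  inside <- trace$time > t0 & trace$time < t1
  tt <- c(t0, trace$time[inside], t1)
  yy <- c(approx(trace$time, trace$a395, t0)$y,
          trace$a395[inside],
          approx(trace$time, trace$a395, t1)$y)
  raw <- pracma::trapz(tt, yy)
  tibble(raw_auc = raw,
         normalized_auc = if (is.null(control_auc)) NA_real_
                          else raw / control_auc,
         t0 = t0, t1 = t1)
}

#' Sedimentation fractions from band intensities
#'
#' Relative abundance of protein in the pellet and supernatant fractions of
#' a sedimentation assay, from densitometry intensities of the two gel
#' bands. The two fractions sum to 1 exactly.
#'
#' @param pellet_intensity,supernatant_intensity Nonnegative intensities
#'   (vectorised pairwise); a pair that is entirely zero is an error.
#' @return Tibble with `fraction_pellet`, `fraction_supernatant`.
#' @export
sedimentation_fractions <- function(pellet_intensity, supernatant_intensity) {
  if (any(pellet_intensity < 0) || any(supernatant_intensity < 0)) {
    abort("intensities must be >= 0")
  }
  tot <- pellet_intensity + supernatant_intensity
  if (any(tot == 0)) abort("pellet and supernatant cannot both be zero")
  tibble(fraction_pellet = pellet_intensity / tot,
         fraction_supernatant = supernatant_intensity / tot)
}
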