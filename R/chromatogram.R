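# Chromatogram traces and peak detection.

#' Construct a chromatogram
#'
#' @param time numeric vector of acquisition times (minutes), strictly
#'   increasing, near-uniformly spaced (max/min step ratio <= 1.5).
#' @param absorbance numeric vector of the same length (arbitrary units).
#' @param sample_id sample label.
#' @return list of class `chromatogram` with elements `time`, `absorbance`,
#'   `sample_id`.
#' @export
chromatogram <- function(time, absorbance, sample_id = "sample") {
  time <- as.numeric(time)
  absorbance <- as.numeric(absorbance)
  if (length(time) < 2 || length(time) != length(absorbance) ||
      anyNA(time) || anyNA(absorbance)) {
    hmwgs_stop("chromatogram needs >= 2 paired numeric samples",
               "hmwgs_format_error")
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    hmwgs_stop("chromatogram time must be strictly increasing",
               "hmwgs_format_error")
  }
  if (max(dt) / min(dt) > 1.5) {
    hmwgs_stop("chromatogram sampling is too non-uniform (step ratio > 1.5)",
               "hmwgs_format_error")
  }
  structure(list(time = time, absorbance = absorbance,
                 sample_id = as.character(sample_id)),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram '%s': %d samples, %.2f-%.2f min>\n",
              x$sample_id, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Read a chromatogram trace from CSV
#'
#' Expects two numeric columns, time (minutes) then absorbance, with an
#' optional header (`time_min,absorbance` by convention).
#'
#' @param path CSV file path.
#' @param sample_id sample label; defaults to the file name without
#'   extension.
#' @return a [chromatogram()].
#' @export
read_trace <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.]", first)
  tab <- tryCatch(
    utils::read.csv(path, header = has_header),
    error = function(e) hmwgs_stop(
      paste0("cannot parse trace CSV: ", conditionMessage(e)),
      "hmwgs_format_error"))
  if (ncol(tab) < 2) {
    hmwgs_stop("trace CSV needs two columns (time_min, absorbance)",
               "hmwgs_format_error")
  }
  chromatogram(tab[[1]], tab[[2]], sample_id)
}

#' Write a chromatogram trace to CSV
#'
#' @param trace a [chromatogram()].
#' @param path output CSV path; columns `time_min,absorbance`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_min = trace$time,
                              absorbance = trace$absorbance),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect peaks in a chromatogram window
#'
#' Peaks are local maxima of the moving-average-smoothed, baseline-corrected
#' signal inside `window`, kept when their height reaches `min_height`. The
#' baseline is the straight line through the smoothed signal at the window
#' endpoints. The apex retention time is refined below the sampling grid by
#' fitting a quadratic through the three samples around each maximum; peak
#' area is the trapezoid integral of the baseline-corrected signal between
#' the flanking local minima (or window edges).
#'
#' @param trace a [chromatogram()].
#' @param window numeric length-2 retention-time window (minutes); must lie
#'   within the trace's time range.
#' @param min_height minimum peak height above baseline (AU). `NULL`
#'   (default) uses 5% of the window's maximum baseline-corrected signal,
#'   which is scale invariant.
#' @param smooth_width moving-average width in minutes (default 0.05).
#' @return data.frame of class `hmwgs_peaks` with columns `apex_rt`,
#'   `height`, `area`, `left_rt`, `right_rt`, sorted by `apex_rt`.
#' @examples
#' t <- seq(20, 60, by = 0.01)
#' tr <- chromatogram(t, 100 * exp(-(t - 38.842)^2 / (2 * 0.15^2)))
#' detect_peaks(tr)
#' @export
detect_peaks <- function(trace, window = c(25, 42), min_height = NULL,
                         smooth_width = 0.05) {
  if (length(window) != 2 || window[1] >= window[2]) {
    hmwgs_stop("window must be an increasing length-2 interval",
               "hmwgs_format_error")
  }
  if (window[1] < min(trace$time) || window[2] > max(trace$time)) {
    hmwgs_stop("window outside trace time range", "hmwgs_format_error")
  }
  step <- stats::median(diff(trace$time))
  half <- max(0L, floor(smooth_width / step / 2))
  y <- moving_average(trace$absorbance, half)
  idx <- which(trace$time >= window[1] & trace$time <= window[2])
  tw <- trace$time[idx]
  yw <- y[idx]
  n <- length(yw)
  if (n < 3) {
    hmwgs_stop("window contains fewer than 3 samples", "hmwgs_format_error")
  }
  # linear baseline between window endpoints
  base <- yw[1] + (yw[n] - yw[1]) * (tw - tw[1]) / (tw[n] - tw[1])
  z <- yw - base
  thr <- if (is.null(min_height)) 0.05 * max(z) else min_height
  # local maxima; ties (flat tops) keep the first sample
  im <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n]) + 1L
  im <- im[z[im] >= thr & z[im] > 0]
  if (!length(im)) {
    return(empty_peaks())
  }
  imn <- which(z[2:(n - 1)] <= z[1:(n - 2)] & z[2:(n - 1)] < z[3:n]) + 1L
  peaks <- lapply(im, function(i) {
    # quadratic apex refinement through the three samples around the max
    yl <- z[i - 1]; ym <- z[i]; yr <- z[i + 1]
    den <- yl - 2 * ym + yr
    delta <- if (den < 0) 0.5 * (yl - yr) / den * (tw[i + 1] - tw[i]) else 0
    delta <- max(-0.5, min(0.5, delta / (tw[i + 1] - tw[i]))) *
      (tw[i + 1] - tw[i])
    apex <- tw[i] + delta
    height <- ym - 0.25 * (yl - yr) * delta / (tw[i + 1] - tw[i])
    lo <- imn[imn < i]
    hi <- imn[imn > i]
    l <- if (length(lo)) max(lo) else 1L
    r <- if (length(hi)) min(hi) else n
    seg <- l:r
    area <- sum(diff(tw[seg]) * (z[seg][-1] + z[seg][-length(seg)]) / 2)
    c(apex_rt = apex, height = height, area = area,
      left_rt = tw[l], right_rt = tw[r])
  })
  out <- as.data.frame(do.call(rbind, peaks))
  out <- out[order(out$apex_rt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hmwgs_peaks", "data.frame")
  out
}

empty_peaks <- function() {
  out <- data.frame(apex_rt = numeric(0), height = numeric(0),
                    area = numeric(0), left_rt = numeric(0),
                    right_rt = numeric(0))
  class(out) <- c("hmwgs_peaks", "data.frame")
  out
}

# centered moving average with shrinking edge windows
moving_average <- function(y, half) {
  if (half < 1) return(y)
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
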