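# Two-part data filter (quality control + meteorological filtering) and
# growing-season delineation.

#' Filter a flux time series
#'
#' Two-stage filter: (1) quality control — records whose quality flag is
#' not among the accepted values are discarded; (2) meteorological
#' filtering — records outside accepted variable ranges, below a friction
#' velocity threshold, or within a post-rain exclusion window are
#' discarded. Discarded records have all their data values set to missing;
#' timestamps are retained, so row count and time step never change and
#' the filter is idempotent.
#'
#' A rain record (precipitation above zero) is itself removed by the
#' precipitation rule, and all records with timestamps in the half-open
#' window `(t, t + rain_window_hours]` after it are removed by the window
#' rule.
#'
#' @param data Data frame with a timestamp column and numeric data columns.
#' @param quality_flags Named list mapping a data column to its quality
#'   flag column, e.g. `list(LE = "LE_qc")`.
#' @param accept_flags Flag values treated as good quality (default
#'   `c(0, 1)`: measured and high-quality gap-filled).
#' @param ranges Named list of accepted ranges `c(min, max)` per variable
#'   (closed lower bound, open filter outside), e.g.
#'   `list(PPFD = c(200, Inf))`. Unknown columns raise an error. Records
#'   where the variable is missing are not failed by its range rule.
#' @param ustar_threshold Friction velocity threshold (m s-1); records with
#'   `ustar` below it are discarded.
#' @param precip_col Name of the precipitation column (per-interval sums).
#' @param rain_window_hours Length of the post-rain exclusion window
#'   (hours); `NULL` disables rain filtering.
#' @param keep Optional logical vector (e.g. a growing-season mask expanded
#'   to record resolution); records with `FALSE` are discarded.
#' @param timestamp_col Name of the timestamp column (default
#'   `"timestamp"`); it and the quality-flag and precipitation columns are
#'   never blanked.
#' @param quiet Suppress the per-rule summary message?
#'
#' @return The input data frame with failing records blanked; the
#'   per-rule counts of newly blanked records are attached as attribute
#'   `"filter_summary"` and reported via `message()`.
#' @examples
#' d <- data.frame(timestamp = seq(as.POSIXct("2020-01-01", tz = "UTC"),
#'                                 by = 1800, length.out = 10),
#'                 PPFD = c(rep(500, 7), 50, 50, 50), LE = 100)
#' filter_data(d, ranges = list(PPFD = c(200, Inf)))
#' @export
filter_data <- function(data,
                        quality_flags = NULL, accept_flags = c(0, 1),
                        ranges = NULL,
                        ustar_threshold = NULL,
                        precip_col = "precip", rain_window_hours = NULL,
                        keep = NULL,
                        timestamp_col = "timestamp",
                        quiet = FALSE) {
  n <- nrow(data)
  bad_by <- list()

  if (!is.null(quality_flags)) {
    for (v in names(quality_flags)) {
      fcol <- quality_flags[[v]]
      .check_columns(data, c(v, fcol))
      bad_by[[paste0("quality_", v)]] <-
        !is.na(data[[fcol]]) & !(data[[fcol]] %in% accept_flags)
    }
  }

  if (!is.null(ranges)) {
    for (v in names(ranges)) {
      .check_columns(data, v)
      r <- ranges[[v]]
      bad_by[[paste0("range_", v)]] <-
        !is.na(data[[v]]) & (data[[v]] < r[1] | data[[v]] > r[2])
    }
  }

  if (!is.null(ustar_threshold)) {
    .check_columns(data, "ustar")
    bad_by$ustar <- !is.na(data$ustar) & data$ustar < ustar_threshold
  }

  if (!is.null(rain_window_hours)) {
    .check_columns(data, c(precip_col, timestamp_col))
    rain <- !is.na(data[[precip_col]]) & data[[precip_col]] > 0
    bad_by$rain <- rain
    t <- as.numeric(data[[timestamp_col]])
    in_window <- rep(FALSE, n)
    for (i in which(rain)) {
      in_window <- in_window | (t > t[i] & t <= t[i] + rain_window_hours * 3600)
    }
    bad_by$rain_window <- in_window & !rain
  }

  if (!is.null(keep)) {
    bad_by$keep <- !keep
  }

  bad <- Reduce(`|`, bad_by, rep(FALSE, n))
  protected <- c(timestamp_col, precip_col,
                 unlist(lapply(quality_flags, identity)))
  blank_cols <- setdiff(names(data), protected)
  already_blank <- rowSums(!is.na(data[, blank_cols, drop = FALSE])) == 0
  data[bad, blank_cols] <- NA

  summary <- c(vapply(bad_by, sum, integer(1)),
               total_blanked = sum(bad & !already_blank))
  attr(data, "filter_summary") <- summary
  if (!quiet && length(bad_by))
    message("filter_data: records failing each rule: ",
            paste(names(summary), summary, sep = "=", collapse = ", "))
  data
}

#' Delineate the growing season from daily GPP
#'
#' Smooths a daily GPP series with a centered moving average of width `ws`
#' days, flags days where the smoothed series exceeds `tGPP` times a
#' reference level (the 95th percentile of the smoothed series by default,
#' robust to outliers; optionally its maximum or a fixed absolute value),
#' and removes runs shorter than `min_int` days by assigning them to the
#' surrounding state in a single chronological scan.
#'
#' @param GPP_daily Daily GPP series (any consistent unit).
#' @param tGPP Relative GPP threshold (0..1), default 0.5.
#' @param ws Smoothing window size (days), default 15.
#' @param min_int Minimum accepted run length (days), default 5.
#' @param normalize Reference level the threshold is relative to:
#'   `"quantile"` (95th percentile, default), `"max"`, or `"absolute"`
#'   (then `tGPP` is an absolute GPP value).
#' @return Logical day mask, `TRUE` inside the growing season; an
#'   all-missing input yields all `FALSE`.
#' @export
growing_season <- function(GPP_daily, tGPP = 0.5, ws = 15, min_int = 5,
                           normalize = c("quantile", "max", "absolute")) {
  normalize <- match.arg(normalize)
  if (tGPP <= 0 || (normalize != "absolute" && tGPP >= 1))
    stop("tGPP must be in (0, 1) for relative thresholds")
  if (ws < 1 || min_int < 1) stop("window lengths must be positive")
  n <- length(GPP_daily)
  if (all(is.na(GPP_daily))) return(rep(FALSE, n))
  if (n < ws) stop("series shorter than the smoothing window")

  h <- floor(ws / 2)
  sm <- vapply(seq_len(n), function(i) {
    w <- GPP_daily[max(1, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))

  ref <- switch(normalize,
                quantile = stats::quantile(sm, 0.95, na.rm = TRUE),
                max = max(sm, na.rm = TRUE),
                absolute = 1)
  mask <- !is.na(sm) & sm > tGPP * ref

  # enforce the minimum run length: short runs take the preceding state
  r <- rle(mask)
  long_idx <- which(r$lengths >= min_int)
  if (length(long_idx)) {
    state <- r$values[long_idx[1]]   # state before the first long run
    for (i in seq_along(r$lengths)) {
      if (r$lengths[i] >= min_int) state <- r$values[i]
      else r$values[i] <- state
    }
    mask <- inverse.rle(r)
  }
  mask
}
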