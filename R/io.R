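# Readers and writers for half-hourly flux/met tables in delimited text.
# Canonical variable set after ingestion (units in parentheses):
#   timestamp (POSIXct, start of interval), Ta (degC), p (kPa), Da (kPa),
#   u (m s-1), ustar (m s-1), H, LE, Rn, G, S (W m-2), NEE, GPP
#   (umol m-2 s-1), SW_in, LW_in, LW_out (W m-2), PPFD (umol m-2 s-1),
#   precip (mm per interval), Ca (umol mol-1), *_qc (integer flags).

.fluxnet2015_map <- c(
  Ta = "TA_F", p = "PA_F", Da = "VPD_F", u = "WS_F", ustar = "USTAR",
  H = "H_F_MDS", LE = "LE_F_MDS", NEE = "NEE_VUT_REF",
  GPP = "GPP_NT_VUT_REF", Rn = "NETRAD", G = "G_F_MDS",
  SW_in = "SW_IN_F", LW_in = "LW_IN_F", LW_out = "LW_OUT",
  PPFD = "PPFD_IN", precip = "P_F", Ca = "CO2_F_MDS",
  Ta_qc = "TA_F_QC", H_qc = "H_F_MDS_QC", LE_qc = "LE_F_MDS_QC",
  NEE_qc = "NEE_VUT_REF_QC", GPP_qc = "NEE_VUT_REF_QC"
)

#' Read a half-hourly flux/met table
#'
#' Reads a delimited-text flux table and returns it with canonical column
#' names and units. For the `"fluxnet2015"` dialect the standard column
#' names are mapped (overridable via `column_map`), the `-9999` sentinel
#' becomes missing, VPD is converted from hPa to kPa, `TIMESTAMP_START`
#' (format `YYYYMMDDHHMM`, local standard time, parsed as UTC without DST
#' handling) becomes the `timestamp` column, and PPFD is derived from
#' shortwave radiation via [Rg_to_PPFD()] when absent. The `"generic"`
#' dialect assumes canonical units and applies only `column_map` and the
#' sentinel rule.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"fluxnet2015"` (default) or `"generic"`.
#' @param column_map Named character vector `canonical = "file_column"`
#'   overriding (or, for generic input, providing) the mapping.
#' @param timestamp_col Timestamp column for the generic dialect.
#' @param sep Field separator (default comma).
#' @param na_sentinel Numeric sentinel encoding missing values.
#' @param keep_extra Keep unmapped columns (under their original names)?
#' @return A data.frame ordered by strictly increasing timestamps.
#' @export
read_fluxnet <- function(path, dialect = c("fluxnet2015", "generic"),
                         column_map = NULL, timestamp_col = "timestamp",
                         sep = ",", na_sentinel = -9999,
                         keep_extra = FALSE) {
  dialect <- match.arg(dialect)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  map <- if (dialect == "fluxnet2015") .fluxnet2015_map else character(0)
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  if (dialect == "fluxnet2015") {
    if (!"TIMESTAMP_START" %in% names(raw))
      stop("timestamp column TIMESTAMP_START not found; candidates: ",
           paste(grep("TIME", names(raw), value = TRUE), collapse = ", "))
    ts <- as.POSIXct(as.character(raw$TIMESTAMP_START),
                     format = "%Y%m%d%H%M", tz = "UTC")
  } else {
    ts_col <- if (!is.null(column_map) && "timestamp" %in% names(column_map))
      column_map[["timestamp"]] else timestamp_col
    if (!ts_col %in% names(raw))
      stop("timestamp column ", ts_col, " not found; candidates: ",
           paste(names(raw), collapse = ", "))
    ts <- as.POSIXct(raw[[ts_col]], tz = "UTC")
    map <- map[names(map) != "timestamp"]
  }

  out <- data.frame(timestamp = ts)
  for (canon in names(map)) {
    src <- map[[canon]]
    if (src %in% names(raw)) {
      x <- raw[[src]]
      x[x == na_sentinel] <- NA
      out[[canon]] <- x
    }
  }
  if (dialect == "generic" && keep_extra == FALSE && !length(map))
    for (nm in setdiff(names(raw), timestamp_col)) {
      x <- raw[[nm]]
      if (is.numeric(x)) x[x == na_sentinel] <- NA
      out[[nm]] <- x
    }
  if (dialect == "fluxnet2015") {
    if ("Da" %in% names(out)) out$Da <- out$Da / 10   # hPa -> kPa
    if (!"PPFD" %in% names(out) && "SW_in" %in% names(out))
      out$PPFD <- Rg_to_PPFD(out$SW_in)
  }
  if (keep_extra) {
    extra <- setdiff(names(raw), c(map, "TIMESTAMP_START", timestamp_col))
    for (nm in extra) {
      x <- raw[[nm]]
      if (is.numeric(x)) x[x == na_sentinel] <- NA
      out[[nm]] <- x
    }
  }
  if (anyNA(out$timestamp) || is.unsorted(as.numeric(out$timestamp),
                                          strictly = TRUE))
    stop("timestamps must parse and be strictly increasing")
  out
}

#' Write a flux table with derived columns
#'
#' Writes the input columns followed by any derived columns as comma
#' separated text, full precision, with a commented units header line that
#' [read_fluxnet()] (generic dialect) skips on re-reading.
#'
#' @param data Flux time series data frame.
#' @param path Output file path.
#' @param derived Optional data.frame of derived per-record columns to
#'   append (must have `nrow(data)` rows).
#' @param units Optional named character vector of unit strings written to
#'   the header comment.
#' @return The output path, invisibly.
#' @export
write_outputs <- function(data, path, derived = NULL, units = NULL) {
  if (!is.null(derived)) {
    if (nrow(derived) != nrow(data))
      stop("derived must have one row per input record")
    clash <- intersect(names(derived), names(data))
    if (length(clash)) names(derived)[names(derived) %in% clash] <-
        paste0(clash, "_derived")
    data <- cbind(data, derived)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units))
    writeLines(paste0("# units: ",
                      paste(names(units), units, sep = "=",
                            collapse = ", ")), con)
  if (inherits(data$timestamp, "POSIXct"))
    data$timestamp <- format(data$timestamp, "%Y-%m-%d %H:%M:%S",
                             tz = "UTC")
  utils::write.table(data, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
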