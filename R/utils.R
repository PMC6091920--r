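# internal helpers

.check_columns <- function(data, cols) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("required column(s) missing from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
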