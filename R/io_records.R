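# Per-tomogram CSV of ribosome context records: one row per ribosome with
# its center->OMM distance, the three relative angles, the nearest-triangle
# id, the exit-tunnel->OMM distance, and the orientation class.

record_cols <- c("particle_id", "tomogram_id", "center_to_omm",
                 "angle_x", "angle_y", "angle_z", "nearest_triangle_id",
                 "exit_to_omm", "orientation_class")

#' Write context records to CSV
#'
#' One CSV per tomogram, one row per ribosome, stable column order;
#' re-readable losslessly (numeric values kept to full precision).
#'
#' @param records A `context_records` data frame from [compute_context()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_context_records <- function(records, path) {
  df <- as.data.frame(records)[, record_cols, drop = FALSE]
  if (nrow(df) && length(unique(df$tomogram_id)) > 1L)
    stopf("records span multiple tomograms; write one CSV per tomogram")
  write.csv(format(df, digits = 15, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read context records from CSV
#'
#' @param path CSV written by [write_context_records()].
#' @return A `context_records` data frame.
#' @export
read_context_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(record_cols, names(df))
  if (length(missing_cols))
    stopf("record CSV %s is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  num <- c("center_to_omm", "angle_x", "angle_y", "angle_z", "exit_to_omm")
  for (nm in num) df[[nm]] <- as.numeric(df[[nm]])
  df$nearest_triangle_id <- as.integer(df$nearest_triangle_id)
  class(df) <- c("context_records", "data.frame")
  df
}
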