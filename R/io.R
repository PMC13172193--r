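# File I/O registry: every table schema has a paired writer and reader
# that round-trip losslessly, and grayscale/label images go through
# single-plane 16-bit TIFF.

intensity_cols <- c("cell_id", "cycle", "time_s", "donor", "fret",
                    "acceptor", "mrfp", "bg_donor", "bg_fret",
                    "bg_acceptor", "bg_mrfp")
detection_cols <- c("frame", "t_s", "x_um", "y_um")
track_cols <- c("track_id", "frame", "t_s", "x_um", "y_um")
record_cols <- c("subject", "experiment", "sirna", "noco", "stimulation",
                 "mean_speed_nm_s")

write_schema_csv <- function(df, path, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_invalid("table is missing column(s): %s",
                 paste(miss, collapse = ", "))
  utils::write.csv(df[, cols], path, row.names = FALSE)
  invisible(path)
}

read_schema_csv <- function(path, cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_invalid("%s is missing column(s): %s", path,
                 paste(miss, collapse = ", "))
  df[, cols]
}

#' Write / read a channel-intensity table
#' @param df intensity table (see [render_fret_channels()]).
#' @param path CSV file path.
#' @return the path (writer) or the table (reader).
#' @export
write_intensity_csv <- function(df, path)
  write_schema_csv(df, path, intensity_cols)

#' @rdname write_intensity_csv
#' @export
read_intensity_csv <- function(path) read_schema_csv(path, intensity_cols)

#' Write / read a per-frame detection table
#' @param df detection table (frame, t_s, x_um, y_um).
#' @param path CSV file path.
#' @return the path (writer) or the table (reader).
#' @export
write_detections_csv <- function(df, path)
  write_schema_csv(df, path, detection_cols)

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) read_schema_csv(path, detection_cols)

#' Write / read a linked track table
#' @param df track table (track_id, frame, t_s, x_um, y_um).
#' @param path CSV file path.
#' @return the path (writer) or the table (reader).
#' @export
write_tracks_csv <- function(df, path) write_schema_csv(df, path, track_cols)

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) read_schema_csv(path, track_cols)

#' Write / read a motility record table
#' @param df record table (subject, experiment, sirna, noco, stimulation,
#'   mean_speed_nm_s).
#' @param path CSV file path.
#' @return the path (writer) or the table (reader).
#' @export
write_records_csv <- function(df, path)
  write_schema_csv(df, path, record_cols)

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) read_schema_csv(path, record_cols)

#' Write / read a grayscale image as 16-bit TIFF
#'
#' Intensities are rounded to integers and stored as 16-bit grayscale
#' (values must lie in [0, 65535]); label masks round-trip exactly.
#'
#' @param img numeric or integer matrix.
#' @param path TIFF file path.
#' @return the path (writer) or the matrix (reader).
#' @export
write_gray_tiff <- function(img, path) {
  m <- round(as.matrix(img))
  m[m < 0] <- 0
  if (max(m) > 65535)
    stop_invalid("image intensities exceed the 16-bit range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_gray_tiff
#' @export
read_gray_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  round(m * 65535)
}
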