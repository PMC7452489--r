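# Marker sets: labelled 3D coordinates tagged with the frame they live in.
# The frame tag is mandatory in files to prevent motion-capture / CT frame
# mix-ups at the transfer step.

MARKER_FRAMES <- c("mocap", "ct", "patella-lcs")

#' Construct a marker set
#'
#' @param coords m x 3 numeric matrix, mm
#' @param labels character vector of marker names (defaults to M1..Mm)
#' @param frame coordinate frame tag: `"mocap"`, `"ct"` or `"patella-lcs"`
#' @return object of class `marker_set`
#' @export
marker_set <- function(coords, labels = NULL, frame = "ct") {
  coords <- as_matrix3(coords, "coords")
  if (nrow(coords) < 1) stop("a marker set needs at least one marker")
  stopifnot_finite(coords, "coords")
  if (is.null(labels)) labels <- paste0("M", seq_len(nrow(coords)))
  if (length(labels) != nrow(coords)) stop("one label per marker required")
  frame <- match.arg(frame, MARKER_FRAMES)
  structure(list(coords = coords, labels = as.character(labels), frame = frame),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d markers in frame '%s'\n", nrow(x$coords), x$frame))
  invisible(x)
}

#' Number of markers in a marker set
#' @param markers a [marker_set()]
#' @return integer marker count
#' @export
n_markers <- function(markers) nrow(markers$coords)

#' Transform a marker set into another frame
#'
#' @param markers a [marker_set()]
#' @param transform a [rigid_transform()] mapping the current frame to `frame`
#' @param frame the frame tag of the result
#' @return a [marker_set()] in the new frame
#' @export
transform_markers <- function(markers, transform, frame) {
  marker_set(apply_transform(transform, markers$coords), markers$labels, frame)
}

#' Read markers from CSV
#'
#' Expects a header `label,x,y,z,frame`; coordinates in mm. All rows must
#' share one frame tag.
#'
#' @param path CSV file path
#' @return a [marker_set()]
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop(sprintf("marker file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z", "frame")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("parse error in %s: missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  for (cc in c("x", "y", "z")) {
    vals <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(vals)) {
      stop(sprintf("parse error in %s: non-numeric '%s' at row %d",
                   path, cc, which(is.na(vals))[1]))
    }
    df[[cc]] <- vals
  }
  fr <- unique(df$frame)
  if (length(fr) != 1) stop(sprintf("parse error in %s: mixed frame tags", path))
  marker_set(as.matrix(df[, c("x", "y", "z")]), df$label, fr)
}

#' Write markers to CSV
#'
#' @param markers a [marker_set()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_markers <- function(markers, path) {
  df <- data.frame(label = markers$labels,
                   x = markers$coords[, 1],
                   y = markers$coords[, 2],
                   z = markers$coords[, 3],
                   frame = markers$frame)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one frame of a TRC motion-capture file
#'
#' Minimal TRC reader: parses the standard two header blocks, the marker
#' name row and the X/Y/Z column row, and returns the marker coordinates
#' of one capture frame as a motion-capture-frame marker set. Units are
#' converted to mm when the header declares m.
#'
#' @param path TRC file path
#' @param frame_number capture frame to extract (default first)
#' @return a [marker_set()] with frame tag `"mocap"`
#' @export
read_trc <- function(path, frame_number = 1) {
  if (!file.exists(path)) stop(sprintf("TRC file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop(sprintf("parse error in %s: truncated TRC header", path))
  hdr_keys <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  units <- hdr_vals[match("Units", hdr_keys)]
  scale <- if (!is.na(units) && units == "m") 1000 else 1
  name_row <- strsplit(lines[4], "\t")[[1]]
  labels <- name_row[-(1:2)]
  labels <- labels[nzchar(labels)]
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (frame_number > length(data_lines)) {
    stop(sprintf("parse error in %s: frame %d beyond %d data rows",
                 path, frame_number, length(data_lines)))
  }
  vals <- suppressWarnings(as.numeric(strsplit(data_lines[frame_number], "\t")[[1]]))
  coords <- matrix(vals[2 + seq_len(3 * length(labels))], ncol = 3, byrow = TRUE)
  if (anyNA(coords)) {
    stop(sprintf("parse error in %s: non-numeric coordinate in frame %d",
                 path, frame_number))
  }
  marker_set(coords * scale, labels, "mocap")
}
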