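#' Localization table constructor
#'
#' The pipeline's primary container: one row per detected blink with nm
#' coordinates (origin top-left, y downward), acquisition frame,
#' intensity and channel label. ROI geometry and assay metadata (ROI id,
#' capture/detection configuration) travel as attributes.
#'
#' @param x_nm,y_nm coordinates in nm.
#' @param frame 1-based acquisition frame.
#' @param intensity photon count (optional information, constant by
#'   default in simulations).
#' @param channel channel label (non-empty string).
#' @param roi an [roi_geometry()].
#' @param roi_id,capture,detection assay metadata labels.
#' @return A data frame of class `loc_table`.
#' @export
loc_table <- function(x_nm, y_nm, frame, intensity = rep(1000, length(x_nm)),
                      channel = rep("ch640", length(x_nm)),
                      roi = roi_geometry(), roi_id = "roi1",
                      capture = NA_character_, detection = NA_character_) {
  stopifnot(inherits(roi, "roi_geometry"))
  n <- length(x_nm)
  if (length(y_nm) != n || length(frame) != n)
    stopf("x_nm, y_nm and frame must have equal length")
  if (n > 0 && (any(!nzchar(channel)) || anyNA(channel)))
    stopf("channel labels must be non-empty")
  if (n > 0 && any(frame < 1)) stopf("frame must be >= 1")
  df <- data.frame(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                   frame = as.integer(frame),
                   intensity = as.numeric(intensity),
                   channel = as.character(channel),
                   stringsAsFactors = FALSE)
  structure(df, roi = roi, roi_id = roi_id, capture = capture,
            detection = detection, class = c("loc_table", "data.frame"))
}

#' Read a localization table
#'
#' Reads delimited text in either the native dialect (header
#' `x_nm,y_nm,frame,intensity,channel`) or a ThunderSTORM-like dialect
#' (`x [nm]`, `y [nm]`, `frame`, optional `intensity [photon]`; no
#' channel column, so `channel` supplies the label). Unknown columns are
#' preserved. Rows whose coordinates violate the ROI bounds are counted,
#' reported via a message, dropped, and recorded in the `n_dropped_oob`
#' attribute.
#'
#' @param path file to read.
#' @param dialect `"native"` or `"thunderstorm"`.
#' @param roi an [roi_geometry()] used for bounds validation.
#' @param sep field separator.
#' @param channel default channel label when the file has none.
#' @param roi_id,capture,detection metadata attached to the table.
#' @return A `loc_table`.
#' @export
read_localizations <- function(path, dialect = c("native", "thunderstorm"),
                               roi = roi_geometry(), sep = ",",
                               channel = "ch640", roi_id = "roi1",
                               capture = NA_character_,
                               detection = NA_character_) {
  dialect <- match.arg(dialect)
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE, colClasses = "character")
  aliases <- if (dialect == "native") {
    c(x_nm = "x_nm", y_nm = "y_nm", frame = "frame",
      intensity = "intensity", channel = "channel")
  } else {
    c(x_nm = "x [nm]", y_nm = "y [nm]", frame = "frame",
      intensity = "intensity [photon]", channel = NA)
  }
  for (need in c("x_nm", "y_nm", "frame")) {
    if (!(aliases[[need]] %in% names(raw)))
      stopf("missing mandatory column '%s' for dialect '%s' in %s",
            aliases[[need]], dialect, path)
  }
  num <- function(field) {
    col <- raw[[aliases[[field]]]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is.na(col) & nzchar(col))
    if (length(bad))
      stopf("unparseable numeric in column '%s', row %d of %s",
            aliases[[field]], bad[1L], path)
    v
  }
  x <- num("x_nm"); y <- num("y_nm"); fr <- num("frame")
  inten <- if (!is.na(aliases[["intensity"]]) &&
               aliases[["intensity"]] %in% names(raw)) num("intensity")
           else rep(1000, nrow(raw))
  ch <- if (!is.na(aliases[["channel"]]) &&
            aliases[["channel"]] %in% names(raw)) raw[[aliases[["channel"]]]]
        else rep(channel, nrow(raw))

  keep <- x >= 0 & x <= roi$width_nm & y >= 0 & y <= roi$height_nm
  keep[is.na(keep)] <- FALSE
  ndrop <- sum(!keep)
  if (ndrop > 0)
    message(sprintf("read_localizations: dropped %d out-of-bounds row(s)",
                    ndrop))
  tab <- loc_table(x[keep], y[keep], fr[keep], inten[keep], ch[keep],
                   roi = roi, roi_id = roi_id, capture = capture,
                   detection = detection)
  known <- unname(aliases[!is.na(aliases)])
  extra <- setdiff(names(raw), known)
  for (nm in extra) tab[[nm]] <- raw[[nm]][keep]
  attr(tab, "n_dropped_oob") <- ndrop
  tab
}

#' Write a localization table
#'
#' Writes the native delimited dialect (`x_nm,y_nm,frame,intensity,
#' channel` plus any extra columns); [read_localizations()] on the result
#' round-trips the table.
#'
#' @param tab a `loc_table`.
#' @param path output file.
#' @param sep field separator.
#' @export
write_localizations <- function(tab, path, sep = ",") {
  utils::write.table(as.data.frame(tab), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a ground-truth sidecar table
#'
#' Flat version of a `particle_truth` (cargo positions serialized as a
#' `;`-separated `x:y` list) so simulator truth can live next to the
#' localization table as plain text.
#'
#' @param truth a `particle_truth`.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  flat <- as.data.frame(truth[setdiff(names(truth), "cargo")])
  flat$cargo <- vapply(truth$cargo, function(m) {
    paste(sprintf("%.3f:%.3f", m[, 1L], m[, 2L]), collapse = ";")
  }, character(1))
  utils::write.table(flat, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth sidecar table
#'
#' @param path file written by [write_truth()].
#' @param roi the [roi_geometry()] to attach.
#' @return A `particle_truth`.
#' @export
read_truth <- function(path, roi = roi_geometry()) {
  flat <- read.csv(path, stringsAsFactors = FALSE)
  cargo <- lapply(flat$cargo, function(s) {
    if (is.na(s) || !nzchar(s))
      return(matrix(numeric(0), 0L, 2L,
                    dimnames = list(NULL, c("x_nm", "y_nm"))))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    m <- do.call(rbind, lapply(parts, as.numeric))
    colnames(m) <- c("x_nm", "y_nm")
    m
  })
  flat$cargo <- NULL
  flat$cargo <- cargo
  attr(flat, "roi") <- roi
  class(flat) <- c("particle_truth", "data.frame")
  flat
}

#' Intensity image container
#'
#' A normalized single-plane image (rows = y, image convention) with its
#' pixel size and channel label.
#'
#' @param mat numeric matrix.
#' @param pixel_size_nm pixel pitch in nm.
#' @param channel channel label.
#' @return An `intensity_image`.
#' @export
intensity_image <- function(mat, pixel_size_nm, channel = "ch561") {
  stopifnot(is.matrix(mat), is.numeric(mat))
  structure(mat, pixel_size_nm = pixel_size_nm, channel = channel,
            class = c("intensity_image", class(mat)))
}
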