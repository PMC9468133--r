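#' Read and write landmark tables
#'
#' The interchange format is a plain CSV with header
#' `individual_id,fdi_code,kind,index,x_mm,y_mm,z_mm` (`kind` is `crown` or
#' `root`, coordinates in millimeters, '.' decimal separator). Writing is
#' deterministic: rows sorted by `individual_id`, then canonical label order,
#' coordinates at 4 decimal places (0.1 um, ample versus scan accuracy), so
#' write/read round-trips a dataset exactly at that precision.
#'
#' @param source file path or data frame with the columns above.
#' @param protocol protocol the table must conform to.
#' @return A [dentition_dataset()].
#' @export
read_landmark_table <- function(source, protocol = default_protocol()) {
  df <- if (is.character(source)) {
    utils::read.csv(source, stringsAsFactors = FALSE)
  } else {
    as.data.frame(source, stringsAsFactors = FALSE)
  }
  need <- c("individual_id", "fdi_code", "kind", "index", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop("landmark table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rowno <- seq_len(nrow(df))
  bad_fdi <- !(df$fdi_code %in% FDI_CODES)
  if (any(bad_fdi)) {
    stop(sprintf("row %d: invalid FDI code %s (wisdom teeth and codes outside 11-47 excluded)",
                 rowno[bad_fdi][1L], df$fdi_code[bad_fdi][1L]), call. = FALSE)
  }
  bad_kind <- !(df$kind %in% c("crown", "root"))
  if (any(bad_kind)) {
    stop(sprintf("row %d: kind must be 'crown' or 'root', got '%s'",
                 rowno[bad_kind][1L], df$kind[bad_kind][1L]), call. = FALSE)
  }
  df$label <- sprintf("%d_%s_%d", as.integer(df$fdi_code), df$kind,
                      as.integer(df$index))
  bad_lab <- !(df$label %in% protocol$labels$label)
  if (any(bad_lab)) {
    stop(sprintf("row %d: label '%s' not in protocol (index out of range?)",
                 rowno[bad_lab][1L], df$label[bad_lab][1L]), call. = FALSE)
  }
  key <- paste(df$individual_id, df$label)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("row %d: duplicate landmark '%s' for individual '%s'",
                 d, df$label[d], df$individual_id[d]), call. = FALSE)
  }
  for (cc in c("x_mm", "y_mm", "z_mm")) {
    if (!is.numeric(df[[cc]])) stop("column ", cc, " must be numeric", call. = FALSE)
  }
  ids <- unique(df$individual_id)
  individuals <- lapply(ids, function(id) {
    sub <- df[df$individual_id == id, , drop = FALSE]
    m <- as.matrix(sub[, c("x_mm", "y_mm", "z_mm")])
    rownames(m) <- sub$label
    dentition_landmarks(as.character(id), m, protocol)
  })
  dentition_dataset(individuals)
}

#' @rdname read_landmark_table
#' @param dataset a [dentition_dataset()].
#' @param sink file path (or `""` for stdout).
#' @param digits decimal places for coordinates.
#' @export
write_landmark_table <- function(dataset, sink, digits = 4L) {
  stopifnot(inherits(dataset, "dentition_dataset"))
  lab <- dataset$protocol$labels
  ids <- sort(names(dataset$individuals))
  rows <- lapply(ids, function(id) {
    d <- dataset$individuals[[id]]
    present <- lab[lab$label %in% rownames(d$points), , drop = FALSE]
    p <- d$points[present$label, , drop = FALSE]
    data.frame(
      individual_id = id,
      fdi_code = present$fdi,
      kind = present$kind,
      index = present$index,
      x_mm = round(p[, 1L], digits),
      y_mm = round(p[, 2L], digits),
      z_mm = round(p[, 3L], digits),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, sink, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Import 3D Slicer fiducial markups as one dentition
#'
#' Reads a Slicer fiducial file — legacy `.fcsv` or markups `.mrk.json` /
#' `.json` — in which each fiducial label encodes a protocol landmark as
#' `<fdi>_<kind>_<index>` (e.g. `24_root_3`). Coordinates are taken as
#' stored (mm); no RAS/LPS conversion is applied.
#'
#' @param path file path.
#' @param individual_id id for the resulting configuration.
#' @param protocol landmark protocol.
#' @return A [dentition_landmarks()].
#' @export
read_slicer_fiducials <- function(path, individual_id,
                                  protocol = default_protocol()) {
  if (grepl("\\.fcsv$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines)]
    if (!length(lines)) stop("no fiducial rows in ", path, call. = FALSE)
    parts <- strsplit(lines, ",", fixed = TRUE)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    labels <- vapply(parts, function(p) p[[12L]], character(1))
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = FALSE)
    cps <- unlist(lapply(j$markups, function(m) m$controlPoints),
                  recursive = FALSE)
    if (!length(cps)) stop("no control points in ", path, call. = FALSE)
    coords <- t(vapply(cps, function(cp) as.numeric(unlist(cp$position)),
                       numeric(3)))
    labels <- vapply(cps, function(cp) cp$label, character(1))
  } else {
    stop("unrecognized fiducial file type: ", path, call. = FALSE)
  }
  if (!all(grepl("^[0-9]{2}_(crown|root)_[0-9]+$", labels))) {
    bad <- labels[!grepl("^[0-9]{2}_(crown|root)_[0-9]+$", labels)][1L]
    stop("fiducial label not of form <fdi>_<kind>_<index>: '", bad, "'",
         call. = FALSE)
  }
  rownames(coords) <- labels
  dentition_landmarks(individual_id, coords, protocol)
}
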