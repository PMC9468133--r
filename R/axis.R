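#' Fit the idealized tooth axis through root-canal landmarks
#'
#' The tooth axis is the 3D least-squares line through the root landmarks
#' LM-1..LM-4 (root-canal centers from the CEJL down to 6 mm apically). The
#' line minimizes the sum of squared *orthogonal* distances (total least
#' squares): it passes through the centroid of the points with direction
#' equal to their dominant principal direction. An orthogonal fit is used
#' because a tooth axis must not depend on an arbitrary coordinate-axis
#' choice. Using four landmarks averages out placement error in any single
#' one. The direction is oriented coronal -> apical (from the LM-1 side
#' toward the LM-4 side). LM-5 (root apex) is deliberately not part of the
#' fit.
#'
#' @param root_points numeric 4x3 matrix: LM-1..LM-4 in order, mm.
#' @return An object of class `tooth_axis`: list with `anchor` (centroid,
#'   mm), `direction` (unit 3-vector), and `residual` (sum of squared
#'   orthogonal distances, mm^2).
#' @examples
#' p <- cbind(0, 0, c(0, 2, 4, 6))
#' fit_tooth_axis(p)   # anchor (0,0,3), direction (0,0,1)
#' @export
fit_tooth_axis <- function(root_points) {
  p <- as.matrix(root_points)
  if (nrow(p) != 4L || ncol(p) != 3L) {
    stop("root_points must be a 4x3 matrix (LM-1..LM-4)", call. = FALSE)
  }
  if (!all(is.finite(p))) stop("root_points must be finite", call. = FALSE)
  ctr <- colMeans(p)
  x <- sweep(p, 2L, ctr)
  s <- svd(x)
  if (s$d[1L] < 1e-9) {
    stop("degenerate axis: all four root landmarks coincide", call. = FALSE)
  }
  dir <- s$v[, 1L]
  # orient coronal (LM-1) -> apical (LM-4)
  if (sum(dir * (p[4L, ] - p[1L, ])) < 0) dir <- -dir
  structure(
    list(anchor = unname(ctr), direction = unname(dir),
         residual = sum(s$d[-1L]^2)),
    class = "tooth_axis"
  )
}

#' @export
print.tooth_axis <- function(x, ...) {
  cat(sprintf("Tooth axis: anchor (%.2f, %.2f, %.2f) mm, direction (%.3f, %.3f, %.3f)\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Undirected angle between two tooth axes
#'
#' Axes are undirected lines, so the angle is
#' `acos(|<a, b>|)` in degrees, clipped into \[0, 90\]; antiparallel
#' directions give 0.
#'
#' @param a,b `tooth_axis` objects (or unit 3-vectors).
#' @return Angle in degrees in \[0, 90\].
#' @export
angle_between_axes <- function(a, b) {
  da <- if (inherits(a, "tooth_axis")) a$direction else as.numeric(a)
  db <- if (inherits(b, "tooth_axis")) b$direction else as.numeric(b)
  for (d in list(da, db)) {
    if (abs(sqrt(sum(d^2)) - 1) > 1e-6) {
      stop("axis direction is not a unit vector", call. = FALSE)
    }
  }
  # atan2 of the cross/dot magnitudes: identical to acos(|<a,b>|) but
  # numerically exact near 0 and 90 degrees
  cr <- c(da[2L] * db[3L] - da[3L] * db[2L],
          da[3L] * db[1L] - da[1L] * db[3L],
          da[1L] * db[2L] - da[2L] * db[1L])
  min(90, atan2(sqrt(sum(cr^2)), abs(sum(da * db))) * 180 / pi)
}

#' Shortest distance from a point to a tooth axis
#'
#' Euclidean distance from `p` to the infinite line; zero iff `p` lies on
#' the line.
#'
#' @param p numeric 3-vector, mm.
#' @param axis a `tooth_axis`.
#' @return Distance in mm.
#' @export
point_to_axis_distance <- function(p, axis) {
  stopifnot(inherits(axis, "tooth_axis"))
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop("p must be a finite 3-vector", call. = FALSE)
  }
  v <- p - axis$anchor
  sqrt(max(0, sum(v^2) - sum(v * axis$direction)^2))
}

#' Accuracy of a predicted tooth axis against the actual one
#'
#' The three evaluation measures of axis-prediction accuracy:
#' * **angle alpha** — undirected angle between the axis fitted to the
#'   predicted LM-1..LM-4 and the axis fitted to the actual ones (degrees);
#' * **distance A** — shortest distance from the *predicted* LM-1 (CEJL
#'   level) to the *actual* axis (mm), i.e. the cervical offset;
#' * **distance B** — shortest distance from the predicted LM-4 (apical
#'   third) to the actual axis (mm).
#'
#' @param predicted_root,actual_root 4x3 matrices of LM-1..LM-4 for the same
#'   tooth, mm.
#' @return List of class `axis_errors` with `angle_deg`, `distance_A_mm`,
#'   `distance_B_mm`.
#' @export
axis_errors <- function(predicted_root, actual_root) {
  pred_axis <- fit_tooth_axis(predicted_root)
  act_axis <- fit_tooth_axis(actual_root)
  structure(
    list(
      angle_deg = angle_between_axes(pred_axis, act_axis),
      distance_A_mm = point_to_axis_distance(predicted_root[1L, ], act_axis),
      distance_B_mm = point_to_axis_distance(predicted_root[4L, ], act_axis)
    ),
    class = "axis_errors"
  )
}

#' Extract fitted tooth axes of a dentition
#'
#' Fits [fit_tooth_axis()] on LM-1..LM-4 of every tooth whose four canal
#' landmarks are present.
#'
#' @param dentition a [dentition_landmarks()].
#' @param teeth optional FDI codes to restrict to.
#' @return Named list (by FDI code) of `tooth_axis` objects; class
#'   `tooth_axes`.
#' @export
tooth_axes <- function(dentition, teeth = NULL) {
  lab <- dentition$protocol$labels
  fdis <- unique(lab$fdi)
  if (!is.null(teeth)) fdis <- intersect(fdis, check_fdi(teeth))
  axes <- list()
  for (fdi in fdis) {
    want <- sprintf("%d_root_%d", fdi, 1:4)
    if (all(want %in% rownames(dentition$points))) {
      axes[[as.character(fdi)]] <- fit_tooth_axis(
        dentition$points[want, , drop = FALSE])
    }
  }
  structure(axes, class = "tooth_axes")
}

#' @export
as.data.frame.tooth_axes <- function(x, ..., individual_id = NA_character_) {
  if (!length(x)) {
    return(data.frame(individual_id = character(), fdi_code = integer(),
                      anchor_x = numeric(), anchor_y = numeric(),
                      anchor_z = numeric(), dir_x = numeric(),
                      dir_y = numeric(), dir_z = numeric()))
  }
  do.call(rbind, lapply(names(x), function(fdi) {
    ax <- x[[fdi]]
    data.frame(individual_id = individual_id, fdi_code = as.integer(fdi),
               anchor_x = ax$anchor[1], anchor_y = ax$anchor[2],
               anchor_z = ax$anchor[3], dir_x = ax$direction[1],
               dir_y = ax$direction[2], dir_z = ax$direction[3])
  }))
}

#' @export
print.tooth_axes <- function(x, ...) {
  cat(sprintf("Tooth axes for %d teeth (coronal->apical unit directions)\n",
              length(x)))
  invisible(x)
}

#' Write fitted axes as CSV
#'
#' Columns: `individual_id,fdi_code,anchor_x,anchor_y,anchor_z,dir_x,dir_y,dir_z`
#' (mm; unit direction, coronal to apical).
#'
#' @param axes a `tooth_axes` object.
#' @param sink file path.
#' @param individual_id id recorded in the table.
#' @export
write_axis_table <- function(axes, sink, individual_id = "case") {
  df <- as.data.frame(axes, individual_id = individual_id)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "fdi_code"
  df[num] <- lapply(df[num], function(v) round(v, 6))
  utils::write.csv(df, sink, row.names = FALSE, quote = FALSE)
  invisible(df)
}
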