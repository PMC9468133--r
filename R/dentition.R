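#' Labeled 3D landmark configuration of one dentition
#'
#' A `dentition_landmarks` object holds one individual's labeled landmark
#' coordinates in millimeters. A configuration is *complete* when it carries
#' every label of its protocol (270 under the default protocol) and *partial*
#' otherwise (e.g. crowns only, or with one tooth absent). Partial
#' configurations are first-class: all downstream operations work on label
#' subsets.
#'
#' @param individual_id character scalar, unique within a dataset.
#' @param points numeric matrix, one row per landmark, 3 columns (x, y, z in
#'   mm); rownames must be protocol labels. Rows are reordered to canonical
#'   protocol order.
#' @param protocol a [landmark_protocol][default_protocol].
#' @return An object of class `dentition_landmarks`.
#' @export
dentition_landmarks <- function(individual_id, points,
                                protocol = default_protocol()) {
  stopifnot(is.character(individual_id), length(individual_id) == 1L,
            inherits(protocol, "landmark_protocol"))
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns (x, y, z)", call. = FALSE)
  if (is.null(rownames(points))) stop("points must have landmark labels as rownames", call. = FALSE)
  unknown <- setdiff(rownames(points), protocol$labels$label)
  if (length(unknown)) {
    stop("labels not in protocol: ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(points))) {
    stop("duplicate landmark labels in points", call. = FALSE)
  }
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  # canonical order
  ord <- protocol$labels$label[protocol$labels$label %in% rownames(points)]
  points <- points[ord, , drop = FALSE]
  structure(
    list(individual_id = individual_id, points = points, protocol = protocol),
    class = "dentition_landmarks"
  )
}

#' @export
print.dentition_landmarks <- function(x, ...) {
  n_total <- nrow(x$protocol$labels)
  cat(sprintf("Dentition landmarks '%s': %d of %d protocol landmarks%s\n",
              x$individual_id, nrow(x$points), n_total,
              if (nrow(x$points) == n_total) " (complete)" else " (partial)"))
  invisible(x)
}

#' Validate a dentition against its protocol
#'
#' Violations are returned as data, not raised: unknown labels (cannot occur
#' for objects built by [dentition_landmarks()] but can for hand-made ones),
#' non-finite coordinates, and — informationally — teeth that are absent or
#' only partially covered.
#'
#' @param dentition a `dentition_landmarks`.
#' @param protocol protocol to check against (defaults to the dentition's own).
#' @return Data frame with columns `type` (`"unknown_label"`,
#'   `"nonfinite_coordinate"`, `"tooth_absent"`, `"tooth_partial"`),
#'   `label` (or FDI code) and `message`. Zero rows for a clean complete
#'   configuration; absent/partial teeth are informational rows.
#' @export
validate_dentition <- function(dentition, protocol = dentition$protocol) {
  stopifnot(inherits(dentition, "dentition_landmarks"))
  out <- list()
  present <- rownames(dentition$points)
  unknown <- setdiff(present, protocol$labels$label)
  for (u in unknown) {
    out[[length(out) + 1L]] <- data.frame(
      type = "unknown_label", label = u,
      message = sprintf("label '%s' not in protocol", u))
  }
  bad <- present[!apply(is.finite(dentition$points), 1L, all)]
  for (b in setdiff(bad, unknown)) {
    out[[length(out) + 1L]] <- data.frame(
      type = "nonfinite_coordinate", label = b,
      message = sprintf("non-finite coordinate at '%s'", b))
  }
  for (fdi in unique(protocol$labels$fdi)) {
    want <- protocol$labels$label[protocol$labels$fdi == fdi]
    have <- sum(want %in% present)
    if (have == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        type = "tooth_absent", label = as.character(fdi),
        message = sprintf("tooth %d: no landmarks present", fdi))
    } else if (have < length(want)) {
      out[[length(out) + 1L]] <- data.frame(
        type = "tooth_partial", label = as.character(fdi),
        message = sprintf("tooth %d: %d of %d landmarks present",
                          fdi, have, length(want)))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(type = character(), label = character(), message = character())
}

#' Flatten / unflatten landmark configurations
#'
#' `to_vector()` concatenates coordinates (x, y, z per landmark) in canonical
#' label order restricted to `labels`; `from_vector()` is its inverse.
#'
#' @param dentition a `dentition_landmarks`.
#' @param labels ordered label subset; defaults to all labels present.
#' @return `to_vector()`: numeric vector of length `3 * length(labels)`;
#'   `from_vector()`: a `dentition_landmarks`.
#' @export
to_vector <- function(dentition, labels = rownames(dentition$points)) {
  missing <- setdiff(labels, rownames(dentition$points))
  if (length(missing)) {
    stop("landmark(s) absent from configuration: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  as.vector(t(dentition$points[labels, , drop = FALSE]))
}

#' @rdname to_vector
#' @param v numeric vector, length `3 * length(labels)`.
#' @param individual_id id for the rebuilt configuration.
#' @param protocol protocol of the rebuilt configuration.
#' @export
from_vector <- function(v, labels, individual_id = "reconstructed",
                        protocol = default_protocol()) {
  stopifnot(length(v) == 3L * length(labels))
  m <- matrix(v, ncol = 3L, byrow = TRUE,
              dimnames = list(labels, c("x", "y", "z")))
  dentition_landmarks(individual_id, m, protocol)
}

#' Remove a tooth's landmarks, or all root landmarks
#'
#' `drop_tooth()` removes every crown and root landmark of one tooth —
#' emulating a missing tooth on a scan. `crowns_only()` keeps only crown
#' landmarks — the information an intraoral or plaster-cast scan provides.
#' Both return modified copies.
#'
#' @param dentition a `dentition_landmarks`.
#' @param tooth two-digit FDI code.
#' @return A `dentition_landmarks` with the corresponding labels removed.
#' @export
drop_tooth <- function(dentition, tooth) {
  check_fdi(tooth)
  lab <- dentition$protocol$labels
  if (!tooth %in% lab$fdi) stop("tooth ", tooth, " not in protocol", call. = FALSE)
  drop <- lab$label[lab$fdi == as.integer(tooth)]
  keep <- setdiff(rownames(dentition$points), drop)
  dentition$points <- dentition$points[keep, , drop = FALSE]
  dentition
}

#' @rdname drop_tooth
#' @export
crowns_only <- function(dentition) {
  lab <- dentition$protocol$labels
  keep <- intersect(rownames(dentition$points),
                    lab$label[lab$kind == "crown"])
  dentition$points <- dentition$points[keep, , drop = FALSE]
  dentition
}

#' An ordered collection of dentitions sharing one protocol
#'
#' @param individuals list of [dentition_landmarks()] objects with unique ids
#'   and identical protocols.
#' @param metadata free-form named list.
#' @return An object of class `dentition_dataset`.
#' @export
dentition_dataset <- function(individuals, metadata = list()) {
  stopifnot(is.list(individuals), length(individuals) >= 1L)
  ok <- vapply(individuals, inherits, logical(1), "dentition_landmarks")
  if (!all(ok)) stop("all individuals must be dentition_landmarks", call. = FALSE)
  ids <- vapply(individuals, function(d) d$individual_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate individual_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  proto <- individuals[[1L]]$protocol
  for (d in individuals[-1L]) {
    if (!same_protocol(proto, d$protocol)) {
      stop("individuals do not share one protocol", call. = FALSE)
    }
  }
  names(individuals) <- ids
  structure(
    list(individuals = individuals, protocol = proto, metadata = metadata),
    class = "dentition_dataset"
  )
}

#' @export
print.dentition_dataset <- function(x, ...) {
  n_lm <- sum(vapply(x$individuals, function(d) nrow(d$points), integer(1)))
  cat(sprintf("Dentition dataset: %d individuals, %d landmarks total\n",
              length(x$individuals), n_lm))
  invisible(x)
}

#' @export
length.dentition_dataset <- function(x) length(x$individuals)

#' @export
`[.dentition_dataset` <- function(x, i) {
  dentition_dataset(x$individuals[i], x$metadata)
}
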