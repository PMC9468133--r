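#' @keywords internal
"_PACKAGE"

# Valid FDI codes: quadrants 1-4, positions 1-7 (no third molars).
FDI_CODES <- as.integer(c(11:17, 21:27, 31:37, 41:47))

# position-from-midline -> morphological class
TOOTH_CLASSES <- c("incisor", "incisor", "canine", "premolar", "premolar",
                   "molar", "molar")

#' Jaw, position, quadrant and class of an FDI tooth code
#'
#' Helpers for the two-digit FDI (Federation Dentaire Internationale) tooth
#' notation: the first digit is the quadrant (1 upper right, 2 upper left,
#' 3 lower left, 4 lower right), the second the position from the midline
#' (1 central incisor .. 7 second molar). Third molars (position 8) are not
#' part of the supported dentition.
#'
#' @param fdi integer vector of two-digit FDI codes.
#' @return `fdi_jaw()`: `"upper"` or `"lower"`; `fdi_position()` /
#'   `fdi_quadrant()`: integers; `tooth_class()`: one of `"incisor"`,
#'   `"canine"`, `"premolar"`, `"molar"`.
#' @examples
#' fdi_jaw(36)        # "lower"
#' tooth_class(13)    # "canine"
#' @export
fdi_jaw <- function(fdi) {
  check_fdi(fdi)
  ifelse(fdi %/% 10L <= 2L, "upper", "lower")
}

#' @rdname fdi_jaw
#' @export
fdi_position <- function(fdi) {
  check_fdi(fdi)
  fdi %% 10L
}

#' @rdname fdi_jaw
#' @export
fdi_quadrant <- function(fdi) {
  check_fdi(fdi)
  fdi %/% 10L
}

#' @rdname fdi_jaw
#' @export
tooth_class <- function(fdi) {
  check_fdi(fdi)
  TOOTH_CLASSES[fdi %% 10L]
}

check_fdi <- function(fdi) {
  fdi <- as.integer(fdi)
  bad <- setdiff(fdi, FDI_CODES)
  if (length(bad)) {
    stop("invalid FDI tooth code(s): ", paste(bad, collapse = ", "),
         " (valid: quadrants 1-4, positions 1-7)", call. = FALSE)
  }
  invisible(fdi)
}

# Default crown landmark allocation per quadrant position. Crown landmarks
# sit on cusp tips, incisal edges and central fissures; lower first molars
# carry an extra (distobuccal) cusp, lower central incisors an extra edge
# point, so the jaws differ. Sums: upper 62, lower 68, total 130.
.default_crown_counts <- function() {
  upper <- c(3L, 3L, 3L, 5L, 5L, 6L, 6L)
  lower <- c(4L, 3L, 3L, 5L, 5L, 7L, 7L)
  pos <- FDI_CODES %% 10L
  n <- ifelse(FDI_CODES %/% 10L <= 2L, upper[pos], lower[pos])
  names(n) <- as.character(FDI_CODES)
  n
}

#' The default dentition landmark protocol
#'
#' A landmark protocol names every landmark of a 28-tooth dentition and fixes
#' their canonical ordering. Each tooth carries a class-dependent number of
#' crown landmarks (placed on cusps, incisal edges and central fissures of a
#' surface scan) and exactly five root landmarks taken from CBCT: LM-1 in the
#' root-canal center at the level of the cemento-enamel junction line (CEJL),
#' LM-2..LM-4 each 2 mm further apically along the canal, and LM-5 at the
#' root apex. Multi-rooted teeth are treated as one merged root.
#'
#' The default allocation yields 130 crown + 140 root = 270 landmarks per
#' individual. Labels are strings `<fdi>_<kind>_<index>` (e.g. `"11_crown_1"`,
#' `"36_root_4"`); the canonical order is by ascending FDI code, crown
#' landmarks before root landmarks, index ascending. This order is
#' deterministic and identical across sessions.
#'
#' @param crown_counts optional named integer vector (names = FDI codes)
#'   overriding the per-tooth crown landmark counts.
#' @return An object of class `landmark_protocol`: a list with
#'   `crown_counts`, `root_count` (always 5) and `labels`, a data frame with
#'   columns `fdi`, `kind`, `index`, `jaw`, `label` in canonical order.
#' @examples
#' p <- default_protocol()
#' nrow(p$labels)                     # 270
#' sum(p$crown_counts)                # 130
#' head(protocol_labels(p, jaw = "upper"))
#' @export
default_protocol <- function(crown_counts = NULL) {
  counts <- .default_crown_counts()
  if (!is.null(crown_counts)) {
    if (is.null(names(crown_counts))) {
      stop("crown_counts must be named by FDI code", call. = FALSE)
    }
    check_fdi(as.integer(names(crown_counts)))
    if (any(crown_counts < 1L)) stop("crown counts must be positive", call. = FALSE)
    counts[names(crown_counts)] <- as.integer(crown_counts)
  }
  rows <- lapply(FDI_CODES, function(fdi) {
    nc <- counts[[as.character(fdi)]]
    data.frame(
      fdi = fdi,
      kind = c(rep("crown", nc), rep("root", 5L)),
      index = c(seq_len(nc), 1:5),
      stringsAsFactors = FALSE
    )
  })
  labels <- do.call(rbind, rows)
  labels$jaw <- ifelse(labels$fdi %/% 10L <= 2L, "upper", "lower")
  labels$label <- sprintf("%d_%s_%d", labels$fdi, labels$kind, labels$index)
  structure(
    list(crown_counts = counts, root_count = 5L, labels = labels),
    class = "landmark_protocol"
  )
}

#' Landmark labels of a protocol, optionally filtered
#'
#' @param protocol a `landmark_protocol`.
#' @param jaw optional `"upper"` or `"lower"`.
#' @param kind optional `"crown"` or `"root"`.
#' @param teeth optional vector of FDI codes.
#' @return Character vector of labels in canonical protocol order.
#' @export
protocol_labels <- function(protocol, jaw = NULL, kind = NULL, teeth = NULL) {
  stopifnot(inherits(protocol, "landmark_protocol"))
  lab <- protocol$labels
  keep <- rep(TRUE, nrow(lab))
  if (!is.null(jaw)) {
    jaw <- match.arg(jaw, c("upper", "lower"))
    keep <- keep & lab$jaw == jaw
  }
  if (!is.null(kind)) {
    kind <- match.arg(kind, c("crown", "root"))
    keep <- keep & lab$kind == kind
  }
  if (!is.null(teeth)) {
    check_fdi(teeth)
    keep <- keep & lab$fdi %in% as.integer(teeth)
  }
  lab$label[keep]
}

#' @export
print.landmark_protocol <- function(x, ...) {
  cat("Dentition landmark protocol\n")
  cat(sprintf("  teeth: %d (FDI 11-17, 21-27, 31-37, 41-47)\n",
              length(x$crown_counts)))
  cat(sprintf("  crown landmarks: %d   root landmarks: %d   total: %d\n",
              sum(x$crown_counts),
              length(x$crown_counts) * x$root_count,
              nrow(x$labels)))
  invisible(x)
}

# identity check used by dataset constructors: same labels in same order
same_protocol <- function(a, b) {
  identical(a$labels$label, b$labels$label)
}

#' Screening arithmetic of a study cohort
#'
#' Bookkeeping helper for a screening flowchart: the number of included cases
#' is the number screened minus all exclusions.
#'
#' @param n_screened integer, cases screened.
#' @param exclusions integer vector (optionally named by reason).
#' @return list with `screened`, `excluded` (total), `included`.
#' @examples
#' cohort_inclusion(230, c(cbct = 49, casts = 42, alignment = 18, premolars = 50))
#' @export
cohort_inclusion <- function(n_screened, exclusions) {
  stopifnot(n_screened >= 0, all(exclusions >= 0))
  excl <- sum(exclusions)
  if (excl > n_screened) stop("more exclusions than screened cases", call. = FALSE)
  list(screened = as.integer(n_screened),
       excluded = as.integer(excl),
       included = as.integer(n_screened - excl))
}
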