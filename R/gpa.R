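#' Rigid transforms in 3D
#'
#' A `rigid_transform` is a proper rotation `R` (3x3, det +1) plus a
#' translation `t` (mm), acting on row-vector points as `x %*% R + t`.
#' There is no scale component: jaw size is anatomical information and is
#' never normalized away in this package.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric 3-vector.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix of points (rows).
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  pts <- as.matrix(points)
  sweep(pts %*% transform$rotation, 2L, -transform$translation)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(transform$translation %*% Rt))
}

#' @rdname rigid_transform
#' @param a,b transforms; the composition applies `a` first, then `b`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$translation %*% b$rotation) + b$translation)
}

# Kabsch: proper rotation R and translation t minimizing ||X R + t - Y||_F,
# reflections forbidden. X, Y are n x 3 with matched rows.
kabsch <- function(X, Y) {
  cx <- colMeans(X)
  cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2L, cx), sweep(Y, 2L, cy))
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rigid_transform(R, cy - as.numeric(cx %*% R))
}

#' Centroid size of a landmark configuration
#'
#' Root-sum-of-squares of landmark distances to their centroid — the scale
#' quantity that the alignment here preserves.
#'
#' @param points n x 3 matrix.
#' @return Numeric scalar, mm.
#' @export
centroid_size <- function(points) {
  pts <- as.matrix(points)
  sqrt(sum(sweep(pts, 2L, colMeans(pts))^2))
}

#' Generalized Procrustes alignment without scaling
#'
#' Aligns complete same-jaw configurations of a dataset into a common
#' coordinate frame by removing translation and rotation only. Scale is
#' deliberately retained: a large jaw is not assumed to be a magnification
#' of a small one, so each aligned configuration keeps its original
#' centroid size. The algorithm is the standard iteration — center each
#' configuration, rotate it onto the running mean (Kabsch, reflections
#' forbidden), update the mean — initialized from the first individual and
#' run until the mean shape moves less than `tol` (RMS, mm) or `max_iter`
#' iterations.
#'
#' @param dataset a [dentition_dataset()]; every individual must carry all
#'   landmarks of the requested jaw.
#' @param jaw `"upper"` or `"lower"`.
#' @param tol convergence tolerance on the RMS change of the mean shape, mm.
#' @param max_iter iteration cap.
#' @return List of class `gpa_alignment`: `aligned` (named list of K x 3
#'   matrices), `mean` (K x 3), `transforms` (named list of
#'   [rigid_transform()] mapping each original configuration into the common
#'   frame), `labels`, `jaw`, `iterations`.
#' @export
gpa_align <- function(dataset, jaw = c("upper", "lower"),
                      tol = 1e-7, max_iter = 100L) {
  stopifnot(inherits(dataset, "dentition_dataset"))
  jaw <- match.arg(jaw)
  if (length(dataset$individuals) < 2L) {
    stop("alignment needs at least 2 individuals", call. = FALSE)
  }
  labels <- protocol_labels(dataset$protocol, jaw = jaw)
  configs <- lapply(dataset$individuals, function(d) {
    missing <- setdiff(labels, rownames(d$points))
    if (length(missing)) {
      stop(sprintf("individual '%s' is incomplete for the %s jaw (%d landmarks missing)",
                   d$individual_id, jaw, length(missing)), call. = FALSE)
    }
    d$points[labels, , drop = FALSE]
  })
  for (id in names(configs)) {
    if (svd(sweep(configs[[id]], 2L, colMeans(configs[[id]])))$d[2L] < 1e-9) {
      stop(sprintf("individual '%s': degenerate configuration (collinear or coincident landmarks)",
                   id), call. = FALSE)
    }
  }
  centroids <- lapply(configs, colMeans)
  centered <- Map(function(x, c) sweep(x, 2L, c), configs, centroids)
  rotations <- lapply(configs, function(x) diag(3))
  aligned <- centered
  mu <- aligned[[1L]]
  for (it in seq_len(max_iter)) {
    for (id in names(aligned)) {
      tf <- kabsch(centered[[id]], mu)
      rotations[[id]] <- tf$rotation
      aligned[[id]] <- centered[[id]] %*% tf$rotation
    }
    mu_new <- Reduce(`+`, aligned) / length(aligned)
    delta <- sqrt(mean((mu_new - mu)^2))
    mu <- mu_new
    if (delta < tol) break
  }
  transforms <- Map(function(R, c) {
    rigid_transform(R, -as.numeric(c %*% R))
  }, rotations, centroids)
  structure(
    list(aligned = aligned, mean = mu, transforms = transforms,
         labels = labels, jaw = jaw, iterations = it),
    class = "gpa_alignment"
  )
}

#' @export
print.gpa_alignment <- function(x, ...) {
  cat(sprintf("Procrustes alignment (%s jaw): %d configurations, %d landmarks, %d iterations\n",
              x$jaw, length(x$aligned), nrow(x$mean), x$iterations))
  invisible(x)
}
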