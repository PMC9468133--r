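#' Fit a statistical shape model of one jaw's dentition
#'
#' Builds a landmark-based statistical shape model (SSM): the training
#' configurations of one jaw are brought into a common frame by
#' generalized Procrustes alignment *without scaling* ([gpa_align()]),
#' and the aligned flat coordinate vectors are decomposed by principal
#' component analysis. The model is the mean configuration plus an
#' orthonormal basis of variation modes with their variances (sample
#' covariance, divisor n-1); the smallest number of leading modes whose
#' cumulative variance reaches `variance_fraction` is retained.
#'
#' Because crown and root landmarks enter one joint configuration, the
#' retained modes encode their spatial covariation — the property that lets
#' the model infer root position and axis from crown landmarks alone, for
#' dentate arches and for a missing tooth.
#'
#' @param data a [dentition_dataset()] with at least 2 individuals, each
#'   complete for `jaw`.
#' @param jaw `"upper"` or `"lower"`. Models are per jaw; fit one per jaw.
#' @param variance_fraction fraction of total variance to retain, in (0, 1].
#' @param tol,max_iter Procrustes convergence controls, passed to
#'   [gpa_align()].
#' @return An object of class `dental_ssm`: list with `mean` (flat 3K
#'   vector), `modes` (3K x m orthonormal), `variances` (length m,
#'   non-increasing), `scores` (n x m training scores), `labels`, `jaw`,
#'   `protocol`, `n_train`, `variance_fraction`, `total_variance`,
#'   `aligned` (training configurations in model frame), `gpa_iterations`.
#' @seealso [predict.dental_ssm()], [reconstruct_dentition()],
#'   [loocv_axes()]
#' @examples
#' pop <- benchmark_dataset("smoke")
#' m <- dental_ssm(pop$dataset, jaw = "upper")
#' summary(m)
#' @export
dental_ssm <- function(data, jaw = c("upper", "lower"),
                       variance_fraction = 0.98,
                       tol = 1e-7, max_iter = 100L) {
  stopifnot(inherits(data, "dentition_dataset"))
  jaw <- match.arg(jaw)
  if (!(variance_fraction > 0 && variance_fraction <= 1)) {
    stop("variance_fraction must be in (0, 1]", call. = FALSE)
  }
  if (length(data$individuals) < 2L) {
    stop("model training needs at least 2 individuals", call. = FALSE)
  }
  g <- gpa_align(data, jaw = jaw, tol = tol, max_iter = max_iter)
  X <- t(vapply(g$aligned, function(a) as.vector(t(a)),
                numeric(3L * nrow(g$mean))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  n <- nrow(X)
  s <- svd(Xc, nu = 0)
  variances <- s$d^2 / (n - 1)
  # numerical rank cut: modes carrying no variance are not modes; the
  # absolute floor (1e-9 mm)^2 is far below any landmark precision
  keep <- variances > max(variances[1L] * 1e-12, 1e-18)
  variances <- variances[keep]
  modes <- s$v[, keep, drop = FALSE]
  total_var <- sum(variances)
  m <- if (total_var == 0) 0L else {
    which(cumsum(variances) / total_var >= variance_fraction - 1e-12)[1L]
  }
  modes <- modes[, seq_len(m), drop = FALSE]
  variances <- variances[seq_len(m)]
  scores <- Xc %*% modes
  rownames(scores) <- names(g$aligned)
  structure(
    list(mean = mu, modes = modes, variances = variances, scores = scores,
         labels = g$labels, jaw = jaw, protocol = data$protocol,
         n_train = n, variance_fraction = variance_fraction,
         total_variance = total_var, aligned = g$aligned,
         gpa_iterations = g$iterations,
         call = match.call()),
    class = "dental_ssm"
  )
}

n_modes <- function(model) length(model$variances)

mean_config <- function(model) {
  matrix(model$mean, ncol = 3L, byrow = TRUE,
         dimnames = list(model$labels, c("x", "y", "z")))
}

#' @export
print.dental_ssm <- function(x, ...) {
  cat(sprintf("Dental shape model (%s jaw)\n", x$jaw))
  cat(sprintf("  landmarks: %d  training individuals: %d\n",
              length(x$labels), x$n_train))
  cat(sprintf("  modes retained: %d (%.1f%% of variance)\n", n_modes(x),
              if (x$total_variance > 0)
                100 * sum(x$variances) / x$total_variance else 100))
  invisible(x)
}

#' @export
summary.dental_ssm <- function(object, ...) {
  v <- object$variances
  tab <- data.frame(
    mode = seq_along(v),
    sd_mm = sqrt(v),
    variance = v,
    cumulative_fraction = if (object$total_variance > 0)
      cumsum(v) / object$total_variance else rep(1, length(v))
  )
  out <- list(jaw = object$jaw, n_train = object$n_train,
              n_landmarks = length(object$labels), modes = tab,
              variance_fraction = object$variance_fraction)
  class(out) <- "summary.dental_ssm"
  out
}

#' @export
print.summary.dental_ssm <- function(x, ...) {
  cat(sprintf("Dental shape model, %s jaw: %d landmarks, %d training shapes\n",
              x$jaw, x$n_landmarks, x$n_train))
  cat(sprintf("Retained %d modes (target variance fraction %.3f):\n",
              nrow(x$modes), x$variance_fraction))
  print(format(x$modes, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.dental_ssm <- function(object, ...) object$scores

#' @export
residuals.dental_ssm <- function(object, ...) {
  X <- t(vapply(object$aligned, function(a) as.vector(t(a)),
                numeric(length(object$mean))))
  Xc <- sweep(X, 2L, object$mean)
  R <- Xc - object$scores %*% t(object$modes)
  rownames(R) <- rownames(object$scores)
  R
}

#' Draw or construct shapes from a fitted model
#'
#' With `scores` given, returns the deterministic shape
#' `mean + modes %*% scores`; otherwise draws each mode score independently
#' from a centered normal with the model's per-mode variance.
#'
#' @param object a `dental_ssm`.
#' @param nsim number of shapes to draw.
#' @param seed optional integer seed (restores the RNG state afterwards as
#'   [stats::simulate()] methods do).
#' @param scores optional numeric vector (length = number of modes) or
#'   matrix (nsim x modes) of fixed mode scores.
#' @param ... unused.
#' @return List of [dentition_landmarks()], length `nsim`.
#' @export
simulate.dental_ssm <- function(object, nsim = 1, seed = NULL, scores = NULL,
                                ...) {
  m <- n_modes(object)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (is.null(scores)) {
    scores <- matrix(stats::rnorm(nsim * m), nsim, m) %*%
      diag(sqrt(object$variances), m)
  } else {
    scores <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1L)
    if (ncol(scores) != m) {
      stop(sprintf("scores must have %d columns (one per mode)", m),
           call. = FALSE)
    }
    nsim <- nrow(scores)
  }
  lapply(seq_len(nsim), function(i) {
    v <- object$mean + as.vector(object$modes %*% scores[i, ])
    from_vector(v, object$labels, individual_id = sprintf("sim_%d", i),
                protocol = object$protocol)
  })
}

#' Plot a dental shape model
#'
#' Occlusal-view (x-y) scatter of the mean configuration, crown landmarks
#' filled, root landmarks open; optionally overlays one mode of variation at
#' +/- `k` standard deviations.
#'
#' @param x a `dental_ssm`.
#' @param mode optional mode index to visualize.
#' @param k displacement in mode standard deviations.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the mean configuration matrix.
#' @export
plot.dental_ssm <- function(x, mode = NULL, k = 2, ...) {
  mu <- mean_config(x)
  kind <- x$protocol$labels$kind[match(x$labels, x$protocol$labels$label)]
  graphics::plot(mu[, 1L], mu[, 2L], asp = 1,
                 pch = ifelse(kind == "crown", 16, 1),
                 col = ifelse(kind == "crown", "grey20", "steelblue"),
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("Mean %s-jaw configuration", x$jaw), ...)
  if (!is.null(mode)) {
    stopifnot(mode >= 1, mode <= n_modes(x))
    for (s in c(-k, k)) {
      v <- x$mean + s * sqrt(x$variances[mode]) * x$modes[, mode]
      p <- matrix(v, ncol = 3L, byrow = TRUE)
      graphics::points(p[, 1L], p[, 2L], pch = 3,
                       col = if (s < 0) "firebrick" else "forestgreen")
    }
    graphics::legend("topright", bty = "n",
                     legend = sprintf("mode %d at %+g sd", mode, c(-k, k)),
                     pch = 3, col = c("firebrick", "forestgreen"))
  }
  invisible(mu)
}

#' Partial observation of a dentition
#'
#' The observed subset of a model's landmarks — typically the crown
#' landmarks of a surface scan, possibly with one tooth missing — in the
#' patient's own coordinate frame.
#'
#' @param dentition a [dentition_landmarks()] (any label subset).
#' @param model a `dental_ssm`; the observation keeps the intersection of
#'   the dentition's labels with the model's.
#' @return Object of class `partial_observation`: `labels`, `points`
#'   (k x 3).
#' @export
as_partial_observation <- function(dentition, model) {
  stopifnot(inherits(dentition, "dentition_landmarks"),
            inherits(model, "dental_ssm"))
  labels <- intersect(model$labels, rownames(dentition$points))
  if (length(labels) == 0L) {
    stop("observation shares no landmarks with the model", call. = FALSE)
  }
  structure(list(labels = labels,
                 points = dentition$points[labels, , drop = FALSE],
                 individual_id = dentition$individual_id),
            class = "partial_observation")
}

#' Pose a partial observation into model space
#'
#' Rigid (rotation + translation, never scaling) Procrustes fit of the
#' observed landmarks onto the corresponding mean-shape landmarks. Needs at
#' least 3 non-collinear observed landmarks; deterministic.
#'
#' @param model a `dental_ssm`.
#' @param obs a [as_partial_observation()] (or `dentition_landmarks`).
#' @return A [rigid_transform()] mapping observation coordinates into model
#'   space.
#' @export
align_partial <- function(model, obs) {
  if (inherits(obs, "dentition_landmarks")) obs <- as_partial_observation(obs, model)
  stopifnot(inherits(obs, "partial_observation"))
  if (length(obs$labels) < 3L) {
    stop("pose alignment needs at least 3 observed landmarks", call. = FALSE)
  }
  if (!all(is.finite(obs$points))) {
    stop("observed coordinates must be finite", call. = FALSE)
  }
  if (svd(sweep(obs$points, 2L, colMeans(obs$points)))$d[2L] < 1e-9) {
    stop("observed landmarks are collinear; pose is not identifiable",
         call. = FALSE)
  }
  target <- mean_config(model)[obs$labels, , drop = FALSE]
  kabsch(obs$points, target)
}

#' Reconstruct a full dentition from a partial observation
#'
#' The central inference of the package: given a fitted shape model and the
#' observed landmark subset of a new case (typically all crown landmarks, or
#' all crowns minus a missing tooth's), estimate every landmark of the jaw —
#' in particular the unobserved root landmarks.
#'
#' The observation is first posed into model space ([align_partial()]);
#' because that initial pose targets the mean shape, pose and scores are
#' then refined alternately (re-posing the observation onto the current
#' reconstruction) until the pose is stationary — a deterministic
#' coordinate descent whose fixed point reproduces noiseless in-model
#' observations exactly.
#' Mode scores are the posterior mean under the probabilistic-PCA
#' observation model `x_obs = mean_obs + M_obs s + e`, with `s ~ N(0,
#' diag(variances))` and isotropic landmark error `e ~ N(0, noise_sd^2 I)`:
#' `s* = (diag(1/variances) + M'M / sd^2)^-1 M'(x_obs - mean_obs) / sd^2`.
#' As `noise_sd -> 0` this tends to the unregularized projection; larger
#' values shrink toward the mean shape. The score vector is optionally
#' clamped so its Mahalanobis norm `sqrt(sum(s^2 / variances))` does not
#' exceed `max_mahalanobis` (default `3 * sqrt(m)`), keeping reconstructions
#' inside the plausible shape region. The full configuration
#' `mean + modes s*` is finally mapped back into the observation's original
#' frame.
#'
#' @param model a `dental_ssm`.
#' @param obs a [as_partial_observation()] or `dentition_landmarks`.
#' @param noise_sd_mm assumed isotropic landmark error, mm; must be > 0.
#'   The default 0.3 mm is the order of scan and landmark-placement error.
#' @param max_mahalanobis clamp on the score Mahalanobis norm; `Inf`
#'   disables clamping.
#' @param method `"posterior"` (default), `"projection"` (unregularized
#'   least squares on the observed block), or `"mean"` (scores fixed at 0 —
#'   the mean-shape baseline).
#' @param pose_iterations cap on the alternating pose/score refinement
#'   (stops earlier once the pose is stationary to 1e-12).
#' @return Object of class `dentition_reconstruction`: `dentition` (full
#'   configuration, observation frame), `scores`, `pose` (observation ->
#'   model transform), `observed_labels`, `model_jaw`.
#' @export
reconstruct_dentition <- function(model, obs, noise_sd_mm = 0.3,
                                  max_mahalanobis = 3 * sqrt(n_modes(model)),
                                  method = c("posterior", "projection", "mean"),
                                  pose_iterations = 20L) {
  method <- match.arg(method)
  if (inherits(obs, "dentition_landmarks")) obs <- as_partial_observation(obs, model)
  if (!is.finite(noise_sd_mm) || noise_sd_mm <= 0) {
    stop("noise_sd_mm must be positive", call. = FALSE)
  }
  pose <- align_partial(model, obs)
  m <- n_modes(model)
  idx <- which(model$labels %in% obs$labels)
  coord_idx <- as.vector(t(outer(idx - 1L, 1:3, function(i, j) 3L * i + j)))
  mu_obs <- model$mean[coord_idx]
  M <- model$modes[coord_idx, , drop = FALSE]
  solve_scores <- function(x_obs) {
    rhs <- crossprod(M, x_obs - mu_obs)
    s <- if (method == "posterior") {
      A <- diag(1 / model$variances, m) + crossprod(M) / noise_sd_mm^2
      as.vector(solve(A, rhs / noise_sd_mm^2))
    } else {
      as.vector(solve(crossprod(M), rhs))
    }
    if (is.finite(max_mahalanobis)) {
      mah <- sqrt(sum(s^2 / model$variances))
      if (mah > max_mahalanobis && mah > 0) s <- s * (max_mahalanobis / mah)
    }
    s
  }
  if (m == 0L || method == "mean") {
    s <- numeric(m)
  } else {
    # alternate pose and scores: the initial pose targets the mean shape,
    # which biases the rotation for shapes far from it; re-posing onto the
    # current reconstruction removes that bias (fixed point is exact for
    # noiseless in-model observations)
    for (it in seq_len(pose_iterations)) {
      s <- solve_scores(as.vector(t(apply_transform(pose, obs$points))))
      target <- matrix(mu_obs + as.vector(M %*% s), ncol = 3L, byrow = TRUE)
      new_pose <- kabsch(obs$points, target)
      delta <- max(abs(new_pose$rotation - pose$rotation),
                   abs(new_pose$translation - pose$translation))
      pose <- new_pose
      if (delta < 1e-12) break
    }
    s <- solve_scores(as.vector(t(apply_transform(pose, obs$points))))
  }
  full_model_frame <- model$mean + as.vector(model$modes %*% s)
  pts <- matrix(full_model_frame, ncol = 3L, byrow = TRUE,
                dimnames = list(model$labels, c("x", "y", "z")))
  pts <- apply_transform(invert_transform(pose), pts)
  dent <- dentition_landmarks(paste0(obs$individual_id %||% "case", "_reconstructed"),
                              pts, model$protocol)
  structure(
    list(dentition = dent, scores = s, pose = pose,
         observed_labels = obs$labels, model_jaw = model$jaw),
    class = "dentition_reconstruction"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dentition_reconstruction <- function(x, ...) {
  cat(sprintf("Dentition reconstruction (%s jaw): %d landmarks estimated from %d observed\n",
              x$model_jaw, nrow(x$dentition$points), length(x$observed_labels)))
  invisible(x)
}

#' Predict tooth axes from a partial observation
#'
#' Runs [reconstruct_dentition()] and fits [fit_tooth_axis()] on the
#' predicted LM-1..LM-4 of every tooth of the jaw; axes are returned in the
#' observation's original coordinate frame.
#'
#' @inheritParams reconstruct_dentition
#' @param teeth optional FDI codes to restrict the output.
#' @return A [tooth_axes] list (named by FDI code), with the underlying
#'   reconstruction in attribute `"reconstruction"`.
#' @export
predict_tooth_axes <- function(model, obs, noise_sd_mm = 0.3,
                               max_mahalanobis = 3 * sqrt(n_modes(model)),
                               method = c("posterior", "projection", "mean"),
                               teeth = NULL) {
  rec <- reconstruct_dentition(model, obs, noise_sd_mm = noise_sd_mm,
                               max_mahalanobis = max_mahalanobis,
                               method = method)
  axes <- tooth_axes(rec$dentition, teeth = teeth)
  attr(axes, "reconstruction") <- rec
  axes
}

#' Predict method for dental shape models
#'
#' `type = "reconstruction"` returns the full estimated landmark
#' configuration ([reconstruct_dentition()]); `type = "axes"` returns the
#' fitted tooth axes ([predict_tooth_axes()]). With `newdata` missing, the
#' mean shape (or its axes) is returned.
#'
#' @param object a `dental_ssm`.
#' @param newdata a [dentition_landmarks()] or [as_partial_observation()].
#' @param type `"reconstruction"` or `"axes"`.
#' @param ... passed on to [reconstruct_dentition()] /
#'   [predict_tooth_axes()] (`noise_sd_mm`, `max_mahalanobis`, `method`,
#'   `teeth`).
#' @return See [reconstruct_dentition()] and [predict_tooth_axes()].
#' @export
predict.dental_ssm <- function(object, newdata = NULL,
                               type = c("reconstruction", "axes"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    mean_dent <- from_vector(object$mean, object$labels,
                             individual_id = "mean_shape",
                             protocol = object$protocol)
    return(if (type == "axes") tooth_axes(mean_dent) else mean_dent)
  }
  if (type == "axes") predict_tooth_axes(object, newdata, ...)
  else reconstruct_dentition(object, newdata, ...)
}

#' Save or load a dental shape model
#'
#' Single-file JSON container with a versioned schema: labels, jaw, mean,
#' modes, variances, training size, the protocol's crown counts, and a
#' protocol hash; numbers are serialized at full double precision so a
#' round trip reproduces the model to machine precision.
#'
#' @param model a `dental_ssm`.
#' @param path file path (conventionally `.json`).
#' @return `load_ssm()` returns the restored `dental_ssm` (training-only
#'   fields `aligned` and `scores` are not persisted).
#' @export
save_ssm <- function(model, path) {
  stopifnot(inherits(model, "dental_ssm"))
  payload <- list(
    schema = "dentaxis-ssm/1",
    jaw = model$jaw,
    labels = model$labels,
    crown_counts = as.list(model$protocol$crown_counts),
    protocol_hash = protocol_hash(model$protocol),
    n_train = model$n_train,
    variance_fraction = model$variance_fraction,
    total_variance = model$total_variance,
    gpa_iterations = model$gpa_iterations,
    mean = model$mean,
    variances = model$variances,
    modes = if (n_modes(model)) t(model$modes) else matrix(0, 0, 0)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_ssm
#' @export
load_ssm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$schema) || !identical(j$schema, "dentaxis-ssm/1")) {
    stop("not a dentaxis shape-model file: ", path, call. = FALSE)
  }
  counts <- unlist(j$crown_counts)
  protocol <- default_protocol(crown_counts = stats::setNames(
    as.integer(counts), names(counts)))
  if (!identical(protocol_hash(protocol), j$protocol_hash)) {
    stop("protocol hash mismatch; model file is corrupt or incompatible",
         call. = FALSE)
  }
  # modes are stored transposed (m x 3K); restore to 3K x m
  modes <- if (length(j$variances)) {
    t(matrix(as.numeric(j$modes), nrow = length(j$variances)))
  } else {
    matrix(0, length(j$mean), 0L)
  }
  structure(
    list(mean = as.numeric(j$mean), modes = modes,
         variances = as.numeric(j$variances),
         scores = NULL, labels = as.character(j$labels), jaw = j$jaw,
         protocol = protocol, n_train = as.integer(j$n_train),
         variance_fraction = as.numeric(j$variance_fraction),
         total_variance = as.numeric(j$total_variance),
         aligned = NULL, gpa_iterations = as.integer(j$gpa_iterations),
         call = NULL),
    class = "dental_ssm"
  )
}

# FNV-1a 32-bit digest over a string; arithmetic kept in doubles (split into
# 16-bit halves) because bitwXor cannot represent values >= 2^31
fnv32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# order-sensitive digest of the label sequence; stable across sessions
protocol_hash <- function(protocol) {
  fnv32(paste(protocol$labels$label, collapse = ";"))
}
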