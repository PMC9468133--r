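#' Parameters of the idealized arch template
#'
#' Geometry of the noiseless template dentition used by the synthetic
#' generator: tooth centers on a parabolic arch per jaw, crown landmarks
#' arranged as cusp/edge/fissure-like offsets around each crown, root
#' landmarks LM-1 at the CEJL reference, LM-2..LM-4 at exactly 2 mm steps
#' apically along a tooth-local inclined axis, LM-5 at the root apex. All
#' lengths in millimeters; defaults are typical adult dimensions.
#'
#' @param arch_width_mm outer arch width.
#' @param arch_depth_mm anterior-posterior arch depth.
#' @param crown_height_mm occlusal surface to CEJL.
#' @param root_length_mm named by tooth class: CEJL to apex.
#' @param root_spacing_mm spacing of the canal landmarks LM-1..LM-4.
#' @param crown_radius_mm named by tooth class: crown landmark ring radius.
#' @param tilt_deg named by tooth class: buccal inclination of the root
#'   axis.
#' @param jaw_gap_mm occlusal separation between the jaws.
#' @return List of class `arch_template_params`.
#' @export
arch_template_params <- function(arch_width_mm = 60, arch_depth_mm = 45,
                                 crown_height_mm = 8,
                                 root_length_mm = c(incisor = 12, canine = 16,
                                                    premolar = 13, molar = 12),
                                 root_spacing_mm = 2,
                                 crown_radius_mm = c(incisor = 2.5, canine = 3,
                                                     premolar = 3.5, molar = 4.5),
                                 tilt_deg = c(incisor = 15, canine = 10,
                                              premolar = 7, molar = 5),
                                 jaw_gap_mm = 2) {
  p <- list(arch_width_mm = arch_width_mm, arch_depth_mm = arch_depth_mm,
            crown_height_mm = crown_height_mm, root_length_mm = root_length_mm,
            root_spacing_mm = root_spacing_mm, crown_radius_mm = crown_radius_mm,
            tilt_deg = tilt_deg, jaw_gap_mm = jaw_gap_mm)
  lens <- c(arch_width_mm, arch_depth_mm, crown_height_mm, root_length_mm,
            root_spacing_mm, crown_radius_mm)
  if (any(lens <= 0)) stop("all template lengths must be positive", call. = FALSE)
  classes <- c("incisor", "canine", "premolar", "molar")
  for (f in c("root_length_mm", "crown_radius_mm", "tilt_deg")) {
    if (!all(classes %in% names(p[[f]]))) {
      stop(f, " must be named by tooth class: ", paste(classes, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(p, class = "arch_template_params")
}

# local frame of one tooth position: center of the occlusal surface,
# radial-outward and tangential unit vectors in the occlusal plane
.tooth_frame <- function(position, quadrant, params) {
  u <- (position - 0.5) / 7
  x <- params$arch_width_mm / 2 * u        # quadrant 1/4 side (x > 0)
  y <- -params$arch_depth_mm * (1 - u^2)
  jaw_up <- if (quadrant <= 2L) 1 else -1  # apical direction sign in z
  z_occ <- if (quadrant <= 2L) 0 else -params$jaw_gap_mm
  r <- c(x, y) - c(0, -params$arch_depth_mm / 2)
  e_r <- c(r / sqrt(sum(r^2)), 0)
  list(center = c(x, y, z_occ), e_r = e_r,
       e_t = c(-e_r[2L], e_r[1L], 0), up = c(0, 0, jaw_up))
}

.tooth_template_points <- function(fdi, protocol, params) {
  pos <- fdi %% 10L
  quad <- fdi %/% 10L
  cls <- TOOTH_CLASSES[pos]
  fr <- .tooth_frame(pos, quad, params)
  nc <- protocol$crown_counts[[as.character(fdi)]]
  rad <- params$crown_radius_mm[[cls]]
  theta <- 2 * pi * (seq_len(nc) - 1L) / nc
  crown <- t(vapply(theta, function(th) {
    fr$center + rad * cos(th) * fr$e_r + rad * sin(th) * fr$e_t +
      0.4 * cos(2 * th) * fr$up
  }, numeric(3)))
  tilt <- params$tilt_deg[[cls]] * pi / 180
  axis_dir <- cos(tilt) * fr$up + sin(tilt) * fr$e_r
  cej <- fr$center + params$crown_height_mm * fr$up
  root <- rbind(
    t(vapply(0:3, function(j) cej + j * params$root_spacing_mm * axis_dir,
             numeric(3))),
    cej + params$root_length_mm[[cls]] * axis_dir)
  pts <- rbind(crown, root)
  rownames(pts) <- c(sprintf("%d_crown_%d", fdi, seq_len(nc)),
                     sprintf("%d_root_%d", fdi, 1:5))
  pts
}

#' Idealized template dentition
#'
#' Deterministic noiseless dentition on a parabolic arch, mirror-symmetric
#' across the midsagittal (x = 0) plane: teeth of quadrants 2 and 3 are the
#' exact x-reflections of their quadrant-1 and 4 counterparts.
#'
#' @param protocol a [landmark_protocol][default_protocol].
#' @param params an [arch_template_params()].
#' @return A complete [dentition_landmarks()] (270 landmarks under the
#'   default protocol), id `"template"`.
#' @export
make_arch_template <- function(protocol = default_protocol(),
                               params = arch_template_params()) {
  stopifnot(inherits(params, "arch_template_params"))
  blocks <- lapply(FDI_CODES, function(fdi) {
    quad <- fdi %/% 10L
    if (quad %in% c(1L, 4L)) {
      .tooth_template_points(fdi, protocol, params)
    } else {
      # mirror of the contralateral tooth (2x <-> 1x, 3x <-> 4x)
      twin <- (if (quad == 2L) 10L else 40L) + fdi %% 10L
      pts <- .tooth_template_points(twin, protocol, params)
      pts[, 1L] <- -pts[, 1L]
      rownames(pts) <- sub(sprintf("^%d_", twin), sprintf("%d_", fdi),
                           rownames(pts))
      pts
    }
  })
  dentition_landmarks("template", do.call(rbind, blocks), protocol)
}

# Parametric deformation fields over a template: smooth, spatially coherent
# displacements coupling crown and root landmarks of the same and
# neighbouring teeth. Returned as orthonormal columns (3K x k). Fields
# beyond the 6 parametric ones are random but seeded, orthonormalized
# against the rest.
#
# Every field is made orthogonal, per jaw, to the rigid tangent space —
# translations, rotations at the centered template, and rotations at every
# previously accepted field. This makes the fields pure shape modes: for
# any population in their affine span, the per-configuration cross-products
# entering the Procrustes rotation are symmetric, so scale-free GPA leaves
# in-span configurations unrotated and PCA recovers the generating
# subspace exactly.
.rigid_tangent_cols <- function(disp, jaw_rows) {
  # rotation generators (row-vector convention p %*% S)
  skews <- list(rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 0)),
                rbind(c(0, 0, 1), c(0, 0, 0), c(-1, 0, 0)),
                rbind(c(0, 0, 0), c(0, 0, 1), c(0, -1, 0)))
  out <- list()
  for (rows in jaw_rows) {
    Cj <- matrix(0, nrow(disp), 3L)
    Cj[rows, ] <- disp[rows, , drop = FALSE]
    for (S in skews) out[[length(out) + 1L]] <- as.vector(t(Cj %*% S))
  }
  out
}

.template_mode_fields <- function(template, n_modes) {
  P <- template$points
  lab <- template$protocol$labels
  lab <- lab[match(rownames(P), lab$label), ]
  K <- nrow(P)
  fdis <- unique(lab$fdi)
  # per-tooth geometry
  tooth_of <- match(lab$fdi, fdis)
  cej <- t(vapply(fdis, function(f) P[sprintf("%d_root_1", f), ], numeric(3)))
  centers <- t(vapply(fdis, function(f)
    colMeans(P[lab$fdi == f, , drop = FALSE]), numeric(3)))
  up_sign <- ifelse(fdis %/% 10L <= 2L, 1, -1)
  e_r <- t(vapply(seq_along(fdis), function(i) {
    r <- centers[i, 1:2] - c(0, mean(P[, 2L]))
    c(r / sqrt(sum(r^2)), 0)
  }, numeric(3)))
  e_t <- cbind(-e_r[, 2L], e_r[, 1L], 0)
  # apical height of each landmark above its tooth's CEJL
  h <- vapply(seq_len(K), function(i) {
    t <- tooth_of[i]
    (P[i, 3L] - cej[t, 3L]) * up_sign[t]
  }, numeric(1))
  fields <- list(
    width = cbind(P[, 1L], 0, 0),
    depth = cbind(0, P[, 2L] - mean(P[, 2L]), 0),
    inclination = h * e_r[tooth_of, , drop = FALSE],
    mesial_tilt = (h * sign(centers[tooth_of, 1L])) * e_t[tooth_of, , drop = FALSE],
    vertical = cbind(0, 0, P[, 3L] - mean(P[, 3L])),
    root_flare = ifelse(lab$kind == "root", h, 0.3 * h) * e_r[tooth_of, , drop = FALSE]
  )
  k_par <- min(n_modes, length(fields))
  raw <- lapply(fields[seq_len(k_par)], function(f) as.vector(t(f)))
  if (n_modes > length(fields)) {
    for (j in seq_len(n_modes - length(fields))) {
      raw[[length(raw) + 1L]] <- stats::rnorm(3L * K)
    }
  }
  jaw_rows <- lapply(c("upper", "lower"), function(j) which(lab$jaw == j))
  # nuisance space: per-jaw translations + rotations at the centered template
  nuisance <- list()
  for (rows in jaw_rows) {
    for (d in 1:3) {
      M <- matrix(0, K, 3L)
      M[rows, d] <- 1
      nuisance[[length(nuisance) + 1L]] <- as.vector(t(M))
    }
  }
  Pc <- P
  for (rows in jaw_rows) {
    Pc[rows, ] <- scale(P[rows, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  nuisance <- c(nuisance, .rigid_tangent_cols(Pc, jaw_rows))
  # incremental Gram-Schmidt that silently drops dependent directions
  extend <- function(B, cols) {
    for (w in cols) {
      w <- w - B %*% crossprod(B, w)
      w <- w - B %*% crossprod(B, w)  # reorthogonalize
      nw <- sqrt(sum(w^2))
      if (nw > 1e-10) B <- cbind(B, as.vector(w) / nw)
    }
    B
  }
  B <- extend(matrix(0, 3L * K, 0L), nuisance)
  accepted <- matrix(0, 3L * K, 0L)
  for (f in raw) {
    v <- f - B %*% crossprod(B, f)
    v <- v - B %*% crossprod(B, v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) {
      stop("deformation field degenerates to a rigid motion", call. = FALSE)
    }
    v <- as.vector(v) / nv
    # deterministic sign: largest-magnitude component positive
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    accepted <- cbind(accepted, v)
    Vmat <- matrix(v, K, 3L, byrow = TRUE)
    B <- extend(B, c(list(v), .rigid_tangent_cols(Vmat, jaw_rows)))
  }
  unname(accepted)
}

#' Specification of a synthetic dentition population
#'
#' @param n_individuals population size.
#' @param n_modes number of generating variation modes (the first 6 are
#'   parametric anatomy-like fields: arch width, arch depth, buccolingual
#'   inclination, mesiodistal tilt, vertical size, root flare; further modes
#'   are seeded random fields). Must not exceed `3K - 7`.
#' @param mode_sd_mm per-mode score standard deviations; default
#'   `c(4, 3, 2, 1.5, 1, 0.8, ...)` mm.
#' @param landmark_noise_sd_mm iid isotropic landmark placement noise.
#' @param pose `"random_rigid"` (each individual gets a random rotation and
#'   translation, as real scans do) or `"none"`.
#' @param seed integer; fixes every draw.
#' @param protocol landmark protocol.
#' @param params template geometry, [arch_template_params()].
#' @return List of class `population_spec`.
#' @export
population_spec <- function(n_individuals, n_modes = 4L, mode_sd_mm = NULL,
                            landmark_noise_sd_mm = 0.05,
                            pose = c("random_rigid", "none"), seed = 1L,
                            protocol = default_protocol(),
                            params = arch_template_params()) {
  pose <- match.arg(pose)
  K <- nrow(protocol$labels)
  if (n_individuals < 1L) stop("n_individuals must be >= 1", call. = FALSE)
  if (n_modes < 0L || n_modes > 3L * K - 7L) {
    stop("n_modes must be in [0, 3K - 7]", call. = FALSE)
  }
  if (is.null(mode_sd_mm)) {
    base <- c(4, 3, 2, 1.5, 1, 0.8)
    mode_sd_mm <- if (n_modes <= 6L) base[seq_len(n_modes)] else
      c(base, rep(0.5, n_modes - 6L))
  }
  if (length(mode_sd_mm) != n_modes || any(mode_sd_mm < 0)) {
    stop("mode_sd_mm must be length n_modes, nonnegative", call. = FALSE)
  }
  if (landmark_noise_sd_mm < 0) stop("noise sd must be >= 0", call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_modes = as.integer(n_modes), mode_sd_mm = mode_sd_mm,
                 landmark_noise_sd_mm = landmark_noise_sd_mm, pose = pose,
                 seed = as.integer(seed), protocol = protocol,
                 params = params),
            class = "population_spec")
}

.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Generate a synthetic dentition population with known ground truth
#'
#' Individuals are drawn from the statistical structure the shape model
#' assumes: `template + sum_j s_ij mode_j + noise`, followed by an optional
#' random rigid motion. Modes are smooth deformation fields that genuinely
#' couple crown and root landmarks of the same and neighbouring teeth, so
#' predicting roots from crowns is an identifiable task. Scores are
#' centered normal with the spec's per-mode sds; everything is reproducible
#' from the spec's seed.
#'
#' @param spec a [population_spec()].
#' @return List with `dataset` (a [dentition_dataset()]) and `ground_truth`:
#'   `template`, `modes` (orthonormal 3K x k), `scores` (n x k),
#'   `true_axes` (per individual, [tooth_axes] fitted on the noiseless posed
#'   configuration), `poses` (per individual [rigid_transform()]), `spec`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  template <- make_arch_template(spec$protocol, spec$params)
  labels <- rownames(template$points)
  v0 <- to_vector(template)
  modes <- if (spec$n_modes > 0L) {
    .template_mode_fields(template, spec$n_modes)
  } else {
    matrix(0, length(v0), 0L)
  }
  n <- spec$n_individuals
  scores <- matrix(stats::rnorm(n * spec$n_modes), n, spec$n_modes) %*%
    diag(spec$mode_sd_mm, spec$n_modes)
  individuals <- vector("list", n)
  true_axes <- vector("list", n)
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    v_clean <- v0 + if (spec$n_modes > 0L)
      as.vector(modes %*% scores[i, ]) else 0
    noise <- stats::rnorm(length(v0), sd = spec$landmark_noise_sd_mm)
    pose <- if (spec$pose == "random_rigid") {
      rigid_transform(.random_rotation(), stats::runif(3, -20, 20))
    } else {
      rigid_transform()
    }
    id <- sprintf("syn_%03d", i)
    clean_pts <- apply_transform(
      pose, matrix(v_clean, ncol = 3L, byrow = TRUE,
                   dimnames = list(labels, c("x", "y", "z"))))
    noisy_pts <- apply_transform(
      pose, matrix(v_clean + noise, ncol = 3L, byrow = TRUE,
                   dimnames = list(labels, c("x", "y", "z"))))
    individuals[[i]] <- dentition_landmarks(id, noisy_pts, spec$protocol)
    true_axes[[i]] <- tooth_axes(
      dentition_landmarks(id, clean_pts, spec$protocol))
    poses[[i]] <- pose
  }
  names(true_axes) <- vapply(individuals, function(d) d$individual_id,
                             character(1))
  names(poses) <- names(true_axes)
  list(
    dataset = dentition_dataset(individuals,
                                metadata = list(seed = spec$seed,
                                                n_modes = spec$n_modes)),
    ground_truth = list(template = template, modes = modes, scores = scores,
                        true_axes = true_axes, poses = poses, spec = spec)
  )
}

#' Benchmark populations with fixed, documented seeds
#'
#' Three canned populations used throughout the test suite and examples:
#' `"smoke"` (n = 10, 2 modes, noise 0.05 mm, seed 1011) for fast
#' end-to-end runs, `"default"` (n = 30, 4 modes, noise 0.05 mm, seed 2022)
#' as the standard validation benchmark, and `"paper_scale"` (n = 71,
#' 6 modes, noise 0.15 mm, seed 3033) matching the cohort size of a
#' realistic clinical study (71 individuals x 270 landmarks = 19,170
#' landmarks). All use random rigid pose per individual.
#'
#' @param preset `"smoke"`, `"default"` or `"paper_scale"`.
#' @param seed optional seed overriding the preset's documented default.
#' @return As [generate_population()].
#' @export
benchmark_dataset <- function(preset = c("smoke", "default", "paper_scale"),
                              seed = NULL) {
  if (!is.character(preset) || length(preset) != 1L ||
      !preset %in% c("smoke", "default", "paper_scale")) {
    stop("unknown preset: ", paste(preset, collapse = ", "),
         " (use smoke, default or paper_scale)", call. = FALSE)
  }
  cfg <- switch(preset,
    smoke = list(n = 10L, k = 2L, noise = 0.05, seed = 1011L),
    default = list(n = 30L, k = 4L, noise = 0.05, seed = 2022L),
    paper_scale = list(n = 71L, k = 6L, noise = 0.15, seed = 3033L))
  generate_population(population_spec(
    n_individuals = cfg$n, n_modes = cfg$k,
    landmark_noise_sd_mm = cfg$noise, pose = "random_rigid",
    seed = if (is.null(seed)) cfg$seed else as.integer(seed)))
}

#' Write the ground-truth sidecar of a synthetic population
#'
#' JSON sidecar holding the generating seed and spec, per-individual mode
#' scores and true tooth axes — everything needed to score a pipeline run
#' against truth.
#'
#' @param ground_truth the `ground_truth` element of
#'   [generate_population()].
#' @param path output path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  axes_df <- do.call(rbind, lapply(names(ground_truth$true_axes), function(id) {
    as.data.frame(ground_truth$true_axes[[id]], individual_id = id)
  }))
  payload <- list(
    schema = "dentaxis-ground-truth/1",
    seed = ground_truth$spec$seed,
    n_individuals = ground_truth$spec$n_individuals,
    n_modes = ground_truth$spec$n_modes,
    mode_sd_mm = ground_truth$spec$mode_sd_mm,
    landmark_noise_sd_mm = ground_truth$spec$landmark_noise_sd_mm,
    pose = ground_truth$spec$pose,
    scores = ground_truth$scores,
    true_axes = axes_df
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
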