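# Shared fixtures and independent oracles. Oracles are deliberately naive
# (grid/dense-sampling search) and never call the code paths they check.

random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, runif(3, -10, 10))
}

# sum of squared orthogonal distances from points to the line
# {anchor + t * dir}
oracle_line_residual <- function(points, anchor, dir) {
  dir <- dir / sqrt(sum(dir^2))
  v <- sweep(as.matrix(points), 2, anchor)
  sum(v^2) - sum((v %*% dir)^2)
}

# best residual over many random candidate directions through the centroid
# (for fixed direction the orthogonal-residual-optimal anchor is the
# centroid, so the search is over directions only)
oracle_best_residual <- function(points, n_candidates = 4000) {
  ctr <- colMeans(points)
  dirs <- matrix(rnorm(3 * n_candidates), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  min(apply(dirs, 1, function(d) oracle_line_residual(points, ctr, d)))
}

# point-to-line distance by sampling the line parameter densely, then
# refining with a 1-D minimization around the best sample
oracle_point_line_distance <- function(p, anchor, dir, span = 200) {
  f <- function(t) sum((anchor + t * dir - p)^2)
  t <- seq(-span, span, length.out = 20001)
  best <- t[which.min(vapply(t, f, numeric(1)))]
  step <- t[2] - t[1]
  sqrt(stats::optimize(f, c(best - step, best + step), tol = 1e-12)$objective)
}

# small complete configuration with every label of the default protocol at
# reproducible pseudo-random coordinates
random_complete_dentition <- function(id = "rnd", seed = 42) {
  p <- default_protocol()
  set.seed(seed)
  m <- matrix(rnorm(3 * nrow(p$labels), sd = 10), ncol = 3,
              dimnames = list(p$labels$label, c("x", "y", "z")))
  dentition_landmarks(id, m, p)
}

# tiny synthetic population shortcut
tiny_population <- function(n = 8, k = 2, noise = 0, pose = "none",
                            seed = 7) {
  generate_population(population_spec(
    n_individuals = n, n_modes = k, landmark_noise_sd_mm = noise,
    pose = pose, seed = seed))
}
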