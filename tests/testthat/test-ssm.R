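test_that("a population of identical shapes yields the mean with zero modes", {
  pop <- tiny_population(n = 1, k = 0)
  base <- pop$dataset$individuals[[1]]
  set.seed(12)
  copies <- lapply(1:5, function(i) {
    d <- base
    d$individual_id <- paste0("c", i)
    d$points <- apply_transform(random_rigid(), d$points)
    d
  })
  m <- dental_ssm(dentition_dataset(copies), "upper")
  expect_equal(dentaxis:::n_modes(m), 0L)
  expect_equal(m$total_variance, 0, tolerance = 1e-12)
})

test_that("modes are orthonormal with non-increasing variances and exact full-rank round trip", {
  pop <- tiny_population(n = 12, k = 3, noise = 0.2, pose = "random_rigid",
                         seed = 99)
  m <- dental_ssm(pop$dataset, "lower", variance_fraction = 1)
  expect_equal(crossprod(m$modes), diag(dentaxis:::n_modes(m)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(m$variances) <= 1e-12))
  expect_lte(dentaxis:::n_modes(m), m$n_train - 1L)
  # projecting any training shape onto all modes and back reproduces it
  for (id in names(m$aligned)) {
    x <- as.vector(t(m$aligned[[id]]))
    s <- crossprod(m$modes, x - m$mean)
    expect_equal(as.vector(m$mean + m$modes %*% s), x, tolerance = 1e-8)
  }
  # residuals of the full-rank model vanish
  expect_lt(max(abs(residuals(m))), 1e-8)
  # training scores have the model variances (n-1 divisor)
  expect_equal(unname(apply(coef(m), 2, stats::var)), m$variances,
               tolerance = 1e-8)
})

test_that("noiseless k-mode populations are recovered: rank and subspace", {
  k <- 3
  pop <- tiny_population(n = 15, k = k, noise = 0, pose = "none", seed = 4)
  m <- dental_ssm(pop$dataset, "upper", variance_fraction = 1)
  expect_equal(dentaxis:::n_modes(m), k)
  # principal angles between generating and recovered subspaces vanish;
  # restrict the generating modes to the upper-jaw coordinates
  proto <- pop$dataset$protocol
  all_labels <- proto$labels$label
  idx <- which(all_labels %in% m$labels)
  coord_idx <- as.vector(t(outer(3 * (idx - 1), 1:3, `+`)))
  G <- pop$ground_truth$modes[coord_idx, , drop = FALSE]
  G <- qr.Q(qr(G))
  sv <- svd(crossprod(G, m$modes))$d
  principal_angles <- acos(pmin(1, sv))
  expect_lt(max(principal_angles), 1e-6)
})

test_that("variance_fraction selects the smallest sufficient mode count", {
  pop <- tiny_population(n = 15, k = 3, noise = 0, seed = 4)
  m_full <- dental_ssm(pop$dataset, "upper", variance_fraction = 1)
  frac <- cumsum(m_full$variances) / sum(m_full$variances)
  m1 <- dental_ssm(pop$dataset, "upper", variance_fraction = frac[1] - 1e-6)
  expect_equal(dentaxis:::n_modes(m1), 1L)
  expect_error(dental_ssm(pop$dataset, "upper", variance_fraction = 0),
               "variance_fraction")
})

test_that("partial alignment recovers a known pose and rejects degenerate input", {
  pop <- tiny_population(n = 8, k = 2, noise = 0.02, seed = 13)
  m <- dental_ssm(pop$dataset, "upper")
  crown_labels <- protocol_labels(m$protocol, jaw = "upper", kind = "crown")
  mean_dent <- from_vector(m$mean, m$labels, "mu", m$protocol)
  obs_dent <- crowns_only(mean_dent)
  set.seed(14)
  tf <- random_rigid()
  obs_dent$points <- apply_transform(tf, obs_dent$points)
  pose <- align_partial(m, obs_dent)
  # recovered pose undoes tf
  round_trip <- compose_transforms(tf, pose)
  expect_equal(round_trip$rotation, diag(3), tolerance = 1e-8)
  expect_equal(round_trip$translation, c(0, 0, 0), tolerance = 1e-6)

  # noise perturbs the pose only at the noise scale
  set.seed(15)
  noisy <- obs_dent
  noisy$points <- noisy$points + matrix(rnorm(length(noisy$points), sd = 0.01),
                                        ncol = 3)
  pose_n <- align_partial(m, noisy)
  expect_equal(pose_n$rotation, pose$rotation, tolerance = 0.01)

  three <- dentition_landmarks("tri", matrix(
    c(0, 0, 0, 1, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE,
    dimnames = list(crown_labels[1:3], NULL)), m$protocol)
  expect_error(align_partial(m, three), "collinear")
  expect_error(align_partial(m, dentition_landmarks(
    "two", matrix(rnorm(6), 2, 3,
                  dimnames = list(crown_labels[1:2], NULL)), m$protocol)),
    "at least 3")
})

test_that("reconstruction is the prior at the mean and converges to observations as noise vanishes", {
  pop <- tiny_population(n = 10, k = 2, noise = 0, seed = 21)
  m <- dental_ssm(pop$dataset, "upper", variance_fraction = 1)
  mean_dent <- from_vector(m$mean, m$labels, "mu", m$protocol)
  rec <- reconstruct_dentition(m, mean_dent, noise_sd_mm = 0.1)
  expect_equal(rec$scores, rep(0, 2), tolerance = 1e-8)
  expect_equal(rec$dentition$points, mean_dent$points, tolerance = 1e-7,
               ignore_attr = TRUE)

  # crowns of a noiseless training individual determine the full shape
  case <- pop$dataset$individuals[[3]]
  obs <- crowns_only(case)
  seen <- intersect(m$labels, rownames(obs$points))
  for (sd in c(0.1, 1e-3, 1e-6)) {
    rec <- reconstruct_dentition(m, obs, noise_sd_mm = sd,
                                 max_mahalanobis = Inf)
    err <- max(abs(rec$dentition$points[seen, ] - obs$points[seen, ]))
    if (sd <= 1e-6) expect_lt(err, 1e-4)
  }
  # and the unobserved root landmarks match the truth
  root_labels <- protocol_labels(m$protocol, jaw = "upper", kind = "root")
  expect_lt(max(abs(rec$dentition$points[root_labels, ] -
                      case$points[root_labels, ])), 1e-4)

  expect_error(reconstruct_dentition(m, obs, noise_sd_mm = 0), "positive")
  empty <- case
  empty$points <- case$points[0, , drop = FALSE]
  expect_error(reconstruct_dentition(m, empty), "no landmarks")
})

test_that("Mahalanobis clamping bounds the score norm", {
  pop <- tiny_population(n = 10, k = 2, noise = 0, seed = 21)
  m <- dental_ssm(pop$dataset, "upper", variance_fraction = 1)
  case <- pop$dataset$individuals[[3]]
  obs <- crowns_only(case)
  rec_free <- reconstruct_dentition(m, obs, noise_sd_mm = 1e-6,
                                    max_mahalanobis = Inf)
  mah_free <- sqrt(sum(rec_free$scores^2 / m$variances))
  clamp <- mah_free / 2
  rec_cl <- reconstruct_dentition(m, obs, noise_sd_mm = 1e-6,
                                  max_mahalanobis = clamp)
  expect_equal(sqrt(sum(rec_cl$scores^2 / m$variances)), clamp,
               tolerance = 1e-8)
})

test_that("predicted axes are rigid-motion equivariant and exact in-sample", {
  pop <- tiny_population(n = 10, k = 2, noise = 0, seed = 33)
  m <- dental_ssm(pop$dataset, "upper", variance_fraction = 1)
  case <- pop$dataset$individuals[[5]]
  obs <- crowns_only(case)
  axes <- predict_tooth_axes(m, obs, noise_sd_mm = 1e-6,
                             max_mahalanobis = Inf)
  true_axes <- tooth_axes(case)
  for (fdi in names(axes)) {
    expect_lt(angle_between_axes(axes[[fdi]], true_axes[[fdi]]), 0.5)
  }
  # rigidly moved observation -> identically moved axes
  set.seed(34)
  tf <- random_rigid()
  moved <- obs
  moved$points <- apply_transform(tf, moved$points)
  axes_m <- predict_tooth_axes(m, moved, noise_sd_mm = 1e-6,
                               max_mahalanobis = Inf)
  for (fdi in names(axes)) {
    a <- axes[[fdi]]
    b <- axes_m[[fdi]]
    expect_equal(b$anchor, as.vector(apply_transform(tf, rbind(a$anchor))),
                 tolerance = 1e-6)
    expect_equal(abs(sum(b$direction * (a$direction %*% tf$rotation))), 1,
                 tolerance = 1e-8)
  }
})

test_that("mean-shape observation predicts the mean shape's axes", {
  pop <- tiny_population(n = 8, k = 2, noise = 0.02, seed = 40)
  m <- dental_ssm(pop$dataset, "upper")
  mean_axes <- predict(m, type = "axes")
  obs <- crowns_only(from_vector(m$mean, m$labels, "mu", m$protocol))
  pred <- predict(m, obs, type = "axes", noise_sd_mm = 0.3)
  for (fdi in names(mean_axes)) {
    expect_lt(angle_between_axes(mean_axes[[fdi]], pred[[fdi]]), 1e-6)
  }
})

test_that("simulated shapes reproduce the model variances", {
  pop <- tiny_population(n = 20, k = 2, noise = 0.05, seed = 55)
  m <- dental_ssm(pop$dataset, "upper")
  sims <- simulate(m, nsim = 1000, seed = 77)
  X <- t(vapply(sims, to_vector, numeric(length(m$mean))))
  S <- sweep(X, 2, m$mean) %*% m$modes
  emp <- apply(S, 2, stats::var)
  expect_equal(emp / m$variances, rep(1, length(emp)), tolerance = 0.1)
  # fixed scores are deterministic
  s0 <- simulate(m, scores = rep(0, dentaxis:::n_modes(m)))[[1]]
  expect_equal(to_vector(s0), m$mean, ignore_attr = TRUE)
  expect_error(simulate(m, scores = rep(0, dentaxis:::n_modes(m) + 1L)),
               "columns")
})

test_that("models round-trip through the JSON container", {
  pop <- tiny_population(n = 8, k = 2, noise = 0.05, seed = 60)
  m <- dental_ssm(pop$dataset, "upper")
  path <- withr::local_tempfile(fileext = ".json")
  save_ssm(m, path)
  back <- load_ssm(path)
  expect_equal(back$mean, m$mean)
  expect_equal(back$modes, m$modes, ignore_attr = TRUE)
  expect_equal(back$variances, m$variances)
  expect_equal(back$labels, m$labels)
  expect_equal(back$jaw, m$jaw)
  expect_equal(back$n_train, m$n_train)
  # a loaded model predicts identically
  case <- crowns_only(pop$dataset$individuals[[2]])
  r1 <- reconstruct_dentition(m, case)
  r2 <- reconstruct_dentition(back, case)
  expect_equal(r1$dentition$points, r2$dentition$points, tolerance = 1e-10)
  expect_error(load_ssm(withr::local_tempfile(fileext = ".json",
                                              lines = "{}")), "not a dentaxis")
})
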