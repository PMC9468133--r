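test_that("LOOCV on identical shapes yields zero error in any scenario", {
  pop <- tiny_population(n = 1, k = 0)
  base <- pop$dataset$individuals[[1]]
  set.seed(70)
  copies <- lapply(1:4, function(i) {
    d <- base
    d$individual_id <- paste0("c", i)
    d$points <- apply_transform(random_rigid(), d$points)
    d
  })
  ds <- dentition_dataset(copies)
  res <- loocv_axes(ds, "upper")
  expect_equal(nrow(res), 4L * 14L)
  expect_lt(max(res$angle_deg), 1e-6)
  expect_lt(max(res$distance_A_mm), 1e-6)
  res_m <- loocv_axes(ds, "upper", scenario = "missing", missing_tooth = 11)
  expect_equal(nrow(res_m), 4L)
  expect_lt(max(res_m$angle_deg), 1e-6)
})

test_that("LOOCV results are invariant to dataset order and leakage-free", {
  pop <- tiny_population(n = 6, k = 2, noise = 0.05, pose = "random_rigid",
                         seed = 71)
  ds <- pop$dataset
  res1 <- loocv_axes(ds, "upper")
  perm <- dentition_dataset(ds$individuals[c(4, 1, 6, 2, 5, 3)])
  res2 <- loocv_axes(perm, "upper")
  key <- function(r) r[order(r$individual_id, r$fdi_code), c(
    "individual_id", "fdi_code", "angle_deg", "distance_A_mm",
    "distance_B_mm")]
  # alignment initializes from the first individual, so permutations agree
  # to the Procrustes convergence tolerance rather than bit-exactly
  expect_equal(key(as.data.frame(res1)), key(as.data.frame(res2)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # no information from the held-out individual enters its fold model
  folds <- loocv_fold_models(ds, "upper")
  for (id in names(folds)) {
    expect_false(id %in% rownames(coef(folds[[id]])))
    expect_equal(folds[[id]]$n_train, length(ds) - 1L)
  }
  expect_error(loocv_axes(dentition_dataset(ds$individuals[1:2]), "upper"),
               "at least 3")
  expect_error(loocv_axes(ds, "upper", scenario = "missing"),
               "missing_tooth")
  expect_error(loocv_axes(ds, "upper", scenario = "missing",
                          missing_tooth = 36), "not in the upper jaw")
})

test_that("SSM predictions beat the mean-shape baseline on a correlated population", {
  pop <- tiny_population(n = 12, k = 3, noise = 0.05, pose = "random_rigid",
                         seed = 72)
  folds <- loocv_fold_models(pop$dataset, "upper")
  ssm <- loocv_axes(pop$dataset, "upper", fold_models = folds)
  base <- loocv_axes(pop$dataset, "upper", method = "mean",
                     fold_models = folds)
  expect_lt(mean(ssm$angle_deg), mean(base$angle_deg))
})

test_that("all 14 per-jaw missing-tooth scenarios agree with direct calls", {
  pop <- tiny_population(n = 5, k = 2, noise = 0.05, seed = 73)
  folds <- loocv_fold_models(pop$dataset, "lower")
  all_sc <- missing_tooth_scenarios(pop$dataset, "lower",
                                    fold_models = folds)
  expect_length(all_sc, 14L)
  expect_setequal(names(all_sc),
                  as.character(unique(default_protocol()$labels$fdi[
                    default_protocol()$labels$jaw == "lower"])))
  direct <- loocv_axes(pop$dataset, "lower", scenario = "missing",
                       missing_tooth = 36, fold_models = folds)
  expect_equal(as.data.frame(all_sc[["36"]]), as.data.frame(direct),
               ignore_attr = TRUE)
  # deterministic end to end
  again <- missing_tooth_scenarios(pop$dataset, "lower", fold_models = folds)
  expect_identical(lapply(all_sc, as.data.frame),
                   lapply(again, as.data.frame))
})

test_that("summaries use the n-1 divisor and pool consistently", {
  res <- data.frame(
    individual_id = rep(c("a", "b", "c"), 2),
    fdi_code = rep(c(11, 12), each = 3),
    angle_deg = c(1, 2, 3, 4, 5, 6),
    distance_A_mm = c(1, 1, 1, 2, 2, 2),
    distance_B_mm = rep(0.5, 6))
  s <- summarize_axis_errors(res)
  r11 <- s[s$fdi_code == "11", ]
  expect_equal(r11$mean_angle_deg, 2)
  expect_equal(r11$sd_angle_deg, 1)
  all_row <- s[s$fdi_code == "all", ]
  expect_equal(all_row$n, 6L)
  # pooled mean equals the measurement-weighted mean of per-tooth means
  per_tooth <- s[s$fdi_code != "all", ]
  expect_equal(all_row$mean_angle_deg,
               sum(per_tooth$mean_angle_deg * per_tooth$n) / sum(per_tooth$n))
  # n = 1 group: sd reported as 0 and flagged
  s1 <- summarize_axis_errors(res[1, , drop = FALSE])
  expect_equal(s1$sd_angle_deg, c(0, 0))
  expect_true(all(s1$sd_undefined))
  expect_error(summarize_axis_errors(res[0, , drop = FALSE]))
})

test_that("paired t-test matches closed-form arithmetic and handles degeneracy", {
  x <- c(2, 3, 4)
  t0 <- paired_axis_test(x, x)
  expect_equal(t0$t_statistic, 0)
  expect_equal(t0$p_value, 1)

  # differences (1, 2, 3): t = 2 / (1 / sqrt(3)), df = 2
  y <- x - c(1, 2, 3)
  tt <- paired_axis_test(x, y)
  expect_equal(tt$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 2)
  expect_equal(tt$p_value,
               2 * stats::pt(2 * sqrt(3), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # constant nonzero difference: infinite t, p -> 0, flagged
  td <- paired_axis_test(c(1, 2, 3), c(0, 1, 2))
  expect_true(is.infinite(td$t_statistic) && td$t_statistic > 0)
  expect_equal(td$p_value, 0)
  expect_true(td$degenerate)
  expect_error(paired_axis_test(1, 1), "at least 2")
})

test_that("Holm adjustment is step-down with a running maximum", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(80)
  p <- runif(20)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= pmin(1, length(p) * p)))
  expect_equal(order(adj[order(p)]), seq_along(p))
})

test_that("scenario comparison pairs by individual and flags injected shifts", {
  pop <- tiny_population(n = 8, k = 2, noise = 0.05, seed = 81)
  folds <- loocv_fold_models(pop$dataset, "upper")
  full <- loocv_axes(pop$dataset, "upper", fold_models = folds)
  miss <- missing_tooth_scenarios(pop$dataset, "upper", fold_models = folds)
  cmp <- compare_scenarios(full, miss)
  expect_equal(nrow(cmp), 14L * 3L)
  expect_true(all(cmp$p_value_holm >= cmp$p_value_raw))
  expect_true(all(cmp$n_pairs == 8L))

  # identical result sets: t = 0, adjusted p = 1 everywhere
  self <- compare_scenarios(full, stats::setNames(
    lapply(unique(full$fdi_code), function(f)
      full[full$fdi_code == f, , drop = FALSE]),
    unique(full$fdi_code)))
  expect_true(all(self$t_statistic == 0))
  expect_true(all(self$p_value_holm == 1))

  # a constant +1 degree shift in one tooth's angles is detected after Holm
  shifted <- miss
  shifted[["11"]]$angle_deg <- shifted[["11"]]$angle_deg + 1
  cmp2 <- compare_scenarios(full, shifted)
  row <- cmp2[cmp2$fdi_code == 11 & cmp2$metric == "angle_deg", ]
  expect_lt(row$p_value_holm, 0.05)

  # unmatched individuals are an error
  broken <- miss
  broken[["11"]] <- broken[["11"]][-1, ]
  expect_error(compare_scenarios(full, broken), "pairing mismatch")
})
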