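#' Leave-one-out cross-validated axis prediction accuracy
#'
#' The accuracy protocol for root-axis prediction: each individual in turn
#' is excluded, a shape model is trained on all others ([dental_ssm()]),
#' the excluded case's crown landmarks are taken as given — all 14 teeth of
#' the jaw (`scenario = "full"`), or all crowns minus those of one
#' designated tooth (`scenario = "missing"`, emulating a missing tooth on
#' the scan) — the root landmarks are reconstructed, and the predicted tooth
#' axes are compared with the axes fitted to the case's actual root
#' landmarks via [axis_errors()]: angle alpha (degrees), distance A (mm, at
#' the CEJL) and distance B (mm, apical). No information from the excluded
#' individual enters its training fold.
#'
#' Training folds do not depend on the scenario, so when running many
#' scenarios on one dataset the per-fold models can be computed once with
#' [loocv_fold_models()] and passed in.
#'
#' @param dataset a [dentition_dataset()], complete for `jaw`, n >= 3.
#' @param jaw `"upper"` or `"lower"`.
#' @param scenario `"full"` (dentate arch) or `"missing"` (one tooth absent
#'   from the observation).
#' @param missing_tooth FDI code; required when `scenario = "missing"`.
#' @param evaluate which teeth to score in the missing-tooth scenario:
#'   `"missing"` (default, the removed tooth only) or `"all"`.
#' @param noise_sd_mm,max_mahalanobis,method reconstruction settings, see
#'   [reconstruct_dentition()]. `method = "mean"` gives the mean-shape
#'   baseline (no crown information used beyond pose).
#' @param variance_fraction model variance retained per fold.
#' @param fold_models optional precomputed [loocv_fold_models()] result.
#' @return Data frame of class `axis_loocv`, one row per (individual,
#'   evaluated tooth): `individual_id`, `fdi_code`, `scenario`,
#'   `missing_tooth`, `angle_deg`, `distance_A_mm`, `distance_B_mm`.
#' @export
loocv_axes <- function(dataset, jaw = c("upper", "lower"),
                       scenario = c("full", "missing"),
                       missing_tooth = NULL,
                       evaluate = c("missing", "all"),
                       noise_sd_mm = 0.3,
                       variance_fraction = 0.98,
                       max_mahalanobis = NULL,
                       method = c("posterior", "projection", "mean"),
                       fold_models = NULL) {
  stopifnot(inherits(dataset, "dentition_dataset"))
  jaw <- match.arg(jaw)
  scenario <- match.arg(scenario)
  evaluate <- match.arg(evaluate)
  method <- match.arg(method)
  n <- length(dataset$individuals)
  if (n < 3L) stop("LOOCV needs at least 3 individuals", call. = FALSE)
  jaw_teeth <- unique(dataset$protocol$labels$fdi[
    dataset$protocol$labels$jaw == jaw])
  if (scenario == "missing") {
    if (is.null(missing_tooth)) {
      stop("scenario 'missing' requires missing_tooth", call. = FALSE)
    }
    check_fdi(missing_tooth)
    if (!missing_tooth %in% jaw_teeth) {
      stop("missing_tooth ", missing_tooth, " is not in the ", jaw, " jaw",
           call. = FALSE)
    }
  }
  if (is.null(fold_models)) {
    fold_models <- loocv_fold_models(dataset, jaw = jaw,
                                     variance_fraction = variance_fraction)
  }
  ids <- names(dataset$individuals)
  stopifnot(all(ids %in% names(fold_models)))
  rows <- vector("list", 0L)
  for (id in ids) {
    model <- fold_models[[id]]
    case <- dataset$individuals[[id]]
    obs_dent <- crowns_only(case)
    eval_teeth <- jaw_teeth
    if (scenario == "missing") {
      obs_dent <- drop_tooth(obs_dent, missing_tooth)
      if (evaluate == "missing") eval_teeth <- missing_tooth
    }
    mm <- if (is.null(max_mahalanobis)) 3 * sqrt(n_modes(model)) else max_mahalanobis
    rec <- reconstruct_dentition(model, as_partial_observation(obs_dent, model),
                                 noise_sd_mm = noise_sd_mm,
                                 max_mahalanobis = mm, method = method)
    for (fdi in eval_teeth) {
      want <- sprintf("%d_root_%d", fdi, 1:4)
      err <- axis_errors(rec$dentition$points[want, , drop = FALSE],
                         case$points[want, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = id, fdi_code = fdi, scenario = scenario,
        missing_tooth = if (scenario == "missing") missing_tooth else NA_integer_,
        angle_deg = err$angle_deg, distance_A_mm = err$distance_A_mm,
        distance_B_mm = err$distance_B_mm, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "jaw") <- jaw
  attr(out, "config") <- list(noise_sd_mm = noise_sd_mm,
                              variance_fraction = variance_fraction,
                              method = method, scenario = scenario,
                              missing_tooth = missing_tooth)
  class(out) <- c("axis_loocv", class(out))
  out
}

#' @rdname loocv_axes
#' @export
loocv_fold_models <- function(dataset, jaw = c("upper", "lower"),
                              variance_fraction = 0.98) {
  jaw <- match.arg(jaw)
  ids <- names(dataset$individuals)
  models <- lapply(ids, function(id) {
    train <- dentition_dataset(dataset$individuals[setdiff(ids, id)])
    dental_ssm(train, jaw = jaw, variance_fraction = variance_fraction)
  })
  stats::setNames(models, ids)
}

#' All 14 single-missing-tooth scenarios of one jaw
#'
#' Runs the missing-tooth LOOCV once per tooth of the jaw (positions 1-7 of
#' both quadrants), reusing one set of per-fold models.
#'
#' @inheritParams loocv_axes
#' @return Named list (by FDI code, 14 entries) of `axis_loocv` result
#'   frames.
#' @export
missing_tooth_scenarios <- function(dataset, jaw = c("upper", "lower"),
                                    evaluate = c("missing", "all"),
                                    noise_sd_mm = 0.3,
                                    variance_fraction = 0.98,
                                    max_mahalanobis = NULL,
                                    method = c("posterior", "projection", "mean"),
                                    fold_models = NULL) {
  jaw <- match.arg(jaw)
  evaluate <- match.arg(evaluate)
  method <- match.arg(method)
  if (is.null(fold_models)) {
    fold_models <- loocv_fold_models(dataset, jaw = jaw,
                                     variance_fraction = variance_fraction)
  }
  teeth <- unique(dataset$protocol$labels$fdi[
    dataset$protocol$labels$jaw == jaw])
  out <- lapply(teeth, function(fdi) {
    loocv_axes(dataset, jaw = jaw, scenario = "missing", missing_tooth = fdi,
               evaluate = evaluate, noise_sd_mm = noise_sd_mm,
               variance_fraction = variance_fraction,
               max_mahalanobis = max_mahalanobis, method = method,
               fold_models = fold_models)
  })
  stats::setNames(out, as.character(teeth))
}

#' Summarize axis-prediction errors per tooth and per jaw
#'
#' Mean and standard deviation (divisor n-1) of angle alpha, distance A and
#' distance B, per tooth and pooled over all (case, tooth) measurements of
#' the jaw. Groups with a single measurement report sd 0 and are flagged
#' (`sd_undefined`), keeping report tables total.
#'
#' @param results an `axis_loocv` frame (or any data frame with the metric
#'   columns and `fdi_code`).
#' @return Data frame with one row per tooth plus one `"all"` row:
#'   `fdi_code`, `n`, mean/sd of each metric, `sd_undefined`.
#' @export
summarize_axis_errors <- function(results) {
  stopifnot(nrow(results) > 0L)
  metrics <- c("angle_deg", "distance_A_mm", "distance_B_mm")
  one <- function(sub, label) {
    n <- nrow(sub)
    row <- data.frame(fdi_code = label, n = n, stringsAsFactors = FALSE)
    for (m in metrics) {
      row[[paste0("mean_", m)]] <- mean(sub[[m]])
      row[[paste0("sd_", m)]] <- if (n > 1L) stats::sd(sub[[m]]) else 0
    }
    row$sd_undefined <- n == 1L
    row
  }
  teeth <- sort(unique(results$fdi_code))
  per_tooth <- do.call(rbind, lapply(teeth, function(fdi) {
    one(results[results$fdi_code == fdi, , drop = FALSE], as.character(fdi))
  }))
  rbind(per_tooth, one(results, "all"))
}

#' Paired t-test on axis error samples
#'
#' Two-sided paired t-test: `t = mean(d) / (sd(d) / sqrt(n))` on the
#' differences `d = x - y`, p-value from Student's t with n-1 degrees of
#' freedom. Zero-variance differences are handled explicitly: t is 0 (p = 1)
#' if all differences are zero, otherwise signed infinite with p = 0 and
#' `degenerate = TRUE`.
#'
#' @param x,y equal-length numeric vectors paired by (individual, tooth).
#' @return List of class `paired_axis_test`: `t_statistic`, `df`,
#'   `p_value`, `mean_difference`, `n_pairs`, `degenerate`.
#' @export
paired_axis_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) stop("paired test needs at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(structure(list(
      t_statistic = if (md == 0) 0 else sign(md) * Inf,
      df = n - 1L, p_value = if (md == 0) 1 else 0,
      mean_difference = md, n_pairs = n, degenerate = TRUE),
      class = "paired_axis_test"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_difference = unname(tt$estimate),
                 n_pairs = n, degenerate = FALSE),
            class = "paired_axis_test")
}

#' @export
print.paired_axis_test <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, df = %d, p = %.4g (n = %d pairs)\n",
              x$t_statistic, x$df, x$p_value, x$n_pairs))
  invisible(x)
}

#' Holm step-down multiplicity adjustment
#'
#' Step-down Holm correction: sort p-values ascending, multiply the k-th by
#' (m - k + 1), enforce monotonicity by a running maximum, cap at 1, and
#' restore the input order. Uniformly more powerful than Bonferroni while
#' controlling the family-wise error rate.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

#' Compare full-dentition and missing-tooth scenarios
#'
#' For each tooth and each accuracy metric, a paired t-test across
#' individuals between the full-dentition errors and the missing-tooth
#' errors of that tooth, Holm-adjusted across the whole family of tests of
#' the jaw (by default 14 teeth x 3 metrics = 42 tests).
#'
#' @param full_results `axis_loocv` frame from the full-dentition scenario.
#' @param missing_results named list from [missing_tooth_scenarios()].
#' @param metrics metric columns entering the family.
#' @return Data frame: `fdi_code`, `metric`, `n_pairs`, `t_statistic`,
#'   `df`, `mean_difference`, `p_value_raw`, `p_value_holm`.
#' @export
compare_scenarios <- function(full_results, missing_results,
                              metrics = c("angle_deg", "distance_A_mm",
                                          "distance_B_mm")) {
  rows <- list()
  for (tooth in names(missing_results)) {
    fdi <- as.integer(tooth)
    f <- full_results[full_results$fdi_code == fdi, , drop = FALSE]
    m <- missing_results[[tooth]]
    m <- m[m$fdi_code == fdi, , drop = FALSE]
    if (!nrow(f) || !nrow(m)) {
      stop("no results for tooth ", tooth, " in one of the scenarios",
           call. = FALSE)
    }
    key_f <- f$individual_id
    key_m <- m$individual_id
    if (!setequal(key_f, key_m)) {
      stop("pairing mismatch for tooth ", tooth, ": unmatched individuals ",
           paste(utils::head(c(setdiff(key_f, key_m), setdiff(key_m, key_f)), 5),
                 collapse = ", "), call. = FALSE)
    }
    m <- m[match(key_f, key_m), , drop = FALSE]
    for (metric in metrics) {
      tt <- paired_axis_test(f[[metric]], m[[metric]])
      rows[[length(rows) + 1L]] <- data.frame(
        fdi_code = fdi, metric = metric, n_pairs = tt$n_pairs,
        t_statistic = tt$t_statistic, df = tt$df,
        mean_difference = tt$mean_difference,
        p_value_raw = tt$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_value_holm <- holm_adjust(out$p_value_raw)
  out
}
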