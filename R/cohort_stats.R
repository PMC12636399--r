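#' Summarize one ROI
#'
#' Aggregates a particle table to the ROI level and normalizes the count
#' to concentration units:
#' `particles_per_ul = particles_detected * dilution_factor /
#' reference_volume_ul`. The dilution factor is the fold-dilution of the
#' sample applied to the capture surface; the reference volume is the
#' volume of diluted sample the ROI represents. When no particles were
#' detected, the per-particle metric means are `NA` (undefined), not 0.
#'
#' @param particles a `particle_records` table (possibly with a
#'   `reporter_positive` column).
#' @param dilution_factor fold-dilution (>= 1).
#' @param reference_volume_ul reference volume in microlitres (> 0).
#' @param roi_id,condition,fraction bookkeeping labels.
#' @return One-row data frame of class `roi_summary`.
#' @examples
#' # 40 admitted particles at 10,000-fold dilution -> 400,000 per ul
#' @export
summarize_roi <- function(particles, dilution_factor = 1,
                          reference_volume_ul = 1, roi_id = "roi1",
                          condition = NA_character_,
                          fraction = NA_character_) {
  check_number(dilution_factor, "dilution_factor", lower = 1)
  check_number(reference_volume_ul, "reference_volume_ul", lower = 1e-12)
  n <- nrow(particles)
  mn <- function(v) if (n == 0L) NA_real_ else mean(v, na.rm = TRUE)
  out <- data.frame(
    roi_id = roi_id, condition = condition, fraction = fraction,
    capture = attr(particles, "capture") %||% NA_character_,
    detection = attr(particles, "detection") %||% NA_character_,
    particles_detected = n,
    particles_per_ul = n * dilution_factor / reference_volume_ul,
    mean_cargo = mn(particles$cargo_estimate),
    mean_diameter = mn(particles$diameter_nm),
    mean_circularity = mn(particles$circularity),
    mean_eccentricity = mn(particles$eccentricity),
    positive_fraction = if (!is.null(particles$reporter_positive) && n > 0L)
      mean(particles$reporter_positive) else NA_real_,
    dilution_factor = dilution_factor,
    stringsAsFactors = FALSE)
  class(out) <- c("roi_summary", "data.frame")
  out
}

#' Aggregate ROI summaries per condition
#'
#' Mean and SEM of each metric over ROI-level values, the ROI being the
#' statistical unit (the standard design images 5 ROIs per fraction and
#' n fractions per condition). Fraction-level nesting is recorded
#' (`n_fractions`) but not modelled; when more than one fraction is
#' present a clustering caveat message is emitted, since ROI values
#' within a fraction are not independent.
#'
#' @param roi_summaries data frame of [summarize_roi()] rows.
#' @return Data frame of class `condition_summary`, one row per
#'   condition, with `<metric>_mean` and `<metric>_sem` columns
#'   (`SEM = sd / sqrt(n)`; `NA` for a single ROI).
#' @export
aggregate_condition <- function(roi_summaries) {
  metrics <- c("particles_detected", "particles_per_ul", "mean_cargo",
               "mean_diameter", "mean_circularity", "mean_eccentricity",
               "positive_fraction")
  sp <- split(roi_summaries, roi_summaries$condition)
  rows <- lapply(sp, function(g) {
    nfrac <- length(unique(g$fraction[!is.na(g$fraction)]))
    out <- data.frame(condition = g$condition[1L],
                      n_fractions = max(nfrac, 1L), n_rois = nrow(g))
    for (m in metrics) {
      v <- g[[m]][!is.na(g[[m]])]
      out[[paste0(m, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(m, "_sem")]] <- if (length(v) >= 2L)
        sd(v) / sqrt(length(v)) else NA_real_
    }
    out
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (any(out$n_fractions > 1L))
    message("aggregate_condition: ROIs are nested in fractions; ",
            "SEMs treat ROIs as independent")
  class(out) <- c("condition_summary", "data.frame")
  out
}

star_code <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Compare conditions on one metric
#'
#' Applies the chosen test to ROI-level metric values. Two-group
#' comparisons default to the two-tailed Student's t-test (equal
#' variances); one-way ANOVA (optionally with Tukey HSD post-hoc) and
#' the Mann-Whitney test are available. When every group has zero
#' variance and all means are equal, `p = 1` by convention (logged).
#'
#' @param groups named list of numeric vectors (one per condition), or a
#'   data frame of [summarize_roi()] rows combined with `metric`.
#' @param metric metric name (column of the ROI summaries) when `groups`
#'   is a data frame.
#' @param test one of `"t_two_tailed"`, `"anova"`, `"anova_tukey"`,
#'   `"mann_whitney"`.
#' @return A `comparison_result` list: `metric`, `groups`, `test`,
#'   `statistic`, `p_value`, `stars`, and `tukey` (pairwise table) when
#'   requested.
#' @export
compare_conditions <- function(groups, metric = NULL,
                               test = c("t_two_tailed", "anova",
                                        "anova_tukey", "mann_whitney")) {
  test <- match.arg(test)
  if (is.data.frame(groups)) {
    stopifnot(!is.null(metric))
    groups <- split(groups[[metric]], groups$condition)
  }
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2L) stopf("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stopf("every group needs >= 2 values")
  if (test %in% c("t_two_tailed", "mann_whitney") && length(groups) != 2L)
    stopf("'%s' requires exactly 2 groups", test)

  vars <- vapply(groups, var, 1)
  means <- vapply(groups, mean, 1)
  tukey <- NULL
  if (all(vars == 0) && length(unique(means)) == 1L) {
    message("compare_conditions: degenerate zero-variance groups with ",
            "equal means; p = 1 by convention")
    stat <- 0; p <- 1
  } else if (test == "t_two_tailed") {
    ht <- t.test(groups[[1L]], groups[[2L]], var.equal = TRUE)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else if (test == "mann_whitney") {
    ht <- suppressWarnings(wilcox.test(groups[[1L]], groups[[2L]]))
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    vals <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), lengths(groups)))
    fit <- aov(vals ~ fac)
    sm <- summary(fit)[[1L]]
    stat <- sm[["F value"]][1L]; p <- sm[["Pr(>F)"]][1L]
    if (test == "anova_tukey") {
      tk <- TukeyHSD(fit)$fac
      tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL)
      tukey$stars <- vapply(tukey$p_adj, star_code, "")
    }
  }
  structure(list(metric = metric %||% "value",
                 groups = names(groups), test = test, statistic = stat,
                 p_value = p, stars = star_code(p), tukey = tukey),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s vs %s | %s | stat = %.3g, p = %.3g %s\n",
              x$metric, x$groups[1L],
              paste(x$groups[-1L], collapse = "/"), x$test,
              x$statistic, x$p_value, x$stars))
  if (!is.null(x$tukey)) print(x$tukey)
  invisible(x)
}

#' Detection and estimation accuracy against ground truth
#'
#' Greedy nearest-centroid matching of detected particles to simulator
#' truth: candidate pairs within `match_radius_nm` are assigned in order
#' of increasing distance, each side matched at most once. Reports
#' detection precision and recall plus per-class bias and RMSE of
#' diameter and cargo, and reporter-positivity accuracy when both sides
#' carry the flag.
#'
#' @param particles a `particle_records` table.
#' @param truth a `particle_truth` table.
#' @param match_radius_nm maximum centroid distance for a match.
#' @return A `recovery_report` list: `matches` (data frame),
#'   `precision`, `recall`, `n_detected`, `n_truth`, `by_class` (data
#'   frame of per-class error summaries).
#' @export
recovery_report <- function(particles, truth, match_radius_nm = 100) {
  nd <- nrow(particles); nt <- nrow(truth)
  if (nd > 0L && nt > 0L) {
    dx <- outer(particles$x_nm, truth$x_nm, "-")
    dy <- outer(particles$y_nm, truth$y_nm, "-")
    dist <- sqrt(dx^2 + dy^2)
    cand <- which(dist <= match_radius_nm, arr.ind = TRUE)
    cand <- cand[order(dist[cand]), , drop = FALSE]
    used_d <- logical(nd); used_t <- logical(nt)
    pick <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- TRUE; used_t[j] <- TRUE; pick[k] <- TRUE
      }
    }
    cand <- cand[pick, , drop = FALSE]
    matches <- data.frame(
      particle_row = cand[, 1L],
      truth_id = truth$particle_id[cand[, 2L]],
      class_name = truth$class_name[cand[, 2L]],
      dist_nm = dist[cand],
      est_diameter = particles$diameter_nm[cand[, 1L]],
      true_diameter = truth$diameter_nm[cand[, 2L]],
      est_cargo = particles$cargo_estimate[cand[, 1L]],
      true_cargo = truth$n_cargo[cand[, 2L]],
      stringsAsFactors = FALSE)
    if (!is.null(particles$reporter_positive)) {
      matches$est_positive <- particles$reporter_positive[cand[, 1L]]
      matches$true_positive <- truth$reporter_positive[cand[, 2L]]
    }
  } else {
    matches <- data.frame(particle_row = integer(0), truth_id = integer(0),
                          class_name = character(0), dist_nm = numeric(0),
                          est_diameter = numeric(0),
                          true_diameter = numeric(0),
                          est_cargo = numeric(0), true_cargo = numeric(0))
  }
  by_class <- if (nrow(matches)) {
    sp <- split(matches, matches$class_name)
    do.call(rbind, c(lapply(sp, function(g) {
      dd <- g$est_diameter - g$true_diameter
      dc <- g$est_cargo - g$true_cargo
      data.frame(class_name = g$class_name[1L], n_matched = nrow(g),
                 diameter_bias = mean(dd),
                 diameter_rmse = sqrt(mean(dd^2)),
                 cargo_bias = mean(dc), cargo_rmse = sqrt(mean(dc^2)),
                 positivity_accuracy = if (!is.null(g$est_positive))
                   mean(g$est_positive == g$true_positive) else NA_real_)
    }), make.row.names = FALSE))
  } else NULL
  structure(list(matches = matches,
                 precision = if (nd > 0L) nrow(matches) / nd else NA_real_,
                 recall = if (nt > 0L) nrow(matches) / nt else NA_real_,
                 n_detected = nd, n_truth = nt, by_class = by_class),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery: %d/%d detected matched (precision %.3f, recall %.3f)\n",
              nrow(x$matches), x$n_truth, x$precision, x$recall))
  if (!is.null(x$by_class)) print(x$by_class)
  invisible(x)
}
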