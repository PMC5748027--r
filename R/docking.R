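# Docking-score threshold calibration and candidate gating.
#
# Docking itself is out of scope: scores are ingested from tables (lower =
# better binding). The calibration sweeps a cutoff t over all observed
# scores plus midpoints, classifies "active iff score <= t", and keeps the
# t with the best F1 (ties resolved toward the more permissive, larger t).

#' Calibrate a docking-score cutoff by maximising F1
#'
#' @param actives numeric scores of known actives.
#' @param inactives numeric scores of known inactives.
#' @param target_id label stored on the calibration.
#' @return object of class `threshold_calibration`: `threshold`, `best_f1`,
#'   `precision_at_best`, `recall_at_best`, medians, Mann-Whitney
#'   diagnostics, the full `sweep_table` (threshold, precision, recall, f1)
#'   and a `degenerate` flag (all scores identical).
#' @examples
#' best_f1_threshold(c(-9, -8), c(-5, -4))$threshold
#' @export
best_f1_threshold <- function(actives, inactives, target_id = "target") {
  if (!length(actives) || !length(inactives)) {
    stop("both score sets must be nonempty")
  }
  if (!all(is.finite(c(actives, inactives)))) stop("scores must be finite")
  all_scores <- sort(unique(c(actives, inactives)))
  grid <- all_scores
  if (length(all_scores) > 1) {
    mids <- (all_scores[-1] + all_scores[-length(all_scores)]) / 2
    grid <- sort(unique(c(all_scores, mids)))
  }
  sweep <- do.call(rbind, lapply(grid, function(t) {
    tp <- sum(actives <= t); fp <- sum(inactives <= t)
    fn <- length(actives) - tp
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(threshold = t, precision = precision, recall = recall,
               f1 = f1)
  }))
  best <- max(sweep$f1)
  # ties -> largest (most permissive) threshold
  at <- max(which(sweep$f1 == best))
  diag <- separation_diagnostics(actives, inactives)
  structure(list(
    target_id = target_id,
    threshold = sweep$threshold[at],
    best_f1 = best,
    precision_at_best = sweep$precision[at],
    recall_at_best = sweep$recall[at],
    median_active = diag$median_active,
    median_inactive = diag$median_inactive,
    mannwhitney_U = diag$U,
    mannwhitney_p = diag$p,
    sweep_table = sweep,
    degenerate = length(all_scores) == 1),
    class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat("<threshold_calibration> ", x$target_id, ": threshold ",
      signif(x$threshold, 4), ", F1 ", signif(x$best_f1, 4),
      " (P ", signif(x$precision_at_best, 3), ", R ",
      signif(x$recall_at_best, 3), "); medians ",
      signif(x$median_active, 4), " / ", signif(x$median_inactive, 4),
      ", Mann-Whitney p ", signif(x$mannwhitney_p, 3),
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Separation diagnostics for labelled score distributions
#'
#' Medians of the two score sets and a two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test: exact when the pooled sample is small (<= 20) without
#' ties, normal approximation with tie correction otherwise.
#'
#' @inheritParams best_f1_threshold
#' @return list with `median_active`, `median_inactive`, `U`, `p`.
#' @export
separation_diagnostics <- function(actives, inactives) {
  if (!length(actives) || !length(inactives)) {
    stop("both score sets must be nonempty")
  }
  exact <- (length(actives) + length(inactives)) <= 20 &&
    !any(duplicated(c(actives, inactives)))
  wt <- suppressWarnings(
    stats::wilcox.test(actives, inactives, exact = exact,
                       correct = !exact))
  list(median_active = stats::median(actives),
       median_inactive = stats::median(inactives),
       U = unname(wt$statistic),
       p = min(1, wt$p.value))
}

#' Gate candidates by prediction and per-target docking thresholds
#'
#' A candidate survives when it is a predicted multi-target ligand and its
#' docking score is at or below the calibrated threshold for every target
#' (in the order given, which defines the funnel stages). Candidates with a
#' missing score are dropped with a warning.
#'
#' @param scores data.frame with columns `compound_id`, `target_id`,
#'   `score`.
#' @param calibrations named list of `threshold_calibration` objects (or
#'   bare numeric thresholds), one per target; names define stage order.
#' @param predicted_multitarget character vector of compound ids predicted
#'   active against all targets.
#' @return list with `survivors` (character vector) and `funnel`
#'   (data.frame: stage, n_in, n_out, fraction of the previous stage).
#' @export
gate_candidates <- function(scores, calibrations, predicted_multitarget) {
  targets <- names(calibrations)
  if (is.null(targets) || any(!nzchar(targets))) {
    stop("calibrations must be a named list (one entry per target)")
  }
  thr <- vapply(calibrations, function(x) {
    if (inherits(x, "threshold_calibration")) x$threshold else as.numeric(x)
  }, numeric(1))
  current <- unique(predicted_multitarget)
  funnel <- data.frame(stage = "predicted_multitarget",
                       n_in = length(current), n_out = length(current),
                       fraction = 1)
  for (tn in targets) {
    st <- scores[scores$target_id == tn, , drop = FALSE]
    have <- current %in% st$compound_id
    if (any(!have)) {
      warning(sum(!have), " candidate(s) lack a ", tn,
              " score and were dropped")
    }
    n_in <- length(current)
    sc <- st$score[match(current[have], st$compound_id)]
    current <- current[have][sc <= thr[tn]]
    funnel <- rbind(funnel, data.frame(
      stage = paste0("dock_", tn), n_in = n_in, n_out = length(current),
      fraction = if (n_in > 0) length(current) / n_in else NA_real_))
  }
  list(survivors = current, funnel = funnel)
}

#' Synthetic docking-score generator
#'
#' Seeded Gaussian score sets for calibration tests, centred on the
#' requested medians. The packaged defaults mirror reported calibration conditions:
#' 81 actives versus 200 inactives per target, with median pairs
#' PDE10A (-6.93, -5.64), A2AR (-7.66, -6.01), A1R (-7.60, -5.66).
#'
#' @param n_active,n_inactive sample sizes (>= 1).
#' @param median_active,median_inactive centre of each score distribution.
#' @param spread Gaussian standard deviation (> 0, default 1).
#' @param seed integer seed.
#' @param target_id label for the score set.
#' @return data.frame with columns `compound_id`, `target_id`, `score`,
#'   `label` (`active`/`inactive`).
#' @export
synth_scores <- function(n_active = 81, n_inactive = 200,
                         median_active = -6.93, median_inactive = -5.64,
                         spread = 1, seed = 1, target_id = "target") {
  if (n_active < 1 || n_inactive < 1) stop("need at least one score per class")
  if (spread <= 0) stop("spread must be > 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  data.frame(
    compound_id = c(paste0("act", seq_len(n_active)),
                    paste0("ina", seq_len(n_inactive))),
    target_id = target_id,
    score = c(stats::rnorm(n_active, median_active, spread),
              stats::rnorm(n_inactive, median_inactive, spread)),
    label = rep(c("active", "inactive"), c(n_active, n_inactive)),
    stringsAsFactors = FALSE)
}

#' Default docking-score medians
#'
#' The per-target active/inactive median docking scores used as
#' [synth_scores()] defaults.
#'
#' @return data.frame with columns `target`, `median_active`,
#'   `median_inactive`.
#' @export
docking_median_defaults <- function() {
  data.frame(target = c("PDE10A", "A2AR", "A1R"),
             median_active = c(-6.93, -7.66, -7.60),
             median_inactive = c(-5.64, -6.01, -5.66))
}
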