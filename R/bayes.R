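# Per-target Bernoulli naive Bayes on binary fingerprints, with Laplace
# smoothing, plus the decision-threshold calibration used for target
# prediction ("keep >= 99% of the training actives").

#' Train a Bernoulli naive Bayes target model
#'
#' Each fingerprint bit is modelled as an independent Bernoulli variable per
#' class, with Laplace smoothing `alpha`; class priors come from the class
#' sizes. The decision threshold is calibrated right after training (see
#' [calibrate_threshold()]); `threshold_mode = "recall"` (default) picks the
#' smallest posterior cutoff retaining at least `recall` of the training
#' actives, `"fixed"` uses `fixed_threshold` directly.
#'
#' @param active_fp binary matrix of active fingerprints (rows = molecules).
#' @param inactive_fp binary matrix of inactive fingerprints, same width.
#' @param alpha Laplace smoothing parameter (> 0, default 1).
#' @param target_id label stored on the model.
#' @param threshold_mode `"recall"` or `"fixed"`.
#' @param recall training recall retained by the calibrated threshold.
#' @param fixed_threshold posterior cutoff used when `threshold_mode` is
#'   `"fixed"`.
#' @return object of class `nb_model`: log-probability tables, priors,
#'   `decision_threshold`, and calibration metadata.
#' @export
nb_train <- function(active_fp, inactive_fp, alpha = 1,
                     target_id = "target",
                     threshold_mode = c("recall", "fixed"),
                     recall = 0.99, fixed_threshold = 0.01) {
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(dim(active_fp))) active_fp <- matrix(active_fp, nrow = 1)
  if (is.null(dim(inactive_fp))) inactive_fp <- matrix(inactive_fp, nrow = 1)
  na <- nrow(active_fp); ni <- nrow(inactive_fp)
  if (na == 0 || ni == 0) stop("both classes must be nonempty")
  if (ncol(active_fp) != ncol(inactive_fp)) {
    stop("fingerprint widths differ between classes")
  }
  if (alpha <= 0) stop("alpha must be > 0")
  p_act <- (colSums(active_fp) + alpha) / (na + 2 * alpha)
  p_ina <- (colSums(inactive_fp) + alpha) / (ni + 2 * alpha)
  model <- structure(list(
    target_id = target_id,
    n_bits = ncol(active_fp),
    alpha = alpha,
    log_p1 = cbind(active = log(p_act), inactive = log(p_ina)),
    log_p0 = cbind(active = log1p(-p_act), inactive = log1p(-p_ina)),
    log_prior = c(active = log(na / (na + ni)),
                  inactive = log(ni / (na + ni))),
    n_train = c(active = na, inactive = ni),
    decision_threshold = fixed_threshold,
    calibration_meta = list(mode = threshold_mode)),
    class = "nb_model")
  if (threshold_mode == "recall") {
    model <- calibrate_threshold(model, active_fp, recall = recall)
  } else {
    model$calibration_meta$fixed_threshold <- fixed_threshold
  }
  model
}

#' @export
print.nb_model <- function(x, ...) {
  cat("<nb_model> target ", x$target_id, ": ", x$n_bits, " bits, ",
      x$n_train["active"], " actives / ", x$n_train["inactive"],
      " inactives, alpha = ", x$alpha, ", threshold = ",
      signif(x$decision_threshold, 4), " (", x$calibration_meta$mode,
      ")\n", sep = "")
  invisible(x)
}

#' Posterior probability of activity
#'
#' @param model an `nb_model`.
#' @param fp binary matrix (or single vector) of fingerprints with the
#'   model's bit width.
#' @return numeric vector of posterior probabilities of the active class.
#' @export
nb_posterior <- function(model, fp) {
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  if (ncol(fp) != model$n_bits) {
    stop("fingerprint width ", ncol(fp), " does not match model (",
         model$n_bits, ")")
  }
  ll_act <- fp %*% model$log_p1[, "active"] +
    (1 - fp) %*% model$log_p0[, "active"] + model$log_prior["active"]
  ll_ina <- fp %*% model$log_p1[, "inactive"] +
    (1 - fp) %*% model$log_p0[, "inactive"] + model$log_prior["inactive"]
  as.numeric(1 / (1 + exp(ll_ina - ll_act)))
}

#' Predict activity calls
#'
#' A molecule is called active when its posterior is greater than or equal
#' to the model's decision threshold (ties at the boundary are active).
#'
#' @inheritParams nb_posterior
#' @return data.frame with columns `posterior` and `call`.
#' @export
nb_predict <- function(model, fp) {
  post <- nb_posterior(model, fp)
  data.frame(posterior = post, call = post >= model$decision_threshold)
}

#' Calibrate the decision threshold for a target recall
#'
#' Sets the model threshold to the largest posterior cutoff that still
#' retains at least `recall` of the given actives (so training-set recall at
#' the threshold is >= `recall` by construction).
#'
#' @param model an `nb_model`.
#' @param active_fp fingerprints of the actives to calibrate on.
#' @param recall minimum fraction of actives retained (default 0.99).
#' @return the model with `decision_threshold` and calibration metadata set.
#' @export
calibrate_threshold <- function(model, active_fp, recall = 0.99) {
  post <- sort(nb_posterior(model, active_fp), decreasing = TRUE)
  k <- ceiling(recall * length(post))
  model$decision_threshold <- post[k]
  model$calibration_meta <- list(mode = "recall", recall = recall,
                                 n_calibration = length(post))
  model
}
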