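# Library-vs-background enrichment statistics for target prediction:
# the empirical estimation score (tail probability of the predicted-active
# rate under background resampling), the average ratio, and the
# Yates-corrected chi-square on the 2x2 predicted/not-predicted table.
# A target counts as enriched when estimation score <= 0.01 AND
# chi-square p <= 0.05.

#' Yates-corrected chi-square for a 2x2 table
#'
#' Closed-form continuity-corrected statistic
#' `n (|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, clamped to 0 when the
#' correction exceeds `|ad - bc|`; p-value from the upper tail of
#' chi-square with 1 degree of freedom.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @return list with `statistic` and `p`.
#' @examples
#' chi_square_yates(matrix(c(30, 10, 70, 90), 2, 2))
#' @export
chi_square_yates <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0)) stop("counts must be nonnegative")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  marg <- c(`row 1` = a + b, `row 2` = c + d,
            `column 1` = a + c, `column 2` = b + d)
  if (any(marg == 0)) {
    stop("chi-square undefined: zero marginal in ",
         names(marg)[which(marg == 0)[1]])
  }
  delta <- max(0, abs(a * d - b * c) - n / 2)
  stat <- n * delta^2 / prod(marg)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Enrichment report for a predicted library
#'
#' Compares the predicted-active rate of a candidate library against
#' seed-determined background samples of equal size (drawn without
#' replacement). The estimation score is the fraction of background samples
#' whose hit rate is at least the library's; the average ratio is the mean
#' of sample rate / library rate. The 2x2 chi-square contrasts
#' predicted/not-predicted counts in the library versus the whole
#' background pool.
#'
#' @param library_calls logical vector: per-candidate predicted-active calls.
#' @param background_calls logical vector of calls over the background pool
#'   (must be longer than the library).
#' @param n_resamples number of background samples (default 1000).
#' @param seed integer seed for the resampling draws.
#' @param target_id label for the report.
#' @param score_cutoff enrichment cutoff on the estimation score
#'   (default 0.01).
#' @param p_cutoff enrichment cutoff on the chi-square p (default 0.05).
#' @param tie_break `"midp"` (default) scores ties between sample and
#'   library hit rates at half weight, which keeps the score uniform under
#'   the null despite the discreteness of hit rates; `"geq"` uses the plain
#'   at-least-as-high tail and is conservative.
#' @return object of class `enrichment_report`: a list with
#'   `library_hit_rate`, `estimation_score`, `average_ratio`, `chi2_stat`,
#'   `chi2_p`, `enriched`, `n_resamples`, `seed`, and a `note` flagging the
#'   empirical-tail definition of the estimation score.
#' @export
enrichment_report <- function(library_calls, background_calls,
                              n_resamples = 1000, seed = 1,
                              target_id = "target",
                              score_cutoff = 0.01, p_cutoff = 0.05,
                              tie_break = c("midp", "geq")) {
  tie_break <- match.arg(tie_break)
  nl <- length(library_calls); nb <- length(background_calls)
  if (nl < 1) stop("empty library")
  if (nb <= nl) {
    stop("background pool (", nb, ") must be larger than the library (",
         nl, ") for sampling without replacement")
  }
  lib_rate <- mean(library_calls)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  calls <- as.numeric(background_calls)
  rates <- vapply(seq_len(n_resamples), function(i) {
    mean(calls[sample.int(nb, nl)])
  }, numeric(1))
  est <- if (tie_break == "midp") {
    mean(rates > lib_rate) + 0.5 * mean(rates == lib_rate)
  } else {
    mean(rates >= lib_rate)
  }
  avg_ratio <- if (lib_rate == 0) Inf else mean(rates) / lib_rate
  tab <- matrix(c(sum(library_calls), nl - sum(library_calls),
                  sum(background_calls), nb - sum(background_calls)),
                nrow = 2, byrow = TRUE)
  # a zero column marginal (nothing predicted active anywhere, or
  # everything) carries no evidence of association
  chi <- if (any(colSums(tab) == 0)) list(statistic = 0, p = 1)
         else chi_square_yates(tab)
  structure(list(
    target_id = target_id,
    library_hit_rate = lib_rate,
    estimation_score = est,
    average_ratio = avg_ratio,
    chi2_stat = chi$statistic,
    chi2_p = chi$p,
    enriched = is.finite(avg_ratio) && est <= score_cutoff &&
      chi$p <= p_cutoff,
    n_resamples = n_resamples,
    seed = seed,
    note = "estimation score: empirical tail probability under background resampling"),
    class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report> ", x$target_id,
      ": hit rate ", signif(x$library_hit_rate, 3),
      ", estimation score ", signif(x$estimation_score, 3),
      ", average ratio ", signif(x$average_ratio, 3),
      ", chi2 p ", signif(x$chi2_p, 3),
      if (x$enriched) " [enriched]" else " [not enriched]", "\n", sep = "")
  invisible(x)
}

#' Multi-target prediction calls
#'
#' A candidate is a predicted multi-target ligand when it is called active
#' by every target model (conjunction).
#'
#' @param models named list of `nb_model` objects.
#' @param fp fingerprint matrix of the candidates.
#' @param ids candidate identifiers (default row indices).
#' @return data.frame with one posterior/call column pair per target and a
#'   `multi_target` conjunction column.
#' @export
multi_target_calls <- function(models, fp, ids = NULL) {
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(fp)))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  all_call <- rep(TRUE, nrow(fp))
  for (tn in names(models)) {
    pred <- nb_predict(models[[tn]], fp)
    out[[paste0("posterior_", tn)]] <- pred$posterior
    out[[paste0("call_", tn)]] <- pred$call
    all_call <- all_call & pred$call
  }
  out$multi_target <- all_call
  out
}
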