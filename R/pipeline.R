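# Campaign orchestration: curate -> scaffolds -> RECAP -> focus ->
# predict + enrich -> gate -> series -> properties, with every stage
# artifact persisted under a run directory and a funnel manifest.

#' Build and validate a campaign configuration
#'
#' @param targets character vector of target ids (>= 2).
#' @param fixtures a fixture bundle from [make_fixtures()], or `NULL` to
#'   generate one from `seed`.
#' @param run_dir directory for stage artifacts.
#' @param seed master seed; stage seeds are derived from it.
#' @param max_value,min_confidence activity curation cutoffs (nM, score).
#' @param top_k heterocycle ranking depth.
#' @param whitelist frameworks always kept in the focused set.
#' @param min_fragment_heavy_atoms,max_products RECAP controls.
#' @param n_bits,alpha,threshold_mode naive Bayes controls.
#' @param n_resamples,score_cutoff,p_cutoff enrichment controls.
#' @param max_profiled cap on compounds sent to property profiling.
#' @return validated config (class `campaign_config`).
#' @export
campaign_config <- function(targets = c("A1R", "A2AR", "PDE10A"),
                            fixtures = NULL,
                            run_dir = tempfile("mtlkit_run_"),
                            seed = 1,
                            max_value = 1000, min_confidence = 8L,
                            top_k = 30, whitelist = character(),
                            min_fragment_heavy_atoms = 3,
                            max_products = 400,
                            n_bits = 2048, alpha = 1,
                            threshold_mode = "recall",
                            n_resamples = 1000,
                            score_cutoff = 0.01, p_cutoff = 0.05,
                            max_profiled = 25) {
  cfg <- list(targets = targets, fixtures = fixtures, run_dir = run_dir,
              seed = seed, max_value = max_value,
              min_confidence = min_confidence, top_k = top_k,
              whitelist = whitelist,
              min_fragment_heavy_atoms = min_fragment_heavy_atoms,
              max_products = max_products, n_bits = n_bits, alpha = alpha,
              threshold_mode = threshold_mode, n_resamples = n_resamples,
              score_cutoff = score_cutoff, p_cutoff = p_cutoff,
              max_profiled = max_profiled)
  if (!length(cfg$targets)) stop("config error: empty target list")
  if (length(cfg$targets) < 2) stop("config error: need >= 2 targets")
  if (cfg$max_products < 1) stop("config error: max_products must be >= 1")
  if (cfg$top_k < 1) stop("config error: top_k must be >= 1")
  structure(cfg, class = "campaign_config")
}

#' Read a campaign configuration from YAML
#'
#' @param path YAML file whose keys match [campaign_config()] arguments.
#' @return validated config.
#' @export
read_campaign_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(campaign_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(campaign_config, vals)
}

#' Run the full design campaign
#'
#' Executes every stage in order on the configured fixture bundle and
#' writes one artifact per stage (CSV/JSON) under `run_dir`, plus
#' `manifest.json` with per-stage counts, parameters, seeds and artifact
#' checksums. Candidate docking scores for the gate are drawn with the
#' synthetic score generator around the per-target active medians, keyed to
#' the master seed. Deterministic: identical config and seed give identical
#' stage artifacts.
#'
#' @param config a `campaign_config`.
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly; stage outputs are in
#'   `attr(manifest, "stages")` and on disk.
#' @export
run_campaign <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "campaign_config"))
  t0 <- Sys.time()
  dir.create(config$run_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[mtlkit] ", ...)
  fx <- config$fixtures
  if (is.null(fx)) fx <- make_fixtures(seed = config$seed)
  stages <- list(); counts <- list()
  art <- function(name, obj) {
    path <- file.path(config$run_dir, name)
    if (is.data.frame(obj)) utils::write.csv(obj, path, row.names = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              force = TRUE)
    path
  }
  paths <- character(0)

  # 1 curate ---------------------------------------------------------------
  curated <- list()
  for (tn in config$targets) {
    cpds <- fx$compounds[fx$compounds$target == tn, , drop = FALSE]
    tab <- compound_table(cpds$smiles, id = cpds$id)
    curated[[tn]] <- filter_actives(tab, fx$activities, tn,
                                    max_value = config$max_value,
                                    min_confidence = config$min_confidence)
    say("curate ", tn, ": ", nrow(tab), " -> ", nrow(curated[[tn]]))
  }
  counts$curated <- vapply(curated, nrow, 0)
  paths <- c(paths, art("curated.csv", do.call(rbind, Map(function(df, tn) {
    df$target <- tn; df
  }, curated, names(curated)))))

  # 2 scaffolds ------------------------------------------------------------
  ranked <- lapply(curated, function(df) {
    frequency_rank(df$smiles_canonical, top_k = config$top_k)
  })
  common <- common_heterocycles(ranked, top_k = config$top_k,
                                whitelist = config$whitelist)
  say("scaffolds: ", length(common), " common heterocycle(s)")
  counts$common_heterocycles <- length(common)
  paths <- c(paths, art("ranked_frameworks.csv",
                        do.call(rbind, Map(function(df, tn) {
                          df$target <- tn; df
                        }, ranked, names(ranked)))))
  paths <- c(paths, art("common_heterocycles.json", as.list(common)))

  # 3 RECAP ----------------------------------------------------------------
  all_actives <- unique(unlist(lapply(curated, `[[`, "smiles_canonical")))
  pools <- lapply(all_actives, function(s) {
    recap_fragment(s, min_heavy_atoms = config$min_fragment_heavy_atoms)
  })
  pool <- do.call(merge_pools, pools)
  library_raw <- recap_recombine(pool, max_products = config$max_products,
                                 seed = config$seed + 101,
                                 parents = all_actives)
  say("recap: ", length(pool), " fragments -> ", nrow(library_raw),
      " candidates")
  counts$fragments <- length(pool)
  counts$library_raw <- nrow(library_raw)
  paths <- c(paths, art("library_raw.csv", library_raw))

  # 4 focus ----------------------------------------------------------------
  focused <- focus_library(library_raw, common)
  say("focus: ", nrow(library_raw), " -> ", nrow(focused))
  counts$library_focused <- nrow(focused)
  paths <- c(paths, art("library_focused.csv", focused))

  # 5 predict + enrich ------------------------------------------------------
  fp_lib <- morgan_fp(focused$smiles, n_bits = config$n_bits)
  fp_bg <- morgan_fp(fx$background$smiles, n_bits = config$n_bits)
  fp_ina <- morgan_fp(fx$inactives$smiles, n_bits = config$n_bits)
  models <- list(); reports <- list()
  for (tn in config$targets) {
    fp_act <- morgan_fp(curated[[tn]]$smiles_canonical,
                        n_bits = config$n_bits)
    models[[tn]] <- nb_train(fp_act, fp_ina, alpha = config$alpha,
                             target_id = tn,
                             threshold_mode = config$threshold_mode)
    lib_calls <- nb_predict(models[[tn]], fp_lib)$call
    bg_calls <- nb_predict(models[[tn]], fp_bg)$call
    reports[[tn]] <- enrichment_report(
      lib_calls, bg_calls, n_resamples = config$n_resamples,
      seed = config$seed + 211, target_id = tn,
      score_cutoff = config$score_cutoff, p_cutoff = config$p_cutoff)
    say("predict ", tn, ": hit rate ",
        signif(reports[[tn]]$library_hit_rate, 3),
        if (reports[[tn]]$enriched) " [enriched]" else "")
  }
  calls <- multi_target_calls(models, fp_lib, ids = focused$id)
  predicted <- calls$id[calls$multi_target]
  counts$predicted_multitarget <- length(predicted)
  say("multi-target predicted: ", length(predicted))
  paths <- c(paths, art("predictions.csv", calls))
  paths <- c(paths, art("enrichment.json", lapply(reports, unclass)))

  # 6 gate ------------------------------------------------------------------
  med <- docking_median_defaults()
  calib <- list(); cand_scores <- list()
  for (i in seq_len(nrow(med))) {
    tn <- med$target[i]
    if (!tn %in% config$targets) next
    lab <- fx$docking[fx$docking$target_id == tn, , drop = FALSE]
    calib[[tn]] <- best_f1_threshold(lab$score[lab$label == "active"],
                                     lab$score[lab$label == "inactive"],
                                     target_id = tn)
    old <- .Random.seed_save()
    set.seed((config$seed + 307 + i) %% .Machine$integer.max)
    cand_scores[[tn]] <- data.frame(
      compound_id = focused$id, target_id = tn,
      score = stats::rnorm(nrow(focused), med$median_active[i], 1))
    .Random.seed_restore(old)
  }
  gate <- gate_candidates(do.call(rbind, cand_scores), calib, predicted)
  say("gate: ", length(predicted), " -> ", length(gate$survivors))
  counts$survivors <- length(gate$survivors)
  paths <- c(paths, art("funnel.csv", gate$funnel))
  paths <- c(paths, art(
    "calibrations.json",
    lapply(calib, function(x) unclass(x)[setdiff(names(unclass(x)),
                                                 "sweep_table")])))

  # 7 series ----------------------------------------------------------------
  surv_smiles <- focused$smiles[focused$id %in% gate$survivors]
  series_on <- if (length(surv_smiles)) surv_smiles else focused$smiles
  series <- series_frequencies(series_on)
  paths <- c(paths, art("series.csv", series))

  # 8 properties -------------------------------------------------------------
  prof_smiles <- utils::head(series_on, config$max_profiled)
  profile <- property_profile(prof_smiles)
  paths <- c(paths, art("profile.csv", profile))

  manifest <- list(
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    seed = config$seed,
    targets = config$targets,
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("fixtures", "run_dir"))],
    counts = counts,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    artifacts = as.list(tools::md5sum(paths)))
  # funnel monotonicity from the focused library onward
  stopifnot(counts$library_focused >= counts$predicted_multitarget,
            counts$predicted_multitarget >= counts$survivors)
  jsonlite::write_json(manifest, file.path(config$run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "stages") <- list(
    curated = curated, ranked = ranked, common = common,
    library_raw = library_raw, focused = focused, models = models,
    reports = reports, calls = calls, calibrations = calib, gate = gate,
    series = series, profile = profile)
  invisible(manifest)
}
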