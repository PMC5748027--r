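# Synthetic campaign fixtures.
#
# make_fixtures() emulates the statistical structure of a realistic input set:
# per-target active sets built by decorating planted heterocycle cores
# (pyridine, pyrimidine, piperazine, 1H-pyrazole -- the cores shared by all
# three targets -- plus purine/xanthine for the adenosine receptors only)
# with RECAP-joinable substituents; inactive and background pools from
# non-core chemotypes; and labelled docking scores drawn around the
# literature-reported median pairs. A ground-truth manifest records every planted
# quantity so tests can assert exact recovery.

.CORES <- list(
  pyridine   = "c1ccncc1",
  pyrimidine = "c1cncnc1",
  piperazine = "C1CNCCN1",
  pyrazole   = "c1cc[nH]n1",
  purine     = "c1nc2[nH]cnc2cn1",     # adenosine-receptor specific
  xanthine   = "Cn1cnc2c1c(=O)[nH]c(=O)n2C"
)

# decorations end with the atom that bonds to the first atom of the core;
# each carries at least one RECAP-cleavable bond (or none, for realism)
.DECORATIONS <- c(
  "CC(=O)N",            # amide
  "CCC(=O)N",           # amide
  "c1ccccc1C(=O)N",     # benzamide
  "CCOC",               # ether
  "c1ccccc1",           # biaryl / aryl-alkyl
  "CCN",                # amine
  "CC(C)C",             # plain alkyl (no cleavable bond)
  "CCS(=O)(=O)N"        # sulfonamide
)

.BG_PARTS1 <- c("CC", "CCC", "CCCO", "c1ccccc1", "C1CCCCC1", "CCN",
                "c1ccc2ccccc2c1", "CC(C)")
.BG_PARTS2 <- c("CC", "CCO", "C(=O)NC", "C(=O)OC", "CCC", "C1CCCCC1",
                "CS(=O)(=O)C", "C(C)O")

# planted per-core composition of each target's active set (fractions)
.CORE_WEIGHTS <- list(
  A1R    = c(pyridine = 0.30, pyrimidine = 0.20, piperazine = 0.15,
             pyrazole = 0.10, purine = 0.15, xanthine = 0.10),
  A2AR   = c(pyridine = 0.25, pyrimidine = 0.25, piperazine = 0.10,
             pyrazole = 0.15, purine = 0.15, xanthine = 0.10),
  PDE10A = c(pyridine = 0.35, pyrimidine = 0.25, piperazine = 0.20,
             pyrazole = 0.20)
)

#' Generate the synthetic fixture bundle
#'
#' Builds per-target actives (decorated planted cores), a non-core
#' inactive set, a diverse background pool, labelled docking scores with
#' literature-reported score medians, and a ground-truth manifest. Roughly 10%
#' of the active-set annotations are planted as filter-failures (activity
#' above 1 uM or confidence below 8) to exercise the curation stage.
#'
#' @param seed integer seed controlling every random draw.
#' @param n_actives_per_target actives per target (>= 10, default 60).
#' @param n_inactives size of the non-core inactive set (>= 10,
#'   default 120).
#' @param n_background size of the background pool (>= 10, default 300).
#' @param dir optional directory; when given, all tables are also written
#'   as CSV files there.
#' @return list with `compounds` (per-target actives, long format),
#'   `activities`, `inactives`, `background`, `docking` (labelled scores,
#'   3 targets), and `ground_truth` (planted core counts per target,
#'   filter-failure counts, seeds, medians).
#' @export
make_fixtures <- function(seed = 1, n_actives_per_target = 60,
                          n_inactives = 120, n_background = 300,
                          dir = NULL) {
  if (n_actives_per_target < 10 || n_inactives < 10 || n_background < 10) {
    stop("fixture sizes must be >= 10")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)

  targets <- names(.CORE_WEIGHTS)
  core_counts <- lapply(.CORE_WEIGHTS, function(w) {
    k <- floor(w * n_actives_per_target)
    # deterministic remainder assignment: largest weights first
    rem <- n_actives_per_target - sum(k)
    ord <- order(-w, names(w))
    if (rem > 0) k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
    k
  })

  actives <- list(); activities <- list()
  for (tn in targets) {
    counts <- core_counts[[tn]]
    cores <- rep(names(counts), counts)
    dec <- sample(.DECORATIONS, length(cores), replace = TRUE)
    smi <- paste0(dec, vapply(cores, function(cn) .CORES[[cn]], ""))
    ids <- sprintf("%s_act%03d", tn, seq_along(smi))
    actives[[tn]] <- data.frame(id = ids, smiles = smi, target = tn,
                                core = cores, stringsAsFactors = FALSE)
    # ~10% planted filter failures
    n_fail <- max(1, round(0.1 * length(ids)))
    fail_idx <- sample(seq_along(ids), n_fail)
    value <- stats::rlnorm(length(ids), meanlog = log(100), sdlog = 1)
    value <- pmin(value, 990)
    confidence <- rep(9L, length(ids))
    half <- fail_idx[seq_len(ceiling(n_fail / 2))]
    value[half] <- stats::runif(length(half), 1500, 9000)
    low_conf <- setdiff(fail_idx, half)
    confidence[low_conf] <- sample(0:7, length(low_conf), replace = TRUE)
    activities[[tn]] <- activity_table(
      id = ids, target = tn,
      kind = sample(c("Ki", "IC50"), length(ids), replace = TRUE),
      value = value, unit = "nM", confidence = confidence)
    activities[[tn]]$planted_fail <- seq_along(ids) %in% fail_idx
  }

  gen_noncore <- function(n, prefix) {
    out <- character(0); guard <- 0
    while (length(out) < n && guard < 50 * n) {
      guard <- guard + 1
      k <- sample(1:2, 1)
      s <- paste0(sample(.BG_PARTS1, 1),
                  paste(sample(.BG_PARTS2, k, replace = TRUE),
                        collapse = ""))
      out <- unique(c(out, s))
    }
    data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
               smiles = out[seq_len(n)], stringsAsFactors = FALSE)
  }
  inactives <- gen_noncore(n_inactives, "ina")
  background <- gen_noncore(n_background, "bg")

  med <- docking_median_defaults()
  docking <- do.call(rbind, lapply(seq_len(nrow(med)), function(i) {
    synth_scores(n_active = 81, n_inactive = 200,
                 median_active = med$median_active[i],
                 median_inactive = med$median_inactive[i],
                 spread = 1, seed = seed + i,
                 target_id = med$target[i])
  }))

  fx <- list(
    compounds = do.call(rbind, actives),
    activities = do.call(rbind, activities),
    inactives = inactives,
    background = background,
    docking = docking,
    ground_truth = list(
      seed = seed,
      core_counts = core_counts,
      core_smiles = .CORES,
      n_filter_fail = vapply(activities, function(a) sum(a$planted_fail), 0),
      docking_medians = med,
      decorations = .DECORATIONS))
  rownames(fx$compounds) <- rownames(fx$activities) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fx$compounds, file.path(dir, "actives.csv"),
                     row.names = FALSE)
    utils::write.csv(fx$activities, file.path(dir, "activities.csv"),
                     row.names = FALSE)
    utils::write.csv(fx$inactives, file.path(dir, "inactives.csv"),
                     row.names = FALSE)
    utils::write.csv(fx$background, file.path(dir, "background.csv"),
                     row.names = FALSE)
    utils::write.csv(fx$docking, file.path(dir, "docking_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(fx$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  fx
}

#' The synthesized 4,6-disubstituted 2-aminopyridine-3-carbonitriles
#'
#' The 25 compounds of the prospective validation series, encoded as SMILES
#' from their published IUPAC names, with printed molecular formulas and the
#' reported activities (PDE10A IC50 in uM; A1R/A2AR Ki in nM where
#' determined) and printed logP/tPSA where stated.
#'
#' @return data.frame, one row per compound.
#' @export
synthesized_compounds <- function() {
  path <- system.file("extdata", "synthesized_compounds.csv",
                      package = "mtlkit")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
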