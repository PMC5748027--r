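# Compound ingestion, standardization and activity filtering.
#
# A compound table is a plain data.frame with one row per compound:
#   id, smiles_raw, smiles_canonical, source
# where source is one of known_active, background, recap_candidate,
# synthesized_fixture. Activity annotations live in a separate long table
# (id, target, kind, value_nM, confidence) so one compound can carry
# measurements against several targets.

STANDARDIZER_META <- list(
  backend = OB_BACKEND,
  steps = c("keep-largest-fragment", "neutralize-simple-charges",
            "canonicalize"),
  tautomer_ruleset = "ob-kekule-canonical-1"
)

#' Standardize SMILES strings
#'
#' Applies the pipeline's standardization: keep the largest covalent
#' fragment, neutralize simple protonation states, and canonicalise.
#' Protonated amines lose a proton, carboxylates/phenolates/thiolates gain
#' one; quaternary ammonium and charge-separated groups whose neighbour
#' carries the opposite charge (nitro, N-oxides) are left untouched.
#' The transform is idempotent: standardizing its own output is a no-op.
#'
#' @param smiles character vector of raw SMILES.
#' @return character vector of standardized canonical SMILES, with the
#'   standardizer description attached as attribute `standardizer`.
#' @examples
#' standardize_smiles(c("CCO.Cl", "CC[NH3+]"))
#' @export
standardize_smiles <- function(smiles) {
  out <- vapply(smiles, function(s) .standardize_one(s), "", USE.NAMES = FALSE)
  attr(out, "standardizer") <- STANDARDIZER_META
  out
}

.standardize_one <- function(s) {
  can <- canonical_smiles(s)
  # largest covalent fragment: split on dot-disconnections
  parts <- strsplit(can, ".", fixed = TRUE)[[1]]
  if (length(parts) > 1) {
    sizes <- vapply(parts, smiles_heavy_atoms, numeric(1))
    parts <- parts[order(-sizes, parts)]
    can <- canonical_smiles(parts[1])
  }
  mg <- parse_mol(can, canonicalize = FALSE)
  chg <- mg$atoms$charge
  if (any(chg != 0)) {
    for (i in which(chg != 0)) {
      nbr <- mg_neighbors(mg, i)$nbr
      opposite <- length(nbr) && any(sign(chg[nbr]) == -sign(chg[i]))
      if (opposite) next
      el <- mg$atoms$elem[i]
      if (chg[i] > 0 && el %in% c("N", "P") && mg$atoms$nH[i] > 0) {
        mg$atoms$charge[i] <- 0L            # deprotonate ammonium-like
      } else if (chg[i] < 0 && el %in% c("O", "S", "N", "C")) {
        mg$atoms$charge[i] <- 0L            # protonate carboxylate-like
      }
    }
    if (!identical(mg$atoms$charge, chg)) can <- mg_smiles(mg)
  }
  canonical_smiles(can)
}

.SOURCES <- c("known_active", "background", "recap_candidate",
              "synthesized_fixture")

#' Build a compound table
#'
#' Standardizes raw SMILES and assembles the data.frame used throughout the
#' pipeline. Unparsable SMILES are dropped with a warning naming them.
#'
#' @param smiles character vector of raw SMILES.
#' @param id compound identifiers (unique); default `cpd1..cpdN`.
#' @param source provenance label, one of `known_active`, `background`,
#'   `recap_candidate`, `synthesized_fixture`.
#' @return data.frame with columns `id`, `smiles_raw`, `smiles_canonical`,
#'   `source`.
#' @export
compound_table <- function(smiles, id = NULL, source = "known_active") {
  source <- match.arg(source, .SOURCES)
  if (is.null(id)) id <- paste0("cpd", seq_along(smiles))
  if (anyDuplicated(id)) stop("compound ids must be unique")
  if (!length(smiles)) {
    return(data.frame(id = character(0), smiles_raw = character(0),
                      smiles_canonical = character(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  std <- vapply(smiles, function(s) {
    tryCatch(.standardize_one(s), error = function(e) NA_character_)
  }, "", USE.NAMES = FALSE)
  bad <- is.na(std)
  if (any(bad)) {
    warning("dropping ", sum(bad), " unparsable SMILES: ",
            paste(sQuote(smiles[bad]), collapse = ", "))
  }
  data.frame(id = id[!bad], smiles_raw = smiles[!bad],
             smiles_canonical = std[!bad], source = source,
             stringsAsFactors = FALSE)
}

#' Build an activity table
#'
#' @param id compound identifiers matching a compound table.
#' @param target target identifier (e.g. `"A1R"`, `"A2AR"`, `"PDE10A"`).
#' @param kind activity type, `"Ki"` or `"IC50"`.
#' @param value numeric activity values (> 0).
#' @param unit unit of `value`: `"nM"` or `"uM"`; converted to nM.
#' @param confidence integer confidence score in \[0, 9\].
#' @return data.frame with columns `id`, `target`, `kind`, `value_nM`,
#'   `confidence`.
#' @export
activity_table <- function(id, target, kind, value, unit = "nM",
                           confidence = 9L) {
  kind <- match.arg(kind, c("Ki", "IC50"), several.ok = TRUE)
  if (any(value <= 0)) stop("activity values must be positive")
  unit <- rep_len(unit, length(value))
  if (!all(unit %in% c("nM", "uM"))) stop("unit must be 'nM' or 'uM'")
  value_nM <- ifelse(unit == "uM", value * 1000, value)
  confidence <- as.integer(rep_len(confidence, length(id)))
  if (any(confidence < 0 | confidence > 9)) {
    stop("confidence must be in [0, 9]")
  }
  data.frame(id = id, target = rep_len(target, length(id)),
             kind = rep_len(kind, length(id)), value_nM = value_nM,
             confidence = confidence, stringsAsFactors = FALSE)
}

#' Filter actives for a target
#'
#' Retains compounds whose activity against `target` is at most `max_value`
#' (nM) with confidence at least `min_confidence` -- the reference-molecule
#' selection rule (Ki/IC50 <= 1 uM, confidence 8-9). When a compound carries
#' several measurements for the target, the most potent one decides and the
#' alternatives are noted in a message. Compounds with no annotation for the
#' target are excluded with a warning, not an error. Input order is kept.
#'
#' @param compounds compound table (see [compound_table()]).
#' @param activities activity table (see [activity_table()]).
#' @param target target id to filter on.
#' @param max_value maximum activity in nM (default 1000 = 1 uM).
#' @param min_confidence minimum confidence score (default 8).
#' @return the filtered compound table.
#' @export
filter_actives <- function(compounds, activities, target,
                           max_value = 1000, min_confidence = 8L) {
  act <- activities[activities$target == target, , drop = FALSE]
  missing <- setdiff(compounds$id, act$id)
  if (length(missing)) {
    warning(length(missing), " compound(s) lack an annotation for ",
            target, " and were excluded: ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  if (nrow(act) && anyDuplicated(act$id)) {
    message("multiple measurements per compound for ", target,
            "; keeping the most potent")
    act <- act[order(act$value_nM), , drop = FALSE]
    act <- act[!duplicated(act$id), , drop = FALSE]
  }
  ok <- act$id[act$value_nM <= max_value & act$confidence >= min_confidence]
  compounds[compounds$id %in% ok, , drop = FALSE]
}

#' Read compounds from a file
#'
#' Supported formats: `csv` (columns `id`, `smiles`, and optionally
#' `target`, `activity_type`, `activity_value`, `activity_unit`,
#' `confidence`), `smiles` (one SMILES per line, optional tab-separated id)
#' and `sdf` (V2000). Malformed rows are skipped with a warning giving the
#' line number.
#'
#' @param path input file.
#' @param format one of `"csv"`, `"smiles"`, `"sdf"`.
#' @param source provenance label for the resulting table.
#' @return a compound table; for csv input with activity columns, the
#'   activity table is attached as attribute `activities`.
#' @export
read_compounds <- function(path, format = c("csv", "smiles", "sdf"),
                           source = "known_active") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df))) {
      stop("csv must have columns 'id' and 'smiles'")
    }
    tab <- .table_skipping_bad(df$smiles, df$id, source)
    actcols <- c("target", "activity_type", "activity_value")
    if (all(actcols %in% names(df))) {
      keep <- df$id %in% tab$id
      attr(tab, "activities") <- activity_table(
        id = df$id[keep], target = df$target[keep],
        kind = df$activity_type[keep], value = df$activity_value[keep],
        unit = if ("activity_unit" %in% names(df)) df$activity_unit[keep] else "nM",
        confidence = if ("confidence" %in% names(df)) df$confidence[keep] else 9L)
    }
    tab
  } else if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      return(compound_table(character(0), character(0), source))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smi <- vapply(parts, `[`, "", 1)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("cpd", i)
    }, "")
    .table_skipping_bad(smi, ids, source)
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    valid <- ChemmineR::validSDF(sdfset)
    if (any(!valid)) {
      warning("skipping ", sum(!valid), " invalid SDF record(s) at ",
              paste(which(!valid), collapse = ", "))
    }
    sdfset <- sdfset[valid]
    smi <- as.character(ChemmineR::sdf2smiles(sdfset))
    ids <- ChemmineR::sdfid(sdfset)
    ids[!nzchar(ids)] <- paste0("cpd", which(!nzchar(ids)))
    .table_skipping_bad(smi, ids, source)
  }
}

.table_skipping_bad <- function(smiles, ids, source) {
  std <- vapply(smiles, function(s) {
    tryCatch(.standardize_one(s), error = function(e) NA_character_)
  }, "", USE.NAMES = FALSE)
  bad <- which(is.na(std))
  if (length(bad)) {
    warning("skipped ", length(bad), " malformed record(s) at row(s): ",
            paste(bad, collapse = ", "))
  }
  keep <- setdiff(seq_along(std), bad)
  data.frame(id = as.character(ids[keep]), smiles_raw = smiles[keep],
             smiles_canonical = std[keep], source = source,
             stringsAsFactors = FALSE)
}

#' Write compounds to a file
#'
#' Round-trips with [read_compounds()]: id and canonical SMILES survive a
#' write/read cycle for every record.
#'
#' @param compounds compound table.
#' @param path output file.
#' @param format one of `"csv"`, `"smiles"`, `"sdf"`.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path,
                            format = c("csv", "smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(
      data.frame(id = compounds$id, smiles = compounds$smiles_canonical),
      path, row.names = FALSE)
  } else if (format == "smiles") {
    writeLines(paste(compounds$smiles_canonical, compounds$id, sep = "\t"),
               path)
  } else {
    blocks <- vapply(seq_len(nrow(compounds)), function(i) {
      mg <- parse_mol(compounds$smiles_canonical[i], canonicalize = FALSE)
      mg_to_molblock(mg, title = compounds$id[i])
    }, "")
    # mg_to_molblock already terminates records with $$$$
    cat(paste(blocks, collapse = ""), file = path)
  }
  invisible(path)
}
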