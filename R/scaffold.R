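# Ring-system (heterocycle) frequency analysis.
#
# A ring system is the framework left after breaking every acyclic single
# bond: fused/bridged/spiro assemblies stay together, substituents are
# stripped, but heteroatoms multiply bonded to a ring atom (the exocyclic
# =O/=S of xanthines, quinones, ...) are retained so that frameworks like
# xanthine survive as one unit. Aromatic perception is the backend's
# (OpenBabel) default model.

#' Extract ring-system frameworks from a molecule
#'
#' @param smiles a single SMILES string.
#' @return character vector of canonical framework SMILES (deduplicated,
#'   sorted); acyclic molecules give `character(0)`.
#' @examples
#' extract_ring_systems("CCCCCC")                  # none
#' extract_ring_systems("c1ccncc1CC1CCCCC1")       # pyridine + cyclohexane
#' @export
extract_ring_systems <- function(smiles) {
  mg <- parse_mol(smiles)
  rb <- mg$bonds[mg$bonds$in_ring, , drop = FALSE]
  if (nrow(rb) == 0) return(character(0))
  g <- igraph::graph_from_edgelist(as.matrix(rb[, c("a1", "a2")]),
                                   directed = FALSE)
  n <- nrow(mg$atoms)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  memb <- igraph::components(g)$membership
  ring_atoms <- unique(c(rb$a1, rb$a2))
  systems <- split(ring_atoms, memb[ring_atoms])
  frameworks <- vapply(systems, function(idx) {
    # retain exocyclic heteroatoms attached by a multiple bond
    extra <- integer(0)
    for (i in idx) {
      nb <- mg_neighbors(mg, i)
      sel <- nb$order >= 2 & !(nb$nbr %in% idx) &
        !(mg$atoms$elem[nb$nbr] %in% c("C", "*"))
      extra <- c(extra, nb$nbr[sel])
    }
    mg_smiles(mg_subset(mg, c(idx, extra)))
  }, "")
  sort(unique(unname(frameworks)))
}

#' Rank ring systems by frequency
#'
#' Counts, over a set of molecules, how many molecules contain each
#' ring-system framework (presence, not multiplicity), and ranks them.
#' Ties are broken by framework SMILES, lexicographically, so the ranking
#' is deterministic.
#'
#' @param smiles character vector of SMILES.
#' @param top_k keep the `top_k` most frequent frameworks (default 30).
#' @return data.frame with columns `framework`, `count`, `rank`.
#' @export
frequency_rank <- function(smiles, top_k = 30) {
  if (!length(smiles)) stop("no molecules given")
  if (top_k < 1) stop("top_k must be >= 1")
  per_mol <- lapply(smiles, extract_ring_systems)
  counts <- table(unlist(per_mol))
  if (!length(counts)) {
    return(data.frame(framework = character(0), count = integer(0),
                      rank = integer(0)))
  }
  df <- data.frame(framework = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$framework), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  utils::head(df, top_k)
}

#' Heterocycles common to all targets
#'
#' Intersects the `top_k` ring systems of every target's ranking, keeping
#' only frameworks that contain at least one non-carbon ring atom. Frameworks
#' on the whitelist are always added (the mechanism used to carry along
#' scaffolds characteristic of a subset of the targets, such as 9H-purine
#' for the adenosine receptors).
#'
#' @param ranked_per_target named list of data.frames from
#'   [frequency_rank()], one per target (>= 2 targets).
#' @param top_k intersect within the top `top_k` ranks.
#' @param whitelist canonical framework SMILES always included.
#' @return character vector of framework SMILES.
#' @export
common_heterocycles <- function(ranked_per_target, top_k = 30,
                                whitelist = character()) {
  if (length(ranked_per_target) < 2) stop("need rankings for >= 2 targets")
  tops <- lapply(ranked_per_target, function(df) {
    utils::head(df$framework[order(df$rank)], top_k)
  })
  common <- Reduce(intersect, tops)
  if (length(common)) {
    hetero <- vapply(common, function(f) {
      any(!smiles_atoms(f)$elem %in% c("C", "*"))
    }, logical(1))
    common <- common[hetero]
  }
  if (!length(common) && !length(whitelist)) {
    warning("no common heterocycle among the top-", top_k,
            " frameworks; returning empty set")
  }
  if (length(whitelist)) whitelist <- canonical_smiles(whitelist)
  sort(unique(c(common, whitelist)))
}

#' Packaged series definitions
#'
#' The four substructural series tracked among final candidates:
#' \[1,2,4\]triazolo\[1,5-c\]quinazolines, imidazo\[1,5-a\]quinoxalines,
#' 6,7-alkoxyisoquinolines and 2-aminopyridine-3-carbonitriles. Definitions
#' are read from a YAML file of `name:`/`smarts:` entries.
#'
#' @param path YAML file with fields `name` and `smarts` per entry;
#'   defaults to the packaged set.
#' @return data.frame with columns `name`, `smarts`.
#' @export
default_series <- function(path = system.file("extdata", "series_smarts.yaml",
                                              package = "mtlkit")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("series definition file not found: ", sQuote(path))
  }
  defs <- yaml::read_yaml(path)
  df <- data.frame(
    name = vapply(defs, `[[`, "", "name"),
    smarts = vapply(defs, `[[`, "", "smarts"),
    stringsAsFactors = FALSE)
  # fail fast on a SMARTS that does not compile
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({
      smarts_count("c1ccccc1", df$smarts[i]); TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("series SMARTS does not compile: ", df$name[i])
  }
  df
}

#' Series membership frequencies
#'
#' Fraction of candidates matching each series substructure. A candidate
#' matching several series counts once per series; candidates matching none
#' fall into the `other` bucket.
#'
#' @param smiles character vector of candidate SMILES (nonempty).
#' @param series data.frame with `name` and `smarts` columns
#'   (default [default_series()]).
#' @return data.frame with columns `series`, `count`, `fraction`; the last
#'   row is the `other` bucket.
#' @export
series_frequencies <- function(smiles, series = default_series()) {
  if (!length(smiles)) stop("no candidates given")
  hits <- vapply(seq_len(nrow(series)), function(i) {
    smarts_match(smiles, series$smarts[i])
  }, logical(length(smiles)))
  hits <- matrix(hits, nrow = length(smiles))
  counts <- colSums(hits)
  other <- sum(rowSums(hits) == 0)
  data.frame(
    series = c(series$name, "other"),
    count = as.integer(c(counts, other)),
    fraction = c(counts, other) / length(smiles),
    stringsAsFactors = FALSE)
}
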