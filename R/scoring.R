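# Molecular simplicity and route-level scores.
#
# Simplicity maps a 1-5 synthetic-complexity score linearly onto [0, 1]
# (1 = trivially simple); a molecule found in the building-block set is
# simple by definition (1.0). The route penalty score multiplies a
# per-step penalty SP^N with every step's forward confidence and the
# simplicity of every starting material along the route, so short,
# confident routes through simple intermediates rank first. CScore is the
# plain product of the per-step confidences.

#' Load or construct a building-block set
#'
#' Members are canonicalized at load; membership is exact string equality
#' on canonical SMILES.
#'
#' @param x Character vector of SMILES, or path to a `.smi` file (one
#'   SMILES per line, optional tab-separated id).
#' @return An object of class `bb_set`.
#' @export
bb_set <- function(x) {
  if (length(x) == 1L && file.exists(x) && grepl("\\.smi$", x)) {
    src <- x
    x <- read_smi(x)$smiles
  } else src <- ""
  members <- sort(unique(canonical_smiles(x)))
  structure(list(members = members, source = src), class = "bb_set")
}

#' @export
print.bb_set <- function(x, ...) {
  cat("<building-block set> ", length(x$members), " members\n", sep = "")
  invisible(x)
}

#' Test building-block membership
#' @param bb A `bb_set`.
#' @param m A `molecule` or SMILES string.
#' @return Logical.
#' @export
is_building_block <- function(bb, m) {
  canonicalize(m)$smiles %in% bb$members
}

#' Heuristic synthetic-complexity scorer
#'
#' Deterministic stand-in for a learned complexity model: a clipped linear
#' function of heavy-atom count, ring count and stereocenter count mapped
#' into the conventional [1, 5] complexity range. Any scorer with the same
#' signature and range can be plugged into [simplicity()] and
#' [rpscore()].
#'
#' @param m A `molecule` or SMILES string.
#' @return Complexity in [1, 5].
#' @export
heuristic_complexity <- function(m) {
  m <- canonicalize(m)
  g <- m$graph
  n_rings <- mg_nbonds(g) - g$n + max(mg_components(g))  # cyclomatic number
  n_stereo <- sum(g$chiral != "")
  raw <- 0.035 * g$n + 0.2 * n_rings + 0.25 * n_stereo
  min(5, max(1, 1 + 4 * raw / 2))
}

#' Simplicity of a molecule
#'
#' `1` when the molecule is in the building-block set; otherwise
#' `1 - (c - 1)/4` for complexity `c` in [1, 5], clipped to [0, 1].
#'
#' @param m A `molecule` or SMILES string.
#' @param bb A `bb_set`.
#' @param scorer Complexity scorer, default [heuristic_complexity()].
#' @return Simplicity in [0, 1].
#' @export
simplicity <- function(m, bb, scorer = heuristic_complexity) {
  m <- canonicalize(m)
  if (is_building_block(bb, m)) return(1.0)
  c_val <- tryCatch(scorer(m), error = function(e)
    stop("complexity scorer failed on ", m$smiles, ": ",
         conditionMessage(e)))
  if (!is.numeric(c_val) || is.na(c_val))
    stop("complexity scorer returned a non-number for ", m$smiles)
  min(1, max(0, 1 - (c_val - 1) / 4))
}

#' Route penalty score
#'
#' `SP^N * prod(CS_i) * prod(Simplicity(m))` over the `N` steps of a route
#' with forward confidences `CS_i`, where the simplicity product runs over
#' the starting materials of all steps (reagents are excluded, and by
#' default each distinct molecule is counted once even when it appears in
#' several steps; set `count_duplicates` in the configuration to count
#' repeats).
#'
#' @param route A `route` (see [search_routes()]) or any list with a
#'   `steps` element of `single_step` objects.
#' @param cfg Configuration; uses `$sp` and `$count_duplicates`.
#' @param bb A `bb_set`.
#' @param scorer Complexity scorer passed to [simplicity()].
#' @return Score in (0, 1].
#' @export
rpscore <- function(route, cfg = default_config(), bb,
                    scorer = heuristic_complexity) {
  steps <- route$steps
  if (length(steps) == 0L) stop("empty route has no penalty score")
  n <- length(steps)
  cs <- vapply(steps, function(s) s$confidence, numeric(1L))
  sm <- unlist(lapply(steps, function(s)
    vapply(s$sm_set, function(m) m$smiles, character(1L))))
  if (!isTRUE(cfg$count_duplicates)) sm <- unique(sm)
  simp <- vapply(sm, function(s) simplicity(s, bb, scorer), numeric(1L))
  cfg$sp^n * prod(cs) * prod(simp)
}

#' Route confidence score
#'
#' Product of the per-step forward-validation confidences.
#'
#' @param route A `route` or list with a `steps` element.
#' @return Score in (0, 1].
#' @export
cscore <- function(route) {
  steps <- route$steps
  if (length(steps) == 0L) stop("empty route has no confidence score")
  prod(vapply(steps, function(s) s$confidence, numeric(1L)))
}
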