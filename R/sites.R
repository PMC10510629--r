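# Enumeration of candidate disconnection sites on a product: the three
# complementary strategies (systematic, template, learned-tagger) and their
# deduplicated union, which feeds the single-step loop.

#' Systematic tagging of single atoms, bonded pairs and connected triplets
#'
#' Tags every single atom, every bonded atom pair, and every connected
#' triplet (three-atom path or three-membered ring). Topologically
#' equivalent tag sets are collapsed, so e.g. propane yields four variants,
#' not six.
#'
#' @param m A `molecule` (or SMILES string).
#' @return List of `tagged_molecule` objects with provenance
#'   `"systematic"`.
#' @export
systematic_tags <- function(m) {
  m <- canonicalize(m)
  g <- m$graph
  sets <- lapply(seq_len(g$n), identity)
  for (b in seq_along(g$bond_from))
    sets[[length(sets) + 1L]] <- c(g$bond_from[b], g$bond_to[b])
  adj <- mg_adj(g)
  trip <- list()
  for (center in seq_len(g$n)) {
    nb <- vapply(adj[[center]], function(b) mg_other(g, b, center),
                 integer(1L))
    if (length(nb) < 2L) next
    for (i in seq_len(length(nb) - 1L))
      for (j in (i + 1L):length(nb))
        trip[[length(trip) + 1L]] <- sort(c(center, nb[i], nb[j]))
  }
  # triangles appear once per vertex; plain set-dedup removes the copies
  if (length(trip) > 0L) {
    keys <- vapply(trip, paste, character(1L), collapse = ",")
    trip <- trip[!duplicated(keys)]
  }
  sets <- c(sets, trip)
  out <- lapply(sets, function(s) {
    tm <- tagged_molecule(m, s)
    attr(tm, "provenance") <- "systematic"
    tm
  })
  dedup_tagged(out)
}

#' Model-based tagging through a tagger contract
#'
#' Queries a tagger model for up to `beam` scored tagged variants of `m`,
#' parses and validates them (a suggestion whose tag-removal does not
#' re-canonicalize to `m` is dropped and counted), and deduplicates.
#'
#' @param m A `molecule` (or SMILES string).
#' @param tagger A tagger contract object (see [tagger_model()]).
#' @param beam Maximum number of suggestions requested.
#' @return List of `tagged_molecule` objects with provenance `"model"` and
#'   attribute `score`; the list carries attribute `dropped`, the count of
#'   invalid suggestions.
#' @export
model_tags <- function(m, tagger, beam = 50L) {
  m <- canonicalize(m)
  preds <- tryCatch(tagger$predict(m, beam),
                    error = function(e) {
                      warning("tagger failure on ", m$smiles, ": ",
                              conditionMessage(e))
                      list()
                    })
  out <- list()
  dropped <- 0L
  for (p in preds) {
    tm <- tryCatch(parse_tagged(p$tagged), error = function(e) NULL)
    if (is.null(tm) || !inherits(tm, "tagged_molecule") ||
        tm$molecule$smiles != m$smiles) {
      dropped <- dropped + 1L
      next
    }
    attr(tm, "provenance") <- "model"
    attr(tm, "score") <- p$score
    out[[length(out) + 1L]] <- tm
  }
  out <- dedup_tagged(out)
  attr(out, "dropped") <- dropped
  out
}

#' Enumerate candidate disconnection sites
#'
#' Union of the configured strategies (systematic, template, model),
#' deduplicated up to molecular symmetry with per-strategy provenance flags
#' retained. Order is deterministic: systematic sites first, then template
#' sites by descending support, then model sites by descending score;
#' lexicographic within a class.
#'
#' @param m A `molecule` (or SMILES string).
#' @param cfg Tagging configuration: list with `strategies` (subset of
#'   `"systematic"`, `"template"`, `"model"`), `radius`, `beam`. See
#'   [default_config()].
#' @param templates Templates for the template strategy (may be `NULL`).
#' @param tagger Tagger contract for the model strategy (may be `NULL`).
#' @return Non-empty list of `tagged_molecule` objects; error when no
#'   strategy yields a site.
#' @export
enumerate_sites <- function(m, cfg = default_config()$tagging,
                            templates = NULL, tagger = NULL) {
  m <- canonicalize(m)
  groups <- list()
  if ("systematic" %in% cfg$strategies) {
    st <- systematic_tags(m)
    ser <- vapply(st, serialize_tagged, character(1L))
    groups <- c(groups, st[order(ser)])
  }
  if ("template" %in% cfg$strategies && length(templates) > 0L) {
    tt <- apply_templates(m, templates)
    sup <- vapply(tt, function(x) {
      s <- attr(x, "support"); if (is.null(s)) 0L else as.integer(s)
    }, integer(1L))
    ser <- vapply(tt, serialize_tagged, character(1L))
    groups <- c(groups, tt[order(-sup, ser)])
  }
  if ("model" %in% cfg$strategies && !is.null(tagger)) {
    mt <- model_tags(m, tagger, cfg$beam)
    sc <- vapply(mt, function(x) {
      s <- attr(x, "score"); if (is.null(s)) 0 else as.numeric(s)
    }, numeric(1L))
    ser <- vapply(mt, serialize_tagged, character(1L))
    groups <- c(groups, mt[order(-sc, ser)])
  }
  out <- dedup_tagged(groups)
  if (length(out) == 0L)
    stop("no candidate sites for ", m$smiles)
  out
}

## per-strategy Venn cell counts of an enumerated site list
site_provenance_counts <- function(sites) {
  cells <- vapply(sites, function(s)
    paste(sort(attr(s, "provenance")), collapse = "+"), character(1L))
  table(cells)
}
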