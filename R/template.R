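# Tagging templates: substructure patterns mined from a reaction corpus that
# mark which atoms of a matching product should be tagged.
#
# A template is the product substructure induced by the reacting atoms plus
# every atom within `radius` bonds of any of them. Pattern atoms are typed
# by element, aromaticity, formal charge, ring membership and degree, all
# frozen from the source product, so a match in a new molecule requires the
# same local context. Templates never rewrite structures; they only tag.

#' Construct a tagging template
#'
#' Usually produced by [extract_templates()]; the constructor is exposed for
#' round-tripping template CSV files.
#'
#' @param atoms List with per-atom vectors `element`, `aromatic`, `charge`,
#'   `ring`, `degree`, `reactive`.
#' @param bonds List with vectors `from`, `to`, `order`.
#' @param radius Conditional-environment radius in bonds (1, 2 or 3).
#' @param support Occurrence count in the mining corpus.
#' @return An object of class `tag_template`.
#' @export
tag_template <- function(atoms, bonds, radius, support = 1L) {
  stopifnot(radius %in% 1:3)
  tpl <- structure(list(atoms = atoms, bonds = bonds,
                        radius = as.integer(radius),
                        support = as.integer(support),
                        pattern = encode_pattern(atoms, bonds)),
                   class = "tag_template")
  tpl
}

#' @export
print.tag_template <- function(x, ...) {
  cat("<tag template> radius ", x$radius, ", support ", x$support, ", ",
      sum(x$atoms$reactive), " reactive atom(s)\n  ", x$pattern, "\n",
      sep = "")
  invisible(x)
}

reactive_positions <- function(tpl) which(tpl$atoms$reactive)

## canonical string encoding of a typed pattern graph; canonical atom order
## is computed from the typing attributes only, so identical environments
## from different reactions produce byte-identical patterns
encode_pattern <- function(atoms, bonds) {
  n <- length(atoms$element)
  mg <- new_molgraph()
  mg$n <- n
  mg$element <- atoms$element
  mg$aromatic <- atoms$aromatic
  mg$charge <- as.integer(atoms$charge)
  mg$hcount <- rep(0L, n)
  mg$h_explicit <- rep(TRUE, n)
  mg$isotope <- rep(0L, n)
  mg$map <- rep(0L, n)
  mg$chiral <- rep("", n)
  mg$chiral_ref <- vector("list", n)
  mg$bond_from <- as.integer(bonds$from)
  mg$bond_to <- as.integer(bonds$to)
  mg$bond_order <- as.numeric(bonds$order)
  extra <- paste(atoms$ring, atoms$degree, atoms$reactive, sep = ".")
  ranks <- canon_ranks(mg, extra = extra)
  ord <- order(ranks)                      # new position -> old index
  newid <- integer(n); newid[ord] <- seq_len(n)
  atom_tok <- vapply(ord, function(i) paste0(
    atoms$element[i], ",", if (atoms$aromatic[i]) "a" else "A", ",",
    atoms$charge[i], ",R", as.integer(atoms$ring[i]), ",D", atoms$degree[i],
    ",", if (atoms$reactive[i]) "*" else "."), character(1L))
  bf <- pmin(newid[mg$bond_from], newid[mg$bond_to])
  bt <- pmax(newid[mg$bond_from], newid[mg$bond_to])
  o <- order(bf, bt)
  bond_tok <- paste0(bf[o], "-", bt[o], ":", mg$bond_order[o])
  paste0(paste(atom_tok, collapse = ";"), "/",
         paste(bond_tok, collapse = ";"))
}

## inverse of encode_pattern
decode_pattern <- function(pattern, radius, support = 1L) {
  halves <- strsplit(pattern, "/", fixed = TRUE)[[1L]]
  atok <- strsplit(halves[1L], ";", fixed = TRUE)[[1L]]
  fields <- strsplit(atok, ",", fixed = TRUE)
  atoms <- list(
    element = vapply(fields, `[`, character(1L), 1L),
    aromatic = vapply(fields, `[`, character(1L), 2L) == "a",
    charge = as.integer(vapply(fields, `[`, character(1L), 3L)),
    ring = vapply(fields, `[`, character(1L), 4L) == "R1",
    degree = as.integer(sub("^D", "", vapply(fields, `[`, character(1L), 5L))),
    reactive = vapply(fields, `[`, character(1L), 6L) == "*")
  bonds <- list(from = integer(), to = integer(), order = numeric())
  if (length(halves) > 1L && nchar(halves[2L]) > 0L) {
    btok <- strsplit(halves[2L], ";", fixed = TRUE)[[1L]]
    m <- regmatches(btok, regexec("^([0-9]+)-([0-9]+):([0-9.]+)$", btok))
    bonds$from <- as.integer(vapply(m, `[`, character(1L), 2L))
    bonds$to <- as.integer(vapply(m, `[`, character(1L), 3L))
    bonds$order <- as.numeric(vapply(m, `[`, character(1L), 4L))
  }
  tag_template(atoms, bonds, radius, support)
}

## template of a single tagged product: environment of the tagged atoms out
## to `radius` bonds
template_from_tagged <- function(tm, radius) {
  g <- tm$molecule$graph
  adj <- mg_adj(g)
  dist <- rep(Inf, g$n)
  dist[tm$tagged_atoms] <- 0
  queue <- tm$tagged_atoms
  while (length(queue) > 0L) {
    a <- queue[1L]; queue <- queue[-1L]
    if (dist[a] >= radius) next
    for (b in adj[[a]]) {
      o <- mg_other(g, b, a)
      if (dist[o] > dist[a] + 1) { dist[o] <- dist[a] + 1; queue <- c(queue, o) }
    }
  }
  keep <- which(is.finite(dist))
  sub <- mg_subgraph(g, keep)
  deg <- mg_degree(g)
  inr <- mg_in_ring(g)
  atoms <- list(element = g$element[keep],
                aromatic = g$aromatic[keep],
                charge = g$charge[keep],
                ring = inr[keep],
                degree = deg[keep],
                reactive = keep %in% tm$tagged_atoms)
  bonds <- list(from = sub$bond_from, to = sub$bond_to,
                order = sub$bond_order)
  tag_template(atoms, bonds, radius)
}

#' Mine tagging templates from a reaction corpus
#'
#' For each mapped reaction the product environment of its reacting atoms
#' (out to `radius` bonds) becomes a candidate template. Identical
#' environments merge and are counted; templates occurring at least
#' `min_support` times and tagging between 1 and `max_reactive_atoms` atoms
#' are kept, sorted by descending support (ties by pattern string).
#'
#' @param corpus List of `mapped_reaction` objects.
#' @param radius Environment radius in bonds (1, 2 or 3).
#' @param min_support Minimum occurrence count (default 2).
#' @param max_reactive_atoms Maximum number of tagged atoms (default 10).
#' @return List of `tag_template` objects. Reactions without a reaction
#'   center are skipped; their count is available as attribute `skipped`.
#' @export
extract_templates <- function(corpus, radius, min_support = 2L,
                              max_reactive_atoms = 10L) {
  stopifnot(radius %in% 1:3)
  counts <- list()
  skipped <- 0L
  for (rxn in corpus) {
    tm <- tag_product(rxn)
    if (is.null(tm)) { skipped <- skipped + 1L; next }
    tpl <- template_from_tagged(tm, radius)
    key <- tpl$pattern
    if (is.null(counts[[key]])) {
      tpl$support <- 1L
      counts[[key]] <- tpl
    } else {
      counts[[key]]$support <- counts[[key]]$support + 1L
    }
  }
  out <- unname(counts)
  keep <- vapply(out, function(t) {
    nr <- sum(t$atoms$reactive)
    t$support >= min_support && nr >= 1L && nr <= max_reactive_atoms
  }, logical(1L))
  out <- out[keep]
  if (length(out) > 0L) {
    sup <- vapply(out, function(t) t$support, integer(1L))
    pat <- vapply(out, function(t) t$pattern, character(1L))
    out <- out[order(-sup, pat)]
  }
  attr(out, "skipped") <- skipped
  out
}

## igraph with typing colors for VF2 matching
pattern_igraph <- function(n, from, to) {
  igraph::make_graph(edges = as.vector(rbind(from, to)), n = n,
                     directed = FALSE)
}

## all distinct matches (lists of molecule atom indices, pattern order) of a
## template in a molecule graph; induced and bond-order exact
match_template <- function(tpl, mol) {
  g <- mol$graph
  np <- length(tpl$atoms$element)
  if (np > g$n) return(list())
  deg <- mg_degree(g)
  inr <- mg_in_ring(g)
  t_type <- paste(g$element, g$aromatic, g$charge, inr, deg, sep = ".")
  p_type <- paste(tpl$atoms$element, tpl$atoms$aromatic, tpl$atoms$charge,
                  tpl$atoms$ring, tpl$atoms$degree, sep = ".")
  lev <- unique(c(t_type, p_type))
  ig_t <- pattern_igraph(g$n, g$bond_from, g$bond_to)
  ig_p <- pattern_igraph(np, tpl$bonds$from, tpl$bonds$to)
  olev <- c(1, 1.5, 2, 3)
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(
      ig_p, ig_t, method = "vf2",
      vertex.color1 = match(t_type, lev), vertex.color2 = match(p_type, lev),
      edge.color1 = match(g$bond_order, olev),
      edge.color2 = match(tpl$bonds$order, olev)),
    error = function(e) list())
  # post-filter: require the match to be induced (no extra bonds among the
  # matched atoms beyond those in the pattern)
  npb <- length(tpl$bonds$from)
  keep <- list()
  for (m in maps) {
    img <- as.integer(m)
    inb <- sum(g$bond_from %in% img & g$bond_to %in% img)
    if (inb == npb) keep[[length(keep) + 1L]] <- img
  }
  keep
}

#' Apply tagging templates to a molecule
#'
#' Each distinct substructure match of each template tags the matched images
#' of the template's reactive positions. Results are deduplicated up to
#' molecular symmetry, so matches that tag topologically equivalent atoms
#' collapse to one tagged molecule.
#'
#' @param m A `molecule` (or SMILES string).
#' @param templates List of `tag_template` objects.
#' @return List of `tagged_molecule` objects (possibly empty), each carrying
#'   a `provenance` attribute `"template"`.
#' @export
apply_templates <- function(m, templates) {
  m <- canonicalize(m)
  out <- list()
  for (tpl in templates) {
    rp <- reactive_positions(tpl)
    for (img in match_template(tpl, m)) {
      tm <- tagged_molecule(m, img[rp])
      attr(tm, "provenance") <- "template"
      attr(tm, "support") <- tpl$support
      out[[length(out) + 1L]] <- tm
    }
  }
  dedup_tagged(out)
}
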