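# Canonical atom ordering and the `molecule` class.
#
# One canonicalization routine is used everywhere in the package: iterative
# neighborhood refinement (Morgan-style) over an invariant of element,
# aromaticity, charge, hydrogen count, isotope, ring membership, degree and
# the atom's BFS distance spectrum, with ties broken by promoting one member
# of the smallest tied class and re-refining. Atom-map labels never enter
# the invariant, so mapped and unmapped forms of a molecule get the same
# canonical order. Tagged positions are always expressed in this order.

## dense ranks (1-based) of a character key vector
dense_rank <- function(keys) match(keys, sort(unique(keys)))

## tag-independent part of the canonical invariant, reusable across
## different tag sets on the same graph
canon_base <- function(mg) {
  n <- mg$n
  partners <- vector("list", n)
  borders <- vector("list", n)
  for (b in seq_along(mg$bond_from)) {
    f <- mg$bond_from[b]; t <- mg$bond_to[b]
    partners[[f]] <- c(partners[[f]], t)
    partners[[t]] <- c(partners[[t]], f)
    borders[[f]] <- c(borders[[f]], mg$bond_order[b])
    borders[[t]] <- c(borders[[t]], mg$bond_order[b])
  }
  # BFS distance spectrum per atom
  ds <- character(n)
  for (s in seq_len(n)) {
    d <- rep(-1L, n)
    d[s] <- 0L
    q <- s
    head <- 1L
    while (head <= length(q)) {
      x <- q[head]; head <- head + 1L
      for (o in partners[[x]]) {
        if (d[o] < 0L) { d[o] <- d[x] + 1L; q <- c(q, o) }
      }
    }
    ds[s] <- paste(sort(d[d > 0L]), collapse = ",")
  }
  deg <- lengths(partners)
  inr <- mg_in_ring(mg)
  inv0 <- paste(mg$element, mg$aromatic, mg$charge, mg$hcount, mg$isotope,
                inr, deg, ds, sep = "~")
  list(partners = partners, borders = borders, inv0 = inv0)
}

## refinement to a stable partition given starting ranks
refine_ranks <- function(ranks, partners, borders) {
  n <- length(ranks)
  repeat {
    padded <- sprintf("%06d", ranks)   # keeps string sort = numeric sort
    keys <- character(n)
    for (a in seq_len(n)) {
      p <- partners[[a]]
      nb <- if (length(p) == 0L) "" else
        paste(sort(paste0(borders[[a]], ":", padded[p])), collapse = "|")
      keys[a] <- paste0(padded[a], ";", nb)
    }
    new <- dense_rank(keys)
    if (identical(new, ranks) || max(new) == n) return(new)
    ranks <- new
  }
}

## total canonical order (all ranks distinct); `extra` appends an additional
## per-atom invariant (used for tag-aware symmetry keys); `base` allows
## reuse of the tag-independent invariants
canon_ranks <- function(mg, extra = NULL, base = NULL) {
  n <- mg$n
  if (is.null(base)) base <- canon_base(mg)
  inv0 <- base$inv0
  if (!is.null(extra)) inv0 <- paste(inv0, extra, sep = "~")
  ranks <- refine_ranks(dense_rank(inv0), base$partners, base$borders)
  while (max(ranks) < n) {
    # promote one member of the smallest tied class; members of a stable
    # tied class are automorphic in molecular graphs at this invariant
    # richness, so the resulting string does not depend on the choice
    counts <- tabulate(ranks)
    tied <- which(counts > 1L)[1L]
    cand <- which(ranks == tied)[1L]
    ranks <- ranks * 2L
    ranks[cand] <- ranks[cand] - 1L
    ranks <- refine_ranks(dense_rank(sprintf("%07d", ranks)),
                          base$partners, base$borders)
  }
  ranks
}

## canonical form of a molgraph: returns graph permuted into emission order,
## the canonical SMILES, and the permutation old index -> new index
canon_build <- function(mg, keep_maps = FALSE) {
  ranks <- canon_ranks(mg)
  w <- smi_write(mg, ranks = ranks, keep_maps = FALSE, return_order = TRUE)
  ord <- w$order                 # emission sequence of old indices
  perm <- integer(mg$n)
  perm[ord] <- seq_len(mg$n)
  mg2 <- mg_permute(mg, perm)
  smiles <- smi_write(mg2, keep_maps = keep_maps)
  list(graph = mg2, smiles = smiles, perm = perm)
}

## reorder atoms so that old atom i becomes perm[i]
mg_permute <- function(mg, perm) {
  inv <- integer(mg$n)
  inv[perm] <- seq_len(mg$n)       # new position -> old index
  out <- new_molgraph()
  out$n <- mg$n
  for (f in c("element", "aromatic", "charge", "hcount", "h_explicit",
              "isotope", "map", "chiral"))
    out[[f]] <- mg[[f]][inv]
  out$chiral_ref <- lapply(mg$chiral_ref[inv], function(r)
    if (is.null(r)) NULL else ifelse(r == 0L, 0L, perm[pmax(r, 1L)]))
  out$bond_from <- perm[mg$bond_from]
  out$bond_to <- perm[mg$bond_to]
  out$bond_order <- mg$bond_order
  out
}

#' Canonicalize a SMILES string
#'
#' Parses a SMILES string and returns the molecule in the package's single
#' canonical form. Atom-map labels are stripped; tetrahedral stereochemistry
#' and isotopes are preserved. The routine is idempotent:
#' `canonicalize(canonicalize(s)$smiles)` equals `canonicalize(s)`.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `molecule` with fields `smiles` (canonical
#'   SMILES) and `atom_count` (number of heavy atoms).
#' @examples
#' canonicalize("OCC")$smiles
#' canonicalize("[CH3:1]O")$smiles   # map label removed
#' @export
canonicalize <- function(smiles) {
  if (inherits(smiles, "molecule")) return(smiles)
  mg <- smi_parse(smiles)
  mg$map <- rep(0L, mg$n)
  cb <- canon_build(mg)
  new_molecule(cb$graph, cb$smiles)
}

new_molecule <- function(graph, smiles) {
  structure(list(smiles = smiles, atom_count = graph$n, graph = graph),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$smiles, "  (", x$atom_count, " heavy atoms)\n",
      sep = "")
  invisible(x)
}

#' @export
format.molecule <- function(x, ...) x$smiles

#' Atom and bond tables of a SMILES string
#'
#' Parses a SMILES string (without canonicalizing) and returns its atoms
#' and bonds as plain data frames, in input atom order. Useful for
#' inspecting atom-map labels and for building independent checks on top of
#' the molecular graph.
#'
#' @param smiles A single SMILES string.
#' @return List with `atoms` (element, aromatic, charge, hcount, isotope,
#'   map) and `bonds` (from, to, order).
#' @export
atom_table <- function(smiles) {
  mg <- smi_parse(smiles)
  list(atoms = data.frame(element = mg$element, aromatic = mg$aromatic,
                          charge = mg$charge, hcount = mg$hcount,
                          isotope = mg$isotope, map = mg$map,
                          stringsAsFactors = FALSE),
       bonds = data.frame(from = mg$bond_from, to = mg$bond_to,
                          order = mg$bond_order))
}

## canonical smiles for a character vector (vectorized convenience)
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) canonicalize(s)$smiles, character(1L),
         USE.NAMES = FALSE)
}
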