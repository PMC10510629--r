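# The "!"-token tagged-SMILES dialect.
#
# A tagged molecule is a canonical molecule plus an ordered set of canonical
# atom indices marking candidate reactive sites. In the serialized form the
# tag token "!" is written directly after the tagged atom's token (after its
# ring-closure digits), with no brackets or whitespace, so deleting every "!"
# recovers the untagged canonical SMILES unchanged. The tag never alters the
# atom token itself, keeping token usage invariant to hydrogen count and
# stereochemistry of the tagged atom.

#' Construct a tagged molecule
#'
#' @param molecule A `molecule` (or SMILES string, canonicalized on the fly).
#' @param tagged_atoms Integer vector of canonical atom indices (1-based)
#'   marking the candidate reactive site. Must be non-empty and within the
#'   molecule's heavy-atom count.
#' @return An object of class `tagged_molecule`.
#' @examples
#' tm <- tagged_molecule("CCO", 2L)
#' serialize_tagged(tm)
#' @export
tagged_molecule <- function(molecule, tagged_atoms) {
  molecule <- canonicalize(molecule)
  tagged_atoms <- sort(unique(as.integer(tagged_atoms)))
  if (length(tagged_atoms) == 0L)
    stop("tagged_atoms must be non-empty for ", molecule$smiles)
  if (any(tagged_atoms < 1L) || any(tagged_atoms > molecule$atom_count))
    stop("tagged atom index out of range for ", molecule$smiles)
  if (grepl(".", molecule$smiles, fixed = TRUE))
    stop("multi-fragment products cannot be tagged: ", molecule$smiles)
  structure(list(molecule = molecule, tagged_atoms = tagged_atoms),
            class = "tagged_molecule")
}

#' @export
print.tagged_molecule <- function(x, ...) {
  cat("<tagged molecule> ", serialize_tagged(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a tagged molecule to tagged SMILES
#'
#' Emits the canonical SMILES with a `!` token directly after each tagged
#' atom (after its ring-closure digits). Deleting all `!` characters yields
#' exactly the untagged canonical SMILES.
#'
#' @param tm A `tagged_molecule`.
#' @return A tagged-SMILES string.
#' @export
serialize_tagged <- function(tm) {
  stopifnot(inherits(tm, "tagged_molecule"))
  smi_write(tm$molecule$graph, tags = tm$tagged_atoms)
}

#' Parse a tagged-SMILES string
#'
#' Inverse of [serialize_tagged()] after canonicalization: the tagged
#' positions are carried through the canonical atom permutation, so
#' `parse_tagged(serialize_tagged(x))` reproduces `x` exactly.
#'
#' @param s A SMILES string with zero or more `!` tokens, each directly
#'   following an atom token.
#' @param allow_untagged If `FALSE` (default) a string without any `!` is an
#'   error; if `TRUE` it returns the bare `molecule`.
#' @return A `tagged_molecule` (or a `molecule` when untagged input is
#'   allowed).
#' @export
parse_tagged <- function(s, allow_untagged = FALSE) {
  mg <- smi_parse(s, allow_tag = TRUE)
  tagged <- attr(mg, "tagged")
  mg$map <- rep(0L, mg$n)
  cb <- canon_build(mg)
  mol <- new_molecule(cb$graph, cb$smiles)
  if (length(tagged) == 0L) {
    if (allow_untagged) return(mol)
    stop("no '!' tag present in '", s,
         "' (set allow_untagged = TRUE to accept)")
  }
  tagged_molecule(mol, cb$perm[tagged])
}

#' Convert atom-map labels to tags
#'
#' Takes a mapped product SMILES and the set of map labels of its reacting
#' atoms, and returns the product as a tagged molecule: labelled reacting
#' atoms become tagged positions, all map labels are stripped, and positions
#' are expressed in canonical atom order.
#'
#' @param mapped_product SMILES of the product carrying atom-map labels.
#' @param reacting_labels Integer vector of map labels; every label must be
#'   present on the product.
#' @return A `tagged_molecule`.
#' @examples
#' maplabels_to_tags("[CH3:1][CH2:2][OH:3]", 3L)
#' @export
maplabels_to_tags <- function(mapped_product, reacting_labels) {
  reacting_labels <- unique(as.integer(reacting_labels))
  if (length(reacting_labels) == 0L)
    stop("empty reacting-label set for product ", mapped_product)
  mg <- smi_parse(mapped_product)
  missing <- setdiff(reacting_labels, mg$map)
  if (length(missing) > 0L)
    stop("reacting label(s) ", paste(missing, collapse = ", "),
         " absent from product ", mapped_product)
  atoms <- which(mg$map %in% reacting_labels)
  mg$map <- rep(0L, mg$n)
  cb <- canon_build(mg)
  tagged_molecule(new_molecule(cb$graph, cb$smiles), cb$perm[atoms])
}

## Symmetry-invariant identity key for a tagged molecule: the canonical
## serialization computed with the tag flag participating in the atom
## invariant. Topologically equivalent tag placements (e.g. either terminal
## carbon of propane) share one key.
tagged_key <- function(tm, base = NULL) {
  mg <- tm$molecule$graph
  extra <- rep("0", mg$n)
  extra[tm$tagged_atoms] <- "1"
  ranks <- canon_ranks(mg, extra = extra, base = base)
  ord <- order(ranks)                  # canonical position -> atom index
  newid <- integer(mg$n); newid[ord] <- seq_len(mg$n)
  atoms <- paste(mg$element, mg$aromatic, mg$charge, mg$hcount,
                 mg$isotope, mg$chiral, extra, sep = ",")[ord]
  bf <- pmin(newid[mg$bond_from], newid[mg$bond_to])
  bt <- pmax(newid[mg$bond_from], newid[mg$bond_to])
  o <- order(bf, bt)
  paste0(paste(atoms, collapse = ";"), "/",
         paste(bf[o], bt[o], mg$bond_order[o], sep = "-", collapse = ";"))
}

## deduplicate a list of tagged molecules on their symmetry key, merging
## character provenance attributes; keeps the lexicographically smallest
## serialized representative per key
dedup_tagged <- function(tms) {
  if (length(tms) == 0L) return(tms)
  bases <- new.env(parent = emptyenv())   # canon_base per distinct molecule
  keys <- vapply(tms, function(tm) {
    s <- tm$molecule$smiles
    b <- bases[[s]]
    if (is.null(b)) {
      b <- canon_base(tm$molecule$graph)
      bases[[s]] <- b
    }
    tagged_key(tm, base = b)
  }, character(1L))
  out <- list()
  for (i in seq_along(tms)) {
    k <- keys[i]
    if (is.null(out[[k]])) {
      out[[k]] <- tms[[i]]
    } else {
      prov <- union(attr(out[[k]], "provenance"), attr(tms[[i]], "provenance"))
      if (serialize_tagged(tms[[i]]) < serialize_tagged(out[[k]])) {
        keep_prov <- prov
        out[[k]] <- tms[[i]]
        attr(out[[k]], "provenance") <- keep_prov
      } else {
        attr(out[[k]], "provenance") <- prov
      }
    }
  }
  unname(out)
}
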