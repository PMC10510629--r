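# Atom-mapped reaction records and reaction-center identification.
#
# A reaction SMILES "SM1.SM2>R1.R2>P" is read into a `mapped_reaction`:
# exactly one product, map labels on the product unique, reagents unmapped.
# Species written on the starting-material side that carry no map label are
# moved to the reagent list (they contribute no atoms to the product).
#
# Reacting atoms are the product atoms whose environment changed between
# their starting-material occurrence and the product: any difference in the
# bonded-neighbor multiset (element and bond order), formal charge, or total
# hydrogen count, plus atoms whose label never occurs on the SM side.

#' Construct a mapped reaction record
#'
#' @param starting_materials Character vector of mapped SMILES.
#' @param reagents Character vector of unmapped SMILES (may be empty).
#' @param product A single mapped SMILES.
#' @param source_id Opaque identifier carried through template mining.
#' @return An object of class `mapped_reaction`.
#' @export
mapped_reaction <- function(starting_materials, reagents, product,
                            source_id = "") {
  if (length(product) != 1L)
    stop("a mapped reaction must have exactly one product")
  pmg <- smi_parse(product)
  if (length(mg_split(pmg)) != 1L)
    stop("multi-fragment product rejected: ", product)
  labs <- pmg$map[pmg$map > 0L]
  if (anyDuplicated(labs))
    stop("duplicate map label on product: ", product)
  # unmapped SM-side species are reagents
  if (length(starting_materials) > 0L) {
    mapped <- vapply(starting_materials,
                     function(s) any(smi_parse(s)$map > 0L), logical(1L))
    reagents <- c(reagents, starting_materials[!mapped])
    starting_materials <- starting_materials[mapped]
  }
  for (r in reagents) {
    if (any(smi_parse(r)$map > 0L))
      stop("reagent carries a map label: ", r)
  }
  structure(list(starting_materials = starting_materials,
                 reagents = as.character(reagents),
                 product = product, source_id = source_id),
            class = "mapped_reaction")
}

#' Parse a reaction SMILES string
#'
#' @param s Reaction SMILES `"SM1.SM2>R1.R2>P"`; the reagent field may be
#'   empty.
#' @param source_id Optional identifier.
#' @return A `mapped_reaction`.
#' @export
parse_reaction <- function(s, source_id = "") {
  parts <- strsplit(s, ">", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop("malformed reaction SMILES (need 'SM>R>P'): ", s)
  split_dot <- function(x) if (nchar(x) == 0L) character() else
    strsplit(x, ".", fixed = TRUE)[[1L]]
  mapped_reaction(split_dot(parts[1L]), split_dot(parts[2L]), parts[3L],
                  source_id = source_id)
}

#' Write a reaction SMILES string
#' @param rxn A `mapped_reaction`.
#' @return A reaction SMILES string.
#' @export
format_reaction <- function(rxn) {
  paste0(paste(rxn$starting_materials, collapse = "."), ">",
         paste(rxn$reagents, collapse = "."), ">", rxn$product)
}

#' @export
print.mapped_reaction <- function(x, ...) {
  cat("<mapped reaction> ", format_reaction(x), "\n", sep = "")
  invisible(x)
}

## environment fingerprint of atom a in graph mg: neighbor multiset by
## (element, bond order) plus charge and hydrogen count
atom_environment <- function(mg, a) {
  nb <- character()
  for (b in seq_along(mg$bond_from)) {
    if (mg$bond_from[b] == a)
      nb <- c(nb, paste0(mg$element[mg$bond_to[b]], ":", mg$bond_order[b]))
    else if (mg$bond_to[b] == a)
      nb <- c(nb, paste0(mg$element[mg$bond_from[b]], ":", mg$bond_order[b]))
  }
  paste0(paste(sort(nb), collapse = ","), ";c", mg$charge[a],
         ";h", mg$hcount[a])
}

#' Identify the reacting atoms of a mapped reaction
#'
#' Returns the map labels of product atoms whose bonding environment changed
#' relative to their starting-material occurrence: any difference in the
#' neighbor multiset (element, bond order), formal charge, or hydrogen
#' count. A product label absent from the starting-material side is always
#' reacting.
#'
#' @param rxn A `mapped_reaction`.
#' @return Sorted integer vector of reacting map labels (possibly empty).
#' @examples
#' rxn <- parse_reaction(
#'   "[CH3:1][OH:2].[CH3:3][C:4](=O)Cl>>[CH3:1][O:2][C:4](=O)[CH3:3]")
#' reacting_atoms(rxn)
#' @export
reacting_atoms <- function(rxn) {
  stopifnot(inherits(rxn, "mapped_reaction"))
  pmg <- smi_parse(rxn$product)
  if (all(pmg$map == 0L))
    stop("product has no atom-map labels: ", rxn$product)
  sm_env <- list()
  for (s in rxn$starting_materials) {
    mg <- smi_parse(s)
    for (a in which(mg$map > 0L))
      sm_env[[as.character(mg$map[a])]] <- atom_environment(mg, a)
  }
  reacting <- integer()
  for (a in which(pmg$map > 0L)) {
    lab <- pmg$map[a]
    se <- sm_env[[as.character(lab)]]
    if (is.null(se) || !identical(se, atom_environment(pmg, a)))
      reacting <- c(reacting, lab)
  }
  sort(reacting)
}

#' Tag the product of a mapped reaction at its reaction center
#'
#' Combines [reacting_atoms()] and [maplabels_to_tags()]. Reactions with an
#' empty reacting set (no environmental change) cannot be tagged and return
#' `NULL`, so corpus passes can count them as skipped.
#'
#' @param rxn A `mapped_reaction`.
#' @return A `tagged_molecule`, or `NULL` when there is no reaction center.
#' @export
tag_product <- function(rxn) {
  labs <- reacting_atoms(rxn)
  if (length(labs) == 0L) return(NULL)
  maplabels_to_tags(rxn$product, labs)
}
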