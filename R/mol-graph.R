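# Internal molecular-graph representation.
#
# A molgraph is a plain list of parallel vectors:
#   n           number of (heavy) atoms
#   element     chemical symbol, e.g. "C", "Cl"
#   aromatic    logical
#   charge      integer formal charge
#   hcount      total attached hydrogens (implicit + bracket-specified)
#   h_explicit  TRUE when hcount was fixed by a bracket expression
#   isotope     integer mass number, 0 = unspecified
#   map         atom-map label, 0 = none
#   chiral      "", "@" or "@@"
#   chiral_ref  list of integer vectors: the neighbor order (0 = implicit H
#               slot) defining the parity reference for chiral atoms
#   bond_from, bond_to, bond_order   bonds; order 1, 2, 3 or 1.5 (aromatic)
# Hydrogens are never graph vertices.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

STD_VALENCE <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
                 F = 1L, Cl = 1L, Br = 1L, I = 1L)

new_molgraph <- function() {
  list(n = 0L,
       element = character(), aromatic = logical(), charge = integer(),
       hcount = integer(), h_explicit = logical(), isotope = integer(),
       map = integer(), chiral = character(), chiral_ref = list(),
       bond_from = integer(), bond_to = integer(), bond_order = numeric())
}

mg_nbonds <- function(mg) length(mg$bond_from)

## adjacency: list of integer bond indices per atom
mg_adj <- function(mg) {
  adj <- vector("list", mg$n)
  for (b in seq_along(mg$bond_from)) {
    f <- mg$bond_from[b]; t <- mg$bond_to[b]
    adj[[f]] <- c(adj[[f]], b)
    adj[[t]] <- c(adj[[t]], b)
  }
  adj
}

mg_other <- function(mg, b, a) {
  if (mg$bond_from[b] == a) mg$bond_to[b] else mg$bond_from[b]
}

mg_degree <- function(mg) {
  d <- integer(mg$n)
  if (mg$n == 0L) return(d)
  tab <- tabulate(c(mg$bond_from, mg$bond_to), nbins = mg$n)
  tab
}

## bond indices that lie on a cycle (non-bridges), via iterative DFS low-link
mg_ring_bonds <- function(mg) {
  nb <- mg_nbonds(mg)
  if (nb == 0L) return(logical(0))
  adj <- mg_adj(mg)
  disc <- integer(mg$n); low <- integer(mg$n)
  bridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(mg$n)) {
    if (disc[root] > 0L) next
    # stack frames: atom, incoming bond, next adj position
    st_atom <- root; st_bond <- 0L; st_pos <- 1L
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(st_atom) > 0L) {
      k <- length(st_atom)
      a <- st_atom[k]
      if (st_pos[k] <= length(adj[[a]])) {
        b <- adj[[a]][st_pos[k]]
        st_pos[k] <- st_pos[k] + 1L
        if (b == st_bond[k]) next
        o <- mg_other(mg, b, a)
        if (disc[o] == 0L) {
          timer <- timer + 1L
          disc[o] <- low[o] <- timer
          st_atom <- c(st_atom, o); st_bond <- c(st_bond, b); st_pos <- c(st_pos, 1L)
        } else {
          low[a] <- min(low[a], disc[o])
        }
      } else {
        # pop
        st_atom <- st_atom[-k]; pb <- st_bond[k]; st_bond <- st_bond[-k]
        st_pos <- st_pos[-k]
        if (pb > 0L) {
          p <- length(st_atom)
          parent <- st_atom[p]
          low[parent] <- min(low[parent], low[a])
          if (low[a] > disc[parent]) bridge[pb] <- TRUE
        }
      }
    }
  }
  !bridge
}

mg_in_ring <- function(mg) {
  inr <- logical(mg$n)
  rb <- mg_ring_bonds(mg)
  if (any(rb)) {
    inr[mg$bond_from[rb]] <- TRUE
    inr[mg$bond_to[rb]] <- TRUE
  }
  inr
}

## all simple cycles of length 5 or 6 (as atom index vectors), deduplicated
mg_small_rings <- function(mg) {
  adj <- mg_adj(mg)
  rings <- list()
  seen <- character()
  for (start in seq_len(mg$n)) {
    # DFS paths from start, only through atoms >= start to dedup rotations
    path <- start
    dfs <- function(path) {
      a <- path[length(path)]
      for (b in adj[[a]]) {
        o <- mg_other(mg, b, a)
        if (o == start && length(path) >= 5L) {
          key <- paste(sort(path), collapse = ",")
          if (!(key %in% seen)) {
            seen <<- c(seen, key)
            rings[[length(rings) + 1L]] <<- path
          }
        } else if (o > start && !(o %in% path) && length(path) < 6L) {
          dfs(c(path, o))
        }
      }
    }
    dfs(path)
  }
  rings
}

## connected components: integer component id per atom
mg_components <- function(mg) {
  comp <- integer(mg$n)
  adj <- mg_adj(mg)
  cid <- 0L
  for (a in seq_len(mg$n)) {
    if (comp[a] > 0L) next
    cid <- cid + 1L
    queue <- a
    comp[a] <- cid
    while (length(queue) > 0L) {
      x <- queue[1L]; queue <- queue[-1L]
      for (b in adj[[x]]) {
        o <- mg_other(mg, b, x)
        if (comp[o] == 0L) { comp[o] <- cid; queue <- c(queue, o) }
      }
    }
  }
  comp
}

## extract induced subgraph on `atoms` (kept in given order); chiral refs that
## reference dropped atoms lose their chirality
mg_subgraph <- function(mg, atoms) {
  newid <- integer(mg$n)
  newid[atoms] <- seq_along(atoms)
  out <- new_molgraph()
  out$n <- length(atoms)
  for (f in c("element", "aromatic", "charge", "hcount", "h_explicit",
              "isotope", "map", "chiral"))
    out[[f]] <- mg[[f]][atoms]
  out$chiral_ref <- vector("list", out$n)
  for (i in seq_along(atoms)) {
    r <- mg$chiral_ref[[atoms[i]]]
    if (is.null(r)) next
    dropped <- r != 0L & newid[pmax(r, 1L)] == 0L
    if (any(dropped)) {
      # a parity-reference neighbor vanished: chirality is no longer defined
      out$chiral[i] <- ""
    } else {
      out$chiral_ref[[i]] <- ifelse(r == 0L, 0L, newid[pmax(r, 1L)])
    }
  }
  keep <- which(newid[mg$bond_from] > 0L & newid[mg$bond_to] > 0L)
  out$bond_from <- newid[mg$bond_from[keep]]
  out$bond_to <- newid[mg$bond_to[keep]]
  out$bond_order <- mg$bond_order[keep]
  out
}

## disjoint union of two molgraphs; returns combined graph, B's atoms offset
mg_union <- function(a, b) {
  off <- a$n
  out <- a
  out$n <- a$n + b$n
  for (f in c("element", "aromatic", "charge", "hcount", "h_explicit",
              "isotope", "map", "chiral"))
    out[[f]] <- c(a[[f]], b[[f]])
  out$chiral_ref <- c(a$chiral_ref, lapply(b$chiral_ref, function(r)
    if (is.null(r)) NULL else ifelse(r == 0L, 0L, r + off)))
  out$bond_from <- c(a$bond_from, b$bond_from + off)
  out$bond_to <- c(a$bond_to, b$bond_to + off)
  out$bond_order <- c(a$bond_order, b$bond_order)
  out
}

## delete atoms (and incident bonds)
mg_drop_atoms <- function(mg, atoms) {
  keep <- setdiff(seq_len(mg$n), atoms)
  mg_subgraph(mg, keep)
}

## add a bond
mg_add_bond <- function(mg, a, b, order = 1) {
  mg$bond_from <- c(mg$bond_from, a)
  mg$bond_to <- c(mg$bond_to, b)
  mg$bond_order <- c(mg$bond_order, order)
  mg
}

## remove the bond between a and b (first match)
mg_del_bond <- function(mg, a, b) {
  hit <- which((mg$bond_from == a & mg$bond_to == b) |
               (mg$bond_from == b & mg$bond_to == a))
  if (length(hit) == 0L) stop("no bond between atoms ", a, " and ", b)
  hit <- hit[1L]
  mg$bond_from <- mg$bond_from[-hit]
  mg$bond_to <- mg$bond_to[-hit]
  mg$bond_order <- mg$bond_order[-hit]
  mg
}

## append one atom, returning its index via attribute-free convention:
## callers use mg$n afterwards
mg_add_atom <- function(mg, element, aromatic = FALSE, charge = 0L,
                        hcount = 0L, h_explicit = FALSE, isotope = 0L,
                        map = 0L) {
  mg$n <- mg$n + 1L
  mg$element <- c(mg$element, element)
  mg$aromatic <- c(mg$aromatic, aromatic)
  mg$charge <- c(mg$charge, as.integer(charge))
  mg$hcount <- c(mg$hcount, as.integer(hcount))
  mg$h_explicit <- c(mg$h_explicit, h_explicit)
  mg$isotope <- c(mg$isotope, as.integer(isotope))
  mg$map <- c(mg$map, as.integer(map))
  mg$chiral <- c(mg$chiral, "")
  mg$chiral_ref <- c(mg$chiral_ref, list(NULL))
  mg
}

## split into per-component molgraphs, atoms in original relative order
mg_split <- function(mg) {
  comp <- mg_components(mg)
  lapply(seq_len(max(comp, 0L)), function(ci) mg_subgraph(mg, which(comp == ci)))
}

## sum of bond orders incident to each atom
mg_bondsum <- function(mg) {
  bs <- numeric(mg$n)
  for (b in seq_along(mg$bond_from)) {
    bs[mg$bond_from[b]] <- bs[mg$bond_from[b]] + mg$bond_order[b]
    bs[mg$bond_to[b]] <- bs[mg$bond_to[b]] + mg$bond_order[b]
  }
  bs
}
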