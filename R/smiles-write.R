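# SMILES writer. Emits a molgraph as SMILES, depth-first, visiting branches
# in increasing `ranks` order. Used both for canonical output (ranks = the
# canonical total order) and for randomized-order round-trip tests.
#
# Tagged positions ("!") are written immediately after the atom token and its
# ring-closure digits. Tetrahedral parity is recomputed for the emitted
# neighbor order.

smi_write <- function(mg, ranks = seq_len(mg$n), tags = integer(0),
                      keep_maps = FALSE, return_order = FALSE) {
  n <- mg$n
  if (n == 0L) stop("cannot write an empty molecule")
  adj <- mg_adj(mg)
  # order each adjacency list by rank of the partner
  for (a in seq_len(n)) {
    if (length(adj[[a]]) > 1L) {
      partners <- vapply(adj[[a]], function(b) mg_other(mg, b, a), integer(1L))
      adj[[a]] <- adj[[a]][order(ranks[partners])]
    }
  }

  visited <- logical(n)
  emit_idx <- integer(n)      # emission position per atom
  order_out <- integer(0)
  tree_child <- vector("list", n)   # ordered tree-edge bond ids
  back_edges <- integer(0)          # bond ids closing rings
  parent_bond <- integer(n)

  roots <- integer(0)
  counter <- 0L
  comp_seen <- logical(n)
  # iterative DFS per fragment, fragments ordered by their min-rank atom
  frag_roots <- order(ranks)
  for (root in frag_roots) {
    if (visited[root]) next
    roots <- c(roots, root)
    stack_a <- root; stack_p <- 1L
    visited[root] <- TRUE
    counter <- counter + 1L
    emit_idx[root] <- counter
    order_out <- c(order_out, root)
    while (length(stack_a) > 0L) {
      k <- length(stack_a)
      a <- stack_a[k]
      if (stack_p[k] <= length(adj[[a]])) {
        b <- adj[[a]][stack_p[k]]
        stack_p[k] <- stack_p[k] + 1L
        if (b == parent_bond[a]) next
        o <- mg_other(mg, b, a)
        if (!visited[o]) {
          visited[o] <- TRUE
          counter <- counter + 1L
          emit_idx[o] <- counter
          order_out <- c(order_out, o)
          tree_child[[a]] <- c(tree_child[[a]], b)
          parent_bond[o] <- b
          stack_a <- c(stack_a, o); stack_p <- c(stack_p, 1L)
        } else if (emit_idx[o] < emit_idx[a]) {
          back_edges <- c(back_edges, b)
        }
      } else {
        stack_a <- stack_a[-k]; stack_p <- stack_p[-k]
      }
    }
  }

  # ring digit numbers in order of first (earlier-emitted) endpoint
  digit_of <- integer(mg_nbonds(mg))
  if (length(back_edges) > 0L) {
    firstpos <- vapply(back_edges, function(b)
      min(emit_idx[mg$bond_from[b]], emit_idx[mg$bond_to[b]]), integer(1L))
    secondpos <- vapply(back_edges, function(b)
      max(emit_idx[mg$bond_from[b]], emit_idx[mg$bond_to[b]]), integer(1L))
    be <- back_edges[order(firstpos, secondpos)]
    digit_of[be] <- seq_along(be)
  }
  ring_at <- vector("list", n)   # bond ids of ring closures per atom
  for (b in back_edges) {
    f <- mg$bond_from[b]; t <- mg$bond_to[b]
    ring_at[[f]] <- c(ring_at[[f]], b)
    ring_at[[t]] <- c(ring_at[[t]], b)
  }
  for (a in seq_len(n))
    if (length(ring_at[[a]]) > 1L)
      ring_at[[a]] <- ring_at[[a]][order(digit_of[ring_at[[a]]])]

  tagset <- rep(FALSE, n)
  tagset[tags] <- TRUE

  bond_token <- function(b) {
    o <- mg$bond_order[b]
    f <- mg$bond_from[b]; t <- mg$bond_to[b]
    if (o == 2) "="
    else if (o == 3) "#"
    else if (o == 1.5) ""                      # aromatic-aromatic, implicit
    else if (mg$aromatic[f] && mg$aromatic[t]) "-"  # single biaryl-type bond
    else ""
  }

  atom_token <- function(a, parent) {
    el <- mg$element[a]
    sym <- if (mg$aromatic[a]) tolower(el) else el
    needs_map <- keep_maps && mg$map[a] > 0L
    chir <- mg$chiral[a]
    chir_out <- ""
    if (chir != "") {
      out_order <- neighbor_out_order(a, parent)
      chir_out <- parity_symbol(chir, mg$chiral_ref[[a]], out_order)
    }
    default_h <- written_default_h(mg, a)
    plain_ok <- el %in% ORGANIC_SUBSET && mg$charge[a] == 0L &&
      mg$isotope[a] == 0L && chir_out == "" && !needs_map &&
      mg$hcount[a] == default_h
    if (plain_ok) return(sym)
    h <- mg$hcount[a]
    htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    chg <- mg$charge[a]
    ctok <- if (chg == 0L) ""
            else if (chg == 1L) "+"
            else if (chg == -1L) "-"
            else if (chg > 0L) paste0("+", chg)
            else as.character(chg)
    itok <- if (mg$isotope[a] > 0L) as.character(mg$isotope[a]) else ""
    mtok <- if (needs_map) paste0(":", mg$map[a]) else ""
    paste0("[", itok, sym, chir_out, htok, ctok, mtok, "]")
  }

  neighbor_out_order <- function(a, parent) {
    out <- integer(0)
    if (parent > 0L) out <- parent
    if (mg$hcount[a] > 0L) out <- c(out, 0L)
    for (b in ring_at[[a]]) out <- c(out, mg_other(mg, b, a))
    for (b in tree_child[[a]]) out <- c(out, mg_other(mg, b, a))
    out
  }

  write_atom <- function(a, parent) {
    tok <- atom_token(a, parent)
    for (b in ring_at[[a]]) {
      d <- digit_of[b]
      bt <- bond_token(b)
      tok <- paste0(tok, bt, if (d > 9L) paste0("%", d) else d)
    }
    if (tagset[a]) tok <- paste0(tok, "!")
    kids <- tree_child[[a]]
    if (length(kids) > 0L) {
      for (j in seq_along(kids)) {
        b <- kids[j]
        o <- mg_other(mg, b, a)
        sub <- paste0(bond_token(b), write_atom(o, a))
        tok <- if (j < length(kids)) paste0(tok, "(", sub, ")")
               else paste0(tok, sub)
      }
    }
    tok
  }

  pieces <- vapply(roots, function(r) write_atom(r, 0L), character(1L))
  out <- paste(pieces, collapse = ".")
  if (return_order) list(smiles = out, order = order_out) else out
}

## H count the parser would infer for this atom written bare
written_default_h <- function(mg, a) {
  el <- mg$element[a]
  if (!(el %in% ORGANIC_SUBSET)) return(-1L)
  deg <- 0L; bs <- 0
  for (b in seq_along(mg$bond_from)) {
    if (mg$bond_from[b] == a || mg$bond_to[b] == a) {
      deg <- deg + 1L
      bs <- bs + mg$bond_order[b]
    }
  }
  if (mg$aromatic[a]) {
    if (el == "C") max(0L, 3L - deg) else 0L
  } else {
    v <- unname(STD_VALENCE[el])
    if (is.na(v)) return(-1L)
    max(0L, as.integer(v - ceiling(bs - 1e-9)))
  }
}

## parity of the permutation taking the reference neighbor order to the
## emitted one; flips @ <-> @@ when odd
parity_symbol <- function(chir, ref, out) {
  if (is.null(ref) || length(ref) != length(out)) return("")
  perm <- match(out, ref)
  if (any(is.na(perm))) return("")
  inversions <- 0L
  k <- length(perm)
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k)
      if (perm[i] > perm[j]) inversions <- inversions + 1L
  if (inversions %% 2L == 0L) chir
  else if (chir == "@") "@@" else "@"
}
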