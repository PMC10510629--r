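# SMILES reader producing a molgraph.
#
# Supported grammar: organic-subset atoms (B C N O P S F Cl Br I and their
# aromatic lowercase forms), bracket atoms with isotope / chirality / H count
# / charge / atom-map label, bond symbols - = # : / \, ring-closure digits
# (incl. %nn), branches, dot-separated fragments, and optionally the "!"
# reactive-site token of the tagged dialect (immediately after an atom's
# token and its ring-bond digits).
#
# E/Z bond direction symbols are accepted and read as single bonds; double
# bond geometry is not retained.

smi_parse <- function(s, allow_tag = FALSE) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L)
    stop("SMILES parse error: expected a single non-empty string")
  mg <- new_molgraph()
  nbr <- list()          # ordered neighbor events per atom (0 = H slot)
  tagged <- integer()    # atoms carrying "!"
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  len <- length(chars)
  i <- 1L
  prev <- 0L             # previous atom index (0 = none / after dot)
  pend <- NA_real_       # pending explicit bond order, NA = default
  pend_explicit <- FALSE
  stack <- integer()
  ring_open <- list()    # digit label -> list(atom, order, explicit, slot)
  impl <- logical()      # per bond: order defaulted (for aromatic resolution)
  last_atom <- 0L        # most recent atom token, for "!" attachment

  add_bond <- function(a, b, order, explicit) {
    mg$bond_from <<- c(mg$bond_from, a)
    mg$bond_to <<- c(mg$bond_to, b)
    mg$bond_order <<- c(mg$bond_order, order)
    impl <<- c(impl, !explicit)
  }

  new_atom <- function(element, aromatic, charge = 0L, hcount = 0L,
                       h_explicit = FALSE, isotope = 0L, map = 0L,
                       chiral = "") {
    mg <<- mg_add_atom(mg, element, aromatic, charge, hcount, h_explicit,
                       isotope, map)
    a <- mg$n
    mg$chiral[a] <<- chiral
    nbr[[a]] <<- integer()
    if (prev > 0L) {
      ord <- if (is.na(pend)) NA_real_ else pend
      add_bond(prev, a, ord, pend_explicit)
      nbr[[prev]] <<- c(nbr[[prev]], a)
      nbr[[a]] <<- c(nbr[[a]], prev)
    }
    if (chiral != "" && h_explicit && hcount > 0L)
      nbr[[a]] <<- c(nbr[[a]], 0L)     # implicit-H parity slot
    prev <<- a
    last_atom <<- a
    pend <<- NA_real_
    pend_explicit <<- FALSE
  }

  close_ring <- function(lab) {
    key <- as.character(lab)
    if (is.null(ring_open[[key]])) {
      # opening occurrence
      if (prev == 0L) stop("SMILES parse error in '", s,
                           "': ring digit with no preceding atom")
      slot <- length(nbr[[prev]]) + 1L
      nbr[[prev]][slot] <- NA_integer_   # placeholder, filled at closure
      ring_open[[key]] <<- list(atom = prev, order = pend,
                                explicit = pend_explicit, slot = slot)
      pend <<- NA_real_; pend_explicit <<- FALSE
    } else {
      op <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      ord <- if (!is.na(pend)) pend else op$order
      explicit <- pend_explicit || op$explicit
      if (!is.na(op$order) && !is.na(pend) && op$order != pend)
        stop("SMILES parse error in '", s, "': conflicting ring-bond orders")
      if (op$atom == prev)
        stop("SMILES parse error in '", s, "': ring bond to self")
      add_bond(op$atom, prev, ord, explicit)
      nbr[[op$atom]][op$slot] <<- prev
      nbr[[prev]] <<- c(nbr[[prev]], op$atom)
      pend <<- NA_real_; pend_explicit <<- FALSE
    }
  }

  while (i <= len) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= len && chars[j] != "]") j <- j + 1L
      if (j > len) stop("SMILES parse error in '", s, "': unclosed bracket")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, s)
      new_atom(at$element, at$aromatic, at$charge, at$hcount, TRUE,
               at$isotope, at$map, at$chiral)
      i <- j + 1L
    } else if (ch %in% c("C", "B", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < len) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        new_atom(two, FALSE); i <- i + 2L
      } else {
        new_atom(ch, FALSE); i <- i + 1L
      }
    } else if (ch %in% c("c", "b", "n", "o", "p", "s")) {
      new_atom(toupper(ch), TRUE); i <- i + 1L
    } else if (ch == "-") {
      pend <- 1; pend_explicit <- TRUE; i <- i + 1L
    } else if (ch == "=") {
      pend <- 2; pend_explicit <- TRUE; i <- i + 1L
    } else if (ch == "#") {
      pend <- 3; pend_explicit <- TRUE; i <- i + 1L
    } else if (ch == ":") {
      pend <- 1.5; pend_explicit <- TRUE; i <- i + 1L
    } else if (ch == "/" || ch == "\\") {
      pend <- 1; pend_explicit <- TRUE; i <- i + 1L
    } else if (ch >= "0" && ch <= "9") {
      close_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > len) stop("SMILES parse error in '", s, "': bad % digit")
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else if (ch == "(") {
      if (prev == 0L) stop("SMILES parse error in '", s,
                           "': branch with no preceding atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L)
        stop("SMILES parse error in '", s, "': unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L; i <- i + 1L
    } else if (ch == "!") {
      if (!allow_tag)
        stop("SMILES parse error in '", s, "': unexpected '!'")
      if (last_atom == 0L || prev != last_atom)
        stop("tagged-SMILES syntax error in '", s,
             "': '!' must directly follow an atom token")
      tagged <- c(tagged, last_atom)
      i <- i + 1L
    } else {
      stop("SMILES parse error in '", s, "': unexpected character '", ch, "'")
    }
  }
  if (length(stack) > 0L)
    stop("SMILES parse error in '", s, "': unbalanced '('")
  if (length(ring_open) > 0L)
    stop("SMILES parse error in '", s, "': unclosed ring bond")
  if (mg$n == 0L) stop("SMILES parse error: no atoms in '", s, "'")

  mg$chiral_ref <- nbr
  mg <- resolve_bonds(mg, impl, s)
  mg <- perceive_aromaticity(mg)
  mg <- assign_implicit_h(mg)
  # only keep parity references on actually chiral atoms
  for (a in seq_len(mg$n))
    if (mg$chiral[a] == "") mg$chiral_ref[a] <- list(NULL)
  attr(mg, "tagged") <- sort(unique(tagged))
  mg
}

parse_bracket_atom <- function(body, s) {
  m <- regexec(
    "^([0-9]+)?([A-Z][a-z]?|as|se|[bcnops])(@@|@)?(H[0-9]*)?([+-][0-9]+|\\++|-+)?(:[0-9]+)?$",
    body)
  g <- regmatches(body, m)[[1L]]
  if (length(g) == 0L)
    stop("SMILES parse error in '", s, "': bad bracket atom [", body, "]")
  isotope <- if (g[2L] != "") as.integer(g[2L]) else 0L
  sym <- g[3L]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "as", "se")
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1L, 1L)), substring(sym, 2L))
  } else sym
  chiral <- g[4L]
  hfield <- g[5L]
  hcount <- if (hfield == "") 0L
            else if (hfield == "H") 1L
            else as.integer(substring(hfield, 2L))
  cfield <- g[6L]
  charge <- if (cfield == "") 0L
            else if (grepl("^[+-][0-9]+$", cfield)) as.integer(cfield)
            else if (substr(cfield, 1L, 1L) == "+") nchar(cfield)
            else -nchar(cfield)
  mfield <- g[7L]
  map <- if (mfield == "") 0L else as.integer(substring(mfield, 2L))
  list(element = element, aromatic = aromatic, charge = as.integer(charge),
       hcount = hcount, isotope = isotope, map = map, chiral = chiral)
}

## decide default bond orders: implicit bonds between two aromatic atoms are
## aromatic when the bond lies in a ring, else single
resolve_bonds <- function(mg, impl, s) {
  und <- which(is.na(mg$bond_order))
  if (length(und) > 0L) {
    # provisionally single so ring detection works
    mg$bond_order[und] <- 1
    ringb <- mg_ring_bonds(mg)
    arom_pair <- mg$aromatic[mg$bond_from] & mg$aromatic[mg$bond_to]
    mg$bond_order[und] <- ifelse(arom_pair[und] & ringb[und], 1.5, 1)
  }
  bad <- which(mg$bond_order == 1.5 &
               !(mg$aromatic[mg$bond_from] & mg$aromatic[mg$bond_to]))
  if (length(bad) > 0L)
    stop("SMILES parse error in '", s,
         "': aromatic bond between non-aromatic atoms")
  mg
}

## mark Kekulé-written benzene/pyridine-like 6-rings and furan/pyrrole/
## thiophene-like 5-rings aromatic; repeated until stable so simple fused
## systems normalize too
perceive_aromaticity <- function(mg) {
  repeat {
    changed <- FALSE
    rings <- mg_small_rings(mg)
    for (ring in rings) {
      k <- length(ring)
      if (all(mg$aromatic[ring])) next
      orders <- ring_bond_orders(mg, ring)
      if (any(is.na(orders))) next
      if (k == 6L) {
        if (!all(mg$element[ring] %in% c("C", "N"))) next
        if (match_alternating(orders)) {
          mg <- set_ring_aromatic(mg, ring)
          changed <- TRUE
        }
      } else if (k == 5L) {
        het <- which(mg$element[ring] %in% c("N", "O", "S") &
                     !mg$aromatic[ring])
        for (h in het) {
          rot <- c(ring[h:k], ring[seq_len(h - 1L)])
          oo <- ring_bond_orders(mg, rot)
          ok <- all(mg$element[rot[-1L]] == "C" | mg$aromatic[rot[-1L]]) &&
            all(oo == c(1, 2, 1, 2, 1) | oo == 1.5)
          if (ok) {
            mg <- set_ring_aromatic(mg, rot)
            changed <- TRUE
            break
          }
        }
      }
    }
    if (!changed) break
  }
  mg
}

ring_bond_orders <- function(mg, ring) {
  k <- length(ring)
  vapply(seq_len(k), function(i) {
    a <- ring[i]; b <- ring[if (i == k) 1L else i + 1L]
    hit <- which((mg$bond_from == a & mg$bond_to == b) |
                 (mg$bond_from == b & mg$bond_to == a))
    if (length(hit) == 0L) NA_real_ else mg$bond_order[hit[1L]]
  }, numeric(1L))
}

match_alternating <- function(orders) {
  pat1 <- rep(c(1, 2), length.out = length(orders))
  pat2 <- rep(c(2, 1), length.out = length(orders))
  all(orders == pat1 | orders == 1.5) || all(orders == pat2 | orders == 1.5)
}

set_ring_aromatic <- function(mg, ring) {
  mg$aromatic[ring] <- TRUE
  k <- length(ring)
  for (i in seq_len(k)) {
    a <- ring[i]; b <- ring[if (i == k) 1L else i + 1L]
    hit <- which((mg$bond_from == a & mg$bond_to == b) |
                 (mg$bond_from == b & mg$bond_to == a))
    mg$bond_order[hit[1L]] <- 1.5
  }
  mg
}

## hydrogen counts for atoms whose H was not fixed by a bracket
assign_implicit_h <- function(mg) {
  if (mg$n == 0L) return(mg)
  deg <- mg_degree(mg)
  bs <- mg_bondsum(mg)
  for (a in seq_len(mg$n)) {
    if (mg$h_explicit[a]) next
    el <- mg$element[a]
    if (mg$aromatic[a]) {
      mg$hcount[a] <- if (el == "C") max(0L, 3L - deg[a]) else 0L
    } else {
      v <- unname(STD_VALENCE[el])
      if (is.na(v)) v <- 0L
      mg$hcount[a] <- max(0L, as.integer(v - ceiling(bs[a] - 1e-9)))
    }
  }
  mg
}
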