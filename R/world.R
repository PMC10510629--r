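# Deterministic rule-based toy chemistry. Three condensation-style coupling
# rules (ester, amide, ether formation) over a small library of mono- and
# bifunctional building blocks give a closed molecule universe with known
# ground-truth routes, consistent forward/retro behaviour and atom-mapped
# reaction records for template mining. The mock predictor contracts built
# on top of it exercise the single-step loop and the tree search end to end;
# no claim of chemical realism is made.

## ---- seeded determinism helpers ----

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## deterministic uniform in [0,1) from a string and integer seed
hash01 <- function(s, seed = 0L) {
  v <- utf8ToInt(s)
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (x in v) h <- (h * 131 + x) %% 2147483647
  (h %% 1000003) / 1000003
}

## ---- functional-group perception on canonical molecule graphs ----

## carbonyl carbons: C with a double-bonded O
carbonyl_carbons <- function(g) {
  cc <- integer()
  for (b in seq_along(g$bond_from)) {
    if (g$bond_order[b] != 2) next
    f <- g$bond_from[b]; t <- g$bond_to[b]
    if (g$element[f] == "C" && g$element[t] == "O") cc <- c(cc, f)
    if (g$element[t] == "C" && g$element[f] == "O") cc <- c(cc, t)
  }
  unique(cc)
}

neighbors_of <- function(g, a) {
  out <- list(atom = integer(), order = numeric())
  for (b in seq_along(g$bond_from)) {
    if (g$bond_from[b] == a) {
      out$atom <- c(out$atom, g$bond_to[b]); out$order <- c(out$order, g$bond_order[b])
    } else if (g$bond_to[b] == a) {
      out$atom <- c(out$atom, g$bond_from[b]); out$order <- c(out$order, g$bond_order[b])
    }
  }
  out
}

## carboxylic-acid sites: list of c(cc, oh) — carbonyl carbon, hydroxyl O
find_acid_sites <- function(g) {
  out <- list()
  for (cc in carbonyl_carbons(g)) {
    nb <- neighbors_of(g, cc)
    oh <- nb$atom[g$element[nb$atom] == "O" & nb$order == 1 &
                  g$hcount[nb$atom] >= 1L]
    for (o in oh) out[[length(out) + 1L]] <- c(cc = cc, oh = o)
  }
  out
}

## alcohol sites: O-H, degree 1, attached to a non-carbonyl carbon
find_alcohol_sites <- function(g) {
  carb <- carbonyl_carbons(g)
  out <- integer()
  deg <- mg_degree(g)
  for (a in which(g$element == "O" & !g$aromatic & g$hcount >= 1L)) {
    if (deg[a] != 1L) next
    nb <- neighbors_of(g, a)
    if (g$element[nb$atom[1L]] == "C" && !(nb$atom[1L] %in% carb) &&
        nb$order[1L] == 1)
      out <- c(out, a)
  }
  out
}

## primary-amine sites: N with >= 2 H, degree 1, on a non-carbonyl carbon
find_amine_sites <- function(g) {
  carb <- carbonyl_carbons(g)
  out <- integer()
  deg <- mg_degree(g)
  for (a in which(g$element == "N" & !g$aromatic & g$hcount >= 2L)) {
    if (deg[a] != 1L) next
    nb <- neighbors_of(g, a)
    if (g$element[nb$atom[1L]] == "C" && !(nb$atom[1L] %in% carb))
      out <- c(out, a)
  }
  out
}

## alkyl-bromide sites: c(c, br)
find_bromide_sites <- function(g) {
  out <- list()
  for (a in which(g$element == "Br")) {
    nb <- neighbors_of(g, a)
    if (length(nb$atom) == 1L && g$element[nb$atom[1L]] == "C" &&
        !g$aromatic[nb$atom[1L]])
      out[[length(out) + 1L]] <- c(c = nb$atom[1L], br = a)
  }
  out
}

## ester linkages: c(cc, ob) — carbonyl carbon and bridging O
find_ester_links <- function(g) {
  out <- list()
  deg <- mg_degree(g)
  for (cc in carbonyl_carbons(g)) {
    nb <- neighbors_of(g, cc)
    for (i in seq_along(nb$atom)) {
      o <- nb$atom[i]
      if (g$element[o] == "O" && nb$order[i] == 1 && deg[o] == 2L) {
        onb <- neighbors_of(g, o)
        other <- onb$atom[onb$atom != cc]
        if (length(other) == 1L && g$element[other] == "C")
          out[[length(out) + 1L]] <- c(cc = cc, ob = o)
      }
    }
  }
  out
}

## amide linkages: c(cc, n)
find_amide_links <- function(g) {
  out <- list()
  for (cc in carbonyl_carbons(g)) {
    nb <- neighbors_of(g, cc)
    for (i in seq_along(nb$atom)) {
      a <- nb$atom[i]
      if (g$element[a] == "N" && nb$order[i] == 1 && !g$aromatic[a])
        out[[length(out) + 1L]] <- c(cc = cc, n = a)
    }
  }
  out
}

## ether linkages: c(o, c) for each C neighbor; excludes ester bridges
find_ether_links <- function(g) {
  out <- list()
  carb <- carbonyl_carbons(g)
  deg <- mg_degree(g)
  inr <- mg_in_ring(g)
  for (o in which(g$element == "O" & !g$aromatic & g$hcount == 0L)) {
    if (deg[o] != 2L || inr[o]) next
    nb <- neighbors_of(g, o)
    if (any(g$element[nb$atom] != "C") || any(nb$order != 1)) next
    if (any(nb$atom %in% carb)) next
    for (c_at in nb$atom)
      out[[length(out) + 1L]] <- c(o = o, c = c_at)
  }
  out
}

## ---- toy rules ----

#' Default toy reaction rules
#'
#' Three bimolecular coupling rules: ester formation (acid + alcohol),
#' amide formation (acid + primary amine) and ether formation (alcohol +
#' alkyl bromide), each with a fixed reagent set and base confidence.
#'
#' @return List of rule objects.
#' @export
toy_rules <- function() {
  list(
    list(rule_id = "ester", kind = "ester",
         reagents = c("O=S(=O)(O)O"), base_confidence = 0.95),
    list(rule_id = "amide", kind = "amide",
         reagents = c("CCN(CC)CC"), base_confidence = 0.90),
    list(rule_id = "ether", kind = "ether",
         reagents = c("CN(C)C=O"), base_confidence = 0.85))
}

## forward application of one rule at specific sites of the union graph of
## A and B (B offset by A's size); returns the product molgraph (with map
## labels preserved) or NULL
forward_edit <- function(kind, u, siteA, siteB) {
  if (kind == "ester" || kind == "amide") {
    cc <- siteA[["cc"]]; oh <- siteA[["oh"]]; x <- siteB
    u <- mg_del_bond(u, cc, oh)
    u <- mg_add_bond(u, cc, x, 1)
    u$hcount[x] <- u$hcount[x] - 1L
    u <- mg_drop_atoms(u, oh)
  } else if (kind == "ether") {
    o <- siteA; c_at <- siteB[["c"]]; br <- siteB[["br"]]
    u <- mg_del_bond(u, c_at, br)
    u <- mg_add_bond(u, o, c_at, 1)
    u$hcount[o] <- u$hcount[o] - 1L
    u <- mg_drop_atoms(u, br)
  } else stop("unknown rule kind: ", kind)
  comps <- mg_split(u)
  if (length(comps) != 1L) return(NULL)
  comps[[1L]]
}

## all (roleA, roleB, siteA, siteB) applications of `rule` to the ordered
## molecule pair; role assignment tries both orientations
rule_applications <- function(rule, mols) {
  if (length(mols) != 2L) return(list())
  gs <- lapply(mols, function(m) m$graph)
  out <- list()
  add <- function(ia, ib, siteA, siteB) {
    out[[length(out) + 1L]] <<- list(ia = ia, ib = ib,
                                     siteA = siteA, siteB = siteB)
  }
  for (ord in list(c(1L, 2L), c(2L, 1L))) {
    ia <- ord[1L]; ib <- ord[2L]
    ga <- gs[[ia]]; gb <- gs[[ib]]
    if (rule$kind == "ester") {
      for (sa in find_acid_sites(ga))
        for (o in find_alcohol_sites(gb))
          add(ia, ib, sa, o)
    } else if (rule$kind == "amide") {
      for (sa in find_acid_sites(ga))
        for (nn in find_amine_sites(gb))
          add(ia, ib, sa, nn)
    } else if (rule$kind == "ether") {
      for (o in find_alcohol_sites(ga))
        for (sb in find_bromide_sites(gb))
          add(ia, ib, o, sb)
    }
  }
  out
}

## all distinct canonical products of rule on a molecule pair
forward_products <- function(rule, mols) {
  apps <- rule_applications(rule, mols)
  out <- character()
  for (ap in apps) {
    ga <- mols[[ap$ia]]$graph; gb <- mols[[ap$ib]]$graph
    u <- mg_union(ga, gb)
    off <- ga$n
    siteA <- ap$siteA
    siteB <- if (is.numeric(ap$siteB) && length(ap$siteB) == 1L)
      ap$siteB + off else ap$siteB + off
    pg <- forward_edit(rule$kind, u, siteA, siteB)
    if (!is.null(pg)) out <- c(out, canon_build(pg)$smiles)
  }
  sort(unique(out))
}

## one mapped reaction record for a specific application
mapped_record <- function(rule, mols, ap, source_id = "") {
  ga <- mols[[ap$ia]]$graph; gb <- mols[[ap$ib]]$graph
  ga$map <- seq_len(ga$n)
  gb$map <- ga$n + seq_len(gb$n)
  u <- mg_union(ga, gb)
  siteB <- ap$siteB + ga$n
  pg <- forward_edit(rule$kind, u, ap$siteA, siteB)
  if (is.null(pg)) return(NULL)
  mapped_reaction(
    starting_materials = c(smi_write(ga, keep_maps = TRUE),
                           smi_write(gb, keep_maps = TRUE)),
    reagents = rule$reagents,
    product = smi_write(pg, keep_maps = TRUE),
    source_id = source_id)
}

## ---- retro application ----

## disconnectable linkages of a molecule under the rules, without building
## the fragments: list of (rule, lk, tags)
retro_links <- function(mol, rules) {
  g <- mol$graph
  out <- list()
  for (rule in rules) {
    links <- switch(rule$kind,
                    ester = find_ester_links(g),
                    amide = find_amide_links(g),
                    ether = find_ether_links(g))
    for (lk in links)
      out[[length(out) + 1L]] <-
        list(rule = rule, lk = lk,
             tags = sort(unname(retro_tag_atoms(rule$kind, lk))))
  }
  out
}

## all retro-disconnection options of a molecule under the rules: list of
## (rule, tag set, starting-material canonical SMILES)
retro_options <- function(mol, rules) {
  out <- list()
  for (ln in retro_links(mol, rules)) {
    sms <- retro_edit(ln$rule$kind, mol$graph, ln$lk)
    if (is.null(sms)) next
    out[[length(out) + 1L]] <- list(rule = ln$rule, tags = ln$tags, sm = sms)
  }
  out
}

## the product atoms whose environment the forward rule changed; these are
## the positions a corpus-derived tagger marks
retro_tag_atoms <- function(kind, lk) {
  switch(kind,
         ester = lk[["ob"]],
         amide = c(lk[["cc"]], lk[["n"]]),
         ether = c(lk[["o"]], lk[["c"]]))
}

## inverse edit: split the product at a linkage, restoring the functional
## groups; returns sorted canonical SMILES of the two starting materials
retro_edit <- function(kind, g, lk) {
  if (kind == "ester") {
    g2 <- mg_del_bond(g, lk[["cc"]], lk[["ob"]])
    g2$hcount[lk[["ob"]]] <- g2$hcount[lk[["ob"]]] + 1L
    g2 <- mg_add_atom(g2, "O", hcount = 1L, h_explicit = FALSE)
    g2 <- mg_add_bond(g2, lk[["cc"]], g2$n, 1)
  } else if (kind == "amide") {
    g2 <- mg_del_bond(g, lk[["cc"]], lk[["n"]])
    g2$hcount[lk[["n"]]] <- g2$hcount[lk[["n"]]] + 1L
    g2 <- mg_add_atom(g2, "O", hcount = 1L, h_explicit = FALSE)
    g2 <- mg_add_bond(g2, lk[["cc"]], g2$n, 1)
  } else if (kind == "ether") {
    g2 <- mg_del_bond(g, lk[["o"]], lk[["c"]])
    g2$hcount[lk[["o"]]] <- g2$hcount[lk[["o"]]] + 1L
    g2 <- mg_add_atom(g2, "Br")
    g2 <- mg_add_bond(g2, lk[["c"]], g2$n, 1)
  } else stop("unknown rule kind: ", kind)
  comps <- mg_split(g2)
  if (length(comps) != 2L) return(NULL)
  sort(vapply(comps, function(cg) canon_build(cg)$smiles, character(1L)))
}

## ---- building-block library and world generation ----

BB_LIBRARY <- list(
  acid = c("CC(=O)O", "CCC(=O)O", "CC(C)C(=O)O", "OC(=O)c1ccccc1",
           "CCCC(=O)O"),
  alcohol = c("CO", "CCO", "CC(C)O", "OCc1ccccc1", "CCCO"),
  diol = c("OCCO", "OCCCO", "OCCCCO"),
  amine = c("CN", "CCN", "NCc1ccccc1", "CCCN"),
  amino_alcohol = c("NCCO", "NCCCO"),
  hydroxy_acid = c("OCCC(=O)O", "OCCCC(=O)O"),
  diacid = c("OC(=O)CC(=O)O", "OC(=O)CCC(=O)O"),
  bromide = c("CBr", "CCBr", "BrCc1ccccc1", "CCCBr"))

#' Specify a synthetic toy world
#'
#' @param seed Integer seed governing every random draw of the generator.
#' @param n_building_blocks Number of building blocks sampled from the
#'   internal library (coverage of all functional classes is enforced).
#' @param rules Toy rule set, default [toy_rules()].
#' @param max_depth Maximum generation depth; every target is reachable from
#'   the building blocks in at most this many rule applications per branch.
#' @param reactions_per_depth Reaction records generated per depth level.
#' @param n_targets Number of target molecules drawn from the deepest level.
#' @return A `world_spec` list.
#' @export
world_spec <- function(seed = 1L, n_building_blocks = 16L,
                       rules = toy_rules(), max_depth = 2L,
                       reactions_per_depth = 10L, n_targets = 6L) {
  stopifnot(max_depth >= 1L, n_building_blocks >= 6L)
  structure(list(seed = as.integer(seed),
                 n_building_blocks = as.integer(n_building_blocks),
                 rules = rules, max_depth = as.integer(max_depth),
                 reactions_per_depth = as.integer(reactions_per_depth),
                 n_targets = as.integer(n_targets)),
            class = "world_spec")
}

#' Generate a synthetic toy world
#'
#' Samples building blocks, applies the toy rules forward up to
#' `max_depth`, and returns the building-block set, an atom-mapped reaction
#' corpus, and target molecules with exhaustively computed minimum route
#' lengths. Only reactions whose outcome is unique (a single possible
#' product over all site/role assignments) are recorded, so the forward
#' model's top prediction is well defined. Byte-identical output for a
#' fixed spec.
#'
#' @param spec A [world_spec()].
#' @return A `toy_world` list with elements `bb`, `corpus`, `targets`,
#'   `rules`, `spec`.
#' @export
generate_world <- function(spec = world_spec()) {
  with_seed(spec$seed, {
    lib <- BB_LIBRARY
    # force one member of each class, then fill up at random
    bb <- vapply(lib, function(x) x[sample.int(length(x), 1L)], character(1L))
    rest <- setdiff(unlist(lib), bb)
    extra <- spec$n_building_blocks - length(bb)
    if (extra > 0L)
      bb <- c(bb, sample(rest, min(extra, length(rest))))
    bb <- canonical_smiles(unname(bb))
    mols <- lapply(bb, canonicalize)
    names(mols) <- bb

    depth <- stats::setNames(rep(0L, length(bb)), bb)
    corpus <- list()
    rid <- 0L
    for (d in seq_len(spec$max_depth)) {
      fresh <- names(depth)[depth == d - 1L]
      older <- names(depth)[depth <= d - 1L]
      cand <- expand.grid(a = fresh, b = older, stringsAsFactors = FALSE)
      if (nrow(cand) == 0L) break
      cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
      made <- 0L
      for (i in seq_len(nrow(cand))) {
        if (made >= spec$reactions_per_depth) break
        pair <- list(mols[[cand$a[i]]], mols[[cand$b[i]]])
        for (rule in spec$rules[sample.int(length(spec$rules))]) {
          prods <- forward_products(rule, pair)
          if (length(prods) != 1L) next        # ambiguous or inapplicable
          p <- prods[1L]
          if (p %in% names(depth)) next        # already reachable
          apps <- rule_applications(rule, pair)
          rid <- rid + 1L
          rec <- mapped_record(rule, pair, apps[[1L]],
                               source_id = sprintf("w%d-r%04d", spec$seed, rid))
          if (is.null(rec)) next
          corpus[[length(corpus) + 1L]] <- rec
          depth[p] <- d
          mols[[p]] <- canonicalize(p)
          made <- made + 1L
          break
        }
      }
    }
    if (length(corpus) == 0L)
      stop("rule set generated no reactions; widen the building-block set")

    deepest <- names(depth)[depth == spec$max_depth]
    if (length(deepest) == 0L)
      deepest <- names(depth)[depth == max(depth)]
    tg <- sample(deepest, min(spec$n_targets, length(deepest)))
    ms <- vapply(tg, function(s) world_min_steps(s, bb, spec$rules),
                 numeric(1L))
    targets <- data.frame(smiles = tg, min_steps = ms,
                          depth = unname(depth[tg]),
                          stringsAsFactors = FALSE, row.names = NULL)
    structure(list(bb = bb, corpus = corpus, targets = targets,
                   rules = spec$rules, spec = spec),
              class = "toy_world")
  })
}

#' @export
print.toy_world <- function(x, ...) {
  cat("<toy world> seed ", x$spec$seed, ": ", length(x$bb),
      " building blocks, ", length(x$corpus), " reactions, ",
      nrow(x$targets), " targets\n", sep = "")
  invisible(x)
}

#' Exhaustive minimum route length to building blocks
#'
#' Ground-truth oracle: dynamic program over all retro-disconnections under
#' the toy rules. A building block costs 0 steps; otherwise one step plus
#' the sum over the fragments of the best disconnection; `Inf` when no rule
#' applies.
#'
#' @param smiles Target molecule.
#' @param bb Character vector of canonical building-block SMILES.
#' @param rules Toy rule list.
#' @return Minimum total number of steps (possibly `Inf`).
#' @export
world_min_steps <- function(smiles, bb, rules = toy_rules()) {
  memo <- new.env(parent = emptyenv())
  rec <- function(s) {
    if (s %in% bb) return(0)
    if (!is.null(memo[[s]])) return(memo[[s]])
    memo[[s]] <- Inf    # guards against revisiting while computing
    best <- Inf
    for (opt in retro_options(canonicalize(s), rules)) {
      cost <- 1 + sum(vapply(opt$sm, rec, numeric(1L)))
      if (cost < best) best <- cost
    }
    memo[[s]] <- best
    best
  }
  rec(canonicalize(smiles)$smiles)
}

## ---- mock predictor contracts ----

#' Mock predictor contracts over a toy world
#'
#' `mock_t1()` inverts the toy rules at the tagged site. `mock_t2()`
#' recovers the reagent set of the rule linking the starting materials to
#' the product (plus a low-scoring decoy when the beam allows, so reagent
#' selection by forward confidence is exercised). `mock_t3()` applies the
#' rule matching the given reagents and returns the possible products,
#' best first; with `noise > 0` a deterministic pseudo-random fraction of
#' calls returns a corrupted product, which forward validation must filter.
#' `mock_tagger()` marks the changed-environment atoms of every
#' disconnectable linkage.
#'
#' @param world A `toy_world` from [generate_world()].
#' @param noise Fraction of `mock_t3` calls that return a wrong product.
#' @return A predictor contract object.
#' @name mock_models
NULL

#' @rdname mock_models
#' @export
mock_t1 <- function(world) {
  rules <- world$rules
  link_cache <- new.env(parent = emptyenv())
  retro_model(function(tagged_product, beam) {
    stopifnot(inherits(tagged_product, "tagged_molecule"))
    key <- tagged_product$molecule$smiles
    links <- link_cache[[key]]
    if (is.null(links)) {
      links <- retro_links(tagged_product$molecule, rules)
      link_cache[[key]] <- links
    }
    matching <- Filter(function(ln)
      identical(ln$tags, tagged_product$tagged_atoms), links)
    hits <- list()
    for (ln in matching) {
      sms <- retro_edit(ln$rule$kind, tagged_product$molecule$graph, ln$lk)
      if (is.null(sms)) next
      hits[[length(hits) + 1L]] <- list(rule = ln$rule, sm = sms)
    }
    if (length(hits) == 0L) return(list())
    keys <- vapply(hits, function(o) paste(o$sm, collapse = "."), character(1L))
    hits <- hits[!duplicated(keys)]
    scores <- vapply(hits, function(o) o$rule$base_confidence, numeric(1L))
    keys <- keys[!duplicated(keys)]
    ord <- order(-scores, keys)
    hits <- hits[ord][seq_len(min(beam, length(hits)))]
    lapply(hits, function(o)
      scored_prediction(lapply(o$sm, canonicalize), o$rule$base_confidence))
  }, name = "mock")
}

#' @rdname mock_models
#' @export
mock_t2 <- function(world) {
  rules <- world$rules
  reagent_model(function(sm, product, beam) {
    product <- canonicalize(product)
    out <- list()
    for (rule in rules) {
      if (product$smiles %in% forward_products(rule, sm)) {
        out[[length(out) + 1L]] <-
          scored_prediction(lapply(rule$reagents, canonicalize),
                            rule$base_confidence, allow_empty = TRUE)
      }
    }
    if (length(out) < beam)   # low-confidence decoy reagent set
      out[[length(out) + 1L]] <-
        scored_prediction(list(canonicalize("O")), 0.25, allow_empty = TRUE)
    scores <- vapply(out, function(p) p$score, numeric(1L))
    out[order(-scores)][seq_len(min(beam, length(out)))]
  }, name = "mock")
}

#' @rdname mock_models
#' @export
mock_t3 <- function(world, noise = 0) {
  rules <- world$rules
  seed <- world$spec$seed
  forward_model(function(sm, reagents) {
    rkey <- paste(sort(vapply(reagents, function(m) canonicalize(m)$smiles,
                              character(1L))), collapse = ".")
    rule <- NULL
    for (r in rules)
      if (identical(rkey, paste(sort(canonical_smiles(r$reagents)),
                                collapse = "."))) rule <- r
    smm <- lapply(sm, canonicalize)
    fallback <- function() {
      # no applicable rule: "predict" the largest input, a wrong product
      sizes <- vapply(smm, function(m) m$atom_count, integer(1L))
      list(scored_prediction(smm[which.max(sizes)], 0.05))
    }
    if (is.null(rule)) return(fallback())
    prods <- forward_products(rule, smm)
    if (length(prods) == 0L) return(fallback())
    if (noise > 0) {
      key <- paste(c(vapply(smm, function(m) m$smiles, character(1L)),
                     rkey), collapse = ">")
      if (hash01(key, seed) < noise)
        return(list(scored_prediction(list(canonicalize("C")),
                                      rule$base_confidence)))
    }
    lapply(seq_along(prods), function(k)
      scored_prediction(list(canonicalize(prods[k])),
                        rule$base_confidence * 0.97^(k - 1)))
  }, name = if (noise > 0) sprintf("mock(noise=%g)", noise) else "mock")
}

#' @rdname mock_models
#' @export
mock_tagger <- function(world) {
  rules <- world$rules
  tagger_model(function(m, beam) {
    m <- canonicalize(m)
    opts <- retro_links(m, rules)
    if (length(opts) == 0L) return(list())
    tags <- lapply(opts, function(o) o$tags)
    scores <- vapply(opts, function(o) o$rule$base_confidence, numeric(1L))
    keys <- vapply(tags, paste, character(1L), collapse = ",")
    keep <- !duplicated(keys)
    tags <- tags[keep]; scores <- scores[keep]
    ord <- order(-scores, keys[keep])
    tags <- tags[ord]; scores <- scores[ord]
    n <- min(beam, length(tags))
    lapply(seq_len(n), function(i)
      list(tagged = serialize_tagged(tagged_molecule(m, tags[[i]])),
           score = scores[i]))
  }, name = "mock")
}

#' All four mock contracts of a world as a model bundle
#'
#' @param world A `toy_world`.
#' @param t3_noise Noise fraction for the forward model.
#' @return List with elements `t1`, `t2`, `t3`, `tagger` and mined
#'   `templates` (radius 2 over the world corpus).
#' @export
mock_models <- function(world, t3_noise = 0) {
  list(t1 = mock_t1(world), t2 = mock_t2(world),
       t3 = mock_t3(world, noise = t3_noise),
       tagger = mock_tagger(world),
       templates = extract_templates(world$corpus, radius = 2L))
}

## ---- random molecules for property tests ----

#' Random valid molecules
#'
#' Seeded generator of random acyclic/ring-bearing molecules over
#' C, N, O, S and halogens, used by the round-trip property suites.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param max_atoms Maximum heavy atoms in the random skeleton (a phenyl
#'   ring may add six more).
#' @return Character vector of SMILES (not necessarily canonical).
#' @export
random_molecules <- function(n, seed = 1L, max_atoms = 12L) {
  with_seed(seed, vapply(seq_len(n), function(i)
    random_molecule_once(max_atoms), character(1L)))
}

random_molecule_once <- function(max_atoms) {
  n <- sample(2:max_atoms, 1L)
  mg <- new_molgraph()
  elements <- c("C", "C", "C", "C", "C", "N", "O", "S")
  mg <- mg_add_atom(mg, sample(elements, 1L))
  for (i in 2:n) {
    parent <- sample.int(mg$n, 1L)
    free_p <- free_valence(mg, parent)
    if (free_p < 1L) next
    el <- sample(c(elements, "F", "Cl", "Br"), 1L)
    order <- 1
    if (free_p >= 2L && el %in% c("C", "N", "O") && stats::runif(1) < 0.2)
      order <- 2
    mg <- mg_add_atom(mg, el)
    if (el %in% c("F", "Cl", "Br")) order <- 1
    mg <- mg_add_bond(mg, parent, mg$n, order)
  }
  # occasionally close a ring
  if (mg$n >= 4L && stats::runif(1) < 0.35) {
    cand <- which(vapply(seq_len(mg$n), function(a)
      free_valence(mg, a) >= 1L, logical(1L)))
    if (length(cand) >= 2L) {
      ab <- sample(cand, 2L)
      if (!any((mg$bond_from == ab[1L] & mg$bond_to == ab[2L]) |
               (mg$bond_from == ab[2L] & mg$bond_to == ab[1L])))
        mg <- mg_add_bond(mg, ab[1L], ab[2L], 1)
    }
  }
  # occasionally fuse on a phenyl substituent
  if (stats::runif(1) < 0.3) {
    att <- which(vapply(seq_len(mg$n), function(a)
      free_valence(mg, a) >= 1L & mg$element[a] == "C", logical(1L)))
    if (length(att) >= 1L) {
      a <- sample(att, 1L)
      base <- mg$n
      for (k in 1:6) mg <- mg_add_atom(mg, "C", aromatic = TRUE)
      for (k in 1:5) mg <- mg_add_bond(mg, base + k, base + k + 1L, 1.5)
      mg <- mg_add_bond(mg, base + 6L, base + 1L, 1.5)
      mg <- mg_add_bond(mg, a, base + 1L, 1)
    }
  }
  mg <- assign_implicit_h(mg)
  smi_write(mg, ranks = sample(mg$n))
}

free_valence <- function(mg, a) {
  if (mg$aromatic[a]) return(if (mg$element[a] == "C") 1L else 0L)
  v <- unname(STD_VALENCE[mg$element[a]])
  if (is.na(v)) return(0L)
  bs <- 0
  for (b in seq_along(mg$bond_from))
    if (mg$bond_from[b] == a || mg$bond_to[b] == a) bs <- bs + mg$bond_order[b]
  as.integer(max(0, v - bs))
}
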