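# Shared fixtures: memoized toy worlds and small constructors used across
# the suite. Everything is generated in code at test time.

.world_cache <- new.env(parent = emptyenv())

helper_world <- function(seed = 1L, max_depth = 2L,
                         reactions_per_depth = 10L) {
  key <- paste(seed, max_depth, reactions_per_depth, sep = "/")
  w <- .world_cache[[key]]
  if (is.null(w)) {
    w <- generate_world(world_spec(seed = seed, max_depth = max_depth,
                                   reactions_per_depth = reactions_per_depth))
    .world_cache[[key]] <- w
  }
  w
}

helper_models <- function(world, t3_noise = 0) {
  key <- paste0("m/", world$spec$seed, "/", world$spec$max_depth, "/",
                world$spec$reactions_per_depth, "/", t3_noise)
  m <- .world_cache[[key]]
  if (is.null(m)) {
    m <- mock_models(world, t3_noise = t3_noise)
    .world_cache[[key]] <- m
  }
  m
}

# brute-force reaction-center oracle over atom_table() output: neighbor
# (element, order) multiset + charge + hydrogen count per map label,
# written independently of the package's environment-diff implementation
oracle_reacting <- function(rxn) {
  env_of <- function(smiles) {
    tab <- atom_table(smiles)
    out <- list()
    for (i in which(tab$atoms$map > 0L)) {
      rows <- tab$bonds$from == i | tab$bonds$to == i
      nbr <- ifelse(tab$bonds$from[rows] == i, tab$bonds$to[rows],
                    tab$bonds$from[rows])
      sig <- paste(sort(paste0(tab$atoms$element[nbr], "/",
                               tab$bonds$order[rows])), collapse = " ")
      out[[as.character(tab$atoms$map[i])]] <-
        paste(sig, tab$atoms$charge[i], tab$atoms$hcount[i])
    }
    out
  }
  sm_env <- list()
  for (s in rxn$starting_materials) sm_env <- c(sm_env, env_of(s))
  p_env <- env_of(rxn$product)
  labs <- as.integer(names(p_env))
  changed <- vapply(names(p_env), function(l)
    is.null(sm_env[[l]]) || !identical(sm_env[[l]], p_env[[l]]),
    logical(1L))
  sort(labs[changed])
}

# a single-step record over abstract molecules, for search-tree tests that
# need no chemistry beyond distinct canonical SMILES
fake_step <- function(product, sm, confidence = 0.9) {
  p <- canonicalize(product)
  single_step(p,
              lapply(sm, canonicalize),
              reagent_set = list(),
              confidence = confidence,
              site = tagged_molecule(p, 1L))
}

# distinct simple molecules (canonical n-alkanes) to label abstract tree
# nodes; canonical form so they can key search-state memos directly
alkane <- function(i)
  canonicalize(paste(rep("C", i), collapse = ""))$smiles

# independent brute-force oracle for route enumeration: tries every full
# assignment of one step per expanded molecule, derives the induced route
# from the target, and keeps the valid ones (deduplicated on step sets)
oracle_enumerate_routes <- function(target, bb_members, steps_by_molecule) {
  mols <- names(steps_by_molecule)
  expanded <- mols[lengths(steps_by_molecule) > 0L]
  combos <- list(stats::setNames(list(), character()))
  for (m in expanded) {
    grown <- list()
    for (a in combos)
      for (i in seq_along(steps_by_molecule[[m]])) {
        a[[m]] <- i
        grown[[length(grown) + 1L]] <- a
      }
    combos <- grown
  }
  routes <- list()
  for (assignment in combos) {
    ok <- TRUE
    steps <- list()
    open <- character()
    walk <- function(m, anc) {
      if (!ok) return()
      if (m %in% bb_members) return()
      st <- steps_by_molecule[[m]]
      if (is.null(st)) { open <<- union(open, m); return() }
      if (length(st) == 0L) { ok <<- FALSE; return() }   # dead
      s <- st[[assignment[[m]]]]
      sms <- vapply(s$sm_set, function(x) x$smiles, character(1L))
      if (any(sms %in% c(anc, m))) { ok <<- FALSE; return() }
      steps[[m]] <<- s
      for (x in sms) walk(x, c(anc, m))
    }
    walk(target, character())
    if (!ok) next
    key <- paste(sort(vapply(steps, function(s)
      paste0(s$product$smiles, "=>", s$sm_key), character(1L))),
      collapse = "|")
    routes[[key]] <- list(key = key, solved = length(open) == 0L &&
                            length(steps) > 0L)
  }
  unname(routes)
}
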