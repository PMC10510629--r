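# Multistep best-first exploration. The search tree is an AND-OR structure:
# a molecule (OR node) may be disconnected by any of its validated single
# steps, and a step (AND node) requires all of its starting materials. A
# route selects exactly one step for every expanded non-building-block
# molecule it contains. Per iteration, routes are enumerated and ranked by
# route penalty score, the best unsolved routes have their open leaves
# expanded by the single-step loop (memoized per molecule), and the loop
# stops once enough solved routes exist or the iteration budget is spent.

#' Construct a search state
#'
#' Mostly internal to [search_routes()], but exposed so route enumeration
#' can be driven over hand-built trees.
#'
#' @param target Target `molecule` (or SMILES).
#' @param bb A `bb_set`.
#' @param steps_by_molecule Named list: canonical SMILES -> list of
#'   `single_step` (empty list marks a dead molecule; absent molecules are
#'   unexpanded open leaves).
#' @return An object of class `search_state`.
#' @export
search_state <- function(target, bb, steps_by_molecule = list()) {
  target <- canonicalize(target)
  memo <- new.env(parent = emptyenv())
  for (k in names(steps_by_molecule))
    memo[[canonicalize(k)$smiles]] <- steps_by_molecule[[k]]
  structure(list(target = target, bb = bb, memo = memo,
                 iteration = 0L), class = "search_state")
}

step_sm_smiles <- function(s)
  vapply(s$sm_set, function(m) m$smiles, character(1L))

route_key <- function(steps) {
  paste(sort(vapply(steps, function(s)
    paste0(s$product$smiles, "=>", s$sm_key), character(1L))),
    collapse = "|")
}

make_route <- function(target, steps, open_leaves, bb) {
  all_sm <- unique(unlist(lapply(steps, step_sm_smiles)))
  leaves <- setdiff(all_sm, vapply(steps, function(s) s$product$smiles,
                                   character(1L)))
  if (length(steps) == 0L) leaves <- target$smiles
  structure(list(target = target, steps = steps, n = length(steps),
                 open_leaves = open_leaves,
                 leaves = leaves,
                 solved = length(open_leaves) == 0L && length(steps) > 0L,
                 key = route_key(steps)),
            class = "route")
}

#' @export
print.route <- function(x, ...) {
  cat("<route> ", x$n, " step(s), ",
      if (x$solved) "solved" else
        paste0("open: ", paste(x$open_leaves, collapse = ", ")), "\n",
      sep = "")
  for (s in x$steps)
    cat("  ", s$product$smiles, " => ", s$sm_key,
        sprintf("  (CS %.3f)\n", s$confidence), sep = "")
  invisible(x)
}

#' Enumerate all routes of the current search tree
#'
#' Every combination of step selections (one step per expanded
#' non-building-block molecule, consistent across branches) yields one
#' route. Acyclicity is enforced: a step whose starting materials contain an
#' ancestor of its position is excluded. Molecules that were expanded but
#' produced no validated step ("dead") prune every route through them.
#'
#' @param state A `search_state`.
#' @param cap Maximum number of routes to generate; the result carries a
#'   `truncated` attribute when the cap bites.
#' @return List of `route` objects.
#' @export
enumerate_routes <- function(state, cap = 10000L) {
  bb_members <- state$bb$members
  memo <- state$memo
  routes <- list()
  seen_keys <- new.env(parent = emptyenv())
  truncated <- FALSE
  rec <- function(stack, assign, open) {
    if (truncated) return()
    if (length(stack) == 0L) {
      r <- make_route(state$target, unname(assign), open, state$bb)
      kk <- paste0("k:", r$key)            # env names must be non-empty
      if (is.null(seen_keys[[kk]])) {      # identical step selections merge
        seen_keys[[kk]] <- TRUE
        routes[[length(routes) + 1L]] <<- r
        if (length(routes) >= cap) truncated <<- TRUE
      }
      return()
    }
    fr <- stack[[1L]]; rest <- stack[-1L]
    m <- fr$m
    if (m %in% bb_members) { rec(rest, assign, open); return() }
    steps <- memo[[m]]
    if (is.null(steps)) { rec(rest, assign, union(open, m)); return() }
    if (length(steps) == 0L) return()        # dead molecule
    if (!is.null(assign[[m]])) {
      s <- assign[[m]]
      sms <- step_sm_smiles(s)
      if (any(sms %in% c(fr$anc, m))) return()  # cycle at this position
      kids <- lapply(sms, function(x) list(m = x, anc = c(fr$anc, m)))
      rec(c(kids, rest), assign, open)
      return()
    }
    for (s in steps) {
      sms <- step_sm_smiles(s)
      if (any(sms %in% c(fr$anc, m))) next
      a2 <- assign
      a2[[m]] <- s
      kids <- lapply(sms, function(x) list(m = x, anc = c(fr$anc, m)))
      rec(c(kids, rest), a2, open)
    }
  }
  rec(list(list(m = state$target$smiles, anc = character())),
      stats::setNames(list(), character()), character())
  attr(routes, "truncated") <- truncated
  routes
}

#' Rank routes by route penalty score
#'
#' Partitions into solved and unsolved routes, each sorted by descending
#' RPScore with ties broken by fewer steps, then by the route identity key.
#' An unexpanded zero-step route scores a neutral 1.
#'
#' @param routes List of `route` objects.
#' @param cfg Configuration (for `sp`, `count_duplicates`).
#' @param bb A `bb_set`.
#' @param scorer Complexity scorer.
#' @return List with sorted elements `solved` and `unsolved`; each route
#'   gains `rpscore` and `cscore` fields.
#' @export
rank_routes <- function(routes, cfg = default_config(), bb,
                        scorer = heuristic_complexity) {
  routes <- lapply(routes, function(r) {
    r$rpscore <- if (r$n == 0L) 1.0 else rpscore(r, cfg, bb, scorer)
    r$cscore <- if (r$n == 0L) 1.0 else cscore(r)
    r
  })
  solved <- Filter(function(r) r$solved, routes)
  unsolved <- Filter(function(r) !r$solved, routes)
  sort_routes <- function(rs) {
    if (length(rs) <= 1L) return(rs)
    rp <- vapply(rs, function(r) r$rpscore, numeric(1L))
    nn <- vapply(rs, function(r) r$n, integer(1L))
    kk <- vapply(rs, function(r) r$key, character(1L))
    rs[order(-rp, nn, kk)]
  }
  list(solved = sort_routes(solved), unsolved = sort_routes(unsolved))
}

#' Multistep retrosynthesis search
#'
#' Best-first iterative exploration from a target molecule down to a
#' building-block set: enumerate routes, rank by RPScore, expand the open
#' leaves of the best unsolved routes with the single-step loop (memoized
#' per molecule), and repeat until enough solved routes exist, the
#' iteration budget is spent, or nothing is left to expand.
#'
#' @param target Target `molecule` or SMILES.
#' @param models Model bundle (`t1`, `t2`, `t3`, optional `tagger`,
#'   `templates`), e.g. [mock_models()].
#' @param bb A `bb_set`.
#' @param cfg Configuration, see [default_config()].
#' @param verbose Emit per-iteration log lines.
#' @return A `search_report`: ranked solved and unsolved routes (with
#'   RPScore/CScore and per-step discovery iteration), iteration count,
#'   number of single-step loop calls, per-iteration best solved RPScore
#'   trace, and an exhaustion flag.
#' @export
search_routes <- function(target, models, bb, cfg = default_config(),
                          verbose = FALSE) {
  target <- canonicalize(target)
  scorer <- resolve_scorer(cfg)
  scfg <- cfg$search
  if (is_building_block(bb, target)) {
    return(structure(list(target = target, solved = list(),
                          unsolved = list(), trivially_solved = TRUE,
                          iterations = 0L, ttl_calls = 0L,
                          exhausted = FALSE, best_trace = numeric(),
                          n_predictions = 0L),
                     class = "search_report"))
  }
  state <- search_state(target, bb)
  ttl_calls <- 0L
  n_predictions <- 0L
  best_trace <- numeric()
  exhausted <- FALSE
  it <- 0L
  while (it < scfg$max_iterations) {
    it <- it + 1L
    routes <- enumerate_routes(state, cap = scfg$route_cap)
    rk <- rank_routes(routes, cfg, bb, scorer)
    best_trace[it] <- if (length(rk$solved) > 0L) rk$solved[[1L]]$rpscore
                      else 0
    if (length(rk$solved) >= scfg$min_solved) break
    top <- rk$unsolved[seq_len(min(scfg$expansion_width,
                                   length(rk$unsolved)))]
    leaves <- unique(unlist(lapply(top, function(r) r$open_leaves)))
    leaves <- setdiff(leaves, c(ls(state$memo), state$bb$members))
    if (length(leaves) == 0L) { exhausted <- TRUE; break }
    for (leaf in sort(leaves)) {
      res <- run_ttl(leaf, cfg, models)
      n_predictions <- n_predictions + attr(res, "n_sites")
      ttl_calls <- ttl_calls + 1L
      if (length(res) > scfg$per_molecule_cap)
        res <- res[seq_len(scfg$per_molecule_cap)]
      res <- lapply(res, function(s) { s$discovered_at <- it; s })
      state$memo[[leaf]] <- res
    }
    if (verbose)
      message(sprintf(
        "iteration %d: expanded %d molecule(s), %d solved / %d unsolved routes, %d cumulative TTL calls",
        it, length(leaves), length(rk$solved), length(rk$unsolved),
        ttl_calls))
  }
  routes <- enumerate_routes(state, cap = scfg$route_cap)
  keys <- vapply(routes, function(r) r$key, character(1L))
  routes <- routes[!duplicated(keys)]
  rk <- rank_routes(routes, cfg, bb, scorer)
  if (length(rk$solved) > 0L)
    best_trace[length(best_trace) + 1L] <- rk$solved[[1L]]$rpscore
  structure(list(target = target, solved = rk$solved,
                 unsolved = rk$unsolved, trivially_solved = FALSE,
                 iterations = it, ttl_calls = ttl_calls,
                 exhausted = exhausted && length(rk$solved) == 0L,
                 best_trace = best_trace,
                 n_predictions = n_predictions,
                 truncated = isTRUE(attr(routes, "truncated"))),
            class = "search_report")
}

#' @export
print.search_report <- function(x, ...) {
  cat("<search report> target ", x$target$smiles, "\n", sep = "")
  if (isTRUE(x$trivially_solved)) {
    cat("  target is a building block; zero-step route\n")
    return(invisible(x))
  }
  cat("  ", length(x$solved), " solved / ", length(x$unsolved),
      " unsolved routes after ", x$iterations, " iteration(s), ",
      x$ttl_calls, " single-step call(s)\n", sep = "")
  if (length(x$solved) > 0L) {
    b <- x$solved[[1L]]
    cat(sprintf("  best solved: %d step(s), RPScore %.4f, CScore %.4f\n",
                b$n, b$rpscore, b$cscore))
  }
  if (x$exhausted) cat("  search space exhausted without a solved route\n")
  invisible(x)
}

resolve_scorer <- function(cfg) {
  if (is.function(cfg$complexity)) return(cfg$complexity)
  switch(as.character(cfg$complexity),
         heuristic = heuristic_complexity,
         stop("unknown complexity scorer: ", cfg$complexity))
}
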