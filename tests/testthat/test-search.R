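# Route enumeration, ranking and the best-first multistep search.

test_that("route enumeration matches the brute-force oracle", {
  # hand-built trees first
  bb <- bb_set(c("C", "CC", "CCC"))
  t8 <- alkane(8)
  steps <- list()
  steps[[t8]] <- list(fake_step(t8, list("C", alkane(5)), 0.9),
                      fake_step(t8, list(alkane(4)), 0.8))
  steps[[alkane(5)]] <- list(fake_step(alkane(5), list("CC", "CCC"), 0.9))
  steps[[alkane(4)]] <- list()    # dead end
  st <- search_state(t8, bb, steps)
  routes <- enumerate_routes(st)
  oracle <- oracle_enumerate_routes(canonicalize(t8)$smiles, bb$members,
                                    steps)
  expect_setequal(vapply(routes, function(r) r$key, character(1L)),
                  vapply(oracle, function(r) r$key, character(1L)))
  expect_length(routes, 1L)     # the dead branch prunes the second option
  expect_true(routes[[1L]]$solved)

  # randomized trees vs the oracle
  set.seed(99)
  for (rep in 1:12) {
    n_mol <- sample(5:9, 1L)
    mols <- vapply(seq_len(n_mol), alkane, character(1L))
    bb_members <- mols[seq_len(2L)]
    bbr <- bb_set(bb_members)
    target <- mols[n_mol]
    steps <- list()
    for (i in seq(3L, n_mol)) {
      k <- sample(0:2, 1L)
      if (i == n_mol) k <- max(k, 1L)
      if (k == 0L && runif(1) < 0.5) next        # leave unexpanded (open)
      steps[[mols[i]]] <- lapply(seq_len(k), function(j) {
        sm <- sample(mols[seq_len(i - 1L)], sample(1:2, 1L))
        fake_step(mols[i], as.list(unique(sm)), runif(1, 0.5, 1))
      })
    }
    st <- search_state(target, bbr, steps)
    routes <- enumerate_routes(st)
    oracle <- oracle_enumerate_routes(target, bbr$members, steps)
    expect_setequal(vapply(routes, function(r) r$key, character(1L)),
                    vapply(oracle, function(r) r$key, character(1L)))
  }
})

test_that("acyclicity excludes steps reusing an ancestor", {
  bb <- bb_set("C")
  a <- alkane(5); b <- alkane(6)
  steps <- list()
  steps[[a]] <- list(fake_step(a, list(b), 0.9))
  steps[[b]] <- list(fake_step(b, list(a), 0.9),    # would loop a -> b -> a
                     fake_step(b, list("C"), 0.8))
  routes <- enumerate_routes(search_state(a, bb, steps))
  expect_length(routes, 1L)
  expect_true(routes[[1L]]$solved)
  prods <- vapply(routes[[1L]]$steps, function(s) s$product$smiles,
                  character(1L))
  expect_identical(anyDuplicated(prods), 0L)   # no molecule re-disconnected
})

test_that("ranking sorts by RPScore with step-count and key tiebreaks", {
  bb <- bb_set(c("C", "CC"))
  cfg <- default_config()
  r_good <- local({
    st <- list(); t6 <- alkane(6)
    st[[t6]] <- list(fake_step(t6, list("C", "CC"), 1.0))
    enumerate_routes(search_state(t6, bb, st))[[1L]]
  })
  r_poor <- local({
    st <- list(); t7 <- alkane(7)
    st[[t7]] <- list(fake_step(t7, list(alkane(5)), 0.6))
    st[[alkane(5)]] <- list(fake_step(alkane(5), list("C"), 0.6))
    enumerate_routes(search_state(t7, bb, st))[[1L]]
  })
  rk <- rank_routes(list(r_poor, r_good), cfg, bb)
  expect_length(rk$solved, 2L)
  expect_gte(rk$solved[[1L]]$rpscore, rk$solved[[2L]]$rpscore)
  expect_identical(rk$solved[[1L]]$key, r_good$key)
  expect_identical(rank_routes(list(), cfg, bb),
                   list(solved = list(), unsolved = list()))
})

test_that("search solves known targets and memoizes expansions", {
  w <- helper_world(1L, max_depth = 2L, reactions_per_depth = 15L)
  models <- helper_models(w)
  # wrap the tagger to record which molecules get expanded
  seen <- character()
  counting <- models
  counting$tagger <- tagger_model(function(m, beam) {
    seen <<- c(seen, m$smiles)
    models$tagger$predict(m, beam)
  })
  bb <- bb_set(w$bb)
  rep <- search_routes(w$targets$smiles[1L], counting, bb, default_config())
  expect_gte(length(rep$solved), 1L)
  best <- rep$solved[[1L]]
  # all leaves of a solved route are building blocks
  expect_true(all(best$leaves %in% bb$members))
  expect_identical(best$n, as.integer(w$targets$min_steps[1L]))
  # memoization: every molecule expanded at most once
  expect_identical(anyDuplicated(seen), 0L)
  expect_identical(rep$ttl_calls, length(seen))
  # anytime property: the best solved RPScore never degrades
  expect_true(all(diff(rep$best_trace) >= -1e-12))
  # steps carry the iteration at which they were discovered
  its <- unlist(lapply(rep$solved, function(r)
    vapply(r$steps, function(s) s$discovered_at, integer(1L))))
  expect_true(all(its >= 1L & its <= rep$iterations))
})

test_that("degenerate searches behave", {
  w <- helper_world(4L, max_depth = 1L, reactions_per_depth = 8L)
  models <- helper_models(w)
  bb <- bb_set(w$bb)
  # a building-block target is trivially solved with no predictor calls
  rep <- search_routes(w$bb[1L], models, bb, default_config())
  expect_true(rep$trivially_solved)
  expect_identical(rep$ttl_calls, 0L)
  # zero iteration budget: only the unexpanded root comes back
  cfg0 <- modifyList(default_config(),
                     list(search = list(max_iterations = 0L)))
  rep0 <- search_routes(w$targets$smiles[1L], models, bb, cfg0)
  expect_length(rep0$solved, 0L)
  expect_length(rep0$unsolved, 1L)
  expect_identical(rep0$unsolved[[1L]]$n, 0L)
  expect_identical(rep0$ttl_calls, 0L)
  # an undisconnectable non-BB target exhausts without an exception
  repx <- search_routes("CCCCCCCC", models, bb, default_config())
  expect_true(repx$exhausted)
  expect_length(repx$solved, 0L)
})

test_that("protecting inverse operations cannot loop the search", {
  # an artificial protect/deprotect pair: a <-> b with b also solvable
  bb <- bb_set(c("C", "CC"))
  a <- alkane(5); b <- alkane(6)
  steps <- list()
  steps[[a]] <- list(fake_step(a, list(b), 0.99))
  steps[[b]] <- list(fake_step(b, list(a), 0.99),
                     fake_step(b, list("C", "CC"), 0.7))
  routes <- enumerate_routes(search_state(a, bb, steps))
  for (r in routes) {
    prods <- vapply(r$steps, function(s) s$product$smiles, character(1L))
    expect_identical(anyDuplicated(prods), 0L)
  }
  expect_true(any(vapply(routes, function(r) r$solved, logical(1L))))
})
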