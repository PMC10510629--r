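# The synthetic toy world: determinism, closure, forward/retro inverse
# consistency, and ground-truth route lengths.

test_that("generation is deterministic per seed", {
  w1 <- generate_world(world_spec(seed = 5L, reactions_per_depth = 6L))
  w2 <- generate_world(world_spec(seed = 5L, reactions_per_depth = 6L))
  expect_identical(w1, w2)
  w3 <- generate_world(world_spec(seed = 6L, reactions_per_depth = 6L))
  expect_false(identical(w1$bb, w3$bb) && identical(w1$targets, w3$targets))
})

test_that("every target is solvable within the generation depth", {
  w <- helper_world(1L, max_depth = 2L, reactions_per_depth = 15L)
  expect_gt(length(w$corpus), 0L)
  expect_true(all(is.finite(w$targets$min_steps)))
  expect_true(all(w$targets$min_steps >= w$targets$depth))
})

test_that("depth-1 worlds have only single-step targets", {
  w <- helper_world(4L, max_depth = 1L, reactions_per_depth = 8L)
  expect_true(all(w$targets$min_steps == 1))
})

test_that("forward and retro rule applications are mutually inverse", {
  # every corpus product disconnects back to its starting materials, and
  # the forward model regenerates the product from them
  n_checked <- 0L
  for (seed in 1:3) {
    w <- helper_world(seed, max_depth = 2L, reactions_per_depth = 15L)
    t3 <- mock_t3(w)
    for (rxn in w$corpus) {
      p <- canonicalize(rxn$product)
      sm <- lapply(rxn$starting_materials, canonicalize)
      opts <- retroplan:::retro_options(p, w$rules)
      sm_keys <- vapply(opts, function(o) paste(o$sm, collapse = "."),
                        character(1L))
      want <- paste(sort(vapply(sm, function(m) m$smiles, character(1L))),
                    collapse = ".")
      expect_true(want %in% sm_keys, info = format_reaction(rxn))
      fwd <- t3$predict(sm, lapply(rxn$reagents, canonicalize))
      expect_identical(fwd[[1L]]$payload[[1L]]$smiles, p$smiles,
                       info = format_reaction(rxn))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 50L)
})

test_that("mock contracts are pure in their inputs", {
  w <- helper_world(1L, max_depth = 2L, reactions_per_depth = 15L)
  models <- helper_models(w)
  tm <- tag_product(w$corpus[[1L]])
  expect_identical(models$t1$predict(tm, 3L), models$t1$predict(tm, 3L))
  m <- canonicalize(w$targets$smiles[1L])
  expect_identical(models$tagger$predict(m, 10L),
                   models$tagger$predict(m, 10L))
})

test_that("world files round-trip through the writers", {
  w <- helper_world(4L, max_depth = 1L, reactions_per_depth = 8L)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_identical(read_smi(file.path(dir, "bb.smi"))$smiles, w$bb)
  corpus <- read_rsmi(file.path(dir, "corpus.rsmi"))
  expect_identical(vapply(corpus, format_reaction, character(1L)),
                   vapply(w$corpus, format_reaction, character(1L)))
})
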