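# The triple-predictor single-step loop: forward validation, beam
# monotonicity, dedup, no-op rejection, noise filtering, efficiency.

test_that("consistent worlds yield validated, round-tripping steps", {
  w <- helper_world(1L, max_depth = 2L, reactions_per_depth = 15L)
  models <- helper_models(w)
  cfg <- default_config()
  for (t in w$targets$smiles[1:3]) {
    res <- run_ttl(t, cfg, models)
    expect_gte(length(res), 1L)
    p <- canonicalize(t)
    for (s in res) {
      # every kept step satisfies forward(sm, r) top-1 == product
      fwd <- models$t3$predict(s$sm_set, s$reagent_set)
      expect_identical(fwd[[1L]]$payload[[1L]]$smiles, p$smiles)
      expect_identical(fwd[[1L]]$score, s$confidence)
      # the product itself never appears among the starting materials
      expect_false(p$smiles %in% vapply(s$sm_set, function(m) m$smiles,
                                        character(1L)))
    }
    # no two results share a starting-material key
    keys <- vapply(res, function(s) s$sm_key, character(1L))
    expect_identical(anyDuplicated(keys), 0L)
  }
})

test_that("wider beams never lose validated steps", {
  w <- helper_world(2L, max_depth = 2L, reactions_per_depth = 10L)
  models <- helper_models(w)
  narrow <- modifyList(default_config(),
                       list(ttl = list(beam_t1 = 1L, beam_t2 = 1L,
                                       min_confidence = 0)))
  wide <- default_config()
  for (t in w$targets$smiles[1:2]) {
    k1 <- vapply(run_ttl(t, narrow, models), function(s) s$sm_key,
                 character(1L))
    k3 <- vapply(run_ttl(t, wide, models), function(s) s$sm_key,
                 character(1L))
    expect_true(all(k1 %in% k3))
  }
})

test_that("full forward noise filters every step", {
  w <- helper_world(1L, max_depth = 2L, reactions_per_depth = 15L)
  noisy <- mock_models(w, t3_noise = 1)
  res <- run_ttl(w$targets$smiles[1L], default_config(), noisy)
  expect_length(res, 0L)
})

test_that("partial forward noise passes its binomial share of round trips", {
  # 200 distinct forward calls at 50% corruption: the validated fraction
  # must land inside the exact binomial 99% interval
  f <- 0.5
  trials <- 0L
  okc <- 0L
  for (seed in 1:8) {
    if (trials >= 200L) break
    w <- helper_world(seed, max_depth = 2L, reactions_per_depth = 15L)
    t3 <- mock_t3(w, noise = f)
    for (rxn in w$corpus) {
      if (trials >= 200L) break
      p <- canonicalize(rxn$product)
      fwd <- t3$predict(lapply(rxn$starting_materials, canonicalize),
                        lapply(rxn$reagents, canonicalize))
      okc <- okc + (fwd[[1L]]$payload[[1L]]$smiles == p$smiles)
      trials <- trials + 1L
    }
  }
  expect_identical(trials, 200L)
  lo <- qbinom(0.005, trials, 1 - f)
  hi <- qbinom(0.995, trials, 1 - f)
  expect_gte(okc, lo)
  expect_lte(okc, hi)
})

test_that("tagging efficiency is validated steps per tagging round", {
  steps <- lapply(1:4, function(i) fake_step(alkane(8), list(alkane(i))))
  expect_identical(tagging_efficiency(steps, 20L), 0.2)
  expect_identical(tagging_efficiency(list(), 10L), 0)
  expect_error(tagging_efficiency(steps, 0L), "positive")
  w <- helper_world(1L, max_depth = 2L, reactions_per_depth = 15L)
  models <- helper_models(w)
  res <- run_ttl(w$targets$smiles[1L], default_config(), models)
  eff <- tagging_efficiency(res, attr(res, "n_sites"))
  expect_gt(eff, 0)
  expect_lte(eff, 1)
})
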