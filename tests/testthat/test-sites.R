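# Disconnection-site enumeration: systematic orbits, tagger validation,
# strategy union with provenance.

test_that("systematic tagging collapses symmetric sites", {
  # propane: 3 singles + 2 pairs + 1 triplet = 6 raw, 4 after symmetry
  expect_length(systematic_tags(canonicalize("CCC")), 4L)
  # methane: one atom, one variant
  expect_length(systematic_tags(canonicalize("C")), 1L)
  # cyclopropane: one single, one pair, one triangle
  expect_length(systematic_tags(canonicalize("C1CC1")), 3L)
  # benzene: one single, one pair, one triplet
  expect_length(systematic_tags(canonicalize("c1ccccc1")), 3L)
})

test_that("systematic tags match brute-force orbit enumeration", {
  for (s in c("CCO", "CC(C)O", "c1ccc(C)cc1")) {
    m <- canonicalize(s)
    g <- m$graph
    raw <- list()
    for (i in seq_len(g$n)) raw[[length(raw) + 1L]] <- i
    for (b in seq_along(g$bond_from))
      raw[[length(raw) + 1L]] <- c(g$bond_from[b], g$bond_to[b])
    for (i in seq_len(g$n))
      for (j in seq_len(g$n))
        for (k in seq_len(g$n)) {
          if (i >= j || j >= k) next
          trip <- c(i, j, k)
          eb <- sum((g$bond_from %in% trip) & (g$bond_to %in% trip))
          if (eb >= 2L) raw[[length(raw) + 1L]] <- trip  # connected triplet
        }
    keys <- unique(vapply(raw, function(t)
      retroplan:::tagged_key(tagged_molecule(m, t)), character(1L)))
    expect_length(systematic_tags(m), length(keys))
  }
})

test_that("tagger suggestions are validated against the query molecule", {
  good_bad_tagger <- tagger_model(function(m, beam) {
    list(list(tagged = serialize_tagged(tagged_molecule(m, 1L)), score = 0.9),
         list(tagged = "C!CCCCCCCC", score = 0.5),   # different molecule
         list(tagged = "not-a-smiles", score = 0.4))
  })
  res <- model_tags(canonicalize("CCO"), good_bad_tagger, beam = 10L)
  expect_length(res, 1L)
  expect_identical(attr(res, "dropped"), 2L)
  # beam bound
  one <- model_tags(canonicalize("CCO"), tagger_model(function(m, beam) {
    lapply(seq_len(beam), function(i)
      list(tagged = serialize_tagged(tagged_molecule(m, i)), score = 1 / i))
  }), beam = 1L)
  expect_length(one, 1L)
})

test_that("strategy union dedups with merged provenance and is monotone", {
  w <- helper_world(1L, max_depth = 2L, reactions_per_depth = 15L)
  models <- helper_models(w)
  m <- canonicalize(w$targets$smiles[1L])
  cfg_all <- default_config()$tagging
  cfg_sys <- modifyList(cfg_all, list(strategies = "systematic"))
  sites_sys <- enumerate_sites(m, cfg_sys)
  expect_identical(
    vapply(sites_sys, serialize_tagged, character(1L)),
    sort(vapply(systematic_tags(m), serialize_tagged, character(1L))))
  sites_all <- enumerate_sites(m, cfg_all, templates = models$templates,
                               tagger = models$tagger)
  # union bound and monotonicity: adding strategies never removes a site
  expect_gte(length(sites_all), length(sites_sys))
  keys_sys <- vapply(sites_sys, retroplan:::tagged_key, character(1L))
  keys_all <- vapply(sites_all, retroplan:::tagged_key, character(1L))
  expect_true(all(keys_sys %in% keys_all))
  # provenance Venn cells sum to the deduplicated total
  counts <- retroplan:::site_provenance_counts(sites_all)
  expect_identical(sum(counts), length(sites_all))
  # at least one site carries two provenance flags (systematic singles
  # coincide with ester tagger sites in this world)
  multi <- vapply(sites_all, function(s)
    length(attr(s, "provenance")) > 1L, logical(1L))
  expect_true(any(multi))
})

test_that("an impossible enumeration errors out", {
  cfg <- modifyList(default_config()$tagging, list(strategies = "template"))
  expect_error(enumerate_sites(canonicalize("CCO"), cfg, templates = list()),
               "no candidate sites")
})
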