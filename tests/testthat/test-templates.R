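# Template mining and application: merging, support filtering, radius
# containment, self-consistency and symmetric-match collapse.

test_that("identical reactions merge into one template with summed support", {
  rxn <- parse_reaction(
    "[CH3:1][OH:2].[CH3:3][C:4](=O)Cl>>[CH3:1][O:2][C:4](=O)[CH3:3]")
  tpls <- extract_templates(list(rxn, rxn, rxn), radius = 1L)
  expect_length(tpls, 1L)
  expect_identical(tpls[[1L]]$support, 3L)
})

test_that("single-occurrence templates are dropped by the support filter", {
  r1 <- parse_reaction(
    "[CH3:1][OH:2].[CH3:3][C:4](=O)Cl>>[CH3:1][O:2][C:4](=O)[CH3:3]")
  r2 <- parse_reaction(
    "[CH3:1][NH2:2].[CH3:3][C:4](=O)Cl>>[CH3:1][NH:2][C:4](=O)[CH3:3]")
  expect_length(extract_templates(list(r1, r2), radius = 1L), 0L)
  expect_length(extract_templates(list(), radius = 1L), 0L)
  # lowering the threshold keeps both
  expect_length(extract_templates(list(r1, r2), radius = 1L,
                                  min_support = 1L), 2L)
})

test_that("every radius-3 pattern contains its radius-1 pattern", {
  w <- helper_world(1L, max_depth = 2L, reactions_per_depth = 15L)
  for (rxn in w$corpus[1:8]) {
    tm <- tag_product(rxn)
    t1 <- retroplan:::template_from_tagged(tm, 1L)
    t3 <- retroplan:::template_from_tagged(tm, 3L)
    # match the radius-1 pattern graph into the radius-3 pattern graph
    n1 <- length(t1$atoms$element); n3 <- length(t3$atoms$element)
    expect_lte(n1, n3)
    type1 <- paste(t1$atoms$element, t1$atoms$aromatic, t1$atoms$charge,
                   t1$atoms$ring, t1$atoms$degree)
    type3 <- paste(t3$atoms$element, t3$atoms$aromatic, t3$atoms$charge,
                   t3$atoms$ring, t3$atoms$degree)
    lev <- unique(c(type1, type3))
    ig1 <- igraph::make_graph(
      edges = as.vector(rbind(t1$bonds$from, t1$bonds$to)), n = n1,
      directed = FALSE)
    ig3 <- igraph::make_graph(
      edges = as.vector(rbind(t3$bonds$from, t3$bonds$to)), n = n3,
      directed = FALSE)
    found <- igraph::subgraph_isomorphic(
      ig1, ig3, method = "vf2",
      vertex.color1 = match(type3, lev), vertex.color2 = match(type1, lev))
    expect_true(found, info = format_reaction(rxn))
  }
})

test_that("each corpus reaction's own template re-tags its product", {
  w <- helper_world(2L, max_depth = 2L, reactions_per_depth = 10L)
  for (rxn in w$corpus) {
    tm <- tag_product(rxn)
    for (radius in 1:3) {
      tpl <- retroplan:::template_from_tagged(tm, radius)
      hits <- apply_templates(tm$molecule, list(tpl))
      keys <- vapply(hits, retroplan:::tagged_key, character(1L))
      expect_true(retroplan:::tagged_key(tm) %in% keys,
                  info = paste(format_reaction(rxn), "radius", radius))
    }
  }
})

test_that("symmetric matches collapse to one tagged result", {
  # a single-atom aromatic CH pattern matches all six benzene positions
  tpl <- tag_template(
    atoms = list(element = "C", aromatic = TRUE, charge = 0L, ring = TRUE,
                 degree = 2L, reactive = TRUE),
    bonds = list(from = integer(), to = integer(), order = numeric()),
    radius = 1L)
  hits <- apply_templates(canonicalize("c1ccccc1"), list(tpl))
  expect_length(hits, 1L)
  expect_length(apply_templates(canonicalize("CCCC"), list(tpl)), 0L)
  # no duplicate serialized tagged strings in any application
  w <- helper_world(1L, max_depth = 2L, reactions_per_depth = 15L)
  tpls <- extract_templates(w$corpus, radius = 2L)
  expect_gte(length(tpls), 1L)
  for (t in w$targets$smiles[1:3]) {
    res <- apply_templates(canonicalize(t), tpls)
    ser <- vapply(res, serialize_tagged, character(1L))
    expect_identical(anyDuplicated(ser), 0L)
  }
})

test_that("support counts sum to records on a disjoint-pattern corpus", {
  w <- helper_world(3L, max_depth = 1L, reactions_per_depth = 12L)
  tpls <- extract_templates(w$corpus, radius = 2L, min_support = 1L)
  expect_identical(sum(vapply(tpls, function(t) t$support, integer(1L))),
                   length(w$corpus) - attr(tpls, "skipped"))
})

test_that("template CSV round-trips", {
  w <- helper_world(1L, max_depth = 2L, reactions_per_depth = 15L)
  tpls <- extract_templates(w$corpus, radius = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_templates_csv(tpls, path)
  back <- read_templates_csv(path)
  expect_identical(vapply(back, function(t) t$pattern, character(1L)),
                   vapply(tpls, function(t) t$pattern, character(1L)))
  expect_identical(vapply(back, function(t) t$support, integer(1L)),
                   vapply(tpls, function(t) t$support, integer(1L)))
})
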