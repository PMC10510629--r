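# Simplicity mapping, building-block membership, RPScore and CScore
# closed forms and invariants.

test_that("simplicity maps complexity linearly and honours the BB set", {
  bb <- bb_set(c("CCO", "CC(=O)O"))
  # membership wins regardless of the scorer
  expect_identical(simplicity("OCC", bb, function(m) 5), 1.0)
  # range endpoints and midpoint of the linear map
  expect_identical(simplicity("CCCCCCCC", bb, function(m) 5), 0.0)
  expect_identical(simplicity("CCCCCCCC", bb, function(m) 1), 1.0)
  expect_identical(simplicity("CCCCCCCC", bb, function(m) 3), 0.5)
  expect_error(simplicity("CCCC", bb, function(m) stop("boom")),
               "scorer failed")
})

test_that("the heuristic complexity scorer stays in [1, 5] and grows", {
  vals <- vapply(c("C", "CCO", "CC(=O)OCCCC", "OC(=O)c1ccccc1",
                   "C[C@H](N)C(=O)OCc1ccccc1"),
                 heuristic_complexity, numeric(1L))
  expect_true(all(vals >= 1 & vals <= 5))
  expect_lt(heuristic_complexity("CC"), heuristic_complexity("CC(=O)OCCCC"))
})

test_that("RPScore closed forms", {
  bb <- bb_set(c("CC(=O)O", "CCO", "CN"))
  cfg <- default_config()
  # one step, unit confidence, all SM in the BB set: exactly SP
  r1 <- list(steps = list(fake_step("CC(=O)OCC", list("CC(=O)O", "CCO"),
                                    confidence = 1.0)))
  expect_equal(rpscore(r1, cfg, bb), 0.8, tolerance = 1e-12)
  # two such steps: SP^2
  r2 <- list(steps = list(
    fake_step("CC(=O)OCC", list("CC(=O)O", "CCO"), confidence = 1.0),
    fake_step("CC(=O)NC", list("CC(=O)O", "CN"), confidence = 1.0)))
  expect_equal(rpscore(r2, cfg, bb), 0.64, tolerance = 1e-12)
  # mixed factors: 0.8 * 0.5 * 0.5 * 1.0
  halfbb <- bb_set("CCO")
  r3 <- list(steps = list(fake_step("CC(=O)OCC", list("CCCCCC", "CCO"),
                                    confidence = 0.5)))
  expect_equal(rpscore(r3, cfg, halfbb, scorer = function(m) 3), 0.2,
               tolerance = 1e-12)
  expect_error(rpscore(list(steps = list()), cfg, bb), "empty route")
})

test_that("CScore is the product of step confidences", {
  r <- list(steps = list(fake_step(alkane(5), list(alkane(1)), 0.9),
                         fake_step(alkane(6), list(alkane(2)), 0.8)))
  expect_equal(cscore(r), 0.72, tolerance = 1e-12)
  r1 <- list(steps = list(fake_step(alkane(5), list(alkane(1)), 0.37)))
  expect_equal(cscore(r1), 0.37)
  expect_error(cscore(list(steps = list())), "empty route")
  # cscore >= rpscore / SP^N since every simplicity factor is <= 1
  bb <- bb_set("C")
  cfg <- default_config()
  expect_gte(cscore(r) + 1e-12, rpscore(r, cfg, bb) / cfg$sp^2)
})

test_that("extending a route strictly decreases RPScore when SP < 1", {
  bb <- bb_set(c("C", "CC", "CCC"))
  cfg <- default_config()
  base <- list(steps = list(fake_step(alkane(6), list("C", "CC"), 0.9)))
  longer <- list(steps = c(base$steps,
                           list(fake_step(alkane(7), list("CCC"), 1.0))))
  expect_lt(rpscore(longer, cfg, bb), rpscore(base, cfg, bb))
})

test_that("RPScore is invariant to step order and counts molecules once", {
  bb <- bb_set("C")
  cfg <- default_config()
  s1 <- fake_step(alkane(6), list("CCCC", "C"), 0.9)
  s2 <- fake_step("CCCC", list("CC", "CC"), 0.8)
  expect_equal(rpscore(list(steps = list(s1, s2)), cfg, bb),
               rpscore(list(steps = list(s2, s1)), cfg, bb))
  # a molecule used by two steps enters the simplicity product once by
  # default, twice with count_duplicates
  s3 <- fake_step(alkane(7), list("CC", "C"), 0.9)
  cfg_dup <- modifyList(cfg, list(count_duplicates = TRUE))
  once <- rpscore(list(steps = list(s2, s3)), cfg, bb)
  twice <- rpscore(list(steps = list(s2, s3)), cfg_dup, bb)
  expect_lt(twice, once)
})

test_that("building-block sets load from .smi files", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("OCC\tbb1", "CC(=O)O\tbb2"), path)
  bb <- bb_set(path)
  expect_true(is_building_block(bb, "CCO"))   # canonicalized at load
  expect_false(is_building_block(bb, "CCCO"))
})
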