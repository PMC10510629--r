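# The "!" tagged-SMILES dialect: serialization syntax, parsing, round
# trips, and map-label conversion.

test_that("serialization places the tag token directly after the atom", {
  # tagging atom i inserts exactly one "!" right after that atom's token
  m <- canonicalize("CCO")
  for (i in seq_len(m$atom_count)) {
    s <- serialize_tagged(tagged_molecule(m, i))
    expect_identical(nchar(s), nchar(m$smiles) + 1L)
    expect_identical(gsub("!", "", s, fixed = TRUE), m$smiles)
  }
  tm <- parse_tagged("CC!O")
  expect_identical(tm$molecule$smiles, canonicalize("CCO")$smiles)
  expect_length(tm$tagged_atoms, 1L)
  tm2 <- parse_tagged("C!C!O")
  expect_length(tm2$tagged_atoms, 2L)
  # tag removal recovers the untagged canonical SMILES exactly
  s <- serialize_tagged(tm2)
  expect_identical(gsub("!", "", s, fixed = TRUE), tm2$molecule$smiles)
})

test_that("untagged input follows the allow_untagged policy", {
  expect_error(parse_tagged("CCO"), "allow_untagged")
  m <- parse_tagged("CCO", allow_untagged = TRUE)
  expect_s3_class(m, "molecule")
})

test_that("misplaced tag tokens are syntax errors", {
  expect_error(parse_tagged("!CCO"), "atom token")
  expect_error(parse_tagged("CC(N)!O"), "atom token")
  expect_error(canonicalize("CC!O"), "unexpected")   # plain parser rejects !
})

test_that("tagging a stereocenter keeps the stereo token invariant", {
  m <- canonicalize("C[C@H](N)O")
  stereo_atom <- which(m$graph$chiral != "")
  tm <- tagged_molecule(m, stereo_atom)
  s <- serialize_tagged(tm)
  expect_identical(gsub("!", "", s, fixed = TRUE), m$smiles)
  back <- parse_tagged(s)
  expect_identical(back$molecule$smiles, m$smiles)
  expect_identical(back$tagged_atoms, tm$tagged_atoms)
})

test_that("serialize/parse round-trips on random molecules and tag sets", {
  smis <- random_molecules(200, seed = 23L)
  set.seed(23)
  for (s in smis) {
    m <- canonicalize(s)
    k <- sample.int(min(3L, m$atom_count), 1L)
    tags <- sort(sample.int(m$atom_count, k))
    tm <- tagged_molecule(m, tags)
    ser <- serialize_tagged(tm)
    back <- parse_tagged(ser)
    expect_identical(back$molecule$smiles, m$smiles, info = ser)
    expect_identical(back$tagged_atoms, tags, info = ser)
    expect_identical(serialize_tagged(back), ser, info = ser)
    expect_identical(gsub("!", "", ser, fixed = TRUE), m$smiles, info = ser)
  }
})

test_that("map labels convert to tags through the canonical permutation", {
  tm <- maplabels_to_tags("[CH3:1][CH2:2][OH:3]", 3L)
  o_atom <- which(tm$molecule$graph$element == "O")
  expect_identical(tm$tagged_atoms, o_atom)
  expect_identical(tm$molecule$smiles, canonicalize("CCO")$smiles)

  # aromatic positions survive canonical reordering: compare against
  # brute-force atom identity through the permutation
  tm2 <- maplabels_to_tags("[cH:1]1[cH:2]cccc1C", c(1L, 2L))
  g <- tm2$molecule$graph
  expect_length(tm2$tagged_atoms, 2L)
  expect_true(all(g$aromatic[tm2$tagged_atoms]))
  expect_true(all(g$element[tm2$tagged_atoms] == "C"))
  # the two tagged aromatic carbons are adjacent, as in the input
  adjacent <- any((g$bond_from %in% tm2$tagged_atoms) &
                    (g$bond_to %in% tm2$tagged_atoms))
  expect_true(adjacent)
})

test_that("empty reacting-label sets and absent labels are errors", {
  expect_error(maplabels_to_tags("[CH3:1][OH:2]", integer()), "empty")
  expect_error(maplabels_to_tags("[CH3:1][OH:2]", 7L), "absent")
})

test_that("multi-fragment products cannot be tagged", {
  expect_error(tagged_molecule("CC.O", 1L), "multi-fragment")
})
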