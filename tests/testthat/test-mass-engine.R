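test_that("neutral mass sums residues plus one water", {
  expect_equal(neutral_mass(composition(Hex = 1)), 180.06338,
               tolerance = 1e-6)
  expect_equal(neutral_mass(composition(Hex = 5, Pent = 3, dHex = 1)),
               1370.45935, tolerance = 1e-6)
  expect_equal(neutral_mass(composition(Hex = 6, Pent = 1), "average"),
               1122.9735, tolerance = 1e-4)
  expect_error(neutral_mass(composition(Ac = 1)), "glycosyl")
})

test_that("sodiated m/z reproduces the recorded integer peaks", {
  trunc_mono <- mass_convention("monoisotopic", rounding = "truncate")
  nearest_avg <- mass_convention("average", rounding = "nearest")
  expect_equal(adduct_mz("XFG", trunc_mono), 1099)
  expect_equal(adduct_mz("XXFG", trunc_mono), 1393)
  expect_equal(adduct_mz("XLFG", trunc_mono), 1555)
  expect_equal(adduct_mz("LGGGG", nearest_avg), 1146)
  expect_equal(adduct_mz("PGGGG", nearest_avg), 1322)
  expect_equal(adduct_mz("LLGGG", nearest_avg), 1440)
  expect_equal(adduct_mz("LPGGG", nearest_avg), 1616)
  # acetylation adds the 42 step seen in the acidic series
  expect_equal(adduct_mz("LPGGG+1Ac", nearest_avg), 1658)
  # the unassigned 1445 peak is consistent with di-sodiated XXPG
  expect_equal(adduct_mz("XXPG", trunc_mono, adduct = "+2Na-H"), 1445)
})

test_that("structure-summed and composition-summed m/z agree", {
  set.seed(5)
  for (code in random_codes(30, 1, 7)) {
    s <- parse_structure(code)
    via_comp <- adduct_mz(composition_of(s))
    # recompute independently: residue masses times counts
    conv <- mass_convention("monoisotopic")
    cmp <- composition_of(s)
    direct <- sum(as.numeric(cmp) * conv$residues[names(cmp)]) +
      conv$water + adducts()[["+Na"]]
    expect_equal(via_comp, direct, tolerance = 1e-9)
  }
})

test_that("composition enumeration matches spec examples", {
  hit <- enumerate_compositions(1085.34, tol = 0.3)
  expect_true("4.3.0.0.0" %in% comp_keys(hit))  # XXXG-type

  only_hex <- enumerate_compositions(203.05, tol = 0.3)
  expect_equal(comp_keys(only_hex), "1.0.0.0.0")

  acidic <- enumerate_compositions(1423.42, tol = 0.3)
  expect_true("5.3.0.1.0" %in% comp_keys(acidic))  # XXPG-type

  expect_true(all(diff(abs(acidic$error)) >= 0))  # sorted by |error|

  out <- enumerate_compositions(150, tol = 0.3)
  expect_true(attr(out, "out_of_range"))
  expect_false(attr(acidic, "out_of_range"))
})

test_that("composition enumeration equals the brute-force oracle", {
  conv <- mass_convention("monoisotopic")
  bounds <- default_bounds()
  set.seed(101)
  mzs <- runif(40, 200, 4000)
  for (mz in mzs) {
    got <- comp_keys(enumerate_compositions(mz, conv, "+Na", tol = 0.5,
                                            bounds = bounds))
    want <- oracle_compositions(mz, conv$residues, conv$water,
                                adducts()[["+Na"]], 0.5, bounds)
    expect_identical(got, want)
  }
})

test_that("adding a residue strictly increases the neutral mass", {
  base <- composition(Hex = 2, Pent = 1)
  m0 <- neutral_mass(base)
  for (cls in residue_classes()) {
    up <- as.integer(base)
    names(up) <- residue_classes()
    up[cls] <- up[cls] + 1L
    expect_gt(neutral_mass(as_comp <- composition(
      Hex = up[["Hex"]], Pent = up[["Pent"]], dHex = up[["dHex"]],
      HexA = up[["HexA"]], Ac = up[["Ac"]])), m0)
  }
})

test_that("structure enumeration is exhaustive and composition-consistent", {
  acidic <- enumerate_structures(composition(Hex = 5, Pent = 3, HexA = 1),
                                 backbone = 4)
  expect_true(all(c("XXPG", "XPXG", "PXXG", "BPGG") %in% acidic$structure))
  expect_equal(sum(acidic$canonical), 1L)
  # every returned structure realizes the target composition
  for (st in acidic$structure)
    expect_equal(as.integer(composition_of(st)),
                 as.integer(composition(Hex = 5, Pent = 3, HexA = 1)))

  expect_equal(enumerate_structures(composition(Hex = 1),
                                    backbone = 1)$structure, "G")

  small <- enumerate_structures(composition(Hex = 4, Pent = 2),
                                backbone = 3:4)
  expect_true(all(c("XLG", "LXG", "XXGG") %in% small$structure))
  for (st in small$structure)
    expect_equal(as.integer(composition_of(st)),
                 as.integer(composition(Hex = 4, Pent = 2)))

  # unachievable composition: empty, not an error
  none <- enumerate_structures(composition(Hex = 1, dHex = 2), backbone = 2:6)
  expect_equal(nrow(none), 0)

  # acetyl carried through as a suffix
  ac <- enumerate_structures(composition(Hex = 4, Pent = 3, Ac = 1),
                             backbone = 4)
  expect_true("XXXG+1Ac" %in% ac$structure)
})
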