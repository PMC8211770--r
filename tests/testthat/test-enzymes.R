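test_that("endo-xyloglucanase rules cut at the specified bonds", {
  xeg <- endo_rule("xeg")
  res <- digest_endo("XXXGXXFG", xeg)
  expect_equal(vapply(res$products, format, ""), c("XXXG", "XXFG"))
  expect_equal(res$cuts, 1L)

  fixed <- digest_endo("XXFG", xeg)
  expect_equal(vapply(fixed$products, format, ""), "XXFG")
  expect_equal(fixed$cuts, 0L)

  xc <- digest_endo("XXXG", endo_rule("xcxgha"))
  expect_equal(vapply(xc$products, format, ""), c("X", "X", "XG"))
  expect_equal(xc$cuts, 2L)

  # minimum product length suppresses cuts that would create fragments
  long <- digest_endo("XXXGXXFG", xeg, min_product_length = 5)
  expect_equal(vapply(long$products, format, ""), "XXXGXXFG")
})

test_that("endo digestion conserves mass across two hundred random substrates", {
  set.seed(202)
  water <- mass_convention("monoisotopic")$water
  codes <- random_codes(200, 2, 9)
  for (rule in list(endo_rule("xeg"), endo_rule("xcxgha"))) {
    for (code in codes) {
      res <- digest_endo(code, rule)
      lhs <- sum(vapply(res$products, neutral_mass, 0))
      rhs <- neutral_mass(code) + res$cuts * water
      expect_equal(lhs, rhs, tolerance = 1e-6)
    }
  }
})

test_that("XEG products end in G or the substrate's own terminal code", {
  set.seed(303)
  for (code in random_codes(60, 2, 8)) {
    s <- parse_structure(code)
    res <- digest_endo(s, endo_rule("xeg"))
    ends <- vapply(res$products, function(p) p$codes[length(p$codes)], "")
    expect_true(all(ends == "G" | ends == s$codes[length(s$codes)]))
  }
})

test_that("exo-glycosidases trim the registry's terminal residues", {
  fuc <- exo_rule("fucosidase")
  gal <- exo_rule("galactosidase")
  expect_equal(format(exo_trim("XXFG", fuc)), "XXLG")
  expect_equal(format(exo_trim("XPG", gal)), "XYG")
  expect_equal(format(exo_trim("XXXG", fuc)), "XXXG")
  expect_equal(format(exo_trim("XLFG+1Ac", fuc)), "XLLG+1Ac")
  # F is galactosidase-resistant: the galactose is capped by fucose
  expect_equal(format(exo_trim("XXFG", gal)), "XXFG")
  # E loses its deoxy-hexose to fucosidase, like F
  expect_equal(format(exo_trim("XEG", fuc)), "XDG")
  # single-step trimming touches one sidechain only
  expect_equal(format(exo_trim("XLLG", gal, exhaustive = FALSE)), "XXLG")
  expect_equal(format(exo_trim("XLLG", gal)), "XXXG")

  # exhaustive trimming is idempotent
  set.seed(404)
  for (code in random_codes(40, 2, 6)) {
    once <- exo_trim(code, gal)
    expect_equal(format(exo_trim(once, gal)), format(once))
    oncef <- exo_trim(code, fuc)
    expect_equal(format(exo_trim(oncef, fuc)), format(oncef))
  }
})

test_that("Driselase releases isoprimeverose plus free monosaccharides", {
  r1 <- driselase_digest("XXXG")
  expect_equal(r1$isoprimeverose, 3L)
  expect_equal(r1$released[["Hex"]], 1)

  r2 <- driselase_digest("G")
  expect_equal(r2$isoprimeverose, 0L)
  expect_equal(r2$released[["Hex"]], 1)

  r3 <- driselase_digest("XLFG")
  expect_equal(r3$isoprimeverose, 3L)
  expect_equal(r3$released[["Hex"]], 3)  # two sidechain Gal + reducing Glc
  expect_equal(r3$released[["dHex"]], 1)

  # residue bookkeeping: isoprimeverose (Hex+Pent each) plus released
  # residues add up to the composition, exactly
  set.seed(505)
  for (code in random_codes(60, 1, 7)) {
    r <- driselase_digest(code)
    total <- r$released
    total[["Hex"]] <- total[["Hex"]] + r$isoprimeverose
    total[["Pent"]] <- total[["Pent"]] + r$isoprimeverose
    expect_equal(unname(total[residue_classes()]),
                 as.numeric(composition_of(code)))
  }
})

test_that("saponification zeroes the acetyl count only", {
  s <- saponify("LPGGG+2Ac")
  expect_equal(format(s), "LPGGG")
  expect_equal(as.integer(composition_of(s)),
               as.integer(composition(Hex = 7, Pent = 2, HexA = 1)))
})

test_that("predicted shift pairs reproduce the fucosidase and galactosidase tables", {
  nominal <- mass_convention("nominal")
  fuc <- predict_shift_pairs(c(1099, 1393, 1555), exo_rule("fucosidase"),
                             nominal)
  expect_equal(fuc$precursor, c(1099, 1393, 1555))
  expect_equal(fuc$product, c(953, 1247, 1409))
  expect_equal(unique(fuc$k), 1L)

  gal <- predict_shift_pairs(1129, exo_rule("galactosidase"), nominal)
  expect_equal(gal$product[gal$k == 1], 967)
  expect_equal(nrow(gal), 2)  # galactosidase reports up to two removals

  none <- predict_shift_pairs(numeric(0), exo_rule("fucosidase"))
  expect_equal(nrow(none), 0)
})
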