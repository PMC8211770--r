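test_that("noiseless simulation places peaks at exact theoretical m/z", {
  cfg <- noiseless_config(c(XXXG = 100, XXFG = 50))
  sp <- simulate_spectrum(cfg)
  expect_equal(sp$peaks$mz, c(1085.33815, 1393.44912), tolerance = 1e-5)
  expect_equal(sp$peaks$intensity, c(100, 50))
})

test_that("a contaminant-only configuration yields the hexose ladder", {
  cfg <- simulation_config(structures = setNames(numeric(0), character(0)),
                           mz_jitter_sd = 0, intensity_noise_cv = 0,
                           contaminant_hexose_range = c(3, 5),
                           decoy_peak_count = 0)
  sp <- simulate_spectrum(cfg)
  expect_equal(length(sp), 3L)
  truth <- attr(sp, "truth")
  ladder <- truth[truth$kind == "contaminant", ]
  expect_equal(nrow(ladder), 3L)
  expect_equal(ladder$code, c("Hex3", "Hex4", "Hex5"))
  expect_equal(ladder$mz_theoretical,
               3:5 * 162.05282 + 18.01056 + 22.98977, tolerance = 1e-5)
})

test_that("simulation is deterministic under its seed", {
  cfg <- simulation_config(seed = 99)
  s1 <- simulate_spectrum(cfg)
  s2 <- simulate_spectrum(cfg)
  expect_identical(s1$peaks, s2$peaks)
  e1 <- simulate_digestion_experiment(cfg, "galactosidase", 0.5)
  e2 <- simulate_digestion_experiment(cfg, "galactosidase", 0.5)
  expect_identical(e1$pre$peaks, e2$pre$peaks)
  expect_identical(e1$post$peaks, e2$post$peaks)
  # a different seed moves the jittered peaks
  s3 <- simulate_spectrum(simulation_config(seed = 100))
  expect_false(identical(s1$peaks, s3$peaks))
})

test_that("digestion experiments move abundance from precursor to product", {
  cfg <- noiseless_config(c(XXFG = 100))
  full <- simulate_digestion_experiment(cfg, "fucosidase", completeness = 1)
  expect_equal(round(full$pre$peaks$mz), 1393)
  expect_equal(round(full$post$peaks$mz), 1247)
  expect_equal(full$truth$precursor_code, "XXFG")
  expect_equal(full$truth$product_code, "XXLG")

  part <- simulate_digestion_experiment(noiseless_config(c(XLFG = 100)),
                                        "fucosidase", completeness = 0.5)
  expect_setequal(trunc(part$post$peaks$mz), c(1555, 1409))

  inert <- simulate_digestion_experiment(noiseless_config(c(XXXG = 100)),
                                         "fucosidase", completeness = 1)
  expect_equal(inert$pre$peaks$mz, inert$post$peaks$mz)
  expect_equal(nrow(inert$truth), 0L)

  expect_error(simulate_digestion_experiment(cfg, "amylase"),
               "unknown enzyme")
})

test_that("endo digestion experiments pool backbone products", {
  cfg <- noiseless_config(c(XXXGXXFG = 100))
  ex <- simulate_digestion_experiment(cfg, "xeg", completeness = 1)
  expect_setequal(ex$truth$product_code, c("XXXG", "XXFG"))
  expect_setequal(round(ex$post$peaks$mz), c(1085, 1393))
})

test_that("noiseless differential analysis recovers exactly the truth pairs", {
  cfg <- noiseless_config(fucosylated_panel, seed = 4)
  ex <- simulate_digestion_experiment(cfg, "fucosidase", completeness = 1)
  dd <- diff_spectra(ex$pre, ex$post, exo_rule("fucosidase"), tol = 0.3)
  got <- sort(paste(round(dd$precursor), round(dd$product)))
  want <- sort(paste(round(ex$truth$precursor_mz),
                     round(ex$truth$product_mz)))
  expect_equal(got, want)
})

test_that("noiseless annotation recovers every generating composition", {
  cfg <- simulation_config(mz_jitter_sd = 0, intensity_noise_cv = 0,
                           decoy_peak_count = 0, seed = 5)
  sp <- simulate_spectrum(cfg)
  ann <- annotate_peaks(sp, annotation_config())
  truth <- attr(sp, "truth")
  for (i in which(truth$kind == "structure")) {
    rows <- ann[abs(ann$peak_mz - truth$mz[i]) < 1e-6, ]
    want <- as.integer(composition_of(truth$code[i]))
    hit <- apply(rows[, c("Hex", "Pent", "dHex", "HexA", "Ac")], 1,
                 function(v) identical(as.integer(v), want))
    expect_true(any(hit))
  }
  # ladder peaks flagged
  for (i in which(truth$kind == "contaminant")) {
    top <- ann[abs(ann$peak_mz - truth$mz[i]) < 1e-6 & ann$rank == 1, ]
    expect_true(top$contaminant)
  }
})
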