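test_that("peak lists read from CSV and TSV, with and without header", {
  f1 <- tempfile(fileext = ".csv")
  writeLines(c("1099,50", "1393,120"), f1)
  sp1 <- read_peaklist(f1)
  expect_equal(length(sp1), 2L)
  expect_equal(sp1$peaks$mz, c(1099, 1393))
  expect_equal(sp1$peaks$intensity, c(50, 120))

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("mz\tintensity", "953.3\t10", "1099.4\t20", "1393.4\t30"), f2)
  sp2 <- read_peaklist(f2, sample = "demo", treatment = "xeg")
  expect_equal(length(sp2), 3L)
  expect_equal(sp2$sample, "demo")
  expect_equal(sp2$treatment, "xeg")

  f3 <- tempfile()
  writeLines("abc,1", f3)
  expect_error(read_peaklist(f3), "line 1")

  f4 <- tempfile()
  writeLines(character(0), f4)
  expect_error(read_peaklist(f4), "empty")

  # round-trip through write_peaklist
  out <- tempfile(fileext = ".csv")
  write_peaklist(sp2, out)
  expect_equal(read_peaklist(out)$peaks, sp2$peaks)

  # the shipped synthetic example parses
  ex <- read_peaklist(system.file("extdata",
                                  "mesotaenium_like_synthetic.csv",
                                  package = "olimpr"))
  expect_equal(length(ex), 11L)
})

test_that("spectra sort and merge duplicate centroids", {
  sp <- spectrum(c(1393, 1099, 1393), c(10, 5, 20))
  expect_equal(sp$peaks$mz, c(1099, 1393))
  expect_equal(sp$peaks$intensity, c(5, 30))
  expect_error(spectrum(c(-1, 2)), "mz > 0")
})

test_that("series detection recovers the acidic sparsely branched ladder", {
  sp <- spectrum(c(1146, 1322, 1440, 1616))
  sg <- find_series(sp, series_steps("nominal"), tol = 0.5)
  key <- paste(sg$edges$mz_i, sg$edges$mz_j, sg$edges$step)
  expect_setequal(key, c("1146 1322 HexA", "1440 1616 HexA",
                         "1146 1440 Xunit", "1322 1616 Xunit"))
  expect_equal(nrow(sg$edges), 4L)
  expect_equal(length(unique(na.omit(sg$membership))), 1L)

  ac <- find_series(spectrum(c(1616, 1658)), series_steps("nominal"),
                    tol = 0.5)
  expect_equal(ac$edges$step, "Ac")

  single <- find_series(spectrum(1146), series_steps("nominal"))
  expect_equal(nrow(single$edges), 0L)
  expect_true(is.na(single$membership))
})

test_that("a planted ladder is recovered exactly, with no spurious edges", {
  steps <- series_steps()[c("HexA", "dHex")]
  set.seed(606)
  for (rep in 1:10) {
    base <- runif(1, 800, 1200)
    labels <- sample(names(steps), 4, replace = TRUE)
    mz <- base + cumsum(c(0, steps[labels]))
    sg <- find_series(spectrum(mz), steps, tol = 0.05)
    # exactly the planted consecutive edges
    expect_equal(nrow(sg$edges), 4L)
    expect_equal(sg$edges$i, 1:4)
    expect_equal(sg$edges$j, 2:5)
    expect_equal(sg$edges$step, labels)
    expect_true(all(abs(sg$edges$error) <= 0.05))
  }
})

test_that("differential spectra pair lost peaks with shifted products", {
  pre <- spectrum(c(953.296, 1099.354, 1247.391, 1393.449, 1409.444,
                    1555.502), 100)
  post <- spectrum(c(953.296, 1247.391, 1409.444), c(200, 200, 130))
  dd <- diff_spectra(pre, post, exo_rule("fucosidase"), tol = 0.3)
  expect_equal(trunc(dd$precursor), c(1099, 1393, 1555))
  expect_equal(trunc(dd$product), c(953, 1247, 1409))
  expect_equal(unique(dd$status), "disappeared")
  # every reported pair's delta matches k residue masses within tolerance
  expect_true(all(abs(dd$delta - dd$k * 146.05791) <= 0.3))

  # partial degradation: shrunk but not gone
  post2 <- spectrum(c(953.296, 1247.391, 1409.444, 1555.502),
                    c(200, 200, 130, 40))
  dd2 <- diff_spectra(pre, post2, exo_rule("fucosidase"), tol = 0.3)
  expect_equal(dd2$status[trunc(dd2$precursor) == 1555], "partial")

  # galactosidase acidic pairs of the tandem-MS series
  pre3 <- spectrum(c(1129.328, 1423.423), 100)
  post3 <- spectrum(c(967.275, 1261.371), 100)
  dd3 <- diff_spectra(pre3, post3, exo_rule("galactosidase"), tol = 0.3)
  expect_equal(trunc(dd3$precursor[dd3$k == 1]), c(1129, 1423))
  expect_equal(trunc(dd3$product[dd3$k == 1]), c(967, 1261))

  # identical spectra produce no pairing
  expect_equal(nrow(diff_spectra(pre, pre, exo_rule("fucosidase"))), 0L)

  # unpaired loss reported with NA product
  post4 <- spectrum(c(953.296, 1247.391, 1409.444, 500.0), c(200, 200, 130, 10))
  pre4 <- spectrum(c(pre$peaks$mz, 700.0), c(pre$peaks$intensity, 50))
  dd4 <- diff_spectra(pre4, post4, exo_rule("fucosidase"), tol = 0.3)
  expect_true(any(is.na(dd4$product) & round(dd4$precursor) == 700))
})
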