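#' Default XGO structure panel
#'
#' Twenty xyloglucan oligosaccharides spanning the assignments reported for
#' charophycean green algae: the XXXG/XXG-core neutral oligos, the
#' galactosylated and fucosylated Mesotaenium-type series, the uronic-acid
#' (P sidechain) series, and the sparsely branched
#' LGGGG/PGGGG/LLGGG/LPGGG family. Branching isomers that share a
#' composition (e.g. XXPG/XPXG) are deliberately included: they are
#' mass-degenerate and collapse onto one peak.
#'
#' @return Character vector of 20 structure codes.
#' @export
default_structure_panel <- function() {
  c("XXG", "XXXG", "XXXXG",
    "XLG", "GXLG", "LLG", "XXLG", "XLXG", "XLLG",
    "XFG", "XXFG", "XLFG",
    "XPG", "PXG", "XXPG", "XPXG",
    "LGGGG", "PGGGG", "LLGGG", "LPGGG")
}

#' Configuration of a synthetic MALDI XGO spectrum
#'
#' Describes a mixture emulating the spectra this pipeline is built for:
#' sodiated XGO peaks from a known structure set, a contaminating hexose
#' oligomer ladder (as seen in untreated cell-wall extracts), uniform-random
#' decoy peaks, Gaussian m/z jitter (in Da — reflectron MALDI error is
#' approximately mass-independent at this scale) and lognormal intensity
#' noise. All randomness is fixed by `seed`.
#'
#' @param structures Named numeric vector: relative abundance per structure
#'   code (default: the 20-structure panel at abundance 100).
#' @param adducts Named numeric vector of adduct fractions (sum <= 1).
#' @param convention Mass-convention name for the theoretical m/z.
#' @param mz_jitter_sd Gaussian m/z jitter, Da (default 0.1).
#' @param intensity_noise_cv Lognormal intensity coefficient of variation.
#' @param contaminant_hexose_range Integer range of hexose-oligomer lengths
#'   for the contaminant ladder (`c(0, 0)` disables it).
#' @param contaminant_abundance Relative abundance of each ladder peak.
#' @param decoy_peak_count Number of uniform-random decoy peaks in the
#'   acquisition range.
#' @param decoy_abundance Relative abundance of decoy peaks.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(structures = NULL,
                              adducts = c("+Na" = 1),
                              convention = "monoisotopic",
                              mz_jitter_sd = 0.1,
                              intensity_noise_cv = 0.3,
                              contaminant_hexose_range = c(3L, 7L),
                              contaminant_abundance = 30,
                              decoy_peak_count = 10L,
                              decoy_abundance = 15,
                              seed = 1L) {
  if (is.null(structures))
    structures <- stats::setNames(rep(100, 20), default_structure_panel())
  stopifnot(all(structures > 0), all(adducts > 0), sum(adducts) <= 1 + 1e-9,
            length(structures) == 0 || !is.null(names(structures)),
            !is.null(names(adducts)))
  structure(list(structures = structures, adducts = adducts,
                 convention = convention, mz_jitter_sd = mz_jitter_sd,
                 intensity_noise_cv = intensity_noise_cv,
                 contaminant_hexose_range = as.integer(contaminant_hexose_range),
                 contaminant_abundance = contaminant_abundance,
                 decoy_peak_count = as.integer(decoy_peak_count),
                 decoy_abundance = decoy_abundance,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a MALDI XGO spectrum
#'
#' One peak per (structure, adduct) at the theoretical m/z plus Gaussian
#' jitter, with abundance-proportional lognormally noised intensities, plus
#' the contaminant hexose ladder and decoy peaks described by the
#' configuration. Deterministic under the configuration seed.
#'
#' @param cfg A [simulation_config()].
#' @param sample Sample label for the resulting spectrum.
#' @param treatment Treatment metadata for the resulting spectrum.
#' @return An `xgo_spectrum`; attribute `truth` is a data frame recording
#'   every generated peak (`kind` in `structure`/`contaminant`/`decoy`,
#'   `code`, `mz_theoretical`, `mz`, `adduct`).
#' @export
#' @examples
#' cfg <- simulation_config(c(XXXG = 100, XXFG = 50), mz_jitter_sd = 0,
#'                          contaminant_hexose_range = c(0, 0),
#'                          decoy_peak_count = 0)
#' simulate_spectrum(cfg)
simulate_spectrum <- function(cfg, sample = "synthetic",
                              treatment = character()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, simulate_spectrum_impl(cfg, sample, treatment))
}

simulate_spectrum_impl <- function(cfg, sample, treatment) {
  conv <- mass_convention(cfg$convention)
  rows <- list()
  for (code in names(cfg$structures)) {
    comp <- composition_of(code)
    for (ad in names(cfg$adducts)) {
      theo <- adduct_mz(comp, conv, ad)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "structure", code = code, mz_theoretical = theo, adduct = ad,
        abundance = cfg$structures[[code]] * cfg$adducts[[ad]],
        stringsAsFactors = FALSE)
    }
  }
  rng <- cfg$contaminant_hexose_range
  if (rng[2] >= rng[1] && rng[2] > 0) {
    for (nh in rng[1]:rng[2]) {
      ad <- names(cfg$adducts)[1]
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "contaminant", code = paste0("Hex", nh),
        mz_theoretical = adduct_mz(composition(Hex = nh), conv, ad),
        adduct = ad, abundance = cfg$contaminant_abundance,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), code = character(0),
               mz_theoretical = numeric(0), adduct = character(0),
               abundance = numeric(0), stringsAsFactors = FALSE)
  m <- nrow(truth)
  truth$mz <- truth$mz_theoretical +
    if (cfg$mz_jitter_sd > 0) stats::rnorm(m, 0, cfg$mz_jitter_sd) else 0
  truth$intensity <- truth$abundance * lognormal_noise(m,
                                                       cfg$intensity_noise_cv)
  if (cfg$decoy_peak_count > 0) {
    rngacq <- acquisition_range()
    dec <- data.frame(
      kind = "decoy", code = NA_character_,
      mz_theoretical = NA_real_, adduct = NA_character_,
      abundance = cfg$decoy_abundance,
      mz = stats::runif(cfg$decoy_peak_count, rngacq[1], rngacq[2]),
      intensity = cfg$decoy_abundance *
        lognormal_noise(cfg$decoy_peak_count, cfg$intensity_noise_cv),
      stringsAsFactors = FALSE)
    truth <- rbind(truth, dec)
  }
  spec <- spectrum(truth$mz, truth$intensity, sample = sample,
                   treatment = treatment)
  attr(spec, "truth") <- truth[order(truth$mz), ]
  spec
}

#' Simulate a pre/post enzymatic digestion experiment
#'
#' Builds the paired spectra of a digestion series: the `pre` spectrum from
#' the configured structure pool, and the `post` spectrum after applying
#' each named enzyme in order, moving `completeness` of every susceptible
#' structure's abundance onto its digestion product (a completeness below 1
#' leaves the precursor partially present, the behavior of partially
#' degraded peaks). Exo-glycosidases trim sidechains exhaustively; endo
#' enzymes split the backbone and pool the products.
#'
#' @param cfg A [simulation_config()].
#' @param enzymes Character vector from
#'   `c("fucosidase", "galactosidase", "xeg", "xcxgha")`, applied in order.
#' @param completeness Fraction of susceptible abundance converted per
#'   enzyme (scalar or one value per enzyme).
#' @return List with `pre` and `post` spectra and `truth`, a data frame of
#'   the implied (precursor, product) pairs: `enzyme`, `precursor_code`,
#'   `product_code`, `precursor_mz`, `product_mz`, `residue`, `k`.
#' @export
#' @examples
#' cfg <- simulation_config(c(XXFG = 100), mz_jitter_sd = 0,
#'                          contaminant_hexose_range = c(0, 0),
#'                          decoy_peak_count = 0)
#' simulate_digestion_experiment(cfg, "fucosidase")
simulate_digestion_experiment <- function(cfg, enzymes, completeness = 1) {
  stopifnot(inherits(cfg, "simulation_config"))
  known <- c("fucosidase", "galactosidase", "xeg", "xcxgha")
  bad <- setdiff(enzymes, known)
  if (length(bad)) stop("unknown enzyme: ", paste(bad, collapse = ", "))
  completeness <- rep_len(completeness, length(enzymes))
  stopifnot(all(completeness >= 0), all(completeness <= 1))

  conv <- mass_convention(cfg$convention)
  ad <- names(cfg$adducts)[1]
  pool <- cfg$structures
  truth <- list()
  for (e in seq_along(enzymes)) {
    enz <- enzymes[e]
    newpool <- stats::setNames(numeric(0), character(0))
    add <- function(code, ab) {
      newpool[code] <<- (if (code %in% names(newpool)) newpool[[code]]
                         else 0) + ab
    }
    for (code in names(pool)) {
      ab <- pool[[code]]
      if (enz %in% c("fucosidase", "galactosidase")) {
        rule <- exo_rule(enz)
        prod <- format(exo_trim(code, rule))
        if (prod == code) { add(code, ab); next }
        k <- composition_of(code)[[rule$removes]] -
          composition_of(prod)[[rule$removes]]
        add(prod, ab * completeness[e])
        if (completeness[e] < 1) add(code, ab * (1 - completeness[e]))
        truth[[length(truth) + 1L]] <- data.frame(
          enzyme = enz, precursor_code = code, product_code = prod,
          precursor_mz = adduct_mz(code, conv, ad),
          product_mz = adduct_mz(prod, conv, ad),
          residue = rule$removes, k = k, stringsAsFactors = FALSE)
      } else {
        res <- digest_endo(code, endo_rule(enz))
        prods <- vapply(res$products, format, "")
        if (length(prods) == 1) { add(code, ab); next }
        for (pr in prods) add(pr, ab * completeness[e])
        if (completeness[e] < 1) add(code, ab * (1 - completeness[e]))
        for (pr in prods)
          truth[[length(truth) + 1L]] <- data.frame(
            enzyme = enz, precursor_code = code, product_code = pr,
            precursor_mz = adduct_mz(code, conv, ad),
            product_mz = adduct_mz(pr, conv, ad),
            residue = NA_character_, k = NA_integer_,
            stringsAsFactors = FALSE)
      }
    }
    pool <- newpool
  }
  pre <- simulate_spectrum(cfg, sample = "pre")
  post_cfg <- cfg
  post_cfg$structures <- pool
  post_cfg$seed <- cfg$seed + 1000000L  # independent noise, still seeded
  post <- simulate_spectrum(post_cfg, sample = "post", treatment = enzymes)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(enzyme = character(0), precursor_code = character(0),
               product_code = character(0), precursor_mz = numeric(0),
               product_mz = numeric(0), residue = character(0),
               k = integer(0), stringsAsFactors = FALSE)
  list(pre = pre, post = post, truth = truth)
}
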