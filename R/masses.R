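#' Residue classes of the xyloglucan mass model
#'
#' Five residue-mass classes carry all mass information in the model: hexose
#' (`Hex`), pentose (`Pent`), deoxy-hexose (`dHex`), hexuronic acid (`HexA`)
#' and the O-acetyl substituent (`Ac`). `Ac` is an ester substituent, not a
#' glycosyl residue; compositions must contain at least one glycosyl residue.
#'
#' @return Character vector of the five class labels, glycosyl classes first.
#' @export
#' @examples
#' residue_classes()
residue_classes <- function() c("Hex", "Pent", "dHex", "HexA", "Ac")

.GLYCOSYL <- c("Hex", "Pent", "dHex", "HexA")

# Residue (anhydro) masses in Da. Monoisotopic and average values from
# standard atomic masses; nominal values are the integer mass differences a
# MALDI operator reads between ladder peaks (162/132/146/176/42).
.MASS_TABLES <- list(
  monoisotopic = list(
    residues = c(Hex = 162.05282, Pent = 132.04226, dHex = 146.05791,
                 HexA = 176.03209, Ac = 42.01057),
    water = 18.01056),
  average = list(
    residues = c(Hex = 162.1406, Pent = 132.1146, dHex = 146.1412,
                 HexA = 176.1241, Ac = 42.0373),
    water = 18.0153),
  nominal = list(
    residues = c(Hex = 162, Pent = 132, dHex = 146, HexA = 176, Ac = 42),
    water = 18)
)

# Cation deltas relative to the neutral molecule (electron mass neglected,
# ~0.5 mDa, far below MALDI-ToF reflectron accuracy at m/z 200-4000).
.ADDUCTS <- c("+Na" = 22.98977, "+K" = 38.96371, "+H" = 1.00783,
              "+2Na-H" = 44.97171)

#' Supported cation adducts
#'
#' MALDI of neutral glycans in positive mode is dominated by the sodium
#' adduct; potassium, proton and the sodiated-salt form of acidic glycans
#' (`"+2Na-H"`, one sodium replacing the carboxylic proton plus the charging
#' sodium) are also supported. All species are singly charged.
#'
#' @return Named numeric vector of mass deltas (Da) added to the neutral mass.
#' @export
adducts <- function() .ADDUCTS

#' Define a mass convention
#'
#' A mass convention bundles the residue-class masses, the mass of water
#' (added once per free oligosaccharide) and the rounding applied to reported
#' m/z. MALDI-ToF xyloglucan work reports integer m/z; depending on the
#' calibration, integer values correspond either to the monoisotopic mass
#' truncated to an integer or to the average mass rounded to the nearest
#' integer, so both are first class here and results carry the convention
#' used.
#'
#' @param name One of `"monoisotopic"`, `"average"`, `"nominal"`.
#' @param rounding Rounding applied by [adduct_mz()]: `"none"` (default),
#'   `"nearest"` or `"truncate"`.
#' @param residues Optional named numeric vector overriding the residue
#'   masses (names from [residue_classes()]).
#' @param water Optional override for the mass of water.
#' @return An object of class `mass_convention`.
#' @export
#' @examples
#' mass_convention("monoisotopic", rounding = "truncate")
mass_convention <- function(name = c("monoisotopic", "average", "nominal"),
                            rounding = c("none", "nearest", "truncate"),
                            residues = NULL, water = NULL) {
  name <- match.arg(name)
  rounding <- match.arg(rounding)
  tab <- .MASS_TABLES[[name]]
  if (!is.null(residues)) {
    stopifnot(all(names(residues) %in% residue_classes()))
    tab$residues[names(residues)] <- residues
  }
  if (!is.null(water)) tab$water <- water
  structure(list(name = name, residues = tab$residues, water = tab$water,
                 rounding = rounding),
            class = "mass_convention")
}

as_mass_convention <- function(x) {
  if (inherits(x, "mass_convention")) x else mass_convention(x)
}

#' @export
print.mass_convention <- function(x, ...) {
  cat("<mass_convention>", x$name, "| rounding:", x$rounding, "\n")
  print(round(x$residues, 5))
  cat("water:", x$water, "\n")
  invisible(x)
}

apply_rounding <- function(mz, rounding) {
  switch(rounding,
         none = mz,
         nearest = round(mz),
         truncate = trunc(mz))
}

#' Build a residue-class composition
#'
#' A composition is a named count vector over the five residue classes; the
#' `Hex` count includes the backbone glucoses. It is the mass-bearing
#' abstraction: two branching isomers such as XXPG and XPXG share one
#' composition and hence one mass.
#'
#' @param Hex,Pent,dHex,HexA,Ac Non-negative integer counts.
#' @return Named integer vector of length five, class `xgo_composition`.
#' @export
#' @examples
#' composition(Hex = 5, Pent = 3, dHex = 1)  # XXFG
composition <- function(Hex = 0, Pent = 0, dHex = 0, HexA = 0, Ac = 0) {
  x <- c(Hex = Hex, Pent = Pent, dHex = dHex, HexA = HexA, Ac = Ac)
  if (any(x < 0) || any(x != trunc(x)))
    stop("composition counts must be non-negative integers")
  structure(as.integer(x), names = residue_classes(),
            class = "xgo_composition")
}

as_composition <- function(x) {
  if (inherits(x, "xgo_composition")) return(x)
  if (inherits(x, "xgo_structure")) return(composition_of(x))
  if (is.numeric(x) && !is.null(names(x))) {
    stopifnot(all(names(x) %in% residue_classes()))
    full <- stats::setNames(integer(5), residue_classes())
    full[names(x)] <- as.integer(x)
    return(structure(full, class = "xgo_composition"))
  }
  stop("cannot interpret object as a composition")
}

#' @export
format.xgo_composition <- function(x, ...) {
  nz <- x[x > 0]
  if (!length(nz)) return("(empty)")
  paste(paste0(names(nz), unname(nz)), collapse = " ")
}

#' @export
print.xgo_composition <- function(x, ...) {
  cat("<composition>", format(x), "\n")
  invisible(x)
}

#' Neutral monosaccharide-polymer mass
#'
#' The neutral mass of a free oligosaccharide is the sum of its residue
#' (anhydro) masses plus one water for the reducing-end hydroxyl pair.
#'
#' @param x A composition, a structure, or a structure code string.
#' @param convention A [mass_convention()] or its name.
#' @return Neutral mass in Da (never rounded; rounding applies to m/z only).
#' @export
#' @examples
#' neutral_mass(composition(Hex = 1))                 # glucose, 180.063
#' neutral_mass("XXFG", "monoisotopic")               # 1370.459
neutral_mass <- function(x, convention = mass_convention("monoisotopic")) {
  conv <- as_mass_convention(convention)
  comp <- as_composition(if (is.character(x)) parse_structure(x) else x)
  if (sum(comp[.GLYCOSYL]) < 1)
    stop("composition must contain at least one glycosyl residue")
  sum(comp * conv$residues[names(comp)]) + conv$water
}

#' Singly charged adduct m/z
#'
#' Adds the cation delta to the neutral mass and applies the convention's
#' rounding. MALDI of underivatized glycans yields singly charged ions, so
#' m/z equals the adduct mass.
#'
#' @inheritParams neutral_mass
#' @param adduct Adduct label (see [adducts()]), default the sodium adduct.
#' @return m/z value (rounded per the convention).
#' @export
#' @examples
#' adduct_mz("XXFG", mass_convention("monoisotopic", rounding = "truncate"))
#' # 1393, the recorded sodiated XXFG peak
adduct_mz <- function(x, convention = mass_convention("monoisotopic"),
                      adduct = "+Na") {
  conv <- as_mass_convention(convention)
  delta <- .ADDUCTS[[match.arg(adduct, names(.ADDUCTS))]]
  apply_rounding(neutral_mass(x, conv) + delta, conv$rounding)
}
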