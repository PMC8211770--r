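#' Endo-xyloglucanase cleavage rules
#'
#' Backbone hydrolysis is modeled positionally. The classical XEG-type
#' endo-xyloglucanase cleaves between a substituted and a non-substituted
#' glucosyl unit: the bond after an unsubstituted glucose (`G`) is
#' hydrolyzed, yielding XXXG-type oligosaccharides. The XcXGHA-type enzyme
#' has the complementary specificity, cleaving between two substituted
#' units.
#'
#' @param name `"xeg"` or `"xcxgha"`.
#' @return An `endo_rule` object: `name` plus a predicate
#'   `cleave_after(code_i, code_next)`.
#' @export
endo_rule <- function(name = c("xeg", "xcxgha")) {
  name <- match.arg(name)
  pred <- switch(name,
    xeg = function(a, b) a == "G",
    xcxgha = function(a, b) a != "G" & b != "G")
  structure(list(name = name, cleave_after = pred), class = "endo_rule")
}

#' Exo-glycosidase trimming rules
#'
#' An exo-glycosidase removes the terminal residue of the sidechains whose
#' exposed terminus matches its specificity: alpha-L-fucosidase removes the
#' terminal deoxy-hexose (F becomes L, E becomes D); beta-galactosidase
#' removes the terminal hexose (L becomes X, P becomes Y). F is
#' galactosidase-resistant because its galactose is capped by the fucose.
#' The rule is derived from the registry's terminal/trim columns, so
#' configured custom sidechains participate automatically.
#'
#' @param name `"fucosidase"` or `"galactosidase"`.
#' @param registry Sidechain registry.
#' @return An `exo_rule`: `name`, `removes` (residue class), `applicable`
#'   (named map code -> trimmed code), `max_multiplicity` (largest number of
#'   sequential removals considered per oligosaccharide when predicting
#'   shifts; one per fucose, up to two galactoses as in XLLG).
#' @export
exo_rule <- function(name = c("fucosidase", "galactosidase"),
                     registry = sidechain_registry()) {
  name <- match.arg(name)
  removes <- switch(name, fucosidase = "dHex", galactosidase = "Hex")
  sel <- !is.na(registry$terminal) & registry$terminal == removes
  applicable <- stats::setNames(registry$trim[sel], registry$code[sel])
  mult <- switch(name, fucosidase = 1L, galactosidase = 2L)
  structure(list(name = name, removes = removes, applicable = applicable,
                 max_multiplicity = mult),
            class = "exo_rule")
}

#' In-silico endo-digestion of a structure
#'
#' Splits the backbone at every bond satisfying the rule's predicate
#' (never after the final unit), preserving product order. Hydrolysis adds
#' one water per cut, so the product masses sum to the substrate mass plus
#' `cuts` waters. Acetyl groups, whose position is not modeled, are assigned
#' to the reducing-end product.
#'
#' @param s Structure or code string.
#' @param rule An [endo_rule()].
#' @param min_product_length Smallest backbone length a cut may create;
#'   cuts that would violate it are skipped left to right. Default 1 (all
#'   cuts made).
#' @param registry Sidechain registry.
#' @return A `digest_result`: list with `products` (list of structures) and
#'   `cuts` (number of hydrolyzed bonds).
#' @export
#' @examples
#' digest_endo("XXXGXXFG", endo_rule("xeg"))   # XXXG + XXFG
#' digest_endo("XXXG", endo_rule("xcxgha"))    # X + X + XG
digest_endo <- function(s, rule, min_product_length = 1L,
                        registry = sidechain_registry()) {
  s <- as_structure(s, registry)
  n <- length(s$codes)
  products <- list()
  cuts <- 0L
  start <- 1L
  for (i in seq_len(max(0L, n - 1L))) {
    if (!rule$cleave_after(s$codes[i], s$codes[i + 1L])) next
    if (i - start + 1L < min_product_length) next
    if (n - i < min_product_length) next
    products[[length(products) + 1L]] <- new_structure(s$codes[start:i], 0L)
    cuts <- cuts + 1L
    start <- i + 1L
  }
  products[[length(products) + 1L]] <- new_structure(s$codes[start:n],
                                                     s$acetyl)
  structure(list(products = products, cuts = cuts), class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat("<digest>", x$cuts, "cut(s):",
      paste(vapply(x$products, format, ""), collapse = " + "), "\n")
  invisible(x)
}

#' In-silico exo-glycosidase trimming
#'
#' @param s Structure or code string.
#' @param rule An [exo_rule()].
#' @param exhaustive Replace every applicable sidechain (default); when
#'   `FALSE`, only the first (leftmost) applicable sidechain is trimmed,
#'   giving a single-step intermediate.
#' @param registry Sidechain registry.
#' @return The trimmed structure (unchanged if no sidechain is applicable;
#'   the acetyl count is untouched).
#' @export
#' @examples
#' format(exo_trim("XXFG", exo_rule("fucosidase")))     # "XXLG"
#' format(exo_trim("XPG", exo_rule("galactosidase")))   # "XYG"
exo_trim <- function(s, rule, exhaustive = TRUE,
                     registry = sidechain_registry()) {
  s <- as_structure(s, registry)
  hit <- which(s$codes %in% names(rule$applicable))
  if (!length(hit)) return(s)
  if (!exhaustive) hit <- hit[1]
  s$codes[hit] <- unname(rule$applicable[s$codes[hit]])
  s
}

#' In-silico Driselase digestion
#'
#' Driselase hydrolyzes the wall polysaccharide down to monosaccharides but
#' cannot cleave the alpha-1,6 xylose off its backbone glucose, so every
#' substituted unit yields one isoprimeverose (Xyl-alpha-1,6-Glc) — the
#' diagnostic disaccharide of xyloglucan — while all other sidechain
#' residues and every bare glucose are released free.
#'
#' @param s Structure or code string.
#' @param registry Sidechain registry.
#' @return A `driselase_result`: `isoprimeverose` (count) and `released`
#'   (named counts of free residues by class, acetyl included).
#' @export
#' @examples
#' driselase_digest("XXXG")  # 3 isoprimeverose + 1 Hex
driselase_digest <- function(s, registry = sidechain_registry()) {
  s <- as_structure(s, registry)
  sub <- s$codes != "G"
  ip <- sum(sub)
  released <- stats::setNames(numeric(5), residue_classes())
  if (any(sub)) {
    side <- colSums(registry[s$codes[sub], .GLYCOSYL, drop = FALSE])
    side["Pent"] <- side["Pent"] - ip  # one xylose per unit stays in the IP
    released[.GLYCOSYL] <- side
  }
  released["Hex"] <- released["Hex"] + sum(!sub)
  released["Ac"] <- s$acetyl
  structure(list(isoprimeverose = ip, released = released),
            class = "driselase_result")
}

#' @export
print.driselase_result <- function(x, ...) {
  rel <- x$released[x$released > 0]
  cat("<driselase>", x$isoprimeverose, "isoprimeverose;",
      if (length(rel)) paste(paste0(names(rel), unname(rel)), collapse = " ")
      else "nothing else", "released\n")
  invisible(x)
}

#' Remove O-acetyl groups (saponification)
#'
#' Alkaline de-esterification frees all acetyls before MALDI analysis; in
#' the model it simply zeroes the acetyl count.
#'
#' @param s Structure or code string.
#' @return The de-acetylated structure.
#' @export
saponify <- function(s) {
  s <- as_structure(s)
  s$acetyl <- 0L
  s
}

#' Predict exo-glycosidase mass-shift pairs for observed peaks
#'
#' For each precursor peak, the products expected after removal of 1..k
#' residues of the rule's class (k = the rule's maximum multiplicity). These
#' are the diagonal "degradable mass" lines drawn between pre- and
#' post-enzyme spectra: e.g. fucosidase predicts 1099 -> 953, 1393 -> 1247
#' and 1555 -> 1409 (one deoxy-hexose, 146 nominal).
#'
#' @param peaks Numeric vector of precursor m/z values.
#' @param rule An [exo_rule()].
#' @param convention Mass convention supplying the residue mass (its
#'   rounding is applied to the products).
#' @return Data frame with columns `precursor`, `product`, `k` (residues
#'   removed) and `residue`.
#' @export
#' @examples
#' predict_shift_pairs(c(1099, 1393, 1555), exo_rule("fucosidase"),
#'                     mass_convention("nominal"))
predict_shift_pairs <- function(peaks, rule,
                                convention = mass_convention("monoisotopic")) {
  conv <- as_mass_convention(convention)
  if (!length(peaks))
    return(data.frame(precursor = numeric(0), product = numeric(0),
                      k = integer(0), residue = character(0)))
  res_mass <- conv$residues[[rule$removes]]
  ks <- seq_len(rule$max_multiplicity)
  out <- expand.grid(precursor = peaks, k = ks, KEEP.OUT.ATTRS = FALSE)
  out$product <- apply_rounding(out$precursor - out$k * res_mass,
                                conv$rounding)
  out$residue <- rule$removes
  out[order(out$precursor, out$k), c("precursor", "product", "k", "residue")]
}
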