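#' Parse a xyloglucan oligosaccharide structure code
#'
#' A structure string gives one sidechain letter per backbone glucosyl unit,
#' reducing end last (so `"XXXG"` has its unsubstituted glucose at the
#' reducing end). O-acetylation is mass-resolvable but not position-
#' resolvable by MALDI, so acetyls are carried as a count, written as a
#' `"+nAc"` suffix, e.g. `"LPGGG+1Ac"`.
#'
#' @param code_string Structure code, e.g. `"XXFG"` or `"LPGGG+1Ac"`.
#' @param registry Sidechain registry (default the active one).
#' @return An object of class `xgo_structure` with fields `codes` (character
#'   vector, one letter per backbone unit) and `acetyl` (integer count).
#' @export
#' @examples
#' parse_structure("XXFG")
#' parse_structure("LPGGG+1Ac")
parse_structure <- function(code_string, registry = sidechain_registry()) {
  if (!is.character(code_string) || length(code_string) != 1 ||
      is.na(code_string) || !nzchar(code_string))
    stop("structure code must be a single non-empty string")
  acetyl <- 0L
  m <- regmatches(code_string,
                  regexec("^([A-Z]+)(\\+([0-9]+)Ac)?$", code_string))[[1]]
  if (!length(m))
    stop("malformed structure code: ", code_string)
  body <- m[2]
  if (nzchar(m[4])) acetyl <- as.integer(m[4])
  codes <- strsplit(body, "")[[1]]
  bad <- which(!codes %in% registry$code)
  if (length(bad))
    stop("unknown sidechain code '", codes[bad[1]], "' at position ", bad[1],
         " in '", code_string, "'")
  new_structure(codes, acetyl)
}

new_structure <- function(codes, acetyl = 0L) {
  structure(list(codes = codes, acetyl = as.integer(acetyl)),
            class = "xgo_structure")
}

as_structure <- function(x, registry = sidechain_registry()) {
  if (inherits(x, "xgo_structure")) x else parse_structure(x, registry)
}

#' @export
format.xgo_structure <- function(x, ...) {
  s <- paste(x$codes, collapse = "")
  if (x$acetyl > 0) s <- paste0(s, "+", x$acetyl, "Ac")
  s
}

#' @export
as.character.xgo_structure <- function(x, ...) format(x)

#' @export
print.xgo_structure <- function(x, ...) {
  cat("<XGO>", format(x), " (", format(composition_of(x)), ")\n", sep = "")
  invisible(x)
}

#' @export
length.xgo_structure <- function(x) length(x$codes)

#' @export
`==.xgo_structure` <- function(e1, e2) {
  format(as_structure(e1)) == format(as_structure(e2))
}

#' Residue-class composition of a structure
#'
#' The `Hex` count is the backbone length plus all sidechain hexoses; the
#' other classes are summed over the sidechains; `Ac` is the acetyl count.
#' Composition is additive under backbone concatenation.
#'
#' @param s Structure (or code string).
#' @param registry Sidechain registry.
#' @return An `xgo_composition`.
#' @export
#' @examples
#' composition_of("XXFG")   # Hex5 Pent3 dHex1
#' composition_of("LPGGG")  # Hex7 Pent2 HexA1
composition_of <- function(s, registry = sidechain_registry()) {
  s <- as_structure(s, registry)
  counts <- colSums(registry[s$codes, .GLYCOSYL, drop = FALSE])
  counts["Hex"] <- counts["Hex"] + length(s$codes)
  composition(Hex = counts[["Hex"]], Pent = counts[["Pent"]],
              dHex = counts[["dHex"]], HexA = counts[["HexA"]],
              Ac = s$acetyl)
}

#' Canonical representative of a set of branching isomers
#'
#' Mass spectrometry cannot fix the backbone position of a sidechain, so a
#' composition usually admits several arrangements (e.g. XXPG / XPXG /
#' PXXG). The representative follows the conventions by which such
#' structures are named in the field: prefer arrangements without
#' unsubstituted glucoses before the reducing end (the shape of a complete
#' endo-xyloglucanase product, XLG over GXXG-type isomers); among those,
#' the most plain-X positions (the XXXG-core convention, XXFG over
#' BFGG-type isomers); then decoration weight non-decreasing toward the
#' reducing end, the most elaborate sidechain adjacent to the reducing-end
#' glucose (XXFG over XFXG); for sparse G-rich oligos, decorated positions
#' early (LGGGG over GGGLG, LPGGG over GLPGG); lexicographic order last,
#' for determinism.
#'
#' @param candidates List (or character vector) of structures sharing one
#'   composition.
#' @param registry Sidechain registry.
#' @return The representative `xgo_structure` (always a member of the input).
#' @export
#' @examples
#' format(canonical_representative(c("XFG", "FXG")))         # "XFG"
#' format(canonical_representative(c("XXFG", "XFXG", "FXXG")))  # "XXFG"
canonical_representative <- function(candidates,
                                     registry = sidechain_registry()) {
  if (length(candidates) == 0) stop("empty candidate set")
  cand <- lapply(candidates, as_structure, registry = registry)
  strings <- vapply(cand, format, "")
  internal_g <- vapply(cand, function(s) {
    n <- length(s$codes)
    if (n <= 1) 0L else sum(s$codes[-n] == "G")
  }, 0L)
  n_x <- vapply(cand, function(s) sum(s$codes == "X"), 0L)
  monotone <- vapply(cand, function(s) {
    w <- code_weight(s$codes, registry)
    n <- length(w)
    while (n > 1 && s$codes[n] == "G") n <- n - 1  # ignore trailing bare G
    w <- w[seq_len(n)]
    all(diff(w) >= 0)
  }, NA)
  # weight vector padded and inverted so that "decoration early" sorts first
  wkey <- vapply(cand, function(s) {
    w <- code_weight(s$codes, registry)
    paste(sprintf("%02d", 99L - c(w, rep(0L, 12 - length(w)))),
          collapse = "")
  }, "")
  ord <- order(internal_g, -n_x, !monotone, wkey, strings)
  cand[[ord[1]]]
}
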