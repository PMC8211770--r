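#' Default residue-count bounds for composition enumeration
#'
#' Generous for the XGO pool released by endo-xyloglucanase digestion of a
#' cell wall: up to ten hexoses (a five-glucose backbone plus sidechain
#' hexoses, and the contaminating hexose-oligomer ladder), six pentoses, two
#' deoxy-hexoses, three uronic acids and two acetyls.
#'
#' @return Named integer vector of per-class maxima.
#' @export
default_bounds <- function() {
  c(Hex = 10L, Pent = 6L, dHex = 2L, HexA = 3L, Ac = 2L)
}

#' Acquisition m/z range considered valid
#'
#' Reflectron MALDI-ToF acquisition for XGO profiling spans m/z 200-4000;
#' peaks outside it are flagged rather than rejected.
#' @return Numeric length-2 vector.
#' @export
acquisition_range <- function() c(200, 4000)

#' Enumerate compositions consistent with an observed peak
#'
#' Exhaustive search over all residue count vectors within `bounds` whose
#' theoretical adduct m/z lies within `tol` Da of the observed peak. This is
#' the computation implicit in reading a MALDI XGO spectrum: every integer
#' peak is first a composition hypothesis, only then a structure hypothesis.
#'
#' @param mz Observed m/z (singly charged).
#' @param convention Mass convention (rounding is ignored here: matching is
#'   done on unrounded theoretical m/z).
#' @param adduct Adduct label.
#' @param tol Mass tolerance in Da (default 0.5, matching integer-reported
#'   MALDI peaks).
#' @param bounds Per-class count maxima, see [default_bounds()].
#' @return Data frame with one row per matching composition: the five count
#'   columns, `mz_theoretical`, and signed `error` (theoretical - observed),
#'   sorted by `abs(error)`. If `mz` lies outside [acquisition_range()] the
#'   result carries attribute `out_of_range = TRUE`.
#' @export
#' @examples
#' enumerate_compositions(1393.45, tol = 0.3)  # XXFG-type composition
enumerate_compositions <- function(mz,
                                   convention = mass_convention("monoisotopic"),
                                   adduct = "+Na", tol = 0.5,
                                   bounds = default_bounds()) {
  stopifnot(is.numeric(mz), length(mz) == 1, tol > 0)
  conv <- as_mass_convention(convention)
  delta <- .ADDUCTS[[match.arg(adduct, names(.ADDUCTS))]]
  grid <- composition_grid(bounds)
  theo <- grid$mass + conv_offset(grid, conv) + conv$water + delta
  err <- theo - mz
  keep <- abs(err) <= tol
  out <- grid$counts[keep, , drop = FALSE]
  out$mz_theoretical <- theo[keep]
  out$error <- err[keep]
  out <- out[order(abs(out$error)), , drop = FALSE]
  rownames(out) <- NULL
  rng <- acquisition_range()
  attr(out, "out_of_range") <- mz < rng[1] || mz > rng[2]
  out
}

# full count grid and its monoisotopic-independent pieces; mass recomputed
# per convention by conv_offset
composition_grid <- function(bounds) {
  cls <- residue_classes()
  counts <- expand.grid(lapply(stats::setNames(bounds[cls], cls),
                               function(b) 0:b),
                        KEEP.OUT.ATTRS = FALSE)
  glyc <- rowSums(counts[, .GLYCOSYL])
  counts <- counts[glyc >= 1, , drop = FALSE]
  list(counts = counts, mass = 0)
}

conv_offset <- function(grid, conv) {
  as.matrix(grid$counts) %*% conv$residues[colnames(grid$counts)]
}

#' Enumerate structures realizing a composition
#'
#' All assignments of registry sidechain codes to backbone positions whose
#' summed composition equals `comp`, for backbone lengths in `backbone`.
#' The search is depth-first with pruning on the remaining residue budget.
#' Mass-degenerate letters (S/D/B, all two pentoses) yield distinct rows;
#' they form a degeneracy group with a single composition.
#'
#' @param comp Composition (or anything [composition_of()] accepts).
#' @param backbone Integer vector of admissible backbone lengths
#'   (default 2:6, XXG-type cores through five-glucose GGGG-type cores;
#'   single glucoses are also valid when `1` is included).
#' @param reducing_end_G Require the reducing-end unit to be unsubstituted
#'   (the signature of endo-xyloglucanase products). Default `TRUE`.
#' @param codes Allowed sidechain letters (default: all registry codes).
#' @param registry Sidechain registry.
#' @param max_structures Stop after this many structures (guards pathological
#'   compositions); the result then carries attribute `truncated = TRUE`.
#' @return Data frame with columns `structure` (code string) and `canonical`
#'   (logical, `TRUE` for the conventional representative). Empty (zero
#'   rows) when the composition is unachievable.
#' @export
#' @examples
#' enumerate_structures(composition(Hex = 5, Pent = 3, HexA = 1),
#'                      backbone = 4)  # XXPG, XPXG, PXXG, BPGG, ...
enumerate_structures <- function(comp, backbone = 2:6,
                                 reducing_end_G = TRUE,
                                 codes = NULL,
                                 registry = sidechain_registry(),
                                 max_structures = 500L) {
  comp <- as_composition(comp)
  if (is.null(codes)) codes <- registry$code
  res_mat <- as.matrix(registry[codes, .GLYCOSYL, drop = FALSE])
  found <- character(0)
  truncated <- FALSE
  for (n in sort(backbone)) {
    target <- as.numeric(comp[.GLYCOSYL])
    target[1] <- target[1] - n  # backbone glucoses
    if (any(target < 0)) next
    acc <- new.env(parent = emptyenv())
    acc$out <- vector("list", 64); acc$k <- 0L; acc$stop <- FALSE
    last_fixed <- if (reducing_end_G) "G" else NA
    recurse_assign(character(n), 1L, n, target, codes, res_mat, last_fixed,
                   acc, max_structures - length(found))
    if (acc$k > 0) found <- c(found, unlist(acc$out[seq_len(acc$k)]))
    if (acc$stop) { truncated <- TRUE; break }
  }
  out <- data.frame(structure = found, canonical = logical(length(found)),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0) {
    # canonical flag within each backbone-length group of this composition
    rep_str <- format(canonical_representative(found))
    out$canonical <- out$structure == rep_str
  }
  if (comp[["Ac"]] > 0 && nrow(out) > 0)
    out$structure <- paste0(out$structure, "+", comp[["Ac"]], "Ac")
  attr(out, "truncated") <- truncated
  out
}

recurse_assign <- function(codes_vec, pos, n, remaining, codes, res_mat,
                           last_fixed, acc, budget) {
  if (acc$stop) return()
  if (pos > n) {
    if (all(remaining == 0)) {
      acc$k <- acc$k + 1L
      if (acc$k > length(acc$out)) length(acc$out) <- 2 * length(acc$out)
      acc$out[[acc$k]] <- paste(codes_vec, collapse = "")
      if (acc$k >= budget) acc$stop <- TRUE
    }
    return()
  }
  opts <- if (pos == n && !is.na(last_fixed)) last_fixed else codes
  for (cd in opts) {
    rem <- remaining - res_mat[cd, ]
    if (any(rem < 0)) next
    codes_vec[pos] <- cd
    recurse_assign(codes_vec, pos + 1L, n, rem, codes, res_mat, last_fixed,
                   acc, budget)
    if (acc$stop) return()
  }
}

# memoized structure enumeration used by annotation (keyed on composition,
# constraints and registry codes)
enumerate_structures_cached <- function(comp, backbone, reducing_end_G,
                                        registry) {
  cache <- .registry_env$structure_cache
  key <- paste(c(as.integer(comp), backbone, reducing_end_G,
                 registry$code), collapse = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  val <- enumerate_structures(comp, backbone = backbone,
                              reducing_end_G = reducing_end_G,
                              registry = registry)
  cache[[key]] <- val
  val
}
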