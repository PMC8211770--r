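# Terminal residues removable from each sidechain in MS/MS neutral-loss
# fragmentation, as (lost class -> resulting code). Wider than the
# exo-glycosidase table because collision-induced losses are not limited to
# enzyme-accessible termini: the xylose of a bare X is terminal, as are both
# branches of P (the galactose and the uronic acid sit side by side on the
# xylose, which is why XPG-type precursors show terminal Hex AND HexA).
.MSMS_EXTRA <- list(
  X = c(Pent = "G"),
  S = c(Pent = "X"),
  D = c(Pent = "X"),
  B = c(Pent = "X"),
  Y = c(HexA = "X"),
  P = c(HexA = "L")
)

msms_losses <- function(code, registry = sidechain_registry()) {
  out <- character(0)
  term <- registry[code, "terminal"]
  if (!is.na(term)) out[term] <- registry[code, "trim"]
  extra <- .MSMS_EXTRA[[code]]
  if (!is.null(extra)) out[names(extra)] <- extra
  out  # named: lost class -> new code
}

.CROSS_RING <- c(60.02113, 120.04226)  # C2H4O2 / C4H8O4 neutrals

#' Predict tandem-MS fragment ions of a sodiated XGO
#'
#' Models the fragments that reflectron MALDI-ToF/ToF spectra of sodiated
#' glycans show: sequential
#' neutral losses of currently terminal residues from the charged precursor
#' (charge retained on the larger fragment), plus the two cross-ring
#' neutrals of 60 and 120 Da from the parent ion. The reducing-end glucose
#' is removable only when unsubstituted (and not the last remaining unit);
#' the non-reducing terminal backbone unit can be lost together with its
#' sidechain as one composite loss, its depth counted as the number of
#' residues it contains.
#'
#' @param s Structure or code string.
#' @param convention Mass convention (rounding applies to reported m/z).
#' @param adduct Adduct label.
#' @param max_depth Maximum number of sequential residue losses.
#' @param registry Sidechain registry.
#' @return Data frame with columns `kind` (`"terminal-loss"`/`"cross-ring"`),
#'   `lost` (loss chain, residues separated by `>`; composite unit losses
#'   bracketed), `depth`, `mz`, plus attribute `precursor` (precursor m/z).
#' @export
#' @examples
#' fragment_ions("XPG", mass_convention("monoisotopic", rounding = "truncate"))
fragment_ions <- function(s, convention = mass_convention("monoisotopic"),
                          adduct = "+Na", max_depth = 2L,
                          registry = sidechain_registry()) {
  stopifnot(max_depth >= 1)
  conv <- as_mass_convention(convention)
  s <- as_structure(s, registry)
  delta <- .ADDUCTS[[match.arg(adduct, names(.ADDUCTS))]]
  precursor <- neutral_mass(s, conv) + delta
  res <- conv$residues

  out_kind <- character(0); out_lost <- character(0)
  out_depth <- integer(0); out_mz <- numeric(0)
  seen <- new.env(parent = emptyenv())

  emit <- function(chain, depth, mz) {
    key <- paste(chain, collapse = ">")
    if (!is.null(seen[[key]])) return(FALSE)
    seen[[key]] <- TRUE
    out_kind <<- c(out_kind, "terminal-loss")
    out_lost <<- c(out_lost, key)
    out_depth <<- c(out_depth, depth)
    out_mz <<- c(out_mz, mz)
    TRUE
  }

  walk <- function(codes, chain, depth, mz) {
    if (depth >= max_depth) return()
    n <- length(codes)
    # sidechain terminal losses
    for (p in seq_len(n)) {
      losses <- msms_losses(codes[p], registry)
      for (cls in names(losses)) {
        codes2 <- codes
        codes2[p] <- losses[[cls]]
        mz2 <- mz - res[[cls]]
        chain2 <- c(chain, cls)
        emit(chain2, depth + 1L, mz2)
        walk(codes2, chain2, depth + 1L, mz2)
      }
    }
    # reducing-end glucose, only when unsubstituted and not the last unit
    if (n >= 2 && codes[n] == "G") {
      mz2 <- mz - res[["Hex"]]
      chain2 <- c(chain, "Hex")
      emit(chain2, depth + 1L, mz2)
      walk(codes[-n], chain2, depth + 1L, mz2)
    }
    # composite loss of the non-reducing terminal unit with its sidechain
    if (n >= 2) {
      unit <- code_residues(codes[1], registry)
      unit["Hex"] <- unit["Hex"] + 1
      nres <- sum(unit)
      if (depth + nres <= max_depth) {
        mz2 <- mz - sum(unit * res[.GLYCOSYL])
        lab <- paste0("[", paste(rep(names(unit[unit > 0]),
                                     unit[unit > 0]), collapse = "+"), "]")
        chain2 <- c(chain, lab)
        emit(chain2, depth + as.integer(nres), mz2)
        walk(codes[-1], chain2, depth + as.integer(nres), mz2)
      }
    }
  }
  walk(s$codes, character(0), 0L, precursor)

  out <- data.frame(kind = out_kind, lost = out_lost, depth = out_depth,
                    mz = out_mz, stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(kind = "cross-ring",
                               lost = paste0("-", round(.CROSS_RING, 3)),
                               depth = 1L, mz = precursor - .CROSS_RING,
                               stringsAsFactors = FALSE))
  out$mz <- apply_rounding(out$mz, conv$rounding)
  out <- out[order(out$depth, -out$mz), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "precursor") <- apply_rounding(precursor, conv$rounding)
  out
}

#' Infer terminal residues from tandem-MS neutral losses
#'
#' A depth-1 neutral loss matching one residue mass marks that residue class
#' as terminal on the precursor: losses of 132/162/176 from m/z 1129
#' identify a terminal pentose, hexose and uronic acid on the XPG-type XGO.
#' Depth-2 chains (two sequential losses, e.g. the two consecutive pentoses
#' taking 1423 to 1159) are reported as ordered pairs.
#'
#' @param precursor_mz Precursor m/z.
#' @param fragments Numeric vector of observed fragment m/z (non-empty).
#' @param convention Mass convention supplying residue masses.
#' @param tol Matching tolerance in Da.
#' @return List with `terminal` (character vector of residue classes with
#'   depth-1 evidence) and `depth2` (data frame `first`, `second`,
#'   `fragment`).
#' @export
#' @examples
#' infer_terminals(1129.33, c(997.29, 967.28, 953.30))
infer_terminals <- function(precursor_mz, fragments,
                            convention = mass_convention("monoisotopic"),
                            tol = 0.3) {
  if (!length(fragments)) stop("at least one fragment m/z is required")
  conv <- as_mass_convention(convention)
  res <- conv$residues[.GLYCOSYL]
  near <- function(mz) any(abs(fragments - mz) <= tol)
  terminal <- names(res)[vapply(names(res),
                                function(cl) near(precursor_mz - res[[cl]]),
                                NA)]
  d2 <- expand.grid(first = names(res), second = names(res),
                    stringsAsFactors = FALSE)
  d2 <- d2[d2$first %in% terminal, , drop = FALSE]
  frag2 <- precursor_mz - res[d2$first] - res[d2$second]
  keep <- vapply(frag2, near, NA)
  depth2 <- data.frame(first = d2$first[keep], second = d2$second[keep],
                       fragment = unname(frag2[keep]),
                       stringsAsFactors = FALSE)
  rownames(depth2) <- NULL
  list(terminal = terminal, depth2 = depth2)
}
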