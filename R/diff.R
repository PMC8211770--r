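#' Differential pre/post-enzyme spectrum analysis
#'
#' Pairs peaks that disappear (or shrink at least `min_ratio`-fold) after an
#' exo-glycosidase treatment with peaks at the precursor m/z minus 1..k
#' residue masses that are present in the post spectrum — the classical
#' before/after reading of an OLIMP digestion series. Peaks shrinking by
#' between `partial_ratio` and `min_ratio` are reported as partially
#' degraded (the behavior of XLFG under limiting fucosidase). Products
#' frequently pre-exist in the substrate pool (XXLG is both a native XGO
#' and the fucosidase product of XXFG), so a product need only be present,
#' not new, in the post spectrum.
#'
#' @param pre,post Spectra from the same sample before/after the enzyme.
#' @param rule An [exo_rule()].
#' @param convention Mass convention supplying the residue mass.
#' @param tol Peak-matching tolerance in Da.
#' @param min_ratio Fold-change (pre/post) at or above which a peak counts
#'   as disappeared; default 5.
#' @param partial_ratio Fold-change at or above which a peak counts as
#'   partially degraded; default 1.5.
#' @return Data frame with one row per (lost peak, product candidate):
#'   `precursor`, `status` (`"disappeared"`/`"partial"`), `product` (NA when
#'   no product peak was found), `k`, `residue`, `delta` (observed mass
#'   difference), `pre_intensity`, `post_intensity`.
#' @export
#' @examples
#' pre  <- spectrum(c(953, 1099, 1247, 1393, 1409, 1555), 100)
#' post <- spectrum(c(953, 1247, 1409), c(200, 200, 180))
#' diff_spectra(pre, post, exo_rule("fucosidase"), mass_convention("nominal"))
diff_spectra <- function(pre, post, rule,
                         convention = mass_convention("monoisotopic"),
                         tol = 0.5, min_ratio = 5, partial_ratio = 1.5) {
  conv <- as_mass_convention(convention)
  res_mass <- conv$residues[[rule$removes]]
  empty <- data.frame(precursor = numeric(0), status = character(0),
                      product = numeric(0), k = integer(0),
                      residue = character(0), delta = numeric(0),
                      pre_intensity = numeric(0), post_intensity = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(pre$peaks)) return(empty)
  match_peak <- function(mz, peaks) {
    if (!nrow(peaks)) return(NA_integer_)
    d <- abs(peaks$mz - mz)
    i <- which.min(d)
    if (d[i] <= tol) i else NA_integer_
  }
  rows <- list()
  for (p in seq_len(nrow(pre$peaks))) {
    mz0 <- pre$peaks$mz[p]; int0 <- pre$peaks$intensity[p]
    j <- match_peak(mz0, post$peaks)
    int1 <- if (is.na(j)) 0 else post$peaks$intensity[j]
    ratio <- if (int1 == 0) Inf else int0 / int1
    status <- if (ratio >= min_ratio) "disappeared"
              else if (ratio >= partial_ratio) "partial"
              else next
    found <- FALSE
    for (k in seq_len(rule$max_multiplicity)) {
      q <- match_peak(mz0 - k * res_mass, post$peaks)
      if (is.na(q)) next
      found <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        precursor = mz0, status = status, product = post$peaks$mz[q],
        k = k, residue = rule$removes, delta = mz0 - post$peaks$mz[q],
        pre_intensity = int0, post_intensity = int1,
        stringsAsFactors = FALSE)
    }
    if (!found)  # unpaired loss, reported separately with NA product
      rows[[length(rows) + 1L]] <- data.frame(
        precursor = mz0, status = status, product = NA_real_, k = NA_integer_,
        residue = rule$removes, delta = NA_real_, pre_intensity = int0,
        post_intensity = int1, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
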