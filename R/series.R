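#' Residue-mass ladder steps
#'
#' The mass differences that relate members of an XGO family: one residue of
#' each class, plus the whole isoprimeverose repeat ("X-unit", one hexose
#' plus one pentose, the step between XPG-type and XXPG-type oligomers).
#'
#' @param convention Mass convention supplying the residue masses.
#' @return Named numeric vector of step masses in Da.
#' @export
#' @examples
#' series_steps("nominal")  # Hex 162, Pent 132, dHex 146, HexA 176, Ac 42, X 294
series_steps <- function(convention = mass_convention("monoisotopic")) {
  conv <- as_mass_convention(convention)
  r <- conv$residues
  c(r, Xunit = unname(r["Hex"] + r["Pent"]))
}

#' Detect residue-mass series in a spectrum
#'
#' Every ordered peak pair whose m/z difference matches a ladder step within
#' `tol` becomes a labeled edge; connected components of the resulting graph
#' are the series of related XGOs (e.g. the sparsely branched
#' LGGGG/PGGGG/LLGGG/LPGGG family, linked by uronic-acid and X-unit steps).
#'
#' @param spec An `xgo_spectrum` (at least 2 peaks for a non-empty result).
#' @param steps Named step masses, see [series_steps()].
#' @param tol Matching tolerance in Da.
#' @return A `series_graph`: list with `edges` (data frame `i`, `j`,
#'   `mz_i`, `mz_j`, `step`, `observed`, `matched`, `error`), `membership`
#'   (series id per peak, NA for isolated peaks) and `peaks`.
#' @export
#' @examples
#' sp <- spectrum(c(1146, 1322, 1440, 1616))
#' find_series(sp, series_steps("nominal"), tol = 0.5)
find_series <- function(spec, steps = series_steps(), tol = 0.5) {
  peaks <- spec$peaks
  n <- nrow(peaks)
  edges <- data.frame(i = integer(0), j = integer(0), mz_i = numeric(0),
                      mz_j = numeric(0), step = character(0),
                      observed = numeric(0), matched = numeric(0),
                      error = numeric(0), stringsAsFactors = FALSE)
  if (n >= 2) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    obs <- peaks$mz[pairs[, 2]] - peaks$mz[pairs[, 1]]
    for (lab in names(steps)) {
      hit <- abs(obs - steps[[lab]]) <= tol
      if (!any(hit)) next
      edges <- rbind(edges, data.frame(
        i = pairs[hit, 1], j = pairs[hit, 2],
        mz_i = peaks$mz[pairs[hit, 1]], mz_j = peaks$mz[pairs[hit, 2]],
        step = lab, observed = obs[hit], matched = steps[[lab]],
        error = obs[hit] - steps[[lab]], stringsAsFactors = FALSE))
    }
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  membership <- rep(NA_integer_, n)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    comp <- igraph::components(g)
    linked <- unique(c(edges$i, edges$j))
    membership[linked] <- comp$membership[as.character(linked)]
    # renumber series 1..k in m/z order, dropping singleton components
    ids <- unique(stats::na.omit(membership[order(peaks$mz)]))
    membership <- match(membership, ids)
  }
  structure(list(edges = edges, membership = membership, peaks = peaks),
            class = "series_graph")
}

#' @export
print.series_graph <- function(x, ...) {
  k <- length(unique(stats::na.omit(x$membership)))
  cat("<series_graph>", nrow(x$edges), "edges,", k, "series\n")
  if (nrow(x$edges))
    print(x$edges[, c("mz_i", "mz_j", "step", "observed", "error")])
  invisible(x)
}
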