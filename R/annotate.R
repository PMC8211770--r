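#' Configuration for spectrum annotation
#'
#' Bundles the matching parameters and optional companion spectra used by
#' [annotate_peaks()].
#'
#' @param conventions Character vector of mass-convention names to try
#'   (default monoisotopic only).
#' @param adducts Adduct labels to try (default sodium only).
#' @param tol Composition-matching tolerance in Da (0.5 for integer-reported
#'   MALDI peaks).
#' @param mass_accuracy Expected absolute mass accuracy of the instrument in
#'   Da (default 0.2, typical of externally calibrated reflectron MALDI-ToF
#'   at m/z 1000-2000). Candidates whose |error| differ by less than this
#'   are treated as mass-indistinguishable and ranked by the evidence keys.
#' @param bounds Residue-count bounds, see [default_bounds()].
#' @param backbone Backbone-length range for structure enumeration.
#' @param reducing_end_G Require endo-xyloglucanase-type products (reducing
#'   end unsubstituted) when enumerating structures.
#' @param structures Enumerate structures per candidate composition
#'   (default TRUE; structure admissibility also informs ranking).
#' @param series Run ladder detection and use series-consistency evidence.
#' @param series_tol Tolerance for ladder steps in Da.
#' @param companions Named list of post-enzyme companion spectra, names from
#'   `c("fucosidase", "galactosidase")`.
#' @param min_ratio,partial_ratio Fold-change thresholds passed to
#'   [diff_spectra()].
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(conventions = "monoisotopic",
                              adducts = "+Na",
                              tol = 0.5,
                              mass_accuracy = 0.2,
                              bounds = default_bounds(),
                              backbone = 2:6,
                              reducing_end_G = TRUE,
                              structures = TRUE,
                              series = TRUE,
                              series_tol = 0.5,
                              companions = list(),
                              min_ratio = 5,
                              partial_ratio = 1.5) {
  stopifnot(all(names(companions) %in% c("fucosidase", "galactosidase")))
  structure(list(conventions = conventions, adducts = adducts, tol = tol,
                 mass_accuracy = mass_accuracy, bounds = bounds,
                 backbone = backbone, reducing_end_G = reducing_end_G,
                 structures = structures, series = series,
                 series_tol = series_tol, companions = companions,
                 min_ratio = min_ratio, partial_ratio = partial_ratio),
            class = "annotation_config")
}

#' Annotate a MALDI XGO spectrum
#'
#' The top-level pipeline: every peak is matched to candidate monosaccharide
#' compositions by exhaustive enumeration under each requested (convention,
#' adduct) pair; candidate branching isomers are enumerated per composition;
#' evidence from residue-mass series and from pre/post-enzyme companion
#' spectra is attached; and candidates are ranked.
#'
#' Ranking follows the reasoning used when reading such spectra by hand:
#' (1) smaller mass error, with errors closer than the instrument's mass
#' accuracy treated as indistinguishable (compositions may differ by as
#' little as 0.036 Da — one Hex+dHex versus one Pent+HexA — far below MALDI
#' accuracy, so raw error cannot separate them); within such a group,
#' (2) candidates admitting at least one grammar-valid structure,
#' (3) candidates whose structures explain an observed enzyme shift,
#' (4) candidates consistent with a detected XGO series — a candidate is
#' series-supported when a ladder neighbor's best composition differs from
#' it by exactly the edge's residue step, the argument by which a
#' BPGG-type reading of an XXPG-type peak is rejected as leaving its
#' series; series support is propagated iteratively so unambiguous anchors
#' resolve their neighbors; then (5) fewer distinct residue classes, fewer
#' total residues, and a lexicographic composition key for determinism.
#'
#' Peaks whose only candidates are pure hexose oligomers are flagged as the
#' contaminating hexose ladder seen in untreated cell-wall extracts.
#'
#' @param spec An `xgo_spectrum`.
#' @param config An [annotation_config()].
#' @return Data frame of class `xgo_annotation`: one row per
#'   (peak, candidate), columns `peak_mz`, `intensity`, `rank`, the five
#'   count columns, `mz_theoretical`, `error`, `convention`, `adduct`,
#'   `structures` (comma-joined, canonical first; empty when none),
#'   `contaminant`, `series_member`, `shift_precursor`, `shift_product`,
#'   `shift_supported`, `series_supported`. Peaks with no candidate within
#'   tolerance appear once with NA candidate fields.
#' @export
#' @examples
#' sp <- spectrum(c(1085.34, 1393.45), c(100, 80), sample = "demo")
#' annotate_peaks(sp, annotation_config())
annotate_peaks <- function(spec, config = annotation_config()) {
  stopifnot(inherits(spec, "xgo_spectrum"),
            inherits(config, "annotation_config"))
  peaks <- spec$peaks
  n <- nrow(peaks)
  if (n == 0) return(empty_annotation())

  registry <- sidechain_registry()

  ## ---- peak-level evidence -------------------------------------------
  series_member <- rep(FALSE, n)
  edges <- NULL
  if (config$series && n >= 2) {
    conv1 <- mass_convention(config$conventions[1])
    sg <- find_series(spec, series_steps(conv1), tol = config$series_tol)
    series_member <- !is.na(sg$membership)
    edges <- sg$edges
  }

  shift_precursor <- rep(FALSE, n)
  shift_product <- rep(FALSE, n)
  shift_enzyme <- vector("list", n)
  shift_pairs <- vector("list", n)  # per precursor peak: (residue, k, q)
  shift_edges <- list()
  for (enz in names(config$companions)) {
    rule <- exo_rule(enz, registry)
    dd <- diff_spectra(spec, config$companions[[enz]], rule,
                       mass_convention(config$conventions[1]),
                       tol = config$tol, min_ratio = config$min_ratio,
                       partial_ratio = config$partial_ratio)
    dd <- dd[!is.na(dd$product), , drop = FALSE]
    for (r in seq_len(nrow(dd))) {
      ip <- which.min(abs(peaks$mz - dd$precursor[r]))
      shift_precursor[ip] <- TRUE
      shift_enzyme[[ip]] <- union(shift_enzyme[[ip]], enz)
      iq <- which(abs(peaks$mz - dd$product[r]) <= config$tol)
      shift_product[iq] <- TRUE
      for (q in iq) {
        shift_pairs[[ip]] <- c(shift_pairs[[ip]],
                               list(list(residue = dd$residue[r],
                                         k = dd$k[r], q = q)))
        # a single-residue enzyme shift is a causally labeled ladder edge
        # from the product peak (when present in the pre spectrum) up to
        # the precursor; multi-residue pairs stay flags only, since a
        # 2-residue window is wide enough to land on unrelated compositions
        if (dd$k[r] == 1)
          shift_edges[[length(shift_edges) + 1L]] <-
            data.frame(i = q, j = ip, step = dd$residue[r],
                       stringsAsFactors = FALSE)
      }
    }
  }

  ## ---- candidate generation ------------------------------------------
  cand <- vector("list", n)
  for (p in seq_len(n)) {
    rows <- list()
    for (cv in config$conventions) {
      conv <- mass_convention(cv)
      for (ad in config$adducts) {
        cc <- enumerate_compositions(peaks$mz[p], conv, ad,
                                     tol = config$tol,
                                     bounds = config$bounds)
        if (!nrow(cc)) next
        cc$convention <- cv
        cc$adduct <- ad
        rows[[length(rows) + 1L]] <- cc
      }
    }
    cand[p] <- list(if (length(rows)) do.call(rbind, rows) else NULL)
  }

  ## ---- per-candidate structure and enzyme evidence -------------------
  cand <- lapply(seq_len(n), function(p) {
    cc <- cand[[p]]
    if (is.null(cc)) return(NULL)
    cc$structures <- ""
    cc$n_structures <- 0L
    cc$shift_level <- 0L   # 1 = structure-susceptible, 2 = product-validated
    for (r in seq_len(nrow(cc))) {
      comp <- as_composition(unlist(cc[r, residue_classes()]))
      if (config$structures) {
        st <- enumerate_structures_cached(comp, config$backbone,
                                          config$reducing_end_G, registry)
        ord <- order(!st$canonical, st$structure)
        cc$structures[r] <- paste(st$structure[ord], collapse = ",")
        cc$n_structures[r] <- nrow(st)
        if (shift_precursor[p] && nrow(st) > 0) {
          for (enz in shift_enzyme[[p]]) {
            rule <- exo_rule(enz, registry)
            if (any(vapply(st$structure, function(s)
                  length(intersect(strsplit(sub("\\+.*$", "", s), "")[[1]],
                                   names(rule$applicable))) > 0, NA))) {
              cc$shift_level[r] <- 1L
              break
            }
          }
        }
      } else if (shift_precursor[p]) {
        for (enz in shift_enzyme[[p]])
          if (comp[[exo_rule(enz, registry)$removes]] >= 1)
            cc$shift_level[r] <- 1L
      }
    }
    cc$contaminant <- cc$Pent == 0 & cc$dHex == 0 & cc$HexA == 0 & cc$Ac == 0
    cc$n_classes <- rowSums(cc[, residue_classes()] > 0)
    cc$n_residues <- rowSums(cc[, residue_classes()])
    cc$comp_key <- apply(cc[, residue_classes()], 1, paste, collapse = ".")
    cc$series_count <- 0L
    cc$series_supported <- FALSE
    cc
  })

  ## ---- iterative ranking with series-consistency propagation ---------
  step_comp <- list(
    Hex = c(1, 0, 0, 0, 0), Pent = c(0, 1, 0, 0, 0),
    dHex = c(0, 0, 1, 0, 0), HexA = c(0, 0, 0, 1, 0),
    Ac = c(0, 0, 0, 0, 1), Xunit = c(1, 1, 0, 0, 0))

  if (length(shift_edges)) {
    se <- do.call(rbind, shift_edges)
    se <- se[se$i < se$j & se$step %in% names(step_comp), , drop = FALSE]
    base <- if (!is.null(edges) && nrow(edges))
      edges[, c("i", "j", "step")] else
      data.frame(i = integer(0), j = integer(0), step = character(0))
    edges <- unique(rbind(base, se))
  } else if (!is.null(edges) && nrow(edges)) {
    edges <- unique(edges[, c("i", "j", "step")])
  }

  rank_one <- function(cc) {
    best <- min(abs(cc$error))
    err_key <- ifelse(abs(cc$error) - best <= config$mass_accuracy,
                      0, abs(cc$error))
    no_struct <- if (config$structures) cc$n_structures == 0 else FALSE
    order(err_key, no_struct, -cc$shift_level, -cc$series_count,
          cc$n_classes, cc$n_residues, cc$comp_key)
  }

  # a peak can anchor its ladder neighbors only when its own identity is
  # settled: a single candidate within the instrument's mass accuracy, or a
  # single candidate singled out by enzyme-shift (or, in later passes,
  # series) evidence -- propagating from merely top-ranked but ambiguous
  # peaks would let a parallel rival series support itself
  anchor_comp <- function(cc, use_series) {
    if (is.null(cc) || !nrow(cc)) return(NULL)
    best <- min(abs(cc$error))
    g0 <- cc[abs(cc$error) - best <= config$mass_accuracy, , drop = FALSE]
    if (config$structures && any(g0$n_structures > 0))
      g0 <- g0[g0$n_structures > 0, , drop = FALSE]
    lev <- g0$shift_level
    cnt <- g0$series_count
    pick <- if (nrow(g0) == 1) 1L
            else if (max(lev) > 0 && sum(lev == max(lev)) == 1)
              which.max(lev)
            else if (use_series && max(cnt) > 0 && sum(cnt == max(cnt)) == 1)
              which.max(cnt)
            else return(NULL)
    as.integer(unlist(g0[pick, residue_classes()]))
  }

  has_edges <- config$series && !is.null(edges) && nrow(edges) > 0
  has_pairs <- any(!vapply(shift_pairs, is.null, NA))
  if (has_edges || has_pairs) {
    for (iter in 1:2) {
      anchors <- lapply(cand, anchor_comp, use_series = iter > 1)
      # enzyme-shift validation against the product peak's settled identity:
      # a candidate is upgraded when subtracting the removed residues lands
      # exactly on the anchored composition of the observed product peak
      for (p in seq_len(n)) {
        prs <- shift_pairs[[p]]
        cc <- cand[[p]]
        if (is.null(prs) || is.null(cc) || !nrow(cc)) next
        for (pr in prs) {
          if (pr$k != 1L) next  # multi-residue windows are too coincidence-prone
          ref <- anchors[[pr$q]]
          if (is.null(ref)) next
          want <- ref + as.integer(step_comp[[pr$residue]])
          for (r in seq_len(nrow(cc)))
            if (cc$shift_level[r] >= 1L &&
                identical(as.integer(unlist(cc[r, residue_classes()])), want))
              cc$shift_level[r] <- 2L
        }
        cand[[p]]$shift_level <- cc$shift_level
      }
      if (!has_edges) next
      for (p in seq_len(n)) {
        cc <- cand[[p]]
        if (is.null(cc) || !nrow(cc)) next
        cnt <- integer(nrow(cc))
        e_lo <- edges[edges$j == p, , drop = FALSE]  # p = heavier peak
        e_hi <- edges[edges$i == p, , drop = FALSE]  # p = lighter peak
        for (r in seq_len(nrow(cc))) {
          this <- as.integer(unlist(cc[r, residue_classes()]))
          for (k in seq_len(nrow(e_lo))) {
            ref <- anchors[[e_lo$i[k]]]
            if (!is.null(ref) &&
                identical(this, ref + as.integer(step_comp[[e_lo$step[k]]])))
              cnt[r] <- cnt[r] + 1L
          }
          for (k in seq_len(nrow(e_hi))) {
            ref <- anchors[[e_hi$j[k]]]
            if (!is.null(ref) &&
                identical(this, ref - as.integer(step_comp[[e_hi$step[k]]])))
              cnt[r] <- cnt[r] + 1L
          }
        }
        cand[[p]]$series_count <- cnt
        cand[[p]]$series_supported <- cnt > 0L
      }
    }
  }

  ## ---- assemble -------------------------------------------------------
  out <- vector("list", n)
  for (p in seq_len(n)) {
    cc <- cand[[p]]
    if (is.null(cc) || !nrow(cc)) {
      out[[p]] <- data.frame(
        peak_mz = peaks$mz[p], intensity = peaks$intensity[p], rank = NA,
        Hex = NA, Pent = NA, dHex = NA, HexA = NA, Ac = NA,
        mz_theoretical = NA, error = NA, convention = NA, adduct = NA,
        structures = NA, contaminant = FALSE,
        series_member = series_member[p],
        shift_precursor = shift_precursor[p],
        shift_product = shift_product[p],
        shift_supported = FALSE, series_supported = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    cc <- cc[rank_one(cc), , drop = FALSE]
    out[[p]] <- data.frame(
      peak_mz = peaks$mz[p], intensity = peaks$intensity[p],
      rank = seq_len(nrow(cc)),
      cc[, c(residue_classes(), "mz_theoretical", "error", "convention",
             "adduct", "structures", "contaminant")],
      series_member = series_member[p],
      shift_precursor = shift_precursor[p],
      shift_product = shift_product[p],
      shift_supported = cc$shift_level > 0L,
      series_supported = cc$series_supported,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("xgo_annotation", "data.frame")
  res
}

empty_annotation <- function() {
  res <- data.frame(
    peak_mz = numeric(0), intensity = numeric(0), rank = integer(0),
    Hex = integer(0), Pent = integer(0), dHex = integer(0),
    HexA = integer(0), Ac = integer(0), mz_theoretical = numeric(0),
    error = numeric(0), convention = character(0), adduct = character(0),
    structures = character(0), contaminant = logical(0),
    series_member = logical(0), shift_precursor = logical(0),
    shift_product = logical(0), shift_supported = logical(0),
    series_supported = logical(0), stringsAsFactors = FALSE)
  class(res) <- c("xgo_annotation", "data.frame")
  res
}

#' Write an annotation report
#'
#' @param x An `xgo_annotation` (from [annotate_peaks()]).
#' @param path Output path.
#' @param format `"tsv"` (flat table) or `"json"` (one record per peak with
#'   nested candidate list).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    recs <- lapply(split(as.data.frame(x), x$peak_mz), function(d) {
      list(peak = list(mz = d$peak_mz[1], intensity = d$intensity[1]),
           evidence = list(series_member = d$series_member[1],
                           shift_precursor = d$shift_precursor[1],
                           shift_product = d$shift_product[1]),
           candidates = if (all(is.na(d$rank))) list() else
             d[, c("rank", residue_classes(), "mz_theoretical", "error",
                   "convention", "adduct", "structures", "contaminant",
                   "shift_supported", "series_supported")])
    })
    jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
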