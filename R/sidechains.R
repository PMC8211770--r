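#' The xyloglucan one-letter sidechain registry
#'
#' Each backbone glucosyl unit of xyloglucan carries at most one sidechain,
#' written as a single uppercase letter: `G` is an unsubstituted glucose, `X`
#' the alpha-1,6 xylose (isoprimeverose unit), `L` galactosylated X, `F`
#' fucosylated L, `Y` a glucuronic/galacturonic acid on X, `P` an L-type
#' galactose together with a uronic acid on the xylose, `S`/`D`/`B` the
#' pentose-pentose variants and `E` a fucosylated D. The registry records,
#' per letter, the residue-class content of the sidechain (excluding the
#' backbone glucose), the exo-glycosidase-accessible terminal residue class,
#' and the letter obtained by trimming that terminal.
#'
#' `S`, `D` and `B` all contain two pentoses and are therefore
#' indistinguishable by mass; they are kept as distinct letters but collapse
#' to one composition, and annotation reports such degeneracy groups rather
#' than choosing an epimer.
#'
#' @param registry For `sidechain_registry()`, an optional replacement
#'   registry data frame (validated); with no argument the default registry
#'   is returned.
#' @return A data frame with columns `code`, `Hex`, `Pent`, `dHex`, `HexA`,
#'   `terminal` (NA when no enzyme-accessible terminus) and `trim` (the code
#'   after removing the terminal residue, NA likewise).
#' @export
#' @examples
#' sidechain_registry()
sidechain_registry <- function(registry = NULL) {
  if (is.null(registry)) return(.registry_env$registry)
  validate_registry(registry)
}

.default_registry <- function() {
  df <- data.frame(
    code     = c("G", "X", "L", "F", "S", "D", "E", "B", "Y", "P"),
    Hex      = c(0, 0, 1, 1, 0, 0, 0, 0, 0, 1),
    Pent     = c(0, 1, 1, 1, 2, 2, 2, 2, 1, 1),
    dHex     = c(0, 0, 0, 1, 0, 0, 1, 0, 0, 0),
    HexA     = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1),
    terminal = c(NA, NA, "Hex", "dHex", NA, NA, "dHex", NA, NA, "Hex"),
    trim     = c(NA, NA, "X", "L", NA, NA, "D", NA, NA, "Y"),
    stringsAsFactors = FALSE)
  validate_registry(df)
}

validate_registry <- function(df) {
  need <- c("code", "Hex", "Pent", "dHex", "HexA", "terminal", "trim")
  if (!all(need %in% names(df)))
    stop("registry must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$code)) stop("duplicated sidechain codes in registry")
  if (!all(nchar(df$code) == 1 & df$code == toupper(df$code)))
    stop("sidechain codes must be single uppercase letters")
  if (!"G" %in% df$code) stop("registry must contain the bare-glucose code G")
  g <- df[df$code == "G", ]
  if (sum(g[, c("Hex", "Pent", "dHex", "HexA")]) != 0)
    stop("code G must carry no sidechain residues")
  nonG <- df[df$code != "G", ]
  if (any(nonG$Pent < 1))
    stop("every substituted code must contain at least one pentose (the xylose)")
  for (i in seq_len(nrow(df))) {
    term <- df$terminal[i]; trm <- df$trim[i]
    if (is.na(term) != is.na(trm))
      stop("terminal and trim must be both present or both absent: ",
           df$code[i])
    if (!is.na(term)) {
      if (!term %in% .GLYCOSYL) stop("unknown terminal class: ", term)
      if (!trm %in% df$code) stop("trim target not in registry: ", trm)
      want <- unlist(df[i, .GLYCOSYL])
      want[term] <- want[term] - 1
      got <- unlist(df[df$code == trm, .GLYCOSYL])
      if (!all(want == got))
        stop("trim target of ", df$code[i],
             " must equal its residues minus one ", term)
    }
  }
  rownames(df) <- df$code
  df
}

.registry_env <- new.env(parent = emptyenv())

#' Install a custom sidechain registry
#'
#' Replaces the active registry for the session, e.g. to add the `Q`
#' sidechain once its residue content is established. The previous registry
#' is returned invisibly so it can be restored.
#'
#' @param registry Data frame in the layout of [sidechain_registry()].
#' @return The previously active registry, invisibly.
#' @export
set_sidechain_registry <- function(registry) {
  old <- .registry_env$registry
  .registry_env$registry <- validate_registry(registry)
  invisible(old)
}

#' Read / write a sidechain registry as delimited text
#'
#' The registry is serialized as a tab-delimited table (columns `code`,
#' `Hex`, `Pent`, `dHex`, `HexA`, `terminal`, `trim`, empty fields for NA).
#' The shipped default lives at
#' `system.file("extdata", "sidechains.tsv", package = "olimpr")`.
#'
#' @param path File path.
#' @param registry Registry data frame (default the active one).
#' @return `read_sidechain_registry()` returns a validated registry data
#'   frame; `write_sidechain_registry()` returns `path` invisibly.
#' @export
read_sidechain_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_registry(df)
}

#' @rdname read_sidechain_registry
#' @export
write_sidechain_registry <- function(path, registry = sidechain_registry()) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# residue counts (glycosyl classes) for one code
code_residues <- function(code, registry = sidechain_registry()) {
  stats::setNames(as.numeric(registry[code, .GLYCOSYL]), .GLYCOSYL)
}

# total residue count of a sidechain; the "decoration weight" used by
# canonicalization
code_weight <- function(codes, registry = sidechain_registry()) {
  rowSums(registry[codes, .GLYCOSYL, drop = FALSE])
}
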