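#' Construct a centroided spectrum
#'
#' A spectrum is a peak list (m/z, intensity) with sample and treatment
#' metadata. Peaks are stored sorted by m/z; duplicates closer than 1e-6 Da
#' are merged by intensity sum. Intensities are arbitrary units and are used
#' only for presence and fold-change decisions — MALDI is semi-quantitative.
#'
#' @param mz Numeric vector of m/z values (> 0).
#' @param intensity Non-negative intensities (recycled scalar allowed).
#' @param sample Sample label.
#' @param treatment Character vector of enzyme treatments applied, in order.
#' @return An `xgo_spectrum`: list with `peaks` (data frame `mz`,
#'   `intensity`), `sample`, `treatment`.
#' @export
#' @examples
#' spectrum(c(1099, 1393, 1555), c(50, 120, 80), sample = "demo")
spectrum <- function(mz, intensity = 1, sample = "", treatment = character()) {
  stopifnot(is.numeric(mz), all(mz > 0), all(intensity >= 0))
  intensity <- rep_len(intensity, length(mz))
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (length(mz) > 1) {
    grp <- cumsum(c(TRUE, diff(mz) > 1e-6))
    mz <- as.numeric(tapply(mz, grp, function(v) v[1]))
    intensity <- as.numeric(tapply(intensity, grp, sum))
  }
  structure(list(peaks = data.frame(mz = mz, intensity = intensity),
                 sample = sample, treatment = as.character(treatment)),
            class = "xgo_spectrum")
}

#' @export
print.xgo_spectrum <- function(x, ...) {
  cat("<spectrum>", nrow(x$peaks), "peaks",
      if (nzchar(x$sample)) paste0("| sample: ", x$sample) else "",
      if (length(x$treatment))
        paste0("| treatment: ", paste(x$treatment, collapse = " > "))
      else "", "\n")
  if (nrow(x$peaks)) print(utils::head(x$peaks, 10))
  invisible(x)
}

#' @export
length.xgo_spectrum <- function(x) nrow(x$peaks)

#' Read a peak list from delimited text
#'
#' Accepts comma-, tab- or semicolon-delimited files with two columns (m/z,
#' intensity), with or without a header line. Rows that fail to parse as
#' numbers are reported with their line number.
#'
#' @param path File path.
#' @param sample Sample label (default: the file name).
#' @param treatment Enzyme treatments applied to this sample.
#' @return An `xgo_spectrum`.
#' @export
read_peaklist <- function(path, sample = basename(path),
                          treatment = character()) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("empty peak list: ", path)
  split1 <- strsplit(trimws(lines), "[,;\t]+|[[:space:]]+")
  first <- suppressWarnings(as.numeric(split1[[1]]))
  # a header line has no numeric field at all; a partially numeric first
  # line is a malformed data row and is reported as such below
  start <- if (length(first) > 0 && all(is.na(first))) 2L else 1L
  if (start > length(lines)) stop("peak list has a header but no data: ", path)
  mz <- numeric(0); intensity <- numeric(0)
  for (i in start:length(lines)) {
    fields <- split1[[i]]
    if (length(fields) < 1)
      stop("malformed row at line ", lineno[i], " of ", path)
    vals <- suppressWarnings(as.numeric(fields[seq_len(min(2, length(fields)))]))
    if (anyNA(vals))
      stop("non-numeric value at line ", lineno[i], " of ", path, ": ",
           lines[i])
    mz <- c(mz, vals[1])
    intensity <- c(intensity, if (length(vals) > 1) vals[2] else 1)
  }
  spectrum(mz, intensity, sample = sample, treatment = treatment)
}

#' Write a spectrum as a CSV peak list
#'
#' @param spec An `xgo_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spec, path) {
  utils::write.csv(spec$peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
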