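# Text and TIFF I/O.

read_two_column <- function(path, names) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\s*[-+0-9.eE]+[\\s,;\t]+[-+0-9.eE]+", first)
  df <- utils::read.table(path,
    header = has_header,
    sep = "", dec = ".", comment.char = "#",
    col.names = NULL, check.names = FALSE
  )
  if (ncol(df) < 2) {
    # retry with comma separation
    df <- utils::read.table(path, header = has_header, sep = ",")
  }
  out <- as_tibble(df[, seq_along(names)])
  names(out) <- names
  out
}

#' Read a decay or IRF histogram from a two-column text file
#'
#' Columns: time (ns), counts. A header line is detected automatically;
#' whitespace or comma delimited.
#'
#' @param path File path.
#' @return A decay tibble (see [decay_histogram()]).
#' @export
read_decay <- function(path) {
  df <- read_two_column(path, c("time", "counts"))
  decay_histogram(df$time - df$time[1], df$counts)
}

#' Write a decay histogram as two-column text
#' @param decay Decay tibble.
#' @param path Output path.
#' @export
write_decay <- function(decay, path) {
  utils::write.table(decay[, c("time", "counts")], path,
    row.names = FALSE, quote = FALSE, sep = "\t"
  )
  invisible(path)
}

#' Read an emission spectrum from a two-column text file
#'
#' Columns: wavelength (nm), intensity.
#'
#' @param path File path.
#' @return A spectrum tibble (see [emission_spectrum()]).
#' @export
read_spectrum <- function(path) {
  df <- read_two_column(path, c("wavelength", "intensity"))
  emission_spectrum(df$wavelength, pmax(df$intensity, 0))
}

#' Read a titration table
#'
#' Columns: concentration (nM), anisotropy, optional per-point sigma.
#'
#' @param path File path.
#' @return A tibble with columns `conc`, `r` and, when present, `sigma`.
#' @export
read_titration <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\s*[-+0-9.eE]", first)
  df <- utils::read.table(path, header = has_header, sep = "")
  if (ncol(df) == 1) df <- utils::read.table(path, header = has_header, sep = ",")
  out <- as_tibble(df[, seq_len(min(3, ncol(df)))])
  names(out) <- c("conc", "r", "sigma")[seq_len(ncol(out))]
  out
}

#' Write a fit report as JSON
#'
#' Serializes the tidy parameter table and the one-row glance summary of any
#' fitted object in the package (`decay_fit`, `rot_fit`, `hill_fit`,
#' `unmix_fit`).
#'
#' @param fit A fitted object.
#' @param path Output path.
#' @export
write_fit_report <- function(fit, path) {
  report <- list(
    class = class(fit)[1],
    parameters = tidy(fit),
    summary = glance(fit)
  )
  jsonlite::write_json(report, path,
    auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE
  )
  invisible(path)
}

#' Write an ROI trace as delimited text
#' @param trace Tibble from [roi_trace()].
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

tiff_to_array <- function(frames, scale) {
  if (is.matrix(frames)) frames <- list(frames)
  arr <- array(0, c(dim(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (length(dim(fr)) == 3) fr <- fr[, , 1] # collapse grayscale-with-channels
    arr[, , f] <- fr * scale
  }
  arr
}

#' Read a polarized stack from two multi-frame TIFF files
#'
#' The tiff package returns intensities normalized to \[0, 1\]; `scale`
#' restores counts (65535 for 16-bit acquisitions).
#'
#' @param parallel_path,perpendicular_path TIFF file paths.
#' @param scale Count scale (default 16-bit full range).
#' @param frame_interval Frame interval in seconds.
#' @param g,f_corr Correction factors.
#' @return A [polarized_stack()].
#' @export
read_polarized_tiff <- function(parallel_path, perpendicular_path,
                                scale = 65535, frame_interval = 1,
                                g = 1, f_corr = 1) {
  p <- tiff_to_array(tiff::readTIFF(parallel_path, all = TRUE), scale)
  q <- tiff_to_array(tiff::readTIFF(perpendicular_path, all = TRUE), scale)
  polarized_stack(round(p), round(q),
    frame_interval = frame_interval,
    g = g, f_corr = f_corr
  )
}

#' Write a polarized stack to two 16-bit multi-frame TIFF files
#'
#' @param stack A [polarized_stack()].
#' @param parallel_path,perpendicular_path Output paths.
#' @param scale Count scale used for normalization.
#' @export
write_polarized_tiff <- function(stack, parallel_path, perpendicular_path,
                                 scale = 65535) {
  to_frames <- function(arr) {
    lapply(seq_len(dim(arr)[3]), function(f) pmin(arr[, , f] / scale, 1))
  }
  tiff::writeTIFF(to_frames(stack$parallel), parallel_path,
    bits.per.sample = 16
  )
  tiff::writeTIFF(to_frames(stack$perpendicular), perpendicular_path,
    bits.per.sample = 16
  )
  invisible(c(parallel_path, perpendicular_path))
}

#' Write an IMD rendering as an RGB multi-frame TIFF
#'
#' @param imd An `imd_movie` from [imd_render()].
#' @param path Output path.
#' @export
write_imd_tiff <- function(imd, path) {
  frames <- lapply(seq_len(dim(imd)[4]), function(f) {
    unclass(imd)[, , , f] / 255
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 8)
  invisible(path)
}
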