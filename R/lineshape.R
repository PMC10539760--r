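## Two-site chemical-exchange lineshapes.
##
## The transverse magnetization of the coupled sites evolves under
##   dM/dt = L M,   L = [ i*2*pi*nuA - r2A - kAB          kBA
##                        kAB            i*2*pi*nuB - r2B - kBA ]
## with detailed balance kAB = pB*kEx, kBA = pA*kEx. The absorption spectrum
## is Re[ 1' (i*2*pi*nu I - L)^{-1} p ] evaluated on the frequency grid; each
## site contributes a Lorentzian of FWHM r2/pi Hz in the no-exchange limit,
## and the total integral is 1/2 independent of kEx.

#' Simulate a two-site exchange absorption lineshape
#'
#' Closed-form solution of the classical two-site exchange problem (2x2
#' complex linear system per frequency). Covers the whole regime from slow
#' exchange (two Lorentzians) through coalescence to fast exchange (a single
#' line at the population-weighted mean frequency).
#'
#' @param system an \linkS4class{ExchangeSystem}
#' @param grid frequency axis, Hz; must span both site frequencies
#' @return a \linkS4class{Spectrum}
#' @examples
#' sys <- ExchangeSystem(pA = 0.5, nuA = -50, nuB = 50,
#'                       r2A = pi * 2, r2B = pi * 2, kEx = 10)
#' sp <- simulateLineshape(sys, seq(-500, 500, by = 0.5))
#' countMaxima(sp)
#' @export
simulateLineshape <- function(system, grid) {
  stopifnot(is(system, "ExchangeSystem"))
  grid <- as.numeric(grid)
  if (length(grid) < 2)
    stop("frequency grid must contain at least two points")
  if (min(grid) > min(system@nuA, system@nuB) ||
      max(grid) < max(system@nuA, system@nuB))
    stop("frequency grid must cover both site frequencies")
  kAB <- system@pB * system@kEx
  kBA <- system@pA * system@kEx
  a11 <- 2i * pi * system@nuA - system@r2A - kAB
  a22 <- 2i * pi * system@nuB - system@r2B - kBA
  w <- 2i * pi * grid
  ## solve (w I - L) x = p for each frequency; 2x2 closed form
  d11 <- w - a11
  d22 <- w - a22
  det <- d11 * d22 - kAB * kBA
  x1 <- (d22 * system@pA + kBA * system@pB) / det
  x2 <- (kAB * system@pA + d11 * system@pB) / det
  intens <- Re(x1 + x2)
  intens[intens < 0 & intens > -1e-12] <- 0
  Spectrum(grid, intens)
}

#' Full width at half maximum of a spectrum
#'
#' Locates the global maximum and the two half-height crossings bracketing
#' it, interpolating linearly between grid points. When further half-height
#' crossings exist beyond the principal peak (several resolved peaks), the
#' measurement is ambiguous: the default is an error; with
#' \code{perPeak = TRUE} the width of every peak above half the global
#' maximum is returned.
#'
#' @param spectrum a \linkS4class{Spectrum} with a unique global maximum
#' @param perPeak return a data.frame of per-peak widths instead of failing
#'   on multi-peak input
#' @return width in Hz, or a data.frame(position, fwhm) when
#'   \code{perPeak = TRUE}
#' @export
measureFwhm <- function(spectrum, perPeak = FALSE) {
  stopifnot(is(spectrum, "Spectrum"))
  f <- spectrum@freq
  y <- spectrum@intensity
  half <- max(y) / 2
  above <- y > half
  if (!any(above)) stop("spectrum has no intensity above half maximum")
  ## contiguous runs above the half level
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  widthOf <- function(i0, i1) {
    ## interpolate the crossing on each side of the run
    lo <- if (i0 > 1)
      f[i0 - 1] + (half - y[i0 - 1]) / (y[i0] - y[i0 - 1]) * (f[i0] - f[i0 - 1])
    else f[i0]
    hi <- if (i1 < length(f))
      f[i1] + (half - y[i1]) / (y[i1 + 1] - y[i1]) * (f[i1 + 1] - f[i1])
    else f[i1]
    c(pos = f[i0:i1][which.max(y[i0:i1])], fwhm = hi - lo)
  }
  if (nrow(runs) == 1L) {
    return(unname(widthOf(runs[1, 1], runs[1, 2])["fwhm"]))
  }
  if (!perPeak)
    stop("multiple half-height regions: ambiguous FWHM; ",
         "use perPeak = TRUE for per-peak widths")
  out <- t(apply(runs, 1, function(r) widthOf(r[1], r[2])))
  data.frame(position = out[, "pos"], fwhm = out[, "fwhm"])
}

#' Equal-population coalescence rate constant
#'
#' The classical condition at which the two lines of an equally populated
#' exchanging pair merge: \code{k_c = pi * delta_nu / sqrt(2)}, where k is
#' the site-to-site rate constant (kAB = kBA; the quantity EXSY measures).
#' In terms of the total exchange rate of an \linkS4class{ExchangeSystem},
#' coalescence occurs at \code{kEx = 2 * k_c}.
#'
#' @param deltaNu frequency separation of the two sites, Hz (> 0)
#' @return coalescence rate constant, 1/s
#' @examples
#' coalescenceRate(100) # ~222.1 1/s
#' @export
coalescenceRate <- function(deltaNu) {
  if (any(deltaNu <= 0)) stop("deltaNu must be > 0")
  pi * deltaNu / sqrt(2)
}

#' Count local maxima of a spectrum
#'
#' Strict local maxima above a relative intensity threshold; flat-topped
#' plateaus count once.
#'
#' @param spectrum a \linkS4class{Spectrum}
#' @param relThreshold minimum intensity relative to the global maximum
#'   (default 1 percent)
#' @return integer count of maxima
#' @export
countMaxima <- function(spectrum, relThreshold = 0.01) {
  stopifnot(is(spectrum, "Spectrum"))
  y <- spectrum@intensity
  if (all(y <= 0)) return(0L)
  thr <- relThreshold * max(y)
  ## collapse exact plateaus so a flat top counts once
  keep <- c(TRUE, diff(y) != 0)
  yy <- y[keep]
  n <- length(yy)
  if (n < 3) return(if (max(y) > thr) 1L else 0L)
  i <- 2:(n - 1)
  peaks <- yy[i] > yy[i - 1] & yy[i] > yy[i + 1] & yy[i] > thr
  sum(peaks)
}

#' Write a spectrum as two-column CSV
#'
#' @param spectrum a \linkS4class{Spectrum}
#' @param path output file path
#' @return the path, invisibly
#' @export
writeSpectrumCsv <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  utils::write.csv(data.frame(freq_hz = spectrum@freq,
                              intensity = spectrum@intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from two-column CSV
#' @param path file written by \code{\link{writeSpectrumCsv}}
#' @return a \linkS4class{Spectrum}
#' @export
readSpectrumCsv <- function(path) {
  d <- utils::read.csv(path)
  Spectrum(d[[1]], d[[2]])
}

#' Tolerant JCAMP-DX 1D reader
#'
#' Minimal reader for fixed-format (AFFN) \code{##XYDATA=(X++(Y..Y))} 1D
#' blocks, sufficient to compare simulated lineshapes against deposited
#' experimental spectra. Unknown labeled data records are skipped; X and Y
#' factors and FIRSTX/LASTX scaling are honored. Not a writer, and not
#' bit-exact for compressed (DIF/DUP) forms, which are rejected.
#'
#' @param path path to a JCAMP-DX file
#' @return a \linkS4class{Spectrum} (axis ascending)
#' @export
readJcampDx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getNum <- function(label, default = NA_real_) {
    hit <- grep(paste0("^##", label, "="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(".*=", "", hit[1]))
  }
  xf <- getNum("XFACTOR", 1)
  yf <- getNum("YFACTOR", 1)
  npoints <- getNum("NPOINTS")
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA block found")
  form <- sub("^##XYDATA=", "", lines[start[1]], ignore.case = TRUE)
  if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", form))
    stop("only (X++(Y..Y)) XYDATA is supported")
  ends <- grep("^##", lines)
  stopIdx <- ends[ends > start[1]]
  stopIdx <- if (length(stopIdx)) min(stopIdx) - 1 else length(lines)
  block <- lines[(start[1] + 1):stopIdx]
  if (any(grepl("[%@JKLMNOPQRSTUVWXYZjklmnopqrstuvwxyz]", block)))
    stop("compressed (non-AFFN) XYDATA is not supported")
  xs <- numeric(0); ys <- numeric(0)
  for (ln in block) {
    vals <- as.numeric(strsplit(trimws(ln), "[ ,\t]+")[[1]])
    if (length(vals) < 2 || any(is.na(vals))) next
    xs <- c(xs, vals[1])
    ys <- c(ys, vals[-1])
  }
  if (!length(ys)) stop("empty XYDATA block")
  npoints <- if (is.na(npoints)) length(ys) else npoints
  firstx <- getNum("FIRSTX", xs[1] * xf)
  lastx <- getNum("LASTX")
  dx <- if (!is.na(lastx) && npoints > 1) (lastx - firstx) / (npoints - 1)
        else getNum("DELTAX", 1)
  freq <- firstx + dx * (seq_along(ys) - 1)
  intens <- ys * yf
  o <- order(freq)
  Spectrum(freq[o], intens[o])
}
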