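#' Photon emission spectrum of a supported isotope
#'
#' Returns the packaged line spectrum, normalized to unit total probability.
#' Lines below the isotope's transport cutoff energy (5 keV for Pd-103,
#' 10 keV for Cs-137 and Ir-192) are dropped with a warning before
#' normalization. Cs-137 is mono-energetic at 0.6617 MeV; Pd-103 and Ir-192
#' are multi-line spectra shipped as versioned reference data.
#'
#' @param isotope One of `"Pd103"`, `"Ir192"`, `"Cs137"`.
#' @param cutoff_MeV Transport cutoff; defaults to the isotope rule above.
#' @return An `emissionSpectrum`: list with `isotope`, `cutoff_MeV` and the
#'   data frame `lines` (`energy_MeV`, `probability`, summing to 1).
#' @export
spectrumFor <- function(isotope, cutoff_MeV = NULL) {
  supported <- c("Pd103", "Ir192", "Cs137")
  if (!isotope %in% supported)
    stop("unknown isotope '", isotope, "'; supported: ",
         paste(supported, collapse = ", "))
  if (is.null(cutoff_MeV)) cutoff_MeV <- defaultCutoff(isotope)
  path <- system.file("extdata", "spectra", paste0(tolower(isotope), ".csv"),
                      package = "brachyscatter", mustWork = TRUE)
  d <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(d$probability > 0))
  drop <- d$energy_MeV < cutoff_MeV
  if (any(drop)) {
    warning(sprintf("%s: dropping %d emission line(s) below the %g MeV cutoff",
                    isotope, sum(drop), cutoff_MeV))
    d <- d[!drop, , drop = FALSE]
  }
  d$probability <- d$probability / sum(d$probability)
  structure(list(isotope = isotope, cutoff_MeV = cutoff_MeV, lines = d),
            class = "emissionSpectrum")
}

defaultCutoff <- function(isotope) {
  switch(isotope, Pd103 = 0.005, Ir192 = 0.010, Cs137 = 0.010,
         stop("unknown isotope '", isotope, "'"))
}

#' Probability-weighted mean emission energy
#' @param spectrum An [spectrumFor()] result.
#' @return Mean photon energy in MeV.
#' @export
meanEmissionEnergy <- function(spectrum) {
  with(spectrum$lines, sum(energy_MeV * probability))
}

#' @export
print.emissionSpectrum <- function(x, ...) {
  cat(sprintf("<emissionSpectrum> %s: %d line(s), mean %.4f MeV, cutoff %g MeV\n",
              x$isotope, nrow(x$lines), meanEmissionEnergy(x), x$cutoff_MeV))
  invisible(x)
}
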