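#' Photon interaction data for a material
#'
#' Loads the packaged photon cross-section table for a material. Tables hold
#' the mass attenuation coefficient mu/rho, the mass energy-absorption
#' coefficient muen/rho (both cm^2/g) and the partial interaction fractions
#' (photoelectric, incoherent/Compton, coherent/Rayleigh) on a coarse energy
#' grid from 1 keV to 2 MeV, interpolated log-log between nodes.
#'
#' @param material `"water"` or `"dry_air"`.
#' @return An object of class `materialTable`: a list with `name`, `rho`
#'   (g/cm^3), and the data frame `data` (columns `energy_MeV`, `mu_rho`,
#'   `muen_rho`, `f_pe`, `f_compton`, `f_rayleigh`).
#' @export
materialTable <- function(material = c("water", "dry_air")) {
  material <- match.arg(material)
  path <- system.file("extdata", "materials", paste0(material, ".csv"),
                      package = "brachyscatter", mustWork = TRUE)
  d <- utils::read.csv(path, comment.char = "#")
  rho <- if (material == "water") 1.0 else 1.205e-3
  obj <- structure(list(name = material, rho = rho, data = d),
                   class = "materialTable")
  validateMaterialTable(obj)
  obj
}

validateMaterialTable <- function(x) {
  d <- x$data
  stopifnot(all(diff(d$energy_MeV) > 0),
            all(d$mu_rho > 0), all(d$muen_rho > 0),
            all(d$muen_rho <= d$mu_rho))
  f <- d$f_pe + d$f_compton + d$f_rayleigh
  if (any(abs(f - 1) > 1e-6))
    stop("interaction fractions must sum to 1 at every grid energy")
  if (any(d$f_pe < 0 | d$f_pe > 1 | d$f_compton < 0 | d$f_compton > 1 |
            d$f_rayleigh < 0 | d$f_rayleigh > 1))
    stop("interaction fractions must lie in [0, 1]")
  invisible(x)
}

#' @export
print.materialTable <- function(x, ...) {
  cat(sprintf("<materialTable> %s (rho = %g g/cm^3), %d energies %g-%g MeV\n",
              x$name, x$rho, nrow(x$data), min(x$data$energy_MeV),
              max(x$data$energy_MeV)))
  invisible(x)
}

#' Interpolate a mass attenuation or energy-absorption coefficient
#'
#' Log-log interpolation between grid nodes (exact at the nodes), the standard
#' practice for photon cross sections.
#'
#' @param material A [materialTable()].
#' @param energy Photon energy in MeV (vectorized).
#' @param kind `"total"` for mu/rho or `"energy_absorption"` for muen/rho.
#' @return Coefficient(s) in cm^2/g.
#' @export
interpolateMu <- function(material, energy,
                          kind = c("total", "energy_absorption")) {
  kind <- match.arg(kind)
  d <- material$data
  lo <- d$energy_MeV[1]; hi <- d$energy_MeV[nrow(d)]
  if (any(energy < lo | energy > hi))
    stop(sprintf("energy outside the tabulated range [%g, %g] MeV", lo, hi))
  y <- if (kind == "total") d$mu_rho else d$muen_rho
  exp(stats::approx(log(d$energy_MeV), log(y), xout = log(energy),
                    rule = 1)$y)
}

#' Interaction fractions at an energy
#'
#' Linear interpolation of the partial fractions in log-energy, renormalized
#' to sum to one.
#'
#' @inheritParams interpolateMu
#' @return Matrix with columns `pe`, `compton`, `rayleigh`.
#' @export
interactionFractions <- function(material, energy) {
  d <- material$data
  lo <- d$energy_MeV[1]; hi <- d$energy_MeV[nrow(d)]
  if (any(energy < lo | energy > hi))
    stop(sprintf("energy outside the tabulated range [%g, %g] MeV", lo, hi))
  le <- log(d$energy_MeV)
  f <- vapply(c("f_pe", "f_compton", "f_rayleigh"), function(col)
    stats::approx(le, d[[col]], xout = log(energy), rule = 1)$y,
    numeric(length(energy)))
  f <- matrix(f, ncol = 3, dimnames = list(NULL, c("pe", "compton", "rayleigh")))
  f / rowSums(f)
}

#' Sample an interaction channel
#'
#' Chooses photoelectric, Compton or Rayleigh proportionally to the partial
#' interaction fractions at `energy`. A uniform deviate falling exactly on a
#' cumulative boundary is assigned to the upper channel.
#'
#' @inheritParams interpolateMu
#' @param rand Uniform deviates in `[0, 1)`; one channel drawn per deviate.
#'   Defaults to fresh `runif` draws.
#' @return Character vector in `{"photoelectric", "compton", "rayleigh"}`.
#' @export
sampleInteraction <- function(material, energy, rand = stats::runif(1)) {
  stopifnot(all(rand >= 0 & rand < 1))
  f <- interactionFractions(material, energy)
  if (nrow(f) == 1 && length(rand) > 1)
    f <- f[rep(1, length(rand)), , drop = FALSE]
  cum1 <- f[, "pe"]
  cum2 <- f[, "pe"] + f[, "compton"]
  # strict < : a deviate exactly on a cumulative boundary takes the upper channel
  unname(ifelse(rand < cum1, "photoelectric",
                ifelse(rand < cum2, "compton", "rayleigh")))
}
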