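# CSV dialects (exact headers):
#   dose tables:   r_cm, theta_deg, side, dose_per_sk, rel_err
#   g curves:      r_cm, g, rel_err
#   anisotropy:    r_cm, theta_deg, side, F, mask
#   coefficients:  isotope, label, a0..a6, r_min, r_max
#   comparisons:   r_cm, value_a, value_b, pct_diff, convention

#' Write / read a dose-rate table
#' @param table A `doseRateTable`.
#' @param path CSV path.
#' @export
writeDoseTable <- function(table, path) {
  utils::write.csv(table[, c("r_cm", "theta_deg", "side", "dose_per_sk",
                             "rel_err")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDoseTable
#' @param label,isotope Tags restored onto the object (the CSV itself is
#'   dialect-pure).
#' @export
readDoseTable <- function(path, label = "(15, 15)", isotope = NA_character_) {
  d <- utils::read.csv(path, comment.char = "#")
  doseRateTable(d$r_cm, d$theta_deg, d$side, d$dose_per_sk, d$rel_err,
                label = label, isotope = isotope)
}

#' Write / read a radial dose curve
#' @param curve A `radialDoseCurve`.
#' @param path CSV path.
#' @export
writeRadialDoseCurve <- function(curve, path) {
  utils::write.csv(curve[, c("r_cm", "g", "rel_err")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRadialDoseCurve
#' @param label,side,isotope Tags restored onto the object.
#' @export
readRadialDoseCurve <- function(path, label = NA_character_,
                                side = NA_character_,
                                isotope = NA_character_) {
  d <- utils::read.csv(path, comment.char = "#")
  radialDoseCurve(d$r_cm, d$g, d$rel_err, label = label, side = side,
                  isotope = isotope)
}

#' Write an anisotropy grid
#' @param grid An `anisotropyGrid`.
#' @param path CSV path.
#' @export
writeAnisotropyGrid <- function(grid, path) {
  out <- data.frame(r_cm = grid$r_cm, theta_deg = grid$theta_deg,
                    side = grid$side, F = grid$F, mask = grid$masked)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read polynomial coefficient sets
#' @param coeffs A [polyCoefficients()] or list of them.
#' @param path CSV path.
#' @export
writeCoefficients <- function(coeffs, path) {
  if (inherits(coeffs, "polyCoefficients")) coeffs <- list(coeffs)
  rows <- do.call(rbind, lapply(coeffs, function(cf)
    data.frame(isotope = cf$isotope, label = cf$label,
               t(stats::setNames(cf$a, paste0("a", 0:6))),
               r_min = cf$r_min, r_max = cf$r_max)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCoefficients
#' @export
readCoefficients <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  lapply(seq_len(nrow(d)), function(i)
    polyCoefficients(as.numeric(d[i, paste0("a", 0:6)]),
                     isotope = d$isotope[i], label = d$label[i],
                     r_min = d$r_min[i], r_max = d$r_max[i]))
}

#' Write a comparison table
#' @param cmp A `comparisonTable`.
#' @param path CSV path.
#' @export
writeComparisonTable <- function(cmp, path) {
  utils::write.csv(cmp[, c("r_cm", "value_a", "value_b", "pct_diff",
                           "convention")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML with fields `isotope`, `label` (configuration grammar of
#' [parseGeometryLabel()]), `histories`, `seed`, and optionally `cutoff_MeV`,
#' `rayleigh`, `radius_scale`, `tally` (lists `r`, `theta_deg`, `sides`).
#'
#' @param path YAML file.
#' @return List with `source`, `phantom`, `config`, `tally`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("isotope", "label", "histories", "seed"))
    if (is.null(y[[f]])) stop("run config is missing field '", f, "'")
  cfg <- simulationConfig(histories = y$histories, seed = y$seed,
                          cutoff_MeV = y$cutoff_MeV,
                          rayleigh = y$rayleigh %||% TRUE,
                          radiusScale = y$radius_scale %||% 10)
  tally <- NULL
  if (!is.null(y$tally))
    tally <- tallyGrid(unlist(y$tally$r),
                       unlist(y$tally$theta_deg) %||% 90,
                       unlist(y$tally$sides) %||% c("away", "toward"),
                       radiusScale = cfg$radiusScale)
  list(source = sourceModel(y$isotope, cutoff_MeV = y$cutoff_MeV),
       phantom = parseGeometryLabel(y$label),
       config = cfg, tally = tally)
}

#' Write a run manifest
#'
#' Records command, config snapshot, seed, package version, input/output
#' paths and a timestamp next to every output so it stays traceable.
#'
#' @param command Stage name.
#' @param config Config snapshot (list).
#' @param inputs,outputs File paths.
#' @param path Manifest destination (YAML).
#' @export
writeRunManifest <- function(command, config, inputs, outputs, path) {
  man <- list(command = command,
              config = config,
              inputs = as.list(inputs), outputs = as.list(outputs),
              version = as.character(utils::packageVersion("brachyscatter")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(man, path)
  invisible(path)
}
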