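#' Missing-tissue perturbation factor
#'
#' PF(r) = g_shifted(r) / g_full(r): the pointwise ratio of the radial dose
#' function in a shifted (missing-tissue) configuration to the full-scatter
#' reference. Relative errors combine in quadrature. When the grids differ,
#' the full-scatter curve is interpolated (log-linearly) onto the overlapping
#' part of the shifted grid.
#'
#' @param gShifted,gFull `radialDoseCurve` objects; `gFull` should come from
#'   the centered `(15, 15)` configuration.
#' @return A `perturbationCurve` data frame (`r_cm`, `pf`, `rel_err`).
#' @export
perturbationFactor <- function(gShifted, gFull) {
  keep <- gShifted$r_cm >= min(gFull$r_cm) & gShifted$r_cm <= max(gFull$r_cm)
  if (!any(keep)) stop("curves have no overlapping r range")
  gs <- gShifted[keep, , drop = FALSE]
  gf <- interpG(gFull, gs$r_cm)
  if (any(gf <= 0)) stop("zero or negative full-scatter denominator")
  fullErr <- stats::approx(gFull$r_cm, gFull$rel_err, xout = gs$r_cm)$y
  structure(data.frame(r_cm = gs$r_cm, pf = gs$g / gf,
                       rel_err = sqrt(gs$rel_err^2 + fullErr^2)),
            label = attr(gShifted, "label"), side = attr(gShifted, "side"),
            isotope = attr(gShifted, "isotope"),
            class = c("perturbationCurve", "data.frame"))
}

#' @export
print.perturbationCurve <- function(x, ...) {
  cat(sprintf("<perturbationCurve> %s side=%s, %d radii\n",
              attr(x, "label"), attr(x, "side"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Polynomial correction-factor coefficients
#'
#' PF(r) = a0 + a1 r + ... + a6 r^6, r in cm, valid on [r_min, r_max].
#'
#' @param a Numeric vector of up to 7 coefficients (a0 first); zero-padded.
#' @param isotope,label Identification tags.
#' @param r_min,r_max Validity range in cm.
#' @param rmse Residual RMS of the fit that produced the coefficients.
#' @return A `polyCoefficients` object.
#' @export
polyCoefficients <- function(a, isotope = NA_character_,
                             label = NA_character_, r_min = 1, r_max = 10,
                             rmse = NA_real_) {
  if (length(a) > 7) stop("at most degree 6 (7 coefficients)")
  a <- c(a, rep(0, 7 - length(a)))
  stopifnot(r_min < r_max)
  obj <- structure(list(a = a, isotope = isotope, label = label,
                        r_min = r_min, r_max = r_max, rmse = rmse),
                   class = "polyCoefficients")
  v1 <- evaluatePolynomial(obj, max(r_min, min(1, r_max)))
  if (v1 < 0.9 || v1 > 1.1)
    warning(sprintf("polynomial evaluates to %.3f near r = 1 cm; expected close to 1",
                    v1))
  obj
}

#' @export
print.polyCoefficients <- function(x, ...) {
  cat(sprintf("<polyCoefficients> %s %s: degree %d, valid [%g, %g] cm\n",
              x$isotope, x$label, max(which(x$a != 0)) - 1, x$r_min, x$r_max))
  print(stats::setNames(x$a, paste0("a", 0:6)))
  invisible(x)
}

#' Packaged polynomial correction factors
#'
#' Loads the published degree-<=6 polynomial fits of the transverse
#' missing-tissue perturbation factor, keyed by isotope and configuration
#' label (e.g. `"(25+5)"` for 5 cm overlying water / 10 cm missing tissue).
#' Each set is valid from 1 cm up to its overlying thickness.
#'
#' @param isotope Optional isotope filter.
#' @param label Optional configuration label filter.
#' @return A list of [polyCoefficients()] (or a single object when both
#'   filters are given).
#' @export
perturbationPolynomials <- function(isotope = NULL, label = NULL) {
  path <- system.file("extdata", "reference", "perturbation_polynomials.csv",
                      package = "brachyscatter", mustWork = TRUE)
  d <- utils::read.csv(path, comment.char = "#")
  if (!is.null(isotope)) d <- d[d$isotope == isotope, , drop = FALSE]
  if (!is.null(label)) d <- d[d$label == label, , drop = FALSE]
  if (nrow(d) == 0) stop("no packaged polynomial for that isotope/label")
  out <- lapply(seq_len(nrow(d)), function(i)
    polyCoefficients(as.numeric(d[i, paste0("a", 0:6)]),
                     isotope = d$isotope[i], label = d$label[i],
                     r_min = d$r_min[i], r_max = d$r_max[i]))
  if (!is.null(isotope) && !is.null(label) && length(out) == 1) out[[1]]
  else out
}

#' Evaluate a correction polynomial
#'
#' Horner (nested) evaluation; queries outside the validity range raise an
#' error rather than extrapolating a high-degree fit.
#'
#' @param coeffs A [polyCoefficients()].
#' @param r Radii in cm.
#' @return PF values.
#' @export
evaluatePolynomial <- function(coeffs, r) {
  if (any(r < coeffs$r_min | r > coeffs$r_max))
    stop(sprintf("r outside the polynomial validity range [%g, %g] cm",
                 coeffs$r_min, coeffs$r_max))
  a <- coeffs$a
  out <- rep(a[7], length(r))
  for (k in 6:1) out <- out * r + a[k]
  out
}

#' Apply a missing-tissue correction to a full-scatter curve
#'
#' g_shifted(r) = PF(r) x g_full(r): the algebraic inverse of
#' [perturbationFactor()].
#'
#' @param gFull A full-scatter `radialDoseCurve`.
#' @param pf A `perturbationCurve` (matched/interpolated on r) or
#'   [polyCoefficients()] (evaluated on r; errors outside validity).
#' @return The corrected `radialDoseCurve`.
#' @export
applyCorrection <- function(gFull, pf) {
  if (inherits(pf, "polyCoefficients")) {
    fac <- evaluatePolynomial(pf, gFull$r_cm)
    facErr <- 0
    lab <- pf$label
  } else {
    keep <- gFull$r_cm >= min(pf$r_cm) & gFull$r_cm <= max(pf$r_cm)
    if (!any(keep)) stop("no overlap between curve and perturbation factor")
    gFull <- gFull[keep, , drop = FALSE]
    fac <- exp(stats::approx(pf$r_cm, log(pf$pf), xout = gFull$r_cm)$y)
    facErr <- stats::approx(pf$r_cm, pf$rel_err, xout = gFull$r_cm)$y
    lab <- attr(pf, "label")
  }
  radialDoseCurve(gFull$r_cm, gFull$g * fac,
                  sqrt(gFull$rel_err^2 + facErr^2),
                  label = lab, side = attr(gFull, "side"),
                  isotope = attr(gFull, "isotope"))
}

#' Least-squares polynomial fit of a perturbation curve
#'
#' Fits PF(r) with increasing degree and keeps the smallest degree whose
#' residual RMS improvement over the next degree is below 10% (the packaged
#' reference fits use degrees 3-6).
#'
#' @param curve A `perturbationCurve` (columns `r_cm`, `pf`).
#' @param max_degree At most 6.
#' @return A [polyCoefficients()] with the residual RMS in `$rmse` and the
#'   curve's r range as validity.
#' @export
fitPolynomial <- function(curve, max_degree = 6) {
  stopifnot(max_degree >= 1, max_degree <= 6)
  r <- curve$r_cm; y <- curve$pf
  if (length(r) < max_degree + 1)
    stop("need at least max_degree + 1 points")
  fits <- list(); rms <- numeric(max_degree)
  for (d in seq_len(max_degree)) {
    X <- outer(r, 0:d, `^`)
    f <- tryCatch(stats::lsfit(X, y, intercept = FALSE),
                  error = function(e)
                    stop("ill-conditioned design; reduce the degree"))
    fits[[d]] <- f$coefficients
    rms[d] <- sqrt(mean(f$residuals^2))
    if (rms[d] < 1e-12) break
  }
  dmax <- length(fits)
  pick <- dmax
  for (d in seq_len(dmax - 1)) {
    if (rms[d] < 1e-12 || (rms[d] - rms[d + 1]) / rms[d] < 0.10) {
      pick <- d
      break
    }
  }
  polyCoefficients(unname(fits[[pick]]), isotope = attr(curve, "isotope"),
                   label = attr(curve, "label"),
                   r_min = min(r), r_max = max(r), rmse = rms[pick])
}

#' Percent difference under an explicit denominator convention
#'
#' The published comparisons use three different denominators, encoded as
#' tags: `"sides"` = 100 (away - toward) / away; `"vs_full"` =
#' 100 (full - shifted) / full; `"vs_shifted"` = 100 |full - shifted| /
#' shifted. Results are rounded to `digits` decimals (report precision).
#'
#' @param a First value: the away-side or full-scatter quantity.
#' @param b Second value: the toward-side or shifted-configuration quantity.
#' @param convention One of `"sides"`, `"vs_full"`, `"vs_shifted"`.
#' @param digits Rounding for report output (default 2).
#' @return Percent difference(s).
#' @export
percentDifference <- function(a, b, convention = c("sides", "vs_full",
                                                   "vs_shifted"),
                              digits = 2) {
  if (length(convention) > 1) convention <- convention[1]
  if (!convention %in% c("sides", "vs_full", "vs_shifted"))
    stop("unknown percent-difference convention '", convention, "'")
  stopifnot(all(a > 0), all(b > 0))
  pct <- switch(convention,
                sides = 100 * (a - b) / a,
                vs_full = 100 * (a - b) / a,
                vs_shifted = 100 * abs(a - b) / b)
  round(pct, digits)
}

#' Tabulated comparison of dose-function curves
#'
#' Builds the per-radius comparison rows (reference value, shifted value,
#' percent difference) for a set of curves against a reference curve.
#'
#' @param curves Named list of `radialDoseCurve`s (names = configuration
#'   labels), or a single `doseRateTable` for a `"sides"` comparison (away vs
#'   toward on the transverse axis).
#' @param reference Label of the reference curve (for `"vs_full"` /
#'   `"vs_shifted"`), ignored for `"sides"`.
#' @param convention See [percentDifference()].
#' @param source Needed only when `curves` is a `doseRateTable`.
#' @return A `comparisonTable` data frame (`label`, `r_cm`, `value_a`,
#'   `value_b`, `pct_diff`, `convention`).
#' @export
buildComparisonReport <- function(curves, reference = "(15, 15)",
                                  convention = "vs_full", source = NULL) {
  if (inherits(curves, "doseRateTable")) {
    if (is.null(source)) stop("a sourceModel is required for a sides report")
    ga <- radialDoseFunction(curves, source, "away")
    gt <- radialDoseFunction(curves, source, "toward")
    curves <- list(away = ga, toward = gt)
    convention <- "sides"
  }
  if (convention == "sides") {
    a <- curves[["away"]]; b <- curves[["toward"]]
    if (is.null(a) || is.null(b)) stop("sides comparison needs 'away' and 'toward' curves")
    rr <- intersect(a$r_cm, b$r_cm)
    out <- data.frame(label = attr(a, "label") %||% "sides",
                      r_cm = rr,
                      value_a = a$g[match(rr, a$r_cm)],
                      value_b = b$g[match(rr, b$r_cm)])
  } else {
    if (!reference %in% names(curves))
      stop("reference configuration '", reference, "' missing from curves")
    ref <- curves[[reference]]
    others <- curves[setdiff(names(curves), reference)]
    out <- do.call(rbind, lapply(names(others), function(nm) {
      cc <- others[[nm]]
      rr <- intersect(ref$r_cm, cc$r_cm)
      data.frame(label = nm, r_cm = rr,
                 value_a = ref$g[match(rr, ref$r_cm)],
                 value_b = cc$g[match(rr, cc$r_cm)])
    }))
  }
  out$pct_diff <- percentDifference(out$value_a, out$value_b, convention)
  out$convention <- convention
  structure(out, class = c("comparisonTable", "data.frame"))
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1 && is.na(x))) y else x
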