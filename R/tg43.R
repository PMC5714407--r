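#' Brachytherapy source model
#'
#' Simplified source geometries: a bare active line for Pd-103 (effective
#' active length 0.455 cm) and Ir-192 (0.5 cm), and a train of spherical
#' active/dummy pellets for the Cs-137 LDR source (default pattern
#' `"NANAANAN"`, 0.25 cm pitch, effective active length 1.5 cm). The TG-43
#' reference point is (r0 = 1 cm, theta0 = pi/2).
#'
#' @param isotope `"Pd103"`, `"Ir192"` or `"Cs137"`.
#' @param activeLength Active length L in cm; default per isotope.
#' @param pellets For Cs137, a string of `"A"` (active) / `"N"` (dummy)
#'   pellets laid along the source axis at `pelletPitch` spacing.
#' @param pelletPitch Pellet center-to-center distance, cm.
#' @param cutoff_MeV Photon transport cutoff; default 5 keV for Pd-103 and
#'   10 keV for Ir-192/Cs-137.
#' @return A `sourceModel` object.
#' @export
sourceModel <- function(isotope, activeLength = NULL, pellets = NULL,
                        pelletPitch = 0.25, cutoff_MeV = NULL) {
  supported <- c("Pd103", "Ir192", "Cs137")
  if (!isotope %in% supported)
    stop("unknown isotope '", isotope, "'; supported: ",
         paste(supported, collapse = ", "))
  if (is.null(cutoff_MeV)) cutoff_MeV <- defaultCutoff(isotope)
  if (isotope == "Cs137" && is.null(pellets)) pellets <- "NANAANAN"
  pelletZ <- NULL
  if (!is.null(pellets)) {
    flags <- strsplit(pellets, "")[[1]]
    if (!all(flags %in% c("A", "N")))
      stop("pellet pattern must contain only 'A' and 'N'")
    n <- length(flags)
    z <- (seq_len(n) - (n + 1) / 2) * pelletPitch
    pelletZ <- z[flags == "A"]
    if (length(pelletZ) == 0) stop("pellet pattern has no active pellet")
    if (is.null(activeLength))
      activeLength <- diff(range(pelletZ)) + pelletPitch
  }
  if (is.null(activeLength))
    activeLength <- switch(isotope, Pd103 = 0.455, Ir192 = 0.5, Cs137 = 1.5)
  stopifnot(activeLength >= 0)  # 0 = point-source limit
  r0 <- 1
  if (r0 <= activeLength / 2)
    stop("reference radius r0 = 1 cm must exceed L/2")
  structure(list(isotope = isotope, L = activeLength, pelletZ = pelletZ,
                 spectrum = spectrumFor(isotope, cutoff_MeV),
                 cutoff_MeV = cutoff_MeV, r0 = r0, theta0 = pi / 2),
            class = "sourceModel")
}

#' @export
print.sourceModel <- function(x, ...) {
  cat(sprintf("<sourceModel> %s, L = %.3f cm%s, %d emission line(s)\n",
              x$isotope, x$L,
              if (!is.null(x$pelletZ))
                sprintf(", %d active pellet(s)", length(x$pelletZ)) else "",
              nrow(x$spectrum$lines)))
  invisible(x)
}

#' TG-43 line-source geometry function
#'
#' GL(r, theta) = beta / (L r sin theta) off-axis, with beta the angle
#' subtended at P(r, theta) by the active line; on the long axis
#' (sin theta = 0) it is (r^2 - L^2/4)^-1. beta is obtained from the two
#' active-line endpoint vectors, which reduces to
#' `atan2(L r sin(theta), r^2 - L^2/4)` and is numerically robust near the
#' line extension.
#'
#' @param r Radial distance(s), cm; must be positive.
#' @param theta Polar angle(s) from the source long axis, radians, in [0, pi].
#' @param L Active length, cm.
#' @return GL in cm^-2 (vectorized over `r`/`theta`).
#' @export
geometryFunction <- function(r, theta, L) {
  stopifnot(L >= 0)
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  if (any(r <= 0)) stop("r must be positive")
  if (any(theta < 0 | theta > pi)) stop("theta must lie in [0, pi]")
  s <- sin(theta)
  onAxis <- s < 1e-12
  if (any(onAxis & r <= L / 2))
    stop("on-axis geometry function requires r > L/2")
  out <- numeric(n)
  if (L == 0) return(1 / r^2)
  # beta from the endpoint vectors v_i = P - (0, 0, +/- L/2):
  # cross(v1, v2) = L r sin(theta), dot(v1, v2) = r^2 - L^2/4
  beta <- atan2(L * r * s, r^2 - L^2 / 4)
  out[!onAxis] <- beta[!onAxis] / (L * r[!onAxis] * s[!onAxis])
  out[onAxis] <- 1 / (r[onAxis]^2 - L^2 / 4)
  out
}

#' Dose-rate table
#'
#' The central tabular container: one row per tally point, identified by
#' radius, polar angle and a side tag (`"away"` / `"toward"` the missing
#' tissue).
#'
#' @param r_cm,theta_deg,side,dose_per_sk,rel_err Columns (recycled).
#' @param label Phantom configuration label, e.g. `"(15, 15)"`.
#' @param isotope Isotope label carried as an attribute.
#' @return A data frame of class `doseRateTable`.
#' @export
doseRateTable <- function(r_cm, theta_deg, side, dose_per_sk, rel_err = 0,
                          label = "(15, 15)", isotope = NA_character_) {
  d <- data.frame(r_cm = r_cm, theta_deg = theta_deg, side = side,
                  dose_per_sk = dose_per_sk, rel_err = rel_err)
  stopifnot(all(d$r_cm > 0), all(d$theta_deg >= 0 & d$theta_deg <= 180),
            all(d$dose_per_sk >= 0), all(d$rel_err >= 0))
  structure(d, label = label, isotope = isotope,
            class = c("doseRateTable", "data.frame"))
}

refSample <- function(table, side, r0 = 1) {
  i <- which(table$theta_deg == 90 & table$side == side &
               abs(table$r_cm - r0) < 1e-9)
  if (length(i) == 0)
    stop("dose table lacks the reference sample at r0 = ", r0,
         " cm, theta = 90 deg, side '", side, "'")
  table[i[1], ]
}

#' Radial dose function g_L(r)
#'
#' g_L(r) = D(r, pi/2) G_L(r0, pi/2) / (D(r0, pi/2) G_L(r, pi/2)), normalized
#' to 1 at the reference radius r0 = 1 cm using the exact r0 sample (no
#' interpolation at the reference point).
#'
#' @param table A [doseRateTable()].
#' @param source A [sourceModel()] (supplies the active length).
#' @param side Which side of the source to extract, `"away"` or `"toward"`.
#' @return A `radialDoseCurve` data frame (`r_cm`, `g`, `rel_err`).
#' @export
radialDoseFunction <- function(table, source, side = "away") {
  tr <- table[table$theta_deg == 90 & table$side == side, , drop = FALSE]
  if (nrow(tr) == 0) stop("no transverse-axis (theta = 90) samples on side '",
                          side, "'")
  ref <- refSample(table, side, source$r0)
  if (ref$dose_per_sk <= 0) stop("zero dose rate at the reference point")
  gl <- geometryFunction(tr$r_cm, pi / 2, source$L)
  gl0 <- geometryFunction(source$r0, pi / 2, source$L)
  g <- (tr$dose_per_sk / ref$dose_per_sk) * (gl0 / gl)
  rel <- sqrt(tr$rel_err^2 + ref$rel_err^2)
  rel[abs(tr$r_cm - source$r0) < 1e-9] <- 0
  ord <- order(tr$r_cm)
  radialDoseCurve(tr$r_cm[ord], g[ord], rel[ord],
                  label = attr(table, "label"), side = side,
                  isotope = attr(table, "isotope"))
}

#' Radial dose curve container
#' @param r_cm,g,rel_err Columns; `r_cm` strictly increasing, `g > 0`.
#' @param label,side,isotope Provenance attributes.
#' @export
radialDoseCurve <- function(r_cm, g, rel_err = 0, label = NA_character_,
                            side = NA_character_, isotope = NA_character_) {
  stopifnot(all(diff(r_cm) > 0), all(g > 0))
  structure(data.frame(r_cm = r_cm, g = g, rel_err = rel_err),
            label = label, side = side, isotope = isotope,
            class = c("radialDoseCurve", "data.frame"))
}

#' @export
print.radialDoseCurve <- function(x, ...) {
  cat(sprintf("<radialDoseCurve> %s side=%s, %d radii %g-%g cm\n",
              attr(x, "label"), attr(x, "side"), nrow(x), min(x$r_cm),
              max(x$r_cm)))
  print.data.frame(x, ...)
  invisible(x)
}

#' 2D anisotropy function F(r, theta)
#'
#' F(r, theta) = D(r, theta) G_L(r, pi/2) / (D(r, pi/2) G_L(r, theta)), equal
#' to 1 on the transverse axis by construction. When a `phantom` is supplied,
#' grid points whose tally position lies outside the phantom are masked
#' (`F = NA`, `masked = TRUE`), never extrapolated.
#'
#' @inheritParams radialDoseFunction
#' @param phantom Optional [phantomConfig()] used to mask out-of-phantom
#'   points.
#' @return An `anisotropyGrid` data frame (`r_cm`, `theta_deg`, `side`, `F`,
#'   `rel_err`, `masked`).
#' @export
anisotropyFunction <- function(table, source, phantom = NULL) {
  sides <- unique(table$side)
  out <- lapply(sides, function(sd) {
    ts <- table[table$side == sd, , drop = FALSE]
    rr <- unique(ts$r_cm)
    tx <- ts[ts$theta_deg == 90, , drop = FALSE]
    if (any(!rr %in% tx$r_cm))
      stop("anisotropy function needs a theta = 90 sample at every radius")
    den <- tx$dose_per_sk[match(ts$r_cm, tx$r_cm)]
    denErr <- tx$rel_err[match(ts$r_cm, tx$r_cm)]
    th <- ts$theta_deg * pi / 180
    f <- (ts$dose_per_sk / den) *
      (geometryFunction(ts$r_cm, pi / 2, source$L) /
         geometryFunction(ts$r_cm, th, source$L))
    rel <- sqrt(ts$rel_err^2 + denErr^2)
    rel[ts$theta_deg == 90] <- 0
    masked <- rep(FALSE, nrow(ts))
    if (!is.null(phantom)) {
      pos <- tallyPosition(ts$r_cm, ts$theta_deg, ts$side, phantom)
      masked <- !insidePhantom(pos, phantom)
    }
    f[masked] <- NA_real_
    data.frame(r_cm = ts$r_cm, theta_deg = ts$theta_deg, side = sd,
               F = f, rel_err = rel, masked = masked)
  })
  d <- do.call(rbind, out)
  d <- d[order(d$side, d$r_cm, d$theta_deg), ]
  rownames(d) <- NULL
  structure(d, label = attr(table, "label"), isotope = attr(table, "isotope"),
            class = c("anisotropyGrid", "data.frame"))
}

#' Air-kerma strength container
#' @param sk Air-kerma strength (kerma x distance^2 per history, or U).
#' @param rel_err Relative standard error of `sk`.
#' @param diagnostics Per-distance `kerma * d^2` table from the fitting run.
#' @export
airKermaStrength <- function(sk, rel_err = 0, diagnostics = NULL) {
  stopifnot(sk > 0, rel_err >= 0)
  structure(list(sk = sk, rel_err = rel_err, diagnostics = diagnostics),
            class = "airKermaStrength")
}

#' @export
print.airKermaStrength <- function(x, ...) {
  cat(sprintf("<airKermaStrength> SK = %.6g (rel err %.2g%%)\n",
              x$sk, 100 * x$rel_err))
  invisible(x)
}

#' Dose rate constant
#'
#' Lambda = D(1 cm, pi/2) / SK, with relative standard errors combined in
#' quadrature. With both sides tabulated at the reference point their mean is
#' used.
#'
#' @inheritParams radialDoseFunction
#' @param sk An [airKermaStrength()].
#' @return A `doseRateConstant` (list: `lambda`, `rel_err`, `label`).
#' @export
doseRateConstant <- function(table, sk) {
  if (inherits(sk, "airKermaStrength")) {
    skv <- sk$sk; ske <- sk$rel_err
  } else {
    skv <- sk; ske <- 0
  }
  stopifnot(skv > 0)
  i <- which(table$theta_deg == 90 & abs(table$r_cm - 1) < 1e-9)
  if (length(i) == 0)
    stop("dose table lacks the reference sample at r = 1 cm, theta = 90 deg")
  d <- mean(table$dose_per_sk[i])
  rel <- sqrt(mean(table$rel_err[i])^2 / length(i) + ske^2)
  structure(list(lambda = d / skv, rel_err = rel,
                 label = attr(table, "label")),
            class = "doseRateConstant")
}

#' @export
print.doseRateConstant <- function(x, ...) {
  cat(sprintf("<doseRateConstant> %s: Lambda = %.4g (rel err %.2g%%)\n",
              x$label, x$lambda, 100 * x$rel_err))
  invisible(x)
}

interpG <- function(curve, r) {
  lo <- min(curve$r_cm); hi <- max(curve$r_cm)
  if (any(r < lo | r > hi))
    stop(sprintf("r outside the tabulated g(r) range [%g, %g] cm", lo, hi))
  # log-linear in r (TG-43U1 practice); exact at nodes
  exp(stats::approx(curve$r_cm, log(curve$g), xout = r)$y)
}

interpF <- function(grid, r, theta_deg, side) {
  g <- grid[grid$side == side & !grid$masked, , drop = FALSE]
  if (nrow(g) == 0) stop("no anisotropy samples on side '", side, "'")
  rs <- sort(unique(g$r_cm)); ths <- sort(unique(g$theta_deg))
  if (r < min(rs) || r > max(rs) || theta_deg < min(ths) || theta_deg > max(ths))
    stop("(r, theta) outside the tabulated anisotropy grid")
  ri <- findInterval(r, rs, rightmost.closed = TRUE)
  ti <- findInterval(theta_deg, ths, rightmost.closed = TRUE)
  r1 <- rs[ri]; r2 <- rs[min(ri + 1, length(rs))]
  t1 <- ths[ti]; t2 <- ths[min(ti + 1, length(ths))]
  fx <- function(rv, tv) {
    i <- which(g$r_cm == rv & g$theta_deg == tv)
    if (length(i) == 0) stop("anisotropy grid has a hole at the query point")
    g$F[i[1]]
  }
  wr <- if (r2 > r1) (r - r1) / (r2 - r1) else 0
  wt <- if (t2 > t1) (theta_deg - t1) / (t2 - t1) else 0
  (1 - wr) * ((1 - wt) * fx(r1, t1) + wt * fx(r1, t2)) +
    wr * ((1 - wt) * fx(r2, t1) + wt * fx(r2, t2))
}

#' Reconstruct a dose rate from TG-43 components
#'
#' D(r, theta) = Lambda SK [G_L(r, theta) / G_L(r0, theta0)] g_L(r)
#' F(r, theta), with g interpolated log-linearly in r and F bilinearly in
#' (r, theta). Queries outside the tabulated grids raise an error.
#'
#' @param source A [sourceModel()].
#' @param lambda A `doseRateConstant` or bare number.
#' @param g A `radialDoseCurve`.
#' @param F An `anisotropyGrid` (or `NULL` to assume F = 1).
#' @param sk An [airKermaStrength()] or bare number.
#' @param r,theta_deg Query point; `side` selects the anisotropy branch.
#' @return Dose rate in the units of `lambda * sk`.
#' @export
reconstructDoseRate <- function(source, lambda, g, F = NULL, sk = 1,
                                r, theta_deg = 90, side = "away") {
  lam <- if (inherits(lambda, "doseRateConstant")) lambda$lambda else lambda
  skv <- if (inherits(sk, "airKermaStrength")) sk$sk else sk
  glr <- geometryFunction(r, theta_deg * pi / 180, source$L)
  gl0 <- geometryFunction(source$r0, source$theta0, source$L)
  fv <- if (is.null(F)) 1 else interpF(F, r, theta_deg, side)
  lam * skv * (glr / gl0) * interpG(g, r) * fv
}
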