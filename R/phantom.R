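#' Cubical water phantom with a shifted source
#'
#' A 30x30x30 cm^3 water cube surrounded by vacuum, with the source either at
#' the center (full scattering, label `"(15, 15)"`) or shifted toward one face
#' along its transverse axis (`"H"`) or longitudinal axis (`"V"`), leaving
#' `overlying` cm of water between the source and the near face. The missing
#' tissue is `15 - overlying` cm. The source sits at the coordinate origin;
#' a transverse shift puts the near face at `x = -overlying`, a longitudinal
#' shift at `z = -overlying`, so the `"toward"` side looks down the negative
#' axis.
#'
#' @param label A configuration label such as `"(15, 15)"`, `"H(25, 5)"`,
#'   `"V(28, 2)"`; parsed with [parseGeometryLabel()]. Alternatively give
#'   `axis` and `overlying`.
#' @param axis `"none"`, `"H"` (transverse) or `"V"` (longitudinal).
#' @param overlying Overlying water thickness x (or y) in cm, 0 < x <= 15.
#' @param side_cm Cube side, default 30.
#' @return A `phantomConfig` object with cube bounds `lo`, `hi` (cm).
#' @export
phantomConfig <- function(label = NULL, axis = c("none", "H", "V"),
                          overlying = 15, side_cm = 30) {
  if (!is.null(label)) return(parseGeometryLabel(label, side_cm))
  axis <- match.arg(axis)
  if (axis == "none") overlying <- side_cm / 2
  half <- side_cm / 2
  if (overlying <= 0 || overlying > half)
    stop("overlying thickness must lie in (0, ", half, "]")
  lo <- c(-half, -half, -half); hi <- c(half, half, half)
  if (axis == "H") { lo[1] <- -overlying; hi[1] <- side_cm - overlying }
  if (axis == "V") { lo[3] <- -overlying; hi[3] <- side_cm - overlying }
  lab <- if (axis == "none") sprintf("(%g, %g)", half, half)
  else sprintf("%s(%g, %g)", axis, side_cm - overlying, overlying)
  structure(list(label = lab, axis = axis, overlying = overlying,
                 missing = half - overlying, side_cm = side_cm,
                 lo = lo, hi = hi),
            class = "phantomConfig")
}

#' Parse a phantom configuration label
#'
#' Grammar: `"(15, 15)"` for the centered source, or `"H(a, x)"` / `"V(a, x)"`
#' with `a + x = 30` and `0 < x <= 15` for transverse / longitudinal shifts,
#' e.g. `"H(25, 5)"` or `"V(28, 2)"`.
#'
#' @param label Label string.
#' @param side_cm Cube side, default 30.
#' @return A [phantomConfig()].
#' @export
parseGeometryLabel <- function(label, side_cm = 30) {
  m <- regmatches(label,
                  regexec("^\\s*([HV]?)\\s*\\(\\s*([0-9.]+)\\s*,\\s*([0-9.]+)\\s*\\)\\s*$",
                          label))[[1]]
  if (length(m) == 0)
    stop("invalid configuration label '", label,
         "': expected \"(15, 15)\" or \"H(25, 5)\" / \"V(28, 2)\" style")
  axis <- if (m[2] == "") "none" else m[2]
  a <- as.numeric(m[3]); x <- as.numeric(m[4])
  if (abs(a + x - side_cm) > 1e-9)
    stop("label '", label, "' inconsistent: thicknesses must sum to ", side_cm)
  if (axis == "none" && abs(x - side_cm / 2) > 1e-9)
    stop("a centered label must be (", side_cm / 2, ", ", side_cm / 2, ")")
  phantomConfig(axis = axis, overlying = x, side_cm = side_cm)
}

#' @export
print.phantomConfig <- function(x, ...) {
  cat(sprintf("<phantomConfig> %s: %g cm cube, axis %s, overlying %g cm, missing %g cm\n",
              x$label, x$side_cm, x$axis, x$overlying, x$missing))
  invisible(x)
}

#' Cartesian tally position for (r, theta, side)
#'
#' Maps polar tally coordinates to Cartesian positions in the source frame.
#' Theta is measured from the source long axis (+z); the `"toward"` side flips
#' the coordinate pointing at the missing tissue (x for transverse shifts,
#' z for longitudinal shifts; x by convention for the centered phantom).
#'
#' @param r_cm,theta_deg,side Vectors (recycled).
#' @param phantom A [phantomConfig()].
#' @return A 3-column matrix (x, y, z) in cm.
#' @export
tallyPosition <- function(r_cm, theta_deg, side, phantom) {
  n <- max(length(r_cm), length(theta_deg), length(side))
  r <- rep_len(r_cm, n); th <- rep_len(theta_deg, n) * pi / 180
  sd <- rep_len(side, n)
  s <- ifelse(sd == "toward", -1, 1)
  if (phantom$axis == "V")
    cbind(x = r * sin(th), y = 0, z = s * r * cos(th))
  else
    cbind(x = s * r * sin(th), y = 0, z = r * cos(th))
}

#' Test whether points lie inside the phantom
#' @param pos 3-column matrix of positions (cm).
#' @param phantom A [phantomConfig()].
#' @return Logical vector; faces are inclusive.
#' @export
insidePhantom <- function(pos, phantom) {
  pos <- matrix(pos, ncol = 3)
  pos[, 1] >= phantom$lo[1] & pos[, 1] <= phantom$hi[1] &
    pos[, 2] >= phantom$lo[2] & pos[, 2] <= phantom$hi[2] &
    pos[, 3] >= phantom$lo[3] & pos[, 3] <= phantom$hi[3]
}
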