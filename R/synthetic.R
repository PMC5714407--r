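#' Specification for synthetic tally-like dose tables
#'
#' Analytic stand-ins for the full-scatter radial dose function of each
#' isotope (fixtures, not physics claims — calibrated loosely to published
#' full-scatter columns): near-flat slow decline for Cs-137, rise-then-decline
#' for Ir-192, steep quasi-exponential decline for Pd-103. Noise is
#' multiplicative Gaussian with sigma(r) growing linearly to `noiseSigma10`
#' at 10 cm (<= 0.5%, the precision of the reference simulations), independent
#' across cells. An injected perturbation multiplies the toward side only.
#'
#' @param isotope `"Pd103"`, `"Ir192"` or `"Cs137"`.
#' @param gModel Full-scatter g(r) function; default per isotope.
#' @param fModel Anisotropy model F(r, theta_deg); default a mild
#'   sin-theta dip, 1 on the transverse axis.
#' @param noiseSigma10 Relative standard deviation at 10 cm (default 0.005).
#' @param perturbation `NULL` (none), a function PF(r), or a
#'   [polyCoefficients()] applied on the `"toward"` side.
#' @param seed RNG seed recorded in the spec and used by
#'   [generateDoseTable()].
#' @return A `syntheticSpec`.
#' @export
syntheticSpec <- function(isotope, gModel = NULL, fModel = NULL,
                          noiseSigma10 = 0.005, perturbation = NULL,
                          seed = 1) {
  stopifnot(noiseSigma10 >= 0, noiseSigma10 <= 0.005)
  if (is.null(gModel)) gModel <- defaultGModel(isotope)
  if (is.null(fModel))
    fModel <- function(r, theta_deg) 1 - 0.15 * (1 - sin(theta_deg * pi / 180))
  structure(list(isotope = isotope, gModel = gModel, fModel = fModel,
                 noiseSigma10 = noiseSigma10, perturbation = perturbation,
                 seed = seed),
            class = "syntheticSpec")
}

defaultGModel <- function(isotope) {
  switch(isotope,
         Cs137 = function(r) exp(-0.008 * (r - 1) - 0.0009 * (r - 1)^2),
         Ir192 = function(r) {
           u <- function(r) (1 + 0.12 * r) * exp(-0.085 * r)
           u(r) / u(1)
         },
         Pd103 = function(r) exp(-0.57 * (r - 1) - 0.005 * (r - 1)^2),
         stop("unknown isotope '", isotope, "'"))
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic dose-rate table
#'
#' Dose = G_L(r, theta) x g(r) x F(r, theta) x PF(r on the toward side) x
#' (1 + sigma(r) N(0,1)); reproducible from the spec's seed. Pushing the
#' result through [radialDoseFunction()] recovers the analytic g model
#' exactly at zero noise.
#'
#' @param spec A [syntheticSpec()].
#' @param grid Data frame with `r_cm`, `theta_deg`, `side` (default a
#'   two-sided transverse grid at 1-10 cm).
#' @param source A [sourceModel()]; default built from the spec's isotope.
#' @param label Configuration label to tag the table with.
#' @return A `doseRateTable`.
#' @export
generateDoseTable <- function(spec, grid = NULL, source = NULL,
                              label = "(15, 15)") {
  if (is.null(source)) source <- sourceModel(spec$isotope)
  if (is.null(grid))
    grid <- expand.grid(r_cm = 1:10, theta_deg = 90,
                        side = c("away", "toward"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gl <- geometryFunction(grid$r_cm, grid$theta_deg * pi / 180, source$L)
  g <- spec$gModel(grid$r_cm)
  f <- spec$fModel(grid$r_cm, grid$theta_deg)
  pf <- rep(1, nrow(grid))
  if (!is.null(spec$perturbation)) {
    tw <- grid$side == "toward"
    pf[tw] <- if (inherits(spec$perturbation, "polyCoefficients"))
      evaluatePolynomial(spec$perturbation, grid$r_cm[tw])
    else spec$perturbation(grid$r_cm[tw])
  }
  sigma <- spec$noiseSigma10 * grid$r_cm / 10
  noise <- withSeed(spec$seed, stats::rnorm(nrow(grid)))
  dose <- gl * g * f * pf * (1 + sigma * noise)
  doseRateTable(grid$r_cm, grid$theta_deg, grid$side, dose,
                rel_err = sigma, label = label, isotope = spec$isotope)
}

#' Published longitudinal-shift radial dose functions
#'
#' The printed full-scatter, V(25, 5) and V(28, 2) radial-dose-function
#' columns for one isotope, as literal `radialDoseCurve`s — fixtures for
#' exact regression tests of the percent-difference and report machinery.
#'
#' @param isotope `"Pd103"`, `"Ir192"` or `"Cs137"`.
#' @return Named list of curves: `"(15, 15)"`, `"V(25, 5)"`, `"V(28, 2)"`.
#' @export
longitudinalShiftFixture <- function(isotope) {
  path <- system.file("extdata", "reference", "g_longitudinal_V.csv",
                      package = "brachyscatter", mustWork = TRUE)
  d <- utils::read.csv(path, comment.char = "#")
  d <- d[d$isotope == isotope, , drop = FALSE]
  if (nrow(d) == 0)
    stop("unknown isotope '", isotope, "'; supported: Pd103, Ir192, Cs137")
  list("(15, 15)" = radialDoseCurve(d$r_cm, d$g_full, label = "(15, 15)",
                                    isotope = isotope),
       "V(25, 5)" = radialDoseCurve(d$r_cm, d$g_V25_5, label = "V(25, 5)",
                                    isotope = isotope),
       "V(28, 2)" = radialDoseCurve(d$r_cm, d$g_V28_2, label = "V(28, 2)",
                                    isotope = isotope))
}

#' Published transverse-shift (H(25, 5)) radial dose functions
#'
#' The printed away/toward-side columns for the 10 cm transverse shift.
#'
#' @param isotope `"Pd103"`, `"Ir192"` or `"Cs137"`.
#' @return Data frame `r_cm`, `g_away`, `g_toward`.
#' @export
transverseShiftFixture <- function(isotope) {
  path <- system.file("extdata", "reference", "g_transverse_H25_5.csv",
                      package = "brachyscatter", mustWork = TRUE)
  d <- utils::read.csv(path, comment.char = "#")
  d <- d[d$isotope == isotope, c("r_cm", "g_away", "g_toward")]
  if (nrow(d) == 0)
    stop("unknown isotope '", isotope, "'; supported: Pd103, Ir192, Cs137")
  rownames(d) <- NULL
  d
}

#' Published dose rate constants per configuration
#'
#' @return Data frame `isotope`, `label`, `lambda` (cGy/h/U).
#' @export
referenceDoseRateConstants <- function() {
  path <- system.file("extdata", "reference", "dose_rate_constants.csv",
                      package = "brachyscatter", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}
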