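# Shared fixtures, all built in code.

# material object with prescribed interaction fractions on a flat grid
fakeMaterial <- function(f_pe, f_compton, f_rayleigh) {
  structure(list(name = "fake", rho = 1,
                 data = data.frame(energy_MeV = c(0.01, 1),
                                   mu_rho = c(1, 1), muen_rho = c(0.5, 0.5),
                                   f_pe = f_pe, f_compton = f_compton,
                                   f_rayleigh = f_rayleigh)),
            class = "materialTable")
}

# noiseless analytic dose table: D = GL * g * F (optionally PF on toward side)
analyticDoseTable <- function(source, gfun, r = 1:10, theta_deg = 90,
                              ffun = NULL, pffun = NULL,
                              label = "(15, 15)") {
  spec <- syntheticSpec(source$isotope, gModel = gfun,
                        fModel = if (is.null(ffun))
                          function(r, th) rep(1, length(r)) else ffun,
                        noiseSigma10 = 0, perturbation = pffun, seed = 1)
  grid <- expand.grid(r_cm = r, theta_deg = theta_deg,
                      side = c("away", "toward"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  generateDoseTable(spec, grid, source, label = label)
}

# independent subtended-angle construction from the line endpoints (acos form)
betaFromEndpoints <- function(r, theta, L) {
  p <- c(r * sin(theta), r * cos(theta))
  v1 <- c(0, L / 2) - p
  v2 <- c(0, -L / 2) - p
  acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
}
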