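test_that("geometry function has the point-source limit, symmetry and axis branch", {
  th <- seq(0, pi, length.out = 19)
  r <- c(0.5, 1, 3, 10)
  for (rr in r) {
    gl <- geometryFunction(rep(rr, length(th)), th, L = rr * 1e-6)
    expect_true(all(abs(gl * rr^2 - 1) < 1e-6))  # uniform in theta
  }
  # theta <-> pi - theta symmetry
  expect_equal(geometryFunction(2, 0.3, 0.5), geometryFunction(2, pi - 0.3, 0.5))
  # printed on-axis branch: (r^2 - L^2/4)^-1
  expect_equal(geometryFunction(1, 0, 0.5), 1 / (1 - 0.0625))
  # continuity of the oblique branch into the axis branch
  expect_equal(geometryFunction(1, 1e-7, 0.5), 1 / (1 - 0.0625),
               tolerance = 1e-9)
})

test_that("geometry function matches the endpoint-vector subtended angle", {
  for (case in list(c(1, pi / 2, 0.5), c(1, pi / 4, 0.5), c(2, 0.2, 1.5),
                    c(0.8, 2.8, 0.455), c(5, 1.0, 1.5))) {
    r <- case[1]; th <- case[2]; L <- case[3]
    beta <- betaFromEndpoints(r, th, L)
    expect_equal(geometryFunction(r, th, L), beta / (L * r * sin(th)),
                 tolerance = 1e-9)
  }
})

test_that("geometry function rejects invalid domains", {
  expect_error(geometryFunction(0.2, 0, 0.5), "L/2")
  expect_error(geometryFunction(1, -0.1, 0.5), "theta")
  expect_error(geometryFunction(1, 3.2, 0.5), "theta")
  expect_error(geometryFunction(-1, 1, 0.5), "positive")
})

test_that("radial dose function round-trips an analytic generator", {
  src <- sourceModel("Cs137")
  gfun <- function(r) exp(-0.05 * (r - 1))
  tab <- analyticDoseTable(src, gfun, r = c(0.5, 1, 2, 3, 5, 8, 10))
  g <- radialDoseFunction(tab, src, "away")
  expect_equal(g$g[g$r_cm == 1], 1)  # exact normalization at r0
  expect_equal(g$g, gfun(g$r_cm), tolerance = 1e-10)
  # invariance under uniform rescaling of the dose table
  tab2 <- tab
  tab2$dose_per_sk <- tab2$dose_per_sk * 17.3
  g2 <- radialDoseFunction(tab2, src, "away")
  expect_equal(g2$g, g$g)
  # missing reference sample
  expect_error(radialDoseFunction(tab[tab$r_cm != 1, ], src, "away"),
               "reference")
})

test_that("anisotropy function is unity transverse and reduces to a GL ratio", {
  src <- sourceModel("Ir192")
  grid <- expand.grid(r_cm = c(1, 3, 5), theta_deg = c(20, 45, 90, 135, 160),
                      side = "away", KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  # isotropic dose field: F(r, theta) = GL(r, 90) / GL(r, theta)
  tab <- doseRateTable(grid$r_cm, grid$theta_deg, grid$side, 1,
                       isotope = "Ir192")
  f <- anisotropyFunction(tab, src)
  expect_equal(f$F[f$theta_deg == 90], rep(1, 3))
  expected <- geometryFunction(f$r_cm, pi / 2, src$L) /
    geometryFunction(f$r_cm, f$theta_deg * pi / 180, src$L)
  expect_equal(f$F, expected, tolerance = 1e-12)
})

test_that("anisotropy points outside the phantom are masked, not extrapolated", {
  src <- sourceModel("Cs137")
  phan <- phantomConfig("V(28, 2)")
  # with side tags theta stays in [0, 90]; a polar angle of 140 degrees from
  # the +z axis in extended notation is (40 degrees, toward) here
  grid <- expand.grid(r_cm = 3, theta_deg = c(30, 40, 50, 90),
                      side = c("away", "toward"), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  tab <- doseRateTable(grid$r_cm, grid$theta_deg, grid$side, 1)
  f <- anisotropyFunction(tab, src, phan)
  tw <- f[f$side == "toward", ]
  # toward the missing tissue the point crosses the face (2 cm of overlying
  # water) once 3 cos(theta) > 2, i.e. for tilts below ~48 degrees
  expect_true(tw$masked[tw$theta_deg == 30])
  expect_true(tw$masked[tw$theta_deg == 40])
  expect_false(tw$masked[tw$theta_deg == 50])
  expect_true(all(is.na(tw$F[tw$masked])))
  expect_true(!any(f$masked[f$side == "away"]))
})

test_that("dose rate constant is the reference dose over SK with propagated error", {
  tab <- doseRateTable(c(1, 2), 90, "away", c(5, 3), rel_err = c(0.01, 0.02))
  expect_equal(doseRateConstant(tab, airKermaStrength(5))$lambda, 1)
  # synthetic: dose = 0.650 s, SK = s
  s <- 7.7
  tab2 <- doseRateTable(1, 90, "away", 0.650 * s)
  expect_equal(doseRateConstant(tab2, airKermaStrength(s))$lambda, 0.650)
  # homogeneity: doubling SK halves lambda
  expect_equal(doseRateConstant(tab2, airKermaStrength(2 * s))$lambda,
               0.650 / 2)
  lam <- doseRateConstant(tab, airKermaStrength(5, rel_err = 0.03))
  expect_equal(lam$rel_err, sqrt(0.01^2 + 0.03^2))
  expect_error(doseRateConstant(tab[tab$r_cm != 1, ], airKermaStrength(1)),
               "reference")
})

test_that("TG-43 reconstruction is the identity on its generating table", {
  src <- sourceModel("Cs137")
  gfun <- function(r) exp(-0.04 * (r - 1) - 0.001 * (r - 1)^2)
  ffun <- function(r, th) 1 - 0.2 * (1 - sin(th * pi / 180))
  tab <- analyticDoseTable(src, gfun, r = c(1, 2, 3, 5, 7),
                           theta_deg = c(30, 60, 90, 120), ffun = ffun)
  sk <- airKermaStrength(2.5)
  g <- radialDoseFunction(tab, src, "away")
  f <- anisotropyFunction(tab, src)
  lam <- doseRateConstant(tab, sk)
  for (i in which(tab$side == "away")) {
    rec <- reconstructDoseRate(src, lam, g, f, sk,
                               r = tab$r_cm[i], theta_deg = tab$theta_deg[i],
                               side = "away")
    expect_equal(rec, tab$dose_per_sk[i], tolerance = 1e-10)
  }
  # linearity: scaling g scales the reconstruction
  g2 <- g; g2$g <- g2$g * 3
  expect_equal(reconstructDoseRate(src, lam, g2, NULL, sk, r = 2),
               3 * reconstructDoseRate(src, lam, g, NULL, sk, r = 2))
  # no silent extrapolation
  expect_error(reconstructDoseRate(src, lam, g, NULL, sk, r = 20), "range")
  expect_error(reconstructDoseRate(src, lam, g, f, sk, r = 3,
                                   theta_deg = 150), "grid")
})
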