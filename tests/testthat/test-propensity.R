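bruteRho <- function(spec, nPts = 2e5) {
  wmax <- 20 * pi / min(spec@tau1, spec@tau2)
  w <- seq(wmax / nPts, wmax, length.out = nPts)
  min(Mod(charValue(w, spec)))
}

test_that("characteristic values match their closed forms", {
  sp <- charSpec(0, 0.5, 0.5, 3, 3)
  expect_lt(Mod(charValue(pi / 3, sp)), 1e-12)   # exact root at pi/tau
  expect_equal(charValue(0, sp), 2 + 0i)         # 1 + p + q at omega = 0
  sp0 <- charSpec(0.7, 0, 0, 2, 2)
  w <- seq(0.1, 10, by = 0.1)
  expect_true(all(Mod(charValue(w, sp0)) >= 1))  # |j w theta + 1| >= 1
  expect_error(charValue(-1, sp), "nonnegative")
  expect_error(charSpec(0.5, -0.1, 0.5, 3, 3), "gains")
})

test_that("propensity handles boundary, root and generic cases", {
  expect_equal(rho(oscillationPropensity(charSpec(0.5, 0, 0, 3, 3))), 1,
               tolerance = 1e-8)                 # infimum as omega -> 0+
  pr <- oscillationPropensity(charSpec(0, 0.5, 0.5, 3, 3))
  expect_lt(rho(pr), 1e-10)
  expect_identical(jstar(pr), Inf)
  expect_equal(omegaStar(pr), pi / 3, tolerance = 1e-6)
  expect_error(oscillationPropensity(charSpec(0, 0.5, 0.5, 3, 3),
                                     nGrid = 50), "coarse")
  ## generic case agrees with a dense brute-force scan
  sp <- charSpec(0.5, 0.5, 0.5, 3, 3)
  expect_equal(rho(oscillationPropensity(sp)), bruteRho(sp, 4e6),
               tolerance = 1e-8)
})

test_that("refined minima agree with brute force over random specs", {
  set.seed(99)
  for (k in 1:30) {
    sp <- charSpec(stats::runif(1, 0, 1), stats::runif(1, 0, 1),
                   stats::runif(1, 0, 1), stats::runif(1, 2, 4),
                   stats::runif(1, 2, 4))
    r <- rho(oscillationPropensity(sp))
    rb <- bruteRho(sp)
    expect_lte(r, rb + 1e-12)          # refinement can only improve
    expect_lt(abs(r - rb), 1e-6)
  }
})

test_that("critical gain obeys the analytic delayed-feedback bounds", {
  for (ratio in c(0.2, 0.5, 0.8)) {
    cg <- criticalGain(0, 3, 3, ratio)
    expect_equal(cg$gain, 1, tolerance = 1e-6)
    expect_equal(cg$omega, pi / 3, tolerance = 1e-4)
  }
  expect_gt(criticalGain(0.5, 3, 3)$gain, 1)
  ## unequal delays, zero time constant: s* = 2 by closed form
  ## (Im c vanishes at 3*omega = k*pi with |cos(omega)| = 1/2 there)
  expect_equal(criticalGain(0, 2, 4, 0.5)$gain, 2, tolerance = 1e-6)
  ## necessary-condition floor over a parameter grid
  grid <- expand.grid(theta = c(0, 0.5, 1), tau1 = c(2, 3, 4),
                      tau2 = c(2, 3, 4), ratio = c(0.2, 0.5, 0.8))
  s <- mapply(function(th, t1, t2, r) criticalGain(th, t1, t2, r)$gain,
              grid$theta, grid$tau1, grid$tau2, grid$ratio)
  expect_true(all(s >= 1 - 1e-9))
  off <- grid$theta > 0 | grid$tau1 != grid$tau2
  expect_true(all(s[off] > 1 + 1e-9))
  expect_error(criticalGain(0, 3, 3, ratio = 1.4), "ratio")
})

test_that("critical gain is an exact root of the characteristic equation", {
  for (par in list(c(0.3, 2.5, 3.5, 0.4), c(0.8, 2, 4, 0.7))) {
    cg <- criticalGain(par[1], par[2], par[3], par[4])
    sp <- charSpec(par[1], par[4] * cg$gain, (1 - par[4]) * cg$gain,
                   par[2], par[3])
    expect_lt(rho(oscillationPropensity(sp)), 1e-6)
    ## slightly below the critical gain there is no root
    spBelow <- charSpec(par[1], par[4] * cg$gain * 0.98,
                        (1 - par[4]) * cg$gain * 0.98, par[2], par[3])
    expect_gt(rho(oscillationPropensity(spBelow)), 1e-4)
  }
})

test_that("propensity surfaces are symmetric and diagonal-maximal", {
  s <- propensitySurface(0.5, 0.5, 0.5, n = 15, nGrid = 1e4)
  J <- jstar(s)
  expect_lt(max(abs(J - t(J))), 1e-12)
  expect_gte(max(diag(J)), max(J) - 1e-9)
  ## asymmetric gains break the symmetry but not the diagonal maximum
  s2 <- propensitySurface(0.5, 0.3, 0.7, n = 15, nGrid = 1e4)
  J2 <- jstar(s2)
  expect_gt(max(abs(J2 - t(J2))), 1e-6)
  expect_gte(max(diag(J2)), max(J2) - 1e-9)
  expect_error(propensitySurface(0.5, 0.5, 0.5, n = 1), "at least 2")
})

test_that("linear onset gain matches nonlinear oscillation onset", {
  pars <- sampleParameters(aavGraph(), seed = 2)
  red <- reduceAAV(buildAAVModel(pars))
  lin <- linearizeAAV(red)
  g <- loopGains(lin)
  s <- sum(g)
  cg <- criticalGain(red@theta, red@tau[["tau1"]], red@tau[["tau2"]],
                     ratio = g[["p"]] / s)
  onset <- function(f) {
    tr <- simulateDDE(setGainScale(red, f * cg$gain / s),
                      horizon = 400, step = 0.2)
    oscillating(detectOscillation(tr, threshold = 1e-6))
  }
  expect_false(onset(0.95))
  expect_true(onset(1.05))
})
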