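aavPars <- function(seed) sampleParameters(aavGraph(), seed = seed)

test_that("the sampled AAV model reproduces the closed-loop structure", {
  m <- buildAAVModel(aavPars(1))
  g <- vasoloop:::graphFromModel(m)
  expect_identical(signPattern(interactionMatrix(g)),
                   signPattern(interactionMatrix(aavGraph())))
  cyc <- enumerateCycles(aavGraph())
  expect_true(all(vapply(cyc, `[[`, numeric(1), "sign") == -1))
  expect_true(isInternalDag(g, paste0("x_", 1:15)))
  ## three delayed arcs with the sampled delays, tau2 = tau3 tied
  tau <- vasoloop:::aavModelDelays(m)
  expect_length(tau, 3)
  expect_equal(tau[["tau2"]], tau[["tau3"]])
  expect_true(all(tau >= 2 & tau <= 4))
})

test_that("internal spectrum is exactly the self-decay rates", {
  ## acyclic internal wiring makes the Jacobian triangular in a
  ## topological order, so the eigenvalues are the -1/Theta_i
  m <- buildAAVModel(aavPars(4))
  internal <- paste0("x_", 1:15)
  set.seed(1)
  st <- stats::setNames(stats::runif(20, 0.2, 1.5), nodeLabels(m))
  th <- thetaMinutes(m)[internal]
  deriv <- function(s)
    (vasoloop:::evalRHS(m, s)[internal] - s[internal]) / th
  J <- matrix(0, 15, 15)
  for (j in seq_len(15)) {
    up <- st; up[internal[j]] <- up[internal[j]] + 1e-6
    dn <- st; dn[internal[j]] <- dn[internal[j]] - 1e-6
    J[, j] <- (deriv(up) - deriv(dn)) / 2e-6
  }
  ev <- eigen(J, only.values = TRUE)$values
  expect_lt(max(abs(Im(ev))), 1e-9)
  expect_equal(sort(Re(ev)), sort(unname(-1 / th)), tolerance = 1e-5)
})

test_that("reduced maps have the predicted monotonicity", {
  red <- reduceAAV(buildAAVModel(aavPars(2)))
  maps <- reducedStaticMaps(red)
  ## ANP drive inhibits contraction, AVP drive activates it
  expect_lt(maps$phi(1.2, 1), maps$phi(1, 1))
  expect_gt(maps$phi(1, 1.2), maps$phi(1, 1))
  ## contraction activates the ANP loop and suppresses the AVP loop
  expect_gt(maps$f1(1.2), maps$f1(1))
  expect_lt(maps$psi(1.2, 1.2), maps$psi(1, 1))
  ## monotone steady-state response of the state itself
  eq <- reducedEquilibrium(red)
  expect_true(eq > 0)
  expect_error(reduceAAV(projectModel(red@model, paste0("x_", 1:15))),
               "20-variable")
})

test_that("frozen feedback gives a pure first-order step response", {
  red <- reduceAAV(buildAAVModel(aavPars(2)))
  eq <- reducedEquilibrium(red)
  frozen <- setGainScale(red, 0)          # feedback pinned at equilibrium
  y0 <- 1.4 * eq
  tr <- simulateDDE(frozen, init = y0, horizon = 5 * red@theta,
                    step = red@theta / 50)
  expected <- eq + (y0 - eq) * exp(-timeGrid(tr) / red@theta)
  expect_lt(max(abs(states(tr)[, 1] - expected)), 1e-6 * eq)
})

test_that("linearisation matches finite differences at the equilibrium", {
  red <- reduceAAV(buildAAVModel(aavPars(2)))
  eq <- reducedEquilibrium(red)
  lin <- linearizeAAV(red)
  maps <- reducedStaticMaps(red)
  h <- 1e-6
  pFD <- abs(maps$phi(maps$f1(eq + h), maps$psi(eq, eq)) -
               maps$phi(maps$f1(eq - h), maps$psi(eq, eq))) / (2 * h)
  qFD <- abs(maps$phi(maps$f1(eq), maps$psi(eq + h, eq + h)) -
               maps$phi(maps$f1(eq), maps$psi(eq - h, eq - h))) / (2 * h)
  g <- loopGains(lin)
  expect_equal(unname(g[["p"]]), unname(pFD), tolerance = 1e-6)
  expect_equal(unname(g[["q"]]), unname(qFD), tolerance = 1e-6)
  ## frozen feedback linearises to zero gains
  g0 <- loopGains(linearizeAAV(setGainScale(red, 0)))
  expect_equal(unname(g0), c(0, 0))
})

test_that("reduced scalar DDE tracks the fast-limit 20-variable model", {
  pars <- aavPars(3)
  pars$theta[paste0("x_", 2:20)] <- pars$theta[["x_1"]] / 100
  full <- buildAAVModel(pars)
  red <- reduceAAV(full)
  eq <- reducedEquilibrium(red)
  evF <- function(lbl, d) if (lbl == "x_1") 1.2 * eq else
    vasoloop:::evalTermsWith(full@rhs[[lbl]], evF, d)
  init <- c(1.2 * eq, vapply(paste0("x_", 2:20), function(v) evF(v, 0),
                             numeric(1)))
  names(init) <- nodeLabels(full)
  trF <- simulateDDE(full, init, horizon = 60, step = 0.1)
  trR <- simulateDDE(red, init = 1.2 * eq, horizon = 60, step = 0.1)
  keep <- timeGrid(trF) >= 5
  err <- max(abs(states(trF)[keep, "x_1"] - states(trR)[keep, "x_1"])) /
    max(abs(states(trR)[, "x_1"]))
  expect_lt(err, 0.05)
})

test_that("the linear DDE obeys its closed forms", {
  mk <- function(theta, p, q, tau)
    new("LinearizedAAV", theta = theta, k1 = 1, k2 = 1, mu1 = p,
        mu2 = q / 2, mu3 = q / 2,
        tau = c(tau1 = tau, tau2 = tau, tau3 = tau), equilibrium = 0)
  ## no feedback: pure exponential decay
  lin0 <- mk(0.5, 0, 0, 3)
  tr0 <- simulateDDE(lin0, init = 1, horizon = 5, step = 0.01)
  expect_lt(max(abs(states(tr0)[, 1] - exp(-timeGrid(tr0) / 0.5))), 1e-6)
  ## above-critical equal-delay loop: sustained growth at period ~ 2*tau
  lin1 <- mk(0.01, 0.6, 0.6, 3)
  tr1 <- simulateDDE(lin1, init = 0.001, horizon = 150, step = 0.02)
  rep1 <- detectOscillation(tr1)
  expect_true(oscillating(rep1))
  expect_equal(rep1@period, 6, tolerance = 0.05)
})

test_that("oscillation detection separates decay, noise floor and cycles", {
  tt <- seq(0, 100, by = 0.05)
  dec <- new("Trajectory", time = tt, state = cbind(y = exp(-tt / 5)),
             metadata = list())
  expect_false(oscillating(detectOscillation(dec)))
  sine <- new("Trajectory", time = tt, state = cbind(y = 1 + sin(tt)),
              metadata = list())
  repS <- detectOscillation(sine)
  expect_true(oscillating(repS))
  expect_equal(repS@period, 2 * pi, tolerance = 0.02)
  ## a would-be oscillation with unresolvable cycles raises an error
  ts <- seq(0, 10, by = 0.01)
  slow <- new("Trajectory", time = ts, state = cbind(y = 1 + sin(0.8 * ts)),
              metadata = list())
  expect_error(detectOscillation(slow), "cycles")
})
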