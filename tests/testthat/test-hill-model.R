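test_that("Hill interaction closed forms and guards", {
  expect_equal(evalInteraction(fTerm("x"), 0), 0)
  expect_equal(evalInteraction(gTerm("x", gamma = 1.7), 0), 1.7)
  expect_equal(evalInteraction(fTerm("x", alpha = 1, beta = 1, nH = 1), 1),
               0.5)
  h <- hTerm("x", "y", sigma = 2, eps = 1, eta = 1, nH = 1)
  expect_equal(evalInteraction(h, 1, 0), 1)          # 2*1/(1+1)
  expect_equal(evalInteraction(h, 1, 1), 2 / 3)
  expect_error(evalInteraction(fTerm("x"), -1), "nonnegative")
  expect_error(fTerm("x", alpha = -1), "positive")
  expect_error(gTerm("x", nH = 0.5), "exponent")
  ## monotonicity of the three forms
  xs <- seq(0, 3, by = 0.5)
  expect_true(all(diff(evalInteraction(fTerm("x"), xs)) > 0))
  expect_true(all(diff(evalInteraction(gTerm("x"), xs)) < 0))
})

test_that("model construction rejects unknown term sources", {
  expect_error(
    hillModel("A", c(A = 1), list(A = list(fTerm("B")))), "unknown")
  expect_error(
    hillModel(c("A", "B"), c(A = 0, B = 1),
              list(A = list(), B = list())), "positive")
})

test_that("fixed-step integration matches the linear closed form", {
  m <- chainModel(gamma = 1.3, thetaB = 1)
  tr <- simulateODE(m, c(A = 0, B = 0), horizon = 10, step = 0.05)
  ## with A pinned at 0, B sees the constant drive g(0) = gamma
  expect_lt(max(abs(states(tr)[, "B"] -
                    1.3 * (1 - exp(-timeGrid(tr))))), 1e-6)
  expect_true(all(states(tr) >= 0))
  ## halving the step moves the terminal state by < 1e-6
  tr2 <- simulateODE(m, c(A = 0, B = 0), horizon = 10, step = 0.025)
  expect_lt(abs(states(tr2)[nrow(states(tr2)), "B"] -
                states(tr)[nrow(states(tr)), "B"]), 1e-6)
})

test_that("the sampled AAR model matches the network sign structure", {
  pars <- sampleParameters(aarFullGraph(), seed = 1)
  m <- buildAARModel(pars)
  expect_identical(signPattern(interactionMatrix(m)),
                   signPattern(interactionMatrix(aarFullGraph())))
  ## from the origin the system settles to a finite interior state
  tr <- simulateODE(m, stats::setNames(rep(0, 10), nodeLabels(m)),
                    horizon = 1500, step = 1, method = "lsoda")
  fin <- states(tr)[nrow(states(tr)), ]
  resid <- max(abs(vasoloop:::evalRHS(m, fin) - fin))
  expect_lt(resid, 1e-6)
  expect_true(all(fin > 0))
})

test_that("time-scale reduction composes to the 6-variable reduced system", {
  pars <- sampleParameters(aarFullGraph(), seed = 2)
  m <- buildAARModel(pars)
  expect_identical(reduceTimeScale(m, character(0)), m)
  red <- reduceTimeScale(m, aarFastNodes())
  expect_identical(nodeLabels(red), aarOrder)
  expect_identical(signPattern(interactionMatrix(red)), refSigmaAAR())
  ## eliminating a cyclic set is rejected
  expect_error(reduceTimeScale(m, c("ACO", "JGC", "DTC")), "cycle")
})

test_that("reduced trajectories track the stiff full model", {
  pars <- sampleParameters(aarFullGraph(), seed = 5)
  pars$theta[aarFastNodes()] <- 0.01
  full <- buildAARModel(pars)
  red <- reduceTimeScale(full, aarFastNodes())
  eq <- findEquilibrium(red, seed = 1)
  init <- eq@state * 1.5
  evF <- function(lbl, d) if (lbl %in% nodeLabels(red)) init[[lbl]] else
    vasoloop:::evalTermsWith(full@rhs[[lbl]], evF)
  initFull <- c(init, vapply(aarFastNodes(), function(v) evF(v, 0),
                             numeric(1)))[nodeLabels(full)]
  trF <- simulateODE(full, initFull, horizon = 200, step = 0.5,
                     method = "lsoda")
  trR <- simulateODE(red, init, horizon = 200, step = 0.5,
                     method = "lsoda")
  keep <- timeGrid(trF) >= 2    # past the fast boundary layer
  err <- vapply(nodeLabels(red), function(v)
    max(abs(states(trF)[keep, v] - states(trR)[keep, v])) /
      max(abs(states(trR)[, v])), numeric(1))
  expect_lt(max(err), 0.02)
})

test_that("splitting the reduced model yields the two regulation schemes", {
  sc <- sampleAARSchemes(seed = 3)
  expect_identical(signPattern(interactionMatrix(sc$dtc)), refSigmaDTC())
  expect_identical(signPattern(interactionMatrix(sc$vsm)), refSigmaVSM())
  expect_error(splitAAR(sc$dtc), "6-variable")
})

test_that("gauged core Jacobian is cooperative at sampled states", {
  sc <- sampleAARSchemes(seed = 4)
  core <- c("ACO", "JGC", "HMY", "SPN")
  flip <- stats::setNames(c(1, 1, -1, 1), core)
  set.seed(42)
  for (k in 1:5) {
    st <- stats::setNames(stats::runif(6, 0.1, 3), aarOrder)
    ## finite-difference Jacobian of the reduced right-hand side
    for (i in core) for (j in setdiff(core, i)) {
      h <- 1e-6
      up <- st; up[j] <- up[j] + h
      dn <- st; dn[j] <- dn[j] - h
      der <- (vasoloop:::evalRHS(sc$reduced, up)[[i]] -
                vasoloop:::evalRHS(sc$reduced, dn)[[i]]) / (2 * h)
      expect_gte(flip[[i]] * flip[[j]] * der, 0)
    }
  }
})

test_that("equilibria are unique and persist under forward simulation", {
  sc <- sampleAARSchemes(seed = 7)
  eq <- findEquilibrium(sc$dtc, nStarts = 20L, seed = 7)
  expect_identical(eq@nEquilibria, 1L)
  expect_true(eq@agree)
  expect_lt(eq@residual, 1e-8)
  tr <- simulateODE(sc$dtc, eq@state, horizon = 1000, step = 1,
                    method = "lsoda")
  expect_lt(max(abs(t(states(tr)) - eq@state)), 1e-6)
  ## decoupled relaxation: equilibrium of theta*x' + x = gamma is gamma
  m <- chainModel(gamma = 0.8)
  eq2 <- findEquilibrium(m, nStarts = 5L, seed = 1)
  expect_equal(unname(eq2@state[["B"]]), 0.8, tolerance = 1e-8)
})

test_that("empirical influence signs sit inside the structural classes", {
  exact <- refInfluenceDTC()
  for (seed in c(21, 22)) {
    sc <- sampleAARSchemes(seed)
    emp <- empiricalInfluence(sc$dtc, seed = seed)
    fixed <- exact != "?"
    expect_true(all(emp[fixed] == exact[fixed]))
    ## robustness: a tenfold smaller probe leaves every sign unchanged
    eq <- findEquilibrium(sc$dtc, seed = seed)
    eps <- 1e-3 * mean(abs(eq@state))
    emp2 <- empiricalInfluence(sc$dtc, eps = eps / 10, seed = seed,
                               equilibrium = eq)
    expect_identical(emp2, emp)
  }
  ## VSM scheme: the first column below the diagonal is empirically zero
  sc <- sampleAARSchemes(23)
  empV <- empiricalInfluence(sc$vsm, seed = 23)
  expect_true(all(empV[-1, "ACO"] == "0"))
})

test_that("perturbation protocols serialise and act additively", {
  sc <- sampleAARSchemes(9)
  pp <- perturbationProtocol(sc$dtc, "DTC", 0.05)
  expect_error(perturbationProtocol(sc$dtc, "XX", 0.1), "unknown")
  json <- jsonlite::toJSON(unclass(pp), auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$eps, pp$eps)
  expect_equal(back$target, pp$target)
  ## eps = 0 leaves the equilibrium untouched
  eq0 <- findEquilibrium(sc$dtc, seed = 2)
  eqP <- findEquilibrium(sc$dtc, seed = 2,
                         bias = perturbationProtocol(sc$dtc, "DTC", 0)$bias)
  expect_equal(eqP@state, eq0@state, tolerance = 1e-9)
  ## a positive DTC input shifts steady states with the DTC column signs
  eqD <- findEquilibrium(sc$dtc, seed = 2, bias = pp$bias,
                         warmStart = eq0@state)
  delta <- eqD@state - eq0@state
  expFixed <- refInfluenceDTC()[, "DTC"]
  for (v in names(delta)[expFixed != "?"]) {
    expect_true(sign(delta[[v]]) == ifelse(expFixed[[v]] == "+", 1, -1))
  }
})
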