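test_that("parameter sampling is deterministic and class-contained", {
  g <- aarFullGraph()
  p1 <- sampleParameters(g, seed = 11)
  p2 <- sampleParameters(g, seed = 11)
  expect_identical(p1, p2)
  p3 <- sampleParameters(g, seed = 12)
  expect_false(identical(p1$theta, p3$theta))
  cls <- nodeClasses(g)
  rg <- parameterRanges()
  for (k in 1:20) {
    th <- sampleParameters(g, seed = k)$theta
    for (v in names(th)) {
      r <- rg@thetaRanges[[cls[[v]]]]
      expect_gte(th[[v]], r[1]); expect_lte(th[[v]], r[2])
    }
  }
  ## every arc receives coefficients of the right monotonicity family
  e <- edgeTable(g)
  for (i in seq_len(nrow(e))) {
    hp <- p1$hill[[paste0(e$from[i], "->", e$to[i])]]
    expect_named(hp, if (e$sign[i] > 0) c("alpha", "beta")
                 else c("gamma", "delta"))
  }
})

test_that("nodes without a time-scale class are rejected", {
  g <- signedDigraph(c("a", "b"),
                     data.frame(from = "a", to = "b", sign = 1))
  expect_error(sampleParameters(g, seed = 1), "class")
  expect_error(parameterRanges(delayRange = c(4, 2)), "ordered")
})

test_that("AAV delays sample inside the physiological window", {
  for (k in 1:10) {
    d <- sampleParameters(aavGraph(), seed = k)$delays
    expect_true(all(d >= 2 & d <= 4))
    expect_equal(d[["tau2"]], d[["tau3"]])
  }
  d2 <- sampleParameters(aavGraph(), seed = 1, tieDelays = FALSE)$delays
  expect_false(d2[["tau2"]] == d2[["tau3"]])
})

test_that("sampled schemes settle to a single equilibrium across seeds", {
  for (seed in 1:20) {
    sc <- sampleAARSchemes(seed)
    eq <- findEquilibrium(sc$dtc, nStarts = 8L, seed = seed)
    expect_identical(eq@nEquilibria, 1L)
    expect_true(all(eq@state > 0))
  }
})
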