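test_that("graph construction validates labels, endpoints and signs", {
  expect_error(signedDigraph(c("a", "a")), "unique")
  expect_error(signedDigraph("a", data.frame(from = "a", to = "b",
                                             sign = 1)), "declared")
  expect_error(signedDigraph(c("a", "b"),
                             data.frame(from = "a", to = "b", sign = 2)),
               "sign")
  expect_error(signedDigraph(c("a", "b"),
                             data.frame(from = "a", to = "a", sign = 1)),
               "[Ss]elf")
  g <- signedDigraph(c("a", "b"))
  expect_length(enumerateCycles(g), 0)   # isolated nodes, no cycles
})

test_that("bundled fixtures have the documented shape", {
  expect_identical(nodeLabels(aavGraph()), paste0("x_", 1:20))
  expect_identical(nodeLabels(aarFullGraph()),
                   c(aarOrder, "ASR", "ACR", "NTS", "SFO"))
  expect_identical(signPattern(sigmaAAR()), refSigmaAAR())
  expect_identical(signPattern(sigmaDTC()), refSigmaDTC())
  expect_identical(signPattern(sigmaVSM()), refSigmaVSM())
  ## the full-graph arc pattern restricted to its matrix form
  S <- signPattern(interactionMatrix(aarFullGraph()))
  expect_equal(unname(diag(S)), rep(-1, 10))
  expect_equal(S["HMY", "ASR"], 1)
  expect_equal(S["SFO", "DTC"], -1)
})

test_that("interaction matrix round-trips through a graph exactly", {
  S <- sigmaAAR()
  expect_identical(signPattern(interactionMatrix(graphFromSignMatrix(S))),
                   signPattern(S))
  ## node with no arcs: all-zero row/column except the -1 diagonal
  g <- signedDigraph(c("a", "b"), data.frame(from = "a", to = "b",
                                             sign = -1))
  S2 <- signPattern(interactionMatrix(g, order = c("b", "a")))
  expect_equal(unname(S2["a", ]), c(0, -1))
  expect_error(interactionMatrix(g, order = c("a", "z")), "permutation")
})

test_that("cycle enumeration finds every elementary cycle with its sign", {
  two <- signedDigraph(c("a", "b"),
                       data.frame(from = c("a", "b"), to = c("b", "a"),
                                  sign = c(1, -1)))
  cyc <- enumerateCycles(two)
  expect_length(cyc, 1)
  expect_equal(cyc[[1]]$sign, -1)
  expect_identical(cyc[[1]]$nodes, c("a", "b"))

  cycAAV <- enumerateCycles(aavGraph())
  expect_length(cycAAV, 13)              # counted by hand on the wiring
  expect_true(all(vapply(cycAAV, `[[`, numeric(1), "sign") == -1))
  expect_true(all(vapply(cycAAV, function(cy) "x_1" %in% cy$nodes,
                         logical(1))))
  ## the cell subsystem alone has no loops at all
  expect_length(enumerateCycles(inducedSubgraph(aavGraph(),
                                                paste0("x_", 1:15))), 0)
})

test_that("candidate-oscillator check flags positive cycles and pivots", {
  expect_true(candidateOscillatorCheck(aavGraph(), pivot = "x_1")$ok)
  expect_true(candidateOscillatorCheck(aarDtcGraph())$ok)
  expect_true(candidateOscillatorCheck(aarVsmGraph())$ok)
  pos2 <- signedDigraph(c("a", "b"),
                        data.frame(from = c("a", "b"), to = c("b", "a"),
                                   sign = c(1, 1)))
  rep <- candidateOscillatorCheck(pos2)
  expect_false(rep$ok)
  expect_length(rep$positiveCycles, 1)
  expect_error(candidateOscillatorCheck(aavGraph(), pivot = "zz"),
               "pivot")
})

test_that("cooperative gauges match the known flip sets", {
  gA <- findCooperativeGauge(aarReducedGraph(),
                             c("ACO", "JGC", "HMY", "SPN"))
  expect_identical(names(gA)[gA < 0], "HMY")
  gV <- findCooperativeGauge(aavGraph(), paste0("x_", 1:15))
  expect_identical(names(gV)[gV < 0],
                   c("x_2", "x_4", "x_7", "x_13", "x_14"))
  ## an all-activating subgraph needs no flips
  chain <- signedDigraph(c("a", "b", "c"),
                         data.frame(from = c("a", "b"), to = c("b", "c"),
                                    sign = c(1, 1)))
  expect_true(all(findCooperativeGauge(chain, c("a", "b", "c")) == 1))
  ## a positive 2-cycle with mixed signs is unbalanceable
  bad <- signedDigraph(c("a", "b"),
                       data.frame(from = c("a", "b"), to = c("b", "a"),
                                  sign = c(1, -1)))
  expect_null(findCooperativeGauge(bad, c("a", "b")))
})

test_that("gauge transformations preserve every cycle sign", {
  set.seed(7)
  for (g in list(aarReducedGraph(), aavGraph())) {
    ref <- cycleSignature(enumerateCycles(g))
    for (k in 1:5) {
      sig <- stats::setNames(sample(c(-1, 1), length(nodeLabels(g)),
                                    replace = TRUE), nodeLabels(g))
      expect_identical(cycleSignature(enumerateCycles(applyGauge(g, sig))),
                       ref)
    }
  }
  ## and on sign matrices the diagonal is untouched
  Sg <- applyGauge(sigmaAAR(), "HMY")
  expect_identical(signPattern(Sg), refSigmaAARGauged())
  expect_equal(unname(diag(signPattern(Sg))), rep(-1, 6))
})

test_that("gauge search agrees with brute force on random graphs", {
  found <- 0
  for (seed in 1:25) {
    g <- randomSignedGraph(6, 0.25, seed)
    fast <- findCooperativeGauge(g, nodeLabels(g))
    brute <- bruteForceGauge(g, nodeLabels(g))
    expect_equal(is.null(fast), is.null(brute), info = paste("seed", seed))
    if (!is.null(fast)) {
      found <- found + 1
      e <- edgeTable(g)
      if (nrow(e))
        expect_true(all(e$sign * fast[e$from] * fast[e$to] > 0))
    }
  }
  expect_gt(found, 0)    # the case split is exercised both ways
})

test_that("internal DAG detection matches the loop structure", {
  expect_true(isInternalDag(aavGraph(), paste0("x_", 1:15)))
  expect_false(isInternalDag(aavGraph()))
  expect_true(isInternalDag(aavGraph(), "x_1"))
  expect_error(isInternalDag(aavGraph(), "nope"), "unknown")
})
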