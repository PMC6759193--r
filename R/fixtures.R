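## Bundled network topologies.
##
## The AAR network couples three neuroendocrine axes regulating blood
## pressure and volume: ACO adrenal cortex, JGC juxtaglomerular cells,
## HMY heart myocytes, SPN supraoptic/paraventricular nuclei, DTC renal
## distal tubule and collecting duct, VSM vascular smooth muscle, ASR
## atrial stretch receptors, ACR aortic arch / carotid sinus stretch
## receptors, NTS nucleus tractus solitarii, SFO subfornical organ.
##
## The AAV network combines the AVP and ANP endocrine limbs with the
## intracellular contraction machinery of vascular smooth muscle cells:
## x_1 actomyosin interaction, x_2 caldesmon, x_3 MLC, x_4 MLCP, x_5
## MLCK, x_6 CaM, x_7 PKG, x_8 CPI-17, x_9 RhoA/ROCK, x_10 IP3R, x_11
## Gq/PLC, x_12 G12/13-GEF, x_13 PMCA, x_14 ANPR/GC, x_15 V1R, and the
## systemic loop x_16 HMY, x_17 SPN, x_18 NTS, x_19 ASR, x_20 ACR.

classDefaultTheta <- c(endocrine = 45, stretch = 3.25, nerve = 0.5,
                       intracellular = 0.1)

edgeFrame <- function(...) {
  rows <- list(...)
  data.frame(from = vapply(rows, `[[`, "", 1L),
             to = vapply(rows, `[[`, "", 2L),
             sign = as.numeric(vapply(rows, `[[`, "", 3L) == "+") * 2 - 1,
             delay = as.numeric(vapply(rows, function(r)
               if (length(r) >= 4L) r[[4L]] else "0", "")))
}

aarNodeClasses <- function() {
  c(ACO = "endocrine", JGC = "endocrine", HMY = "endocrine",
    SPN = "endocrine", DTC = "endocrine", VSM = "endocrine",
    ASR = "stretch", ACR = "stretch", NTS = "nerve", SFO = "nerve")
}

#' Bundled network topologies
#'
#' Constructors for the signed digraphs analysed by the package:
#' * `aarFullGraph()` — the complete 10-node AVP-ANP-RAAS (AAR) loop
#'   network (six endocrine nodes, two stretch-receptor nodes, two
#'   neural nodes);
#' * `aarReducedGraph()` — its 6-node reduction after eliminating the
#'   fast stretch-receptor and neural nodes by time-scale separation;
#' * `aarDtcGraph()`, `aarVsmGraph()` — the two coexisting 5-node
#'   feedback schemes (renal distal tubule regulation and vascular
#'   smooth muscle regulation) obtained by splitting the reduced
#'   network;
#' * `aavGraph()` — the 20-node AVP-ANP-VSM (AAV) closed loop combining
#'   intracellular signalling with systemic feedback through stretch
#'   receptors, with delayed arcs on the three endocrine loops.
#'
#' Node time-scale classes and nominal time constants (class midpoints)
#' are attached; the same topologies ship as JSON under
#' `system.file("extdata", package = "vasoloop")`.
#'
#' @param tau1,tau2,tau3 loop delays in minutes for the delayed arcs of
#'   the AAV graph (ANP loop; aortic/carotid AVP loop; atrial AVP
#'   loop).
#' @return a [SignedDigraph-class].
#' @examples
#' candidateOscillatorCheck(aarDtcGraph())$ok
#' @export
aarFullGraph <- function() {
  cls <- aarNodeClasses()
  signedDigraph(names(cls), edgeFrame(
    c("JGC", "ACO", "+"), c("HMY", "ACO", "-"),
    c("HMY", "JGC", "-"), c("DTC", "JGC", "-"),
    c("ASR", "HMY", "+"),
    c("NTS", "SPN", "-"), c("SFO", "SPN", "+"),
    c("ACO", "DTC", "+"), c("HMY", "DTC", "-"), c("SPN", "DTC", "+"),
    c("JGC", "VSM", "+"), c("HMY", "VSM", "-"), c("SPN", "VSM", "+"),
    c("DTC", "ASR", "+"), c("VSM", "ASR", "+"),
    c("DTC", "ACR", "+"), c("VSM", "ACR", "+"),
    c("ASR", "NTS", "+"), c("ACR", "NTS", "+"),
    c("JGC", "SFO", "+"), c("DTC", "SFO", "-")),
    nodeClass = unname(cls), theta = unname(classDefaultTheta[cls]))
}

#' @rdname aarFullGraph
#' @export
aarReducedGraph <- function() {
  cls <- aarNodeClasses()[1:6]
  signedDigraph(names(cls), edgeFrame(
    c("JGC", "ACO", "+"), c("HMY", "ACO", "-"),
    c("HMY", "JGC", "-"), c("DTC", "JGC", "-"),
    c("DTC", "HMY", "+"), c("VSM", "HMY", "+"),
    c("JGC", "SPN", "+"), c("DTC", "SPN", "-"), c("VSM", "SPN", "-"),
    c("ACO", "DTC", "+"), c("HMY", "DTC", "-"), c("SPN", "DTC", "+"),
    c("JGC", "VSM", "+"), c("HMY", "VSM", "-"), c("SPN", "VSM", "+")),
    nodeClass = unname(cls), theta = unname(classDefaultTheta[cls]))
}

#' @rdname aarFullGraph
#' @export
aarDtcGraph <- function() {
  g <- aarReducedGraph()
  inducedSubgraph(g, c("ACO", "JGC", "HMY", "SPN", "DTC"))
}

#' @rdname aarFullGraph
#' @export
aarVsmGraph <- function() {
  g <- aarReducedGraph()
  inducedSubgraph(g, c("ACO", "JGC", "HMY", "SPN", "VSM"))
}

aavNodeClasses <- function() {
  cls <- c(rep("intracellular", 15), "endocrine", "endocrine", "nerve",
           "stretch", "stretch")
  stats::setNames(cls, paste0("x_", 1:20))
}

#' @rdname aarFullGraph
#' @export
aavGraph <- function(tau1 = 3, tau2 = 3, tau3 = 3) {
  cls <- aavNodeClasses()
  th <- unname(classDefaultTheta[cls])
  th[1] <- 0.5        # actomyosin: overall VSM response time constant
  signedDigraph(names(cls), edgeFrame(
    c("x_2", "x_1", "-"), c("x_3", "x_1", "+"),
    c("x_6", "x_2", "-"),
    c("x_4", "x_3", "-"), c("x_5", "x_3", "+"), c("x_9", "x_3", "+"),
    c("x_7", "x_4", "+"), c("x_8", "x_4", "-"), c("x_9", "x_4", "-"),
    c("x_6", "x_5", "+"),
    c("x_10", "x_6", "+"), c("x_13", "x_6", "-"),
    c("x_14", "x_7", "+"),
    c("x_9", "x_8", "+"),
    c("x_12", "x_9", "+"),
    c("x_11", "x_10", "+"),
    c("x_15", "x_11", "+"),
    c("x_15", "x_12", "+"),
    c("x_14", "x_13", "+"),
    c("x_16", "x_14", "+"),
    c("x_17", "x_15", "+"),
    c("x_19", "x_16", "+", tau1),
    c("x_18", "x_17", "-"),
    c("x_19", "x_18", "+", tau3), c("x_20", "x_18", "+", tau2),
    c("x_1", "x_19", "+"),
    c("x_1", "x_20", "+")),
    nodeClass = unname(cls), theta = th)
}

#' Sign matrices of the reduced AAR schemes
#'
#' `sigmaAAR()` is the interaction matrix of the 6-variable reduced AAR
#' network; `sigmaDTC()` and `sigmaVSM()` are those of the two 5-node
#' regulation schemes.  Identical to
#' `interactionMatrix(aarReducedGraph())` etc.; provided as explicit
#' constructors for direct use in influence analysis.
#'
#' @return a [SignMatrix-class].
#' @export
sigmaAAR <- function() interactionMatrix(aarReducedGraph())

#' @rdname sigmaAAR
#' @export
sigmaDTC <- function() interactionMatrix(aarDtcGraph())

#' @rdname sigmaAAR
#' @export
sigmaVSM <- function() interactionMatrix(aarVsmGraph())
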