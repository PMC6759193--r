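#' Build a signed interaction digraph
#'
#' @param nodes ordered character vector of unique node labels.
#' @param edges `data.frame` with columns `from`, `to`, `sign` (+1/-1)
#'   and optionally `delay` (nonnegative minutes, default 0).  Signs may
#'   also be given as `"+"`/`"-"`.
#' @param nodeClass optional character vector of time-scale classes
#'   parallel to `nodes`.
#' @param theta optional numeric vector of nominal time constants
#'   (minutes) parallel to `nodes`.
#' @return a [SignedDigraph-class].
#' @examples
#' g <- signedDigraph(c("a", "b"),
#'                    data.frame(from = c("a", "b"), to = c("b", "a"),
#'                               sign = c(1, -1)))
#' enumerateCycles(g)[[1]]$sign   # -1: a negative two-cycle
#' @export
signedDigraph <- function(nodes, edges = NULL, nodeClass = NULL,
                          theta = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        sign = numeric(0), delay = numeric(0))
  } else {
    edges <- as.data.frame(edges)
    if (is.character(edges$sign))
      edges$sign <- ifelse(edges$sign == "+", 1, -1)
    if (is.null(edges$delay)) edges$delay <- 0
    edges <- edges[, c("from", "to", "sign", "delay")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$sign <- as.numeric(edges$sign)
    edges$delay <- as.numeric(edges$delay)
    rownames(edges) <- NULL
  }
  new("SignedDigraph", nodes = nodes,
      nodeClass = nodeClass %||% rep(NA_character_, length(nodes)),
      theta = theta %||% rep(NA_real_, length(nodes)),
      edges = edges)
}

#' @rdname accessors
#' @export
setMethod("nodeLabels", "SignedDigraph", function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("edgeTable", "SignedDigraph", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("nodeClasses", "SignedDigraph", function(object)
  stats::setNames(object@nodeClass, object@nodes))

#' @rdname accessors
#' @export
setMethod("thetaMinutes", "SignedDigraph", function(object)
  stats::setNames(object@theta, object@nodes))

setMethod("show", "SignedDigraph", function(object) {
  e <- object@edges
  cat(sprintf("SignedDigraph: %d nodes, %d arcs (%d activating, %d inhibitory, %d delayed)\n",
              length(object@nodes), nrow(e), sum(e$sign > 0),
              sum(e$sign < 0), sum(e$delay > 0)))
  cat("  nodes:", paste(utils::head(object@nodes, 10), collapse = ", "),
      if (length(object@nodes) > 10) "..." else "", "\n")
})

adjacencyList <- function(graph, reverse = FALSE) {
  e <- graph@edges
  adj <- stats::setNames(vector("list", length(graph@nodes)), graph@nodes)
  for (v in graph@nodes) adj[[v]] <- character(0)
  if (nrow(e)) {
    a <- if (reverse) e$to else e$from
    b <- if (reverse) e$from else e$to
    for (i in seq_len(nrow(e))) adj[[a[i]]] <- c(adj[[a[i]]], b[i])
  }
  adj
}

#' Induced subgraph on a subset of nodes
#'
#' @param graph a [SignedDigraph-class].
#' @param keep character vector of node labels to retain.
#' @return the induced [SignedDigraph-class] (arcs with both endpoints
#'   in `keep`).
#' @export
inducedSubgraph <- function(graph, keep) {
  unknown <- setdiff(keep, graph@nodes)
  if (length(unknown))
    stop("unknown node labels: ", paste(unknown, collapse = ", "))
  sel <- graph@nodes %in% keep
  e <- graph@edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  rownames(e) <- NULL
  new("SignedDigraph", nodes = graph@nodes[sel],
      nodeClass = graph@nodeClass[sel], theta = graph@theta[sel],
      edges = e)
}

#' @describeIn interactionMatrix sign matrix of a signed digraph: entry
#'   (i, j) is the sign of the arc from j to i, the diagonal is -1.
#' @export
setMethod("interactionMatrix", "SignedDigraph", function(object, order = NULL) {
  order <- order %||% object@nodes
  if (!setequal(order, object@nodes) || length(order) != length(object@nodes))
    stop("'order' must be a permutation of the node labels")
  n <- length(order)
  m <- matrix(0, n, n, dimnames = list(order, order))
  diag(m) <- -1
  e <- object@edges
  for (i in seq_len(nrow(e))) m[e$to[i], e$from[i]] <- e$sign[i]
  new("SignMatrix", mat = m)
})

#' Construct a sign matrix directly
#'
#' @param mat numeric matrix with entries in `{-1, 0, +1}`, identical
#'   row/column names and a -1 diagonal.
#' @return a [SignMatrix-class].
#' @export
signMatrix <- function(mat) new("SignMatrix", mat = mat)

#' @rdname accessors
#' @export
setMethod("signPattern", "SignMatrix", function(object) object@mat)

#' @rdname accessors
#' @export
setMethod("nodeLabels", "SignMatrix", function(object) rownames(object@mat))

setMethod("show", "SignMatrix", function(object) {
  cat(sprintf("SignMatrix (%d x %d):\n", nrow(object@mat), ncol(object@mat)))
  disp <- matrix(c("-", "0", "+")[object@mat + 2],
                 nrow(object@mat), dimnames = dimnames(object@mat))
  print(disp, quote = FALSE)
})

#' Rebuild the signed digraph encoded by a sign matrix
#'
#' Inverse of [interactionMatrix()]: each nonzero off-diagonal entry
#' (i, j) becomes an arc from j to i with that sign.  The -1 diagonal is
#' dropped (self-decay is implicit).
#'
#' @param sigma a [SignMatrix-class].
#' @return a [SignedDigraph-class].
#' @export
graphFromSignMatrix <- function(sigma) {
  m <- sigma@mat
  lab <- rownames(m)
  idx <- which(m != 0 & row(m) != col(m), arr.ind = TRUE)
  edges <- data.frame(from = lab[idx[, "col"]], to = lab[idx[, "row"]],
                      sign = m[idx], delay = 0)
  edges <- edges[order(match(edges$from, lab), match(edges$to, lab)), ]
  rownames(edges) <- NULL
  signedDigraph(lab, edges)
}

#' @describeIn enumerateCycles elementary-circuit search by depth-first
#'   traversal restricted to start nodes of smallest index, so each
#'   cycle is produced exactly once in canonical rotation.
#' @export
setMethod("enumerateCycles", "SignedDigraph", function(object) {
  nodes <- object@nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  e <- object@edges
  adj <- stats::setNames(vector("list", n), nodes)
  sgn <- list()
  for (v in nodes) adj[[v]] <- character(0)
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
    sgn[[paste(e$from[i], e$to[i])]] <- e$sign[i]
  }
  cycles <- list()
  path <- character(0)
  onPath <- stats::setNames(logical(n), nodes)
  start <- NA_character_
  visit <- function(v, acc) {
    path <<- c(path, v)
    onPath[v] <<- TRUE
    for (w in adj[[v]]) {
      s <- acc * sgn[[paste(v, w)]]
      if (w == start) {
        cycles[[length(cycles) + 1L]] <<- list(nodes = path, sign = s)
      } else if (idx[[w]] > idx[[start]] && !onPath[[w]]) {
        visit(w, s)
      }
    }
    path <<- path[-length(path)]
    onPath[v] <<- FALSE
  }
  for (s in nodes) {
    start <- s
    visit(s, 1)
  }
  cycles
})

#' Candidate-oscillator structure check
#'
#' A network is a candidate oscillator when it is the negative feedback
#' loop of a monotone system: it then admits a single equilibrium that
#' is either stable (homeostasis) or gives rise to persistent
#' oscillations.  A necessary structural signature is that every
#' elementary cycle is negative; optionally all cycles must pass through
#' a pivot node.
#'
#' @param graph a [SignedDigraph-class].
#' @param pivot optional node label every cycle must contain.
#' @return list with elements `ok` (logical), `nCycles`,
#'   `positiveCycles` (list of offending cycles) and `missingPivot`
#'   (cycles avoiding the pivot).
#' @examples
#' candidateOscillatorCheck(aavGraph(), pivot = "x_1")$ok  # TRUE
#' @export
candidateOscillatorCheck <- function(graph, pivot = NULL) {
  if (!is.null(pivot) && !(pivot %in% graph@nodes))
    stop("unknown pivot label: ", pivot)
  cyc <- enumerateCycles(graph)
  pos <- Filter(function(cy) cy$sign > 0, cyc)
  miss <- if (is.null(pivot)) list() else
    Filter(function(cy) !(pivot %in% cy$nodes), cyc)
  list(ok = length(pos) == 0L && length(miss) == 0L,
       nCycles = length(cyc), positiveCycles = pos, missingPivot = miss)
}

#' Find a cooperative gauge for a subsystem
#'
#' Searches for a sign change of variables making every arc internal to
#' the subsystem activating.  Such a gauge exists iff the subsystem's
#' signed structure is balanced, decided exactly by two-colouring each
#' connected component by arc sign.  The returned gauge is normalised so
#' the lowest-ordered node of each component keeps sign +1.
#'
#' @param graph a [SignedDigraph-class].
#' @param subsystem nonempty character vector of node labels.
#' @return named vector of +1/-1 over the subsystem, or `NULL` when no
#'   cooperative gauge exists.
#' @examples
#' sigma <- findCooperativeGauge(aarReducedGraph(),
#'                               c("ACO", "JGC", "HMY", "SPN"))
#' names(sigma)[sigma < 0]   # "HMY"
#' @export
findCooperativeGauge <- function(graph, subsystem) {
  unknown <- setdiff(subsystem, graph@nodes)
  if (length(unknown))
    stop("unknown node labels: ", paste(unknown, collapse = ", "))
  if (length(subsystem) == 0L) stop("subsystem must be nonempty")
  sub <- inducedSubgraph(graph, subsystem)
  nodes <- sub@nodes
  e <- sub@edges
  ## constraint per unordered pair: sigma_u * sigma_v = arc sign;
  ## contradictory parallel/antiparallel arcs make it unsatisfiable
  con <- list()
  for (i in seq_len(nrow(e))) {
    key <- paste(sort(c(e$from[i], e$to[i])), collapse = "\r")
    if (!is.null(con[[key]]) && con[[key]] != e$sign[i]) return(NULL)
    con[[key]] <- e$sign[i]
  }
  nbr <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) nbr[[v]] <- character(0)
  for (key in names(con)) {
    uv <- strsplit(key, "\r", fixed = TRUE)[[1]]
    nbr[[uv[1]]] <- c(nbr[[uv[1]]], uv[2])
    nbr[[uv[2]]] <- c(nbr[[uv[2]]], uv[1])
  }
  sigma <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  for (root in nodes) {
    if (!is.na(sigma[[root]])) next
    sigma[[root]] <- 1
    queue <- root
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      for (w in nbr[[u]]) {
        key <- paste(sort(c(u, w)), collapse = "\r")
        want <- sigma[[u]] * con[[key]]
        if (is.na(sigma[[w]])) {
          sigma[[w]] <- want
          queue <- c(queue, w)
        } else if (sigma[[w]] != want) {
          return(NULL)
        }
      }
    }
  }
  sigma
}

#' Is the induced subsystem a directed acyclic graph?
#'
#' @param graph a [SignedDigraph-class].
#' @param subsystem character vector of node labels (defaults to the
#'   whole graph).
#' @return `TRUE` iff the induced subgraph has no directed cycle.
#' @examples
#' isInternalDag(aavGraph(), paste0("x_", 1:15))  # TRUE
#' @export
isInternalDag <- function(graph, subsystem = nodeLabels(graph)) {
  sub <- inducedSubgraph(graph, subsystem)
  !is.null(topoSort(sub@nodes, adjacencyList(sub)))
}

normalizeGauge <- function(object, gauge) {
  labs <- nodeLabels(object)
  if (is.character(gauge)) {
    unknown <- setdiff(gauge, labs)
    if (length(unknown))
      stop("unknown node labels: ", paste(unknown, collapse = ", "))
    g <- stats::setNames(rep(1, length(labs)), labs)
    g[gauge] <- -1
    return(g)
  }
  if (!all(gauge %in% c(-1, 1))) stop("gauge entries must be +1 or -1")
  g <- stats::setNames(rep(1, length(labs)), labs)
  g[names(gauge)] <- gauge
  g
}

#' @describeIn applyGauge arcs incident to flipped nodes change sign.
#' @export
setMethod("applyGauge", "SignedDigraph", function(object, gauge) {
  g <- normalizeGauge(object, gauge)
  e <- object@edges
  if (nrow(e)) e$sign <- e$sign * g[e$from] * g[e$to]
  rownames(e) <- NULL
  initialize(object, edges = e)
})

#' @describeIn applyGauge conjugation by the diagonal sign matrix; the
#'   diagonal is preserved.
#' @export
setMethod("applyGauge", "SignMatrix", function(object, gauge) {
  g <- normalizeGauge(object, gauge)
  m <- diag(g) %*% object@mat %*% diag(g)
  dimnames(m) <- dimnames(object@mat)
  new("SignMatrix", mat = m)
})
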