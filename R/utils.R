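# Internal helpers shared across modules.

## Topological sort of a directed graph given as an adjacency list
## (list keyed by node label, each element the character vector of
## successors).  Returns the node order, or NULL if a cycle exists.
topoSort <- function(nodes, adj) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in nodes) {
    for (w in adj[[v]]) indeg[[w]] <- indeg[[w]] + 1L
  }
  queue <- nodes[indeg[nodes] == 0L]
  out <- character(0)
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

## Connected components of an undirected adjacency list; returns a list
## of character vectors, each ordered as in `nodes`.
undirectedComponents <- function(nodes, adj) {
  seen <- stats::setNames(logical(length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[[v]]) next
    comp <- character(0)
    queue <- v
    seen[[v]] <- TRUE
    while (length(queue) > 0L) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, u)
      for (w in adj[[u]]) {
        if (!seen[[w]]) {
          seen[[w]] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- nodes[nodes %in% comp]
  }
  comps
}

## Sign-class algebra over {+, -, 0, ?}, represented internally as the
## set of term signs observed (integer subset of c(-1L, 1L)).
signSetToClass <- function(s) {
  s <- unique(s)
  if (length(s) == 0L) return("0")
  if (all(s == 1L)) return("+")
  if (all(s == -1L)) return("-")
  "?"
}

flipSignClass <- function(cls) {
  switch(cls, "+" = "-", "-" = "+", cls)
}

## Sign classification of det(M) where M is a sign-pattern matrix with
## entries in {-1, 0, +1} and every nonzero entry stands for a free
## positive magnitude times that sign.  Expands the determinant into
## permutation terms (skipping zero entries) and collects the term
## signs; exact because independent magnitudes can make any single
## monomial dominate.  Early exit once both signs are seen.
detSignSet <- function(M) {
  n <- nrow(M)
  if (n == 0L) return(1L)           # det of empty matrix = +1
  signs <- integer(0)
  rows <- seq_len(n)
  recurse <- function(col, used, acc) {
    if (length(signs) == 2L) return()
    if (col > n) {
      signs <<- unique(c(signs, acc))
      return()
    }
    for (r in rows[!used]) {
      e <- M[r, col]
      if (e == 0) next
      ## parity contribution: number of unused rows above r
      above <- sum(!used[seq_len(r - 1L)])
      parity <- if (above %% 2L == 0L) 1L else -1L
      used2 <- used
      used2[r] <- TRUE
      recurse(col + 1L, used2, acc * parity * as.integer(e))
    }
  }
  recurse(1L, logical(n), 1L)
  signs
}

## Inline-or-default, used for optional arguments.
`%||%` <- function(a, b) if (is.null(a)) b else a
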