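#' Read / write signed digraphs as JSON
#'
#' The interchange format is a JSON object with a `nodes` array of
#' `{"label": ..., "theta_minutes": ...}` records (optionally a
#' `"class"` field) and an `edges` array of
#' `{"from": ..., "to": ..., "sign": "+"|"-", "delay_minutes": ...}`
#' records.
#'
#' @param path file path.
#' @return `readGraphJSON` returns a [SignedDigraph-class];
#'   `writeGraphJSON` returns `path` invisibly.
#' @examples
#' p <- file.path(tempdir(), "g.json")
#' writeGraphJSON(aarDtcGraph(), p)
#' identical(edgeTable(readGraphJSON(p)), edgeTable(aarDtcGraph()))
#' @export
readGraphJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  nodes <- obj$nodes
  edges <- obj$edges
  e <- if (is.null(edges) || length(edges) == 0L) NULL else
    data.frame(from = edges$from, to = edges$to,
               sign = ifelse(edges$sign == "+", 1, -1),
               delay = edges$delay_minutes %||% rep(0, nrow(edges)))
  signedDigraph(nodes$label, e,
                nodeClass = if (!is.null(nodes$class)) nodes$class,
                theta = nodes$theta_minutes)
}

#' @param graph a [SignedDigraph-class].
#' @rdname readGraphJSON
#' @export
writeGraphJSON <- function(graph, path) {
  e <- graph@edges
  obj <- list(
    nodes = data.frame(label = graph@nodes,
                       theta_minutes = graph@theta,
                       class = graph@nodeClass),
    edges = data.frame(from = e$from, to = e$to,
                       sign = ifelse(e$sign > 0, "+", "-"),
                       delay_minutes = e$delay))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Export the arc list as tab-separated values
#'
#' Columns `from`, `to`, `sign` (`+`/`-`), `delay`, with a header row.
#'
#' @param graph a [SignedDigraph-class].
#' @param path file path.
#' @export
writeEdgeTSV <- function(graph, path) {
  e <- graph@edges
  out <- data.frame(from = e$from, to = e$to,
                    sign = ifelse(e$sign > 0, "+", "-"), delay = e$delay)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an influence matrix as CSV
#'
#' Entries `"+"`, `"-"`, `"0"`, `"?"` with a labelled header row and a
#' leading label column.
#'
#' @param x an [InfluenceMatrix-class] (or character matrix).
#' @param path file path.
#' @export
writeInfluenceCSV <- function(x, path) {
  m <- if (is(x, "InfluenceMatrix")) x@mat else x
  utils::write.csv(as.data.frame(m), path, quote = FALSE)
  invisible(path)
}

#' Export a trajectory as CSV
#'
#' One `time` column (minutes) plus one column per labelled state.
#'
#' @param traj a [Trajectory-class].
#' @param path file path.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  out <- data.frame(time = traj@time, traj@state, check.names = FALSE)
  utils::write.csv(out, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
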