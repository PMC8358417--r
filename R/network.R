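# Comparator benefit network: one directed edge per graded trial, from the
# comparator arm to the experimental arm, weighted by the final MCBS grade.

#' Normalize a treatment-arm label
#'
#' Case-folds, collapses whitespace, rewrites "plus"/"+" conjunctions to the
#' slash form, and then canonicalizes through a curated synonym table so
#' that e.g. "Carboplatin plus paclitaxel" and "carboplatin/paclitaxel"
#' merge to one network node.
#'
#' @param label Arm label as printed.
#' @param synonyms Synonym table with columns `variant`, `canonical`;
#'   defaults to the curated table shipped with the package.
#' @return Normalized label string.
#' @export
normalize_arm_label <- function(label, synonyms = arm_synonyms()) {
  x <- tolower(trimws(label))
  x <- gsub("\\s+", " ", x)
  x <- gsub(" \\+ | plus ", "/", x)
  x <- gsub("\\s*/\\s*", "/", x)
  hit <- match(x, synonyms$variant)
  if (!is.na(hit)) x <- synonyms$canonical[hit]
  x
}

#' Curated arm-label synonym table
#'
#' @return data.frame with columns `variant`, `canonical`.
#' @export
arm_synonyms <- function() {
  path <- system.file("extdata", "arm_synonyms.csv", package = "mcbscore")
  utils::read.csv(path, colClasses = "character")
}

#' Build the relative-benefit comparator network for one setting
#'
#' One directed edge per graded trial in the setting, from the normalized
#' comparator label to the normalized experimental label, carrying the final
#' MCBS grade as edge weight (the "distance" between the arms), together
#' with the trial id and setting. Ungraded trials contribute no edge.
#'
#' @param records List of [trial_record()]s.
#' @param results List of [graded_result()]s covering every record (matched
#'   by `trial_id`; a missing result is an error naming the trial).
#' @param setting Which treatment setting to build
#'   (`"platinum_sensitive"`, `"maintenance"`, `"platinum_resistant"`).
#' @return An [igraph::igraph] directed graph with vertex attribute `name`
#'   and edge attributes `grade`, `trial_id`, `setting`.
#' @export
build_network <- function(records, results,
                          setting = c("platinum_sensitive", "maintenance",
                                      "platinum_resistant")) {
  setting <- match.arg(setting)
  ids <- vapply(results, `[[`, character(1), "trial_id")
  edges <- list()
  for (record in records) {
    hit <- match(record$trial_id, ids)
    if (is.na(hit))
      stop("no graded result for trial '", record$trial_id, "'", call. = FALSE)
    if (!identical(record$setting, setting)) next
    res <- results[[hit]]
    if (identical(res$form, "not_graded")) next
    src <- normalize_arm_label(record$comparator_label)
    dst <- normalize_arm_label(record$experimental_label)
    if (identical(src, dst))
      stop("degenerate edge for trial '", record$trial_id,
           "': comparator and experimental arm normalize to the same label",
           call. = FALSE)
    edges[[length(edges) + 1L]] <- data.frame(
      from = src, to = dst, grade = res$final,
      trial_id = record$trial_id, setting = setting,
      stringsAsFactors = FALSE)
  }
  if (length(edges) == 0L)
    return(igraph::make_empty_graph(directed = TRUE))
  df <- do.call(rbind, edges)
  dup <- duplicated(df[, c("from", "to", "trial_id")])
  df <- df[!dup, , drop = FALSE]
  igraph::graph_from_data_frame(df, directed = TRUE)
}

#' Export a benefit network
#'
#' Writes the graph in DOT, GraphML, or a JSON nodes/edges document. DOT and
#' GraphML exports preserve the `grade` and `trial_id` edge attributes via
#' igraph's writers; the JSON form round-trips through [import_network()].
#'
#' @param network An igraph graph from [build_network()].
#' @param path Output file path.
#' @param format `"dot"`, `"graphml"` or `"json"`.
#' @export
export_network <- function(network, path, format = c("dot", "graphml", "json")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown network format", call. = FALSE))
  if (format %in% c("dot", "graphml")) {
    igraph::write_graph(network, path, format = format)
    return(invisible(NULL))
  }
  el <- igraph::as_data_frame(network, what = "edges")
  nodes <- igraph::V(network)$name %||% character()
  jsonlite::write_json(
    list(nodes = as.list(nodes),
         edges = lapply(seq_len(nrow(el)), function(i) as.list(el[i, ]))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Import a JSON benefit network written by [export_network()]
#'
#' @param path JSON file path.
#' @return An igraph directed graph.
#' @export
import_network <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- unlist(raw$nodes, use.names = FALSE) %||% character()
  if (length(raw$edges) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
    return(igraph::add_vertices(g, length(nodes), name = nodes))
  }
  df <- do.call(rbind, lapply(raw$edges, function(e)
    data.frame(from = e$from, to = e$to, grade = as.integer(e$grade),
               trial_id = e$trial_id, setting = e$setting,
               stringsAsFactors = FALSE)))
  igraph::graph_from_data_frame(df, directed = TRUE,
                                vertices = data.frame(name = nodes))
}
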