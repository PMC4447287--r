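dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a solution as Graphviz DOT text
#'
#' Emits a syntactically valid DOT digraph of the full PKN with the trained
#' solution highlighted: stimuli are filled light blue, measured signals
#' light green, other included nodes cyan; conflict nodes admitted into the
#' solution carry a crimson outline; nodes and reactions excluded from the
#' compressed model are drawn dashed.
#'
#' @param state a [solution_state].
#' @param file optional output path; when `NULL` the DOT text is returned
#'   only.
#' @return the DOT text as a single string, invisibly when `file` is given.
#' @export
write_dot <- function(state, file = NULL) {
  stopifnot(inherits(state, "solution_state"))
  net <- state$net
  m <- state$m
  inc_nodes <- included_nodes(state)
  inc_keys <- edge_key_set(state)
  conflicts <- unique(unlist(state$admitted, use.names = FALSE))

  node_lines <- vapply(net$nodes, function(nd) {
    fill <- if (nd %in% m$stimuli) "lightblue"
    else if (nd %in% m$signals) "lightgreen"
    else if (nd %in% inc_nodes) "cyan"
    else "white"
    style <- if (nd %in% inc_nodes) "filled" else "filled,dashed"
    attrs <- sprintf('style="%s", fillcolor="%s"', style, fill)
    if (nd %in% conflicts) {
      attrs <- paste0(attrs, ', color="crimson", penwidth=2')
    }
    sprintf("  %s [%s];", dot_quote(nd), attrs)
  }, character(1))

  en <- edge_names(net)
  edge_lines <- if (nrow(en)) {
    keys <- paste(en[, 1L], en[, 2L], sep = "\t")
    vapply(seq_len(nrow(en)), function(i) {
      solid <- keys[[i]] %in% inc_keys
      sprintf("  %s -> %s%s;", dot_quote(en[i, 1L]), dot_quote(en[i, 2L]),
              if (solid) "" else ' [style="dashed"]')
    }, character(1))
  } else character()

  dot <- paste(c("digraph compressed_model {",
                 "  rankdir=LR;",
                 '  node [shape=ellipse];',
                 node_lines, edge_lines, "}"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}

#' Write the per-dependency decision log
#'
#' Exports [decision_log()] both as line-oriented text (`<file>.log`) and as
#' machine-readable JSON (`<file>.json`).
#'
#' @param state a [solution_state].
#' @param stem output path stem (extensions are appended).
#' @return character vector of the two paths written, invisibly.
#' @export
write_decision_log <- function(state, stem) {
  recs <- decision_log(state)
  txt <- vapply(recs, function(r) {
    sprintf("k=%d %s -> %s: %s%s%s", r$k, r$stimulus, r$signal, r$status,
            if (!is.null(r$path)) paste0(" path=", paste(r$path, collapse = ",")) else "",
            if (!is.na(r$score)) paste0(" score=", r$score) else "")
  }, character(1))
  txt_file <- paste0(stem, ".log")
  json_file <- paste0(stem, ".json")
  writeLines(txt, txt_file)
  jsonlite::write_json(recs, json_file, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(c(txt_file, json_file))
}
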