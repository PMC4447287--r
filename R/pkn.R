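#' Prior knowledge network (PKN)
#'
#' A PKN is a directed graph of named protein nodes and unit-weight reactions
#' (edges), used as the scaffold for network training. Nodes are kept in
#' first-appearance order and indexed 1..n_V; every reaction has a reactant
#' and a product and an implicit weight of +1.
#'
#' @param edges a two-column character matrix or data frame; column 1 holds
#'   reactants, column 2 products.
#' @param nodes optional character vector fixing the node order; must contain
#'   every edge endpoint. By default nodes are collected in first-appearance
#'   order (reactant before product, edge by edge).
#' @return an object of class `"pkn"`: a list with elements `nodes`
#'   (character), `edges` (integer matrix, one row per reaction, columns
#'   `from`/`to`), and `adj` (per-node integer list of out-neighbours in
#'   edge-input order).
#' @examples
#' net <- pkn(cbind(c("EGF", "EGFR"), c("EGFR", "GRB2")))
#' n_nodes(net)
#' @export
pkn <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), 0L, 2L)
  }
  if (ncol(edges) != 2L) {
    stop("`edges` must have exactly two columns (reactant, product)")
  }
  storage.mode(edges) <- "character"
  edges[] <- trimws(edges)
  if (any(edges == "")) stop("empty node name in edge list")
  if (is.null(nodes)) {
    nodes <- unique(as.vector(t(edges)))
  } else {
    nodes <- trimws(as.character(nodes))
    if (anyDuplicated(nodes)) stop("duplicate names in `nodes`")
    missing <- setdiff(unique(as.vector(edges)), nodes)
    if (length(missing)) {
      stop("edge endpoint(s) not in `nodes`: ", paste(missing, collapse = ", "))
    }
  }
  if (length(nodes) < 1L) stop("a PKN must contain at least one node")
  ei <- matrix(match(edges, nodes), ncol = 2L,
               dimnames = list(NULL, c("from", "to")))
  structure(
    list(nodes = nodes, edges = ei, adj = build_adjacency(ei, length(nodes))),
    class = "pkn"
  )
}

build_adjacency <- function(edges, n) {
  adj <- rep(list(integer()), n)
  if (nrow(edges)) {
    sp <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(n)))
    adj <- lapply(sp, as.integer)
  }
  adj
}

#' @rdname pkn
#' @param net,x a `pkn` object.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname pkn
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname pkn
#' @return `edge_names()` returns the reactions as a two-column character
#'   matrix in edge-input order.
#' @export
edge_names <- function(net) {
  matrix(net$nodes[net$edges], ncol = 2L,
         dimnames = list(NULL, c("from", "to")))
}

#' @rdname pkn
#' @param ... ignored.
#' @export
print.pkn <- function(x, ...) {
  cat(sprintf("PKN: %d nodes, %d reactions\n", n_nodes(x), n_edges(x)))
  rep_ <- attr(x, "parse_report")
  if (!is.null(rep_)) {
    cat(sprintf("  parsed from %d line(s); %d duplicate(s), %d self-loop(s) dropped\n",
                rep_$lines_read, rep_$duplicates_dropped, rep_$self_loops_dropped))
  }
  show <- utils::head(edge_names(x), 6L)
  if (nrow(show)) {
    cat(paste0("  ", show[, 1L], " -> ", show[, 2L], collapse = "\n"), "\n")
    if (n_edges(x) > 6L) cat(sprintf("  ... %d more\n", n_edges(x) - 6L))
  }
  invisible(x)
}

node_index <- function(net, name) {
  i <- match(name, net$nodes)
  if (anyNA(i)) {
    stop("unknown node name(s): ", paste(name[is.na(i)], collapse = ", "))
  }
  i
}

#' Parse a tab-delimited directed edge list into a PKN
#'
#' Reads the plain-text reaction format: one reaction per line,
#' `reactant<TAB>product`. Lines starting with `#` are treated as comments;
#' blank lines are skipped; CRLF endings are tolerated. Duplicate reactions
#' are collapsed and self-loops dropped (they cannot affect shortest paths or
#' reachability); both are counted in the attached parse report. Node names
#' are case-sensitive and whitespace-trimmed.
#'
#' @param file path to an edge-list file. Exactly one of `file`/`text` must
#'   be given.
#' @param text edge-list content as a single string or character vector of
#'   lines (mostly for examples and tests).
#' @param sif3 if `TRUE`, accept 3-column simple-interaction-format lines
#'   (`source<TAB>relation<TAB>target`) and ignore the middle column.
#' @return a [pkn] with attribute `"parse_report"`: a list with
#'   `lines_read`, `edges_kept`, `duplicates_dropped`, `self_loops_dropped`.
#' @examples
#' net <- parse_edge_list(text = "EGF\tEGFR\nEGFR\tGRB2")
#' attr(net, "parse_report")$edges_kept
#' @export
parse_edge_list <- function(file = NULL, text = NULL, sif3 = FALSE) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `file` or `text`")
  }
  if (is.null(text)) {
    if (!file.exists(file)) stop("edge-list file not found: ", file)
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)
  n_raw <- length(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  want <- if (sif3) 3L else 2L
  from <- to <- character(0)
  for (ln in which(keep)) {
    fields <- trimws(strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]])
    if (length(fields) != want || any(fields == "")) {
      stop(sprintf("malformed edge-list line %d: expected %d tab-separated fields, got %d",
                   ln, want, length(fields)))
    }
    from <- c(from, fields[[1L]])
    to <- c(to, fields[[want]])
  }
  if (!length(from)) stop("edge-list contains no reactions")
  self <- from == to
  if (any(self)) {
    warning(sprintf("dropped %d self-loop(s)", sum(self)))
    from <- from[!self]; to <- to[!self]
  }
  if (!length(from)) stop("edge-list contains no reactions after dropping self-loops")
  key <- paste(from, to, sep = "\t")
  dup <- duplicated(key)
  net <- pkn(cbind(from[!dup], to[!dup]))
  attr(net, "parse_report") <- list(
    lines_read = n_raw,
    edges_kept = sum(!dup),
    duplicates_dropped = sum(dup),
    self_loops_dropped = sum(self)
  )
  net
}

#' All-pairs shortest paths with canonical path reconstruction
#'
#' Runs the Floyd-Warshall algorithm on the unit-weight PKN, producing the
#' n_V x n_V distance matrix and a next-hop matrix encoding one canonical
#' shortest path per ordered node pair. Intermediate nodes are scanned in
#' ascending first-appearance index and a path is replaced only on strict
#' improvement, so ties are broken deterministically and repeated runs give
#' identical paths.
#'
#' @param net a [pkn].
#' @return an object of class `"shortest_path_table"`: list with `dist`
#'   (integer matrix, `NA` marking unreachable pairs, zero diagonal),
#'   `next_hop` (integer matrix: the node index following the row node on the
#'   canonical path to the column node), and `nodes`.
#' @examples
#' net <- parse_edge_list(text = "A\tB\nB\tC")
#' tab <- all_pairs_shortest_paths(net)
#' tab$dist["A", "C"]
#' @export
all_pairs_shortest_paths <- function(net) {
  stopifnot(inherits(net, "pkn"))
  n <- n_nodes(net)
  inf <- n  # any true distance is <= n - 1
  d <- matrix(inf, n, n)
  nh <- matrix(NA_integer_, n, n)
  if (nrow(net$edges)) {
    # first-seen edge wins when duplicates slipped past the parser
    e <- net$edges[!duplicated(net$edges), , drop = FALSE]
    d[e] <- 1L
    nh[e] <- e[, 2L]
  }
  diag(d) <- 0L
  nh[cbind(seq_len(n), seq_len(n))] <- seq_len(n)
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], `+`)
    better <- via < d
    if (any(better)) {
      d[better] <- via[better]
      nh[better] <- nh[, k][row(d)[better]]
    }
  }
  unreach <- d >= inf
  d[unreach] <- NA_integer_
  nh[unreach] <- NA_integer_
  storage.mode(d) <- "integer"
  dimnames(d) <- dimnames(nh) <- list(net$nodes, net$nodes)
  structure(list(dist = d, next_hop = nh, nodes = net$nodes),
            class = "shortest_path_table")
}

#' @export
print.shortest_path_table <- function(x, ...) {
  n <- length(x$nodes)
  cat(sprintf("shortest-path table over %d nodes (%d reachable ordered pairs)\n",
              n, sum(!is.na(x$dist)) - n))
  invisible(x)
}

#' Read one canonical shortest path back from the table
#'
#' @param table a [all_pairs_shortest_paths] result.
#' @param source,target node names.
#' @return a character vector of node names from `source` to `target`
#'   (length `dist + 1`), or `NULL` when the target is unreachable. The
#'   zero-length path from a node to itself is that single node.
#' @export
path_between <- function(table, source, target) {
  stopifnot(inherits(table, "shortest_path_table"))
  i <- match(source, table$nodes)
  j <- match(target, table$nodes)
  if (is.na(i) || is.na(j)) {
    stop("unknown node name(s): ",
         paste(c(source, target)[is.na(c(i, j))], collapse = ", "))
  }
  if (is.na(table$dist[i, j])) return(NULL)
  path <- i
  while (i != j) {
    i <- table$next_hop[i, j]
    path <- c(path, i)
  }
  table$nodes[path]
}

# integer BFS reachability over an adjacency list; returns logical vector
reach_logical <- function(adj, sources, blocked = integer()) {
  n <- length(adj)
  seen <- logical(n)
  if (length(blocked)) {
    ok <- !(sources %in% blocked)
    sources <- sources[ok]
  }
  seen[sources] <- TRUE
  frontier <- sources
  while (length(frontier)) {
    nxt <- unlist(adj[frontier], use.names = FALSE)
    if (length(blocked)) nxt <- nxt[!(nxt %in% blocked)]
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) break
    nxt <- unique(nxt)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

as_edge_matrix <- function(edges) {
  if (inherits(edges, "pkn")) return(edge_names(edges))
  if (inherits(edges, "solution_state")) return(included_edges(edges))
  edges <- as.matrix(edges)
  if (length(edges) == 0L) return(matrix(character(), 0L, 2L))
  if (ncol(edges) != 2L) stop("an edge set needs two columns (from, to)")
  storage.mode(edges) <- "character"
  edges
}

#' Directed reachability from a source node
#'
#' Nodes reachable from `source` by directed traversal of the given edge set,
#' including the source itself. Accepts a [pkn], a solution state, or any
#' two-column character edge matrix/data frame, so it can be applied to the
#' full scaffold as well as to a trained submodel.
#'
#' @param edges edge set (see above).
#' @param source a node name.
#' @return character vector of reachable node names.
#' @export
reachable_set <- function(edges, source) {
  em <- as_edge_matrix(edges)
  nodes <- unique(c(source, as.vector(t(em))))
  ei <- matrix(match(em, nodes), ncol = 2L)
  adj <- build_adjacency(ei, length(nodes))
  nodes[reach_logical(adj, match(source, nodes))]
}

induced_subnetwork <- function(net, keep_idx) {
  keep_idx <- sort(unique(keep_idx))
  if (!length(keep_idx)) stop("induced subnetwork would be empty")
  nodes <- net$nodes[keep_idx]
  e <- edge_names(net)
  sel <- net$edges[, 1L] %in% keep_idx & net$edges[, 2L] %in% keep_idx
  pkn(e[sel, , drop = FALSE], nodes = nodes)
}

#' Observable-controllable subnetwork
#'
#' Trims a PKN to the nodes lying on at least one directed path from some
#' stimulus to some measured signal: a node is kept iff it is reachable from
#' a stimulus AND can reach a signal. All edges induced by the retained nodes
#' are kept. The operation is idempotent.
#'
#' @param net a [pkn].
#' @param stimuli,signals character vectors of node names (non-empty subsets
#'   of the network's nodes).
#' @return a [pkn] restricted to the observable-controllable part, nodes in
#'   the original first-appearance order.
#' @export
observable_controllable <- function(net, stimuli, signals) {
  stopifnot(inherits(net, "pkn"))
  if (!length(stimuli)) stop("`stimuli` must be non-empty")
  if (!length(signals)) stop("`signals` must be non-empty")
  st <- node_index(net, stimuli)
  sg <- node_index(net, signals)
  fwd <- reach_logical(net$adj, st)
  radj <- build_adjacency(net$edges[, 2:1, drop = FALSE], n_nodes(net))
  bwd <- reach_logical(radj, sg)
  keep <- which(fwd & bwd)
  if (!length(keep)) {
    stop("no node lies on a directed path from a stimulus to a signal")
  }
  induced_subnetwork(net, keep)
}
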