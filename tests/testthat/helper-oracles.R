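# Independent oracles kept deliberately naive: exhaustive simple-path
# enumeration for shortest distances, and Boolean matrix squaring for
# transitive closure. Only usable at tiny n.

# adjacency (logical matrix) of a pkn
adj_matrix <- function(net) {
  n <- n_nodes(net)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (n_edges(net)) A[net$edges] <- TRUE
  A
}

# min length over all simple paths i -> j by depth-first enumeration
brute_shortest <- function(A, i, j) {
  n <- nrow(A)
  best <- Inf
  walk <- function(v, visited, len) {
    if (len >= best) return()
    if (v == j) { best <<- len; return() }
    for (w in which(A[v, ])) {
      if (!visited[w]) {
        visited[w] <- TRUE
        walk(w, visited, len + 1L)
        visited[w] <- FALSE
      }
    }
  }
  visited <- logical(n)
  visited[i] <- TRUE
  walk(i, visited, 0L)
  best
}

brute_dist_matrix <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) for (j in seq_len(n)) D[i, j] <- brute_shortest(A, i, j)
  D
}

# reachability closure by repeated Boolean squaring
closure_by_squaring <- function(A) {
  R <- A | diag(TRUE, nrow(A))
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) return(R)
    R <- R2
  }
}

# random digraph (cycles allowed) as a pkn; at least one edge
rand_pkn <- function(n, p = 0.3) {
  nodes <- LETTERS[seq_len(n)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  take <- stats::runif(nrow(pairs)) < p
  if (!any(take)) take[sample.int(length(take), 1L)] <- TRUE
  pkn(as.matrix(pairs[take, ]), nodes = nodes)
}

# structural DOT validity: one digraph block, balanced braces, every
# statement is a recognised node or edge line
expect_valid_dot <- function(dot) {
  lines <- strsplit(dot, "\n", fixed = TRUE)[[1]]
  expect_identical(lines[[1]], "digraph compressed_model {")
  expect_identical(lines[[length(lines)]], "}")
  body <- lines[-c(1L, length(lines))]
  pat_node <- '^  "[^"]+" \\[[^]]*\\];$'
  pat_edge <- '^  "[^"]+" -> "[^"]+"( \\[[^]]*\\])?;$'
  pat_attr <- "^  (rankdir=|node )[^;]*;$"
  ok <- grepl(pat_node, body) | grepl(pat_edge, body) | grepl(pat_attr, body)
  expect_true(all(ok), info = paste("unparsed DOT line:", body[!ok][1]))
  expect_equal(sum(grepl("\\{", lines)), sum(grepl("\\}", lines)))
}
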