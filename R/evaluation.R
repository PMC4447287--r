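#' Reachable-signals matrix of a (compressed) model
#'
#' Boolean matrix of the same shape and labels as the experiment matrix:
#' entry (r, c) is 1 iff signal c is reachable from stimulus r by directed
#' traversal of the model's reactions. Apply it to a [solution_state] for
#' the trained model, or to the full [pkn] for the untrained baseline.
#'
#' @param edges a [solution_state], [pkn], or two-column character edge
#'   matrix/data frame. An empty edge set yields an all-zero matrix.
#' @param m the [experiment_matrix] supplying row/column labels.
#' @return an [experiment_matrix] (additionally classed
#'   `"reachable_matrix"`) of 0/1 reachability indicators.
#' @export
reachable_matrix <- function(edges, m) {
  stopifnot(inherits(m, "experiment_matrix"))
  em <- as_edge_matrix(edges)
  x <- matrix(0L, m$n_st, m$n_sig)
  if (nrow(em)) {
    nodes <- unique(as.vector(t(em)))
    ei <- matrix(match(em, nodes), ncol = 2L)
    adj <- build_adjacency(ei, length(nodes))
    sig_i <- match(m$signals, nodes)
    for (r in seq_len(m$n_st)) {
      src <- match(m$stimuli[[r]], nodes)
      if (is.na(src)) next
      seen <- reach_logical(adj, src)
      x[r, ] <- as.integer(!is.na(sig_i) & seen[ifelse(is.na(sig_i), 1L, sig_i)])
    }
  }
  out <- suppressWarnings(experiment_matrix(x, m$stimuli, m$signals))
  class(out) <- c("reachable_matrix", class(out))
  out
}

#' @export
print.reachable_matrix <- function(x, ...) {
  cat(sprintf("reachable-signals matrix: %d stimuli x %d signals (%d reachable)\n",
              x$n_st, x$n_sig, sum(x$x)))
  print(x$x)
  invisible(x)
}

#' Percentage fit error between model reachability and data
#'
#' The goodness-of-fit metric: 100 times the number of mismatching cells
#' between the reachable-signals matrix of the compressed model and the
#' measured data matrix, divided by the total number of measurements
#' `n_s = n_st * n_sig`. Symmetric in its two arguments and invariant under
#' consistent row/column permutation.
#'
#' @param cm,m two [experiment_matrix] objects (or plain 0/1 matrices) of
#'   identical shape and labels.
#' @return a percentage in \[0, 100\].
#' @examples
#' fx <- toy_fixture()
#' sol <- reconstruct(fx$net, fx$data)
#' fit_error(reachable_matrix(sol, fx$data), fx$data)
#' @export
fit_error <- function(cm, m) {
  a <- if (inherits(cm, "experiment_matrix")) cm$x else as.matrix(cm)
  b <- if (inherits(m, "experiment_matrix")) m$x else as.matrix(m)
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("shape mismatch: %d x %d vs %d x %d",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  }
  if (!is.null(dimnames(a)) && !is.null(dimnames(b))) {
    if (!identical(rownames(a), rownames(b)) ||
        !identical(colnames(a), colnames(b))) {
      stop("row/column labels differ between the two matrices")
    }
  }
  100 * sum(abs(a - b)) / length(a)
}

edge_key_set <- function(x) {
  if (is.character(x) && is.null(dim(x))) return(unique(x))
  em <- as_edge_matrix(x)
  unique(paste(em[, 1L], em[, 2L], sep = "\t"))
}

#' Jaccard similarity of two reaction sets
#'
#' `|A intersect B| / |A union B|` over directed edges, used to compare a
#' trained topology with an externally derived one (e.g. an ILP solution).
#' Defined as 1 when both sets are empty.
#'
#' @param edges_a,edges_b edge sets: [pkn]s, solution states, two-column
#'   matrices/data frames, or character vectors of `"from<TAB>to"` keys.
#' @return a fraction in \[0, 1\].
#' @export
jaccard_index <- function(edges_a, edges_b) {
  a <- edge_key_set(edges_a)
  b <- edge_key_set(edges_b)
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Random Boolean data matrix with a fixed activation count
#'
#' Emulates an experimental dataset by placing exactly `n_activations` ones
#' uniformly at random among the `n_st * n_sig` cells. Used by the
#' cross-validation harness, which keeps the activation count equal to the
#' original data's.
#'
#' @param n_st,n_sig numbers of stimuli and signals.
#' @param n_activations number of 1-cells, between 0 and `n_st * n_sig`.
#' @param seed optional integer for reproducible draws (the caller's RNG
#'   state is left untouched).
#' @param stimuli,signals optional label vectors (defaults `st1..`, `sig1..`).
#' @return an [experiment_matrix].
#' @export
random_data_matrix <- function(n_st, n_sig, n_activations, seed = NULL,
                               stimuli = paste0("st", seq_len(n_st)),
                               signals = paste0("sig", seq_len(n_sig))) {
  n_cells <- n_st * n_sig
  if (n_activations < 0 || n_activations > n_cells) {
    stop(sprintf("n_activations must lie in [0, %d], got %s",
                 n_cells, format(n_activations)))
  }
  draw <- function() sample.int(n_cells, n_activations)
  on_cells <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  x <- integer(n_cells)
  x[on_cells] <- 1L
  experiment_matrix(matrix(x, n_st, n_sig), stimuli, signals)
}

#' Cross-validation of the reconstruction against random data
#'
#' Repeatedly reconstructs the network against random data matrices drawn
#' with the same shape, labels and activation count as a template matrix,
#' recording how often each PKN reaction is selected. Incidence is
#' checkpointed halfway through the runs and at completion, so convergence
#' of the reaction ranking can be inspected. One master seed spawns per-run
#' child seeds, making individual runs replayable.
#'
#' @param net a [pkn].
#' @param template an [experiment_matrix] supplying shape, labels and the
#'   constant activation count.
#' @param runs number of random datasets (>= 1).
#' @param seed optional master seed.
#' @param include_draws,cap passed to [reconstruct()].
#' @param trim_observable if `TRUE`, the PKN is first reduced to its
#'   observable-controllable part with respect to the template's stimuli and
#'   signals.
#' @return an object of class `"incidence_table"`: data frame with one row
#'   per PKN reaction (`from`, `to`, `count_50pct`, `count_100pct`,
#'   `fraction`), sorted by final incidence descending; attributes `runs`
#'   and `checkpoint` record the run counts.
#' @export
cross_validate <- function(net, template, runs = 500L, seed = NULL,
                           include_draws = TRUE, cap = 1000L,
                           trim_observable = FALSE) {
  stopifnot(inherits(net, "pkn"), inherits(template, "experiment_matrix"),
            runs >= 1L)
  if (trim_observable) {
    net <- observable_controllable(net,
                                   intersect(template$stimuli, net$nodes),
                                   intersect(template$signals, net$nodes))
  }
  table <- all_pairs_shortest_paths(net)
  n_act <- sum(template$x)
  draw_seeds <- function() sample.int(.Machine$integer.max, runs)
  child <- if (is.null(seed)) draw_seeds() else withr::with_seed(seed, draw_seeds())
  en <- edge_names(net)
  keys <- paste(en[, 1L], en[, 2L], sep = "\t")
  counts <- integer(length(keys))
  half <- ceiling(runs / 2)
  count_half <- counts
  for (i in seq_len(runs)) {
    mi <- random_data_matrix(template$n_st, template$n_sig, n_act,
                             seed = child[[i]], stimuli = template$stimuli,
                             signals = template$signals)
    sol <- reconstruct(net, mi, include_draws = include_draws, cap = cap,
                       table = table)
    hit <- keys %in% edge_key_set(sol)
    counts <- counts + hit
    if (i == half) count_half <- counts
  }
  ord <- order(-counts, seq_along(counts))
  out <- data.frame(from = en[ord, 1L], to = en[ord, 2L],
                    count_50pct = count_half[ord], count_100pct = counts[ord],
                    fraction = counts[ord] / runs,
                    stringsAsFactors = FALSE)
  attr(out, "runs") <- runs
  attr(out, "checkpoint") <- half
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' Export helpers for evaluation results
#'
#' `write_incidence_tsv()` writes an [cross_validate()] incidence table as
#' tab-separated text; `write_matrix_grid()` writes an experiment or
#' reachable matrix in the same grid dialect as the data input file
#' (header row of signal names, leading stimulus column).
#'
#' @param x the object to write.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_incidence_tsv <- function(x, file) {
  stopifnot(inherits(x, "incidence_table"))
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_incidence_tsv
#' @export
write_matrix_grid <- function(x, file) {
  stopifnot(inherits(x, "experiment_matrix"))
  header <- paste(c("", x$signals), collapse = "\t")
  body <- vapply(seq_len(x$n_st), function(r) {
    paste(c(x$stimuli[[r]], x$x[r, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), file)
  invisible(file)
}
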