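#' @title Solution state of a network reconstruction
#' @description The growing compressed model: which reactions and nodes have
#'   been admitted, which dependencies are satisfied and how, which conflict
#'   nodes were accepted per stimulus, and an ordered decision log. Created
#'   by [direct_paths()] and threaded through [scoring_pass()] and
#'   [nullified_rescoring()]; [reconstruct()] orchestrates the whole pipeline.
#' @name solution_state
NULL

new_solution_state <- function(net, m, table) {
  deps <- extract_dependencies(m)
  structure(
    list(net = net, m = m, table = table, deps = deps,
         status = rep("unmet", nrow(deps)),
         routes = vector("list", nrow(deps)),
         scores = rep(NA_real_, nrow(deps)),
         included = matrix(integer(), 0L, 2L,
                           dimnames = list(NULL, c("from", "to"))),
         admitted = stats::setNames(rep(list(character()), m$n_st), m$stimuli),
         log = list()),
    class = "solution_state"
  )
}

#' @rdname solution_state
#' @param state a solution state.
#' @return `included_edges()`: the admitted reactions as a two-column
#'   character matrix in order of first inclusion.
#' @export
included_edges <- function(state) {
  stopifnot(inherits(state, "solution_state"))
  matrix(state$net$nodes[state$included], ncol = 2L,
         dimnames = list(NULL, c("from", "to")))
}

#' @rdname solution_state
#' @return `included_nodes()`: endpoints of the included reactions plus the
#'   stimuli of satisfied dependencies.
#' @export
included_nodes <- function(state) {
  stopifnot(inherits(state, "solution_state"))
  sat <- startsWith(state$status, "satisfied")
  unique(c(state$net$nodes[as.vector(t(state$included))],
           state$deps$stimulus[sat]))
}

#' @rdname solution_state
#' @return `satisfied_dependencies()` / `unmet_dependencies()`: the relevant
#'   rows of the dependency table, with a `status` column.
#' @export
satisfied_dependencies <- function(state) {
  d <- state$deps
  d$status <- state$status
  d[startsWith(state$status, "satisfied"), , drop = FALSE]
}

#' @rdname solution_state
#' @export
unmet_dependencies <- function(state) {
  d <- state$deps
  d$status <- state$status
  d[startsWith(state$status, "unmet"), , drop = FALSE]
}

#' @export
print.solution_state <- function(x, ...) {
  tab <- table(x$status)
  cat(sprintf("compressed model: %d node(s), %d reaction(s) of %d in the PKN\n",
              length(included_nodes(x)), nrow(x$included), n_edges(x$net)))
  cat(sprintf("dependencies: %d satisfied / %d total (%s)\n",
              sum(startsWith(x$status, "satisfied")), length(x$status),
              paste(names(tab), as.integer(tab), sep = ": ", collapse = ", ")))
  cm <- reachable_matrix(x, x$m)
  cat(sprintf("fit error: %.1f%%\n", fit_error(cm, x$m)))
  invisible(x)
}

log_event <- function(state, ...) {
  state$log[[length(state$log) + 1L]] <- list(...)
  state
}

add_path_edges <- function(state, path) {
  idx <- match(path, state$net$nodes)
  if (length(idx) < 2L) return(state)
  e <- cbind(idx[-length(idx)], idx[-1L])
  key <- paste(state$included[, 1L], state$included[, 2L])
  new <- !(paste(e[, 1L], e[, 2L]) %in% key) & !duplicated(paste(e[, 1L], e[, 2L]))
  if (any(new)) {
    state$included <- rbind(state$included, e[new, , drop = FALSE])
  }
  state
}

# deterministic FIFO breadth-first path search; neighbours expanded in
# edge-input order; `blocked` nodes are never entered
bfs_path <- function(adj, from, to, blocked = integer()) {
  if (from %in% blocked || to %in% blocked) return(NULL)
  n <- length(adj)
  parent <- integer(n)
  seen <- logical(n)
  seen[from] <- TRUE
  if (from == to) return(from)
  queue <- from
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[[head]]; head <- head + 1L
    for (w in adj[[v]]) {
      if (seen[w] || w %in% blocked) next
      seen[w] <- TRUE
      parent[w] <- v
      if (w == to) {
        path <- w
        while (w != from) { w <- parent[w]; path <- c(w, path) }
        return(path)
      }
      queue <- c(queue, w)
    }
  }
  NULL
}

# conflict-free route for a stimulus over an arbitrary edge subset;
# returns character path or NULL
conflict_free_route <- function(state, stimulus, signal, edges_int) {
  net <- state$net
  i <- match(stimulus, net$nodes)
  j <- match(signal, net$nodes)
  if (is.na(i) || is.na(j)) return(NULL)
  blocked <- match(setdiff(conflict_nodes(state$m, stimulus), c(stimulus, signal)),
                   net$nodes)
  blocked <- blocked[!is.na(blocked)]
  adj <- build_adjacency(edges_int, n_nodes(net))
  p <- bfs_path(adj, i, j, blocked)
  if (is.null(p)) NULL else net$nodes[p]
}

#' Direct Paths: satisfy dependencies through conflict-free shortest paths
#'
#' For each dependency in row-major order the canonical shortest path from
#' its stimulus to its signal is looked up in the Floyd-Warshall table. If
#' the path exists and carries no conflict node for that stimulus, its
#' reactions enter the model and the dependency is marked
#' `satisfied-direct`; a conflicted path leaves the dependency `unmet`, and
#' an unreachable signal (or a name absent from the PKN) is marked
#' `unmet-unreachable` and logged.
#'
#' @param net a [pkn].
#' @param table its [all_pairs_shortest_paths()] table.
#' @param m an [experiment_matrix].
#' @return a [solution_state].
#' @export
direct_paths <- function(net, table, m) {
  stopifnot(inherits(net, "pkn"), inherits(table, "shortest_path_table"),
            inherits(m, "experiment_matrix"))
  state <- new_solution_state(net, m, table)
  for (k in seq_len(nrow(state$deps))) {
    stim <- state$deps$stimulus[[k]]
    sig <- state$deps$signal[[k]]
    known <- all(c(stim, sig) %in% net$nodes)
    path <- if (known) path_between(table, stim, sig) else NULL
    if (is.null(path)) {
      state$status[[k]] <- "unmet-unreachable"
      state <- log_event(state, stage = "direct", k = k, stimulus = stim,
                         signal = sig, status = "unmet-unreachable",
                         path = NULL, score = NA_real_,
                         conflicts = character())
      next
    }
    confl <- path_conflicts(path, conflict_nodes(m, stim), sig)
    if (length(confl) == 0L) {
      state <- add_path_edges(state, path)
      state$status[[k]] <- "satisfied-direct"
      state$routes[[k]] <- path
      state <- log_event(state, stage = "direct", k = k, stimulus = stim,
                         signal = sig, status = "satisfied-direct",
                         path = path, score = NA_real_,
                         conflicts = character())
    } else {
      state <- log_event(state, stage = "direct", k = k, stimulus = stim,
                         signal = sig, status = "unmet",
                         path = path, score = NA_real_, conflicts = confl)
    }
  }
  state
}

#' Alternative path candidates for an unmet dependency
#'
#' Searches for routes that could still satisfy a dependency whose canonical
#' shortest path is conflicted. The search proceeds in two stages. First a
#' conflict-free path is sought directly: the canonical path is returned if
#' it is itself conflict-free, otherwise a breadth-first search on the
#' conflict-masked network returns the shortest conflict-free route as the
#' sole candidate (this subsumes returning a conflict-free composite the
#' moment one is found). If no conflict-free route exists, alternative
#' starting points are enumerated by BFS from the stimulus: for each
#' discovered node v, the BFS-tree path stimulus->v is composed with the
#' canonical shortest path v->signal; distinct simple composites are
#' collected (up to `cap`, with a warning when hit) and returned ordered by
#' total length, ties broken by BFS discovery order.
#'
#' @param net a [pkn].
#' @param table its shortest-path table.
#' @param dep a list/one-row data frame with `stimulus` and `signal`.
#' @param conflicts the conflict set of the stimulus (see [conflict_nodes()]).
#' @param cap maximum number of composites collected (default 1000).
#' @return a list of character paths; empty when the signal is unreachable.
#'   Attribute `"conflict_free"` is `TRUE` when the single returned path is
#'   conflict-free.
#' @export
alternative_candidates <- function(net, table, dep, conflicts, cap = 1000L) {
  stim <- dep$stimulus
  sig <- dep$signal
  if (!all(c(stim, sig) %in% net$nodes)) return(list())
  i <- match(stim, net$nodes)
  j <- match(sig, net$nodes)
  if (is.na(table$dist[i, j])) return(list())

  canonical <- path_between(table, stim, sig)
  if (length(path_conflicts(canonical, conflicts, sig)) == 0L) {
    return(structure(list(canonical), conflict_free = TRUE))
  }
  blocked <- match(setdiff(conflicts, c(stim, sig)), net$nodes)
  blocked <- blocked[!is.na(blocked)]
  p <- bfs_path(net$adj, i, j, blocked)
  if (!is.null(p)) {
    return(structure(list(net$nodes[p]), conflict_free = TRUE))
  }

  # no conflict-free route: enumerate scored composites
  n <- n_nodes(net)
  parent <- integer(n)
  seen <- logical(n)
  seen[i] <- TRUE
  order_disc <- i
  queue <- i
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[[head]]; head <- head + 1L
    for (w in net$adj[[v]]) {
      if (seen[w]) next
      seen[w] <- TRUE
      parent[w] <- v
      order_disc <- c(order_disc, w)
      queue <- c(queue, w)
    }
  }
  paths <- list()
  keys <- character()
  lens <- integer()
  capped <- FALSE
  for (v in order_disc) {
    if (is.na(table$dist[v, j])) next
    prefix <- v
    u <- v
    while (u != i) { u <- parent[u]; prefix <- c(u, prefix) }
    suffix <- prefix[[length(prefix)]]
    u <- v
    while (u != j) { u <- table$next_hop[u, j]; suffix <- c(suffix, u) }
    composite <- c(prefix[-length(prefix)], suffix)
    if (anyDuplicated(composite)) next
    key <- paste(composite, collapse = "\r")
    if (key %in% keys) next
    if (length(paths) >= cap) { capped <- TRUE; break }
    keys <- c(keys, key)
    paths[[length(paths) + 1L]] <- net$nodes[composite]
    lens <- c(lens, length(composite) - 1L)
  }
  if (capped) {
    warning(sprintf("candidate cap (%d) hit for dependency %s -> %s",
                    cap, stim, sig))
  }
  paths[order(lens, seq_along(lens))]
}

#' Score a candidate pathway
#'
#' Weighs the dependencies a pathway serves against the inconsistencies it
#' introduces. The candidate serves its own dependency, any still-unmet
#' dependency of the same stimulus whose signal lies on the path, and any
#' previously satisfied dependency of that stimulus whose recorded route
#' passes through one of the candidate's conflict nodes (admitting the
#' conflict is what keeps those routes alive). Conflicts are the measured-0
#' signals of the stimulus appearing on the path beyond the source and
#' excluding the candidate's own target; nodes listed in `nullify` (used by
#' the nullification pass) are not counted. The score is
#' `n_satisfied - n_conflicts`; zero is a draw.
#'
#' @param state a [solution_state].
#' @param path character vector of node names, stimulus first.
#' @param nullify conflict nodes exempt from counting (default none).
#' @return an object of class `"path_score"`: list with `path`,
#'   `n_satisfied`, `n_conflicts`, `score`, `served` (dependency indices),
#'   `conflicts` (all conflict nodes on the path) and `counted_conflicts`.
#' @export
score_candidate <- function(state, path, nullify = character()) {
  stopifnot(inherits(state, "solution_state"), length(path) >= 1L)
  stim <- path[[1L]]
  target <- path[[length(path)]]
  confl <- path_conflicts(path, conflict_nodes(state$m, stim), target)
  counted <- setdiff(confl, nullify)
  dk <- which(state$deps$stimulus == stim)
  own <- dk[state$deps$signal[dk] == target]
  onpath <- dk[startsWith(state$status[dk], "unmet") &
                 state$deps$signal[dk] %in% path[-1L] &
                 state$deps$signal[dk] != target]
  kept <- dk[startsWith(state$status[dk], "satisfied") &
               vapply(state$routes[dk],
                      function(r) !is.null(r) && any(r %in% confl), logical(1))]
  served <- unique(c(own, onpath, kept))
  structure(
    list(path = path, served = served, conflicts = confl,
         counted_conflicts = counted,
         n_satisfied = length(served), n_conflicts = length(counted),
         score = length(served) - length(counted)),
    class = "path_score"
  )
}

#' @export
print.path_score <- function(x, ...) {
  cat(sprintf("%s: %d served - %d conflict(s) = %d%s\n",
              paste(x$path, collapse = " -> "),
              x$n_satisfied, x$n_conflicts, x$score,
              if (x$score == 0) " (draw)" else ""))
  invisible(x)
}

commit_candidate <- function(state, k, sc, stage) {
  stim <- state$deps$stimulus[[k]]
  state <- add_path_edges(state, sc$path)
  state$status[[k]] <- if (sc$score == 0L) "satisfied-draw" else
    paste0("satisfied-", stage)
  state$routes[[k]] <- sc$path
  state$scores[[k]] <- sc$score
  for (k2 in setdiff(sc$served, k)) {
    if (!startsWith(state$status[[k2]], "unmet")) next
    sig2 <- state$deps$signal[[k2]]
    cut <- match(sig2, sc$path)
    state$status[[k2]] <- "satisfied-onpath"
    state$routes[[k2]] <- sc$path[seq_len(cut)]
    state$scores[[k2]] <- sc$score
  }
  state$admitted[[stim]] <- union(state$admitted[[stim]], sc$conflicts)
  log_event(state, stage = stage, k = k, stimulus = stim,
            signal = state$deps$signal[[k]],
            status = state$status[[k]], path = sc$path, score = sc$score,
            conflicts = sc$conflicts)
}

# mark unmet dependencies that have gained a conflict-free route over the
# included reactions since the last commit
incidental_update <- function(state, stage) {
  for (k in which(state$status == "unmet")) {
    p <- conflict_free_route(state, state$deps$stimulus[[k]],
                             state$deps$signal[[k]], state$included)
    if (!is.null(p)) {
      state$status[[k]] <- "satisfied-incidental"
      state$routes[[k]] <- p
      state <- log_event(state, stage = stage, k = k,
                         stimulus = state$deps$stimulus[[k]],
                         signal = state$deps$signal[[k]],
                         status = "satisfied-incidental", path = p,
                         score = NA_real_, conflicts = character())
    }
  }
  state
}

#' Scoring pass over the unmet dependencies
#'
#' Processes the unmet dependencies in order. Each is first checked for
#' incidental satisfaction (a conflict-free route over the reactions already
#' included); otherwise candidates from [alternative_candidates()] are
#' scored shortest-first and the first candidate with score > 0 — or
#' score >= 0 when `include_draws` is on — is committed: its reactions, the
#' dependencies it serves, and its conflict nodes enter the state.
#'
#' @param state a [solution_state] (after [direct_paths()]).
#' @param include_draws accept draw-case candidates (score 0)? Default `TRUE`.
#' @param cap candidate cap per dependency, passed through.
#' @param nullify if `TRUE`, conflict nodes already admitted for the same
#'   stimulus are not counted against candidates (the nullification rule).
#' @param stage label recorded in the decision log.
#' @return the updated state.
#' @export
scoring_pass <- function(state, include_draws = TRUE, cap = 1000L,
                         nullify = FALSE, stage = "alternative") {
  stopifnot(inherits(state, "solution_state"))
  threshold <- if (include_draws) 0L else 1L
  for (k in seq_len(nrow(state$deps))) {
    if (state$status[[k]] != "unmet") next
    state <- incidental_update(state, stage)
    if (state$status[[k]] != "unmet") next
    stim <- state$deps$stimulus[[k]]
    cands <- alternative_candidates(state$net, state$table, state$deps[k, ],
                                    conflict_nodes(state$m, stim), cap = cap)
    if (!length(cands)) {
      state <- log_event(state, stage = stage, k = k, stimulus = stim,
                         signal = state$deps$signal[[k]], status = "unmet",
                         path = NULL, score = NA_real_,
                         conflicts = character())
      next
    }
    nul <- if (nullify) state$admitted[[stim]] else character()
    best <- NA_real_
    for (cand in cands) {
      sc <- score_candidate(state, cand, nullify = nul)
      if (is.na(best) || sc$score > best) best <- sc$score
      if (sc$score >= threshold) {
        state <- commit_candidate(state, k, sc, stage)
        state <- incidental_update(state, stage)
        break
      }
    }
    if (state$status[[k]] == "unmet") {
      state <- log_event(state, stage = stage, k = k, stimulus = stim,
                         signal = state$deps$signal[[k]], status = "unmet",
                         path = NULL, score = best, conflicts = character())
    }
  }
  state
}

#' Nullified rescoring of the remaining unmet dependencies
#'
#' Re-runs the scoring pass with the conflict nodes already admitted to the
#' model (per stimulus) removed from conflict counting: a conflict accepted
#' for one dependency no longer counts against candidates for another. The
#' pass repeats until no dependency changes status, so the operation is
#' idempotent. With no admitted conflicts it reduces to a plain scoring pass.
#'
#' @inheritParams scoring_pass
#' @return the updated state.
#' @export
nullified_rescoring <- function(state, include_draws = TRUE, cap = 1000L) {
  repeat {
    before <- state$status
    state <- scoring_pass(state, include_draws = include_draws, cap = cap,
                          nullify = TRUE, stage = "nullified")
    if (identical(state$status, before)) break
  }
  state
}

#' Reconstruct a compressed signaling model
#'
#' Full training pipeline: all-pairs shortest paths on the PKN, Direct Paths
#' for every dependency, a scoring pass over the alternatives, and the final
#' nullified rescoring. Dependencies are processed in row-major matrix order
#' (all of row 1, then row 2, ...).
#'
#' @param net a [pkn].
#' @param m an [experiment_matrix].
#' @param include_draws include draw-case pathways (score 0) in the model?
#'   Default `TRUE`; draws add connectivity information at the price of
#'   admitted conflicts.
#' @param cap candidate cap per dependency (default 1000).
#' @param table optionally a precomputed [all_pairs_shortest_paths()] table
#'   for `net` (reused across cross-validation runs).
#' @return a [solution_state] with the full decision log.
#' @examples
#' fx <- toy_fixture()
#' sol <- reconstruct(fx$net, fx$data)
#' sol
#' @export
reconstruct <- function(net, m, include_draws = TRUE, cap = 1000L,
                        table = NULL) {
  stopifnot(inherits(net, "pkn"), inherits(m, "experiment_matrix"))
  if (is.null(table)) table <- all_pairs_shortest_paths(net)
  state <- direct_paths(net, table, m)
  state <- scoring_pass(state, include_draws = include_draws, cap = cap)
  state <- nullified_rescoring(state, include_draws = include_draws, cap = cap)
  state$options <- list(include_draws = include_draws, cap = cap)
  state
}

#' Per-dependency decision log
#'
#' Condenses a solution's event log into one record per dependency: its
#' final status, the committed route (if any), the committed score and the
#' conflict nodes accepted with it.
#'
#' @param state a [solution_state].
#' @return a list of records (one per dependency) with fields `k`,
#'   `stimulus`, `signal`, `status`, `path`, `score`, `conflicts`; suitable
#'   for JSON export via [write_decision_log()].
#' @export
decision_log <- function(state) {
  stopifnot(inherits(state, "solution_state"))
  lapply(seq_len(nrow(state$deps)), function(k) {
    confl <- character()
    for (ev in state$log) {
      if (identical(ev$k, k) && startsWith(ev$status, "satisfied") &&
          length(ev$conflicts)) {
        confl <- ev$conflicts
      }
    }
    list(k = k, stimulus = state$deps$stimulus[[k]],
         signal = state$deps$signal[[k]], status = state$status[[k]],
         path = state$routes[[k]], score = state$scores[[k]],
         conflicts = confl)
  })
}
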