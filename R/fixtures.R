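#' Toy EGF/TNFA fixture: network and data matrix
#'
#' A small two-stimulus signaling scaffold downstream of EGF and TNFA with
#' ten measured signals, bundled with its Boolean data matrix (EGF row all
#' active; TNFA activates AP1, GSK-3, P38 and NFKB only). The wiring keeps
#' the canonical TNF arm TNFA -> TNFR -> TRAF2 -> MAP3K7 -> MKK4 -> P38, the
#' TNFR -> PI3K crosstalk edge, the IKK -> NFKB arm, and an EGF arm in which
#' NFKB, IKK and MAP3K7 are unreachable; a JNK/AP1 route via MKK7 provides
#' TNFA's single conflict-free path, and a small apoptosis arm
#' (TNFR -> FADD -> CASP8) plus RAS -> RAL are decoy reactions that no
#' trained model retains. Running [reconstruct()] on this fixture yields 14
#' dependencies, three committed draw cases under TNFA, and a 35% fit error.
#'
#' @return a list with elements `net` (a [pkn], 25 core + 3 decoy
#'   reactions) and `data` (an [experiment_matrix], 2 stimuli x 10 signals).
#' @examples
#' fx <- toy_fixture()
#' nrow(extract_dependencies(fx$data))
#' @export
toy_fixture <- function() {
  edges <- rbind(
    # EGF arm: MAPK cascade to RAF-1/MEK/ERK/AP1
    c("EGF",    "EGFR"),
    c("EGFR",   "GRB2"),
    c("GRB2",   "SOS"),
    c("SOS",    "RAS"),
    c("RAS",    "RAF-1"),
    c("RAF-1",  "MEK"),
    c("MEK",    "ERK"),
    c("ERK",    "AP1"),
    # EGF arm: PI3K branch to GSK-3 and, via RAC/MAP3K1, to P38
    c("EGFR",   "PI3K"),
    c("PI3K",   "AKT"),
    c("AKT",    "GSK-3"),
    c("PI3K",   "RAC"),
    c("RAC",    "MAP3K1"),
    c("MAP3K1", "MKK4"),
    c("MKK4",   "P38"),
    # TNFA arm: TRAF2 hub, MAP3K7 route to P38 and IKK/NFKB
    c("TNFA",   "TNFR"),
    c("TNFR",   "TRAF2"),
    c("TRAF2",  "MAP3K7"),
    c("MAP3K7", "MKK4"),
    c("MAP3K7", "IKK"),
    c("IKK",    "NFKB"),
    # crosstalk and the conflict-free JNK/AP1 route
    c("TNFR",   "PI3K"),
    c("TRAF2",  "MKK7"),
    c("MKK7",   "JNK"),
    c("JNK",    "AP1"),
    # decoy reactions excluded from every trained model
    c("TNFR",   "FADD"),
    c("FADD",   "CASP8"),
    c("RAS",    "RAL")
  )
  signals <- c("RAF-1", "ERK", "AP1", "GSK-3", "P38", "NFKB", "IKK",
               "MAP3K1", "MAP3K7", "PI3K")
  x <- rbind(
    EGF  = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    TNFA = c(0, 0, 1, 1, 1, 1, 0, 0, 0, 0)
  )
  list(net = pkn(edges),
       data = experiment_matrix(x, c("EGF", "TNFA"), signals))
}

#' Hepatocyte stimulus-response dataset (medium-scale design)
#'
#' Loads the packaged discretized 5-stimulus x 16-signal hepatocyte
#' phosphoprotein matrix (IL6, TNFA, IL1B, TGFA, INS against 16 key
#' phosphoproteins; 22 activations in total, INS all-zero). The matching
#' medium-scale prior knowledge network is an external input and is not
#' bundled.
#'
#' @return an [experiment_matrix].
#' @export
hepatocyte_data <- function() {
  d <- system.file("extdata", package = "sigrecon", mustWork = TRUE)
  parse_experiment(file.path(d, "hepatocyte_stimuli.txt"),
                   file.path(d, "hepatocyte_signals.txt"),
                   file.path(d, "hepatocyte_data.txt"))
}

#' Random DAG test-bed generator
#'
#' Draws a random directed acyclic PKN: nodes are placed in a random
#' topological order and each forward pair becomes a reaction independently
#' with probability `edge_density` (density 1 gives the complete DAG with
#' n(n-1)/2 reactions). The first `n_stimuli` nodes of the order receive no
#' incoming reactions, so stimuli are genuine sources; signals are drawn
#' from the remaining nodes.
#'
#' @param n_nodes total node count.
#' @param edge_density probability in (0, 1\] for each forward pair.
#' @param n_stimuli,n_signals counts with `n_stimuli + n_signals <= n_nodes`.
#' @param seed optional integer; same seed, same instance.
#' @return list with `net` (a [pkn]), `stimuli`, `signals`.
#' @export
random_dag <- function(n_nodes, edge_density = 0.3, n_stimuli = 1L,
                       n_signals = 1L, seed = NULL) {
  if (n_stimuli + n_signals > n_nodes) {
    stop("n_stimuli + n_signals must not exceed n_nodes")
  }
  if (edge_density <= 0 || edge_density > 1) {
    stop("edge_density must lie in (0, 1]")
  }
  build <- function() {
    ord <- sample.int(n_nodes)
    names <- sprintf("n%02d", seq_len(n_nodes))
    pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
    # no reactions into the stimulus tier (positions 1..n_stimuli of the order)
    pairs <- pairs[pairs[, 2L] > n_stimuli, , drop = FALSE]
    take <- stats::runif(nrow(pairs)) <= edge_density
    e <- pairs[take, , drop = FALSE]
    stimuli <- names[ord[seq_len(n_stimuli)]]
    others <- names[ord[(n_stimuli + 1L):n_nodes]]
    signals <- sort(sample(others, n_signals))
    edges <- cbind(names[ord[e[, 1L]]], names[ord[e[, 2L]]])
    net <- if (nrow(edges)) pkn(edges, nodes = names[ord]) else
      pkn(matrix(character(), 0, 2), nodes = names[ord])
    list(net = net, stimuli = stimuli, signals = signals)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Planted-subnetwork benchmark instance
#'
#' Generates a consistency benchmark: a random DAG scaffold in which every
#' non-stimulus node is measured, a hidden planted subnetwork (the subgraph
#' induced by a random node subset containing the stimuli), and a data
#' matrix that records exactly the reachability of each measured node from
#' each stimulus inside the planted subnetwork. Because the planted part is
#' an induced subgraph and every node is observed, any conflict-free path
#' in the scaffold stays inside the planted reactions, so the data is
#' realizable: a correct reconstruction reaches zero fit error and recovers
#' the planted stimulus-to-signal connectivity.
#'
#' @param n_nodes,edge_density,n_stimuli,seed as in [random_dag()].
#' @param keep_frac fraction of non-stimulus nodes placed in the planted
#'   subnetwork (default 0.6).
#' @return list with `net`, `data`, `planted_nodes`, `planted_edges` (the
#'   induced edge matrix).
#' @export
planted_instance <- function(n_nodes, edge_density = 0.35, n_stimuli = 2L,
                             keep_frac = 0.6, seed = NULL) {
  build <- function() {
    dag <- random_dag(n_nodes, edge_density, n_stimuli,
                      n_signals = n_nodes - n_stimuli)
    net <- dag$net
    others <- setdiff(net$nodes, dag$stimuli)
    keep <- sort(c(dag$stimuli,
                   sample(others, max(1L, round(keep_frac * length(others))))))
    en <- edge_names(net)
    planted <- en[en[, 1L] %in% keep & en[, 2L] %in% keep, , drop = FALSE]
    signals <- others  # every non-stimulus node is measured
    x <- matrix(0L, length(dag$stimuli), length(signals))
    for (r in seq_along(dag$stimuli)) {
      rs <- reachable_set(planted, dag$stimuli[[r]])
      x[r, ] <- as.integer(signals %in% rs)
    }
    list(net = net,
         data = experiment_matrix(x, dag$stimuli, signals),
         planted_nodes = keep, planted_edges = planted)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
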