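test_that("edge-list parsing reads back edges, collapses duplicates, reports", {
  net <- parse_edge_list(text = "EGF\tEGFR\nEGFR\tGRB2")
  expect_equal(n_nodes(net), 3L)
  expect_equal(n_edges(net), 2L)
  expect_equal(net$nodes, c("EGF", "EGFR", "GRB2"))

  net2 <- parse_edge_list(text = "A\tB\nA\tB")
  expect_equal(n_nodes(net2), 2L)
  expect_equal(n_edges(net2), 1L)
  expect_equal(attr(net2, "parse_report")$duplicates_dropped, 1L)

  # comments, blank lines and CRLF are tolerated
  net3 <- parse_edge_list(text = "# scaffold\r\nA\tB\r\n\r\nB\tC\r\n")
  expect_equal(edge_names(net3), cbind(from = c("A", "B"), to = c("B", "C")))

  # self-loops are dropped with a warning
  expect_warning(net4 <- parse_edge_list(text = "A\tA\nA\tB"), "self-loop")
  expect_equal(n_edges(net4), 1L)

  # 3-column SIF convenience
  net5 <- parse_edge_list(text = "A\tactivates\tB", sif3 = TRUE)
  expect_equal(edge_names(net5), cbind(from = "A", to = "B"))
})

test_that("malformed or empty edge lists raise informative errors", {
  expect_error(parse_edge_list(text = "A\tB\nA B"), "line 2")
  expect_error(parse_edge_list(text = "A\tB\tC"), "line 1")
  expect_error(parse_edge_list(text = "# nothing\n"), "no reactions")
  expect_error(parse_edge_list(file = "no/such/file.txt"), "not found")
})

test_that("Floyd-Warshall table matches the brute-force enumeration oracle", {
  withr::with_seed(421, {
    for (rep in 1:40) {
      net <- rand_pkn(sample(2:8, 1), stats::runif(1, 0.15, 0.6))
      tab <- all_pairs_shortest_paths(net)
      D <- brute_dist_matrix(net)
      got <- ifelse(is.na(tab$dist), Inf, tab$dist)
      expect_equal(got, D)
    }
  })
})

test_that("Floyd-Warshall distances agree with igraph on a larger graph", {
  skip_if_not_installed("igraph")
  withr::with_seed(99, net <- rand_pkn(20, 0.12))
  tab <- all_pairs_shortest_paths(net)
  g <- igraph::graph_from_edgelist(edge_names(net))
  D <- igraph::distances(g, v = net$nodes, to = net$nodes, mode = "out")
  expect_equal(ifelse(is.na(tab$dist), Inf, tab$dist), D)
})

test_that("reconstructed canonical paths are valid, simple, and of stated length", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      net <- rand_pkn(sample(3:8, 1), 0.35)
      tab <- all_pairs_shortest_paths(net)
      en <- paste(edge_names(net)[, 1], edge_names(net)[, 2])
      for (i in net$nodes) for (j in net$nodes) {
        p <- path_between(tab, i, j)
        d <- tab$dist[i, j]
        if (is.na(d)) {
          expect_null(p)
        } else {
          expect_equal(length(p) - 1L, as.integer(d))
          expect_identical(p[1], i)
          expect_identical(p[length(p)], j)
          expect_equal(anyDuplicated(p), 0L)
          if (length(p) > 1L) {
            steps <- paste(p[-length(p)], p[-1])
            expect_true(all(steps %in% en))
          }
        }
      }
    }
  })
})

test_that("chain distances behave directionally and self-paths are trivial", {
  net <- parse_edge_list(text = "A\tB\nB\tC")
  tab <- all_pairs_shortest_paths(net)
  expect_equal(tab$dist["A", "C"], 2L)
  expect_equal(path_between(tab, "A", "C"), c("A", "B", "C"))
  expect_true(is.na(tab$dist["C", "A"]))
  expect_null(path_between(tab, "C", "A"))
  expect_equal(path_between(tab, "A", "A"), "A")
  expect_error(path_between(tab, "A", "Z"), "unknown node")
})

test_that("reachable_set matches the matrix-closure oracle and is monotone", {
  net <- parse_edge_list(text = "A\tB\nB\tC")
  expect_equal(reachable_set(net, "A"), c("A", "B", "C"))
  expect_equal(reachable_set(matrix(character(), 0, 2), "A"), "A")
  withr::with_seed(11, {
    for (rep in 1:25) {
      net <- rand_pkn(sample(2:8, 1), 0.3)
      R <- closure_by_squaring(adj_matrix(net))
      for (v in net$nodes) {
        expect_setequal(reachable_set(net, v), net$nodes[R[v, ]])
      }
      # adding an edge never shrinks any reachable set
      en <- edge_names(net)
      extra <- c(sample(net$nodes, 1), sample(net$nodes, 1))
      if (extra[1] != extra[2]) {
        bigger <- rbind(en, extra)
        for (v in net$nodes) {
          expect_true(all(reachable_set(en, v) %in% reachable_set(bigger, v)))
        }
      }
    }
  })
})

test_that("observable-controllable trimming keeps exactly the double-reachable nodes", {
  net <- parse_edge_list(text = "S\tA\nA\tM")
  oc <- observable_controllable(net, "S", "M")
  expect_equal(n_nodes(oc), 3L)
  expect_equal(n_edges(oc), 2L)

  net2 <- parse_edge_list(text = "S\tA\nA\tM\nX\tY")
  oc2 <- observable_controllable(net2, "S", "M")
  expect_setequal(oc2$nodes, c("S", "A", "M"))

  withr::with_seed(5150, {
    for (rep in 1:20) {
      dag <- random_dag(sample(5:10, 1), 0.3, n_stimuli = 2, n_signals = 2)
      kept <- tryCatch(
        observable_controllable(dag$net, dag$stimuli, dag$signals)$nodes,
        error = function(e) character())
      for (v in dag$net$nodes) {
        fwd <- any(vapply(dag$stimuli,
                          function(s) v %in% reachable_set(dag$net, s), logical(1)))
        bwd <- any(dag$signals %in% reachable_set(dag$net, v))
        expect_equal(v %in% kept, fwd && bwd)
      }
      if (length(kept)) {  # idempotence
        oc <- observable_controllable(dag$net, dag$stimuli, dag$signals)
        st2 <- intersect(dag$stimuli, oc$nodes)
        sg2 <- intersect(dag$signals, oc$nodes)
        oc2 <- observable_controllable(oc, st2, sg2)
        expect_equal(edge_names(oc2), edge_names(oc))
      }
    }
  })
  expect_error(observable_controllable(net, character(), "M"), "non-empty")
})
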