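toy_state_after_direct <- function() {
  fx <- toy_fixture()
  tab <- all_pairs_shortest_paths(fx$net)
  list(fx = fx, tab = tab, state = direct_paths(fx$net, tab, fx$data))
}

test_that("Direct Paths satisfy exactly the conflict-free reachable dependencies", {
  ts <- toy_state_after_direct()
  d <- ts$state$deps
  d$status <- ts$state$status
  egf <- d[d$stimulus == "EGF", ]
  # EGF reaches everything except NFKB, IKK, MAP3K7
  expect_setequal(egf$signal[egf$status == "unmet-unreachable"],
                  c("NFKB", "IKK", "MAP3K7"))
  expect_true(all(egf$status[!egf$signal %in% c("NFKB", "IKK", "MAP3K7")] ==
                    "satisfied-direct"))
  # under TNFA only AP1 has a conflict-free direct path
  tnfa <- d[d$stimulus == "TNFA", ]
  expect_equal(tnfa$signal[tnfa$status == "satisfied-direct"], "AP1")
  expect_setequal(tnfa$signal[tnfa$status == "unmet"],
                  c("GSK-3", "P38", "NFKB"))
  # satisfied signals are reachable over included edges only
  for (k in which(startsWith(ts$state$status, "satisfied"))) {
    expect_true(d$signal[k] %in%
                  reachable_set(included_edges(ts$state), d$stimulus[k]))
  }
})

test_that("an empty dependency list produces an empty solution", {
  net <- parse_edge_list(text = "S\tA")
  m <- experiment_matrix(matrix(0, 1, 1), "S", "A")
  sol <- reconstruct(net, m)
  expect_equal(nrow(sol$included), 0L)
  expect_equal(nrow(sol$deps), 0L)
  expect_equal(fit_error(reachable_matrix(sol, m), m), 0)
})

test_that("a single supported dependency is recovered exactly", {
  net <- parse_edge_list(text = "S\tA")
  m <- experiment_matrix(matrix(1, 1, 1), "S", "A")
  sol <- reconstruct(net, m)
  expect_equal(included_edges(sol), cbind(from = "S", to = "A"))
  expect_equal(fit_error(reachable_matrix(sol, m), m), 0)
})

test_that("alternative candidates include the attested crosstalk composite", {
  ts <- toy_state_after_direct()
  dep <- ts$state$deps[ts$state$deps$stimulus == "TNFA" &
                         ts$state$deps$signal == "GSK-3", ]
  cands <- alternative_candidates(ts$fx$net, ts$tab, dep,
                                  conflict_nodes(ts$fx$data, "TNFA"))
  expect_true(length(cands) >= 1L)
  steps <- lapply(cands, function(p) paste(p[-length(p)], p[-1]))
  expect_true(any(vapply(steps, function(s) "TNFR PI3K" %in% s, logical(1))))

  # a conflict-free canonical path is returned as the sole candidate
  dep2 <- ts$state$deps[ts$state$deps$stimulus == "TNFA" &
                          ts$state$deps$signal == "AP1", ]
  cands2 <- alternative_candidates(ts$fx$net, ts$tab, dep2,
                                   conflict_nodes(ts$fx$data, "TNFA"))
  expect_length(cands2, 1L)
  expect_true(attr(cands2, "conflict_free"))
  expect_equal(cands2[[1]], path_between(ts$tab, "TNFA", "AP1"))

  # unreachable signal: empty candidate list
  dep3 <- data.frame(stimulus = "EGF", signal = "NFKB")
  expect_length(alternative_candidates(ts$fx$net, ts$tab, dep3,
                                       conflict_nodes(ts$fx$data, "EGF")), 0L)
})

test_that("all-conflicted star candidates match exhaustive enumeration", {
  # stimulus -> m1..m4 -> target, every intermediate measured inactive
  net <- parse_edge_list(text = paste(
    c("S\tm1", "S\tm2", "S\tm3", "S\tm4",
      "m1\tT", "m2\tT", "m3\tT", "m4\tT"), collapse = "\n"))
  m <- experiment_matrix(matrix(c(0, 0, 0, 0, 1), 1), "S",
                         c("m1", "m2", "m3", "m4", "T"))
  tab <- all_pairs_shortest_paths(net)
  dep <- data.frame(stimulus = "S", signal = "T")
  cands <- alternative_candidates(net, tab, dep, conflict_nodes(m, "S"))
  expect_equal(length(cands), 4L)  # one composite per spoke
  for (p in cands) {
    expect_length(path_conflicts(p, conflict_nodes(m, "S"), "T"), 1L)
  }
  lens <- vapply(cands, length, integer(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("candidate scoring reproduces the worked toy examples", {
  ts <- toy_state_after_direct()
  state <- ts$state
  # commit the P38 pathway through MAP3K7 first (1 served - 1 conflict)
  p38_path <- path_between(ts$tab, "TNFA", "P38")
  sc_p38 <- score_candidate(state, p38_path)
  expect_equal(sc_p38$n_satisfied, 1L)
  expect_equal(sc_p38$conflicts, "MAP3K7")
  expect_equal(sc_p38$score, 0L)
  state <- scoring_pass(state)
  # after the pass, the NFKB candidate served 2 dependencies at 2 conflicts
  lg <- decision_log(state)
  nfkb <- Filter(function(r) r$stimulus == "TNFA" && r$signal == "NFKB", lg)[[1]]
  expect_equal(nfkb$score, 0)
  expect_setequal(nfkb$conflicts, c("MAP3K7", "IKK"))
  gsk <- Filter(function(r) r$stimulus == "TNFA" && r$signal == "GSK-3", lg)[[1]]
  expect_equal(gsk$score, 0)
  expect_equal(gsk$conflicts, "PI3K")
})

test_that("score arithmetic: conflict-free +1, two fresh conflicts -1, nullification", {
  net <- parse_edge_list(text = "S\tu\nu\tA\nS\tc1\nc1\tc2\nc2\tB")
  m <- experiment_matrix(matrix(c(1, 1, 0, 0), 1), "S", c("A", "B", "c1", "c2"))
  tab <- all_pairs_shortest_paths(net)
  st <- direct_paths(net, tab, m)
  expect_equal(score_candidate(st, c("S", "u", "A"))$score, 1L)
  sc <- score_candidate(st, c("S", "c1", "c2", "B"))
  expect_equal(sc$n_satisfied, 1L)
  expect_equal(sc$n_conflicts, 2L)
  expect_equal(sc$score, -1L)
  expect_equal(score_candidate(st, c("S", "c1", "c2", "B"),
                               nullify = c("c1", "c2"))$score, 1L)
})

test_that("draw cases are committed only when include_draws is on", {
  fx <- toy_fixture()
  on <- reconstruct(fx$net, fx$data, include_draws = TRUE)
  off <- reconstruct(fx$net, fx$data, include_draws = FALSE)
  don <- on$deps; don$status <- on$status
  doff <- off$deps; doff$status <- off$status
  draws_on <- don[don$stimulus == "TNFA" &
                    don$signal %in% c("P38", "NFKB", "GSK-3"), "status"]
  expect_true(all(draws_on == "satisfied-draw"))
  draws_off <- doff[doff$stimulus == "TNFA" &
                      doff$signal %in% c("P38", "NFKB", "GSK-3"), "status"]
  expect_true(all(draws_off == "unmet"))
})

test_that("nullification satisfies a dependency blocked by an admitted conflict", {
  # A1's draw path admits conflict c1; B's only route carries c1 plus two
  # fresh conflicts (f1, f2), scoring 2 - 3 in the plain pass but 2 - 2
  # once c1 is nullified.
  net <- parse_edge_list(text = "S\tc1\nc1\tA1\nc1\tf1\nf1\tf2\nf2\tB")
  m <- experiment_matrix(matrix(c(1, 1, 0, 0, 0), 1), "S",
                         c("A1", "B", "c1", "f1", "f2"))
  tab <- all_pairs_shortest_paths(net)
  st <- direct_paths(net, tab, m)
  st <- scoring_pass(st)
  d <- st$deps; d$status <- st$status
  expect_equal(d$status[d$signal == "A1"], "satisfied-draw")
  expect_equal(d$status[d$signal == "B"], "unmet")
  expect_equal(st$admitted[["S"]], "c1")
  st2 <- nullified_rescoring(st)
  d2 <- st2$deps; d2$status <- st2$status
  expect_equal(d2$status[d2$signal == "B"], "satisfied-draw")
  expect_true(all(startsWith(st2$status, "satisfied")))
  # idempotent once stable
  st3 <- nullified_rescoring(st2)
  expect_identical(st3$status, st2$status)
})

test_that("solution-state invariants hold across the pipeline stages", {
  fx <- toy_fixture()
  tab <- all_pairs_shortest_paths(fx$net)
  s1 <- direct_paths(fx$net, tab, fx$data)
  s2 <- scoring_pass(s1)
  s3 <- nullified_rescoring(s2)
  sat <- function(s) which(startsWith(s$status, "satisfied"))
  expect_true(all(sat(s1) %in% sat(s2)))
  expect_true(all(sat(s2) %in% sat(s3)))
  for (k in sat(s3)) {
    expect_true(s3$deps$signal[k] %in%
                  reachable_set(included_edges(s3), s3$deps$stimulus[k]))
  }
  # every committed path met the acceptance threshold at commit time
  commits <- Filter(function(ev) startsWith(ev$status, "satisfied") &&
                      !is.na(ev$score), s3$log)
  expect_true(all(vapply(commits, function(ev) ev$score >= 0, logical(1))))
})

test_that("on consistent planted data every dependency is satisfied exactly", {
  withr::with_seed(2024, {
    for (rep in 1:15) {
      inst <- planted_instance(n_nodes = 12, edge_density = 0.3, n_stimuli = 2)
      sol <- reconstruct(inst$net, inst$data)
      cm <- reachable_matrix(sol, inst$data)
      expect_equal(fit_error(cm, inst$data), 0)
      expect_true(all(startsWith(sol$status, "satisfied")))
      # training never hurts relative to the untrained scaffold
      expect_lte(fit_error(cm, inst$data),
                 fit_error(reachable_matrix(inst$net, inst$data), inst$data))
    }
  })
})
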