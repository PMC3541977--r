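test_that("the trade-off pool enumerates every two-dimension upgrade pair", {
  # sum over dimension pairs of C(m_i,2) * C(m_j,2)
  ps <- table1_points_system()
  pool <- enumerate_tradeoff_pairs(ps)
  m <- vapply(ps$dimensions, function(d) length(d$labels), integer(1))
  expected <- sum(combn(length(m), 2, function(ij) choose(m[ij[1]], 2) * choose(m[ij[2]], 2)))
  expect_equal(nrow(pool), expected)
  expect_equal(nrow(pool), 247)
  expect_equal(nrow(unique(pool)), 247)
  # every question is a genuine trade-off: left better on dim_a, worse on dim_b
  lev <- function(key, lab) {
    d <- ps$dimensions[[key]]
    match(tolower(gsub("\\s", "", lab)), tolower(gsub("\\s", "", d$labels)))
  }
  for (i in sample(nrow(pool), 25)) {
    q <- pool[i, ]
    expect_gt(lev(q$dim_a, q$left_a), lev(q$dim_a, q$right_a))
    expect_lt(lev(q$dim_b, q$left_b), lev(q$dim_b, q$right_b))
  }
  expect_equal(nrow(enumerate_tradeoff_pairs(toy_system())), 1)
  three <- points_system(list(ps_dimension("A", c(l = 0, h = 1)),
                              ps_dimension("B", c(l = 0, h = 1)),
                              ps_dimension("C", c(l = 0, h = 1))))
  expect_equal(nrow(enumerate_tradeoff_pairs(three)), 3)
})

test_that("next_question skips implied questions and signals completion", {
  ps <- toy_system()
  st <- ranking_state(ps)
  q <- next_question(st)
  expect_s3_class(q, "data.frame")
  st <- record_judgment(st, q, "left")
  expect_null(next_question(st))
  expect_true(session_complete(st))

  # chained strict judgments imply the third relation, which is never asked:
  # upgrade(A) > upgrade(B) and upgrade(B) > upgrade(C) => A vs C resolved
  three <- points_system(list(ps_dimension("A", c(l = 0, h = 1)),
                              ps_dimension("B", c(l = 0, h = 1)),
                              ps_dimension("C", c(l = 0, h = 1))))
  st3 <- ranking_state(three)
  qAB <- data.frame(dim_a = "a", dim_b = "b", left_a = "h", left_b = "l",
                    right_a = "l", right_b = "h", stringsAsFactors = FALSE)
  qBC <- data.frame(dim_a = "b", dim_b = "c", left_a = "h", left_b = "l",
                    right_a = "l", right_b = "h", stringsAsFactors = FALSE)
  st3 <- record_judgment(st3, qAB, "left")
  st3 <- record_judgment(st3, qBC, "left")
  expect_true(session_complete(st3))   # A vs C implied by transitivity
  expect_equal(st3$asked, 2L)
})

test_that("contradictory and cyclic judgments raise a typed inconsistency error", {
  three <- points_system(list(ps_dimension("A", c(l = 0, h = 1)),
                              ps_dimension("B", c(l = 0, h = 1)),
                              ps_dimension("C", c(l = 0, h = 1))))
  q <- function(d1, d2) data.frame(dim_a = d1, dim_b = d2, left_a = "h", left_b = "l",
                                   right_a = "l", right_b = "h", stringsAsFactors = FALSE)
  st <- ranking_state(three)
  st <- record_judgment(st, q("a", "b"), "left")    # A > B
  st <- record_judgment(st, q("b", "c"), "left")    # B > C
  # C > A closes a strict cycle
  expect_error(record_judgment(st, q("c", "a"), "left"), class = "vfm_inconsistency")
  # equal against an implied strict relation is also inconsistent
  expect_error(record_judgment(st, q("a", "c"), "equal"))
  # re-answering a resolved question is rejected
  expect_error(record_judgment(st, q("a", "b"), "left"), "resolved")
})

test_that("equal verdicts propagate through the closure like equivalences", {
  three <- points_system(list(ps_dimension("A", c(l = 0, h = 1)),
                              ps_dimension("B", c(l = 0, h = 1)),
                              ps_dimension("C", c(l = 0, h = 1))))
  q <- function(d1, d2) data.frame(dim_a = d1, dim_b = d2, left_a = "h", left_b = "l",
                                   right_a = "l", right_b = "h", stringsAsFactors = FALSE)
  st <- ranking_state(three)
  st <- record_judgment(st, q("a", "b"), "equal")
  st <- record_judgment(st, q("b", "c"), "left")    # B > C
  expect_true(session_complete(st))                 # A > C implied via A = B
  der <- derive_point_values(st)
  tops <- vapply(der$dimensions, function(d) max(d$points), numeric(1))
  expect_equal(tops[["a"]], tops[["b"]], tolerance = 1e-9)
  expect_gt(tops[["a"]], tops[["c"]])
})

test_that("incremental closure equals brute-force path search on small instances", {
  set.seed(7)
  for (rep in 1:8) {
    nl <- sample(2:4, sample(3:4, 1), replace = TRUE)
    hidden <- random_points_system(nl)
    st <- run_elicitation(hidden, simulate_answers(hidden), method = "random")
    bf <- brute_closure(st)
    expect_identical(st$W, bf$W)
    expect_identical(st$S, bf$S)
  }
})

test_that("the simulated answerer matches the hidden schedule and never contradicts itself", {
  ps <- table1_points_system()
  oracle <- simulate_answers(ps)
  # a few-lives upgrade (0.091) against a large QoL upgrade (0.217)
  q <- data.frame(dim_a = "lives_saved", dim_b = "qol_gains",
                  left_a = "Few: 1-50 lives saved",
                  left_b = "None/Very small (or not yet known)",
                  right_a = "None (or not yet known)",
                  right_b = "Large QoL gains", stringsAsFactors = FALSE)
  expect_equal(oracle(q), "right")
  tie <- points_system(list(ps_dimension("A", c(l = 0, h = 0.5)),
                            ps_dimension("B", c(l = 0, h = 0.5))))
  tq <- data.frame(dim_a = "a", dim_b = "b", left_a = "h", left_b = "l",
                   right_a = "l", right_b = "h", stringsAsFactors = FALSE)
  expect_equal(simulate_answers(tie)(tq), "equal")
  # random answering orders never trip the consistency check
  set.seed(11)
  for (rep in 1:5) {
    hidden <- random_points_system(sample(2:4, 3, replace = TRUE))
    expect_no_error(run_elicitation(hidden, simulate_answers(hidden), method = "random"))
  }
})

test_that("derived point values reproduce the hidden ranking of every pool pair", {
  set.seed(12)
  for (rep in 1:6) {
    nl <- sample(2:5, sample(3:5, 1), replace = TRUE)
    hidden <- random_points_system(nl)
    st <- run_elicitation(hidden, simulate_answers(hidden))
    expect_lt(st$asked, nrow(st$pool))
    der <- derive_point_values(st)
    expect_equal(nrow(validate_points_system(der)), 0)
    tops <- vapply(der$dimensions, function(d) max(d$points), numeric(1))
    expect_equal(sum(tops), 1, tolerance = 1e-9)
    qs <- enumerate_tradeoff_pairs(hidden)
    oh <- simulate_answers(hidden); od <- simulate_answers(der)
    agree <- vapply(seq_len(nrow(qs)), function(i) oh(qs[i, ]) == od(qs[i, ]), logical(1))
    expect_true(all(agree))
  }
})

test_that("single-question and all-equal sessions derive the expected schedules", {
  # two 2-level dimensions: one answer decides which top value is larger
  ps <- toy_system()
  st <- run_elicitation(ps, function(q) "left")
  der <- derive_point_values(st)
  tops <- vapply(der$dimensions, function(d) max(d$points), numeric(1))
  expect_gt(tops[[1]], tops[[2]])
  expect_equal(sum(tops), 1, tolerance = 1e-9)
  # all verdicts equal: every top value identical
  three <- points_system(list(ps_dimension("A", c(l = 0, h = 1)),
                              ps_dimension("B", c(l = 0, h = 1)),
                              ps_dimension("C", c(l = 0, h = 1))))
  der_eq <- derive_point_values(run_elicitation(three, function(q) "equal"))
  tops_eq <- vapply(der_eq$dimensions, function(d) max(d$points), numeric(1))
  expect_equal(unname(tops_eq), rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("the final closure and derived values do not depend on question order", {
  hidden <- withr::with_seed(5, random_points_system(c(4L, 3L, 3L)))
  runs <- lapply(c(101, 202, 303), function(seed) {
    withr::with_seed(seed, run_elicitation(hidden, simulate_answers(hidden),
                                           method = "random"))
  })
  greedy <- run_elicitation(hidden, simulate_answers(hidden), method = "greedy")
  vals <- function(st) unlist(lapply(derive_point_values(st)$dimensions, `[[`, "points"))
  ref <- vals(greedy)
  for (r in runs) {
    expect_identical(r$W, greedy$W)
    expect_identical(r$S, greedy$S)
    expect_equal(vals(r), ref, tolerance = 1e-9)
  }
})

test_that("sessions persist to JSON and resume with the identical closure", {
  hidden <- withr::with_seed(21, random_points_system(c(3L, 3L, 2L)))
  st <- run_elicitation(hidden, simulate_answers(hidden))
  f <- tempfile(fileext = ".json")
  save_session(st, f)
  back <- load_session(f)
  expect_identical(back$W, st$W)
  expect_identical(back$S, st$S)
  expect_equal(back$asked, st$asked)
  v1 <- unlist(lapply(derive_point_values(st)$dimensions, `[[`, "points"))
  v2 <- unlist(lapply(derive_point_values(back)$dimensions, `[[`, "points"))
  expect_equal(v2, v1, tolerance = 1e-12)
})

test_that("derivation refuses an incomplete session", {
  st <- ranking_state(table1_points_system())
  expect_error(derive_point_values(st), "incomplete")
})
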