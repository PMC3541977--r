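ps <- table1_points_system()
pf <- table2_technologies()
pts <- build_vfm_points(pf, ps)

test_that("scoring the bundled portfolio reproduces the narrative ordering", {
  expect_equal(nrow(pts), 18)
  score <- function(id) pts$benefit[pts$tech_id == id]
  expect_true(score("t1") > score("t2"))
  expect_true(score("t2") > score("t3"))
  expect_true(score("t3") > score("t5"))
  expect_true(score("t5") > score("t6"))
  # Herceptin's edge over Visudyne is marginal relative to the score range
  expect_lt(score("t3") - score("t5"), 0.05)
  # X-factors flag exactly the technologies with a non-"none" note
  expect_equal(sort(pts$tech_id[pts$x_flag]), c("t1", "t10", "t16", "t4", "t7"))
  expect_equal(build_vfm_points(pf[0, ], ps)$tech_id, character(0))
})

test_that("frontier layers peel exactly as the worked example describes", {
  expect_equal(pareto_frontier(pts), c("t16", "t14", "t2", "t1"))
  rest14 <- pts[!(pts$tech_id %in% c("t1", "t2", "t4", "t6")), ]
  f2 <- pareto_frontier(rest14)
  expect_equal(f2, c("t16", "t14", "t7", "t5", "t3"))
  rest9 <- rest14[!(rest14$tech_id %in% f2), ]
  expect_equal(pareto_frontier(rest9), c("t18", "t15", "t11", "t9", "t8"))
  expect_equal(pareto_frontier(pts[pts$tech_id == "t9", ]), "t9")
  # successive frontiers are disjoint
  expect_length(intersect(pareto_frontier(pts), f2), 2)  # t16, t14 persist
  expect_length(intersect(f2, pareto_frontier(rest9)), 0)
})

test_that("the frontier equals the brute-force non-dominated set on random portfolios", {
  set.seed(314)
  for (rep in 1:40) {
    p <- random_points(sample(1:50, 1), tie_prob = 0.2)
    expect_equal(pareto_frontier(p), brute_frontier(p))
  }
})

test_that("the frontier is upward-sloping and carries the steepest ray", {
  set.seed(2718)
  for (rep in 1:20) {
    p <- random_points(sample(2:40, 1))
    f <- pareto_frontier(p)
    fp <- p[match(f, p$tech_id), ]
    if (nrow(fp) > 1) {
      expect_true(all(diff(fp$cost) > 0))
      expect_true(all(diff(fp$benefit) > 0))
    }
    # dominance can only lower benefit/cost, so the steepest ray from the
    # origin to any point is attained on the frontier
    expect_true(max(fp$benefit / fp$cost) >= max(p$benefit / p$cost) - 1e-12)
  }
  # exact (cost, benefit) ties are all retained and flagged as frontier members
  tied <- structure(data.frame(tech_id = c("a", "b", "c"),
                               benefit = c(0.5, 0.5, 0.2), cost = c(10, 10, 20),
                               stringsAsFactors = FALSE),
                    class = c("vfm_points", "data.frame"))
  expect_equal(pareto_frontier(tied), c("a", "b"))
})

test_that("cost comparisons match the quoted differences", {
  expect_equal(compare_costs("t3", "t5", pf), 97.53, tolerance = 1e-9)
  expect_equal(compare_costs("t3", "t6", pf), 119.17, tolerance = 1e-9)
  expect_equal(compare_costs("t5", "t6", pf), 21.64, tolerance = 1e-9)
  expect_equal(compare_costs("t9", "t9", pf), 0)
  expect_error(compare_costs("t99", "t1", pf), "unknown")
})

test_that("selection tracks spending, conserves the budget and guards overspend", {
  st <- selection_state(pf, 300)
  st <- select_technologies(st, c("t1", "t2", "t4", "t6"))
  expect_equal(st$spent, 20.17, tolerance = 1e-9)
  st2 <- select_technologies(st, c("t16", "t14", "t7", "t5", "t3"))
  expect_equal(st2$spent - st$spent, 172.91, tolerance = 1e-9)
  expect_identical(select_technologies(st2, character(0)), st2)
  # money conservation at every logged step
  for (a in st2$log) {
    if (identical(a$action, "select"))
      expect_equal(a$spent + a$unallocated, 300, tolerance = 1e-9)
  }
  expect_equal(length(intersect(st2$selected, st2$remaining)), 0)
  expect_error(select_technologies(st2, "t1"), "already")
  expect_error(select_technologies(st2, "nope"), "unknown")
  expect_error(select_technologies(st2, c("t8", "t8")), "duplicate")
  tight <- selection_state(pf, 5)
  expect_error(select_technologies(tight, "t3"), "overspend")
  forced <- select_technologies(tight, "t3", force = TRUE)
  expect_equal(forced$spent, 124)
  f <- tempfile(fileext = ".json")
  save_selection_log(st2, f)
  log <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(log$budget, 300)
  expect_equal(length(log$actions), 3)
})

test_that("knapsack solver is exact against exhaustive enumeration", {
  sub <- pts[pts$tech_id %in% c("t1", "t2", "t6", "t14", "t16", "t18"), ]
  expect_equal(knapsack_optimal(sub, 20), c("t1", "t14", "t2", "t6"))
  expect_equal(knapsack_optimal(sub, 20), sort(brute_knapsack(sub, 20)))
  expect_equal(knapsack_optimal(pts, 1e6), sort(pts$tech_id))
  expect_equal(knapsack_optimal(pts, 0), character(0))
  set.seed(1618)
  for (rep in 1:12) {
    p <- random_points(sample(2:12, 1))
    budget <- round(stats::runif(1, 5, 0.8 * sum(p$cost)), 2)
    expect_equal(knapsack_optimal(p, budget), brute_knapsack(p, budget))
  }
})

test_that("knapsack honors lock-in and lock-out constraints", {
  sub <- pts[pts$tech_id %in% c("t1", "t2", "t6", "t14", "t16", "t18"), ]
  with_t18 <- knapsack_optimal(sub, 20, locked_in = "t18")
  expect_true("t18" %in% with_t18)
  without_t1 <- knapsack_optimal(sub, 20, locked_out = "t1")
  expect_false("t1" %in% without_t1)
  # lock-in consumes budget; the rest is re-optimized exactly
  rest <- sub[sub$tech_id != "t18", ]
  expect_equal(setdiff(with_t18, "t18"), brute_knapsack(rest, 20 - 3.49))
  expect_error(knapsack_optimal(sub, 3, locked_in = c("t1", "t2")), "exceed")
  expect_error(knapsack_optimal(sub, 20, locked_in = "t1", locked_out = "t1"), "overlap")
  expect_error(knapsack_optimal(sub, 20, locked_in = "t99"), "unknown")
})

test_that("what-would-it-take finds the smallest rating upgrade to reach contention", {
  expect_equal(what_would_it_take("t16", pf, ps)$status, "on_frontier")
  # t11 (25.6m, benefit 0.333) is dominated, and every cheaper competitor is
  # topped by t1's 0.891, which no single-dimension upgrade can reach --
  # verify the returned set by re-running the frontier on the modified table
  res <- what_would_it_take("t11", pf, ps)
  expect_equal(res$status, "upgrades")
  mod <- pf
  for (k in names(res$upgrades)) mod[[k]][mod$id == "t11"] <- res$upgrades[[k]]
  expect_true("t11" %in% pareto_frontier(build_vfm_points(mod, ps)))
  expect_equal(length(res$upgrades), 2)
  # minimality: exhaustive check that no single-dimension upgrade suffices
  for (k in names(ps$dimensions)) {
    d <- ps$dimensions[[k]]
    cur <- match(pf[[k]][pf$id == "t11"], d$labels)
    for (l in seq_along(d$labels)) {
      if (l <= cur) next
      one <- pf
      one[[k]][one$id == "t11"] <- d$labels[l]
      expect_false("t11" %in% pareto_frontier(build_vfm_points(one, ps)))
    }
  }
  # a technology dominated even at the maximum rating is flagged as such:
  # an all-top competitor (score 0.999) at cost 1 dominates any pricier rival
  block <- rbind(pf, pf[pf$id == "t18", ], pf[pf$id == "t18", ])
  block$id[19:20] <- c("t98", "t99")
  for (k in names(ps$dimensions))
    block[[k]][19] <- ps$dimensions[[k]]$labels[length(ps$dimensions[[k]]$labels)]
  block$total_cost[19:20] <- c(1, 50)
  expect_equal(what_would_it_take("t99", block, ps)$status, "not_achievable")
})

test_that("committee shortlisting splits majority from question-marked nominations", {
  b <- data.frame(member_id = c("m1", "m2", "m3", "m1"),
                  tech_id = c("t1", "t1", "t1", "t2"))
  out <- committee_shortlist(b, n_members = 3)
  expect_equal(out$majority$tech_id, "t1")
  expect_equal(out$majority$nominations, 3L)
  expect_equal(out$question_marked$tech_id, "t2")
  empty <- committee_shortlist(data.frame(member_id = character(0),
                                          tech_id = character(0)), 3)
  expect_equal(nrow(empty$majority), 0)
  expect_equal(nrow(empty$question_marked), 0)
  # exactly half is not a majority; counts sort the lists
  b4 <- data.frame(member_id = c("m1", "m2", "m1", "m2", "m3", "m4"),
                   tech_id = c("t5", "t5", "t7", "t7", "t7", "t9"))
  out4 <- committee_shortlist(b4, n_members = 4)
  expect_equal(out4$majority$tech_id, "t7")
  expect_equal(out4$question_marked$tech_id, c("t5", "t9"))
  over <- data.frame(member_id = rep("m1", 11), tech_id = sprintf("t%d", 1:11))
  expect_error(committee_shortlist(over, 3, k = 10), "more than k")
})
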