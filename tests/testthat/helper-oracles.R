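# Independent oracles and small builders used across the test files.

# O(n^2) non-dominated set by direct definition (double loop)
brute_frontier <- function(points) {
  n <- nrow(points)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j != i &&
          points$cost[j] <= points$cost[i] &&
          points$benefit[j] >= points$benefit[i] &&
          (points$cost[j] < points$cost[i] || points$benefit[j] > points$benefit[i])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  ids <- points$tech_id[keep]
  ids[order(points$cost[keep], points$benefit[keep])]
}

# exhaustive 0-1 knapsack with the same tie-breaks the solver promises:
# max benefit, then min cost, then lexicographically smallest id set
brute_knapsack <- function(points, budget) {
  n <- nrow(points)
  best <- list(benefit = -Inf, cost = Inf, key = "￿", ids = character(0))
  for (mask in 0:(2^n - 1)) {
    inc <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    cost <- sum(round(points$cost[inc] * 100)) / 100
    if (cost > budget + 1e-9) next
    benefit <- sum(points$benefit[inc])
    ids <- sort(points$tech_id[inc])
    key <- paste(ids, collapse = ",")
    better <- benefit > best$benefit + 1e-9 ||
      (abs(benefit - best$benefit) <= 1e-9 &&
         (cost < best$cost - 1e-9 ||
            (abs(cost - best$cost) <= 1e-9 && key < best$key)))
    if (better) best <- list(benefit = benefit, cost = cost, key = key, ids = ids)
  }
  best$ids
}

# brute-force closure by Floyd-Warshall path search over interval nodes:
# weak edges = containment + all judged relations, strict flag carried on
# paths that use at least one strict edge
brute_closure <- function(st) {
  n <- nrow(st$nodes)
  W <- matrix(FALSE, n, n); S <- matrix(FALSE, n, n)
  diag(W) <- TRUE
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u != v && st$nodes$dim[u] == st$nodes$dim[v] &&
        st$nodes$lo[u] <= st$nodes$lo[v] && st$nodes$hi[u] >= st$nodes$hi[v])
      W[u, v] <- TRUE
  }
  for (j in st$judgments) {
    q <- data.frame(j[c("dim_a", "dim_b", "left_a", "left_b", "right_a", "right_b")],
                    stringsAsFactors = FALSE)
    nd <- vfmchart:::question_nodes(st, q)
    if (j$verdict == "equal") {
      W[nd$a, nd$b] <- TRUE; W[nd$b, nd$a] <- TRUE
    } else {
      hi <- if (j$verdict == "left") nd$a else nd$b
      lo <- if (j$verdict == "left") nd$b else nd$a
      W[hi, lo] <- TRUE; S[hi, lo] <- TRUE
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (W[i, k] && W[k, j]) {
      S[i, j] <- S[i, j] || S[i, k] || S[k, j]
      W[i, j] <- TRUE
    }
  }
  list(W = W, S = S)
}

# tiny two-dimension system for hand-checkable elicitation cases
toy_system <- function(vals_a = c(0, 0.6), vals_b = c(0, 0.4)) {
  points_system(list(
    ps_dimension("Alpha", stats::setNames(vals_a, paste("a level", seq_along(vals_a)))),
    ps_dimension("Beta",  stats::setNames(vals_b, paste("b level", seq_along(vals_b))))
  ))
}

fixture_rating <- function(lives = "None (or not yet known)",
                           prolong = "None/Very small (or not yet known)",
                           qol = "None/Very small (or not yet known)",
                           funded = "Many/most patients will be able to pay for it themselves (privately)",
                           social = "None/Very small (or not yet known)") {
  c(lives_saved = lives, life_prolongation = prolong, qol_gains = qol,
    if_not_funded = funded, social_benefits = social)
}

# random vfm point clouds for property tests
random_points <- function(n, tie_prob = 0) {
  cost <- round(stats::rlnorm(n, log(20), 1), 2)
  benefit <- round(stats::runif(n, 0, 1), 3)
  if (tie_prob > 0 && n > 1) {
    dup <- stats::runif(n) < tie_prob
    src <- sample(seq_len(n), sum(dup), replace = TRUE)
    cost[dup] <- cost[src]
  }
  structure(data.frame(tech_id = sprintf("p%02d", seq_len(n)),
                       benefit = benefit, cost = cost,
                       evidence = sample(c("poor", "medium", "high"), n, TRUE),
                       x_flag = stats::runif(n) < 0.3,
                       stringsAsFactors = FALSE),
            class = c("vfm_points", "data.frame"))
}

svg_doc <- function(svg) xml2::read_xml(paste(svg, collapse = "\n"))

svg_count <- function(doc, xpath) {
  length(xml2::xml_find_all(doc, xpath, xml2::xml_ns(doc)))
}

frontier_vertices <- function(doc) {
  pl <- xml2::xml_find_first(doc, "//d1:polyline[@class='frontier']", xml2::xml_ns(doc))
  strsplit(xml2::xml_attr(pl, "points"), " ")[[1]]
}
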