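#' Project technologies onto value-for-money points
#'
#' Scores each technology's rating under the points system and pairs the
#' benefit score with the technology's annual total cost, quality-of-
#' evidence grade and X-factor flag.  These four variables are what the
#' value-for-money chart displays; evidence and X-factors are never folded
#' into the score.
#'
#' @param portfolio A technology table as returned by [load_portfolio()]
#'   or [generate_synthetic()]: columns `id`, one column per dimension key,
#'   `total_cost`, `evidence`, `x_factors`.
#' @param ps The governing [points_system()].
#' @return A data frame of class `vfm_points` with columns `tech_id`,
#'   `benefit`, `cost`, `evidence`, `x_flag`.
#' @export
build_vfm_points <- function(portfolio, ps) {
  keys <- dim_keys(ps)
  missing <- setdiff(keys, names(portfolio))
  if (length(missing) > 0L)
    stop(sprintf("portfolio lacks rating column(s): %s", paste(missing, collapse = ", ")))
  n <- nrow(portfolio)
  benefit <- numeric(n)
  for (i in seq_len(n)) {
    rating <- stats::setNames(
      vapply(keys, function(k) as.character(portfolio[[k]][i]), character(1)), keys)
    benefit[i] <- total_score(rating, ps)
  }
  xf <- as.character(portfolio$x_factors)
  xf[is.na(xf)] <- ""
  out <- data.frame(
    tech_id = as.character(portfolio$id),
    benefit = benefit,
    cost = as.numeric(portfolio$total_cost),
    evidence = as.character(portfolio$evidence),
    x_flag = nzchar(trimws(xf)) & normalize_label(xf) != "none",
    stringsAsFactors = FALSE
  )
  class(out) <- c("vfm_points", "data.frame")
  out
}

#' Pareto efficiency frontier
#'
#' A point is on the frontier when no other point has cost no higher and
#' benefit no lower, with at least one strict inequality.  Points with
#' identical (cost, benefit) do not dominate one another and are all
#' retained.  Computed by a cost-sorted sweep.
#'
#' @param points A `vfm_points` data frame (or anything with `tech_id`,
#'   `benefit`, `cost` columns).
#' @return Character vector of `tech_id`s on the frontier, sorted by cost
#'   (then benefit) ascending.
#' @export
pareto_frontier <- function(points) {
  n <- nrow(points)
  if (n == 0L) return(character(0))
  ord <- order(points$cost, -points$benefit)
  cost <- points$cost[ord]; benefit <- points$benefit[ord]
  id <- points$tech_id[ord]
  keep <- logical(n)
  best_cheaper <- -Inf                 # max benefit among strictly cheaper points
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && cost[j + 1L] == cost[i]) j <- j + 1L
    grp_max <- benefit[i]              # group sorted benefit-descending
    keep[i:j] <- benefit[i:j] == grp_max & grp_max > best_cheaper
    best_cheaper <- max(best_cheaper, grp_max)
    i <- j + 1L
  }
  sel <- which(keep)
  sel <- sel[order(cost[sel], benefit[sel])]
  id[sel]
}

#' Cost difference between two technologies
#'
#' Exact difference of the stored annual costs (cost of `a` minus cost of
#' `b`), in millions.  Rounding (e.g. to the nearest million for large
#' differences) is left to the reporting layer.
#'
#' @param a,b Technology ids.
#' @param portfolio A technology table with `id` and `total_cost` columns.
#' @return Signed difference in millions.
#' @export
compare_costs <- function(a, b, portfolio) {
  cost_of <- function(id) {
    i <- match(id, portfolio$id)
    if (is.na(i)) stop(sprintf("unknown technology id '%s'", id))
    as.numeric(portfolio$total_cost[i])
  }
  cost_of(a) - cost_of(b)
}

#' Budget-constrained selection state
#'
#' Tracks the deliberation loop: the budget, the ordered list of selected
#' technologies, money spent and the remaining candidates.  Every action
#' is appended to an audit log that can be written out with
#' [save_selection_log()].
#'
#' @param portfolio A technology table (`id`, `total_cost`, ...).
#' @param budget Budget in millions.
#' @return An object of class `selection_state`.
#' @export
selection_state <- function(portfolio, budget) {
  stopifnot(is.numeric(budget), length(budget) == 1L, budget >= 0)
  st <- list(
    budget = budget,
    costs = stats::setNames(as.numeric(portfolio$total_cost),
                            as.character(portfolio$id)),
    selected = character(0),
    spent = 0,
    remaining = as.character(portfolio$id),
    log = list(list(action = "init", budget = budget))
  )
  class(st) <- "selection_state"
  st
}

#' Select technologies into the basket
#'
#' Moves `ids` from the remaining candidates to the selected list and adds
#' their costs to the running total.  Exceeding the budget is an error
#' unless `force = TRUE` (an explicit, logged overspend).
#'
#' @param st A [selection_state()].
#' @param ids Character vector of technology ids (may be empty).
#' @param force Allow the budget to be exceeded.
#' @return The updated `selection_state`.
#' @export
select_technologies <- function(st, ids, force = FALSE) {
  ids <- as.character(ids)
  if (length(ids) == 0L) return(st)
  if (anyDuplicated(ids))
    stop("duplicate ids in selection")
  unknown <- setdiff(ids, names(st$costs))
  if (length(unknown) > 0L)
    stop(sprintf("unknown technology id '%s'", unknown[1L]))
  already <- setdiff(ids, st$remaining)
  if (length(already) > 0L)
    stop(sprintf("technology '%s' is already selected", already[1L]))
  add <- sum(st$costs[ids])
  if (st$spent + add > st$budget + 1e-9 && !force)
    stop(sprintf(paste0("selection would overspend the budget: ",
                        "%.2f spent + %.2f new > %.2f budget ",
                        "(use force = TRUE to overspend explicitly)"),
                 st$spent, add, st$budget))
  st$selected <- c(st$selected, ids)
  st$spent <- st$spent + add
  st$remaining <- setdiff(st$remaining, ids)
  st$log[[length(st$log) + 1L]] <-
    list(action = "select", ids = ids, cost = add,
         spent = st$spent, unallocated = st$budget - st$spent,
         forced = isTRUE(force) && st$spent > st$budget)
  st
}

#' @export
print.selection_state <- function(x, ...) {
  cat(sprintf("Selection: %d chosen (%.2f m spent), %d remaining, %.2f m of %.2f m unallocated\n",
              length(x$selected), x$spent, length(x$remaining),
              x$budget - x$spent, x$budget))
  if (length(x$selected) > 0L)
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Write the selection audit log
#'
#' JSON log of every action with its cost and the running budget trace,
#' enabling replay and audit of a deliberation session.
#'
#' @param st A [selection_state()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
save_selection_log <- function(st, path) {
  jsonlite::write_json(list(budget = st$budget, actions = st$log),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## max benefit achievable with integer weights w, values v, capacity cap
## (classic 0-1 knapsack DP, capacity-indexed)
dp_max_benefit <- function(w, v, cap) {
  dp <- numeric(cap + 1L)
  for (i in seq_along(w)) {
    wi <- w[i]
    if (wi <= cap) {
      idx <- seq(wi, cap)
      dp[idx + 1L] <- pmax(dp[idx + 1L], dp[idx - wi + 1L] + v[i])
    }
  }
  dp
}

## max benefit using weight exactly c, for every c in 0..cap (-Inf if unreachable)
dp_exact_weight <- function(w, v, cap) {
  f <- c(0, rep(-Inf, cap))
  for (i in seq_along(w)) {
    wi <- w[i]
    if (wi <= cap) {
      idx <- seq(wi, cap)
      f[idx + 1L] <- pmax(f[idx + 1L], f[idx - wi + 1L] + v[i])
    }
  }
  f
}

#' Exact knapsack benchmark for basket selection
#'
#' Solves the 0-1 knapsack problem over the technologies: pick the subset
#' maximizing total benefit score subject to total cost not exceeding the
#' budget, honoring lock-ins (X-factor mandates) and lock-outs.  Costs are
#' held at two-decimal precision (millions) and scaled by 100 to integers,
#' making the dynamic program exact.  Among benefit-optimal subsets the
#' cheapest is returned; remaining ties are broken by lexicographically
#' smallest id set (R's default string ordering, so `"t10" < "t2"`).
#'
#' The benchmark deliberately optimizes benefit only: evidence grades and
#' X-factors enter as lock constraints or stay with the deliberating
#' committee, never as objective weights.
#'
#' @param points A `vfm_points` data frame (see [build_vfm_points()]).
#' @param budget Budget in millions.
#' @param locked_in Ids that must be included (e.g. a political mandate).
#' @param locked_out Ids that must be excluded.
#' @return Character vector of selected ids (sorted), including
#'   `locked_in`.
#' @export
knapsack_optimal <- function(points, budget, locked_in = character(0),
                             locked_out = character(0)) {
  locked_in <- as.character(locked_in); locked_out <- as.character(locked_out)
  unknown <- setdiff(c(locked_in, locked_out), points$tech_id)
  if (length(unknown) > 0L)
    stop(sprintf("unknown technology id '%s'", unknown[1L]))
  if (length(intersect(locked_in, locked_out)) > 0L)
    stop("locked_in and locked_out overlap")
  to_int <- function(x) {
    xi <- round(x * 100)
    if (any(abs(x * 100 - xi) > 1e-6))
      warning("costs rounded to two decimals (millions) for the exact knapsack")
    as.integer(xi)
  }
  cost_in <- sum(points$cost[match(locked_in, points$tech_id)])
  cap <- to_int(budget) - to_int(cost_in)
  if (cap < 0) stop("locked-in technologies alone exceed the budget")

  free <- points[!(points$tech_id %in% c(locked_in, locked_out)), , drop = FALSE]
  free <- free[order(free$tech_id), , drop = FALSE]
  w <- to_int(free$cost)
  v <- free$benefit
  n <- nrow(free)
  if (n == 0L) return(sort(locked_in))
  if (sum(w) <= cap) return(sort(c(locked_in, free$tech_id)))   # budget is slack
  cap <- min(cap, sum(w))

  eps <- 1e-9
  B <- max(dp_max_benefit(w, v, cap))
  # cheapest capacity at which the optimum is attained = minimal total cost
  f_all <- dp_exact_weight(w, v, cap)
  Cstar <- min(which(f_all >= B - eps)) - 1L

  # lexicographically smallest optimal id set: include each id (ascending)
  # iff an exact completion from the later items still reaches the optimum
  chosen <- logical(n)
  needB <- B; needW <- Cstar
  for (i in seq_len(n)) {
    if (w[i] <= needW) {
      rest <- if (i < n) seq(i + 1L, n) else integer(0)
      f <- dp_exact_weight(w[rest], v[rest], needW - w[i])
      if (f[needW - w[i] + 1L] >= needB - v[i] - eps) {
        chosen[i] <- TRUE
        needB <- needB - v[i]
        needW <- needW - w[i]
      }
    }
  }
  stopifnot(abs(needB) <= 1e-6, needW == 0L)
  sort(c(locked_in, free$tech_id[chosen]))
}

#' What would it take for a technology to be in contention?
#'
#' Sensitivity analysis for a technology off the frontier: searches all
#' combinations of single-dimension rating upgrades (never cost changes),
#' ordered by the number of dimensions changed and then by the score
#' increase, and returns the smallest upgrade set under which the
#' re-scored technology is no longer dominated by any other point.
#'
#' @param tech_id Technology of interest.
#' @param portfolio Technology table containing it.
#' @param ps The governing [points_system()].
#' @return A list with `status` one of `"on_frontier"` (no upgrade
#'   needed), `"upgrades"` (with `upgrades`, a named character vector of
#'   new level labels by dimension key, and `new_benefit`), or
#'   `"not_achievable"` (dominated even at the maximum rating).
#' @export
what_would_it_take <- function(tech_id, portfolio, ps) {
  i <- match(tech_id, portfolio$id)
  if (is.na(i)) stop(sprintf("unknown technology id '%s'", tech_id))
  points <- build_vfm_points(portfolio, ps)
  me <- points[points$tech_id == tech_id, ]
  others <- points[points$tech_id != tech_id, ]
  dominated <- function(benefit) {
    any(others$cost <= me$cost & others$benefit >= benefit &
        (others$cost < me$cost | others$benefit > benefit))
  }
  if (!dominated(me$benefit))
    return(list(status = "on_frontier"))

  keys <- dim_keys(ps)
  cur_idx <- vapply(keys, function(k)
    match_level(ps$dimensions[[k]], portfolio[[k]][i]), integer(1))
  # candidate levels per dimension: current and every higher level
  cand <- lapply(seq_along(keys), function(d)
    seq(cur_idx[d], length(ps$dimensions[[d]]$labels)))
  grid <- expand.grid(cand)
  base <- me$benefit
  # score through total_score so exact ties compare identically with the
  # other technologies' benefits
  new_benefit <- apply(grid, 1L, function(lv) {
    rating <- stats::setNames(vapply(seq_along(keys), function(d)
      ps$dimensions[[d]]$labels[lv[d]], character(1)), keys)
    total_score(rating, ps)
  })
  n_changed <- apply(grid, 1L, function(lv) sum(lv != cur_idx))
  ord <- order(n_changed, new_benefit - base)
  for (g in ord) {
    if (n_changed[g] == 0L) next
    if (!dominated(new_benefit[g])) {
      changed <- which(grid[g, ] != cur_idx)
      upgrades <- vapply(changed, function(d)
        ps$dimensions[[d]]$labels[grid[g, d][[1L]]], character(1))
      names(upgrades) <- keys[changed]
      return(list(status = "upgrades", upgrades = upgrades,
                  new_benefit = new_benefit[g]))
    }
  }
  list(status = "not_achievable")
}

#' Committee top-k shortlisting
#'
#' Each committee member nominates up to `k` technologies.  Technologies
#' nominated by a strict majority of members form the main list;
#' technologies nominated by at least one but not a majority are flagged
#' with a question mark (less support).  Both lists are sorted by
#' nomination count, descending (ties by id).
#'
#' @param ballots Data frame with columns `member_id` and `tech_id`
#'   (one row per nomination).
#' @param n_members Number of committee members (>= 1).
#' @param k Maximum nominations per member (default 10, the "top ten").
#' @return A list with data frames `majority` and `question_marked`, each
#'   with columns `tech_id`, `nominations`.
#' @export
committee_shortlist <- function(ballots, n_members, k = 10) {
  stopifnot(n_members >= 1)
  empty <- data.frame(tech_id = character(0), nominations = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(ballots) || nrow(ballots) == 0L)
    return(list(majority = empty, question_marked = empty))
  ballots <- unique(ballots[, c("member_id", "tech_id")])
  per_member <- table(ballots$member_id)
  if (any(per_member > k))
    stop(sprintf("member '%s' nominated more than k = %d technologies",
                 names(per_member)[which.max(per_member)], k))
  counts <- table(ballots$tech_id)
  df <- data.frame(tech_id = names(counts),
                   nominations = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$nominations, df$tech_id), , drop = FALSE]
  rownames(df) <- NULL
  maj <- df[df$nominations > n_members / 2, , drop = FALSE]
  qm <- df[df$nominations <= n_members / 2, , drop = FALSE]
  rownames(maj) <- rownames(qm) <- NULL
  list(majority = maj, question_marked = qm)
}
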