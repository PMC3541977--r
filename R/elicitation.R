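#' @name elicitation
#' @title Pairwise-ranking elicitation of point values
#'
#' @description
#' Point values are elicited by asking decision-makers to rank pairs of
#' hypothetical technologies defined on two dimensions at a time, chosen so
#' that each pair is a genuine trade-off: one side is better on one
#' dimension and worse on the other (all remaining dimensions implicitly
#' held equal).  Answering "left", "right" or "equal" pins down the
#' relative worth of two within-dimension level upgrades.  Transitivity
#' plus dominance (a larger upgrade on the same dimension is worth at
#' least as much as one it contains) let each answer implicitly resolve
#' further questions, so far fewer questions are asked than exist in the
#' pool.  Once every pool question is resolved, a complete points schedule
#' consistent with all the judgments is derived by linear programming.
#'
#' Internally each question compares two "gain" intervals
#' (dimension, lower level, upper level); the session keeps the weak and
#' strict transitive closures of the judged relation over all intervals
#' as boolean reachability matrices, updated incrementally.
NULL

## ---- pool construction -----------------------------------------------------

## all (lo, hi) level-index intervals of every dimension, in canonical order
build_nodes <- function(labels_per_dim) {
  rows <- list()
  for (d in seq_along(labels_per_dim)) {
    m <- length(labels_per_dim[[d]])
    for (lo in seq_len(m - 1L))
      for (hi in seq((lo + 1L), m))
        rows[[length(rows) + 1L]] <- c(d, lo, hi)
  }
  nodes <- do.call(rbind, rows)
  colnames(nodes) <- c("dim", "lo", "hi")
  as.data.frame(nodes)
}

#' Start a pairwise-ranking session
#'
#' Builds the full question pool for the structure (dimensions and level
#' labels; any point values in `ps` are ignored) and initializes the
#' preference closure with the dominance relations.
#'
#' @param ps A [points_system()] (or structure-only equivalent) with at
#'   least two dimensions.
#' @return An object of class `ranking_state`.
#' @seealso [next_question()], [record_judgment()], [derive_point_values()]
#' @export
ranking_state <- function(ps) {
  if (length(ps$dimensions) < 2L)
    stop("elicitation needs at least 2 dimensions")
  labels <- lapply(ps$dimensions, function(d) d$labels)
  nodes <- build_nodes(labels)
  n <- nrow(nodes)
  node_key <- paste(nodes$dim, nodes$lo, nodes$hi)

  # weak closure seeded with reflexivity and same-dimension containment:
  # interval u contains v  =>  gain(u) >= gain(v)
  W <- matrix(FALSE, n, n)
  for (d in unique(nodes$dim)) {
    idx <- which(nodes$dim == d)
    for (u in idx) for (v in idx)
      W[u, v] <- nodes$lo[u] <= nodes$lo[v] && nodes$hi[u] >= nodes$hi[v]
  }
  diag(W) <- TRUE
  S <- matrix(FALSE, n, n)

  # pool: one question per unordered pair of intervals on distinct dimensions
  nd <- length(labels)
  a_list <- list()
  for (i in seq_len(nd - 1L)) for (j in seq((i + 1L), nd)) {
    ia <- which(nodes$dim == i)
    ib <- which(nodes$dim == j)
    g <- expand.grid(b = ib, a = ia)   # a varies slowest
    a_list[[length(a_list) + 1L]] <- g[, c("a", "b")]
  }
  pool <- do.call(rbind, a_list)
  rownames(pool) <- NULL

  st <- list(
    structure = lapply(ps$dimensions, function(d)
      list(name = d$name, key = d$key, labels = d$labels)),
    nodes = nodes, node_key = node_key,
    W = W, S = S, pool = pool,
    resolved = logical(nrow(pool)),
    judgments = list(), asked = 0L
  )
  class(st) <- "ranking_state"
  st$resolved <- pool_resolution(st)
  st
}

pool_resolution <- function(st) {
  n <- nrow(st$nodes)
  iab <- st$pool$a + (st$pool$b - 1L) * n
  iba <- st$pool$b + (st$pool$a - 1L) * n
  st$S[iab] | st$S[iba] | (st$W[iab] & st$W[iba])
}

#' Enumerate the full trade-off question pool
#'
#' Every unordered pair of level upgrades on two distinct dimensions gives
#' one question; the pool size is the sum over dimension pairs (i, j) of
#' `choose(m_i, 2) * choose(m_j, 2)` where `m` is the level count.
#'
#' @inheritParams ranking_state
#' @return A data frame of questions, one per row, in canonical order,
#'   with columns `dim_a`, `dim_b` (dimension keys), `left_a`, `left_b`
#'   (the left profile's levels on the two dimensions) and `right_a`,
#'   `right_b`; the left profile is always the one that is better on
#'   `dim_a` and worse on `dim_b`.
#' @export
enumerate_tradeoff_pairs <- function(ps) {
  st <- if (inherits(ps, "ranking_state")) ps else ranking_state(ps)
  do.call(rbind, lapply(seq_len(nrow(st$pool)), function(q) question_from_pool(st, q)))
}

question_from_pool <- function(st, q) {
  a <- st$pool$a[q]; b <- st$pool$b[q]
  da <- st$nodes$dim[a]; db <- st$nodes$dim[b]
  la <- st$structure[[da]]$labels; lb <- st$structure[[db]]$labels
  data.frame(
    dim_a = st$structure[[da]]$key, dim_b = st$structure[[db]]$key,
    left_a = la[st$nodes$hi[a]], left_b = lb[st$nodes$lo[b]],
    right_a = la[st$nodes$lo[a]], right_b = lb[st$nodes$hi[b]],
    stringsAsFactors = FALSE
  )
}

## map a question (possibly hand-built) to its two advantage intervals:
## node a = the left profile's advantage, node b = the right profile's;
## verdict "left" means gain(a) > gain(b)
question_nodes <- function(st, question) {
  keys <- vapply(st$structure, function(d) d$key, character(1))
  nms <- vapply(st$structure, function(d) d$name, character(1))
  locate_dim <- function(ref) {
    i <- match(ref, keys)
    if (is.na(i)) i <- match(normalize_label(ref), normalize_label(nms))
    if (is.na(i)) stop(sprintf("unknown dimension '%s' in question", ref))
    i
  }
  i <- locate_dim(question$dim_a)
  j <- locate_dim(question$dim_b)
  if (i == j) stop("a trade-off question needs two distinct dimensions")
  lev <- function(d, label) {
    k <- match(normalize_label(label), normalize_label(st$structure[[d]]$labels))
    if (is.na(k))
      stop(sprintf("unknown level '%s' in dimension '%s'", label, st$structure[[d]]$name))
    k
  }
  la <- lev(i, question$left_a); ra <- lev(i, question$right_a)
  lb <- lev(j, question$left_b); rb <- lev(j, question$right_b)
  node <- function(d, lo, hi) {
    k <- match(paste(d, lo, hi), st$node_key)
    stopifnot(!is.na(k))
    k
  }
  if (la > ra && lb < rb) {
    list(a = node(i, ra, la), b = node(j, lb, rb))
  } else if (la < ra && lb > rb) {
    list(a = node(j, rb, lb), b = node(i, la, ra))
  } else {
    stop("not a genuine trade-off: one side must be strictly better on one dimension and strictly worse on the other")
  }
}

## incremental closure update after adding edge a -> b (weak or strict):
## every i reaching a now reaches every j reachable from b
add_edge <- function(W, S, a, b, strict) {
  M <- outer(W[, a], W[b, ])
  if (strict) {
    S <- S | M
  } else {
    S <- S | (outer(S[, a], W[b, ]) | outer(W[, a], S[b, ]))
  }
  list(W = W | M, S = S)
}

#' Record a judgment in an elicitation session
#'
#' Adds the verdict's preference relation, recomputes the transitive
#' closure (propagating through dominance and earlier judgments), and
#' verifies consistency.  A verdict that would create a strict preference
#' cycle raises an error of class `vfm_inconsistency`.
#'
#' @param st A [ranking_state()].
#' @param question A one-row question data frame (from [next_question()],
#'   [enumerate_tradeoff_pairs()], or built by hand with the same columns).
#' @param verdict `"left"`, `"right"` or `"equal"`.
#' @return The updated `ranking_state`.
#' @export
record_judgment <- function(st, question, verdict = c("left", "right", "equal")) {
  verdict <- match.arg(verdict)
  nd <- question_nodes(st, question)
  q <- which(st$pool$a == nd$a & st$pool$b == nd$b |
             st$pool$a == nd$b & st$pool$b == nd$a)
  if (length(q) == 1L && st$resolved[q]) {
    # the closure already answers this question: re-stating the implied
    # verdict is redundant (error), contradicting it is an inconsistency
    implied <- if (st$S[nd$a, nd$b]) "left" else if (st$S[nd$b, nd$a]) "right" else "equal"
    if (verdict == implied)
      stop("question is already resolved (answered or implied); ask next_question() for an open one")
    stop(structure(
      class = c("vfm_inconsistency", "error", "condition"),
      list(message = sprintf(paste0(
        "inconsistent judgment: verdict '%s' contradicts the verdict '%s' ",
        "already answered or implied by transitivity/dominance over %d judgment(s)"),
        verdict, implied, length(st$judgments)),
        call = sys.call(-1))))
  }
  n <- nrow(st$nodes)
  if (verdict == "equal") {
    up <- add_edge(st$W, st$S, nd$a, nd$b, strict = FALSE)
    up <- add_edge(up$W, up$S, nd$b, nd$a, strict = FALSE)
  } else {
    hi <- if (verdict == "left") nd$a else nd$b
    lo <- if (verdict == "left") nd$b else nd$a
    up <- add_edge(st$W, st$S, hi, lo, strict = TRUE)
  }
  if (any(diag(up$S))) {
    stop(structure(
      class = c("vfm_inconsistency", "error", "condition"),
      list(message = paste0(
        "inconsistent judgment: the verdict '", verdict, "' on this question ",
        "contradicts a preference already answered or implied by transitivity/",
        "dominance (it would create a strict preference cycle); ",
        sprintf("%d judgment(s) recorded so far", length(st$judgments))),
        call = sys.call(-1))))
  }
  st$W <- up$W; st$S <- up$S
  st$resolved <- pool_resolution(st)
  st$judgments[[length(st$judgments) + 1L]] <-
    c(as.list(question), list(verdict = verdict))
  st$asked <- st$asked + 1L
  st
}

#' Next question to ask
#'
#' Returns a pool question whose verdict is not yet answered or implied,
#' or `NULL` when the whole pool is resolved.  The default `"greedy"`
#' ordering picks the open question whose answer is guaranteed to imply
#' the most other open questions (the minimum of the counts implied by
#' its two strict verdicts), which empirically keeps the number of
#' questions asked well below the pool size; `"canonical"` takes pool
#' order and `"random"` samples uniformly (seed via [set.seed()]).
#'
#' @param st A [ranking_state()].
#' @param method `"greedy"`, `"canonical"` or `"random"`.
#' @return A one-row question data frame, or `NULL` when done.
#' @export
next_question <- function(st, method = c("greedy", "canonical", "random")) {
  method <- match.arg(method)
  open <- which(!st$resolved)
  if (length(open) == 0L) return(NULL)
  q <- switch(method,
    canonical = open[1L],
    random = open[sample.int(length(open), 1L)],
    greedy = {
      n <- nrow(st$nodes)
      xs <- st$pool$a[open]; ys <- st$pool$b[open]
      W <- st$W
      score <- vapply(open, function(qq) {
        a <- st$pool$a[qq]; b <- st$pool$b[qq]
        # verdict a > b: open pair (x, y) resolves if x ->w a and b ->w y
        # (strictly, through the new edge), in either orientation
        n_ab <- sum((W[xs + (a - 1L) * n] & W[b + (ys - 1L) * n]) |
                    (W[ys + (a - 1L) * n] & W[b + (xs - 1L) * n]))
        n_ba <- sum((W[xs + (b - 1L) * n] & W[a + (ys - 1L) * n]) |
                    (W[ys + (b - 1L) * n] & W[a + (xs - 1L) * n]))
        min(n_ab, n_ba)
      }, numeric(1))
      open[which.max(score)]
    })
  question_from_pool(st, q)
}

#' Is the elicitation session complete?
#'
#' @param st A [ranking_state()].
#' @return `TRUE` when every pool question is answered or implied.
#' @export
session_complete <- function(st) all(st$resolved)

## ---- derivation ------------------------------------------------------------

## LP coefficient row for gain(interval) over the free variables
## (one variable per non-bottom level; bottom level pinned to 0)
gain_row <- function(st, node, var_of) {
  row <- numeric(max(var_of, na.rm = TRUE))
  d <- st$nodes$dim[node]
  hi <- st$nodes$hi[node]; lo <- st$nodes$lo[node]
  if (hi > 1L) row[var_of[d, hi]] <- row[var_of[d, hi]] + 1
  if (lo > 1L) row[var_of[d, lo]] <- row[var_of[d, lo]] - 1
  row
}

#' Derive point values from a completed session
#'
#' Solves a linear program over the non-bottom level values: every
#' strictly judged (or implied) preference must hold with a common
#' positive slack in the two-dimension score sums, every "equal" verdict
#' holds with equality, values are non-decreasing within each dimension
#' with the bottom level at 0, and the top-level values sum to 1.  Among
#' feasible schedules the minimum slack is maximized, yielding a schedule
#' that reproduces the ranking of every pool pair.  Constraints already
#' implied by transitivity are dropped (the strict relation is reduced to
#' its covering edges over the equivalence classes of tied gains), which
#' keeps the program small without changing its feasible set.
#'
#' @param st A consistent, fully resolved [ranking_state()].
#' @param name,metadata Passed to the returned [points_system()].
#' @return A `points_system` with the derived values.
#' @export
derive_point_values <- function(st, name = "Derived points system",
                                metadata = "Point values derived from pairwise-ranking judgments") {
  if (!session_complete(st))
    stop("session incomplete: unresolved questions remain (use next_question())")
  nd <- length(st$structure)
  m <- vapply(st$structure, function(d) length(d$labels), integer(1))
  var_of <- matrix(NA_integer_, nd, max(m))
  k <- 0L
  for (d in seq_len(nd)) for (l in seq(2L, m[d])) {
    k <- k + 1L
    var_of[d, l] <- k
  }
  K <- k                                  # free (non-bottom) level values

  # equivalence classes of intervals with tied gains, and the strict
  # partial order between classes
  n <- nrow(st$nodes)
  eq <- st$W & t(st$W)
  class_of <- integer(n)
  reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- which(eq[i, seq_len(i)])[1L]
    if (hit == i) {
      reps <- c(reps, i)
      class_of[i] <- length(reps)
    } else {
      class_of[i] <- class_of[hit]
    }
  }
  nc <- length(reps)
  CS <- st$S[reps, reps, drop = FALSE]
  # covering edges: strict relations not implied by a two-step strict chain
  red <- CS & !((CS %*% CS) > 0)

  # variables: the K free level values plus the common slack s (index K+1);
  # maximize s subject to every strict covering relation separating by at
  # least s, tied gains exactly equal, within-dimension monotonicity, and
  # top-level values summing to 1
  rows <- list(); rhs <- numeric(0)       # rows as A x <= rhs
  le <- function(r, hi) { rows[[length(rows) + 1L]] <<- r; rhs <<- c(rhs, hi) }
  ge <- function(r, lo) le(-r, -lo)
  eq <- function(r, v) { le(r, v); ge(r, v) }
  pad <- function(r, s = 0) c(r, s)
  any_strict <- FALSE
  for (i in seq_len(nc)) for (j in seq_len(nc)) if (red[i, j]) {
    any_strict <- TRUE
    ge(pad(gain_row(st, reps[i], var_of) - gain_row(st, reps[j], var_of), s = -1), 0)
  }
  # tied gains: chain of equalities through each multi-member class
  for (cl in seq_len(nc)) {
    members <- which(class_of == cl)
    if (length(members) > 1L)
      for (t in seq(2L, length(members)))
        eq(pad(gain_row(st, members[t - 1L], var_of) - gain_row(st, members[t], var_of)), 0)
  }
  # within-dimension monotonicity (v_{l} >= v_{l-1}; l = 2 is implied by x >= 0)
  for (d in seq_len(nd)) if (m[d] > 2L) for (l in seq(3L, m[d])) {
    r <- numeric(K)
    r[var_of[d, l]] <- 1
    r[var_of[d, l - 1L]] <- -1
    ge(pad(r), 0)
  }
  top <- numeric(K)
  for (d in seq_len(nd)) top[var_of[d, m[d]]] <- 1
  eq(pad(top), 1)                         # normalization: tops sum to 1
  le(pad(numeric(K), 1), 1)               # s <= 1 keeps the program bounded

  A <- do.call(rbind, rows)
  sol <- lp_min_leq(c(numeric(K), -1), A, rhs)   # maximize s
  if (sol$status != "optimal")
    stop("internal consistency error: the judgment constraints admit no point schedule")
  if (any_strict && sol$x[K + 1L] <= 1e-12)
    stop("internal consistency error: no schedule separates the strict judgments")
  x <- sol$x

  dims <- lapply(seq_len(nd), function(d) {
    vals <- c(0, x[var_of[d, seq(2L, m[d])]])
    vals <- pmax(0, cummax(vals))         # guard tiny negative/rounding drift
    list(name = st$structure[[d]]$name, key = st$structure[[d]]$key,
         labels = st$structure[[d]]$labels, points = vals)
  })
  points_system(dims, name = name, metadata = metadata)
}

## ---- oracle and session runner --------------------------------------------

#' Simulated answerer backed by a hidden points system
#'
#' Returns a function that answers any trade-off question by comparing the
#' two profiles' two-dimension score sums under `hidden`; exact ties give
#' `"equal"`.  Used for parameter-recovery testing: answers are transitive
#' by construction, so a session driven by this oracle never raises an
#' inconsistency.
#'
#' @param hidden A [points_system()] providing the ground-truth values.
#' @return `function(question) -> "left" | "right" | "equal"`.
#' @export
simulate_answers <- function(hidden) {
  force(hidden)
  function(question) {
    da <- find_dimension(hidden, question$dim_a)
    db <- find_dimension(hidden, question$dim_b)
    if (is.null(da) || is.null(db)) stop("question references a dimension unknown to the hidden system")
    v <- function(d, label) {
      i <- match_level(d, label)
      if (is.na(i)) stop(sprintf("unknown level '%s' in hidden dimension '%s'", label, d$name))
      d$points[i]
    }
    left <- v(da, question$left_a) + v(db, question$left_b)
    right <- v(da, question$right_a) + v(db, question$right_b)
    if (abs(left - right) <= 1e-9) "equal" else if (left > right) "left" else "right"
  }
}

#' Run a full elicitation session against an answerer
#'
#' Repeatedly asks [next_question()] and records the answerer's verdicts
#' until the pool is resolved.
#'
#' @param ps Structure for the session (see [ranking_state()]).
#' @param answerer `function(question) -> verdict`, e.g. from
#'   [simulate_answers()].
#' @param method Question ordering, see [next_question()].
#' @return The completed `ranking_state` (see `$asked` for the number of
#'   questions actually posed).
#' @export
run_elicitation <- function(ps, answerer, method = "greedy") {
  st <- if (inherits(ps, "ranking_state")) ps else ranking_state(ps)
  repeat {
    q <- next_question(st, method = method)
    if (is.null(q)) break
    st <- record_judgment(st, q, answerer(q))
  }
  st
}

#' @export
print.ranking_state <- function(x, ...) {
  cat(sprintf("Pairwise-ranking session: %d dimensions, pool of %d questions\n",
              length(x$structure), nrow(x$pool)))
  cat(sprintf("  answered: %d; resolved (incl. implied): %d; open: %d\n",
              x$asked, sum(x$resolved), sum(!x$resolved)))
  invisible(x)
}

## ---- persistence -----------------------------------------------------------

#' Save / load an elicitation session
#'
#' The session is stored as JSON holding the structure (dimension names,
#' keys and level labels) and the ordered list of judgments; loading
#' replays the judgments, reproducing the closure exactly.
#'
#' @param st A [ranking_state()].
#' @param path JSON file path.
#' @return `save_session()`: `path`, invisibly. `load_session()`: the
#'   rebuilt `ranking_state`.
#' @export
save_session <- function(st, path) {
  out <- list(
    structure = lapply(unname(st$structure), function(d)
      list(name = d$name, key = d$key, labels = d$labels)),
    judgments = lapply(st$judgments, function(j) j)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dims <- lapply(raw$structure, function(d)
    ps_dimension(d$name, stats::setNames(rep(0, length(d$labels)),
                                         unlist(d$labels)), key = d$key))
  st <- ranking_state(points_system(dims))
  for (j in raw$judgments) {
    q <- data.frame(dim_a = j$dim_a, dim_b = j$dim_b,
                    left_a = j$left_a, left_b = j$left_b,
                    right_a = j$right_a, right_b = j$right_b,
                    stringsAsFactors = FALSE)
    st <- record_judgment(st, q, j$verdict)
  }
  st
}
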