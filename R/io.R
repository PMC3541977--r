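#' Load a technology table from CSV
#'
#' Reads a portfolio CSV with header
#' `id,name,indication,n_patients,<one column per dimension key>,total_cost,evidence,x_factors`
#' and validates every row against the points system: level labels are
#' matched case-insensitively after whitespace normalization and replaced
#' by the system's canonical spelling; costs must parse as non-negative
#' numbers; evidence must be one of poor/medium/high.  All row-level
#' problems are collected and reported together.  An `x_factors` cell of
#' `"none"` (or empty) means no X-factors; multiple notes are separated by
#' semicolons.
#'
#' @param path CSV file path (UTF-8, comma-separated).
#' @param ps The governing [points_system()].
#' @return A data frame of class `vfm_portfolio`; one row per technology.
#' @export
load_portfolio <- function(path, ps) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  keys <- dim_keys(ps)
  required <- c("id", "total_cost", "evidence", "x_factors", keys)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) {
    warning(sprintf("%s: no technology rows (header only); returning an empty portfolio", path))
    df$total_cost <- numeric(0)
    df$n_patients <- integer(0)
    class(df) <- c("vfm_portfolio", "data.frame")
    return(df)
  }

  problems <- character(0)
  note <- function(row, msg)
    problems <<- c(problems, sprintf("row %d (%s): %s", row, df$id[row], msg))

  if (anyDuplicated(df$id))
    problems <- c(problems, sprintf("duplicate technology id '%s'",
                                    df$id[duplicated(df$id)][1L]))
  for (k in keys) {
    d <- ps$dimensions[[k]]
    idx <- match_level_vec(d, df[[k]])
    bad <- which(is.na(idx))
    for (r in bad)
      note(r, sprintf("unknown level '%s' in dimension '%s'", df[[k]][r], d$name))
    ok <- which(!is.na(idx))
    df[[k]][ok] <- d$labels[idx[ok]]      # canonical spelling
  }
  cost <- suppressWarnings(as.numeric(df$total_cost))
  for (r in which(is.na(cost) | cost < 0))
    note(r, sprintf("total_cost '%s' is not a non-negative number", df$total_cost[r]))
  ev_ok <- normalize_label(df$evidence) %in% c("poor", "medium", "high")
  for (r in which(!ev_ok))
    note(r, sprintf("evidence grade '%s' is not one of poor/medium/high", df$evidence[r]))

  if (length(problems) > 0L)
    stop(sprintf("%s: %d problem(s):\n%s", path, length(problems),
                 paste("  -", problems, collapse = "\n")))

  df$total_cost <- cost
  df$evidence <- normalize_label(df$evidence)
  if ("n_patients" %in% names(df))
    df$n_patients <- suppressWarnings(as.integer(df$n_patients))
  df$x_factors <- ifelse(normalize_label(df$x_factors) %in% c("none", ""),
                         "", df$x_factors)
  class(df) <- c("vfm_portfolio", "data.frame")
  df
}

match_level_vec <- function(dimension, labels) {
  match(normalize_label(labels), normalize_label(dimension$labels))
}

#' X-factor notes of a technology as a list
#'
#' @param portfolio A `vfm_portfolio`.
#' @param id Technology id.
#' @return Character vector of notes; empty when there are none.
#' @export
x_factor_notes <- function(portfolio, id) {
  i <- match(id, portfolio$id)
  if (is.na(i)) stop(sprintf("unknown technology id '%s'", id))
  raw <- trimws(portfolio$x_factors[i])
  if (!nzchar(raw)) character(0) else trimws(strsplit(raw, ";")[[1L]])
}

#' Write a technology table to CSV
#'
#' Inverse of [load_portfolio()] modulo label canonicalization: empty
#' X-factors are written as `"none"`.
#'
#' @param portfolio A `vfm_portfolio`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_portfolio <- function(portfolio, path) {
  out <- as.data.frame(portfolio)
  out$x_factors <- ifelse(nzchar(trimws(out$x_factors)), out$x_factors, "none")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The bundled illustrative 18-technology portfolio
#'
#' Eighteen technologies (mostly pharmaceuticals) with ratings on the
#' bundled points system, annual total costs in millions of shekels,
#' quality-of-evidence grades and X-factor notes.  The data are realistic
#' but illustrative; they are the worked example used throughout the
#' package documentation.
#'
#' @return A `vfm_portfolio` data frame with 18 rows.
#' @export
table2_technologies <- function() {
  load_portfolio(system.file("extdata", "table2_technologies.csv",
                             package = "vfmchart", mustWork = TRUE),
                 table1_points_system())
}

#' Generate a random points system
#'
#' Structure and values for testing and simulation: per-dimension level
#' counts as given, strictly increasing point values built from uniform
#' increments, bottom levels at 0, top-level values summing to 1.
#'
#' @param n_levels Integer vector of level counts, one per dimension
#'   (default mirrors the bundled system's 5/4/4/3/2 structure).
#' @return A [points_system()].
#' @export
random_points_system <- function(n_levels = c(5L, 4L, 4L, 3L, 2L)) {
  stopifnot(all(n_levels >= 2L))
  tops <- stats::runif(length(n_levels), 0.2, 1)
  tops <- tops / sum(tops)
  dims <- lapply(seq_along(n_levels), function(d) {
    m <- n_levels[d]
    inc <- stats::runif(m - 1L, 0.2, 1)
    vals <- c(0, cumsum(inc) / sum(inc) * tops[d])
    labs <- c("level 1 (worst)", paste("level", seq(2L, m)))
    if (m > 2L) labs[m] <- paste("level", m, "(best)")
    ps_dimension(sprintf("Criterion %s", LETTERS[d]), stats::setNames(vals, labs),
                 key = paste0("crit_", tolower(LETTERS[d])))
  })
  points_system(dims, name = "Random points system",
                metadata = "synthetic system for simulation/testing")
}

#' Generate a synthetic technology portfolio
#'
#' Random portfolios for property testing and demos.  Costs are drawn
#' log-normally (default location/scale chosen so annual costs typically
#' span roughly 2-120 million, the order of magnitude of the bundled
#' portfolio); ratings are drawn per dimension with probability weights
#' decreasing in level rank (most technologies offer modest benefits);
#' evidence grades favor `high` as in the bundled portfolio; X-factor
#' notes occur with probability `x_prob`.
#'
#' @param n Number of technologies (>= 1).
#' @param ps Governing [points_system()]; `NULL` generates a random one
#'   (see [random_points_system()]).
#' @param seed Optional integer seed for reproducibility.
#' @param cost_meanlog,cost_sdlog Log-normal cost parameters (millions).
#' @param rating_weights Optional list (one numeric vector per dimension,
#'   summing to 1) of level probabilities; default `1/rank`, normalized.
#' @param evidence_probs Probabilities for poor/medium/high.
#' @param x_prob Probability a technology carries an X-factor note.
#' @return A list with elements `ps` and `portfolio`.
#' @export
generate_synthetic <- function(n, ps = NULL, seed = NULL,
                               cost_meanlog = log(15), cost_sdlog = 1,
                               rating_weights = NULL,
                               evidence_probs = c(poor = 0.1, medium = 0.25, high = 0.65),
                               x_prob = 0.25) {
  stopifnot(n >= 1L, x_prob >= 0, x_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ps)) ps <- random_points_system()
  keys <- dim_keys(ps)
  if (is.null(rating_weights)) {
    rating_weights <- lapply(ps$dimensions, function(d) {
      w <- 1 / seq_along(d$labels)
      w / sum(w)
    })
  }
  if (length(rating_weights) != length(keys))
    stop("rating_weights must have one entry per dimension")
  for (w in rating_weights)
    if (abs(sum(w) - 1) > 1e-6 || any(w < 0))
      stop("each rating_weights entry must be a probability vector summing to 1")
  if (abs(sum(evidence_probs) - 1) > 1e-6 || any(evidence_probs < 0))
    stop("evidence_probs must sum to 1")

  df <- data.frame(id = sprintf("s%d", seq_len(n)),
                   name = sprintf("Synthetic technology %d", seq_len(n)),
                   indication = "synthetic", n_patients = stats::rpois(n, 500),
                   stringsAsFactors = FALSE)
  for (d in seq_along(keys)) {
    dim <- ps$dimensions[[d]]
    lv <- sample(seq_along(dim$labels), n, replace = TRUE,
                 prob = rating_weights[[d]])
    df[[keys[d]]] <- dim$labels[lv]
  }
  df$total_cost <- round(stats::rlnorm(n, cost_meanlog, cost_sdlog), 2)
  df$total_cost <- pmax(df$total_cost, 0.01)
  df$evidence <- sample(c("poor", "medium", "high"), n, replace = TRUE,
                        prob = evidence_probs)
  df$x_factors <- ifelse(stats::runif(n) < x_prob, "synthetic consideration", "")
  class(df) <- c("vfm_portfolio", "data.frame")
  list(ps = ps, portfolio = df)
}
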