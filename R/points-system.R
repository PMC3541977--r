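#' Construct a points system
#'
#' A points system is an additive multi-criteria scoring schedule: each
#' benefit dimension has ordered achievement levels (worst to best), each
#' level carries a non-negative point value, and a technology's total
#' benefit score is the sum of the point values of its assigned levels.
#' Point values express both the relative importance of the dimensions and
#' the degree of achievement within them; by construction the bottom level
#' of every dimension is worth 0 points.
#'
#' @param dimensions A list of dimensions as returned by [ps_dimension()].
#' @param name Short name for the system.
#' @param metadata Free-form provenance text.
#' @return An object of class `points_system`.
#' @seealso [ps_dimension()], [validate_points_system()], [total_score()]
#' @examples
#' ps <- points_system(list(
#'   ps_dimension("Survival", c("none" = 0, "some" = 0.6)),
#'   ps_dimension("Comfort",  c("none" = 0, "some" = 0.4))
#' ))
#' max_score(ps)
#' @export
points_system <- function(dimensions, name = "", metadata = "") {
  stopifnot(is.list(dimensions))
  keys <- vapply(dimensions, function(d) d$key, character(1))
  names(dimensions) <- keys
  structure(
    list(name = name, metadata = metadata, dimensions = dimensions),
    class = "points_system"
  )
}

#' Construct a single benefit dimension
#'
#' @param name Dimension name (free text, unique within a system).
#' @param levels Either a named numeric vector (names = level labels,
#'   values = points, ordered worst to best) or a data frame with columns
#'   `label` and `points`.
#' @param key Short machine key used as the portfolio CSV column name;
#'   defaults to a slug of `name`.
#' @return A list with elements `name`, `key`, `labels`, `points`.
#' @export
ps_dimension <- function(name, levels, key = NULL) {
  if (is.data.frame(levels)) {
    labels <- as.character(levels$label)
    points <- as.numeric(levels$points)
  } else {
    labels <- names(levels)
    points <- as.numeric(levels)
  }
  if (is.null(key)) key <- make_key(name)
  list(name = name, key = key, labels = labels, points = points)
}

make_key <- function(name) {
  key <- tolower(gsub("[^a-z0-9]+", "_", tolower(name)))
  key <- gsub("^_+|_+$", "", key)
  substr(key, 1, 40)
}

## normalized label matching: case-insensitive and whitespace-insensitive,
## so that hand-edited CSV cells survive minor retyping ("> 500" vs ">500")
normalize_label <- function(x) {
  tolower(gsub("\\s+", "", as.character(x)))
}

dim_keys <- function(ps) names(ps$dimensions)

n_levels <- function(ps) {
  vapply(ps$dimensions, function(d) length(d$labels), integer(1))
}

## resolve a dimension given either its key or full name; NULL if unknown
find_dimension <- function(ps, ref) {
  keys <- dim_keys(ps)
  i <- match(ref, keys)
  if (is.na(i)) {
    nms <- vapply(ps$dimensions, function(d) d$name, character(1))
    i <- match(normalize_label(ref), normalize_label(nms))
  }
  if (is.na(i)) NULL else ps$dimensions[[i]]
}

## index of a level label in a dimension, via normalized matching; NA if unknown
match_level <- function(dimension, label) {
  match(normalize_label(label), normalize_label(dimension$labels))
}

#' Validate a points system
#'
#' Checks the structural invariants of a points system and reports every
#' violation rather than stopping at the first: at least two dimensions
#' with unique names; at least two levels per dimension with unique,
#' non-empty labels; non-negative point values, non-decreasing in level
#' order; and (by default) a bottom level worth exactly 0 points.
#'
#' @param ps A [points_system()].
#' @param require_zero_bottom Enforce that each dimension's worst level has
#'   value 0.  Set to `FALSE` for foreign points systems that use a
#'   non-zero floor.
#' @return A data frame with columns `dimension`, `level`, `rule`,
#'   `message`; zero rows when the system is valid.
#' @export
validate_points_system <- function(ps, require_zero_bottom = TRUE) {
  bad <- list()
  note <- function(dimension, level, rule, message) {
    bad[[length(bad) + 1L]] <<-
      data.frame(dimension = dimension, level = level, rule = rule,
                 message = message, stringsAsFactors = FALSE)
  }
  dims <- ps$dimensions
  if (length(dims) < 2L)
    note(NA, NA, "n_dimensions", "a points system needs at least 2 dimensions")
  nms <- vapply(dims, function(d) d$name, character(1))
  if (anyDuplicated(nms))
    note(nms[duplicated(nms)][1L], NA, "unique_names", "dimension names must be unique")
  if (anyDuplicated(names(dims)))
    note(names(dims)[duplicated(names(dims))][1L], NA, "unique_keys",
         "dimension keys must be unique")
  for (d in dims) {
    m <- length(d$labels)
    if (m < 2L)
      note(d$name, NA, "n_levels", "a dimension needs at least 2 levels")
    if (any(!nzchar(trimws(d$labels))))
      note(d$name, which(!nzchar(trimws(d$labels)))[1L], "label_nonempty",
           "level labels must be non-empty")
    if (anyDuplicated(normalize_label(d$labels)))
      note(d$name, d$labels[duplicated(normalize_label(d$labels))][1L],
           "label_unique", "level labels must be unique within a dimension")
    if (any(!is.finite(d$points)) || any(d$points < 0))
      note(d$name, NA, "nonnegative", "point values must be finite and >= 0")
    if (m >= 2L && any(diff(d$points) < 0)) {
      i <- which(diff(d$points) < 0)[1L]
      note(d$name, d$labels[i + 1L], "monotone",
           sprintf("point values must be non-decreasing (%.4g after %.4g)",
                   d$points[i + 1L], d$points[i]))
    }
    if (require_zero_bottom && m >= 1L && d$points[1L] != 0)
      note(d$name, d$labels[1L], "bottom_zero",
           sprintf("bottom level must be worth 0 points (found %.4g)", d$points[1L]))
  }
  if (length(bad) == 0L)
    data.frame(dimension = character(), level = character(),
               rule = character(), message = character(),
               stringsAsFactors = FALSE)
  else
    do.call(rbind, bad)
}

#' Total benefit score of a rated technology
#'
#' Looks up each assigned level's point value and sums them.  Labels are
#' matched case-insensitively after whitespace normalization; dimensions
#' can be referenced by key or by full name.
#'
#' @param rating Named character vector or list: one level label per
#'   dimension of `ps`, named by dimension key (or name).
#' @param ps The governing [points_system()].
#' @return The total score (a single number).
#' @examples
#' ps <- table1_points_system()
#' total_score(
#'   c(lives_saved = "Very many: > 500 lives saved",
#'     life_prolongation = "Large benefits",
#'     qol_gains = "Large QoL gains",
#'     if_not_funded = "Many/most patients will be able to pay for it themselves (privately)",
#'     social_benefits = "Yes"), ps)
#' @export
total_score <- function(rating, ps) {
  rating <- unlist(rating)
  keys <- dim_keys(ps)
  missing <- setdiff(keys, names(rating))
  if (length(missing) > 0L) {
    nm <- vapply(missing, function(k) is.null(find_dimension(ps, k)), logical(1))
    # allow ratings named by full dimension name instead of key
    resolved <- vapply(names(rating), function(r) {
      d <- find_dimension(ps, r)
      if (is.null(d)) NA_character_ else d$key
    }, character(1))
    if (anyNA(resolved))
      stop_rating(sprintf("unknown dimension in rating: '%s'",
                          names(rating)[is.na(resolved)][1L]))
    names(rating) <- resolved
    missing <- setdiff(keys, names(rating))
    if (length(missing) > 0L)
      stop_rating(sprintf("rating lacks an assignment for dimension '%s'", missing[1L]))
  }
  extra <- setdiff(names(rating), keys)
  if (length(extra) > 0L)
    stop_rating(sprintf("unknown dimension in rating: '%s'", extra[1L]))
  total <- 0
  for (k in keys) {
    d <- ps$dimensions[[k]]
    i <- match_level(d, rating[[k]])
    if (is.na(i))
      stop_rating(sprintf("unknown level '%s' in dimension '%s'", rating[[k]], d$name))
    total <- total + d$points[i]
  }
  total
}

stop_rating <- function(msg) {
  stop(structure(class = c("vfm_rating_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Maximum attainable benefit score
#'
#' Sum over dimensions of the largest point value; the upper bound of
#' [total_score()] over all valid ratings.
#'
#' @inheritParams validate_points_system
#' @return A single number.
#' @export
max_score <- function(ps) {
  sum(vapply(ps$dimensions, function(d) max(d$points), numeric(1)))
}

#' Insert interpolated mid levels
#'
#' Returns a new points system in which, between every adjacent pair of
#' levels, a "mid" level is inserted whose point value is the arithmetic
#' mean of the flanking values.  Mid levels soften the sensitivity of
#' total scores to borderline rating judgments; the original levels (and
#' hence the scores of ratings expressed in them) are unchanged.
#'
#' @inheritParams validate_points_system
#' @return A new `points_system` with `2n - 1` levels per original
#'   `n`-level dimension.
#' @export
interpolate_mid_levels <- function(ps) {
  dims <- lapply(ps$dimensions, function(d) {
    m <- length(d$labels)
    labels <- character(2L * m - 1L)
    points <- numeric(2L * m - 1L)
    labels[seq(1L, 2L * m - 1L, by = 2L)] <- d$labels
    points[seq(1L, 2L * m - 1L, by = 2L)] <- d$points
    if (m > 1L) {
      mid <- seq_len(m - 1L)
      labels[2L * mid] <- sprintf("Mid: %s / %s", d$labels[mid], d$labels[mid + 1L])
      points[2L * mid] <- (d$points[mid] + d$points[mid + 1L]) / 2
    }
    list(name = d$name, key = d$key, labels = labels, points = points)
  })
  points_system(dims, name = ps$name,
                metadata = paste(ps$metadata, "(with interpolated mid levels)"))
}

#' Net present value of a cash-flow series
#'
#' Discounts a series of per-period net amounts (future spending net of
#' any cost savings) back to period 0 using end-of-period discounting:
#' `sum(amount / (1 + rate)^period)`.  With rate 0 this is the plain sum.
#'
#' @param flows Data frame with integer column `period` (>= 0, strictly
#'   increasing) and numeric column `amount` (millions of currency).
#' @param discount_rate Per-period discount rate, >= 0.
#' @return NPV in millions of currency.
#' @examples
#' npv_cost(data.frame(period = c(0, 1), amount = c(5, -2)), 0.05)
#' @export
npv_cost <- function(flows, discount_rate = 0) {
  if (!is.numeric(discount_rate) || length(discount_rate) != 1L ||
      !is.finite(discount_rate) || discount_rate < 0)
    stop("discount_rate must be a single finite number >= 0")
  period <- as.numeric(flows$period)
  amount <- as.numeric(flows$amount)
  if (length(period) == 0L) return(0)
  if (any(period < 0) || any(period != floor(period)))
    stop("periods must be non-negative integers")
  if (any(diff(period) <= 0))
    stop("periods must be strictly increasing")
  sum(amount / (1 + discount_rate)^period)
}

#' @export
print.points_system <- function(x, ...) {
  cat(sprintf("Points system: %s\n", if (nzchar(x$name)) x$name else "<unnamed>"))
  for (d in x$dimensions) {
    cat(sprintf("  %s [%s]\n", d$name, d$key))
    for (i in seq_along(d$labels))
      cat(sprintf("    %-70s %.4g\n", d$labels[i], d$points[i]))
  }
  cat(sprintf("  maximum total score: %.4g\n", max_score(x)))
  invisible(x)
}

#' Read a points system from YAML or JSON
#'
#' Expected schema: `{name, metadata?, dimensions: [{name, key?, levels:
#'   [{label, points}]}]}`.  Schema violations are reported with the path
#' of the offending element.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A [points_system()].
#' @export
read_points_system <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw) || is.null(raw$dimensions))
    stop(sprintf("%s: missing top-level 'dimensions' list", path))
  dims <- lapply(seq_along(raw$dimensions), function(i) {
    d <- raw$dimensions[[i]]
    where <- sprintf("%s: dimensions[%d]", path, i)
    if (is.null(d$name)) stop(sprintf("%s: missing 'name'", where))
    if (is.null(d$levels) || length(d$levels) == 0L)
      stop(sprintf("%s ('%s'): missing 'levels'", where, d$name))
    labels <- character(0); points <- numeric(0)
    for (j in seq_along(d$levels)) {
      lv <- d$levels[[j]]
      if (is.null(lv$label) || is.null(lv$points))
        stop(sprintf("%s, levels[%d]: each level needs 'label' and 'points'", where, j))
      if (!is.numeric(lv$points))
        stop(sprintf("%s, levels[%d] ('%s'): 'points' must be numeric", where, j, lv$label))
      labels <- c(labels, lv$label)
      points <- c(points, lv$points)
    }
    ps_dimension(d$name, stats::setNames(points, labels), key = d$key)
  })
  points_system(dims,
                name = if (is.null(raw$name)) "" else raw$name,
                metadata = if (is.null(raw$metadata)) "" else raw$metadata)
}

#' Write a points system to YAML or JSON
#'
#' @param ps A [points_system()].
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_points_system <- function(ps, path) {
  out <- list(
    name = ps$name, metadata = ps$metadata,
    dimensions = lapply(ps$dimensions, function(d) {
      list(name = d$name, key = d$key,
           levels = lapply(seq_along(d$labels), function(i)
             list(label = d$labels[i], points = d$points[i])))
    })
  )
  names(out$dimensions) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path, precision = 15L)  # keep exact ties exact
  }
  invisible(path)
}

#' The bundled illustrative points system
#'
#' Five benefit dimensions (lives saved; life prolongation; quality-of-life
#' gains; access if not funded; other social/ethical benefits) with
#' 5/4/4/3/2 levels.  Point values were elicited from a convenience sample
#' and are illustrative only; the top levels sum to 0.999.
#'
#' @return A [points_system()].
#' @export
table1_points_system <- function() {
  read_points_system(system.file("extdata", "table1_points.yaml",
                                 package = "vfmchart", mustWork = TRUE))
}
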