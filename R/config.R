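#' Package configuration
#'
#' A YAML configuration file can hold the display and workflow defaults:
#' the demo budget, quadrant-guide thresholds, the evidence-to-bubble
#' area mapping and the chart style options.  `vfm_config()` returns the
#' defaults, merged with any overrides read from `path`; unknown keys are
#' rejected so typos fail loudly.  The CLI accepts `--config file.yaml`
#' on the relevant subcommands.
#'
#' @param path Optional YAML file with a subset of the keys below.
#' @return A named list: `budget` (millions; default 300), `cost_threshold`
#'   and `benefit_threshold` (`NULL` = data midrange), `max_bubble_radius`,
#'   `x_factor_fill`, `neutral_fill`, `hatch_x_factors`, `evidence_areas`
#'   (relative areas for poor/medium/high).
#' @export
vfm_config <- function(path = NULL) {
  cfg <- list(
    budget = 300,
    cost_threshold = NULL,
    benefit_threshold = NULL,
    max_bubble_radius = 16,
    x_factor_fill = "#3b7dd8",
    neutral_fill = "#c8c8c8",
    hatch_x_factors = FALSE,
    evidence_areas = c(poor = 1, medium = 2, high = 3)
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0L)
      stop(sprintf("%s: unknown config key '%s'", path, unknown[1L]))
    for (k in names(user)) cfg[[k]] <- user[[k]]
    if (!is.null(cfg$evidence_areas)) {
      ev <- unlist(cfg$evidence_areas)
      if (!all(c("poor", "medium", "high") %in% names(ev)) || any(diff(ev[c("poor", "medium", "high")]) <= 0))
        stop(sprintf("%s: evidence_areas needs strictly increasing poor/medium/high", path))
      cfg$evidence_areas <- ev[c("poor", "medium", "high")]
    }
  }
  cfg
}

#' Display-round a monetary amount in millions
#'
#' Reporting convention for narrative text: sums and small differences
#' are shown to one decimal ("20.2", "21.6"), while differences of 50
#' million or more are shown to the nearest million with an
#' approximately-equal mark ("~ 98").  Raw values are never rounded
#' internally; this is a formatting layer only.
#'
#' @param x Amount(s) in millions.
#' @param difference Format as a cost difference (enables the >= 50
#'   nearest-million rule).
#' @return Character vector.
#' @examples
#' format_millions(20.17)           # "20.2"
#' format_millions(97.53, TRUE)     # "~ 98"
#' @export
format_millions <- function(x, difference = FALSE) {
  vapply(x, function(v) {
    if (difference && abs(v) >= 50) sprintf("~ %d", round(v))
    else sprintf("%.1f", round(v, 1))
  }, character(1))
}
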