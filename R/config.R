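# Configuration: one nested list with validated defaults, loadable from
# YAML or JSON. Unknown keys are rejected so typos fail loudly; a single
# `seed` field governs every stochastic component (the search itself is
# deterministic).

#' Default configuration
#'
#' @return Nested list: `sp` (step penalty, 0.8), `complexity` scorer name,
#'   `count_duplicates` (count repeated starting materials in the
#'   simplicity product), `seed`, `tagging` (strategies, template radius 2,
#'   tagger beam 50), `ttl` (T1 beam 3, T2 beam 3, `min_confidence` 0) and
#'   `search` (expansion width 20, minimum solved routes 10, maximum 10
#'   iterations, route cap 10000, 50 kept steps per molecule).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    sp = 0.8,
    complexity = "heuristic",
    count_duplicates = FALSE,
    tagging = list(
      strategies = c("systematic", "template", "model"),
      radius = 2L,
      beam = 50L),
    ttl = list(
      beam_t1 = 3L,
      beam_t2 = 3L,
      min_confidence = 0),
    search = list(
      expansion_width = 20L,
      min_solved = 10L,
      max_iterations = 10L,
      route_cap = 10000L,
      per_molecule_cap = 50L))
}

#' Load and validate a configuration file
#'
#' Reads YAML or JSON, overlays the values onto [default_config()], rejects
#' unknown keys, and validates ranges (`sp` in (0, 1], radius in 1..3,
#' beams and widths positive). An empty file yields the full default
#' configuration.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for pure
#'   defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- merge_config(cfg, user, path = "")
  }
  validate_config(cfg)
}

merge_config <- function(base, user, path = "") {
  if (!is.list(user))
    stop("configuration section '", path, "' must be a mapping")
  bad <- setdiff(names(user), names(base))
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ",
         paste(paste0(path, bad), collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], as.list(user[[k]]),
                                path = paste0(path, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  check <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  check(is.numeric(cfg$sp) && cfg$sp > 0 && cfg$sp <= 1,
        "sp must lie in (0, 1]")
  check(all(cfg$tagging$strategies %in%
              c("systematic", "template", "model")),
        "tagging.strategies must be a subset of systematic/template/model")
  check(length(cfg$tagging$strategies) >= 1L,
        "at least one tagging strategy is required")
  check(cfg$tagging$radius %in% 1:3, "tagging.radius must be 1, 2 or 3")
  check(cfg$tagging$beam >= 1, "tagging.beam must be positive")
  check(cfg$ttl$beam_t1 >= 1 && cfg$ttl$beam_t2 >= 1,
        "TTL beams must be positive")
  check(is.numeric(cfg$ttl$min_confidence) && cfg$ttl$min_confidence >= 0 &&
          cfg$ttl$min_confidence <= 1,
        "ttl.min_confidence must lie in [0, 1]")
  check(cfg$search$expansion_width >= 1, "search.expansion_width must be positive")
  check(cfg$search$min_solved >= 1, "search.min_solved must be positive")
  check(cfg$search$max_iterations >= 0, "search.max_iterations must be >= 0")
  check(cfg$search$route_cap >= 1, "search.route_cap must be positive")
  check(cfg$search$per_molecule_cap >= 1,
        "search.per_molecule_cap must be positive")
  for (k in c("seed")) cfg[[k]] <- as.integer(cfg[[k]])
  cfg
}
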