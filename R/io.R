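# File round-trips for the artifacts the tool reads and writes: .smi
# molecule lists, .rsmi reaction lists, template CSV, route-report JSON and
# serialized toy worlds.

#' Read / write .smi molecule lists
#'
#' One SMILES per line with an optional tab-separated identifier.
#'
#' @param path File path.
#' @return `read_smi()`: data frame with columns `smiles` and `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(smiles = vapply(parts, `[`, character(1L), 1L),
             id = vapply(parts, function(p)
               if (length(p) > 1L) p[2L] else "", character(1L)),
             stringsAsFactors = FALSE)
}

#' @rdname read_smi
#' @param smiles Character vector of SMILES.
#' @param id Optional identifiers.
#' @export
write_smi <- function(smiles, path, id = NULL) {
  lines <- if (is.null(id)) smiles else paste(smiles, id, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write reaction SMILES (.rsmi) files
#'
#' One `SM>R>P` reaction per line; an optional second tab-separated column
#' is kept as the record's `source_id`.
#'
#' @param path File path.
#' @return `read_rsmi()`: list of `mapped_reaction` objects.
#' @export
read_rsmi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    p <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    parse_reaction(p[1L], source_id = if (length(p) > 1L) p[2L] else "")
  })
}

#' @rdname read_rsmi
#' @param corpus List of `mapped_reaction` objects.
#' @export
write_rsmi <- function(corpus, path) {
  writeLines(vapply(corpus, function(r)
    paste(format_reaction(r), r$source_id, sep = "\t"), character(1L)), path)
  invisible(path)
}

#' Read / write template CSV
#'
#' Columns: `pattern`, `reactive_positions` (semicolon-joined indices into
#' the canonical pattern order), `radius`, `support`.
#'
#' @param path File path.
#' @return `read_templates_csv()`: list of `tag_template` objects.
#' @export
read_templates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    decode_pattern(df$pattern[i], df$radius[i], df$support[i]))
}

#' @rdname read_templates_csv
#' @param templates List of `tag_template` objects.
#' @export
write_templates_csv <- function(templates, path) {
  df <- data.frame(
    pattern = vapply(templates, function(t) t$pattern, character(1L)),
    reactive_positions = vapply(templates, function(t)
      paste(reactive_positions(t), collapse = ";"), character(1L)),
    radius = vapply(templates, function(t) t$radius, integer(1L)),
    support = vapply(templates, function(t) t$support, integer(1L)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

route_to_list <- function(r, rank) {
  list(rank = rank, rpscore = r$rpscore, cscore = r$cscore,
       n_steps = r$n, solved = r$solved,
       steps = lapply(r$steps, function(s) list(
         product = s$product$smiles,
         sm = step_sm_smiles(s),
         reagents = vapply(s$reagent_set, function(m) m$smiles,
                           character(1L)),
         confidence = s$confidence,
         site = serialize_tagged(s$site),
         discovered_at_iteration =
           if (is.null(s$discovered_at)) NA_integer_ else s$discovered_at)))
}

#' Write / read a search report as JSON
#'
#' The JSON schema carries per route: rank, RPScore, CScore, step count,
#' solved flag and the step list (product, starting materials, reagents,
#' confidence, tagged site, discovery iteration). `read_routes_json()`
#' restores an equal report object (molecules re-canonicalized from their
#' SMILES).
#'
#' @param report A `search_report`.
#' @param path Output path.
#' @export
write_routes_json <- function(report, path) {
  solved <- report$solved; unsolved <- report$unsolved
  out <- list(
    target = report$target$smiles,
    trivially_solved = isTRUE(report$trivially_solved),
    iterations = report$iterations,
    ttl_calls = report$ttl_calls,
    exhausted = isTRUE(report$exhausted),
    solved = lapply(seq_along(solved), function(i)
      route_to_list(solved[[i]], i)),
    unsolved = lapply(seq_along(unsolved), function(i)
      route_to_list(unsolved[[i]], i)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_routes_json
#' @export
read_routes_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Write a toy world to a directory
#'
#' Emits `bb.smi`, `corpus.rsmi`, `targets.smi` (ids carry the ground-truth
#' minimum step count) and `world.json` (the generating spec).
#'
#' @param world A `toy_world`.
#' @param dir Output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_smi(world$bb, file.path(dir, "bb.smi"))
  write_rsmi(world$corpus, file.path(dir, "corpus.rsmi"))
  write_smi(world$targets$smiles, file.path(dir, "targets.smi"),
            id = paste0("min_steps=", world$targets$min_steps))
  spec <- world$spec
  jsonlite::write_json(
    list(seed = spec$seed, n_building_blocks = spec$n_building_blocks,
         max_depth = spec$max_depth,
         reactions_per_depth = spec$reactions_per_depth,
         n_targets = spec$n_targets,
         rules = lapply(spec$rules, function(r)
           r[c("rule_id", "kind", "reagents", "base_confidence")])),
    file.path(dir, "world.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
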