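#' Define an appraisal criterion
#'
#' A criterion of the early-access framework. Quantitative criteria belong to
#' the core model, carry a [scoring_scale()] and enter the additive value
#' estimate; qualitative criteria belong to the contextual tool, carry no
#' numeric scale and are rated favourable / neutral / unfavourable only.
#'
#' @param id short stable identifier (snake_case), unique within a framework.
#' @param name display name.
#' @param kind `"quantitative"` or `"qualitative"`.
#' @param scale a [scoring_scale()] for quantitative criteria; must be `NULL`
#'   for qualitative ones.
#' @param subcriteria character vector of free-text subcriterion labels.
#' @param definition free-text definition.
#' @return an object of class `mcda_criterion`.
#' @export
criterion <- function(id, name = id, kind = c("quantitative", "qualitative"),
                      scale = NULL, subcriteria = character(),
                      definition = "") {
  kind <- match.arg(kind)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_mcda("criterion id must be a non-empty string")
  if (kind == "qualitative" && !is.null(scale))
    stop_mcda("qualitative criterion '", id, "' must not carry a scale")
  if (kind == "quantitative") {
    if (is.null(scale)) scale <- scoring_scale()
    stopifnot(inherits(scale, "scoring_scale"))
  }
  structure(
    list(id = id, name = name, kind = kind, scale = scale,
         subcriteria = as.character(subcriteria),
         definition = as.character(definition)),
    class = "mcda_criterion"
  )
}

#' Assemble a criteria framework
#'
#' A framework version: an ordered quantitative core model plus an ordered
#' qualitative contextual tool, with unique criterion ids across both parts.
#'
#' @param version_tag short label for this framework version.
#' @param core list of quantitative [criterion()] objects.
#' @param contextual list of qualitative [criterion()] objects.
#' @return an object of class `mcda_framework`.
#' @seealso [default_framework()] for the bundled pilot and final versions,
#'   [load_framework()] / [save_framework()] for file I/O.
#' @export
mcda_framework <- function(version_tag, core, contextual = list()) {
  stopifnot(is.list(core), is.list(contextual))
  for (cr in core) {
    if (!inherits(cr, "mcda_criterion")) stop_mcda("core entries must be criteria")
    if (cr$kind != "quantitative")
      stop_mcda("core criterion '", cr$id, "' is not quantitative")
  }
  for (cr in contextual) {
    if (!inherits(cr, "mcda_criterion"))
      stop_mcda("contextual entries must be criteria")
    if (cr$kind != "qualitative")
      stop_mcda("contextual criterion '", cr$id, "' is not qualitative")
  }
  ids <- c(vapply(core, `[[`, "", "id"), vapply(contextual, `[[`, "", "id"))
  if (anyDuplicated(ids))
    stop_mcda("duplicate criterion id: ", ids[duplicated(ids)][1])
  structure(
    list(version_tag = as.character(version_tag),
         core = core, contextual = contextual),
    class = "mcda_framework"
  )
}

#' Criterion ids of a framework
#'
#' @param framework an [mcda_framework()].
#' @return character vector of ids, in framework order.
#' @export
core_ids <- function(framework) {
  stopifnot(inherits(framework, "mcda_framework"))
  vapply(framework$core, `[[`, "", "id")
}

#' @rdname core_ids
#' @export
contextual_ids <- function(framework) {
  stopifnot(inherits(framework, "mcda_framework"))
  vapply(framework$contextual, `[[`, "", "id")
}

core_scales <- function(framework) {
  stats::setNames(lapply(framework$core, `[[`, "scale"), core_ids(framework))
}

#' @export
print.mcda_framework <- function(x, ...) {
  cat(sprintf("<mcda_framework '%s'>  %d core + %d contextual criteria\n",
              x$version_tag, length(x$core), length(x$contextual)))
  cat("Core model (quantitative):\n")
  for (cr in x$core) {
    sc <- cr$scale
    lab <- if (sc$dichotomous) sprintf("{%d,%d}", sc$minimum, sc$maximum)
           else sprintf("%d..%d", sc$minimum, sc$maximum)
    cat(sprintf("  %-22s %-55s %s\n", cr$id, cr$name, lab))
  }
  cat("Contextual tool (qualitative):\n")
  for (cr in x$contextual)
    cat(sprintf("  %-22s %s\n", cr$id, cr$name))
  invisible(x)
}

# ---- file I/O --------------------------------------------------------------

criterion_to_list <- function(cr) {
  out <- list(id = cr$id, name = cr$name)
  if (cr$kind == "quantitative")
    out$scale <- list(minimum = cr$scale$minimum, maximum = cr$scale$maximum,
                      dichotomous = cr$scale$dichotomous,
                      anchor_labels = as.list(cr$scale$anchor_labels))
  if (length(cr$subcriteria)) out$subcriteria <- as.list(cr$subcriteria)
  if (nzchar(cr$definition)) out$definition <- cr$definition
  out
}

need_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop_mcda("framework config: missing field '", field, "' in ", where)
  x[[field]]
}

criterion_from_list <- function(x, kind, where) {
  id <- need_field(x, "id", where)
  if (kind == "qualitative" && !is.null(x$scale))
    stop_mcda("framework config: qualitative criterion '", id,
              "' must not have field 'scale'")
  scale <- NULL
  if (kind == "quantitative") {
    sc <- x$scale
    if (is.null(sc))
      stop_mcda("framework config: missing field 'scale' for core criterion '",
                id, "'")
    scale <- scoring_scale(
      minimum = need_field(sc, "minimum", paste0("scale of '", id, "'")),
      maximum = need_field(sc, "maximum", paste0("scale of '", id, "'")),
      dichotomous = isTRUE(sc$dichotomous),
      anchor_labels = unlist(sc$anchor_labels %||% c("worst", "best"))
    )
  }
  criterion(id = id, name = x$name %||% id, kind = kind, scale = scale,
            subcriteria = unlist(x$subcriteria %||% character()),
            definition = x$definition %||% "")
}

#' Load a framework configuration file
#'
#' Reads and validates a framework from YAML (or JSON, by file extension).
#' The file must provide `version_tag`, a `core` list of quantitative
#' criteria (each with a `scale`) and a `contextual` list of qualitative
#' criteria (without scales). Validation errors name the offending field.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` framework file.
#' @return an [mcda_framework()].
#' @seealso [save_framework()]; files round-trip losslessly.
#' @export
load_framework <- function(path) {
  if (!file.exists(path)) stop_mcda("framework file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) stop_mcda("framework config: top level must be a mapping")
  version_tag <- need_field(raw, "version_tag", "top level")
  core_raw <- need_field(raw, "core", "top level")
  ctx_raw <- raw$contextual %||% list()
  core <- lapply(seq_along(core_raw), function(i)
    criterion_from_list(core_raw[[i]], "quantitative",
                        paste0("core[", i, "]")))
  contextual <- lapply(seq_along(ctx_raw), function(i)
    criterion_from_list(ctx_raw[[i]], "qualitative",
                        paste0("contextual[", i, "]")))
  mcda_framework(version_tag, core, contextual)
}

#' Save a framework configuration file
#'
#' @param framework an [mcda_framework()].
#' @param path destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
save_framework <- function(framework, path) {
  stopifnot(inherits(framework, "mcda_framework"))
  out <- list(
    version_tag = framework$version_tag,
    core = lapply(framework$core, criterion_to_list),
    contextual = lapply(framework$contextual, criterion_to_list)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(out, path)
  invisible(path)
}

#' Bundled early-access frameworks
#'
#' Returns one of the two bundled framework versions. The `"final"` framework
#' has eight quantitative core criteria (disease severity, medical urgency,
#' efficacy, safety, internal validity, therapeutic benefit, external
#' validity and plausibility — the last on a dichotomous \{0, 5\} scale) and
#' four qualitative contextual criteria (therapeutic alternatives, existence
#' of precedent and coherence of decisions, management impact, direct medical
#' costs and budget impact): 12 criteria in total. The `"pilot"` framework is
#' the earlier draft with eight quantitative and three qualitative criteria,
#' in which therapeutic alternatives was still quantitative.
#'
#' @param which `"final"` or `"pilot"`.
#' @return an [mcda_framework()].
#' @examples
#' fw <- default_framework("final")
#' length(fw$core)        # 8
#' length(fw$contextual)  # 4
#' @export
default_framework <- function(which = c("final", "pilot")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("framework_", which, ".yaml"),
                      package = "earlymcda", mustWork = TRUE)
  load_framework(path)
}

# ---- criterion-selection consensus rule ------------------------------------

#' Panel consensus rule for criterion selection
#'
#' Decides a criterion's fate from the panel's ballots. Each panellist votes
#' to include the criterion, exclude it, or include it with modifications.
#' A strict majority of the full panel (> 50%) voting "include" selects the
#' criterion; a strict majority voting "exclude" drops it; any other
#' combination sends the criterion back for adaptation. Ballots of "modify"
#' count toward neither threshold.
#'
#' @param votes character vector of ballots, each one of `"include"`,
#'   `"exclude"`, `"modify"`; at most one per panellist.
#' @param n_panel panel size (>= 1); abstentions are `n_panel - length(votes)`.
#' @return `"include"`, `"exclude"` or `"adapt"`.
#' @examples
#' consensus_vote(rep("include", 9), n_panel = 16)  # "include" (56% > 50%)
#' consensus_vote(c(rep("include", 8), rep("exclude", 8)), 16)  # "adapt"
#' @export
consensus_vote <- function(votes, n_panel) {
  if (!is.numeric(n_panel) || length(n_panel) != 1L || n_panel < 1)
    stop_mcda("empty panel: n_panel must be >= 1")
  votes <- as.character(votes)
  bad <- setdiff(unique(votes), c("include", "exclude", "modify"))
  if (length(bad)) stop_mcda("unknown ballot: ", bad[1])
  if (length(votes) > n_panel)
    stop_mcda("ballot count (", length(votes), ") exceeds panel size (",
              n_panel, ")")
  if (sum(votes == "include") > n_panel / 2) "include"
  else if (sum(votes == "exclude") > n_panel / 2) "exclude"
  else "adapt"
}
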