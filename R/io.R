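# Tabular file I/O.
#
# Weights travel as long CSV (panellist_id, profile, criterion_id, weight);
# scores as long CSV (panellist_id, criterion_id, value) where value is an
# integer for core criteria and favourable/neutral/unfavourable for
# contextual criteria. Parsing errors always carry the file name and the
# offending data row number; out-of-range values are never coerced.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_mcda("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_mcda(basename(path), ": missing column '", miss[1], "'")
  if (!nrow(df)) stop_mcda(basename(path), ": no data rows")
  df
}

row_fail <- function(path, i, ...) {
  # i indexes data rows; +1 accounts for the header line in the file
  stop_mcda(basename(path), " row ", i + 1L, ": ", ...)
}

#' Read a panel weights CSV
#'
#' Long format with header `panellist_id, profile, criterion_id, weight`;
#' weights must be integers in 1..5 and profiles one of the four panel
#' profiles. Each panellist must weight every core criterion of the
#' framework exactly once.
#'
#' @param path CSV file path.
#' @param framework an [mcda_framework()] used to validate criterion ids.
#' @return list with `weights` (long data.frame) and `roster`
#'   (panellist_id, profile).
#' @export
read_weights_csv <- function(path, framework = default_framework("final")) {
  df <- read_csv_checked(path, c("panellist_id", "profile", "criterion_id",
                                 "weight"))
  ids <- core_ids(framework)
  w <- suppressWarnings(as.numeric(df$weight))
  for (i in seq_len(nrow(df))) {
    if (!df$profile[i] %in% panel_profiles())
      row_fail(path, i, "unknown profile '", df$profile[i], "'")
    if (!df$criterion_id[i] %in% ids)
      row_fail(path, i, "unknown core criterion '", df$criterion_id[i], "'")
    if (is.na(w[i]) || !(w[i] %in% 1:5))
      row_fail(path, i, "weight '", df$weight[i],
               "' is not an integer in 1..5")
  }
  key <- paste(df$panellist_id, df$criterion_id)
  if (anyDuplicated(key))
    row_fail(path, which(duplicated(key))[1], "duplicate weight for '",
             key[which(duplicated(key))[1]], "'")
  out <- data.frame(panellist_id = df$panellist_id, profile = df$profile,
                    criterion_id = df$criterion_id, weight = as.integer(w))
  for (p in unique(out$panellist_id)) {
    have <- out$criterion_id[out$panellist_id == p]
    miss <- setdiff(ids, have)
    if (length(miss))
      stop_mcda(basename(path), ": panellist '", p,
                "' missing weight for criterion '", miss[1], "'")
  }
  roster <- unique(out[c("panellist_id", "profile")])
  if (anyDuplicated(roster$panellist_id))
    stop_mcda(basename(path), ": panellist with inconsistent profile")
  list(weights = out, roster = roster)
}

#' Write a panel weights CSV
#'
#' @param weights long data.frame with `panellist_id`, `profile`,
#'   `criterion_id`, `weight`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(weights, path) {
  utils::write.csv(weights[c("panellist_id", "profile", "criterion_id",
                             "weight")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a case scores CSV
#'
#' Long format with header `panellist_id, criterion_id, value`. Rows for
#' core criteria must carry an admissible integer score; rows for contextual
#' criteria one of `favourable`, `neutral`, `unfavourable`.
#'
#' @param path CSV file path.
#' @param framework an [mcda_framework()].
#' @param case_id case identifier for the resulting assessment (defaults to
#'   the file name without extension).
#' @return an [mcda_assessment()].
#' @export
read_scores_csv <- function(path, framework = default_framework("final"),
                            case_id = NULL) {
  df <- read_csv_checked(path, c("panellist_id", "criterion_id", "value"))
  case_id <- case_id %||% sub("\\.[^.]*$", "", basename(path))
  ids <- core_ids(framework)
  ctx <- contextual_ids(framework)
  scales <- core_scales(framework)
  quant <- qual <- list()
  for (i in seq_len(nrow(df))) {
    cid <- df$criterion_id[i]
    val <- df$value[i]
    if (cid %in% ids) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num) || num != as.integer(num))
        row_fail(path, i, "score '", val, "' for core criterion '", cid,
                 "' is not an integer")
      sc <- scales[[cid]]
      ok <- tryCatch({ check_score(as.integer(num), sc); TRUE },
                     error = function(e) FALSE)
      if (!ok)
        row_fail(path, i, "score ", num, " not admissible on scale of '",
                 cid, "'")
      quant[[length(quant) + 1L]] <-
        data.frame(panellist_id = df$panellist_id[i], criterion_id = cid,
                   score = as.integer(num))
    } else if (cid %in% ctx) {
      if (!val %in% QUAL_LEVELS)
        row_fail(path, i, "rating '", val, "' for contextual criterion '",
                 cid, "' must be one of ", paste(QUAL_LEVELS, collapse = "/"))
      qual[[length(qual) + 1L]] <-
        data.frame(panellist_id = df$panellist_id[i], criterion_id = cid,
                   rating = val)
    } else {
      row_fail(path, i, "unknown criterion '", cid, "'")
    }
  }
  key <- paste(df$panellist_id, df$criterion_id)
  if (anyDuplicated(key))
    row_fail(path, which(duplicated(key))[1], "duplicate entry for '",
             key[which(duplicated(key))[1]], "'")
  mcda_assessment(case_id,
                  if (length(quant)) do.call(rbind, quant)
                  else stop_mcda(basename(path), ": no quantitative scores"),
                  if (length(qual)) do.call(rbind, qual) else NULL,
                  framework)
}

#' Write a case scores CSV
#'
#' @param assessment an [mcda_assessment()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(assessment, path) {
  stopifnot(inherits(assessment, "mcda_assessment"))
  q <- data.frame(panellist_id = assessment$quant$panellist_id,
                  criterion_id = assessment$quant$criterion_id,
                  value = as.character(assessment$quant$score))
  r <- if (nrow(assessment$qual))
    data.frame(panellist_id = assessment$qual$panellist_id,
               criterion_id = assessment$qual$criterion_id,
               value = assessment$qual$rating)
  else NULL
  utils::write.csv(rbind(q, r), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- structured reports ----------------------------------------------------

report_schema_version <- "1.0"

wilcoxon_to_list <- function(w) {
  if (is.null(w)) return(NULL)
  list(n = w$n, n_nonzero = w$n_nonzero, w_plus = w$w_plus,
       w_minus = w$w_minus, statistic = w$statistic,
       p_two_sided = w$p_value, method = w$method, ties = w$ties,
       no_information = w$no_information)
}

#' Serialize a report to JSON
#'
#' Writes a [group_value_report()], [compare_assessments()] or
#' [aggregate_weights()] result as structured JSON with a schema version.
#' Full numeric precision is retained (display rounding is a print-method
#' concern only).
#'
#' @param x a `value_report`, `retest_comparison` or `weight_summary`.
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  body <- if (inherits(x, "value_report")) {
    list(schema_version = report_schema_version, type = "value_report",
         case_id = x$case_id, framework_version = x$framework_version,
         mode = x$mode, n_panel = x$n_panel, group_ve = x$group_ve,
         per_panellist = x$per_panellist, vc_mean = as.list(x$vc_mean),
         contextual = x$contextual, excluded = x$excluded)
  } else if (inherits(x, "retest_comparison")) {
    list(schema_version = report_schema_version, type = "retest_comparison",
         case_id = x$case_id, alpha = x$alpha, verdict = x$verdict,
         n_shared = x$n_shared, group_ve_test = x$group_ve_test,
         group_ve_retest = x$group_ve_retest,
         group_ve_delta = x$group_ve_delta,
         ve = wilcoxon_to_list(x$ve),
         per_criterion = lapply(x$per_criterion, wilcoxon_to_list),
         dropped_panellists = x$dropped_panellists)
  } else if (inherits(x, "weight_summary")) {
    list(schema_version = report_schema_version, type = "weight_summary",
         panel_size = x$panel_size, dispersion = x$dispersion,
         overall = x$overall, by_profile = x$by_profile)
  } else stop_mcda("unsupported report type: ", class(x)[1])
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
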