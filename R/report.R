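# Statistical report: self-contained HTML in three sections (commands,
# QC metrics passed through, mutation landscape) plus a machine-readable
# JSON twin of every number.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return("<p class=\"na\">not available</p>")
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<tr>", paste0("<td>", html_escape(as.character(unlist(df[i, ]))),
                          "</td>", collapse = ""), "</tr>")
  }, character(1))
  paste0("<table>", head, paste(rows, collapse = ""), "</table>")
}

#' Render the statistical report
#'
#' Writes a self-contained `report.html` with three sections — the command
#' lines and parameters of the run, upstream QC/alignment metrics passed
#' through when available, and the mutation landscape (type proportions,
#' Ti/Tv, TMB, caller-evidence histogram) — plus `report.json`, a
#' machine-readable twin of every number in the HTML.  Report generation
#' is deterministic: the same inputs yield byte-identical JSON.
#'
#' @param stats A `mutation_summary` from [summarize_variants()].
#' @param run_meta Optional list with `command_lines` (character vector),
#'   `parameters` (named list), `qc_metrics` (data frame or named list)
#'   and `flagged_genes` (character vector of user-supplied genes of
#'   interest to highlight).  Missing pieces render as "not available".
#' @param out_dir Output directory (created if needed).
#' @param name Basename for the two files (default `"report"`).
#' @return Named character vector with the `html` and `json` paths,
#'   invisibly.
#' @export
render_report <- function(stats, run_meta = list(), out_dir, name = "report") {
  stopifnot(inherits(stats, "mutation_summary"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  json_path <- file.path(out_dir, paste0(name, ".json"))
  html_path <- file.path(out_dir, paste0(name, ".html"))

  payload <- list(
    commands = if (is.null(run_meta$command_lines)) character(0) else run_meta$command_lines,
    parameters = if (is.null(run_meta$parameters)) stats::setNames(list(), character(0)) else run_meta$parameters,
    qc_metrics = if (is.null(run_meta$qc_metrics)) NULL else run_meta$qc_metrics,
    mutation_landscape = list(
      n_variants = stats$n_variants,
      class_proportions = stats$class_proportions,
      n_transitions = stats$n_transitions,
      n_transversions = stats$n_transversions,
      titv_ratio = if (is.na(stats$titv_ratio)) NULL else stats$titv_ratio,
      tmb = stats$tmb,
      target_size_bp = stats$target_size_bp,
      per_caller_counts = stats$per_caller_counts,
      consensus_histogram = stats$consensus_histogram,
      flagged_genes = if (is.null(run_meta$flagged_genes)) character(0) else run_meta$flagged_genes))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                              pretty = TRUE, digits = NA),
             json_path, useBytes = TRUE)

  sec1 <- if (length(payload$commands) > 0L) {
    paste0("<pre>", html_escape(paste(payload$commands, collapse = "\n")), "</pre>")
  } else "<p class=\"na\">not available</p>"
  par_html <- if (length(payload$parameters) > 0L) {
    html_table(data.frame(parameter = names(payload$parameters),
                          value = vapply(payload$parameters, function(v)
                            paste(as.character(v), collapse = ","), character(1)),
                          stringsAsFactors = FALSE))
  } else ""
  sec2 <- if (is.null(payload$qc_metrics)) {
    "<p class=\"na\">not available</p>"
  } else if (is.data.frame(payload$qc_metrics)) {
    html_table(payload$qc_metrics)
  } else {
    html_table(data.frame(metric = names(payload$qc_metrics),
                          value = vapply(payload$qc_metrics, function(v)
                            paste(as.character(v), collapse = ","), character(1)),
                          stringsAsFactors = FALSE))
  }
  ml <- payload$mutation_landscape
  landscape <- data.frame(
    quantity = c("variants", "transitions", "transversions", "Ti/Tv",
                 "TMB (mut/Mb)"),
    value = c(ml$n_variants, ml$n_transitions, ml$n_transversions,
              if (is.null(ml$titv_ratio)) "undefined" else format(ml$titv_ratio),
              if (is.null(ml$tmb)) "not computed" else format(ml$tmb)),
    stringsAsFactors = FALSE)
  prop_df <- if (length(ml$class_proportions) > 0L) {
    data.frame(type = names(ml$class_proportions),
               proportion = format(unlist(ml$class_proportions)),
               stringsAsFactors = FALSE)
  } else NULL
  hist_df <- if (length(ml$consensus_histogram) > 0L) {
    data.frame(supporting_callers = names(ml$consensus_histogram),
               variants = unlist(ml$consensus_histogram),
               stringsAsFactors = FALSE)
  } else NULL
  flagged <- if (length(ml$flagged_genes) > 0L) {
    paste0("<p>flagged genes: ", html_escape(paste(ml$flagged_genes, collapse = ", ")),
           "</p>")
  } else ""

  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
            sprintf("<title>%s</title>", name),
            "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}td,th{border:1px solid #999;padding:4px 8px}.na{color:#888;font-style:italic}</style>",
            "</head><body>",
            sprintf("<h1>%s</h1>", name),
            "<h2>1. Commands and parameters</h2>", sec1, par_html,
            "<h2>2. Quality-control metrics</h2>", sec2,
            "<h2>3. Mutation landscape</h2>",
            html_table(landscape),
            "<h3>Mutation type proportions</h3>", html_table(prop_df),
            "<h3>Caller evidence</h3>", html_table(hist_df),
            flagged,
            "</body></html>")
  writeLines(html, html_path, useBytes = TRUE)
  invisible(c(html = html_path, json = json_path))
}
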