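# Execution engine: render a workflow against macro bindings, run it as a
# DAG with parallel launch of independent steps, write the auxiliary logs,
# and resume an interrupted run from the recorded checkpoint.

#' Read macro bindings from a file
#'
#' Accepts either a flat `KEY=value` text file (one pair per line, `#`
#' comments allowed) or a JSON object.  Uppercase keys bind macros;
#' lowercase keys bind unlinked input ports (external inputs).
#'
#' @param path Bindings file.
#' @return Named list of character values.
#' @export
read_bindings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- trimws(paste(lines, collapse = "\n"))
  if (startsWith(txt, "{")) {
    vals <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
    return(lapply(vals, as.character))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0L)) {
    stop(sprintf("bindings line without '=': %s", lines[eq < 0L][1]), call. = FALSE)
  }
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substr(lines, eq + 1L, nchar(lines)))
  stats::setNames(as.list(vals), keys)
}

#' Render a workflow into concrete commands
#'
#' Every step gets its own working directory `run_dir/<step_name>/`.  An
#' output token `[port]` resolves to the file `port` inside the step's
#' working directory; a linked input token `<port>` resolves to the
#' upstream step's output file; an unlinked input token resolves to the
#' binding of the same (lowercase) name; a macro token `#NAME#` resolves to
#' its binding or declared default; `##` becomes a literal `#`.  Rendering
#' is deterministic given (spec, bindings, run_dir).
#'
#' @param spec A valid `workflow_spec`.
#' @param bindings Named list/character vector of values for macros
#'   (uppercase keys) and unlinked input ports (lowercase keys).
#' @param run_dir Run directory (created later by [wf_execute()]).
#' @return List of `rendered_step` objects in topological order, each with
#'   `name`, `command` (no residual markup), `input_paths`, `output_paths`,
#'   `workdir`.  The run directory is attached as attribute `run_dir`.
#' @export
wf_render <- function(spec, bindings = list(), run_dir) {
  wf_validate(spec)
  bindings <- as.list(bindings)
  run_dir <- absolute_path(run_dir)
  ord <- topo_order(names(spec$steps), spec$links)
  link_src <- function(step, port) {
    lk <- spec$links
    hit <- lk$to_step == step & lk$to_port == port
    if (!any(hit)) return(NULL)
    file.path(run_dir, lk$from_step[hit][1], lk$from_port[hit][1])
  }
  steps <- lapply(ord, function(nm) {
    step <- spec$steps[[nm]]
    workdir <- file.path(run_dir, nm)
    inputs <- list(); outputs <- list()
    cmd <- rebuild_command(step, function(tok) {
      switch(tok$type,
        hash = "#",
        output = {
          p <- file.path(workdir, tok$text)
          outputs[[tok$text]] <<- p
          p
        },
        input = {
          p <- link_src(nm, tok$text)
          if (is.null(p)) {
            p <- bindings[[tok$text]]
            if (is.null(p)) {
              stop(sprintf("unbound input port '%s' of step '%s': not linked and no binding",
                           tok$text, nm), call. = FALSE)
            }
          }
          inputs[[tok$text]] <<- p
          p
        },
        macro = {
          v <- bindings[[tok$text]]
          if (is.null(v)) v <- spec$macros[[tok$text]]
          if (is.null(v)) {
            stop(sprintf("unbound macro '%s' in step '%s': no binding and no default",
                         tok$text, nm), call. = FALSE)
          }
          as.character(v)
        })
    })
    structure(list(name = nm, command = cmd,
                   input_paths = inputs, output_paths = outputs,
                   workdir = workdir),
              class = "rendered_step")
  })
  names(steps) <- ord
  attr(steps, "run_dir") <- run_dir
  steps
}

absolute_path <- function(path) {
  if (startsWith(path, "/")) path
  else file.path(normalizePath(".", winslash = "/"), path)
}

run_prefix <- function(run_dir) basename(normalizePath(run_dir, mustWork = FALSE))

run_file <- function(run_dir, ext) {
  file.path(run_dir, paste0(run_prefix(run_dir), ".", ext))
}

# Fingerprint of (exported workflow JSON, sorted bindings); stored in the
# run directory so a resume against a different workflow or bindings is
# refused as stale.
run_fingerprint <- function(spec, bindings) {
  bindings <- as.list(bindings)
  if (length(bindings) > 0L) bindings <- bindings[order(names(bindings))]
  payload <- c(as.character(wf_export_json(spec)),
               paste(names(bindings), unlist(bindings, use.names = FALSE),
                     sep = "=", collapse = "\n"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(payload, tmp, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}

# Launch one rendered step: a wrapper script runs the command in the step's
# workdir with stdout/stderr captured, then writes the exit status to a
# sentinel file the scheduler polls.  The sentinel write is the completion
# signal, so status is never read before it is durable.
launch_step <- function(rstep) {
  script <- file.path(rstep$workdir, ".step.sh")
  # the command runs in a subshell so an `exit` inside it cannot skip the
  # exit-status sentinel the scheduler polls for
  writeLines(c("#!/bin/sh",
               paste0("cd '", rstep$workdir, "'"),
               "(",
               rstep$command,
               ") > .step.out 2> .step.err",
               "echo $? > .step.exit"),
             script)
  system2("sh", shQuote(script), wait = FALSE)
}

step_exit_status <- function(rstep) {
  f <- file.path(rstep$workdir, ".step.exit")
  if (!file.exists(f)) return(NA_integer_)
  v <- suppressWarnings(as.integer(readLines(f, warn = FALSE)[1]))
  if (is.na(v)) NA_integer_ else v
}

# Core scheduler: repeatedly launch ready steps (all upstreams succeeded)
# up to max_parallel, ties broken lexicographically by step name, and poll
# running steps for completion.  `done` names steps treated as already
# succeeded (resume).  `interrupt_after` stops launching new work after
# that many completions in this call — already-running steps still finish —
# emulating an external interruption for checkpoint testing.
run_scheduler <- function(steps, spec, run_dir, max_parallel,
                          done = character(0), interrupt_after = Inf,
                          poll = 0.005) {
  nm <- names(steps)
  ups <- upstream_map(spec)
  status <- stats::setNames(rep("pending", length(nm)), nm)
  status[done] <- "succeeded"
  ok_log <- run_file(run_dir, "ok.log")
  cmd_log <- run_file(run_dir, "command.log")
  launch_order <- character(0)
  timing <- list()
  completions <- 0L
  interrupted <- FALSE

  ready_steps <- function() {
    cand <- nm[status[nm] == "pending"]
    ok <- vapply(cand, function(s) all(status[ups[[s]]] == "succeeded"), logical(1))
    sort(cand[ok])
  }

  repeat {
    running <- nm[status == "running"]
    # reap finished steps first so the ok-log is durable before dependents
    # are considered ready
    for (s in running) {
      code <- step_exit_status(steps[[s]])
      if (!is.na(code)) {
        timing[[s]]$finish <- as.numeric(Sys.time())
        timing[[s]]$exit <- code
        if (code == 0L) {
          status[s] <- "succeeded"
          cat(s, "\n", sep = "", file = ok_log, append = TRUE)
        } else {
          status[s] <- "failed"
        }
        completions <- completions + 1L
        if (completions >= interrupt_after) interrupted <- TRUE
      }
    }
    running <- nm[status == "running"]
    if (!interrupted) {
      for (s in ready_steps()) {
        if (length(running) >= max_parallel) break
        status[s] <- "running"
        timing[[s]] <- list(start = as.numeric(Sys.time()))
        launch_order <- c(launch_order, s)
        cat(steps[[s]]$command, "\n", sep = "", file = cmd_log, append = TRUE)
        launch_step(steps[[s]])
        running <- c(running, s)
      }
    }
    if (length(running) == 0L && (interrupted || length(ready_steps()) == 0L)) break
    if (length(running) > 0L) Sys.sleep(poll)
  }

  state <- structure(list(
    statuses = status,
    ok_entries = if (file.exists(ok_log)) readLines(ok_log, warn = FALSE) else character(0),
    run_dir = run_dir,
    launch_order = launch_order,
    timing = timing,
    interrupted = interrupted), class = "run_state")
  wf_write_logs(state, steps, run_dir)
  state
}

#' Execute a rendered workflow
#'
#' Steps start only after all their upstream steps succeeded; independent
#' steps run concurrently up to `max_parallel`, ties among ready steps
#' broken by step name so serial runs have a fixed launch order.  A step
#' succeeds iff its shell exits with status zero.  On a failure,
#' already-running steps finish and independent branches continue, but
#' nothing downstream of the failure ever starts.  Each successful step is
#' appended to the ok-log before any dependent becomes ready, so an
#' interrupted run can be resumed with [wf_resume()].
#'
#' @param steps Rendered steps from [wf_render()].
#' @param spec The `workflow_spec` they were rendered from.
#' @param max_parallel Maximum concurrently running steps (default: number
#'   of available processors).
#' @param fresh Wipe previous checkpoint/log files in `run_dir` (default
#'   `TRUE`; [wf_resume()] sets `FALSE`).
#' @param done Step names to treat as already succeeded (internal, resume).
#' @param interrupt_after Stop launching new steps after this many step
#'   completions (already-running steps finish); used to test
#'   checkpoint/resume behavior.
#' @param bindings Bindings used for the run fingerprint (defaults to
#'   empty; [wf_run()] passes the real ones).
#' @return A `run_state` with per-step `statuses` (`pending`, `running`,
#'   `succeeded`, `failed`), the ok-log entries, launch order and per-step
#'   start/finish timestamps.
#' @export
wf_execute <- function(steps, spec, max_parallel = parallel::detectCores(),
                       fresh = TRUE, done = character(0),
                       interrupt_after = Inf, bindings = list()) {
  stopifnot(max_parallel >= 1L)
  run_dir <- attr(steps, "run_dir")
  if (!dir.exists(run_dir) && !dir.create(run_dir, recursive = TRUE)) {
    stop(sprintf("cannot create run directory '%s'", run_dir), call. = FALSE)
  }
  if (fresh) {
    for (ext in c("ok.log", "command.log", "out", "err")) {
      unlink(run_file(run_dir, ext))
    }
    writeLines(run_fingerprint(spec, bindings), run_file(run_dir, "fingerprint"))
  }
  for (s in steps) {
    if (!dir.exists(s$workdir) && !dir.create(s$workdir, recursive = TRUE)) {
      stop(sprintf("cannot create step directory '%s'", s$workdir), call. = FALSE)
    }
    if (!s$name %in% done) {
      unlink(file.path(s$workdir, c(".step.exit", ".step.out", ".step.err")))
    }
  }
  run_scheduler(steps, spec, run_dir, max_parallel,
                done = done, interrupt_after = interrupt_after)
}

#' Resume an interrupted run
#'
#' Steps recorded in the run directory's ok-log are skipped (their
#' processes are not re-spawned); the remainder executes as in
#' [wf_execute()].  Resuming a fully successful run spawns nothing.  The
#' run directory stores a fingerprint of (workflow JSON, bindings); a
#' mismatch, or an ok-log entry naming a step absent from the workflow, is
#' a stale-state error.
#'
#' @param spec A `workflow_spec`.
#' @param bindings Macro/input bindings (same as the original run).
#' @param run_dir Run directory of the interrupted run.
#' @param max_parallel Maximum concurrently running steps.
#' @return A `run_state` covering the whole workflow.
#' @export
wf_resume <- function(spec, bindings = list(), run_dir,
                      max_parallel = parallel::detectCores()) {
  run_dir <- absolute_path(run_dir)
  fp_file <- run_file(run_dir, "fingerprint")
  ok_log <- run_file(run_dir, "ok.log")
  if (!file.exists(fp_file)) {
    stop(sprintf("no checkpoint in '%s': missing fingerprint file", run_dir),
         call. = FALSE)
  }
  fp <- readLines(fp_file, warn = FALSE)[1]
  if (!identical(fp, run_fingerprint(spec, bindings))) {
    stop("stale checkpoint: run directory was produced by a different workflow or bindings",
         call. = FALSE)
  }
  done <- if (file.exists(ok_log)) readLines(ok_log, warn = FALSE) else character(0)
  unknown <- setdiff(done, names(spec$steps))
  if (length(unknown) > 0L) {
    stop(sprintf("stale checkpoint: ok-log names unknown step '%s'", unknown[1]),
         call. = FALSE)
  }
  steps <- wf_render(spec, bindings, run_dir)
  wf_execute(steps, spec, max_parallel = max_parallel,
             fresh = FALSE, done = done, bindings = bindings)
}

#' Write the auxiliary log files of a run
#'
#' Four files named after the run directory's basename: `<run>.command.log`
#' (every executed concrete command, launch order), `<run>.ok.log`
#' (successful steps, append-only, written during the run), `<run>.out` and
#' `<run>.err` (per-step-delimited concatenation of the children's standard
#' output and error).  The first two are streamed during execution; this
#' function (re)assembles the last two and is called automatically at the
#' end of a run.
#'
#' @param state A `run_state`.
#' @param steps The rendered steps of the run.
#' @param run_dir The run directory.
#' @return Named character vector of the four file paths, invisibly.
#' @export
wf_write_logs <- function(state, steps, run_dir) {
  for (ext in c("command.log", "ok.log")) {
    f <- run_file(run_dir, ext)
    if (!file.exists(f)) file.create(f)
  }
  ran <- names(steps)[vapply(names(steps), function(s)
    state$statuses[[s]] %in% c("succeeded", "failed"), logical(1))]
  for (chan in c("out", "err")) {
    con <- file(run_file(run_dir, chan), open = "w")
    for (s in ran) {
      part <- file.path(steps[[s]]$workdir, paste0(".step.", chan))
      writeLines(sprintf("==> %s <==", s), con)
      if (file.exists(part)) writeLines(readLines(part, warn = FALSE), con)
    }
    close(con)
  }
  invisible(stats::setNames(
    vapply(c("command.log", "ok.log", "out", "err"),
           function(e) run_file(run_dir, e), character(1)),
    c("command_log", "ok_log", "out", "err")))
}

#' Run a workflow end to end
#'
#' Convenience wrapper: render, then execute (or resume).  With
#' `dry_run = TRUE` the rendered commands are printed in launch order and
#' nothing executes.
#'
#' @param spec A `workflow_spec`, or path to a workflow JSON document.
#' @param bindings Named list, or path to a bindings file
#'   ([read_bindings()]).
#' @param run_dir Run directory.
#' @param max_parallel Maximum concurrently running steps.
#' @param resume Resume from the run directory's checkpoint.
#' @param dry_run Print rendered commands, execute nothing.
#' @return A `run_state` (invisibly for dry runs: the rendered steps).
#' @export
wf_run <- function(spec, bindings = list(), run_dir,
                   max_parallel = parallel::detectCores(),
                   resume = FALSE, dry_run = FALSE) {
  if (is.character(spec)) spec <- wf_import_json(spec)
  if (is.character(bindings)) bindings <- read_bindings(bindings)
  if (dry_run) {
    steps <- wf_render(spec, bindings, run_dir)
    for (s in steps) cat(s$command, "\n", sep = "")
    return(invisible(steps))
  }
  if (resume) {
    wf_resume(spec, bindings, run_dir, max_parallel = max_parallel)
  } else {
    steps <- wf_render(spec, bindings, run_dir)
    wf_execute(steps, spec, max_parallel = max_parallel, bindings = bindings)
  }
}

#' @export
print.run_state <- function(x, ...) {
  tb <- table(factor(x$statuses,
                     levels = c("pending", "ready", "running", "succeeded", "failed")))
  cat(sprintf("run_state in %s%s\n", x$run_dir,
              if (isTRUE(x$interrupted)) " (interrupted)" else ""))
  for (s in names(tb)) if (tb[[s]] > 0L) cat(sprintf("  %s: %d\n", s, tb[[s]]))
  invisible(x)
}
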