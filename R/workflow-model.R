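# Workflow model: step markup grammar, port links, macro table, JSON round-trip.

STEP_NAME_RE <- "^[a-z0-9_]+$"
MACRO_NAME_RE <- "^[A-Z0-9_]+$"
PORT_NAME_RE <- "^[a-z0-9_]+$"
WORKFLOW_SCHEMA_VERSION <- "1.0"

#' Tokenize a step command
#'
#' Scans a command line for the three markup token kinds: `<name>` input
#' ports, `[name]` output ports, and `#NAME#` macros.  A literal `#` must be
#' written `##`.  Everything else is plain shell text; `<`, `[` and `#`
#' always open a token, so bare shell redirection characters are not part of
#' the grammar.
#'
#' @param command Command string.
#' @return A data frame with one row per token: `type` (one of `"input"`,
#'   `"output"`, `"macro"`, `"hash"`), `text` (the token's name; `""` for a
#'   `##` escape), `start`, `end` (1-based character offsets of the whole
#'   token, delimiters included).
#' @keywords internal
scan_markup <- function(command) {
  stopifnot(is.character(command), length(command) == 1L, !is.na(command))
  chars <- strsplit(command, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "<" || ch == "[") {
      close <- if (ch == "<") ">" else "]"
      j <- i + 1L
      while (j <= n && chars[j] != close) j <- j + 1L
      if (j > n) {
        stop(sprintf("unclosed '%s' at offset %d in command: %s", ch, i, command),
             call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        type = if (ch == "<") "input" else "output",
        text = paste(chars[seq.int(i + 1L, length.out = j - i - 1L)], collapse = ""),
        start = i, end = j, stringsAsFactors = FALSE)
      i <- j + 1L
    } else if (ch == "#") {
      if (i < n && chars[i + 1L] == "#") {
        out[[length(out) + 1L]] <- data.frame(
          type = "hash", text = "", start = i, end = i + 1L,
          stringsAsFactors = FALSE)
        i <- i + 2L
      } else {
        j <- i + 1L
        while (j <= n && chars[j] != "#") j <- j + 1L
        if (j > n) {
          stop(sprintf("unmatched '#' at offset %d in command: %s", i, command),
               call. = FALSE)
        }
        out[[length(out) + 1L]] <- data.frame(
          type = "macro",
          text = paste(chars[seq.int(i + 1L, length.out = j - i - 1L)], collapse = ""),
          start = i, end = j, stringsAsFactors = FALSE)
        i <- j + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(type = character(), text = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Parse a step command's markup into a workflow step
#'
#' A step is a named shell command whose inputs are marked `<port>`, outputs
#' `[port]`, and macros `#NAME#`.  Step and port names use lowercase letters,
#' digits and underscores; macro names the uppercase equivalent.
#'
#' @param name Step name (`[a-z0-9_]+`).
#' @param command Command line with markup; preserved verbatim.
#' @return A `workflow_step` object with fields `name`, `command`,
#'   `inputs`, `outputs` (character vectors in order of appearance),
#'   `macros` (unique, in order of first appearance) and the token table.
#' @examples
#' s <- parse_step_markup("qc", "fastp -i <r1> -o [clean1] -w #THREADS#")
#' s$inputs; s$outputs; s$macros
#' @export
parse_step_markup <- function(name, command) {
  if (!is.character(name) || length(name) != 1L || !grepl(STEP_NAME_RE, name)) {
    stop(sprintf("invalid step name '%s': use lowercase letters, digits, underscores",
                 as.character(name)[1]), call. = FALSE)
  }
  if (!is.character(command) || length(command) != 1L || !nzchar(command)) {
    stop("step command must be a nonempty string", call. = FALSE)
  }
  tok <- scan_markup(command)
  bad_port <- tok$type %in% c("input", "output") & !grepl(PORT_NAME_RE, tok$text)
  if (any(bad_port)) {
    stop(sprintf("invalid port name '%s' in step '%s'", tok$text[bad_port][1], name),
         call. = FALSE)
  }
  bad_macro <- tok$type == "macro" & !grepl(MACRO_NAME_RE, tok$text)
  if (any(bad_macro)) {
    stop(sprintf("invalid macro name '%s' in step '%s': use uppercase letters, digits, underscores",
                 tok$text[bad_macro][1], name), call. = FALSE)
  }
  inputs <- tok$text[tok$type == "input"]
  outputs <- tok$text[tok$type == "output"]
  if (anyDuplicated(inputs)) {
    stop(sprintf("duplicate input port '%s' in step '%s'",
                 inputs[duplicated(inputs)][1], name), call. = FALSE)
  }
  if (anyDuplicated(outputs)) {
    stop(sprintf("duplicate output port '%s' in step '%s'",
                 outputs[duplicated(outputs)][1], name), call. = FALSE)
  }
  structure(list(name = name, command = command,
                 inputs = inputs, outputs = outputs,
                 macros = unique(tok$text[tok$type == "macro"]),
                 tokens = tok),
            class = "workflow_step")
}

#' Create an empty workflow specification
#'
#' A workflow is a named collection of steps, a list of port links
#' (upstream output port -> downstream input port) and a macro table.
#' Steps are added with [wf_add_step()] and connected with [wf_link()].
#'
#' @param macros Optional named list of macro defaults (`NULL` value means
#'   the macro is required at render time).
#' @return A `workflow_spec` object.
#' @export
workflow_spec <- function(macros = list()) {
  stopifnot(is.list(macros))
  if (length(macros) > 0L) {
    if (is.null(names(macros)) || any(!nzchar(names(macros)))) {
      stop("macros must be a named list", call. = FALSE)
    }
    bad <- !grepl(MACRO_NAME_RE, names(macros))
    if (any(bad)) {
      stop(sprintf("invalid macro name '%s'", names(macros)[bad][1]), call. = FALSE)
    }
  }
  structure(list(steps = list(),
                 links = empty_links(),
                 macros = macros),
            class = "workflow_spec")
}

empty_links <- function() {
  data.frame(from_step = character(), from_port = character(),
             to_step = character(), to_port = character(),
             stringsAsFactors = FALSE)
}

#' Add a step to a workflow
#'
#' Macros referenced by the step's command that are not yet in the macro
#' table are registered as required (no default).
#'
#' @param spec A `workflow_spec`.
#' @param name Step name, or a ready-made `workflow_step` (then `command`
#'   is ignored).
#' @param command Command line with markup.
#' @return The updated `workflow_spec`.
#' @export
wf_add_step <- function(spec, name, command = NULL) {
  stopifnot(inherits(spec, "workflow_spec"))
  step <- if (inherits(name, "workflow_step")) name else parse_step_markup(name, command)
  if (step$name %in% names(spec$steps)) {
    stop(sprintf("duplicate step name '%s'", step$name), call. = FALSE)
  }
  spec$steps[[step$name]] <- step
  for (m in step$macros) {
    if (!m %in% names(spec$macros)) spec$macros[m] <- list(NULL)
  }
  spec
}

#' Declare a macro (optionally with a default value)
#' @param spec A `workflow_spec`.
#' @param name Macro name (`[A-Z0-9_]+`).
#' @param default Default value as a string, or `NULL` for required.
#' @return The updated `workflow_spec`.
#' @export
wf_declare_macro <- function(spec, name, default = NULL) {
  stopifnot(inherits(spec, "workflow_spec"))
  if (!grepl(MACRO_NAME_RE, name)) {
    stop(sprintf("invalid macro name '%s'", name), call. = FALSE)
  }
  spec$macros[name] <- list(default)
  spec
}

#' Link an upstream output port to a downstream input port
#'
#' At render time the downstream step's `<to_port>` token resolves to the
#' file the upstream step wrote for `[from_port]`.  Fan-out is permitted
#' (one output port may feed several downstream inputs) but each downstream
#' input port can be the target of at most one link.  Adding a link that
#' would close a cycle is an error naming one offending cycle.
#'
#' @param spec A `workflow_spec`.
#' @param from_step,from_port Upstream step and output port.
#' @param to_step,to_port Downstream step and input port.
#' @return The updated `workflow_spec`.
#' @export
wf_link <- function(spec, from_step, from_port, to_step, to_port) {
  stopifnot(inherits(spec, "workflow_spec"))
  if (identical(from_step, to_step)) {
    stop(sprintf("self-link on step '%s' is not allowed", from_step), call. = FALSE)
  }
  for (s in c(from_step, to_step)) {
    if (!s %in% names(spec$steps)) {
      stop(sprintf("unknown step '%s'", s), call. = FALSE)
    }
  }
  if (!from_port %in% spec$steps[[from_step]]$outputs) {
    stop(sprintf("step '%s' has no output port '%s'", from_step, from_port),
         call. = FALSE)
  }
  if (!to_port %in% spec$steps[[to_step]]$inputs) {
    stop(sprintf("step '%s' has no input port '%s'", to_step, to_port),
         call. = FALSE)
  }
  dup <- spec$links$to_step == to_step & spec$links$to_port == to_port
  if (any(dup)) {
    stop(sprintf("input port '%s' of step '%s' is already linked (from %s.%s)",
                 to_port, to_step, spec$links$from_step[dup][1],
                 spec$links$from_port[dup][1]), call. = FALSE)
  }
  spec$links <- rbind(spec$links,
                      data.frame(from_step = from_step, from_port = from_port,
                                 to_step = to_step, to_port = to_port,
                                 stringsAsFactors = FALSE))
  cyc <- find_cycle(names(spec$steps), spec$links)
  if (!is.null(cyc)) {
    stop(sprintf("link closes a cycle: %s", paste(cyc, collapse = " -> ")),
         call. = FALSE)
  }
  spec
}

# Kahn's algorithm; ties among ready nodes broken lexicographically so the
# order (and hence serial launch order) is reproducible.  Returns NULL if a
# cycle prevents completion.
topo_order <- function(step_names, links) {
  indeg <- stats::setNames(integer(length(step_names)), step_names)
  if (nrow(links) > 0L) {
    tb <- table(links$to_step)
    indeg[names(tb)] <- as.integer(tb)
  }
  order <- character(0)
  remaining <- step_names
  while (length(remaining) > 0L) {
    ready <- sort(remaining[indeg[remaining] == 0L])
    if (length(ready) == 0L) return(NULL)
    nxt <- ready[1]
    order <- c(order, nxt)
    remaining <- setdiff(remaining, nxt)
    out_edges <- links$to_step[links$from_step == nxt]
    for (v in out_edges) indeg[v] <- indeg[v] - 1L
  }
  order
}

# Returns one cycle (as a vector of step names, first repeated last) or NULL.
find_cycle <- function(step_names, links) {
  if (!is.null(topo_order(step_names, links))) return(NULL)
  adj <- split(links$to_step, factor(links$from_step, levels = step_names))
  color <- stats::setNames(rep.int(0L, length(step_names)), step_names)
  stack_path <- character(0)
  cycle <- NULL
  visit <- function(u) {
    if (!is.null(cycle)) return()
    color[u] <<- 1L
    stack_path <<- c(stack_path, u)
    for (v in adj[[u]]) {
      if (color[v] == 1L) {
        i <- match(v, stack_path)
        cycle <<- c(stack_path[i:length(stack_path)], v)
        return()
      }
      if (color[v] == 0L) visit(v)
      if (!is.null(cycle)) return()
    }
    color[u] <<- 2L
    stack_path <<- stack_path[-length(stack_path)]
  }
  for (u in step_names) if (color[u] == 0L) visit(u)
  cycle
}

# Upstream dependency map: step name -> character vector of direct upstreams.
upstream_map <- function(spec) {
  lapply(stats::setNames(names(spec$steps), names(spec$steps)), function(s) {
    unique(spec$links$from_step[spec$links$to_step == s])
  })
}

#' Validate a workflow specification
#'
#' Checks step-name uniqueness and grammar, macro coverage, link port
#' existence and direction, single-target input ports, and acyclicity.
#'
#' @param spec A `workflow_spec`.
#' @return `spec`, invisibly; stops with an informative error otherwise.
#' @export
wf_validate <- function(spec) {
  stopifnot(inherits(spec, "workflow_spec"))
  nm <- names(spec$steps)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate step name '%s'", nm[duplicated(nm)][1]), call. = FALSE)
  }
  for (step in spec$steps) {
    missing <- setdiff(step$macros, names(spec$macros))
    if (length(missing) > 0L) {
      stop(sprintf("macro '%s' used in step '%s' is not declared",
                   missing[1], step$name), call. = FALSE)
    }
  }
  lk <- spec$links
  for (i in seq_len(nrow(lk))) {
    if (!lk$from_step[i] %in% nm || !lk$to_step[i] %in% nm) {
      stop(sprintf("link references unknown step '%s'",
                   setdiff(c(lk$from_step[i], lk$to_step[i]), nm)[1]),
           call. = FALSE)
    }
    if (!lk$from_port[i] %in% spec$steps[[lk$from_step[i]]]$outputs) {
      stop(sprintf("link references missing output port '%s.%s'",
                   lk$from_step[i], lk$from_port[i]), call. = FALSE)
    }
    if (!lk$to_port[i] %in% spec$steps[[lk$to_step[i]]]$inputs) {
      stop(sprintf("link references missing input port '%s.%s'",
                   lk$to_step[i], lk$to_port[i]), call. = FALSE)
    }
  }
  key <- paste(lk$to_step, lk$to_port)
  if (anyDuplicated(key)) {
    stop(sprintf("input port '%s' has multiple incoming links",
                 key[duplicated(key)][1]), call. = FALSE)
  }
  cyc <- find_cycle(nm, lk)
  if (!is.null(cyc)) {
    stop(sprintf("workflow contains a cycle: %s", paste(cyc, collapse = " -> ")),
         call. = FALSE)
  }
  invisible(spec)
}

# Rewrite a step's command for export: each linked input token <to_port>
# becomes <from_step.from_port>, a reference to the upstream output.
export_command <- function(spec, step_name) {
  step <- spec$steps[[step_name]]
  lk <- spec$links[spec$links$to_step == step_name, , drop = FALSE]
  if (nrow(lk) == 0L) return(step$command)
  repl <- stats::setNames(paste0("<", lk$from_step, ".", lk$from_port, ">"),
                          lk$to_port)
  rebuild_command(step, function(tok) {
    if (tok$type == "input" && tok$text %in% names(repl)) repl[[tok$text]] else NULL
  })
}

# Reassemble a command, substituting tokens.  `f(tok)` returns replacement
# text or NULL to keep the token verbatim.
rebuild_command <- function(step, f) {
  cmd <- step$command
  tok <- step$tokens
  if (nrow(tok) == 0L) return(cmd)
  pieces <- character(0)
  pos <- 1L
  for (i in seq_len(nrow(tok))) {
    pieces <- c(pieces, substr(cmd, pos, tok$start[i] - 1L))
    sub <- f(tok[i, ])
    pieces <- c(pieces, if (is.null(sub)) substr(cmd, tok$start[i], tok$end[i]) else sub)
    pos <- tok$end[i] + 1L
  }
  pieces <- c(pieces, substr(cmd, pos, nchar(cmd)))
  paste(pieces, collapse = "")
}

#' Export a workflow to its JSON document
#'
#' The document has three top-level fields: `schema_version`, `macro`
#' (macro name to default value or `null`) and `workflow`, an array of step
#' objects sorted by step name.  Each step object carries `name`, `command`
#' (with every linked input token `<port>` replaced by a reference
#' `<upstream.output_port>` to the connected upstream output), a `from`
#' array of incoming link statements (`from`/`frompid`/`topid`) and a `to`
#' array of outgoing ones (`to`/`topid`/`frompid`).  Serialization is
#' deterministic: the same spec always yields the same bytes.
#'
#' @param spec A valid `workflow_spec`.
#' @return A JSON string (class `json`).
#' @export
wf_export_json <- function(spec) {
  wf_validate(spec)
  macro <- if (length(spec$macros) > 0L) spec$macros[order(names(spec$macros))]
           else stats::setNames(list(), character())
  steps <- lapply(sort(names(spec$steps)), function(nm) {
    inc <- spec$links[spec$links$to_step == nm, , drop = FALSE]
    inc <- inc[order(inc$to_port), , drop = FALSE]
    out <- spec$links[spec$links$from_step == nm, , drop = FALSE]
    out <- out[order(out$to_step, out$to_port), , drop = FALSE]
    list(name = nm,
         command = export_command(spec, nm),
         from = unname(lapply(seq_len(nrow(inc)), function(i) {
           list(from = inc$from_step[i], frompid = inc$from_port[i],
                topid = inc$to_port[i])
         })),
         to = unname(lapply(seq_len(nrow(out)), function(i) {
           list(to = out$to_step[i], topid = out$to_port[i],
                frompid = out$from_port[i])
         })))
  })
  jsonlite::toJSON(list(schema_version = WORKFLOW_SCHEMA_VERSION,
                        macro = macro, workflow = steps),
                   auto_unbox = TRUE, null = "null", pretty = TRUE, digits = NA)
}

#' Write a workflow JSON document to a file
#' @param spec A `workflow_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
wf_write_json <- function(spec, path) {
  writeLines(wf_export_json(spec), path, useBytes = TRUE)
  invisible(path)
}

#' Import a workflow from its JSON document
#'
#' Reconstructs steps, links and macros from a document written by
#' [wf_export_json()]; `import(export(spec))` is structurally equal to
#' `spec`.  Linked input references `<upstream.port>` in commands are folded
#' back to the local `<topid>` token named by the step's `from` statements.
#'
#' @param x JSON string, or path to a JSON file.
#' @return A validated `workflow_spec`.
#' @export
wf_import_json <- function(x) {
  txt <- if (length(x) == 1L && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  for (field in c("macro", "workflow")) {
    if (is.null(doc[[field]])) {
      stop(sprintf("workflow document is missing the '%s' field", field),
           call. = FALSE)
    }
  }
  spec <- workflow_spec()
  for (m in names(doc$macro)) {
    spec <- wf_declare_macro(spec, m, doc$macro[[m]])
  }
  links <- empty_links()
  for (st in doc$workflow) {
    if (is.null(st$name) || is.null(st$command)) {
      stop("workflow step entry needs 'name' and 'command'", call. = FALSE)
    }
    cmd <- st$command
    for (fr in st$from) {
      ref <- paste0("<", fr$from, ".", fr$frompid, ">")
      cmd <- gsub(ref, paste0("<", fr$topid, ">"), cmd, fixed = TRUE)
      links <- rbind(links, data.frame(
        from_step = fr$from, from_port = fr$frompid,
        to_step = st$name, to_port = fr$topid, stringsAsFactors = FALSE))
    }
    spec <- wf_add_step(spec, st$name, cmd)
  }
  spec$links <- links
  wf_validate(spec)
  spec
}

#' @export
print.workflow_spec <- function(x, ...) {
  cat(sprintf("workflow_spec: %d steps, %d links, %d macros\n",
              length(x$steps), nrow(x$links), length(x$macros)))
  ord <- topo_order(names(x$steps), x$links)
  for (nm in ord) {
    up <- unique(x$links$from_step[x$links$to_step == nm])
    cat(sprintf("  %s%s\n", nm,
                if (length(up)) paste0("  <- ", paste(up, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' @export
print.workflow_step <- function(x, ...) {
  cat(sprintf("step '%s': %s\n  inputs: %s\n  outputs: %s\n  macros: %s\n",
              x$name, x$command,
              paste(x$inputs, collapse = ", "),
              paste(x$outputs, collapse = ", "),
              paste(x$macros, collapse = ", ")))
  invisible(x)
}
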