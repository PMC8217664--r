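# Shared helpers: independent oracles and small utilities the tests use to
# check the package against brute-force implementations.

tmp_run_dir <- function(name = "run") {
  d <- file.path(tempfile("dagcall-"), name)
  dir.create(dirname(d), recursive = TRUE, showWarnings = FALSE)
  d
}

read_stamp <- function(workdir, file) {
  as.numeric(readLines(file.path(workdir, file), warn = FALSE)[1])
}

# Start/finish timestamps written by the stub steps of a fixture run.
collect_timestamps <- function(run_dir, step_names) {
  do.call(rbind, lapply(step_names, function(s) {
    wd <- file.path(run_dir, s)
    data.frame(step = s,
               start = read_stamp(wd, "start.t"),
               finish = read_stamp(wd, "finish.t"),
               stringsAsFactors = FALSE)
  }))
}

runs_count <- function(run_dir, step) {
  f <- file.path(run_dir, step, "runs.t")
  if (!file.exists(f)) 0L else length(readLines(f, warn = FALSE))
}

# Independent DAG oracle via igraph: is the link set acyclic?
igraph_is_dag <- function(step_names, links) {
  g <- igraph::graph_from_data_frame(
    if (nrow(links) > 0L) links[, c("from_step", "to_step")]
    else data.frame(from = character(), to = character()),
    directed = TRUE,
    vertices = data.frame(name = step_names))
  igraph::is_dag(g)
}

# Brute-force consensus oracle: dictionary of normalized-key -> caller set,
# built with nothing but normalize_variant() and base R set arithmetic.
oracle_evidence <- function(vcf_sets) {
  dict <- list()
  for (cn in names(vcf_sets)) {
    df <- vcf_sets[[cn]]
    for (i in seq_len(nrow(df))) {
      k <- normalize_variant(df$chrom[i], df$pos[i], df$ref[i], df$alt[i])
      key <- paste(k$chrom, k$pos, k$ref, k$alt, sep = ":")
      dict[[key]] <- union(dict[[key]], cn)
    }
  }
  dict
}

oracle_candidate_count <- function(dict, min_callers) {
  sum(vapply(dict, length, integer(1)) >= min_callers)
}

# Structural workflow equality: same steps (name/command/ports/macros),
# same link set, same macro table.
expect_spec_equal <- function(a, b) {
  expect_setequal(names(a$steps), names(b$steps))
  for (nm in names(a$steps)) {
    expect_identical(a$steps[[nm]]$command, b$steps[[nm]]$command)
    expect_identical(a$steps[[nm]]$inputs, b$steps[[nm]]$inputs)
    expect_identical(a$steps[[nm]]$outputs, b$steps[[nm]]$outputs)
    expect_identical(a$steps[[nm]]$macros, b$steps[[nm]]$macros)
  }
  key <- function(s) sort(paste(s$links$from_step, s$links$from_port,
                                s$links$to_step, s$links$to_port))
  expect_identical(key(a), key(b))
  expect_identical(a$macros[sort(names(a$macros))], b$macros[sort(names(b$macros))])
}

cohort_dir <- function() file.path(tempfile("cohort-"))
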