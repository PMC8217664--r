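# Synthetic fixtures: stub-command workflows with a known execution oracle,
# and toy multi-caller VCF cohorts with a ground-truth evidence table.
# Stub commands are plain shell one-liners (timestamp files, sleep, exit),
# so engine tests need no bioinformatics tools.

#' Generate a random stub workflow with an execution oracle
#'
#' Builds an acyclic workflow of `n_steps` stub steps; edges run only from
#' lower to higher rank, so the graph is a DAG by construction.  Each stub
#' writes `start.t` and `finish.t` wall-clock timestamp files and appends
#' to `runs.t` (an execution counter), which lets tests check scheduling
#' soundness (every edge's upstream finish precedes the downstream start)
#' and that no step ever runs twice across resume.  Generation is
#' seed-deterministic.
#'
#' @param n_steps Number of steps.
#' @param edge_probability Probability of an edge between any ordered step
#'   pair.
#' @param seed Random seed.
#' @param step_kind `"instant"` (default), `"sleep"` (adds
#'   `sleep sleep_seconds`), matching the stub's runtime profile.
#' @param sleep_seconds Sleep duration for `step_kind = "sleep"`.
#' @param fail_at Optional index of a step forced to exit nonzero.
#' @return List with `spec` (the `workflow_spec`), `bindings`, `edges`
#'   (data frame `from`/`to` of step names), and `expected_success(fail_at)`,
#'   a brute-force reachability oracle returning the step names that must
#'   succeed when the given step fails (dependents of the failure never
#'   run).
#' @export
make_workflow_fixture <- function(n_steps, edge_probability = 0.25, seed = 1L,
                                  step_kind = c("instant", "sleep"),
                                  sleep_seconds = 1, fail_at = NULL) {
  step_kind <- match.arg(step_kind)
  stopifnot(n_steps >= 1L)
  set.seed(seed)
  nm <- sprintf("s%02d", seq_len(n_steps))
  edges <- list()
  if (n_steps > 1L) {
    for (i in seq_len(n_steps - 1L)) {
      for (j in seq.int(i + 1L, n_steps)) {
        if (stats::runif(1) < edge_probability) {
          edges[[length(edges) + 1L]] <- c(nm[i], nm[j])
        }
      }
    }
  }
  edges <- if (length(edges) > 0L) {
    data.frame(from = vapply(edges, `[`, character(1), 1L),
               to = vapply(edges, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  } else data.frame(from = character(), to = character(), stringsAsFactors = FALSE)

  spec <- workflow_spec()
  for (i in seq_len(n_steps)) {
    ins <- edges$from[edges$to == nm[i]]
    in_tokens <- if (length(ins) > 0L) {
      paste(sprintf("cat <in_%s> > /dev/null;", ins), collapse = " ")
    } else ""
    body <- c("date +%s.%N > start.t;",
              if (step_kind == "sleep") sprintf("sleep %s;", format(sleep_seconds)),
              in_tokens,
              "date +%s.%N > finish.t;",
              "echo 1 >> runs.t;",
              if (!is.null(fail_at) && i == fail_at) "exit 1;",
              sprintf("echo %s > [done]", nm[i]))
    spec <- wf_add_step(spec, nm[i], paste(body[nzchar(body)], collapse = " "))
  }
  for (k in seq_len(nrow(edges))) {
    spec <- wf_link(spec, edges$from[k], "done", edges$to[k],
                    paste0("in_", edges$from[k]))
  }

  reach_from <- function(start) {
    seen <- start
    frontier <- start
    while (length(frontier) > 0L) {
      nxt <- setdiff(unique(edges$to[edges$from %in% frontier]), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  expected_success <- function(fail_at = NULL) {
    if (is.null(fail_at)) return(nm)
    failed <- nm[fail_at]
    setdiff(nm, reach_from(failed))
  }

  list(spec = spec, bindings = list(), edges = edges,
       expected_success = expected_success)
}

#' Build a linear chain of stub steps
#' @param n Number of steps.
#' @param fail_at Optional index of a step forced to exit nonzero.
#' @return A `workflow_spec` `s01 -> s02 -> ... -> sNN`.
#' @export
make_chain_workflow <- function(n, fail_at = NULL) {
  spec <- workflow_spec()
  nm <- sprintf("s%02d", seq_len(n))
  for (i in seq_len(n)) {
    prev <- if (i > 1L) "cat <prev> > /dev/null; " else ""
    fail <- if (!is.null(fail_at) && i == fail_at) "exit 1; " else ""
    spec <- wf_add_step(spec, nm[i], sprintf(
      "date +%%s.%%N > start.t; %sdate +%%s.%%N > finish.t; echo 1 >> runs.t; %secho %s > [done]",
      prev, fail, nm[i]))
  }
  for (i in seq_len(n - 1L)) {
    spec <- wf_link(spec, nm[i], "done", nm[i + 1L], "prev")
  }
  spec
}

#' Build a diamond workflow a -> {b, c} -> d of stub steps
#' @param sleep_seconds Sleep duration of the two middle steps.
#' @return A `workflow_spec`.
#' @export
make_diamond_workflow <- function(sleep_seconds = 1) {
  stamp <- function(extra = "") sprintf(
    "date +%%s.%%N > start.t; %sdate +%%s.%%N > finish.t; echo 1 >> runs.t; ",
    extra)
  spec <- workflow_spec()
  spec <- wf_add_step(spec, "a", paste0(stamp(), "echo a > [out]"))
  mid <- sprintf("cat <src> > /dev/null; sleep %s; ", format(sleep_seconds))
  spec <- wf_add_step(spec, "b", paste0(stamp(mid), "echo b > [out]"))
  spec <- wf_add_step(spec, "c", paste0(stamp(mid), "echo c > [out]"))
  spec <- wf_add_step(spec, "d",
                      paste0(stamp("cat <left> <right> > /dev/null; "),
                             "echo d > [out]"))
  spec <- wf_link(spec, "a", "out", "b", "src")
  spec <- wf_link(spec, "a", "out", "c", "src")
  spec <- wf_link(spec, "b", "out", "d", "left")
  spec <- wf_link(spec, "c", "out", "d", "right")
  spec
}

DEFAULT_CALLERS <- c("strelka2", "vardict", "varscan2", "pindel")

#' Generate a toy multi-caller VCF cohort with ground truth
#'
#' Writes one syntactically valid VCFv4.2 file per caller for a single
#' tumor/normal pair, with seeded caller membership, allele fractions,
#' depths and population allele frequencies, plus a truth table giving
#' every variant's true caller set — so consensus results are checkable
#' exactly.  To exercise normalization, a fraction of the records are
#' written in a padded representation (shared flanking bases around the
#' minimal alleles) that differs between callers but normalizes to the
#' same key.  A fraction of the variants are "spiked" with a population
#' frequency above 1% and marked `is_common` in the truth table.
#' Generation is seed-deterministic and byte-stable.
#'
#' @param out_dir Directory for the VCF files (created if needed).
#' @param n_variants Number of distinct variants.
#' @param n_callers Number of callers (named from strelka2, vardict,
#'   varscan2, pindel, then `callerN`).
#' @param seed Random seed.
#' @param p_caller Per-caller membership probability for each variant
#'   (every variant is reported by at least one caller).
#' @param vaf_range Tumor allele-fraction range.
#' @param depth_range Tumor/normal depth range.
#' @param popfreq_spike_fraction Fraction of variants spiked with a
#'   population frequency above 0.01.
#' @param pad_fraction Probability that a caller writes a given variant in
#'   padded (non-minimal) representation.
#' @param indel_fraction Fraction of variants that are indels.
#' @return List with `files` (named vector caller -> VCF path), `truth`
#'   (data frame with `key`, `chrom`, `pos`, `ref`, `alt`, `class`,
#'   `callers`, `n_callers`, `vaf`, `t_depth`, `n_depth`, `is_common` and
#'   `pf_*` columns) and `callers`.
#' @export
make_vcf_cohort <- function(out_dir, n_variants = 200L, n_callers = 4L,
                            seed = 1L, p_caller = 0.55,
                            vaf_range = c(0.02, 0.4),
                            depth_range = c(600L, 1500L),
                            popfreq_spike_fraction = 0.1,
                            pad_fraction = 0.35,
                            indel_fraction = 0.3) {
  stopifnot(n_variants >= 1L, n_callers >= 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  callers <- c(DEFAULT_CALLERS, sprintf("caller%d", seq_len(max(0L, n_callers - 4L)) + 4L))
  callers <- callers[seq_len(n_callers)]
  bases <- c("A", "C", "G", "T")
  chroms <- c("chr1", "chr2", "chr3")

  chrom <- sample(chroms, n_variants, replace = TRUE)
  pos <- integer(n_variants)
  for (cr in chroms) {
    ii <- which(chrom == cr)
    pos[ii] <- 10000L + cumsum(sample(10:60, length(ii), replace = TRUE))
  }
  is_indel <- stats::runif(n_variants) < indel_fraction
  ref <- alt <- character(n_variants)
  for (i in seq_len(n_variants)) {
    if (!is_indel[i]) {
      ref[i] <- sample(bases, 1L)
      alt[i] <- sample(setdiff(bases, ref[i]), 1L)
    } else {
      anchor <- sample(bases, 1L)
      # event must not end with the anchor base: such indels are ambiguous
      # (left-alignable) without a reference, and the truth table is exact
      ev_len <- sample(1:3, 1L)
      event <- paste(c(if (ev_len > 1L) sample(bases, ev_len - 1L, replace = TRUE),
                       sample(setdiff(bases, anchor), 1L)), collapse = "")
      if (stats::runif(1) < 0.5) {            # deletion
        ref[i] <- paste0(anchor, event); alt[i] <- anchor
      } else {                                # insertion
        ref[i] <- anchor; alt[i] <- paste0(anchor, event)
      }
    }
  }
  membership <- matrix(stats::runif(n_variants * n_callers) < p_caller,
                       nrow = n_variants)
  for (i in which(rowSums(membership) == 0L)) {
    membership[i, sample(n_callers, 1L)] <- TRUE
  }
  vaf <- round(stats::runif(n_variants, vaf_range[1], vaf_range[2]), 4)
  t_depth <- sample(depth_range[1]:depth_range[2], n_variants, replace = TRUE)
  n_depth <- sample(depth_range[1]:depth_range[2], n_variants, replace = TRUE)

  n_common <- round(popfreq_spike_fraction * n_variants)
  common_idx <- sample(n_variants, n_common)
  pf <- matrix(NA_real_, nrow = n_variants, ncol = length(POPFREQ_KEYS),
               dimnames = list(NULL, names(POPFREQ_KEYS)))
  for (i in seq_len(n_variants)) {
    present <- stats::runif(length(POPFREQ_KEYS)) < 0.4
    pf[i, present] <- round(stats::runif(sum(present), 0, 0.009), 5)
  }
  for (i in common_idx) {
    src <- sample(length(POPFREQ_KEYS), 1L)
    pf[i, src] <- round(stats::runif(1, 0.011, 0.2), 5)
  }
  is_common <- seq_len(n_variants) %in% common_idx

  pad_flag <- matrix(stats::runif(n_variants * n_callers) < pad_fraction,
                     nrow = n_variants)
  files <- stats::setNames(character(n_callers), callers)
  for (k in seq_len(n_callers)) {
    sel <- which(membership[, k])
    p2 <- pos[sel]; r2 <- ref[sel]; a2 <- alt[sel]
    for (j in seq_along(sel)) {
      i <- sel[j]
      if (pad_flag[i, k]) {
        left <- sample(bases, 1L); right <- sample(bases, 1L)
        p2[j] <- p2[j] - 1L
        r2[j] <- paste0(left, r2[j], right)
        a2[j] <- paste0(left, a2[j], right)
      }
    }
    info <- vapply(seq_along(sel), function(j) {
      i <- sel[j]
      kv <- sprintf("%s=%g", POPFREQ_KEYS[!is.na(pf[i, ])], pf[i, !is.na(pf[i, ])])
      if (length(kv) == 0L) "." else paste(kv, collapse = ";")
    }, character(1))
    gt_t <- sprintf("0/1:%d,%d:%g:%d",
                    round(t_depth[sel] * (1 - vaf[sel])),
                    round(t_depth[sel] * vaf[sel]),
                    vaf[sel], t_depth[sel])
    gt_n <- sprintf("0/0:%d,0:0:%d", n_depth[sel], n_depth[sel])
    rows <- data.frame(chrom = chrom[sel], pos = p2, ref = r2, alt = a2,
                       info = info, gt_n = gt_n, gt_t = gt_t,
                       stringsAsFactors = FALSE)
    rows <- rows[order(match(rows$chrom, chroms), rows$pos), , drop = FALSE]
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##source=%s", callers[k]),
             sprintf("##contig=<ID=%s>", chroms),
             vapply(seq_along(POPFREQ_KEYS), function(s) sprintf(
               "##INFO=<ID=%s,Number=1,Type=Float,Description=\"Population AF\">",
               POPFREQ_KEYS[s]), character(1)),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR")
    body <- paste(rows$chrom, rows$pos, ".", rows$ref, rows$alt, "60", "PASS",
                  rows$info, "GT:AD:AF:DP", rows$gt_n, rows$gt_t, sep = "\t")
    files[k] <- file.path(out_dir, paste0(callers[k], ".vcf"))
    writeLines(c(hdr, body), files[k])
  }

  truth <- data.frame(
    key = paste(chrom, pos, ref, alt, sep = ":"),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    class = variant_class(ref, alt),
    callers = apply(membership, 1L, function(m) paste(callers[m], collapse = ",")),
    n_callers = as.integer(rowSums(membership)),
    vaf = vaf, t_depth = t_depth, n_depth = n_depth,
    is_common = is_common, stringsAsFactors = FALSE)
  for (s in names(POPFREQ_KEYS)) truth[[paste0("pf_", s)]] <- pf[, s]
  truth <- truth[order(match(truth$chrom, chroms), truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(files = files, truth = truth, callers = callers)
}

#' Build the bundled somatic-analysis stub workflow
#'
#' Mirrors the topology of a tumor/normal whole-exome somatic pipeline —
#' qc -> align -> four parallel caller steps -> merge -> report — with
#' stub commands: the caller steps copy pre-generated cohort VCFs, and the
#' merge/report steps call back into this package's command-line interface
#' through `Rscript`.  Serves as living documentation of the markup
#' grammar and as the end-to-end test workflow.
#'
#' @param lib_paths Library paths embedded in the `Rscript` calls so the
#'   stub steps can load this package from a child process; `NULL` embeds
#'   none (the child uses its default library paths), which is what the
#'   portable copy under `inst/extdata/` ships.
#' @return A `workflow_spec` using macros `VCFDIR` (directory holding
#'   `<caller>.vcf` files), `SAMPLE`, `TARGETBP`, and the external input
#'   port `<fq>`.
#' @export
example_somatic_workflow <- function(lib_paths = .libPaths()) {
  libs <- if (is.null(lib_paths)) "" else
    sprintf(".libPaths(%s); ", paste(deparse(lib_paths), collapse = ""))
  rscript <- sprintf("Rscript -e '%sinvisible(quit(status=dagcall::cli_dispatch(commandArgs(TRUE))))'",
                     libs)
  spec <- workflow_spec()
  spec <- wf_add_step(spec, "qc",
    "cat <fq> > /dev/null; echo clean > [clean]")
  spec <- wf_add_step(spec, "align",
    "cat <clean> > /dev/null; echo bam > [bam]")
  for (cal in DEFAULT_CALLERS) {
    spec <- wf_add_step(spec, cal,
      sprintf("cat <bam> > /dev/null; cp #VCFDIR#/%s.vcf [vcf]", cal))
    spec <- wf_link(spec, "align", "bam", cal, "bam")
  }
  spec <- wf_add_step(spec, "merge", paste0(
    rscript,
    " merge --caller strelka2=<v1> --caller vardict=<v2>",
    " --caller varscan2=<v3> --caller pindel=<v4>",
    " --min-callers 2 --min-vaf 0.01 --sample #SAMPLE#",
    " --out [merged] --table [candidates]"))
  spec <- wf_add_step(spec, "report", paste0(
    rscript,
    " maf --in <merged> --sample #SAMPLE# --popfreq-threshold 0.01",
    " --target-bp #TARGETBP# --out [results]"))
  spec <- wf_link(spec, "qc", "clean", "align", "clean")
  ports <- c(strelka2 = "v1", vardict = "v2", varscan2 = "v3", pindel = "v4")
  for (cal in names(ports)) {
    spec <- wf_link(spec, cal, "vcf", "merge", ports[[cal]])
  }
  spec <- wf_link(spec, "merge", "merged", "report", "merged")
  spec <- wf_declare_macro(spec, "SAMPLE", "S1")
  spec <- wf_declare_macro(spec, "TARGETBP", "1760000")
  spec
}
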