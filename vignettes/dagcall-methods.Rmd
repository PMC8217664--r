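---
title: "dagcall: methods, design decisions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dagcall: methods, design decisions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dagcall)
```

`dagcall` couples a small workflow engine to a multi-caller somatic
variant consensus layer. This vignette explains the model behind each
part, the parameters that matter, the numerical and design choices made
where more than one reasonable option existed, and what the synthetic
fixtures do and do not demonstrate about real sequencing data.

## 1. The workflow model

A workflow is a directed acyclic graph whose nodes are *steps* — plain
shell command lines — and whose edges are *port links*. The markup
grammar annotates a command with its data flow: `<name>` marks an input
port, `[name]` an output port, `#NAME#` a macro. Step and port names use
`[a-z0-9_]+`, macro names `[A-Z0-9_]+`, so the two namespaces cannot
collide. A literal `#` is written `##`; without that escape the paired
`#NAME#` notation would be ambiguous. The scanner treats every `<`, `[`
and `#` as opening a token, which means bare shell redirection characters
are fine but constructs like `sort < file` must be written with the file
as a port or the redirection dropped. Tokenization is a partition of the
command string: tests verify that re-inserting the extracted tokens at
their recorded offsets reconstructs the command byte for byte.

### Serialization

The exported JSON document has `schema_version`, `macro` (name to default
or `null`) and `workflow` (step objects sorted by name, each with incoming
`from` and outgoing `to` link statements carrying `frompid`/`topid`).
Two choices deserve a note:

* **Ports are identified by name, not position.** `frompid`/`topid` hold
  port names; names survive command edits that reorder tokens, positions
  do not.
* **Export rewrites linked inputs.** A linked input token `<reads>`
  serializes as `<qc.clean1>` — a visible reference to the upstream
  output. Import folds the reference back using the `from` statements, so
  `import(export(s))` is structurally equal to `s` and export is
  byte-stable (sorted steps, sorted links, fixed JSON formatting). This
  idempotence is what the round-trip tests assert.

Fan-out is allowed (one output port may feed any number of downstream
inputs); each downstream input port accepts at most one incoming link.

### Rendering

`wf_render()` maps the abstract spec to concrete commands under a run
directory. Each step owns `run_dir/<step>/` as its working directory; an
output port `[p]` resolves to the file `p` in that directory; a linked
input resolves to the upstream output's path; an *unlinked* input port is
an external input and resolves from the bindings entry of the same
(lowercase) name, while macros resolve from the (uppercase) bindings or
their declared defaults. The lowercase/uppercase split lets one flat
bindings file serve both roles unambiguously. Rendering is a pure
function of (spec, bindings, run directory).

## 2. The execution engine

The scheduler maintains the classic ready-set loop: launch every step
whose upstream steps have all succeeded, up to `max_parallel`
concurrently; when a running step finishes, recompute the ready set;
repeat until nothing is running or launchable. Choices made where the
behavior was genuinely open:

* **Success is exit status zero.** Commands run through `sh` in the
  step's working directory with the parent environment.
* **Failure policy is fail-downstream-only.** A failure never cancels
  running steps and never blocks independent branches; it only prevents
  its own dependents from starting. This maximizes the work a subsequent
  resume can skip.
* **Tie-break is lexicographic.** Among equally ready steps the
  lexicographically smallest name launches first, so a serial run
  (`max_parallel = 1`) has a fixed topological launch order and
  byte-identical command logs across repeats.
* **`max_parallel` defaults to the processor count.**
* **Process supervision is sentinel-file based.** Each step runs under a
  tiny wrapper script that executes the command in a subshell, captures
  its stdout/stderr, and then writes the exit status to a `.step.exit`
  sentinel; the scheduler polls sentinels (5 ms interval). The sentinel
  write is the completion signal, so a status is never read before it is
  durable, and a command that calls `exit` cannot skip it.

Four auxiliary files named after the run directory's basename record the
run: `<run>.command.log` (every launched concrete command, in launch
order), `<run>.ok.log` (successful steps, appended and flushed *before*
any dependent is considered ready), `<run>.out` / `<run>.err`
(concatenated child output, delimited per step). Children write to
per-step files during execution and the two aggregate files are assembled
at the end; real-time interleaving is deliberately not promised.

### Checkpoint and resume

`wf_resume()` re-renders the workflow, marks every step listed in the
ok-log as succeeded without re-spawning it, and schedules the remainder.
Because ok-log entries are flushed before dependents become ready, any
interruption point leaves a consistent checkpoint: the tests interrupt a
six-step chain and a six-step diamond after every possible completion
count and verify that partial run + resume produces the same output tree
as an uninterrupted run with no step executed twice. Staleness is
detected by a fingerprint (MD5 over the exported workflow JSON and the
sorted bindings) stored in the run directory; resume refuses on mismatch
or on an ok-log entry naming an unknown step. Interruption in tests is
cooperative (`interrupt_after` stops launching after *k* completions);
kill-signal interruption exercises the same code path because the
checkpoint is already on disk either way.

## 3. Variant normalization and consensus

Callers emit the same event in different VCF spellings: padded alleles,
right-anchored indels, multi-allelic rows. Comparison therefore operates
on *normalized keys* (chrom, pos, ref, alt):

1. multi-allelic rows are split into bi-allelic records at read time;
2. the shared allele suffix is trimmed (never below one base on both
   sides simultaneously);
3. if an allele empties, the reference base to the left is prepended and
   the position decremented — this re-anchors right-anchored indels and,
   iterated, left-aligns through repeat runs; without a reference window
   this situation is an explicit error rather than a guess;
4. the shared prefix is trimmed while advancing the position.

The operation is idempotent (property-tested on 10,000 random allele
pairs). Matching across callers is **exact key equality** — no fuzzy
position-window matching — because only an exact rule is deterministic
and checkable against a brute-force oracle. Variants whose minimal form
is ambiguous without a reference (e.g. indels in homopolymer runs
presented right-anchored) normalize only when a reference window is
supplied.

Each caller receives a small integer code in registration order; codes
identify callers in the evidence annotations and deliberately carry no
priority semantics. The merged record keeps the evidence set, per-caller
allele fraction and depths, and the per-source maximum population
frequency.

### Candidate selection

`filter_policy()` defaults: `min_callers = 2` (the
at-least-two-callers consensus rule), `min_vaf = 0.01` (strictly greater
than), depth filter disabled. `min_depth = 500` with
`apply_depth_to = "both"` reproduces a deep-panel baseline of at least
500× in tumor and normal. Interpretations where the rule needed
sharpening:

* The VAF test uses the **maximum** per-caller allele fraction, read
  from FORMAT `AF`, then `FREQ` (percent style), then an `AD`-derived
  ratio, then INFO `AF` — callers encode it differently.
* The depth test requires every supporting caller **that reports** the
  designated depth field to meet the threshold; a caller that omits the
  field does not fail the record. Records with no VAF data anywhere are
  likewise not failed by the VAF test.
* Non-PASS FILTER records are excluded at read time by default
  (`keep_filtered = TRUE` overrides).

## 4. Population-frequency filter, MAF, summary statistics

The population frequency of a record is the **maximum over the sources
that report it** (defaults map the four usual databases to the INFO keys
`AF_1000G`, `AF_GNOMAD`, `AF_ESP`, `AF_EXAC`; both the keys and the
sidecar route are overridable). A record is dropped when that maximum
exceeds the threshold (1% by default); a record with no frequency data
anywhere is **kept** — the filter removes proven-common loci only, which
is the conservative direction for somatic candidates.

MAF conversion follows the TCGA conventions, spelled out exactly:
coordinates are 1-based inclusive; an SNP keeps its position; a deletion
drops the VCF anchor base, starts one base right of it, and writes `-`
as the tumor allele; an insertion spans its two flanking positions with
`-` as the reference allele. The anchor base is not representable in
MAF, so recovering a VCF key from an indel MAF row requires it
(`maf_to_key(..., anchor =)`); the round-trip property test supplies it.
Unannotated records get gene `Unknown` and classification
`Targeted_Region` (a package convention). Functional annotation itself
is consumed, never computed: gene/classification pairs enter through a
sidecar table, and pathogenicity scoring is reduced to an optional
user-supplied gene list that flags report rows.

Summary statistics: transitions are A↔G and C↔T; all other single-base
substitutions are transversions; Ti/Tv with zero transversions (or no
SNVs at all) is reported as `NA`, not an error. TMB is qualifying
variants per megabase of the supplied target size — by default all
surviving SNVs and indels, configurable to subsets via `tmb_classes`;
TMB without a target size is simply not computed, and a zero or negative
target size is an error. The report writes self-contained HTML in three
sections (commands/parameters, QC metrics passed through from upstream
tools when present, mutation landscape) plus a JSON twin of every
number; regeneration from the same inputs is byte-identical, and missing
sections render as explicit "not available" markers.

## 5. Synthetic fixtures: what they show and what they cannot

The fixtures module generates both study objects in code, seeded and
byte-stable:

* **Stub workflows** (`make_workflow_fixture()`): random DAGs whose edges
  only go from lower to higher rank (acyclic by construction), with stub
  commands that record start/finish wall-clock timestamps and an
  execution counter. The accompanying oracle computes the dependency
  closure by brute-force reachability, predicting exactly which steps
  survive an injected failure. None of the fixture parameters model real
  pipelines; they are chosen to keep a single test case well under a
  second.
* **Toy VCF cohorts** (`make_vcf_cohort()`): a single tumor/normal pair,
  3–5 callers, seeded caller membership (default per-caller probability
  0.55, every variant reported at least once), tumor VAF uniform in
  0.02–0.4, depths uniform in 600–1500, 10% of variants spiked with a
  population frequency above 1% and marked in the truth table, and 35%
  of caller records written in a padded (non-minimal) representation to
  force the normalizer to earn its keep. Generated indel events never
  end in their own anchor base, so every fixture variant has a unique
  minimal form without a reference genome and the truth table is exact.

These fixtures make the *logic* fully checkable: evidence sets equal a
brute-force dictionary-of-sets oracle, filters remove exactly the
truth-marked records, and the end-to-end stub pipeline's report totals
equal the truth table's. What they do **not** emulate: real caller error
profiles and disagreements beyond representation (the fixture's caller
membership is random, real callers disagree systematically), sequencing
noise, strand bias, mutational signatures (substitutions are uniform, so
fixture Ti/Tv sits near 0.5 rather than an exome's 2–3), or reference
context (no homopolymer ambiguity by construction). Passing tests
therefore demonstrate correctness of the consensus arithmetic and
plumbing, not calling accuracy on real tumors.

### Problem sizes used by the test suite and acceptance script

Scheduling soundness runs 200 seeded DAGs of 2–30 stub steps
(about 7,600 edges checked); crash-resume covers all five interruption
points of a six-step chain and a six-step diamond; the consensus oracle
runs 100 cohorts of 40–425 variants and 3–5 callers; normalization
idempotence samples 10,000 random allele pairs. These sizes give each
property thousands of independent trials while keeping a full run of the
suite in the minutes range on a single core.

## 6. Known limitations

* The engine targets POSIX systems: steps run under `sh`, and stub
  fixtures use `date +%s.%N`.
* No cluster submission, containers, retry policies, or real-time log
  interleaving; `.out`/`.err` are assembled per step at run end.
* The grammar reserves `<`, `[` and `#` in commands; shell input
  redirection must be expressed through ports or escapes.
* Consensus matching is exact-key; a caller that reports a genuinely
  different-but-overlapping event (e.g. an MNP spanning an SNV) counts
  as separate evidence.
* CNVs and structural variants are out of scope, as is running the
  upstream tools themselves; the engine executes whatever commands the
  workflow declares.
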