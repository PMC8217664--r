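# dagcall

Cancer genome sequencing analysis chains a dozen command-line tools —
read trimming, alignment, several variant callers, annotation — and every
caller disagrees with every other about which somatic mutations are real.
`dagcall` packages the two pieces of plumbing that problem needs:

1. **A lightweight workflow system.** Pipeline steps are ordinary shell
   command lines annotated with a three-token markup grammar. Workflows are
   exported to a port-linked JSON document, rendered against a macro
   bindings file, and executed as a directed acyclic graph (DAG): steps
   with no unmet dependencies launch in parallel, every successful step is
   checkpointed, and an interrupted run resumes from the last error point
   without re-executing finished work.

2. **A multi-caller somatic variant consensus layer.** Per-caller VCFs for
   one tumor/normal pair are normalized to minimal left-aligned keys,
   merged into a single caller-evidence-tagged variant list, filtered by
   the *supported-by-at-least-k-callers* rule (k = 2 by default) together
   with allele-fraction, depth and population-frequency cutoffs, converted
   to the Mutation Annotation Format (MAF), and summarized in a three-part
   statistical report (commands, QC pass-through, mutation landscape with
   Ti/Tv and TMB).

It is aimed at people who run tumor/normal panels or exomes and want a
reproducible, resumable pipeline without adopting a heavyweight workflow
DSL, plus a deterministic, testable consensus rule across callers such as
Strelka2, VarDict, VarScan 2 and Pindel.

## The workflow markup grammar

A step is a named shell command. Three token kinds carry the structure:

| token | meaning |
|---|---|
| `<name>`  | an input port (lowercase letters, digits, underscores) |
| `[name]`  | an output port; resolves to the file `name` in the step's own working directory |
| `#NAME#`  | a macro (uppercase), bound at render time; `##` is a literal `#` |

```r
library(dagcall)

spec <- workflow_spec()
spec <- wf_add_step(spec, "qc",  "fastp -i <r1> -o [clean1] -w #THREADS#")
spec <- wf_add_step(spec, "bwa", "bwa mem #REF# <reads> > [bam]")
spec <- wf_link(spec, "qc", "clean1", "bwa", "reads")
wf_export_json(spec)
```

The exported document has the fields `macro` and `workflow`; linking
`qc.clean1` to `bwa.reads` rewrites the downstream command to reference
the upstream output:

```json
"command": "bwa mem #REF# <qc.clean1> > [bam]",
"from": [{"from": "qc", "frompid": "clean1", "topid": "reads"}]
```

`wf_run(spec, bindings, run_dir)` renders and executes. Each step gets its
own subdirectory of the run directory, and four auxiliary files record the
run: `<run>.command.log` (every executed command, launch order),
`<run>.ok.log` (the append-only checkpoint used by `--resume`),
`<run>.out` and `<run>.err` (per-step-delimited child output). A step
succeeds iff its shell exits zero; on failure, independent branches keep
running but nothing downstream of the failure starts.

## Consensus calling: a worked example

The package generates its own toy cohorts, so the example is fully
reproducible:

```r
library(dagcall)

co   <- make_vcf_cohort(tempfile("cohort-"), n_variants = 80, seed = 42)
sets <- lapply(co$files, read_caller_vcf)   # strelka2, vardict, varscan2, pindel
vs   <- merge_callers(sets)
cand <- select_candidates(vs, filter_policy(min_callers = 2, min_vaf = 0.01))
surv <- popfreq_filter(cand, threshold = 0.01)
summarize_variants(surv, target_size_bp = 1.76e6)
```

```
mutation_summary: 58 variants
  type proportions: DEL 0.155, INS 0.190, SNP 0.655
  Ti/Tv: 0.357 (10/28)
  TMB: 32.955 mutations/Mb (target 1760000 bp)
```

Reading the numbers: 80 seeded variants collapse to 63 candidates
supported by at least two callers; 5 of those are spiked "common"
variants (population allele frequency above 1% in gnomAD/1000G/ESP/ExAC
style INFO keys) and are filtered out, leaving 58. Transitions are
A↔G/C↔T substitutions; the toy generator draws substitutions uniformly,
so its Ti/Tv hovers around the random 1/2, not the ~2–3 of real exomes.
TMB is survivors per megabase of the supplied target territory.

`vcf_to_maf()` converts the survivors to MAF rows (TCGA coordinate
conventions, with caller evidence carried in extra columns) and
`render_report()` writes `report.html` plus a machine-readable
`report.json` twin.

## Command-line interface

A thin wrapper over the same functions is installed as `exec/dagcall`:

```
dagcall run wes_somatic.json --macros bindings.txt --out run_dir --max-parallel 4
dagcall run wes_somatic.json --macros bindings.txt --out run_dir --resume
dagcall merge --caller strelka2=a.vcf --caller vardict=b.vcf \
        --min-callers 2 --min-vaf 0.01 --out merged.vcf
dagcall maf --in merged.vcf --sample S1 --popfreq-threshold 0.01 \
        --target-bp 1760000 --out outdir/
dagcall fixture cohort --n-variants 200 --seed 1 --out cohort/
```

`inst/extdata/wes_somatic_stub.json` is a bundled stub pipeline with the
topology of a tumor/normal exome analysis (qc → align → four parallel
caller steps → merge → report) whose caller steps copy fixture VCFs; it
doubles as living documentation and as the end-to-end test workflow.

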