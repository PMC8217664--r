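# Population-frequency filter, MAF conversion, summary statistics, report.

as_vset <- function(df) {
  df$key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  df$class <- dagcall:::variant_class(df$ref, df$alt)
  structure(list(records = df, per_caller = NULL, registry = NULL,
                 contigs = unique(df$chrom)), class = "variant_set")
}

test_that("population-frequency filter takes the max over present sources", {
  df <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "T",
                   pf_gnomad = c(0.02, NA, 0.005, 0.009),
                   pf_exac = c(NA, NA, 0.009, 0.011),
                   stringsAsFactors = FALSE)
  out <- popfreq_filter(as_vset(df), threshold = 0.01)
  # row 1 dropped (0.02), row 2 kept (no data), row 3 kept (max 0.009),
  # row 4 dropped (exac 0.011)
  expect_identical(out$records$pos, c(2L, 3L))
})

test_that("population-frequency filter is monotone with exact boundaries", {
  d <- cohort_dir()
  co <- make_vcf_cohort(d, n_variants = 100, seed = 23,
                        popfreq_spike_fraction = 0.2)
  vs <- merge_callers(lapply(co$files, read_caller_vcf))
  survivors <- function(thr) nrow(popfreq_filter(vs, thr)$records)
  expect_identical(survivors(0.01), sum(!co$truth$is_common))
  thrs <- c(0, 0.005, 0.01, 0.05, 1)
  expect_true(all(diff(sapply(thrs, survivors)) >= 0))
  expect_identical(survivors(1), nrow(vs$records))
  pf <- as.matrix(co$truth[, grep("^pf_", names(co$truth))])
  any_nonzero <- apply(pf, 1, function(x) any(!is.na(x) & x > 0))
  expect_identical(survivors(0), sum(!any_nonzero))
  unlink(d, recursive = TRUE)
})

test_that("MAF coordinates follow the SNP/DEL/INS conventions", {
  df <- data.frame(chrom = "chr1", pos = c(101L, 100L, 100L),
                   ref = c("A", "CA", "C"), alt = c("T", "C", "CT"),
                   stringsAsFactors = FALSE)
  maf <- vcf_to_maf(as_vset(df), sample_id = "S1")
  expect_identical(maf$Variant_Type, c("SNP", "DEL", "INS"))
  expect_identical(maf$Start_Position, c(101L, 101L, 100L))
  expect_identical(maf$End_Position, c(101L, 101L, 101L))
  expect_identical(maf$Reference_Allele, c("A", "A", "-"))
  expect_identical(maf$Tumor_Seq_Allele2, c("T", "-", "T"))
  expect_identical(unique(maf$Tumor_Sample_Barcode), "S1")
  expect_identical(unique(maf$Hugo_Symbol), "Unknown")
  expect_identical(unique(maf$Variant_Classification), "Targeted_Region")
})

test_that("annotations attach gene and classification by key", {
  df <- data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T",
                   stringsAsFactors = FALSE)
  ann <- data.frame(key = "chr1:10:A:T", gene = "TP53",
                    classification = "Missense_Mutation",
                    stringsAsFactors = FALSE)
  maf <- vcf_to_maf(as_vset(df), annotations = ann)
  expect_identical(maf$Hugo_Symbol, c("TP53", "Unknown"))
  expect_identical(maf$Variant_Classification,
                   c("Missense_Mutation", "Targeted_Region"))
})

test_that("MAF rows convert back to normalized keys (coordinate oracle)", {
  set.seed(13)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    kind <- sample(c("snv", "del", "ins"), 1)
    pos <- sample(100:10000, 1)
    anchor <- sample(bases, 1)
    if (kind == "snv") {
      ref <- sample(bases, 1); alt <- sample(setdiff(bases, ref), 1)
    } else {
      ev <- paste(c(sample(bases, sample(0:2, 1), replace = TRUE),
                    sample(setdiff(bases, anchor), 1)), collapse = "")
      if (kind == "del") { ref <- paste0(anchor, ev); alt <- anchor }
      else { ref <- anchor; alt <- paste0(anchor, ev) }
    }
    df <- data.frame(chrom = "chr2", pos = pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
    row <- vcf_to_maf(as_vset(df))
    key <- maf_to_key(row$Chromosome, row$Start_Position, row$End_Position,
                      row$Reference_Allele, row$Tumor_Seq_Allele2,
                      row$Variant_Type,
                      anchor = if (kind == "snv") NULL else anchor)
    expect_identical(key, list(chrom = "chr2", pos = as.integer(pos),
                               ref = ref, alt = alt))
  }
})

test_that("Ti/Tv classifies the constructed four-SNV set as 3.0", {
  df <- data.frame(chrom = "chr1", pos = 1:4 * 10L,
                   ref = c("A", "C", "G", "A"), alt = c("G", "T", "A", "C"),
                   stringsAsFactors = FALSE)
  st <- summarize_variants(as_vset(df))
  expect_identical(st$n_transitions, 3L)
  expect_identical(st$n_transversions, 1L)
  expect_equal(st$titv_ratio, 3.0)
})

test_that("TMB is survivors per megabase and proportions sum to one", {
  df <- data.frame(chrom = "chr1", pos = 1:5 * 10L,
                   ref = c("A", "C", "GA", "T", "C"),
                   alt = c("G", "T", "G", "TA", "A"),
                   stringsAsFactors = FALSE)
  st <- summarize_variants(as_vset(df), target_size_bp = 1e6)
  expect_equal(st$tmb, 5.0)
  expect_equal(sum(unlist(st$class_proportions)), 1, tolerance = 1e-12)
  st2 <- summarize_variants(as_vset(df), target_size_bp = 2.5e6)
  expect_equal(st2$tmb, 2.0)
  expect_error(summarize_variants(as_vset(df), target_size_bp = 0))
})

test_that("degenerate summaries are well defined", {
  empty <- as_vset(data.frame(chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              stringsAsFactors = FALSE))
  st <- summarize_variants(empty)
  expect_identical(st$n_variants, 0L)
  expect_identical(length(st$class_proportions), 0L)
  expect_true(is.na(st$titv_ratio))
  # all transitions: ratio undefined, not a division error
  ti <- as_vset(data.frame(chrom = "chr1", pos = c(10L, 20L),
                           ref = c("A", "C"), alt = c("G", "T"),
                           stringsAsFactors = FALSE))
  expect_true(is.na(summarize_variants(ti)$titv_ratio))
})

test_that("summary agrees with a naive recount on a cohort", {
  d <- cohort_dir()
  co <- make_vcf_cohort(d, n_variants = 120, seed = 31)
  vs <- select_candidates(merge_callers(lapply(co$files, read_caller_vcf)),
                          filter_policy(min_callers = 2))
  st <- summarize_variants(vs, target_size_bp = 1.76e6)
  rec <- vs$records
  expect_identical(st$n_variants, nrow(rec))
  snv <- rec[rec$class == "SNV", ]
  ti <- sum(paste0(snv$ref, ">", snv$alt) %in% c("A>G", "G>A", "C>T", "T>C"))
  expect_identical(st$n_transitions, as.integer(ti))
  expect_equal(st$tmb, nrow(rec) / 1.76)
  expect_identical(sum(unlist(st$consensus_histogram)), nrow(rec))
  # caller-evidence histogram equals the truth table's candidate counts
  truth_cand <- co$truth[co$truth$n_callers >= 2, ]
  expect_identical(unlist(st$consensus_histogram),
                   stats::setNames(as.vector(table(truth_cand$n_callers)),
                                   names(table(truth_cand$n_callers))))
  unlink(d, recursive = TRUE)
})

test_that("the report writes three sections and a faithful JSON twin", {
  df <- data.frame(chrom = "chr1", pos = 1:4 * 10L,
                   ref = c("A", "C", "G", "A"), alt = c("G", "T", "A", "C"),
                   stringsAsFactors = FALSE)
  st <- summarize_variants(as_vset(df), target_size_bp = 1e6)
  out <- tempfile("report-")
  paths <- render_report(st, run_meta = list(command_lines = "dagcall maf --in x.vcf"),
                         out_dir = out)
  html <- readLines(paths["html"])
  expect_true(any(grepl("1. Commands and parameters", html)))
  expect_true(any(grepl("2. Quality-control metrics", html)))
  expect_true(any(grepl("3. Mutation landscape", html)))
  expect_true(any(grepl("not available", html)))  # no QC metrics supplied
  tw <- jsonlite::fromJSON(paths["json"])
  expect_equal(tw$mutation_landscape$titv_ratio, 3.0)
  expect_equal(tw$mutation_landscape$tmb, st$tmb)
  expect_identical(tw$mutation_landscape$n_variants, st$n_variants)
  # regeneration is byte-identical
  b1 <- readBin(paths["json"], "raw", file.size(paths["json"]))
  render_report(st, run_meta = list(command_lines = "dagcall maf --in x.vcf"),
                out_dir = out)
  b2 <- readBin(paths["json"], "raw", file.size(paths["json"]))
  expect_identical(b1, b2)
})

test_that("MAF files round-trip through write and read", {
  d <- cohort_dir()
  co <- make_vcf_cohort(d, n_variants = 40, seed = 8)
  vs <- select_candidates(merge_callers(lapply(co$files, read_caller_vcf)),
                          filter_policy())
  maf <- vcf_to_maf(vs, sample_id = "S1")
  f <- tempfile(fileext = ".maf")
  write_maf(maf, f)
  back <- read_maf(f)
  expect_identical(nrow(back), nrow(maf))
  expect_identical(back$Start_Position, maf$Start_Position)
  expect_identical(back$caller_evidence, maf$caller_evidence)
  unlink(d, recursive = TRUE)
})
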