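# Variant normalization, caller-evidence merge, candidate selection.

test_that("normalization trims shared prefix/suffix and advances position", {
  k <- normalize_variant("chr1", 100, "CAG", "CTG")
  expect_identical(k[c("pos", "ref", "alt")], list(pos = 101L, ref = "A", alt = "T"))
  expect_identical(normalize_variant("chr1", 100, "A", "T")$pos, 100L)
  # padded deletion vs minimal deletion
  expect_identical(normalize_variant("chr1", 99, "GCAT", "GCT"),
                   normalize_variant("chr1", 100, "CA", "C"))
})

test_that("normalization is idempotent on random keys", {
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  for (i in 1:300) {
    ref <- paste(sample(bases, sample(1:4, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:4, 1), replace = TRUE), collapse = "")
    if (ref == alt) next
    k1 <- tryCatch(normalize_variant("chr1", 500L, ref, alt), error = function(e) NULL)
    if (is.null(k1)) next  # ambiguous without a reference window
    k2 <- normalize_variant(k1$chrom, k1$pos, k1$ref, k1$alt)
    expect_identical(k1, k2)
  }
})

test_that("a reference window left-aligns and re-anchors indels", {
  #          123456789
  # window:  TTTTCCCCA  — one C deleted from the C run, two representations
  win <- "TTTTCCCCA"
  left <- normalize_variant("chr1", 4, "TC", "T", reference_window = win)
  right <- normalize_variant("chr1", 8, "CA", "A", reference_window = win)
  expect_identical(left, list(chrom = "chr1", pos = 4L, ref = "TC", alt = "T"))
  expect_identical(right, left)
  # a right-anchored indel without a window is the documented error
  expect_error(normalize_variant("chr1", 8, "CA", "A"), "no reference window")
})

test_that("degenerate keys are rejected", {
  expect_error(normalize_variant("chr1", 100, "A", "A"), "identical")
  expect_error(normalize_variant("chr1", 100, "A", "N"), "A/C/G/T")
})

test_that("the reader parses VCFs, splits multi-allelics, honors FILTER", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=AF_GNOMAD,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR",
    "chr1\t100\t.\tA\tT,G\t60\tPASS\tAF_GNOMAD=0.002\tGT:AD:AF:DP\t0/0:700,1,1:0.001,0.001:702\t0/1:600,80,20:0.11,0.03:700",
    "chr1\t200\t.\tC\tG\t60\tLowQual\t.\tGT:AD:AF:DP\t0/0:700,0:0:700\t0/1:650,60:0.09:710"),
    f)
  df <- read_caller_vcf(f)
  expect_identical(nrow(df), 2L)               # multi-allelic split, LowQual dropped
  expect_identical(df$alt, c("T", "G"))
  expect_equal(df$vaf, c(0.11, 0.03))
  expect_equal(df$t_depth, c(700, 700))
  expect_equal(df$n_depth, c(702, 702))
  expect_equal(df$pf_gnomad, c(0.002, 0.002))
  expect_identical(attr(df, "contigs"), "chr1")
  df2 <- read_caller_vcf(f, keep_filtered = TRUE)
  expect_identical(nrow(df2), 3L)
})

test_that("the reader falls back to AD-derived allele fraction", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR",
    "chr1\t100\t.\tA\tT\t60\tPASS\t.\tGT:AD\t0/0:100,0\t0/1:75,25"),
    f)
  expect_equal(read_caller_vcf(f)$vaf, 0.25)
})

simple_sets <- function() {
  v1 <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = c("A", "C"),
                   alt = c("T", "G"), vaf = c(0.1, 0.2),
                   stringsAsFactors = FALSE)
  v2 <- data.frame(chrom = "chr1", pos = c(200L, 300L), ref = c("C", "G"),
                   alt = c("G", "A"), vaf = c(0.25, 0.3),
                   stringsAsFactors = FALSE)
  v3 <- data.frame(chrom = "chr1", pos = 200L, ref = "C", alt = "G",
                   vaf = 0.15, stringsAsFactors = FALSE)
  list(one = v1, two = v2, three = v3)
}

test_that("evidence sets match the worked example", {
  vs <- merge_callers(simple_sets())
  expect_identical(nrow(vs$records), 3L)
  rec <- vs$records[order(vs$records$pos), ]
  expect_identical(rec$evidence, c("1", "1,2,3", "2"))
  expect_identical(rec$callers, c("one", "one,two,three", "two"))
  expect_equal(rec$max_vaf, c(0.1, 0.25, 0.3))
})

test_that("differently represented indels merge into one record", {
  a <- data.frame(chrom = "chr1", pos = 100L, ref = "CA", alt = "C",
                  vaf = 0.1, stringsAsFactors = FALSE)
  b <- data.frame(chrom = "chr1", pos = 99L, ref = "GCAT", alt = "GCT",
                  vaf = 0.12, stringsAsFactors = FALSE)
  vs <- merge_callers(list(x = a, y = b))
  expect_identical(nrow(vs$records), 1L)
  expect_identical(vs$records$evidence, "1,2")
  expect_identical(vs$records$class, "deletion")
})

test_that("merge requires registered callers and preserves key count", {
  sets <- simple_sets()
  expect_error(merge_callers(sets, caller_registry(c("one", "two"))),
               "not registered")
  vs <- merge_callers(sets)
  dict <- oracle_evidence(sets)
  expect_identical(nrow(vs$records), length(dict))
})

test_that("candidate selection applies the caller, VAF and depth rules", {
  vs <- merge_callers(simple_sets())
  cand <- select_candidates(vs, filter_policy(min_callers = 2))
  expect_identical(cand$records$evidence, "1,2,3")
  all_in <- select_candidates(vs, filter_policy(min_callers = 1, min_vaf = 0))
  expect_identical(nrow(all_in$records), 3L)
  # VAF boundary: 0.005 is not > 0.01
  low <- merge_callers(list(a = data.frame(chrom = "chr1", pos = 1L, ref = "A",
                                           alt = "T", vaf = 0.005,
                                           stringsAsFactors = FALSE)))
  expect_identical(nrow(select_candidates(low, filter_policy(min_callers = 1,
                                                             min_vaf = 0.01))$records), 0L)
  # depth: every reporting caller must reach min_depth on the chosen fields
  deep <- merge_callers(list(
    a = data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "T", vaf = 0.2,
                   t_depth = 600, n_depth = 550, stringsAsFactors = FALSE),
    b = data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "T", vaf = 0.2,
                   t_depth = 450, n_depth = 700, stringsAsFactors = FALSE)))
  pol <- filter_policy(min_callers = 2, min_depth = 500, apply_depth_to = "both")
  expect_identical(nrow(select_candidates(deep, pol)$records), 0L)
  pol_n <- filter_policy(min_callers = 2, min_depth = 500, apply_depth_to = "normal")
  expect_identical(nrow(select_candidates(deep, pol_n)$records), 1L)
})

test_that("evidence matches the brute-force oracle on seeded cohorts", {
  for (seed in 1:10) {
    d <- cohort_dir()
    co <- make_vcf_cohort(d, n_variants = 120, n_callers = sample(3:5, 1),
                          seed = seed)
    sets <- lapply(co$files, read_caller_vcf)
    vs <- merge_callers(sets)
    dict <- oracle_evidence(sets)
    expect_identical(nrow(vs$records), length(dict))
    expect_identical(nrow(vs$records), nrow(co$truth))
    m <- match(vs$records$key, co$truth$key)
    expect_false(anyNA(m))
    for (i in seq_len(nrow(vs$records))) {
      expect_setequal(strsplit(vs$records$callers[i], ",")[[1]],
                      strsplit(co$truth$callers[m[i]], ",")[[1]])
    }
    for (k in 1:3) {
      cand <- select_candidates(vs, filter_policy(min_callers = k, min_vaf = 0))
      expect_identical(nrow(cand$records), oracle_candidate_count(dict, k))
    }
    unlink(d, recursive = TRUE)
  }
})

test_that("caller input order changes codes but not surviving keys", {
  d <- cohort_dir()
  co <- make_vcf_cohort(d, n_variants = 80, n_callers = 4, seed = 99)
  sets <- lapply(co$files, read_caller_vcf)
  vs1 <- select_candidates(merge_callers(sets), filter_policy())
  vs2 <- select_candidates(merge_callers(rev(sets)), filter_policy())
  expect_setequal(vs1$records$key, vs2$records$key)
  unlink(d, recursive = TRUE)
})

test_that("candidate counts are monotone in every policy knob", {
  d <- cohort_dir()
  co <- make_vcf_cohort(d, n_variants = 150, n_callers = 4, seed = 17)
  vs <- merge_callers(lapply(co$files, read_caller_vcf))
  n_of <- function(...) nrow(select_candidates(vs, filter_policy(...))$records)
  expect_true(all(diff(sapply(1:4, function(k) n_of(min_callers = k))) <= 0))
  expect_true(all(diff(sapply(c(0, 0.05, 0.2, 0.5),
                              function(v) n_of(min_callers = 1, min_vaf = v))) <= 0))
  expect_true(all(diff(sapply(c(0, 700, 1000, 1600),
                              function(dp) n_of(min_callers = 1, min_vaf = 0,
                                                min_depth = dp))) <= 0))
  unlink(d, recursive = TRUE)
})

test_that("the merged VCF round-trips its records and annotations", {
  d <- cohort_dir()
  co <- make_vcf_cohort(d, n_variants = 60, n_callers = 3, seed = 5)
  cand <- select_candidates(merge_callers(lapply(co$files, read_caller_vcf)),
                            filter_policy())
  f <- tempfile(fileext = ".vcf")
  write_merged_vcf(cand, f, sample_id = "S1")
  back <- read_merged_vcf(f)
  expect_identical(back$records$key, cand$records$key)
  expect_identical(back$records$evidence, cand$records$evidence)
  expect_identical(back$records$n_callers, cand$records$n_callers)
  expect_equal(back$records$max_vaf, cand$records$max_vaf, tolerance = 1e-5)
  expect_equal(back$records$pf_gnomad, cand$records$pf_gnomad, tolerance = 1e-6)
  expect_identical(back$registry$name, cand$registry$name)
  unlink(d, recursive = TRUE)
})
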