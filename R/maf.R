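# Population-frequency filtering, MAF conversion, and mutation summary
# statistics (type proportions, Ti/Tv, TMB).

#' Filter out common variants by population allele frequency
#'
#' A record is dropped when the maximum frequency over the population
#' sources that report it exceeds `threshold` (default 1%).  Records with
#' no frequency data in any source are kept: the filter removes
#' proven-common loci only, which is the conservative behavior for somatic
#' candidates.  Order is preserved.
#'
#' @param vset A `variant_set` whose records carry `pf_<source>` columns.
#' @param threshold Frequency cutoff in `[0, 1]`.
#' @param sources Population sources to consult (default: every `pf_*`
#'   column present).
#' @return The filtered `variant_set`.
#' @export
popfreq_filter <- function(vset, threshold = 0.01, sources = NULL) {
  stopifnot(inherits(vset, "variant_set"), threshold >= 0, threshold <= 1)
  rec <- vset$records
  cols <- if (is.null(sources)) grep("^pf_", names(rec), value = TRUE)
          else paste0("pf_", sources)
  cols <- intersect(cols, names(rec))
  if (length(cols) == 0L || nrow(rec) == 0L) return(vset)
  m <- as.matrix(rec[, cols, drop = FALSE])
  maxf <- apply(m, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  keep <- is.na(maxf) | maxf <= threshold
  vset$records <- rec[keep, , drop = FALSE]
  if (!is.null(vset$per_caller)) {
    vset$per_caller <- vset$per_caller[vset$per_caller$key %in% vset$records$key, ,
                                       drop = FALSE]
  }
  rownames(vset$records) <- NULL
  vset
}

MAF_COLUMNS <- c("Hugo_Symbol", "Chromosome", "Start_Position", "End_Position",
                 "Reference_Allele", "Tumor_Seq_Allele1", "Tumor_Seq_Allele2",
                 "Variant_Classification", "Variant_Type",
                 "Tumor_Sample_Barcode", "caller_evidence", "caller_names")

#' Convert a variant set to Mutation Annotation Format rows
#'
#' Coordinates follow the MAF conventions (1-based inclusive): an SNP keeps
#' its position and single-base alleles; a deletion drops the anchor base,
#' shifts `Start_Position` one to the right and writes `-` as the tumor
#' allele; an insertion spans the two flanking positions and writes `-` as
#' the reference allele.  Records without an annotation get gene `Unknown`
#' and classification `Targeted_Region`.  Caller evidence is carried in a
#' `caller_evidence` column (comma-joined caller codes) plus
#' `caller_names`.
#'
#' @param vset A `variant_set` of normalized records.
#' @param annotations Optional data frame with columns `key` (the
#'   `chrom:pos:ref:alt` string), `gene`, `classification`.
#' @param sample_id Value for `Tumor_Sample_Barcode`.
#' @return Data frame of MAF rows.
#' @export
vcf_to_maf <- function(vset, annotations = NULL, sample_id = "SAMPLE") {
  stopifnot(inherits(vset, "variant_set"))
  rec <- vset$records
  n <- nrow(rec)
  gene <- rep("Unknown", n)
  cls <- rep("Targeted_Region", n)
  if (!is.null(annotations) && n > 0L) {
    i <- match(rec$key, annotations$key)
    hit <- !is.na(i)
    gene[hit] <- annotations$gene[i[hit]]
    cls[hit] <- annotations$classification[i[hit]]
  }
  start <- end <- integer(n)
  ref <- alt <- character(n)
  vt <- character(n)
  for (i in seq_len(n)) {
    r <- rec$ref[i]; a <- rec$alt[i]; p <- rec$pos[i]
    if (nchar(r) == nchar(a)) {
      start[i] <- p; end[i] <- p + nchar(r) - 1L
      ref[i] <- r; alt[i] <- a
      vt[i] <- if (nchar(r) == 1L) "SNP" else paste0(c("", "D", "T", "O")[min(nchar(r), 4L)], "NP")
    } else if (nchar(r) > nchar(a)) {       # deletion: drop anchor base
      del <- substr(r, nchar(a) + 1L, nchar(r))
      start[i] <- p + nchar(a); end[i] <- start[i] + nchar(del) - 1L
      ref[i] <- del; alt[i] <- "-"
      vt[i] <- "DEL"
    } else {                                # insertion: flanking positions
      ins <- substr(a, nchar(r) + 1L, nchar(a))
      start[i] <- p + nchar(r) - 1L; end[i] <- start[i] + 1L
      ref[i] <- "-"; alt[i] <- ins
      vt[i] <- "INS"
    }
  }
  data.frame(Hugo_Symbol = gene,
             Chromosome = rec$chrom,
             Start_Position = start,
             End_Position = end,
             Reference_Allele = ref,
             Tumor_Seq_Allele1 = ref,
             Tumor_Seq_Allele2 = alt,
             Variant_Classification = cls,
             Variant_Type = vt,
             Tumor_Sample_Barcode = rep(sample_id, n),
             caller_evidence = if (n > 0L && !is.null(rec$evidence)) rec$evidence else character(n),
             caller_names = if (n > 0L && !is.null(rec$callers)) rec$callers else character(n),
             stringsAsFactors = FALSE)
}

#' Recover the normalized variant key from a MAF row
#'
#' MAF deletion/insertion rows do not carry the VCF anchor base, so
#' recovering the key of an indel needs the reference base immediately
#' before the event (`anchor`).
#'
#' @param chrom,start,end,ref,alt,variant_type MAF row fields.
#' @param anchor Reference base preceding an indel event.
#' @return List with `chrom`, `pos`, `ref`, `alt`.
#' @export
maf_to_key <- function(chrom, start, end, ref, alt, variant_type,
                       anchor = NULL) {
  if (variant_type %in% c("SNP", "DNP", "TNP", "ONP")) {
    return(list(chrom = chrom, pos = as.integer(start), ref = ref, alt = alt))
  }
  if (is.null(anchor)) {
    stop("recovering an indel key from MAF coordinates requires the anchor base",
         call. = FALSE)
  }
  if (variant_type == "DEL") {
    list(chrom = chrom, pos = as.integer(start) - 1L,
         ref = paste0(anchor, ref), alt = anchor)
  } else if (variant_type == "INS") {
    list(chrom = chrom, pos = as.integer(start),
         ref = anchor, alt = paste0(anchor, alt))
  } else {
    stop(sprintf("unknown Variant_Type '%s'", variant_type), call. = FALSE)
  }
}

#' Write a MAF file
#' @param maf Data frame from [vcf_to_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path) {
  con <- file(path, open = "w")
  writeLines("#version 2.4", con)
  utils::write.table(maf, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a MAF file written by [write_maf()]
#' @param path MAF file.
#' @return Data frame of MAF rows.
#' @export
read_maf <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Summarize a mutation set
#'
#' Computes the mutation-landscape numbers of the final report: variant
#' count, mutation-type proportions, transition/transversion ratio over
#' SNVs (transitions are A<->G and C<->T; all other substitutions are
#' transversions), tumor mutation burden (variants per megabase of target
#' territory), per-caller counts and the caller-evidence histogram.
#'
#' @param x A `variant_set`, or a MAF data frame from [vcf_to_maf()].
#' @param target_size_bp Size of the sequenced target territory in bases;
#'   required for TMB (`NULL` disables TMB).
#' @param tmb_classes Variant classes counted into TMB (default: all).
#' @return A `mutation_summary` list: `n_variants`, `class_proportions`,
#'   `n_transitions`, `n_transversions`, `titv_ratio` (`NA` when there are
#'   no transversions or no SNVs), `tmb`, `per_caller_counts`,
#'   `consensus_histogram`.
#' @export
summarize_variants <- function(x, target_size_bp = NULL,
                               tmb_classes = c("SNP", "INS", "DEL")) {
  if (inherits(x, "variant_set")) {
    rec <- x$records
    cls <- c(SNV = "SNP", insertion = "INS", deletion = "DEL")[rec$class]
    snv <- rec[rec$class == "SNV" & nchar(rec$ref) == 1L, , drop = FALSE]
    subs <- if (nrow(snv) > 0L) paste0(snv$ref, ">", snv$alt) else character(0)
    evidence <- rec$evidence
    callers <- rec$callers
  } else {
    rec <- x
    cls <- rec$Variant_Type
    snv <- rec[rec$Variant_Type == "SNP", , drop = FALSE]
    subs <- if (nrow(snv) > 0L) paste0(snv$Reference_Allele, ">", snv$Tumor_Seq_Allele2)
            else character(0)
    evidence <- rec$caller_evidence
    callers <- rec$caller_names
  }
  n <- length(cls)
  props <- if (n > 0L) {
    tb <- table(cls)
    stats::setNames(as.numeric(tb) / n, names(tb))
  } else stats::setNames(numeric(0), character(0))
  n_ti <- sum(subs %in% TRANSITIONS)
  n_tv <- length(subs) - n_ti
  titv <- if (n_tv > 0L) n_ti / n_tv else NA_real_
  tmb <- if (!is.null(target_size_bp)) {
    stopifnot(target_size_bp > 0)
    sum(cls %in% tmb_classes) / (target_size_bp / 1e6)
  } else NULL
  per_caller <- if (!is.null(callers) && n > 0L) {
    cc <- unlist(strsplit(callers, ",", fixed = TRUE))
    tb <- table(cc)
    stats::setNames(as.integer(tb), names(tb))
  } else stats::setNames(integer(0), character(0))
  hist <- if (!is.null(evidence) && n > 0L) {
    sizes <- lengths(strsplit(evidence, ",", fixed = TRUE))
    tb <- table(sizes)
    stats::setNames(as.integer(tb), names(tb))
  } else stats::setNames(integer(0), character(0))
  structure(list(n_variants = n,
                 class_proportions = as.list(props),
                 n_transitions = n_ti,
                 n_transversions = n_tv,
                 titv_ratio = titv,
                 tmb = tmb,
                 target_size_bp = target_size_bp,
                 per_caller_counts = as.list(per_caller),
                 consensus_histogram = as.list(hist)),
            class = "mutation_summary")
}

#' @export
print.mutation_summary <- function(x, ...) {
  cat(sprintf("mutation_summary: %d variants\n", x$n_variants))
  if (length(x$class_proportions) > 0L) {
    cat("  type proportions:",
        paste(sprintf("%s %.3f", names(x$class_proportions),
                      unlist(x$class_proportions)), collapse = ", "), "\n")
  }
  cat(sprintf("  Ti/Tv: %s (%d/%d)\n",
              if (is.na(x$titv_ratio)) "undefined" else sprintf("%.3f", x$titv_ratio),
              x$n_transitions, x$n_transversions))
  if (!is.null(x$tmb)) {
    cat(sprintf("  TMB: %.3f mutations/Mb (target %d bp)\n",
                x$tmb, as.integer(x$target_size_bp)))
  }
  invisible(x)
}
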