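# Multi-caller consensus: normalize per-caller variant representations,
# merge them into one caller-evidence-tagged list, and apply the
# candidate-selection filters (>= k callers, VAF, depth).

#' Register variant callers
#'
#' Assigns each caller a small integer code in registration order.  Codes
#' identify callers in evidence annotations and carry no priority
#' semantics.
#'
#' @param names Character vector of caller names (unique).
#' @return A `caller_registry` data frame with columns `name` and `code`.
#' @export
caller_registry <- function(names) {
  stopifnot(is.character(names), length(names) > 0L, !anyDuplicated(names))
  structure(data.frame(name = names, code = seq_along(names),
                       stringsAsFactors = FALSE),
            class = c("caller_registry", "data.frame"))
}

#' Normalize a variant to its minimal left-aligned key
#'
#' Callers emit the same event in different representations (padded
#' alleles, right-anchored indels).  Normalization trims the shared allele
#' suffix, then extends left from the reference when an allele empties
#' (this is what left-aligns right-anchored indels), then trims the shared
#' prefix while advancing `pos`.  The result is minimal and, when
#' `reference_window` is supplied, left-aligned; the operation is
#' idempotent.
#'
#' @param chrom Contig name.
#' @param pos 1-based position.
#' @param ref,alt Allele strings over A/C/G/T (uppercased internally).
#' @param reference_window Optional flanking reference sequence used to
#'   re-anchor and left-align indels.
#' @param window_start 1-based position of the first base of
#'   `reference_window`.
#' @return A list with `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant("chr1", 100, "CAG", "CTG")  # -> pos 101, A>T
#' @export
normalize_variant <- function(chrom, pos, ref, alt,
                              reference_window = NULL, window_start = 1L) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt)) {
    stop(sprintf("alleles must be nonempty A/C/G/T strings (got '%s'>'%s')",
                 ref, alt), call. = FALSE)
  }
  if (identical(ref, alt)) {
    stop(sprintf("ref and alt are identical ('%s') at %s:%d", ref, chrom, pos),
         call. = FALSE)
  }
  pos <- as.integer(pos)
  stopifnot(pos >= 1L)
  win_at <- function(p) {
    if (is.null(reference_window)) return(NA_character_)
    i <- p - as.integer(window_start) + 1L
    if (i < 1L || i > nchar(reference_window)) return(NA_character_)
    substr(reference_window, i, i)
  }
  last <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    if (nchar(ref) > 0L && nchar(alt) > 0L && last(ref) == last(alt) &&
        !(nchar(ref) == 1L && nchar(alt) == 1L)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    } else if (nchar(ref) == 0L || nchar(alt) == 0L) {
      anchor <- win_at(pos - 1L)
      if (is.na(anchor)) {
        stop(sprintf("cannot normalize %s:%d: allele empties and no reference window covers the anchor base",
                     chrom, pos), call. = FALSE)
      }
      ref <- paste0(anchor, ref)
      alt <- paste0(anchor, alt)
      pos <- pos - 1L
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), "SNV",
         ifelse(nchar(ref) > nchar(alt), "deletion", "insertion"))
}

# Default INFO keys carrying population allele frequencies.
POPFREQ_KEYS <- c(thousand_genomes = "AF_1000G", gnomad = "AF_GNOMAD",
                  esp = "AF_ESP", exac = "AF_EXAC")

#' Read one caller's VCF into a normalized variant table
#'
#' Parses a VCFv4.x file (plain or bgzipped) with \pkg{vcfR}, splits
#' multi-allelic rows into bi-allelic records, and extracts per-record
#' allele fraction, tumor/normal depth, FILTER status, and any population
#' allele frequencies present under the configured INFO keys.  The tumor
#' allele fraction is taken from the first available of: FORMAT `AF`,
#' FORMAT `FREQ` (percent style), an `AD`-derived alt/(ref+alt) ratio, or
#' INFO `AF` — callers encode it differently.
#'
#' @param path VCF file.
#' @param tumor,normal Sample column names; by default a sample named
#'   `TUMOR`/`NORMAL` is used, otherwise the last/first sample column.
#' @param keep_filtered Keep records whose FILTER is neither `PASS` nor
#'   `.` (default `FALSE`).
#' @param popfreq_keys Named character vector mapping population sources to
#'   INFO keys (default `POPFREQ_KEYS`).
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `vaf`,
#'   `t_depth`, `n_depth`, `filter`, and one `pf_<source>` column per
#'   population source; contig header order is attached as attribute
#'   `contigs`.
#' @export
read_caller_vcf <- function(path, tumor = NULL, normal = NULL,
                            keep_filtered = FALSE,
                            popfreq_keys = POPFREQ_KEYS) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  contigs <- sub("^##contig=<ID=([^,>]+).*$", "\\1",
                 grep("^##contig=", v@meta, value = TRUE))
  n <- nrow(fix)
  if (n == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vaf = numeric(), t_depth = numeric(),
                      n_depth = numeric(), filter = character(),
                      stringsAsFactors = FALSE)
    for (src in names(popfreq_keys)) out[[paste0("pf_", src)]] <- numeric()
    attr(out, "contigs") <- contigs
    return(out)
  }

  samples <- colnames(v@gt)[-1]
  pick <- function(requested, preferred, fallback_idx) {
    if (!is.null(requested)) {
      if (!requested %in% samples) {
        stop(sprintf("sample '%s' not in VCF (%s)", requested,
                     paste(samples, collapse = ", ")), call. = FALSE)
      }
      return(requested)
    }
    if (preferred %in% samples) return(preferred)
    if (length(samples) >= fallback_idx) return(samples[fallback_idx])
    NA_character_
  }
  t_sample <- if (length(samples) > 0L) pick(tumor, "TUMOR", length(samples)) else NA
  n_sample <- if (length(samples) > 1L) pick(normal, "NORMAL", 1L) else NA

  gt_elem <- function(elem, sample) {
    if (is.na(sample)) return(rep(NA_character_, n))
    m <- tryCatch(vcfR::extract.gt(v, element = elem),
                  error = function(e) NULL)
    if (is.null(m)) return(rep(NA_character_, n))
    unname(m[, sample])
  }
  info_elem <- function(key) {
    x <- tryCatch(vcfR::extract.info(v, element = key),
                  error = function(e) rep(NA_character_, n))
    if (is.null(x)) rep(NA_character_, n) else unname(x)
  }

  af_fmt <- gt_elem("AF", t_sample)
  freq_fmt <- gt_elem("FREQ", t_sample)
  ad_fmt <- gt_elem("AD", t_sample)
  dp_t <- gt_elem("DP", t_sample)
  dp_n <- gt_elem("DP", n_sample)
  af_info <- info_elem("AF")
  dp_info <- info_elem("DP")
  pf <- lapply(popfreq_keys, info_elem)

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  nth <- function(x, i) {
    parts <- strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)
    vapply(seq_along(parts), function(k) {
      p <- parts[[k]]
      if (length(p) >= i && nzchar(p[i])) p[i] else NA_character_
    }, character(1))
  }

  rows <- list()
  for (ai in seq_len(max(lengths(alts)))) {
    sel <- lengths(alts) >= ai
    if (!any(sel)) next
    alt_i <- vapply(alts[sel], `[[`, character(1), ai)
    vaf <- suppressWarnings(as.numeric(nth(af_fmt[sel], ai)))
    fr <- nth(freq_fmt[sel], ai)
    vaf2 <- suppressWarnings(as.numeric(sub("%", "", fr, fixed = TRUE))) / 100
    ad <- ifelse(is.na(ad_fmt[sel]), NA_character_, ad_fmt[sel])
    ad_ref <- suppressWarnings(as.numeric(nth(ad, 1L)))
    ad_alt <- suppressWarnings(as.numeric(nth(ad, ai + 1L)))
    vaf3 <- ifelse(!is.na(ad_ref) & !is.na(ad_alt) & (ad_ref + ad_alt) > 0,
                   ad_alt / (ad_ref + ad_alt), NA_real_)
    vaf4 <- suppressWarnings(as.numeric(nth(af_info[sel], ai)))
    vaf_final <- ifelse(!is.na(vaf), vaf,
                        ifelse(!is.na(vaf2), vaf2,
                               ifelse(!is.na(vaf3), vaf3, vaf4)))
    td <- suppressWarnings(as.numeric(dp_t[sel]))
    td <- ifelse(is.na(td), suppressWarnings(as.numeric(dp_info[sel])), td)
    df <- data.frame(chrom = fix$CHROM[sel],
                     pos = as.integer(fix$POS[sel]),
                     ref = fix$REF[sel], alt = alt_i,
                     vaf = vaf_final, t_depth = td,
                     n_depth = suppressWarnings(as.numeric(dp_n[sel])),
                     filter = ifelse(is.na(fix$FILTER[sel]), ".", fix$FILTER[sel]),
                     stringsAsFactors = FALSE)
    for (src in names(popfreq_keys)) {
      df[[paste0("pf_", src)]] <- suppressWarnings(as.numeric(pf[[src]][sel]))
    }
    rows[[ai]] <- df
  }
  out <- do.call(rbind, rows)
  out <- out[out$alt != "*", , drop = FALSE]
  if (!keep_filtered) {
    out <- out[out$filter %in% c("PASS", "."), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "contigs") <- contigs
  out
}

normalize_table <- function(df, reference = NULL) {
  if (nrow(df) == 0L) return(df)
  for (i in seq_len(nrow(df))) {
    win <- if (is.null(reference)) NULL else reference[[df$chrom[i]]]
    k <- normalize_variant(df$chrom[i], df$pos[i], df$ref[i], df$alt[i],
                           reference_window = win, window_start = 1L)
    df$pos[i] <- k$pos; df$ref[i] <- k$ref; df$alt[i] <- k$alt
  }
  df
}

#' Merge per-caller variant tables into a caller-evidence-tagged set
#'
#' Each caller's records are normalized ([normalize_variant()]) and merged
#' on exact key equality (chrom, pos, ref, alt).  The result holds one
#' record per distinct key with the set of caller codes reporting it
#' (the caller evidence), the per-caller attributes, and the maximum
#' population frequency seen per source.
#'
#' @param vcf_sets Named list: caller name -> variant data frame as
#'   returned by [read_caller_vcf()] (minimally `chrom`, `pos`, `ref`,
#'   `alt`; optionally `vaf`, `t_depth`, `n_depth`, `filter`, `pf_*`).
#' @param registry A [caller_registry()] covering every caller in
#'   `vcf_sets`; defaults to one built from `names(vcf_sets)`.
#' @param reference Optional named list contig -> reference sequence used
#'   for left-alignment during normalization.
#' @return A `variant_set`: list with `records` (one row per key, sorted by
#'   contig order then position/ref/alt, with `evidence` as comma-joined
#'   caller codes, `callers` as comma-joined names, `n_callers`, `class`,
#'   `max_vaf`, aggregated `pf_*`), `per_caller` (long table of per-caller
#'   attributes) and the registry.
#' @export
merge_callers <- function(vcf_sets, registry = NULL, reference = NULL) {
  stopifnot(is.list(vcf_sets), length(vcf_sets) > 0L,
            !is.null(names(vcf_sets)), all(nzchar(names(vcf_sets))))
  if (is.null(registry)) registry <- caller_registry(names(vcf_sets))
  missing <- setdiff(names(vcf_sets), registry$name)
  if (length(missing) > 0L) {
    stop(sprintf("caller '%s' is not registered", missing[1]), call. = FALSE)
  }
  contigs <- character(0)
  long <- list()
  for (cn in names(vcf_sets)) {
    df <- normalize_table(as.data.frame(vcf_sets[[cn]]), reference)
    contigs <- c(contigs, attr(vcf_sets[[cn]], "contigs"), df$chrom)
    if (nrow(df) == 0L) next
    if (anyDuplicated(paste(df$chrom, df$pos, df$ref, df$alt))) {
      df <- df[!duplicated(paste(df$chrom, df$pos, df$ref, df$alt)), , drop = FALSE]
    }
    df$caller <- cn
    df$code <- registry$code[match(cn, registry$name)]
    for (col in c("vaf", "t_depth", "n_depth")) {
      if (is.null(df[[col]])) df[[col]] <- NA_real_
    }
    if (is.null(df$filter)) df$filter <- "."
    long[[cn]] <- df
  }
  contig_levels <- unique(contigs)
  base_cols <- c("chrom", "pos", "ref", "alt", "caller", "code",
                 "vaf", "t_depth", "n_depth", "filter")
  pf_cols <- unique(unlist(lapply(long, function(d) grep("^pf_", names(d), value = TRUE))))
  long <- lapply(long, function(d) {
    for (col in pf_cols) if (is.null(d[[col]])) d[[col]] <- NA_real_
    d[, c(base_cols, pf_cols), drop = FALSE]
  })
  long <- if (length(long) > 0L) do.call(rbind, long) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), caller = character(), code = integer(),
               vaf = numeric(), t_depth = numeric(), n_depth = numeric(),
               filter = character(), stringsAsFactors = FALSE)
  rownames(long) <- NULL
  key <- paste(long$chrom, long$pos, long$ref, long$alt, sep = ":")
  long$key <- key

  uk <- unique(key)
  idx <- split(seq_along(key), factor(key, levels = uk))
  agg_max <- function(col) {
    vapply(idx, function(ii) {
      x <- long[[col]][ii]
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    }, numeric(1))
  }
  records <- data.frame(
    key = uk,
    chrom = vapply(idx, function(ii) long$chrom[ii[1]], character(1)),
    pos = vapply(idx, function(ii) long$pos[ii[1]], integer(1)),
    ref = vapply(idx, function(ii) long$ref[ii[1]], character(1)),
    alt = vapply(idx, function(ii) long$alt[ii[1]], character(1)),
    stringsAsFactors = FALSE)
  records$class <- variant_class(records$ref, records$alt)
  codes <- lapply(idx, function(ii) sort(unique(long$code[ii])))
  records$evidence <- vapply(codes, paste, character(1), collapse = ",")
  records$callers <- vapply(codes, function(cc)
    paste(registry$name[match(cc, registry$code)], collapse = ","), character(1))
  records$n_callers <- lengths(codes)
  records$max_vaf <- agg_max("vaf")
  for (col in pf_cols) records[[col]] <- agg_max(col)
  ord <- order(match(records$chrom, contig_levels), records$pos,
               records$ref, records$alt)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 per_caller = long[, c("key", base_cols, pf_cols), drop = FALSE],
                 registry = registry,
                 contigs = contig_levels),
            class = "variant_set")
}

#' Candidate-selection filter policy
#'
#' Defaults follow consensus-calling practice for somatic panels: a
#' candidate must be supported by at least two callers and exceed a
#' variant allele fraction of 0.01.  The depth filter is disabled by
#' default; `min_depth = 500, apply_depth_to = "both"` reproduces a
#' deep-panel baseline (tumor and normal each at >= 500x).
#'
#' @param min_callers Minimum callers supporting a candidate (>= 1).
#' @param min_vaf Candidate kept when its maximum per-caller allele
#'   fraction is strictly greater than this (0..1).
#' @param min_depth Minimum read depth, or `NULL` to disable.
#' @param apply_depth_to Which depth fields the depth filter inspects:
#'   `"tumor"`, `"normal"` or `"both"`.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(min_callers = 2L, min_vaf = 0.01,
                          min_depth = NULL,
                          apply_depth_to = c("both", "tumor", "normal")) {
  apply_depth_to <- match.arg(apply_depth_to)
  stopifnot(min_callers >= 1L, min_vaf >= 0, min_vaf <= 1,
            is.null(min_depth) || min_depth >= 0)
  structure(list(min_callers = as.integer(min_callers),
                 min_vaf = min_vaf,
                 min_depth = min_depth,
                 apply_depth_to = apply_depth_to),
            class = "filter_policy")
}

#' Select candidate variants under a filter policy
#'
#' Keeps records supported by at least `min_callers` callers whose maximum
#' per-caller allele fraction exceeds `min_vaf`; when the depth filter is
#' enabled, every supporting caller that reports the designated depth
#' field(s) must report at least `min_depth`.  Record order is preserved
#' and each survivor is annotated with the filters it passed.
#'
#' @param vset A `variant_set` from [merge_callers()].
#' @param policy A [filter_policy()].
#' @return A `variant_set` whose `records`/`per_caller` are restricted to
#'   the candidates, with a `filters_passed` column added.
#' @export
select_candidates <- function(vset, policy = filter_policy()) {
  stopifnot(inherits(vset, "variant_set"), inherits(policy, "filter_policy"))
  rec <- vset$records
  if (nrow(rec) == 0L) return(vset)
  pass_callers <- rec$n_callers >= policy$min_callers
  pass_vaf <- is.na(rec$max_vaf) | rec$max_vaf > policy$min_vaf
  pass_depth <- rep(TRUE, nrow(rec))
  if (!is.null(policy$min_depth)) {
    cols <- switch(policy$apply_depth_to,
                   tumor = "t_depth", normal = "n_depth",
                   both = c("t_depth", "n_depth"))
    pc <- vset$per_caller
    bad_keys <- unique(unlist(lapply(cols, function(col) {
      pc$key[!is.na(pc[[col]]) & pc[[col]] < policy$min_depth]
    })))
    pass_depth <- !(rec$key %in% bad_keys)
  }
  keep <- pass_callers & pass_vaf & pass_depth
  rec <- rec[keep, , drop = FALSE]
  rec$filters_passed <- rep(paste0("callers,vaf",
                                   if (!is.null(policy$min_depth)) ",depth" else ""),
                            nrow(rec))
  vset$records <- rec
  vset$per_caller <- vset$per_caller[vset$per_caller$key %in% rec$key, , drop = FALSE]
  rownames(vset$records) <- rownames(vset$per_caller) <- NULL
  vset
}

#' Write a merged variant set as an annotated VCF
#'
#' Emits a VCFv4.2 file with the caller evidence in INFO: `CALLERS`
#' (comma-joined integer codes), `CALLER_NAMES`, `NCALLERS`, `MAX_VAF`, and
#' any aggregated population-frequency keys.
#'
#' @param vset A `variant_set`.
#' @param path Output path.
#' @param sample_id Sample name recorded in the header.
#' @param popfreq_keys Source-to-INFO-key map used for the `pf_*` columns.
#' @return `path`, invisibly.
#' @export
write_merged_vcf <- function(vset, path, sample_id = "SAMPLE",
                             popfreq_keys = POPFREQ_KEYS) {
  rec <- vset$records
  pf_cols <- grep("^pf_", names(rec), value = TRUE)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=dagcall_merge",
           sprintf("##sample=<ID=%s>", sample_id),
           sprintf("##contig=<ID=%s>", vset$contigs),
           "##INFO=<ID=CALLERS,Number=.,Type=Integer,Description=\"Codes of callers reporting this variant\">",
           "##INFO=<ID=CALLER_NAMES,Number=.,Type=String,Description=\"Names of callers reporting this variant\">",
           "##INFO=<ID=NCALLERS,Number=1,Type=Integer,Description=\"Number of supporting callers\">",
           "##INFO=<ID=MAX_VAF,Number=1,Type=Float,Description=\"Maximum per-caller tumor allele fraction\">",
           vapply(pf_cols, function(col) {
             src <- sub("^pf_", "", col)
             key <- if (src %in% names(popfreq_keys)) popfreq_keys[[src]] else toupper(col)
             sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Population allele frequency (%s), max over callers\">",
                     key, src)
           }, character(1)),
           vapply(vset$registry$name, function(nm) {
             sprintf("##caller=<ID=%d,Name=%s>",
                     vset$registry$code[vset$registry$name == nm], nm)
           }, character(1)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(rec)), function(i) {
    kv <- c(sprintf("CALLERS=%s", rec$evidence[i]),
            sprintf("CALLER_NAMES=%s", rec$callers[i]),
            sprintf("NCALLERS=%d", rec$n_callers[i]),
            if (!is.na(rec$max_vaf[i])) sprintf("MAX_VAF=%.6g", rec$max_vaf[i]))
    for (col in pf_cols) {
      if (!is.na(rec[[col]][i])) {
        src <- sub("^pf_", "", col)
        key <- if (src %in% names(popfreq_keys)) popfreq_keys[[src]] else toupper(col)
        kv <- c(kv, sprintf("%s=%.6g", key, rec[[col]][i]))
      }
    }
    paste(kv, collapse = ";")
  }, character(1))
  body <- if (nrow(rec) > 0L) {
    paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt, ".", "PASS", info,
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a merged VCF back into a variant set
#'
#' Inverse of [write_merged_vcf()] for downstream MAF conversion and
#' reporting.
#'
#' @param path Merged VCF written by [write_merged_vcf()].
#' @param popfreq_keys Source-to-INFO-key map.
#' @return A `variant_set`.
#' @export
read_merged_vcf <- function(path, popfreq_keys = POPFREQ_KEYS) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  contigs <- sub("^##contig=<ID=([^,>]+).*$", "\\1",
                 grep("^##contig=", v@meta, value = TRUE))
  caller_meta <- grep("^##caller=", v@meta, value = TRUE)
  registry <- if (length(caller_meta) > 0L) {
    nm <- sub("^##caller=<ID=[0-9]+,Name=([^>]+)>$", "\\1", caller_meta)
    caller_registry(nm)
  } else NULL
  n <- nrow(fix)
  info <- function(key) unname(vcfR::extract.info(v, element = key))
  rec <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  rec$key <- paste(rec$chrom, rec$pos, rec$ref, rec$alt, sep = ":")
  rec$class <- variant_class(rec$ref, rec$alt)
  rec$evidence <- info("CALLERS")
  rec$callers <- info("CALLER_NAMES")
  rec$n_callers <- as.integer(info("NCALLERS"))
  rec$max_vaf <- suppressWarnings(as.numeric(info("MAX_VAF")))
  for (src in names(popfreq_keys)) {
    rec[[paste0("pf_", src)]] <- suppressWarnings(as.numeric(info(popfreq_keys[[src]])))
  }
  rec <- rec[, c("key", setdiff(names(rec), "key"))]
  structure(list(records = rec, per_caller = NULL,
                 registry = registry, contigs = contigs),
            class = "variant_set")
}

#' Write the candidate table
#'
#' Tab-separated table of the merged records — one row per candidate with
#' its caller evidence and aggregated attributes.
#'
#' @param vset A `variant_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(vset, path) {
  utils::write.table(vset$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d records, %d callers (%s)\n",
              nrow(x$records),
              if (is.null(x$registry)) 0L else nrow(x$registry),
              if (is.null(x$registry)) "" else paste(x$registry$name, collapse = ", ")))
  if (nrow(x$records) > 0L) {
    print(utils::head(x$records[, setdiff(names(x$records), "key")], 6))
  }
  invisible(x)
}
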