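# Per-read methylation status characters:
#   M = methylated, U = unmethylated, A = ambiguous (unexpected base),
#   . = CpG site not covered by the read
# A read's `status` string has one character per region CpG site.

# internal: base matrix B[read, region position] with NA outside the read
base_matrix <- function(read_seq, offset, region_len) {
  n <- length(read_seq)
  L <- nchar(read_seq)
  B <- matrix(NA_character_, nrow = n, ncol = region_len)
  for (p in seq_len(region_len)) {          # p is 1-based region position
    rel <- p - offset                        # 1-based position within read
    cov <- rel >= 1L & rel <= L
    if (any(cov)) B[cov, p] <- substring(read_seq[cov], rel[cov], rel[cov])
  }
  B
}

# internal: per-region methylation/QC computation shared by the exported
# wrappers; returns the calls tibble for the given alignment subset
meth_core <- function(aln, region) {
  n <- nrow(aln)
  region_len <- region$length
  sites <- region$cpg_sites                       # 0-based C offsets
  s_chars <- strsplit(region$sequence, "")[[1L]]
  ot_like <- conversion_of_mode(aln$strand_mode) == "OT"
  B <- base_matrix(aln$read_seq, aln$offset, region_len)

  # methylation status at each CpG site (both bases must be covered)
  k <- length(sites)
  status <- matrix(".", nrow = n, ncol = max(k, 1L))
  if (k > 0L) for (i in seq_len(k)) {
    c_pos <- sites[i] + 1L; g_pos <- sites[i] + 2L
    covered <- !is.na(B[, c_pos]) & !is.na(B[, g_pos])
    b <- ifelse(ot_like, B[, c_pos], B[, g_pos])
    exp_m <- ifelse(ot_like, "C", "G")
    exp_u <- ifelse(ot_like, "T", "A")
    st <- ifelse(b == exp_m, "M", ifelse(b == exp_u, "U", "A"))
    status[covered, i] <- st[covered]
  }
  status_str <- if (k > 0L) apply(status, 1L, paste, collapse = "") else rep("", n)

  # conversion rate over non-CpG cytosines of the read's converted strand:
  # OT reads interrogate non-CpG Cs (expect T); OB reads interrogate the
  # complement-strand Cs, i.e. forward-strand non-CpG Gs (expect A)
  is_cpg_c <- seq_len(region_len) %in% (sites + 1L)
  is_cpg_g <- seq_len(region_len) %in% (sites + 2L)
  p_ot <- which(s_chars == "C" & !is_cpg_c)
  p_ob <- which(s_chars == "G" & !is_cpg_g)
  conv_frac <- function(pos, expect) {
    if (length(pos) == 0L) return(list(conv = rep(0, n), den = rep(0, n)))
    sub <- B[, pos, drop = FALSE]
    list(conv = rowSums(sub == expect, na.rm = TRUE), den = rowSums(!is.na(sub)))
  }
  ot_c <- conv_frac(p_ot, "T")
  ob_c <- conv_frac(p_ob, "A")
  conv_num <- ifelse(ot_like, ot_c$conv, ob_c$conv)
  conv_den <- ifelse(ot_like, ot_c$den, ob_c$den)
  conversion_rate <- ifelse(conv_den > 0, conv_num / conv_den, 1.0)

  # identity: bisulfite-compatible matches over the full read length
  ref_mat <- matrix(s_chars, nrow = n, ncol = region_len, byrow = TRUE)
  match_mat <- !is.na(B) & B != "N" & ref_mat != "N" &
    (B == ref_mat |
       (ot_like & ref_mat == "C" & B == "T") |
       (!ot_like & ref_mat == "G" & B == "A"))
  identity <- rowSums(match_mat) / nchar(aln$read_seq)

  tibble(
    read_id = aln$read_id,
    region_name = aln$region_name,
    offset = aln$offset,
    strand_mode = aln$strand_mode,
    read_seq = aln$read_seq,
    status = status_str,
    conversion_rate = conversion_rate,
    identity = identity
  )
}

#' Call per-read CpG methylation with QC metrics
#'
#' For every aligned read, calls the methylation status at each CpG site it
#' covers and computes two per-read quality metrics. Top-strand (OT-type)
#' reads are read at the CpG cytosine: `C` = methylated, `T` = unmethylated,
#' anything else ambiguous. Bottom-strand (OB-type) reads are read at the CpG
#' guanine in forward coordinates: `G` = methylated, `A` = unmethylated. Both
#' strands' calls are projected onto the forward-strand CpG coordinate, so a
#' site's status is comparable across strands.
#'
#' The bisulfite conversion rate is the fraction of covered non-CpG
#' cytosines of the read's converted strand observed as converted (`T` for
#' OT, `A` for OB); reads covering none of these pass with rate 1 (no
#' evidence of conversion failure). Sequence identity is the fraction of
#' read positions matching the reference under bisulfite-compatible matching
#' (reference `C` vs read `T` for OT, reference `G` vs read `A` for OB);
#' `N` never matches.
#'
#' @param aln Alignment tibble from [align_reads()] or [import_sam()].
#' @param regions Region tibble from [load_references()].
#' @return Tibble with one row per read: `read_id`, `region_name`, `offset`,
#'   `strand_mode`, `read_seq`, `status` (one character per region CpG site:
#'   `M`/`U`/`A`/`.` for methylated/unmethylated/ambiguous/uncovered),
#'   `conversion_rate`, `identity`.
#' @export
call_methylation <- function(aln, regions) {
  if (nrow(aln) == 0L) {
    return(tibble(read_id = character(), region_name = character(),
                  offset = integer(), strand_mode = character(),
                  read_seq = character(), status = character(),
                  conversion_rate = numeric(), identity = numeric()))
  }
  idx <- split(seq_len(nrow(aln)), aln$region_name)
  parts <- lapply(names(idx), function(nm) {
    res <- meth_core(aln[idx[[nm]], , drop = FALSE], region_row(regions, nm))
    res$.row <- idx[[nm]]
    res
  })
  out <- bind_rows(parts)
  out <- out[order(out$.row), , drop = FALSE]
  out$.row <- NULL
  out
}

#' Per-read bisulfite conversion rate
#'
#' @inheritParams call_methylation
#' @return Numeric vector aligned with the rows of `aln`.
#' @export
bisulfite_conversion_rate <- function(aln, regions) {
  call_methylation(aln, regions)$conversion_rate
}

#' Per-read bisulfite-compatible sequence identity
#'
#' @inheritParams call_methylation
#' @return Numeric vector aligned with the rows of `aln`.
#' @export
sequence_identity <- function(aln, regions) {
  call_methylation(aln, regions)$identity
}

#' Filter reads by conversion rate and identity
#'
#' Annotates every read as kept or discarded: kept reads have
#' `conversion_rate >= min_conversion` and `identity >= min_identity` (both
#' thresholds inclusive, so a read sitting exactly on a threshold passes).
#' Discarded reads carry a `reason` (`"conversion"`, `"identity"`, or
#' `"conversion+identity"`). Kept and discarded rows partition the input.
#'
#' @param calls Methylation-call tibble from [call_methylation()].
#' @param min_conversion Minimum bisulfite conversion rate (default 0.95).
#' @param min_identity Minimum sequence identity (default 0.9).
#' @return The input tibble with logical `kept` and character `reason`
#'   columns (`reason` is `NA` for kept reads). Use
#'   `dplyr::filter(x, kept)` for the retained set.
#' @export
filter_reads <- function(calls, min_conversion = 0.95, min_identity = 0.9) {
  if (min_conversion < 0 || min_conversion > 1 || min_identity < 0 || min_identity > 1) {
    abort_mc("QC thresholds must lie in [0, 1]")
  }
  fail_conv <- calls$conversion_rate < min_conversion
  fail_id <- calls$identity < min_identity
  calls$kept <- !fail_conv & !fail_id
  calls$reason <- dplyr::case_when(
    fail_conv & fail_id ~ "conversion+identity",
    fail_conv ~ "conversion",
    fail_id ~ "identity",
    TRUE ~ NA_character_
  )
  calls
}

#' Write per-read QC metrics to TSV
#'
#' @param calls Output of [filter_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_tsv <- function(calls, path) {
  out <- calls[, c("read_id", "region_name", "offset", "strand_mode",
                   "conversion_rate", "identity", "kept", "reason")]
  out$conversion_rate <- sprintf("%.4f", out$conversion_rate)
  out$identity <- sprintf("%.4f", out$identity)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
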