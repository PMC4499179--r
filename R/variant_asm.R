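#' Per-position allele counts from aligned reads
#'
#' Pileup of read bases at every region position, excluding
#' conversion-confounded comparisons: top-strand (OT-type) reads are skipped
#' at reference-`C` positions and bottom-strand (OB-type) reads at
#' reference-`G` positions, because there the C/T (or G/A) state reflects
#' methylation, not genotype. A mutation at a CpG position is therefore
#' informed only by reads of the non-confounded strand. `N` read bases are
#' tallied but never treated as an allele.
#'
#' @param calls Methylation-call tibble (typically QC-kept reads; ambiguous
#'   methylation calls do not exclude a read here).
#' @param regions Region tibble.
#' @param region Region name (default: the single region present in `calls`).
#' @return Tibble with one row per region position: `region_name`, `position`
#'   (0-based), `ref` (reference base), counts `A`, `C`, `G`, `T`, `N`, and
#'   `depth` (counted `A/C/G/T` reads at the position).
#' @export
count_alleles <- function(calls, regions, region = NULL) {
  if (is.null(region)) {
    region <- unique(calls$region_name)
    if (length(region) != 1L) abort_mc("specify `region` when calls span several regions")
  }
  r <- region_row(regions, region)
  sub <- calls[calls$region_name == region, , drop = FALSE]
  s_chars <- strsplit(r$sequence, "")[[1L]]
  bases <- c("A", "C", "G", "T", "N")
  cnt <- matrix(0L, nrow = r$length, ncol = length(bases),
                dimnames = list(NULL, bases))
  if (nrow(sub) > 0L) {
    B <- base_matrix(sub$read_seq, sub$offset, r$length)
    ot_like <- conversion_of_mode(sub$strand_mode) == "OT"
    for (p in seq_len(r$length)) {
      confounded <- if (s_chars[p] == "C") ot_like
                    else if (s_chars[p] == "G") !ot_like
                    else rep(FALSE, nrow(sub))
      b <- B[!confounded, p]
      b <- b[!is.na(b)]
      if (length(b) > 0L) cnt[p, ] <- tabulate(factor(b, levels = bases), length(bases))
    }
  }
  tibble(
    region_name = region,
    position = seq_len(r$length) - 1L,
    ref = s_chars,
    A = cnt[, "A"], C = cnt[, "C"], G = cnt[, "G"], T = cnt[, "T"], N = cnt[, "N"],
    depth = as.integer(rowSums(cnt[, c("A", "C", "G", "T"), drop = FALSE]))
  )
}

#' Call mutations from allele counts
#'
#' A mutation is a mismatch supported by an excessive number of reads: at
#' each position the most frequent non-reference base is called a variant
#' when its fraction of the position's counted reads reaches `threshold`,
#' subject to a minimum coverage floor to suppress noise at thin positions.
#'
#' @param counts Allele-count tibble from [count_alleles()].
#' @param threshold Minimum variant fraction, in `(0, 1]` (default 0.2).
#' @param min_coverage Minimum counted reads at the position (default 10).
#' @return Tibble of mutations: `region_name`, `position` (0-based),
#'   `ref_allele`, `var_allele`, `var_count`, `covering`, `var_fraction`.
#' @export
call_mutations <- function(counts, threshold = 0.2, min_coverage = 10L) {
  if (threshold <= 0 || threshold > 1) abort_mc("mutation threshold must lie in (0, 1]")
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    if (row$depth < min_coverage || !row$ref %in% bases) return(NULL)
    alt <- setdiff(bases, row$ref)
    alt_counts <- unlist(row[alt])
    j <- which.max(alt_counts)
    vc <- alt_counts[[j]]
    if (vc == 0L || vc / row$depth < threshold) return(NULL)
    tibble(region_name = row$region_name, position = row$position,
           ref_allele = row$ref, var_allele = alt[j],
           var_count = as.integer(vc), covering = as.integer(row$depth),
           var_fraction = vc / row$depth)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(region_name = character(), position = integer(),
                  ref_allele = character(), var_allele = character(),
                  var_count = integer(), covering = integer(),
                  var_fraction = numeric())
  }
  res
}

#' Assign reads to reference / variant allele groups
#'
#' Reads covering the mutation position are labelled `REF` or `VAR` by their
#' base there; reads not covering the position, carrying a third base, or
#' whose bisulfite strand confounds the position (top-strand reads at a
#' reference-`C` site, bottom-strand at a reference-`G` site) are left
#' unassigned (`NA`). The three groups partition the input.
#'
#' @param calls Methylation-call tibble.
#' @param mutation One-row mutation tibble from [call_mutations()].
#' @return `calls` with an added `allele` column (`"REF"`, `"VAR"` or `NA`).
#' @export
split_by_allele <- function(calls, mutation) {
  stopifnot(nrow(mutation) == 1L)
  pos <- mutation$position
  allele <- rep(NA_character_, nrow(calls))
  in_region <- calls$region_name == mutation$region_name
  rel <- pos - calls$offset + 1L
  covers <- in_region & rel >= 1L & rel <= nchar(calls$read_seq)
  ot_like <- conversion_of_mode(calls$strand_mode) == "OT"
  confounded <- (mutation$ref_allele == "C" & ot_like) |
                (mutation$ref_allele == "G" & !ot_like)
  idx <- which(covers & !confounded)
  if (length(idx) > 0L) {
    b <- substring(calls$read_seq[idx], rel[idx], rel[idx])
    allele[idx][b == mutation$ref_allele] <- "REF"
    allele[idx][b == mutation$var_allele] <- "VAR"
  }
  calls$allele <- allele
  calls
}

#' Categorise a methylation level
#'
#' Three-way banding of per-site methylation proportions: `LOW` when at most
#' 20% of reads are methylated, `HIGH` when at least 80% are, otherwise
#' `INTERMEDIATE`. Both boundaries are inclusive.
#'
#' @param level Numeric vector of methylation proportions in `[0, 1]`.
#' @return Character vector of `"LOW"`, `"HIGH"`, `"INTERMEDIATE"`.
#' @examples
#' categorize_level(c(0.2, 0.8, 0.5)) # LOW HIGH INTERMEDIATE
#' @export
categorize_level <- function(level) {
  if (any(is.na(level)) || any(level < 0 | level > 1)) {
    abort_mc("methylation levels must lie in [0, 1]")
  }
  ifelse(level <= 0.20, "LOW", ifelse(level >= 0.80, "HIGH", "INTERMEDIATE"))
}

#' Screen a mutation for allele-specific methylation
#'
#' Splits window-covering reads by allele, assesses per-CpG-site methylation
#' levels in each group, and flags the region as a candidate allele-specific
#' methylation (ASM) region when at least one CpG site has the two groups in
#' different methylation categories ([categorize_level()]) AND their level
#' difference exceeds 20 percentage points (strict). Per-allele
#' co-occurrence pattern sets are computed for both groups.
#'
#' @param calls QC-kept methylation-call tibble.
#' @param window `meth_window` from [select_window()].
#' @param mutation One-row mutation tibble from [call_mutations()].
#' @param min_group Minimum reads per allele group (default 10); below the
#'   floor no call is made and the result is flagged insufficient.
#' @return An `asm_result`: list with `mutation`, `window`, `status`
#'   (`"ok"` or `"insufficient"`), `groups` (per-allele read counts),
#'   `sites` (per-site levels, categories, differences, `discriminating`
#'   flag), `discriminating_sites` (0-based region offsets), `is_candidate`
#'   (`NA` when insufficient), and per-allele `ref_patterns`/`var_patterns`.
#' @export
detect_asm <- function(calls, window, mutation, min_group = 10L) {
  covering <- reads_covering_window(calls, window)
  covering <- split_by_allele(covering, mutation)
  ref_reads <- covering[!is.na(covering$allele) & covering$allele == "REF", , drop = FALSE]
  var_reads <- covering[!is.na(covering$allele) & covering$allele == "VAR", , drop = FALSE]
  groups <- tibble(allele = c("REF", "VAR"),
                   n_reads = c(nrow(ref_reads), nrow(var_reads)))
  k <- length(window$sites)
  if (nrow(ref_reads) < min_group || nrow(var_reads) < min_group) {
    res <- list(mutation = mutation, window = window, status = "insufficient",
                groups = groups,
                sites = tibble(site_index = seq_len(k), position = window$sites,
                               level_ref = NA_real_, level_var = NA_real_,
                               category_ref = NA_character_, category_var = NA_character_,
                               difference = NA_real_, discriminating = NA),
                discriminating_sites = integer(0), is_candidate = NA,
                ref_patterns = NULL, var_patterns = NULL)
    return(structure(res, class = "asm_result"))
  }
  lv_ref <- site_levels(ref_reads, window)
  lv_var <- site_levels(var_reads, window)
  cat_ref <- categorize_level(lv_ref)
  cat_var <- categorize_level(lv_var)
  diff <- abs(lv_ref - lv_var)
  disc <- cat_ref != cat_var & diff > 0.20
  sites <- tibble(site_index = seq_len(k), position = window$sites,
                  level_ref = lv_ref, level_var = lv_var,
                  category_ref = cat_ref, category_var = cat_var,
                  difference = diff, discriminating = disc)
  res <- list(mutation = mutation, window = window, status = "ok",
              groups = groups, sites = sites,
              discriminating_sites = window$sites[disc],
              is_candidate = any(disc),
              ref_patterns = group_patterns(ref_reads, window),
              var_patterns = group_patterns(var_reads, window))
  structure(res, class = "asm_result")
}

#' @export
print.asm_result <- function(x, ...) {
  m <- x$mutation
  cat(sprintf("<asm_result> %s pos %d %s>%s (var fraction %.3f)\n",
              m$region_name, m$position, m$ref_allele, m$var_allele, m$var_fraction))
  if (x$status == "insufficient") {
    cat(sprintf("  insufficient data: REF n=%d, VAR n=%d\n",
                x$groups$n_reads[1L], x$groups$n_reads[2L]))
  } else {
    cat(sprintf("  candidate ASM: %s (%d discriminating site(s))\n",
                x$is_candidate, length(x$discriminating_sites)))
    print(x$sites, ...)
  }
  invisible(x)
}

#' Tidy an ASM result into its per-site table
#'
#' @param x An `asm_result`.
#' @param ... Unused.
#' @return Tibble of per-site levels/categories with mutation metadata.
#' @export
tidy.asm_result <- function(x, ...) {
  m <- x$mutation
  out <- x$sites
  out$region_name <- m$region_name
  out$mutation_position <- m$position
  out$ref_allele <- m$ref_allele
  out$var_allele <- m$var_allele
  out[, c("region_name", "mutation_position", "ref_allele", "var_allele",
          "site_index", "position", "level_ref", "level_var",
          "category_ref", "category_var", "difference", "discriminating")]
}

#' One-row summary of an ASM result
#'
#' @param x An `asm_result`.
#' @param ... Unused.
#' @return One-row tibble with the mutation, group sizes, candidate flag and
#'   discriminating-site count.
#' @export
glance.asm_result <- function(x, ...) {
  m <- x$mutation
  tibble(
    region_name = m$region_name,
    position = m$position,
    ref_allele = m$ref_allele,
    var_allele = m$var_allele,
    var_fraction = m$var_fraction,
    n_ref = x$groups$n_reads[1L],
    n_var = x$groups$n_reads[2L],
    status = x$status,
    is_candidate = x$is_candidate,
    n_discriminating = length(x$discriminating_sites)
  )
}

#' Annotate mutations with IDs from a local VCF
#'
#' Position-based lookup in a plain-text VCF (e.g. a dbSNP extract): a
#' mutation matches a VCF record when the chromosome and genome position
#' agree and the ref/alt alleles are compatible. Requires region genome
#' coordinates; mutations in regions without coordinates keep `NA`.
#'
#' @param mutations Mutation tibble from [call_mutations()].
#' @param regions Region tibble with genome coordinates attached.
#' @param vcf_path Path to an uncompressed VCF file.
#' @return `mutations` with an added `dbsnp_id` column.
#' @export
annotate_mutations <- function(mutations, regions, vcf_path) {
  if (!file.exists(vcf_path)) abort_mc("VCF file not found: %s", vcf_path)
  lines <- readLines(vcf_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  mutations$dbsnp_id <- NA_character_
  if (length(lines) == 0L || nrow(mutations) == 0L) return(mutations)
  f <- strsplit(lines, "\t")
  vcf <- tibble(
    chrom = vapply(f, `[`, "", 1L),
    pos1 = as.integer(vapply(f, `[`, "", 2L)),   # VCF is 1-based
    id = vapply(f, `[`, "", 3L),
    ref = vapply(f, `[`, "", 4L),
    alt = vapply(f, `[`, "", 5L)
  )
  for (i in seq_len(nrow(mutations))) {
    r <- region_row(regions, mutations$region_name[i])
    if (is.na(r$chrom)) next
    gpos1 <- if (r$genome_strand == "-") {
      r$genome_start + (r$length - 1L - mutations$position[i]) + 1L
    } else {
      r$genome_start + mutations$position[i] + 1L
    }
    hit <- vcf$chrom == r$chrom & vcf$pos1 == gpos1
    if (any(hit)) mutations$dbsnp_id[i] <- vcf$id[which(hit)[1L]]
  }
  mutations
}
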