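#' In-silico bisulfite conversion of a DNA string
#'
#' `OT` mode (original top strand) replaces every `C` with `T`; `OB` mode
#' (original bottom strand, expressed in forward coordinates) replaces every
#' `G` with `A`. Other characters are unchanged and length is preserved.
#' Comparing reads and references after conversion makes mapping blind to
#' methylation state.
#'
#' @param seq Character vector of DNA strings over `A,C,G,T,N`.
#' @param mode `"OT"` or `"OB"`.
#' @return Converted strings, same length as `seq`.
#' @examples
#' convert_bisulfite("ACGT", "OT") # "ATGT"
#' convert_bisulfite("ACGT", "OB") # "ACAT"
#' @export
convert_bisulfite <- function(seq, mode = c("OT", "OB")) {
  mode <- match.arg(mode)
  if (mode == "OT") chartr("C", "T", seq) else chartr("G", "A", seq)
}

# internal: reverse-complement plain character strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# The four bisulfite strand modes factor into (conversion, orientation):
#   OT   = top-strand conversion (C->T), read sequenced in forward orientation
#   OB   = bottom-strand conversion (G->A in forward coords), read sequenced
#          reverse-complemented
#   CTOT = complementary-to-OT: top-strand conversion, reverse orientation
#   CTOB = complementary-to-OB: bottom-strand conversion, forward orientation
# Methylation readout depends only on the conversion component: OT/CTOT read
# the CpG C (C = methylated), OB/CTOB read the CpG G (G = methylated).
strand_mode_table <- function(include_complementary = FALSE) {
  modes <- data.frame(
    strand_mode = c("OT", "OB", "CTOT", "CTOB"),
    conversion  = c("OT", "OB", "OT", "OB"),
    reversed    = c(FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  if (include_complementary) modes else modes[modes$strand_mode %in% c("OT", "OB"), ]
}

# internal: OT-type modes read the CpG cytosine, OB-type modes the guanine
conversion_of_mode <- function(strand_mode) {
  unname(c(OT = "OT", OB = "OB", CTOT = "OT", CTOB = "OB")[strand_mode])
}

# internal: byte matrix of a converted region at all offsets for reads of
# length L: column o holds region_conv[o .. o+L-1] (1-based o)
offset_matrix <- function(region_conv_raw, L) {
  n_off <- length(region_conv_raw) - L + 1L
  if (n_off < 1L) return(NULL)
  idx <- outer(seq_len(L), seq_len(n_off) - 1L, "+")
  matrix(region_conv_raw[idx], nrow = L)
}

RAW_N <- charToRaw("N")

#' Align bisulfite reads to reference regions
#'
#' Gap-free, mismatch-budgeted mapping in converted space. Every read is
#' compared against every region at every offset, for each bisulfite strand
#' mode: the read (or its reverse complement, per mode) and the region are
#' both converted (`C->T` for top-strand modes, `G->A` for bottom-strand
#' modes) and compared by Hamming distance. A candidate hit needs at most
#' `seed_mismatches` mismatches within the first `seed_length` sequenced
#' bases and at most `max_mismatches` overall. The unique best hit (fewest
#' total mismatches) wins; ties across offsets, regions or strands discard
#' the read as ambiguous, so every reported alignment is unique. `N` in read
#' or reference always counts as a mismatch.
#'
#' @param reads Tibble from [read_reads()] (columns `read_id`, `seq`).
#' @param regions Region tibble from [load_references()].
#' @param max_mismatches Total converted-space mismatch budget (default 2).
#' @param seed_length Sequenced-seed length in bases (default 28).
#' @param seed_mismatches Mismatch budget inside the seed (default 3).
#' @param include_complementary Also search the complementary-to-converted
#'   strands (CTOT/CTOB); off by default, as for directional libraries.
#' @return Tibble of accepted alignments: `read_id`, `region_name`, `offset`
#'   (0-based), `strand_mode`, `read_seq` (forward-region orientation),
#'   `mismatch_count`. A `summary` attribute (see [mapping_summary()]) holds
#'   total reads, uniquely mapped count/percentage and per-region depth.
#' @export
align_reads <- function(reads, regions, max_mismatches = 2L, seed_length = 28L,
                        seed_mismatches = 3L, include_complementary = FALSE) {
  stopifnot(is.data.frame(reads), is.data.frame(regions))
  modes <- strand_mode_table(include_complementary)
  empty <- tibble(read_id = character(), region_name = character(),
                  offset = integer(), strand_mode = character(),
                  read_seq = character(), mismatch_count = integer())
  if (nrow(reads) == 0L) {
    return(structure(empty, summary = summarise_mapping(empty, reads, regions)))
  }

  seqs <- toupper(reads$seq)
  rc <- revcomp(seqs)
  # converted query per (read, conversion, orientation); forward-oriented
  # sequence per mode for the output
  qconv <- list(OT = convert_bisulfite(seqs, "OT"), OB = convert_bisulfite(rc, "OB"),
                CTOT = convert_bisulfite(rc, "OT"), CTOB = convert_bisulfite(seqs, "OB"))
  fwd_seq <- list(OT = seqs, OB = rc, CTOT = rc, CTOB = seqs)

  region_conv <- lapply(c(OT = "OT", OB = "OB"), function(cv) {
    lapply(setNames(regions$sequence, regions$name),
           function(s) charToRaw(convert_bisulfite(s, cv)))
  })

  lens <- nchar(seqs)
  best_mm <- rep(NA_integer_, length(seqs))
  best_n <- integer(length(seqs))          # how many hits at best score
  best_region <- character(length(seqs))
  best_offset <- integer(length(seqs))
  best_mode <- character(length(seqs))

  for (L in sort(unique(lens))) {
    ridx <- which(lens == L)
    seed_rows_fwd <- seq_len(min(seed_length, L))
    seed_rows_rev <- seq.int(L - min(seed_length, L) + 1L, L)
    for (g in seq_len(nrow(regions))) {
      for (m in seq_len(nrow(modes))) {
        mode <- modes$strand_mode[m]
        conv <- modes$conversion[m]
        M <- offset_matrix(region_conv[[conv]][[regions$name[g]]], L)
        if (is.null(M)) next
        ref_is_n <- M == RAW_N
        seed_rows <- if (modes$reversed[m]) seed_rows_rev else seed_rows_fwd
        for (j in ridx) {
          q <- charToRaw(qconv[[mode]][j])
          mism <- (M != q) | ref_is_n | (q == RAW_N)
          tot <- .colSums(mism, nrow(mism), ncol(mism))
          sd_mm <- .colSums(mism[seed_rows, , drop = FALSE], length(seed_rows), ncol(mism))
          ok <- which(tot <= max_mismatches & sd_mm <= seed_mismatches)
          if (length(ok) == 0L) next
          mn <- min(tot[ok])
          cnt <- sum(tot[ok] == mn)
          if (is.na(best_mm[j]) || mn < best_mm[j]) {
            best_mm[j] <- mn
            best_n[j] <- cnt
            o <- ok[which(tot[ok] == mn)[1L]]
            best_region[j] <- regions$name[g]
            best_offset[j] <- o - 1L
            best_mode[j] <- mode
          } else if (mn == best_mm[j]) {
            best_n[j] <- best_n[j] + cnt
          }
        }
      }
    }
  }

  hit <- !is.na(best_mm) & best_n == 1L
  aln <- tibble(
    read_id = reads$read_id[hit],
    region_name = best_region[hit],
    offset = best_offset[hit],
    strand_mode = best_mode[hit],
    read_seq = vapply(which(hit), function(j) fwd_seq[[best_mode[j]]][j], character(1)),
    mismatch_count = best_mm[hit]
  )
  structure(aln, summary = summarise_mapping(aln, reads, regions))
}

#' Align a single read (convenience wrapper)
#'
#' @inheritParams align_reads
#' @param seq Read sequence; `read_id` names it.
#' @param read_id Identifier for the read.
#' @return A one-row alignment tibble, or a zero-row tibble if the read has
#'   no unique hit within budget (no-hit is a value, not an error).
#' @export
align_read <- function(seq, regions, read_id = "read1", ...) {
  aln <- align_reads(tibble(read_id = read_id, seq = seq), regions, ...)
  attr(aln, "summary") <- NULL
  aln
}

summarise_mapping <- function(aln, reads, regions) {
  depth <- if (nrow(aln) > 0L) {
    tab <- table(factor(aln$region_name, levels = regions$name))
    tibble(region_name = names(tab), n_reads = as.integer(tab))
  } else {
    tibble(region_name = regions$name, n_reads = 0L)
  }
  n_total <- nrow(reads)
  list(
    n_total = n_total,
    n_mapped = nrow(aln),
    pct_mapped = if (n_total > 0L) 100 * nrow(aln) / n_total else 0,
    per_region = depth
  )
}

#' Mapping summary of an alignment set
#'
#' @param aln Alignment tibble from [align_reads()] or [import_sam()].
#' @return A list: `n_total`, `n_mapped`, `pct_mapped`, and `per_region`
#'   depth tibble.
#' @export
mapping_summary <- function(aln) attr(aln, "summary")

#' Import pre-aligned reads from a SAM file
#'
#' For interoperability with upstream bisulfite mappers. Only gap-free
#' alignments (CIGAR a single `M` run, no indels or clipping) to known
#' regions are accepted; others are skipped and counted. The bisulfite
#' strand mode is taken from the `XG` tag (`CT` = top strand, `GA` = bottom
#' strand) when present, otherwise from whichever of OT/OB interpretation
#' yields fewer converted-space mismatches.
#'
#' @param path SAM file whose reference names match region names.
#' @param regions Region tibble from [load_references()].
#' @return Alignment tibble as from [align_reads()], with a `summary`
#'   attribute including the skipped-record count (`n_skipped`).
#' @export
import_sam <- function(path, regions) {
  if (!file.exists(path)) abort_mc("SAM file not found: %s", path)
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
                               tag = "XG")
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  rname <- as.character(rec$rname)
  mapped <- !is.na(rec$pos)
  known <- rname %in% regions$name
  if (any(mapped & !known)) {
    abort_mc("SAM reference '%s' not present in the reference FASTA",
             rname[mapped & !known][1L])
  }
  gapfree <- grepl("^[0-9]+M$", rec$cigar %||% "")
  keep <- mapped & known & gapfree
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warn_mc("%d SAM record(s) skipped (unmapped, or CIGAR with indels/clips)", n_skipped)
  }
  seqs <- as.character(rec$seq)[keep]
  rev_flag <- bitwAnd(rec$flag[keep], 16L) > 0L
  # BAM stores SEQ in forward-reference orientation already
  xg <- rec$tag$XG[keep] %||% rep(NA_character_, sum(keep))
  aln <- tibble(
    read_id = rec$qname[keep],
    region_name = rname[keep],
    offset = rec$pos[keep] - 1L,
    strand_mode = ifelse(is.na(xg), NA_character_, ifelse(xg == "GA", "OB", "OT")),
    read_seq = toupper(seqs),
    mismatch_count = NA_integer_
  )
  # fill missing strand modes / mismatch counts from the sequences themselves
  if (nrow(aln) > 0L) {
    for (j in seq_len(nrow(aln))) {
      r <- region_row(regions, aln$region_name[j])
      ref <- substr(r$sequence, aln$offset[j] + 1L, aln$offset[j] + nchar(aln$read_seq[j]))
      if (nchar(ref) < nchar(aln$read_seq[j])) {
        abort_mc("SAM record '%s' extends past region '%s'", aln$read_id[j], r$name)
      }
      mm_ot <- hamming_chr(convert_bisulfite(aln$read_seq[j], "OT"), convert_bisulfite(ref, "OT"))
      mm_ob <- hamming_chr(convert_bisulfite(aln$read_seq[j], "OB"), convert_bisulfite(ref, "OB"))
      if (is.na(aln$strand_mode[j])) {
        aln$strand_mode[j] <- if (mm_ob < mm_ot) "OB" else "OT"
      }
      aln$mismatch_count[j] <- if (aln$strand_mode[j] %in% c("OB", "CTOB")) mm_ob else mm_ot
    }
  }
  reads_stub <- tibble(read_id = rec$qname)
  s <- summarise_mapping(aln, reads_stub, regions)
  s$n_skipped <- n_skipped
  structure(aln, summary = s)
}

# internal: Hamming distance between equal-length strings; N is a mismatch
hamming_chr <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  sum(ra != rb | ra == RAW_N | rb == RAW_N)
}

#' Export accepted alignments as SAM
#'
#' Minimal single-end SAM: header `@SQ` lines from the regions plus one line
#' per alignment (QNAME/FLAG/RNAME/POS/MAPQ/CIGAR/SEQ). Sequences are
#' written in forward-region orientation; bottom-strand reads carry the
#' reverse flag and an `XG` tag records the bisulfite conversion strand.
#'
#' @param aln Alignment tibble from [align_reads()].
#' @param regions Region tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, regions, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", regions$name, regions$length))
  if (nrow(aln) > 0L) {
    reversed <- aln$strand_mode %in% c("OB", "CTOT")
    xg <- ifelse(conversion_of_mode(aln$strand_mode) == "OB", "GA", "CT")
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tXG:Z:%s",
                    aln$read_id, ifelse(reversed, 16L, 0L), aln$region_name,
                    aln$offset + 1L, nchar(aln$read_seq), aln$read_seq, xg)
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
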