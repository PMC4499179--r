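#' Find CpG sites in a DNA sequence
#'
#' Returns the 0-based offsets of the cytosine of every CpG dinucleotide on
#' the forward strand. `N` never forms a CpG, and CG cannot overlap CG, so the
#' result is strictly increasing and exhaustive by construction.
#'
#' @param sequence A single DNA string over `A,C,G,T,N` (case-insensitive).
#' @return Integer vector of 0-based offsets (possibly empty).
#' @examples
#' find_cpg_sites("ACGT")   # 1
#' find_cpg_sites("CGCGCG") # 0 2 4
#' @export
find_cpg_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 2L) return(integer(0))
  hits <- gregexpr("(?=CG)", sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Load reference amplicon regions from a FASTA file
#'
#' Each FASTA record becomes one region row. Sequences are uppercased
#' (soft-masking is irrelevant for amplicon analysis) and CpG sites are
#' indexed on load. Genome coordinate columns are initialised empty; attach
#' them with [load_region_coords()].
#'
#' @param path Path to a FASTA file of targeted region sequences (one record
#'   per amplicon, not a whole genome).
#' @return A tibble with one row per region: `name`, `sequence`, `length`,
#'   `cpg_sites` (list column of 0-based offsets), and genome columns
#'   `chrom`, `genome_start` (0-based), `genome_strand`, `assembly` (all `NA`
#'   until coordinates are supplied). Record order is preserved.
#' @export
load_references <- function(path) {
  if (!file.exists(path)) abort_mc("reference FASTA not found: %s", path)
  seqs <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) abort_mc("malformed FASTA '%s': %s", path, conditionMessage(e))
    ),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        abort_mc("malformed FASTA '%s': %s", path, conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(seqs) == 0L) abort_mc("reference FASTA '%s' contains no records", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    abort_mc("duplicate region name(s) in '%s': %s", path,
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sq <- unname(toupper(as.character(seqs)))
  if (any(nchar(sq) == 0L)) {
    abort_mc("empty sequence for record '%s' in %s", nm[which(nchar(sq) == 0L)[1L]], path)
  }
  bad <- grepl("[^ACGTN]", sq)
  if (any(bad)) {
    abort_mc("record '%s' contains non-ACGTN characters", nm[which(bad)[1L]])
  }
  tibble(
    name = nm,
    sequence = unname(sq),
    length = nchar(sq),
    cpg_sites = lapply(unname(sq), find_cpg_sites),
    chrom = NA_character_,
    genome_start = NA_integer_,
    genome_strand = NA_character_,
    assembly = NA_character_
  )
}

#' Write reference regions back to FASTA
#'
#' @param regions Region tibble from [load_references()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_references <- function(regions, path) {
  x <- Biostrings::DNAStringSet(setNames(regions$sequence, regions$name))
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

supported_assemblies <- c("hg38", "hg19", "hg18")

#' Attach genome coordinates to reference regions
#'
#' Reads either BED6 (`chrom start end name score strand`) or a 4-column
#' tab-delimited file (`name chrom start strand`); coordinates are 0-based
#' half-open per the BED convention. Regions absent from the file keep empty
#' genome fields (analysis still runs; only the UCSC track output needs
#' coordinates). Lines naming unknown regions are skipped with a warning;
#' on duplicate entries for a region the first wins.
#'
#' @param regions Region tibble from [load_references()].
#' @param path Coordinates file (BED6 or 4-column `name chrom start strand`).
#' @param assembly Genome assembly label; one of `"hg38"`, `"hg19"`, `"hg18"`.
#' @return The region tibble with `chrom`, `genome_start`, `genome_strand`,
#'   `assembly` filled for the regions present in the file.
#' @export
load_region_coords <- function(regions, path, assembly = "hg38") {
  if (!assembly %in% supported_assemblies) {
    abort_mc("unsupported assembly '%s' (supported: %s)", assembly,
             paste(supported_assemblies, collapse = ", "))
  }
  if (!file.exists(path)) abort_mc("coordinates file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) return(regions)
  seen <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "[\t ]+")[[1L]]
    if (length(f) >= 6L && grepl("^[0-9]+$", f[2L]) && grepl("^[0-9]+$", f[3L])) {
      # BED6: chrom start end name score strand
      nm <- f[4L]; chrom <- f[1L]; start <- as.integer(f[2L]); strand <- f[6L]
    } else if (length(f) >= 4L && grepl("^[0-9]+$", f[3L])) {
      # name chrom start strand
      nm <- f[1L]; chrom <- f[2L]; start <- as.integer(f[3L]); strand <- f[4L]
    } else {
      abort_mc("malformed coordinates line %d in %s: '%s'", i, path, lines[i])
    }
    if (!strand %in% c("+", "-")) {
      abort_mc("malformed coordinates line %d in %s: strand must be + or -", i, path)
    }
    j <- match(nm, regions$name)
    if (is.na(j)) {
      warn_mc("coordinates line %d names unknown region '%s'; skipped", i, nm)
      next
    }
    if (nm %in% seen) next  # first entry wins
    seen <- c(seen, nm)
    regions$chrom[j] <- chrom
    regions$genome_start[j] <- start
    regions$genome_strand[j] <- strand
    regions$assembly[j] <- assembly
  }
  regions
}

# internal: fetch one region row as a plain list, with unwrapped cpg_sites
region_row <- function(regions, name) {
  j <- match(name, regions$name)
  if (is.na(j)) abort_mc("unknown region '%s'", name)
  r <- as.list(regions[j, , drop = FALSE])
  r$cpg_sites <- r$cpg_sites[[1L]]
  r
}
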