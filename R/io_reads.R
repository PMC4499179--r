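#' Read sequencing reads from FASTA or FASTQ
#'
#' The file format is detected from the extension (`.fa/.fasta` vs
#' `.fq/.fastq`) or can be forced. For FASTQ the base-quality encoding label
#' must be one of `phred33` (offset 33, the modern default), `phred64`,
#' `solexa` or `solexa1.3`; qualities are validated against the encoding's
#' ASCII range but are not used in alignment scoring.
#'
#' @param path Input reads file.
#' @param quality_encoding Quality encoding label for FASTQ input.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return Tibble with columns `read_id`, `seq`, `qual` (`NA` for FASTA).
#' @export
read_reads <- function(path, quality_encoding = "phred33", format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_mc("reads file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
    return(tibble(
      read_id = sub("\\s.*$", "", names(seqs)),
      seq = toupper(unname(as.character(seqs))),
      qual = NA_character_
    ))
  }
  offset <- quality_offset(quality_encoding)
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(seqs)$qualities)
  validate_qualities(qual, quality_encoding, offset)
  tibble(
    read_id = sub("\\s.*$", "", names(seqs)),
    seq = toupper(unname(as.character(seqs))),
    qual = unname(qual)
  )
}

quality_offset <- function(label) {
  switch(label,
    phred33 = 33L,
    phred64 = 64L,
    solexa = 59L,
    solexa1.3 = 64L,
    abort_mc("unknown quality encoding '%s' (use phred33, phred64, solexa or solexa1.3)", label)
  )
}

validate_qualities <- function(qual, label, offset) {
  if (length(qual) == 0L) return(invisible(TRUE))
  rng <- range(utf8ToInt(paste(qual, collapse = "")))
  if (rng[1L] < offset) {
    abort_mc("quality characters below the %s offset (%d); wrong encoding label?", label, offset)
  }
  invisible(TRUE)
}

#' Write reads to FASTQ (phred33, constant quality)
#'
#' @param reads Tibble with `read_id`, `seq`, and optionally `qual` and
#'   `comment` columns; missing qualities are written as constant `"I"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else rep(NA_character_, nrow(reads))
  qual <- ifelse(is.na(qual), vapply(nchar(reads$seq), function(n) strrep("I", n), ""), qual)
  hdr <- paste0("@", reads$read_id,
                if ("comment" %in% names(reads)) paste0(" ", reads$comment) else "")
  writeLines(as.vector(rbind(hdr, reads$seq, "+", qual)), path)
  invisible(path)
}
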