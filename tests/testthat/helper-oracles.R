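# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# all CpG offsets by checking every 2-mer
brute_cpg_sites <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2) return(integer(0))
  out <- integer(0)
  for (i in seq_len(n - 1)) {
    if (substr(seq, i, i + 1) == "CG") out <- c(out, i - 1L)
  }
  out
}

brute_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

brute_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  sum(ca != cb | ca == "N" | cb == "N")
}

# enumerate every (region, offset, strand mode) and apply the scoring rules;
# returns a list(region, offset, mode, mm) or NULL for no-hit/ambiguous
brute_align <- function(seq, regions, max_mm = 2, seed_len = 28, seed_mm = 3) {
  hits <- list()
  combos <- list(
    OT = list(conv = function(s) gsub("C", "T", s), rev = FALSE),
    OB = list(conv = function(s) gsub("G", "A", s), rev = TRUE)
  )
  for (g in seq_len(nrow(regions))) {
    for (mode in names(combos)) {
      cb <- combos[[mode]]
      q_src <- if (cb$rev) brute_revcomp(seq) else seq
      q <- cb$conv(q_src)
      t <- cb$conv(regions$sequence[g])
      L <- nchar(q)
      if (L > nchar(t)) next
      for (o in 0:(nchar(t) - L)) {
        sub <- substr(t, o + 1, o + L)
        mm <- brute_hamming(q, sub)
        # seed = first seed_len sequenced bases; for reverse-oriented modes
        # that is the tail of the forward-oriented comparison
        sl <- min(seed_len, L)
        if (cb$rev) {
          smm <- brute_hamming(substr(q, L - sl + 1, L), substr(sub, L - sl + 1, L))
        } else {
          smm <- brute_hamming(substr(q, 1, sl), substr(sub, 1, sl))
        }
        if (mm <= max_mm && smm <= seed_mm) {
          hits[[length(hits) + 1]] <- list(region = regions$name[g], offset = o,
                                           mode = mode, mm = mm)
        }
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  mms <- vapply(hits, `[[`, numeric(1), "mm")
  best <- which(mms == min(mms))
  if (length(best) > 1) return(NULL)  # ambiguous
  hits[[best]]
}

# dictionary-of-signatures tally, independent of table()
brute_tally <- function(signatures) {
  env <- new.env()
  for (s in signatures) {
    assign(s, (if (exists(s, env, inherits = FALSE)) get(s, env) else 0L) + 1L, env)
  }
  sigs <- ls(env)
  data.frame(signature = sigs,
             support = vapply(sigs, function(s) get(s, env), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# build a region tibble from a raw sequence
make_region <- function(seq, name = "r1", chrom = NA_character_,
                        genome_start = NA_integer_, genome_strand = NA_character_,
                        assembly = NA_character_) {
  tibble::tibble(
    name = name, sequence = toupper(seq), length = nchar(seq),
    cpg_sites = list(find_cpg_sites(seq)),
    chrom = chrom, genome_start = genome_start,
    genome_strand = genome_strand, assembly = assembly
  )
}

# build a hand-specified alignment tibble
make_aln <- function(read_seq, offset, strand_mode = "OT", region_name = "r1",
                     read_id = NULL) {
  n <- length(read_seq)
  tibble::tibble(
    read_id = read_id %||% sprintf("r%03d", seq_len(n)),
    region_name = region_name,
    offset = as.integer(offset),
    strand_mode = strand_mode,
    read_seq = toupper(read_seq),
    mismatch_count = 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random DNA string
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# minimal BED validator: start < end, blocks inside [start, end), first
# block at start and last block ending at end for BED12 lines
validate_bed <- function(lines) {
  body <- lines[!grepl("^track", lines)]
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    start <- as.integer(f[2]); end <- as.integer(f[3])
    if (!(start < end)) return(FALSE)
    if (length(f) >= 12) {
      sizes <- as.integer(strsplit(f[11], ",")[[1]])
      starts <- as.integer(strsplit(f[12], ",")[[1]])
      if (length(sizes) != as.integer(f[10])) return(FALSE)
      if (starts[1] != 0) return(FALSE)
      ends <- starts + sizes
      if (ends[length(ends)] != end - start) return(FALSE)
      if (any(starts < 0 | ends > end - start)) return(FALSE)
      if (any(diff(starts) <= 0)) return(FALSE)
      if (any(utils::head(ends, -1) > utils::tail(starts, -1))) return(FALSE)
    }
    if (length(f) >= 5) {
      score <- as.numeric(f[5])
      if (score < 0 || score > 1000) return(FALSE)
    }
  }
  TRUE
}
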