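# Synthetic targeted bisulfite amplicon reads with known truth. The
# generator emulates deep amplicon sequencing of a small region (~127 bp,
# reads ~70 bp): a mixture of planted methylation signatures over the window
# CpG sites, per-base bisulfite conversion failure, per-base sequencing
# error, both bisulfite strands, and an optional variant allele whose
# frequency can be linked to methylation state. Bottom-strand (OB) reads are
# emitted reverse-complemented in the FASTQ, as a sequencer would produce
# them, so alignment orientation logic is exercised.

# internal: save/restore the global RNG around seeded simulation
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic reference amplicon
#'
#' Random DNA of the given length with exactly `n_cpg` CpG sites planted at
#' evenly spaced offsets (accidental CpGs are removed first), so the default
#' 70 bp analysis window contains all of them. Deterministic given `seed`.
#'
#' @param length Region length in bases (default 127, a typical amplicon).
#' @param n_cpg Number of CpG sites (default 5).
#' @param seed Integer seed.
#' @param name Region name.
#' @return A one-row region tibble as from [load_references()].
#' @export
simulate_reference <- function(length = 127L, n_cpg = 5L, seed = 1L, name = "simregion") {
  stopifnot(length >= 40L, n_cpg >= 1L, n_cpg <= 15L)
  with_seed(seed, {
    ch <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    # strip accidental CpGs (left-to-right pass cannot create new ones)
    for (i in seq_len(length - 1L)) {
      if (ch[i] == "C" && ch[i + 1L] == "G") ch[i + 1L] <- "T"
    }
    sites0 <- 20L + round(seq(0, min(40L, length - 25L), length.out = n_cpg))
    ch[sites0 + 1L] <- "C"
    ch[sites0 + 2L] <- "G"
    sq <- paste(ch, collapse = "")
    tibble(name = name, sequence = sq, length = length,
           cpg_sites = list(find_cpg_sites(sq)),
           chrom = NA_character_, genome_start = NA_integer_,
           genome_strand = NA_character_, assembly = NA_character_)
  })
}

#' Simulate bisulfite amplicon reads with known truth
#'
#' Each read draws a methylation signature from `pattern_mix` (or from the
#' allele-specific mixes when a variant is configured), an allele, a
#' bisulfite strand, and a start offset uniform among offsets covering all
#' window CpG sites. Bisulfite conversion is methylation-aware: an
#' unmethylated cytosine of the read's strand converts with probability
#' `1 - conversion_failure`, a methylated CpG cytosine never converts. CpG
#' sites outside the analysis window are treated as unmethylated. The
#' variant base is applied after conversion, then per-base substitution
#' errors. Deterministic given `seed`.
#'
#' @param region One-row region tibble (e.g. from [simulate_reference()]).
#' @param pattern_mix Named numeric vector: names are `M`/`U` signature
#'   strings over the window CpG sites, values are mixture proportions
#'   summing to 1. Default: half fully methylated, half fully unmethylated.
#' @param n_reads Number of reads (default 2000; targeted amplicon
#'   sequencing is far deeper, but pattern estimates stabilise well below
#'   real depths).
#' @param read_length Read length in bases (default 70).
#' @param conversion_failure Probability an unmethylated cytosine stays
#'   unconverted (default 0.01, i.e. a 99% conversion chemistry).
#' @param seq_error Per-base substitution error probability (default 0.005).
#' @param meth_flip Probability of flipping each site's planted methylation
#'   state (epiallele noise; default 0).
#' @param strand_mix Proportion of top-strand (OT) reads (default 0.5).
#' @param variant Optional list: `position` (0-based), `var_allele`,
#'   `frequency` (variant allele frequency), and optionally `ref_mix` /
#'   `var_mix` pattern mixes overriding `pattern_mix` per allele.
#' @param window Optional `meth_window`; default from [select_window()].
#' @param seed Integer seed.
#' @return A list of class `meth_sim`: `regions`, `window`, `reads` (FASTQ
#'   tibble: `read_id`, `seq` as sequenced, `qual`, `comment` recording the
#'   seed), `truth` (`read_id`, `signature` planted, `realized_signature`
#'   after flips, `allele`, `offset`, `strand_mode`), `aligned`
#'   (truth alignments in forward-region orientation, usable directly by
#'   [call_methylation()]), and `params`.
#' @export
simulate_reads <- function(region, pattern_mix = NULL, n_reads = 2000L,
                           read_length = 70L, conversion_failure = 0.01,
                           seq_error = 0.005, meth_flip = 0,
                           strand_mix = 0.5, variant = NULL,
                           window = NULL, seed = 1L) {
  stopifnot(nrow(region) == 1L)
  r <- region_row(region, region$name[1L])
  if (read_length > r$length) abort_mc("read_length exceeds the region length")
  if (is.null(window)) window <- select_window(region, r$name)
  S <- window$sites
  k <- length(S)
  if (is.null(pattern_mix)) {
    pattern_mix <- setNames(c(0.5, 0.5), c(strrep("M", k), strrep("U", k)))
  }
  check_mix <- function(mix, what) {
    if (abs(sum(mix) - 1) > 1e-9) abort_mc("%s proportions must sum to 1", what)
    if (any(nchar(names(mix)) != k)) {
      abort_mc("%s signatures must have one character per window CpG site (k=%d)", what, k)
    }
  }
  check_mix(pattern_mix, "pattern_mix")
  lo <- max(0L, max(S) + 2L - read_length)
  hi <- min(min(S), r$length - read_length)
  if (lo > hi) abort_mc("read_length %d cannot cover all window CpG sites", read_length)

  ref_mix <- pattern_mix
  var_mix <- pattern_mix
  if (!is.null(variant)) {
    stopifnot(all(c("position", "var_allele", "frequency") %in% names(variant)))
    if (!is.null(variant$ref_mix)) { check_mix(variant$ref_mix, "ref_mix"); ref_mix <- variant$ref_mix }
    if (!is.null(variant$var_mix)) { check_mix(variant$var_mix, "var_mix"); var_mix <- variant$var_mix }
  }

  with_seed(seed, {
    n <- n_reads
    allele <- if (is.null(variant)) rep("REF", n) else {
      ifelse(runif(n) < variant$frequency, "VAR", "REF")
    }
    pick_sig <- function(mix, m) {
      if (m == 0L) return(character(0))
      names(mix)[sample.int(length(mix), m, replace = TRUE, prob = mix)]
    }
    signature <- character(n)
    signature[allele == "REF"] <- pick_sig(ref_mix, sum(allele == "REF"))
    signature[allele == "VAR"] <- pick_sig(var_mix, sum(allele == "VAR"))

    # methylation state matrix over window sites, with optional flip noise
    meth <- matrix(FALSE, n, max(k, 1L))
    if (k > 0L && n > 0L) {
      for (i in seq_len(k)) meth[, i] <- substring(signature, i, i) == "M"
      if (meth_flip > 0) {
        flip <- matrix(runif(n * k) < meth_flip, n, k)
        meth <- xor(meth, flip)
      }
    }
    realized <- if (k > 0L) {
      apply(meth, 1L, function(m) paste(ifelse(m, "M", "U"), collapse = ""))
    } else rep("", n)

    strand <- ifelse(runif(n) < strand_mix, "OT", "OB")
    offset <- if (lo == hi) rep(lo, n) else lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

    # molecule matrix in forward coordinates
    s_chars <- strsplit(r$sequence, "")[[1L]]
    mol <- matrix(s_chars, nrow = n, ncol = r$length, byrow = TRUE)
    ot <- strand == "OT"
    c_pos <- which(s_chars == "C")
    g_pos <- which(s_chars == "G")
    site_c <- S + 1L   # 1-based C of window CpGs
    site_g <- S + 2L
    # top strand: every C converts unless methylated window CpG or failure
    for (p in c_pos) {
      i <- match(p, site_c)
      protected <- if (!is.na(i)) meth[, i] else rep(FALSE, n)
      stay <- protected | (runif(n) < conversion_failure)
      conv <- ot & !stay
      mol[conv, p] <- "T"
    }
    # bottom strand: every G (a bottom-strand C) converts to A in forward
    # coordinates unless methylated window CpG or failure
    for (p in g_pos) {
      i <- match(p, site_g)
      protected <- if (!is.na(i)) meth[, i] else rep(FALSE, n)
      stay <- protected | (runif(n) < conversion_failure)
      conv <- !ot & !stay
      mol[conv, p] <- "A"
    }
    if (!is.null(variant)) {
      vsel <- allele == "VAR"
      mol[vsel, variant$position + 1L] <- variant$var_allele
    }
    if (seq_error > 0) {
      err <- matrix(runif(n * r$length) < seq_error, n, r$length)
      if (any(err)) {
        idx <- which(err)
        cur <- mol[idx]
        shift <- sample.int(3L, length(idx), replace = TRUE)
        pool <- c("A", "C", "G", "T")
        mol[idx] <- pool[(match(cur, pool) - 1L + shift) %% 4L + 1L]
      }
    }

    mol_str <- apply(mol, 1L, paste, collapse = "")
    fragment <- substring(mol_str, offset + 1L, offset + read_length)
    read_id <- sprintf("read_%06d", seq_len(n))
    seq_out <- fragment
    if (any(!ot)) seq_out[!ot] <- revcomp(fragment[!ot])

    reads <- tibble(read_id = read_id, seq = seq_out,
                    qual = strrep("I", read_length),
                    comment = sprintf("seed=%d", seed))
    truth <- tibble(read_id = read_id, signature = signature,
                    realized_signature = realized, allele = allele,
                    offset = offset, strand_mode = strand)
    aligned <- tibble(read_id = read_id, region_name = r$name, offset = offset,
                      strand_mode = strand, read_seq = fragment,
                      mismatch_count = NA_integer_)
    structure(
      list(regions = region, window = window, reads = reads, truth = truth,
           aligned = aligned,
           params = list(n_reads = n_reads, read_length = read_length,
                         conversion_failure = conversion_failure,
                         seq_error = seq_error, meth_flip = meth_flip,
                         strand_mix = strand_mix, variant = variant, seed = seed)),
      class = "meth_sim"
    )
  })
}

#' @export
print.meth_sim <- function(x, ...) {
  cat(sprintf("<meth_sim> %d reads of %d bp from region '%s' (%d window CpGs), seed %d\n",
              nrow(x$reads), x$params$read_length, x$regions$name[1L],
              length(x$window$sites), x$params$seed))
  invisible(x)
}

#' Write canonical simulation fixture scenarios
#'
#' Four reproducible scenarios, each written as FASTQ + reference FASTA +
#' truth TSV + a key-value config file under `outdir/<scenario>/`:
#' `null_uniform` (signatures uniform over all 2^k patterns),
#' `planted_mixture` (three signatures at 0.6/0.3/0.1),
#' `planted_asm` (a variant allele linked to hypomethylation), and
#' `meth_unmeth_duality` (an equal mix of fully methylated and fully
#' unmethylated reads).
#'
#' @param outdir Output directory (created if needed).
#' @param seed Base seed; each scenario derives its own from it.
#' @return Tibble with `scenario`, `seed`, `n_reads`, `dir`.
#' @export
make_fixture_suite <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  all_sigs <- function(k) {
    apply(expand.grid(rep(list(c("M", "U")), k)), 1L, paste, collapse = "")
  }
  scen <- list(
    null_uniform = function(sd) {
      reg <- simulate_reference(n_cpg = 3L, seed = sd)
      sigs <- all_sigs(3L)
      simulate_reads(reg, setNames(rep(1 / 8, 8), sigs), n_reads = 2000L,
                     seq_error = 0, conversion_failure = 0, seed = sd)
    },
    planted_mixture = function(sd) {
      reg <- simulate_reference(n_cpg = 4L, seed = sd)
      simulate_reads(reg, c(MMMM = 0.6, UUUU = 0.3, MMUU = 0.1),
                     n_reads = 2000L, meth_flip = 0.01, seed = sd)
    },
    planted_asm = function(sd) {
      reg <- simulate_reference(n_cpg = 4L, seed = sd)
      r <- region_row(reg, reg$name[1L])
      g_after_window <- setdiff(which(strsplit(r$sequence, "")[[1L]] == "G") - 1L,
                                c(r$cpg_sites, r$cpg_sites + 1L))
      pos <- g_after_window[g_after_window > 25L & g_after_window < 60L][1L]
      simulate_reads(reg, n_reads = 2000L, seed = sd,
                     variant = list(position = pos, var_allele = "A", frequency = 0.5,
                                    ref_mix = c(MMMM = 1), var_mix = c(UUUU = 1)))
    },
    meth_unmeth_duality = function(sd) {
      reg <- simulate_reference(n_cpg = 4L, seed = sd)
      simulate_reads(reg, c(MMMM = 0.5, UUUU = 0.5), n_reads = 400L, seed = sd)
    }
  )
  out <- lapply(seq_along(scen), function(i) {
    name <- names(scen)[i]
    sd <- seed + i - 1L
    sim <- scen[[i]](sd)
    d <- file.path(outdir, name)
    dir.create(d, showWarnings = FALSE)
    write_fastq(sim$reads, file.path(d, "reads.fastq"))
    write_references(sim$regions, file.path(d, "reference.fasta"))
    write.table(sim$truth, file.path(d, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    p <- sim$params
    cfg <- c(sprintf("scenario=%s", name), sprintf("seed=%d", sd),
             sprintf("n_reads=%d", p$n_reads),
             sprintf("read_length=%d", p$read_length),
             sprintf("conversion_failure=%g", p$conversion_failure),
             sprintf("seq_error=%g", p$seq_error),
             sprintf("meth_flip=%g", p$meth_flip),
             if (!is.null(p$variant)) {
               sprintf("variant=%d%s@%g", p$variant$position, p$variant$var_allele,
                       p$variant$frequency)
             })
    writeLines(cfg, file.path(d, "config.txt"))
    tibble(scenario = name, seed = sd, n_reads = p$n_reads, dir = d)
  })
  bind_rows(out)
}
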