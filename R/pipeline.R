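# Two-stage workflow: a mapping stage (reads -> alignments + summary) and an
# analysis stage (alignments -> QC -> patterns -> mutations/ASM -> reports).
# Every tunable threshold is part of the run config and is written to a
# run-manifest file alongside outputs for provenance.

#' Default run configuration
#'
#' All pattern-analysis defaults follow the method's standard settings:
#' mismatch budget 2 with a 28 bp seed allowing 3 seed mismatches,
#' bisulfite conversion rate 0.95, sequence identity 0.9, significance
#' threshold 0.05, mutation threshold 0.2, and a 70 bp window starting at
#' the first CpG site.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    quality_encoding = "phred33",
    max_mismatches = 2L,
    seed_length = 28L,
    seed_mismatches = 3L,
    min_conversion = 0.95,
    min_identity = 0.9,
    alpha = 0.05,
    min_fraction = NULL,
    mutation_threshold = 0.2,
    min_coverage = 10L,
    min_group = 10L,
    window_size = 70L,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) abort_mc("unknown config option(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

write_manifest <- function(cfg, outdir, extra = character(0)) {
  vals <- vapply(cfg, function(v) if (is.null(v)) "" else paste(format(v), collapse = ","), "")
  writeLines(c(sprintf("%s=%s", names(vals), vals), extra),
             file.path(outdir, "run_manifest.txt"))
}

#' Mapping stage: align reads and write SAM + summary
#'
#' @param reads_path FASTA/FASTQ reads file.
#' @param reference_path Reference region FASTA.
#' @param outdir Output directory (created if needed).
#' @param config Configuration list from [default_config()].
#' @return The alignment tibble (invisibly); writes `alignments.sam` and
#'   `mapping_summary.txt` under `outdir`.
#' @export
run_align <- function(reads_path, reference_path, outdir, config = default_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  regions <- load_references(reference_path)
  reads <- read_reads(reads_path, quality_encoding = config$quality_encoding)
  aln <- align_reads(reads, regions,
                     max_mismatches = config$max_mismatches,
                     seed_length = config$seed_length,
                     seed_mismatches = config$seed_mismatches)
  write_sam(aln, regions, file.path(outdir, "alignments.sam"))
  s <- mapping_summary(aln)
  writeLines(c(
    sprintf("total_reads=%d", s$n_total),
    sprintf("uniquely_mapped=%d", s$n_mapped),
    sprintf("pct_uniquely_mapped=%.2f", s$pct_mapped),
    sprintf("depth_%s=%d", s$per_region$region_name, s$per_region$n_reads)
  ), file.path(outdir, "mapping_summary.txt"))
  write_manifest(config, outdir, sprintf("stage=align"))
  invisible(aln)
}

#' Analysis stage: QC, patterns, mutations/ASM and reports per region
#'
#' Runs the full analysis for every region: QC filtering, window selection,
#' co-occurrence pattern grouping and significance, the all-pairs CpG
#' dependence screen, mutation calling and ASM screening, and report
#' rendering (pattern TSV, text report, figure; UCSC track when genome
#' coordinates are available; ASM TSV when mutations are called). Regions
#' with no covering reads produce empty tables with a warning, not an error.
#'
#' @param aln Alignment tibble from [run_align()], [align_reads()] or
#'   [import_sam()].
#' @param regions Region tibble (with coordinates attached if track output
#'   is wanted).
#' @param outdir Output directory.
#' @param config Configuration list from [default_config()].
#' @param windows Optional named list of `c(start, end)` user windows per
#'   region name.
#' @param sample Sample label for track/report headers.
#' @return Named list per region: `pattern_set`, `significant`,
#'   `dependency`, `mutations`, `asm` (list of `asm_result`), invisibly.
#' @export
run_analyze <- function(aln, regions, outdir, config = default_config(),
                        windows = NULL, sample = "sample") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  calls_all <- call_methylation(aln, regions)
  calls_all <- filter_reads(calls_all, config$min_conversion, config$min_identity)
  write_qc_tsv(calls_all, file.path(outdir, "read_qc.tsv"))
  kept <- calls_all[calls_all$kept, , drop = FALSE]

  results <- list()
  for (nm in regions$name) {
    rdir <- file.path(outdir, nm)
    dir.create(rdir, showWarnings = FALSE)
    reg_calls <- kept[kept$region_name == nm, , drop = FALSE]
    win <- tryCatch(
      select_window(regions, nm, window = windows[[nm]], size = config$window_size),
      error = function(e) {
        warn_mc("region '%s': %s", nm, conditionMessage(e))
        NULL
      }
    )
    if (is.null(win)) next
    covering <- reads_covering_window(reg_calls, win)
    ps <- group_patterns(covering, win)
    if (ps$n == 0L) warn_mc("region '%s': no reads cover the analysis window", nm)
    write_pattern_tsv(ps, file.path(rdir, "patterns.tsv"), alpha = config$alpha)
    writeLines(render_text(ps, alpha = config$alpha, min_fraction = config$min_fraction),
               file.path(rdir, "patterns.txt"))
    dep <- cpg_dependency_all(ps)
    write.table(as.data.frame(dep), file.path(rdir, "cpg_dependency.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    r <- region_row(regions, nm)
    if (!is.na(r$chrom)) {
      writeLines(render_track(ps, regions, sample = sample, alpha = config$alpha,
                              min_fraction = config$min_fraction),
                 file.path(rdir, "track.bed"))
    }

    counts <- count_alleles(reg_calls, regions, region = nm)
    muts <- call_mutations(counts, threshold = config$mutation_threshold,
                           min_coverage = config$min_coverage)
    asm <- list()
    if (nrow(muts) > 0L) {
      asm <- lapply(seq_len(nrow(muts)), function(i) {
        detect_asm(reg_calls, win, muts[i, , drop = FALSE],
                   min_group = config$min_group)
      })
      write_asm_tsv(asm, file.path(rdir, "asm.tsv"))
    }
    if (ps$n > 0L) {
      render_figure(ps, file.path(rdir, "patterns.png"), mutations = muts,
                    alpha = config$alpha, min_fraction = config$min_fraction)
    }
    results[[nm]] <- list(pattern_set = ps,
                          significant = significant_patterns(ps, config$alpha,
                                                             config$min_fraction),
                          dependency = dep, mutations = muts, asm = asm)
  }
  write_manifest(config, outdir, "stage=analyze")
  invisible(results)
}

#' Full pipeline: mapping stage then analysis stage
#'
#' @inheritParams run_align
#' @param coords_path Optional region coordinates file (BED6 or
#'   `name chrom start strand`).
#' @param assembly Assembly label for the coordinates.
#' @param windows,sample Passed to [run_analyze()].
#' @return The analysis results list, invisibly.
#' @export
run_pipeline <- function(reads_path, reference_path, outdir,
                         config = default_config(), coords_path = NULL,
                         assembly = "hg38", windows = NULL, sample = "sample") {
  aln <- run_align(reads_path, reference_path, outdir, config)
  regions <- load_references(reference_path)
  if (!is.null(coords_path)) {
    regions <- load_region_coords(regions, coords_path, assembly = assembly)
  }
  run_analyze(aln, regions, outdir, config, windows = windows, sample = sample)
}

#' Simulation stage: write the fixture scenario suite
#'
#' @param outdir Output directory.
#' @param seed Base seed.
#' @return Scenario tibble from [make_fixture_suite()], invisibly.
#' @export
run_simulate <- function(outdir, seed = 1L) {
  invisible(make_fixture_suite(outdir, seed = seed))
}
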