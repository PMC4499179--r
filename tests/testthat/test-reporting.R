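# "TACGTT" has a single CpG at offset 2; a full-region window renders 6 cells.
text_ps <- function(n_m, n_u) {
  reg <- make_region("TACGTT")
  w <- select_window(reg, window = c(0, 6))
  pattern_set_from_signatures(c(rep("M", n_m), rep("U", n_u)), w)
}

test_that("text report encodes @@/**/- cells with support and percentage", {
  lines <- render_text(text_ps(80, 20))
  expect_equal(lines[1], "# r1 1-6 (n=100 reads, 2 patterns)")
  expect_equal(lines[2], "--@@--\t80\t80.0%")   # only the dominant pattern is significant

  lines_u <- render_text(text_ps(20, 80))
  expect_equal(lines_u[2], "--**--\t80\t80.0%")

  # a variant allele is shown as its base character at its position
  mut <- tibble::tibble(region_name = "r1", position = 0L, ref_allele = "T",
                        var_allele = "A", var_count = 10L, covering = 100L,
                        var_fraction = 0.1)
  lines_v <- render_text(text_ps(80, 20), mutations = mut)
  expect_equal(lines_v[2], "A-@@--\t80\t80.0%")

  empty <- render_text(pattern_set_from_signatures(character(0),
                                                   select_window(make_region("TACGTT"),
                                                                 window = c(0, 6))))
  expect_equal(empty[2], "# no significant patterns")
})

test_that("pattern line counts match the significant pattern count in all formats", {
  reg <- make_region(paste0("TT", strrep("ACGT", 10)), "r1", chrom = "chr1",
                     genome_start = 1000L, genome_strand = "+", assembly = "hg38")
  set.seed(51)
  k <- length(find_cpg_sites(reg$sequence[1]))
  w <- select_window(reg, window = c(0, reg$length))
  sigs <- c(rep(strrep("M", k), 70), rep(strrep("U", k), 25),
            apply(matrix(sample(c("M", "U"), 5 * k, replace = TRUE), 5), 1,
                  paste, collapse = ""))
  ps <- pattern_set_from_signatures(sigs, w)
  n_sig <- nrow(significant_patterns(ps))
  txt <- render_text(ps)
  expect_equal(length(txt) - 1L, n_sig)
  trk <- render_track(ps, reg)
  expect_equal(sum(grepl("^chr1\t.*pattern_", trk)), n_sig)
})

test_that("track lines follow BED conventions with genome coordinates and scores", {
  # region at chr1:1000 (+): CpG at region offset 10 -> genome 1010-1012
  reg <- make_region(paste0(strrep("AT", 5), "CG", strrep("TA", 20)), "r1",
                     chrom = "chr1", genome_start = 1000L, genome_strand = "+",
                     assembly = "hg38")
  w <- select_window(reg, window = c(5, 20))
  ps <- pattern_set_from_signatures(c(rep("M", 80), rep("U", 20)), w)
  trk <- render_track(ps, reg)
  expect_match(trk[1], '^track name="r1"')
  pat_line <- strsplit(trk[grepl("pattern_1", trk)], "\t")[[1]]
  expect_equal(pat_line[1:3], c("chr1", "1005", "1020"))
  expect_equal(pat_line[5], "800")   # score = round(fraction * 1000)
  blocks_start <- as.integer(strsplit(pat_line[12], ",")[[1]])
  blocks_size <- as.integer(strsplit(pat_line[11], ",")[[1]])
  # the methylated CpG block sits at genome 1010-1012
  expect_true(any(1005 + blocks_start == 1010 & blocks_size == 2))
  expect_true(validate_bed(trk))

  # fraction 1 clamps to score 1000 (single unanimous significant pattern
  # needs alternatives to be possible, so add a tiny second pattern)
  ps2 <- pattern_set_from_signatures(c(rep("M", 999), "U"), w)
  trk2 <- render_track(ps2, reg)
  expect_match(trk2[grepl("pattern_1", trk2)], "\t999\t")  # 0.999 -> 999
  expect_true(validate_bed(trk2))

  # missing genome coordinates: actionable error
  reg_nc <- make_region(reg$sequence, "r1")
  expect_error(render_track(ps, reg_nc), "coordinates")
})

test_that("minus-strand regions map blocks through reverse coordinates", {
  reg <- make_region(paste0(strrep("AT", 5), "CG", strrep("TA", 20)), "r1",
                     chrom = "chr2", genome_start = 5000L, genome_strand = "-",
                     assembly = "hg19")
  w <- select_window(reg, window = c(5, 20))
  ps <- pattern_set_from_signatures(rep(c("M", "U"), c(60, 40)), w)
  trk <- render_track(ps, reg)
  expect_true(validate_bed(trk))
  # region length 52: window [5,20) -> genome [5000+32, 5000+47)
  pat_line <- strsplit(trk[grepl("pattern_1", trk)], "\t")[[1]]
  expect_equal(pat_line[2:3], c("5032", "5047"))
})

test_that("text and track renderers are pure (byte-identical on re-run)", {
  ps <- text_ps(80, 20)
  expect_identical(render_text(ps), render_text(ps))
  reg <- make_region("TACGTT", "r1", chrom = "chr1", genome_start = 100L,
                     genome_strand = "+", assembly = "hg38")
  w <- select_window(reg, window = c(0, 6))
  ps2 <- pattern_set_from_signatures(c(rep("M", 80), rep("U", 20)), w)
  expect_identical(render_track(ps2, reg), render_track(ps2, reg))
})

test_that("autoplot draws one row per significant pattern plus a summary row", {
  ps <- text_ps(80, 20)
  p <- autoplot(ps)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  # layer 1: pattern circles (1 significant pattern x 1 site)
  expect_equal(nrow(built$data[[1]]), 1L)
  # layer 2: summary circles, one per site
  expect_equal(nrow(built$data[[2]]), 1L)

  empty <- pattern_set_from_signatures(character(0),
                                       select_window(make_region("TACGTT"),
                                                     window = c(0, 6)))
  expect_s3_class(autoplot(empty), "ggplot")
  expect_match(autoplot(empty)$labels$caption, "[Nn]o significant")
})

test_that("figures are written as PNG and EPS files", {
  skip_if_not(capabilities("png"), "no png device")
  ps <- text_ps(80, 20)
  png_path <- tempfile(fileext = ".png")
  render_figure(ps, png_path, format = "png")
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
  eps_path <- tempfile(fileext = ".eps")
  render_figure(ps, eps_path, format = "eps")
  expect_true(file.exists(eps_path) && file.size(eps_path) > 0)
})

test_that("pattern and ASM TSV writers produce the documented columns", {
  ps <- text_ps(80, 20)
  f <- tempfile(fileext = ".tsv")
  write_pattern_tsv(ps, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("region", "window_start", "window_end", "signature",
                             "support", "percent", "z", "p_value", "significant"))
  expect_equal(tab$window_start[1], 1L)  # 1-based in output
  expect_equal(tab$percent[tab$signature == "M"], 80.0)

  reg <- asm_region <- make_region("TACGTCATCGACTGA", "r1")
  w <- select_window(reg, window = c(0, 15))
  mut <- tibble::tibble(region_name = "r1", position = 13L, ref_allele = "G",
                        var_allele = "A", var_count = 50L, covering = 100L,
                        var_fraction = 0.5)
  # 30 REF reads (G at the variant position, methylated) and 30 VAR reads
  # (A there, unmethylated)
  calls <- call_methylation(make_aln(c(rep("TACGTTATCGATTGA", 30),
                                       rep("TATGTTATTGATTAA", 30)),
                                     0, "OT"), reg)
  asm <- detect_asm(calls, w, mut)
  f2 <- tempfile(fileext = ".tsv")
  write_asm_tsv(asm, f2)
  tab2 <- read.delim(f2)
  expect_true(all(c("mutation_position", "level_ref", "level_var",
                    "category_ref", "category_var", "is_candidate") %in% names(tab2)))
  expect_equal(tab2$mutation_position[1], 14L)  # 1-based in output
})
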