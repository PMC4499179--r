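# Region used throughout: CpGs at 2 and 8; non-CpG C at 5, non-CpG G at 13.
asm_region <- function() make_region("TACGTCATCGACTGA", "r1")

test_that("allele counts exclude conversion-confounded strand/position pairs", {
  reg <- asm_region()
  # an OT read with T at the non-CpG C position 5 contributes nothing there,
  # but its A at the reference-G position 13 is counted as an allele
  aln <- make_aln("TACGTTATCGATTAA", 0, "OT")
  calls <- call_methylation(aln, reg)
  cnt <- count_alleles(calls, reg)
  expect_equal(cnt$depth[cnt$position == 5], 0L)   # ref C, OT confounded
  expect_equal(cnt$A[cnt$position == 13], 1L)      # ref G, OT informative
  # an OB read is confounded at G positions but informative at C positions
  aln2 <- make_aln("TACGTCATCAACTAA", 0, "OB")
  cnt2 <- count_alleles(call_methylation(aln2, reg), reg)
  expect_equal(cnt2$depth[cnt2$position == 13], 0L)
  expect_equal(cnt2$C[cnt2$position == 5], 1L)
})

test_that("a 25% variant at a CpG guanine is counted from top-strand reads only", {
  reg <- asm_region()
  # 100 OT reads; 25 carry A at the CpG G offset 9 (the biallelic G>A case)
  seqs <- c(rep("TACGTTATCGATTGA", 75), rep("TACGTTATCAATTGA", 25))
  aln <- make_aln(seqs, 0, "OT")
  cnt <- count_alleles(call_methylation(aln, reg), reg)
  expect_equal(cnt$G[cnt$position == 9], 75L)
  expect_equal(cnt$A[cnt$position == 9], 25L)
  muts <- call_mutations(cnt, threshold = 0.2)
  hit <- muts[muts$position == 9, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$ref_allele, "G")
  expect_equal(hit$var_allele, "A")
  expect_equal(hit$var_fraction, 0.25)
})

test_that("mutation calling respects the fraction threshold and coverage floor", {
  reg <- asm_region()
  seqs <- c(rep("TACGTTATCGATTGA", 91), rep("TACGTTATCAATTGA", 9))
  aln <- make_aln(seqs, 0, "OT")
  cnt <- count_alleles(call_methylation(aln, reg), reg)
  expect_equal(nrow(call_mutations(cnt, threshold = 0.2)[
    call_mutations(cnt, threshold = 0.2)$position == 9, ]), 0L)  # 0.09 < 0.2

  # 5 covering reads: below the default floor of 10, no call
  aln5 <- make_aln(rep("TACGTTATCAATTGA", 5), 0, "OT")
  cnt5 <- count_alleles(call_methylation(aln5, reg), reg)
  expect_equal(nrow(call_mutations(cnt5)), 0L)
  expect_gt(nrow(call_mutations(cnt5, min_coverage = 1)), 0L)
  expect_error(call_mutations(cnt5, threshold = 0), "threshold")
})

test_that("allele splitting partitions reads into REF, VAR and unassigned", {
  reg <- asm_region()
  aln <- make_aln(
    c("TACGTTATCGATTGA",   # OT, G at pos 9 -> REF
      "TACGTTATCAATTGA",   # OT, A at pos 9 -> VAR
      "TACGTTATCTATTGA"),  # OT, T at pos 9 -> third base, unassigned
    0, "OT")
  calls <- call_methylation(aln, reg)
  mut <- tibble::tibble(region_name = "r1", position = 9L, ref_allele = "G",
                        var_allele = "A", var_count = 1L, covering = 2L,
                        var_fraction = 0.5)
  sp <- split_by_allele(calls, mut)
  expect_equal(sp$allele, c("REF", "VAR", NA))

  # an OB read is confounded at this reference-G position -> unassigned
  ob <- call_methylation(make_aln("TACGTCATCGACTAA", 0, "OB"), reg)
  expect_true(is.na(split_by_allele(ob, mut)$allele))

  # a read not covering the position -> unassigned
  short <- call_methylation(make_aln("TACGTTAT", 0, "OT"), reg)
  expect_true(is.na(split_by_allele(short, mut)$allele))
})

test_that("methylation levels band into LOW (<=0.2), HIGH (>=0.8), INTERMEDIATE", {
  expect_equal(categorize_level(0.20), "LOW")
  expect_equal(categorize_level(0.80), "HIGH")
  expect_equal(categorize_level(0.50), "INTERMEDIATE")
  expect_equal(categorize_level(0), "LOW")
  expect_equal(categorize_level(1), "HIGH")
  expect_equal(categorize_level(c(0.21, 0.79)), c("INTERMEDIATE", "INTERMEDIATE"))
  expect_error(categorize_level(1.1), "0, 1")
})

# build calls with exact per-allele methylation levels at both sites:
# the first round(p * n) reads of a group are methylated at both CpGs
asm_calls <- function(n_ref, n_var, p_ref, p_var) {
  reg <- asm_region()
  mk <- function(n, p, allele_base) {
    n_m <- round(p * n)
    vapply(seq_len(n), function(i) {
      s <- "TACGTTATCGATTGA"
      if (i > n_m) {
        substr(s, 3, 3) <- "T"
        substr(s, 9, 9) <- "T"
      }
      substr(s, 14, 14) <- allele_base   # offset 13, ref G
      s
    }, "")
  }
  seqs <- c(mk(n_ref, p_ref, "G"), mk(n_var, p_var, "A"))
  make_aln(seqs, 0, "OT") |> call_methylation(reg)
}

test_that("ASM fires only when categories differ AND the level gap exceeds 20%", {
  reg <- asm_region()
  w <- select_window(reg, window = c(0, 15))
  mut <- tibble::tibble(region_name = "r1", position = 13L, ref_allele = "G",
                        var_allele = "A", var_count = 50L, covering = 100L,
                        var_fraction = 0.5)
  # HIGH (0.9) vs LOW (0.1), gap 0.8: candidate at every site
  a <- detect_asm(asm_calls(50, 50, 0.9, 0.1), w, mut)
  expect_true(a$is_candidate)
  expect_equal(a$sites$level_ref, c(0.9, 0.9))
  expect_equal(a$sites$level_var, c(0.1, 0.1))
  expect_equal(a$sites$category_ref, c("HIGH", "HIGH"))
  expect_equal(a$sites$category_var, c("LOW", "LOW"))
  expect_true(all(a$sites$discriminating))
  expect_s3_class(a$ref_patterns, "pattern_set")
  expect_equal(glance(a)$is_candidate, TRUE)

  # LOW (0.15) vs INTERMEDIATE (0.30): categories differ but the gap is
  # 0.15 <= 0.20, so both conditions are not met
  b <- detect_asm(asm_calls(100, 100, 0.15, 0.30), w, mut)
  expect_false(b$is_candidate)
  expect_equal(b$sites$category_ref, c("LOW", "LOW"))
  expect_equal(b$sites$category_var, c("INTERMEDIATE", "INTERMEDIATE"))

  # both INTERMEDIATE (0.50 vs 0.79) despite a 0.29 gap: category fails
  cc <- detect_asm(asm_calls(100, 100, 0.50, 0.79), w, mut)
  expect_false(cc$is_candidate)
  expect_equal(unique(c(cc$sites$category_ref, cc$sites$category_var)),
               "INTERMEDIATE")
})

test_that("allele groups below the size floor give an insufficient-data result", {
  reg <- asm_region()
  w <- select_window(reg, window = c(0, 15))
  mut <- tibble::tibble(region_name = "r1", position = 13L, ref_allele = "G",
                        var_allele = "A", var_count = 3L, covering = 8L,
                        var_fraction = 0.4)
  a <- detect_asm(asm_calls(5, 3, 0.9, 0.1), w, mut)
  expect_equal(a$status, "insufficient")
  expect_true(is.na(a$is_candidate))
  expect_equal(length(a$discriminating_sites), 0L)
})

test_that("mutations gain dbSNP IDs from a local VCF by genome position", {
  regs <- make_region("TACGTCATCGACTGA", "r1", chrom = "chr11",
                      genome_start = 1000L, genome_strand = "+", assembly = "hg19")
  muts <- tibble::tibble(region_name = "r1", position = 13L, ref_allele = "G",
                         var_allele = "A", var_count = 25L, covering = 100L,
                         var_fraction = 0.25)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr11\t1014\trs0000001\tG\tA\t.\t.\t."), vcf)
  out <- annotate_mutations(muts, regs, vcf)
  expect_equal(out$dbsnp_id, "rs0000001")
  # position mismatch -> no annotation
  muts2 <- dplyr::mutate(muts, position = 5L)
  expect_true(is.na(annotate_mutations(muts2, regs, vcf)$dbsnp_id))
})
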