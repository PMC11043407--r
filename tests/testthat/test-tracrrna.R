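test_that("Karlin-Altschul parameters match the +1/-1 closed forms", {
  ka <- casforge:::karlin_altschul(0.25)
  expect_equal(ka$lambda, log(3), tolerance = 1e-12)
  expect_equal(ka$H, log(3) / 2, tolerance = 1e-12)
  # K for the uniform-composition +/-1 walk
  expect_equal(ka$K, 1 / 3, tolerance = 1e-6)
})

test_that("planted anti-repeats are found with oracle-checked scores", {
  set.seed(11)
  rep24 <- rand_seq(24)
  flank <- paste0(rand_seq(1000), revcomp(rep24), rand_seq(1976))
  h <- find_anti_repeats(flank, rep24)
  expect_equal(h$strand[1L], "-")
  expect_equal(h$score[1L], 24)
  expect_equal(c(h$start[1L], h$end[1L]), c(1001L, 1024L))
  expect_equal(h$aligned_frac[1L], 1)

  # random flank with no planted copy: no reported hit scores >= 16, in
  # agreement with an exhaustive Smith-Waterman oracle over the same flank
  f2 <- rand_seq(3000)
  h2 <- find_anti_repeats(f2, rep24)
  if (nrow(h2)) expect_true(all(h2$score < 16))
  sw <- max(oracle_sw_score(rep24, f2), oracle_sw_score(revcomp(rep24), f2))
  expect_lt(sw, 16)

  # planted copy with 3 mismatches: oracle alignment score 21 - 3 = 18
  r2 <- mutate_at(rep24, c(3, 12, 21))
  f3 <- paste0(rand_seq(800), revcomp(r2), rand_seq(1000))
  h3 <- find_anti_repeats(f3, rep24)
  expect_equal(h3$score[1L], 18)
  expect_equal(h3$strand[1L], "-")
  expect_equal(oracle_sw_score(revcomp(rep24), revcomp(r2)), 18)

  # hit scores never exceed repeat length; strands swap under reverse
  # complement of the flank and nothing else
  expect_true(all(h3$score <= 24))
  h3rc <- find_anti_repeats(revcomp(f3), rep24)
  expect_equal(h3rc$score, h3$score)
  expect_equal(h3rc$strand, chartr("+-", "-+", h3$strand))
  expect_equal(h3rc$start, nchar(f3) - h3$end + 1L)

  expect_error(find_anti_repeats(f2, "ACGTA"), "word_size")
})

test_that("hits overlapping the array and weak e-values are filtered", {
  set.seed(4)
  rep24 <- rand_seq(24)
  flank <- paste0(rand_seq(500), rep24, rand_seq(500), revcomp(rep24),
                  rand_seq(500))
  h_all <- find_anti_repeats(flank, rep24)
  expect_equal(nrow(h_all), 2L)
  h_flt <- find_anti_repeats(flank, rep24, array_span = c(501L, 524L))
  expect_equal(nrow(h_flt), 1L)
  expect_equal(h_flt$strand, "-")
  expect_true(all(h_flt$evalue <= 1))
})

test_that("terminator detection follows the hairpin + T-tract rule", {
  # 7-bp stem, 4-nt loop, 6 T -> score 2*7 + 6 = 20
  t1 <- predict_terminators("GGGGCGCAAAAGCGCCCCTTTTTTCAGCAT")
  expect_equal(t1$stem_len[1L], 7L)
  expect_equal(t1$u_tract_len[1L], 6L)
  expect_equal(t1$score[1L], 20L)
  # hairpin without a downstream T-tract
  expect_equal(nrow(predict_terminators("GGGGCGCAAAAGCGCCCCAAAAAAAAAAAA")), 0L)
  # poly-A window
  expect_equal(nrow(predict_terminators(strrep("A", 40))), 0L)
  expect_error(predict_terminators("ACGTACGT"), "20")
})

planted_tracr_fixture <- function(seed, mism = c(10, 25)) {
  set.seed(seed)
  rep36 <- rand_seq(36)
  anti <- revcomp(rep36)
  if (length(mism)) anti <- mutate_at(anti, mism)
  tracr <- paste0(anti, "AA", "GCGGCTTCGGCCGC", "AA",
                  "GGCGCGCCTTCGGGCGCGCCTTTTTT")
  list(repeat_seq = rep36,
       contig = paste0(rand_seq(500), tracr, rand_seq(500)),
       anti_span = c(501L, 536L),
       tracr_span = c(501L, 500L + nchar(tracr)))
}

test_that("candidates run from the anti-repeat to the terminator", {
  fx <- planted_tracr_fixture(5)
  h <- find_anti_repeats(fx$contig, fx$repeat_seq)
  cands <- build_tracr_candidates(fx$contig, h[1, , drop = FALSE])
  expect_length(cands, 1L)
  cand <- cands[[1L]]
  expect_equal(cand$span[1L], fx$anti_span[1L])
  expect_equal(cand$strand, "+")
  expect_false(is.character(cand$terminator))   # a real terminator, not poly-T
  expect_lte(abs(cand$span[2L] - fx$tracr_span[2L]), 3L)
  expect_match(cand$sequence, "^[ACGU]+$")
})

test_that("sgRNA scaffolds assemble with the tetraloop at the junction", {
  # fully complementary anti-repeat: tetraloop between repeat and anti parts
  rep16 <- "GTTTTAGAGCTATGCT"
  cand <- structure(list(sequence = dna_to_rna(paste0(revcomp(rep16),
                                                      "AAGGCCGGCCTT")),
                         anti_repeat = c(1L, 16L), terminator = "polyT",
                         span = c(1L, 28L), strand = "+"),
                    class = "tracr_candidate")
  sc <- assemble_sgrna(rep16, cand, form = "FS")
  expect_equal(lengths(regmatches(sc$sequence, gregexpr("GAAA", sc$sequence))), 1L)
  expect_equal(nrow(sc$duplex_pairs), 16L)
  expect_equal(substr(sc$sequence, 17, 20), "GAAA")

  # TS with trim_len 6 from a longer duplex keeps 6 junction-proximal pairs
  ts <- assemble_sgrna(rep16, cand, form = "TS", trim_len = 6L)
  expect_equal(nrow(ts$duplex_pairs), 6L)
  expect_lt(nchar(ts$sequence), nchar(sc$sequence))

  # opt forms demand substitutions; applied substitutions change the sequence
  expect_error(assemble_sgrna(rep16, cand, form = "FS-opt"),
               "opt form requires substitutions")
  opt <- assemble_sgrna(rep16, cand, form = "FS-opt",
                        substitutions = data.frame(pos = 1L, base = "C"))
  expect_equal(substr(opt$sequence, 1, 1), "C")

  # non-complementary candidate: no duplex
  bad <- cand
  bad$sequence <- dna_to_rna(strrep("A", 27))
  expect_error(assemble_sgrna(rep16, bad, form = "FS"), "no duplex")
})

test_that("module checks pass planted scaffolds and reject broken ones", {
  fx <- planted_tracr_fixture(9)
  h <- find_anti_repeats(fx$contig, fx$repeat_seq)
  cand <- build_tracr_candidates(fx$contig, h[1, , drop = FALSE])[[1L]]
  sc <- assemble_sgrna(fx$repeat_seq, cand, form = "FS")
  pr <- fold(sc$sequence)
  expect_true(check_modules(sc, pr)$pass)

  # scrambled anti-repeat segment: the duplex module must fail
  set.seed(42)
  cand2 <- cand
  scr <- paste(sample(strsplit(substr(cand2$sequence, 1, 36), "")[[1]]),
               collapse = "")
  cand2$sequence <- paste0(scr, substr(cand2$sequence, 37, nchar(cand2$sequence)))
  res2 <- tryCatch({
    sc2 <- assemble_sgrna(fx$repeat_seq, cand2, form = "FS")
    check_modules(sc2, fold(sc2$sequence))
  }, error = function(e) list(pass = FALSE, reasons = "duplex"))
  expect_false(res2$pass)
  expect_true("duplex" %in% res2$reasons)

  # truncation before the terminator hairpin: the 3' hairpin must fail
  cand3 <- cand
  cut <- nchar(cand3$sequence) - 28L
  cand3$sequence <- substr(cand3$sequence, 1, cut)
  sc3 <- assemble_sgrna(fx$repeat_seq, cand3, form = "FS")
  res3 <- check_modules(sc3, fold(sc3$sequence))
  expect_false(res3$pass)
  expect_true("3' hairpin" %in% res3$reasons)

  # missing annotations are an error
  sc_bad <- sc
  sc_bad$duplex_pairs <- NULL
  expect_error(check_modules(sc_bad, pr), "annotations")
})
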