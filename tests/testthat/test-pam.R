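toy_reads <- function(pams, design, mutate_anchor = 0L) {
  anchor <- design$anchor
  if (mutate_anchor > 0L) anchor <- mutate_at(anchor, seq_len(mutate_anchor))
  sequence_set(sprintf("r%04d", seq_along(pams)),
               paste0("GACGCATAAAG", anchor, pams, design$backbone_context),
               quality = strrep("I", 11L + nchar(anchor) + 8L +
                                  nchar(design$backbone_context)))
}

test_that("PAM extraction counts anchored 8-mers and applies QC rules", {
  des <- pam_library_design()
  reads <- toy_reads(rep("ACGTACGT", 1000L), des)
  cnt <- extract_pams(reads, des)
  expect_equal(as.integer(cnt["ACGTACGT"]), 1000L)
  expect_equal(attr(cnt, "total"), 1000L)

  # anchor too close to the read end: the PAM would run off -> skipped
  short <- sequence_set("s1", paste0("GACGCATAAAG", des$anchor, "ACGT"),
                        quality = strrep("I", 11L + nchar(des$anchor) + 4L))
  expect_error(extract_pams(short, des), "no PAMs extracted")
  mixed <- rbind(toy_reads("AAAATTTT", des), short)
  class(mixed) <- c("sequence_set", "data.frame")
  cnt2 <- extract_pams(mixed, des)
  expect_equal(attr(cnt2, "qc")[["off_end"]], 1L)
  expect_equal(attr(cnt2, "total"), 1L)

  # one anchor mismatch: counted at max_anchor_mismatch 1, skipped at 0
  mm <- toy_reads(rep("GGGGCCCC", 10L), des, mutate_anchor = 1L)
  c1 <- extract_pams(mm, des, max_anchor_mismatch = 1L)
  expect_equal(attr(c1, "total"), 10L)
  expect_error(extract_pams(mm, des, max_anchor_mismatch = 0L),
               "no PAMs extracted")
})

test_that("position profiles have unit columns and bounded information", {
  des <- pam_library_design()
  prof1 <- position_profile(extract_pams(toy_reads(rep("ACGTACGT", 50L), des), des))
  expect_true(all(abs(colSums(prof1$freq) - 1) < 1e-9))
  expect_equal(unname(prof1$info), rep(2, 8), tolerance = 1e-12)

  # uniform over all 4 bases at each position -> 0 bits
  unif <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1,
                paste, collapse = "")
  prof0 <- position_profile(extract_pams(
    toy_reads(paste0(unif, unif), des), des))
  expect_equal(unname(prof0$info), rep(0, 8), tolerance = 1e-12)

  # 50/50 A/T at one position -> exactly 1 bit there
  pams <- paste0(rep(c("A", "T"), 25L), strrep("C", 7L))
  prof2 <- position_profile(extract_pams(toy_reads(pams, des), des))
  expect_equal(unname(prof2$info[1L]), 1, tolerance = 1e-12)
  expect_equal(unname(prof2$info[2L]), 2, tolerance = 1e-12)
})

test_that("informative position selection takes the top-k, ties leftmost", {
  prof <- structure(list(info = c(0, 0, 0, 0, 1.2, 0.8, 0.1, 1.5)),
                    class = "position_profile")
  expect_equal(select_informative_positions(prof, 4L), c(5L, 6L, 7L, 8L))
  prof2 <- structure(list(info = rep(0.5, 8)), class = "position_profile")
  expect_equal(select_informative_positions(prof2, 4L), 1:4)
  expect_equal(select_informative_positions(prof, 8L), 1:8)
  expect_error(select_informative_positions(prof, 9L), "exceeds")
})

test_that("enrichment ratios follow the marginal-frequency definition", {
  des <- pam_library_design()
  # identical libraries -> every ratio exactly 1
  pams <- paste0(rep(c("AACC", "GGTT", "ACGT", "TGCA"), 25L), "AAAA")
  cl <- extract_pams(toy_reads(pams, des), des)
  en <- pam_enrichment(cl, cl, positions = 1:4)
  expect_equal(nrow(en), 256L)
  expect_true(all(en$ratio == 1))

  # brute-force count oracle on a 12-read toy per library
  clv <- c(rep("AAAAAAAA", 6L), rep("CCCCAAAA", 3L), rep("GGGGAAAA", 3L))
  ctl <- c(rep("AAAAAAAA", 3L), rep("CCCCAAAA", 6L), rep("TTTTAAAA", 3L))
  enr <- pam_enrichment(extract_pams(toy_reads(clv, des), des),
                        extract_pams(toy_reads(ctl, des), des),
                        positions = 1:4, pseudocount = 1)
  oracle_ratio <- function(cmb) {
    nc <- sum(substr(clv, 1, 4) == cmb)
    nu <- sum(substr(ctl, 1, 4) == cmb)
    ((nc + 1) / (12 + 256)) / ((nu + 1) / (12 + 256))
  }
  for (cmb in c("AAAA", "CCCC", "GGGG", "TTTT", "ACGT"))
    expect_equal(enr$ratio[enr$combo == cmb], oracle_ratio(cmb), info = cmb)

  # swapping libraries inverts ratios (up to pseudocount terms; exact here
  # because totals are equal)
  swap <- pam_enrichment(extract_pams(toy_reads(ctl, des), des),
                         extract_pams(toy_reads(clv, des), des),
                         positions = 1:4, pseudocount = 1)
  expect_equal(swap$ratio, 1 / enr$ratio, tolerance = 1e-12)
})

test_that("consensus calling recovers degenerate patterns losslessly", {
  planted <- c("GWNT", "GCDT", "ATDT")
  E <- unique(unlist(lapply(planted, expand_iupac)))
  expect_length(E, 14L)   # 8 + 3 + 3 disjoint combinations
  cons <- call_consensus(toy_enrichment(E), tau = 0.2)
  expect_setequal(cons$patterns, planted)
  expect_setequal(cons$patterns_full, paste0("NNNN", planted))
  expect_setequal(cons$enriched, E)

  # a single enriched combination is its own pattern
  cons1 <- call_consensus(toy_enrichment("GATT"))
  expect_equal(cons1$patterns, "GATT")

  # random enriched set: the cover is exact and minimal against a
  # brute-force search over all valid IUPAC products
  set.seed(5)
  E2 <- sample(all_kmers(4), 6L)
  cons2 <- call_consensus(toy_enrichment(E2))
  expect_setequal(unique(unlist(lapply(cons2$patterns, expand_iupac))), E2)
  prods <- casforge:::valid_products(E2)
  k <- length(cons2$patterns)
  if (k > 1L) {
    smaller_cover_exists <- FALSE
    for (kk in seq_len(k - 1L)) {
      for (rows in utils::combn(length(prods), kk, simplify = FALSE)) {
        covered <- unique(unlist(lapply(prods[rows], `[[`, "members")))
        if (setequal(covered, E2)) { smaller_cover_exists <- TRUE; break }
      }
      if (smaller_cover_exists) break
    }
    expect_false(smaller_cover_exists)
  }
  expect_error(call_consensus(toy_enrichment(character(0), lo = 0)),
               "no enriched")
})

test_that("cut-site calls report offset and geometry from strand modes", {
  ends <- make_cut_fragments(seed = 4)
  call <- infer_cut_site(ends)
  expect_equal(call$offset_bp, 3L)
  expect_equal(call$geometry, "blunt")

  # top mode 4 / bottom mode 3 -> 1-nt overhang (geometry arithmetic)
  ends2 <- data.frame(strand = rep(c("+", "-"), each = 30L),
                      pos = c(rep(4L, 30L), rep(3L, 30L)))
  call2 <- infer_cut_site(ends2)
  expect_equal(call2$overhang, 1L)
  expect_match(call2$geometry, "overhang\\(1\\)")

  # insufficient support -> undetermined
  few <- data.frame(strand = c(rep("+", 5L), rep("-", 12L)),
                    pos = rep(3L, 17L))
  expect_equal(infer_cut_site(few, min_support = 10L)$geometry, "undetermined")
})
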