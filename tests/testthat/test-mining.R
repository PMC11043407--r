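plant_array <- function(bg_before, repeats, spacers, bg_after) {
  units <- character(0)
  for (i in seq_along(spacers)) units <- c(units, repeats[i], spacers[i])
  units <- c(units, repeats[length(repeats)])
  list(contig = paste0(bg_before, paste(units, collapse = ""), bg_after),
       start = nchar(bg_before) + 1L,
       end = nchar(bg_before) + sum(nchar(units)))
}

test_that("planted repeat arrays are detected with exact spans", {
  set.seed(7)
  rep30 <- rand_seq(30)
  pl <- plant_array(rand_seq(2000), rep(rep30, 3),
                    c(rand_seq(35), rand_seq(36)), rand_seq(2000))
  arrays <- detect_crispr_arrays(pl$contig)
  expect_length(arrays, 1L)
  expect_equal(arrays[[1]]$n_repeats, 3L)
  expect_equal(arrays[[1]]$n_spacers, 2L)
  expect_equal(arrays[[1]]$start, pl$start)
  expect_equal(arrays[[1]]$end, pl$end)
  expect_equal(arrays[[1]]$repeat_consensus, rep30)

  # repeats below the 23-nt minimum are not reported
  rep20 <- rand_seq(20)
  pl2 <- plant_array(rand_seq(1000), rep(rep20, 3),
                     c(rand_seq(35), rand_seq(36)), rand_seq(1000))
  expect_length(detect_crispr_arrays(pl2$contig), 0L)

  # two arrays 5 kb apart, spans compared to the planting record
  repA <- rand_seq(30); repB <- rand_seq(33)
  plA <- plant_array(rand_seq(500), rep(repA, 3),
                     c(rand_seq(31), rand_seq(37)), "")
  plB <- plant_array(paste0(plA$contig, rand_seq(5000)), rep(repB, 4),
                     c(rand_seq(29), rand_seq(40), rand_seq(33)), rand_seq(500))
  arr2 <- detect_crispr_arrays(plB$contig)
  expect_length(arr2, 2L)
  expect_equal(arr2[[1]]$start, plA$start)
  expect_equal(arr2[[1]]$end, plA$end)
  expect_equal(arr2[[2]]$start, plB$start)
  expect_equal(arr2[[2]]$end, plB$end)
})

test_that("array detection respects length bounds and non-overlap invariants", {
  params <- default_config()$mining
  set.seed(21)
  for (trial in 1:5) {
    g <- make_crispr_genome(n_loci = 1L, seed = 100 + trial, n_decoys = 0L)
    arrays <- detect_crispr_arrays(g$contigs[1, ])
    expect_length(arrays, 1L)
    for (a in arrays) {
      sl <- nchar(a$spacers)
      expect_true(all(sl >= params$spacer_min & sl <= params$spacer_max))
      rl <- nchar(a$repeat_consensus)
      expect_true(rl >= params$repeat_min && rl <= params$repeat_max)
    }
    if (length(arrays) > 1L) {
      spans <- t(vapply(arrays, function(a) c(a$start, a$end), c(0L, 0L)))
      expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
    }
  }
  # short contig: empty result, not an error
  expect_length(detect_crispr_arrays(rand_seq(60)), 0L)
})

make_locus_features <- function(contig_id, spans, cas9_aa = 1004,
                                protein = NULL, coverage = 20,
                                species = "sp1") {
  kinds <- names(spans)
  feature_set(rep(contig_id, length(spans)),
              vapply(spans, `[`, 0L, 1L), vapply(spans, `[`, 0L, 2L),
              "+", kinds,
              attributes = lapply(kinds, function(k) {
                list(ID = paste0(contig_id, "_", k), species_id = species,
                     protein_length_aa = if (k == "cas9") cas9_aa else 300,
                     protein_sequence = protein %||%
                       paste(rep("M", if (k == "cas9") cas9_aa else 300),
                             collapse = ""),
                     coverage = coverage)
              }))
}

fake_array <- function(contig_id, start, end, n_spacers = 24L) {
  structure(list(contig_id = contig_id, start = start, end = end,
                 repeat_consensus = strrep("A", 36), repeat_spans = NULL,
                 spacers = character(n_spacers), n_repeats = n_spacers + 1L,
                 n_spacers = n_spacers), class = "crispr_array")
}

test_that("locus assembly enforces the 10-kbp co-localization rule", {
  arr <- fake_array("c1", 20000L, 21700L)
  # all components within 8 kbp of each other
  f1 <- make_locus_features("c1", list(cas9 = c(12500L, 15515L),
                                       cas1 = c(16000L, 16900L),
                                       cas2 = c(17200L, 17500L)))
  expect_length(assemble_loci(list(arr), f1), 1L)
  # cas2 12 kbp from the array -> no locus
  f2 <- make_locus_features("c1", list(cas9 = c(12500L, 15515L),
                                       cas1 = c(16000L, 16900L),
                                       cas2 = c(7500L, 7800L)))
  expect_length(assemble_loci(list(arr), f2), 0L)
  # missing cas1 -> no complete locus
  f3 <- make_locus_features("c1", list(cas9 = c(12500L, 15515L),
                                       cas2 = c(17200L, 17500L)))
  expect_length(assemble_loci(list(arr), f3), 0L)
})

test_that("locus filters apply the Cas9 length and spacer-count rules", {
  arr <- fake_array("c1", 20000L, 21700L, n_spacers = 24L)
  spans <- list(cas9 = c(12500L, 15515L), cas1 = c(16000L, 16900L),
                cas2 = c(17200L, 17500L))
  mk <- function(aa, nsp) {
    a <- fake_array("c1", 20000L, 21700L, n_spacers = nsp)
    assemble_loci(list(a), make_locus_features("c1", spans, cas9_aa = aa))
  }
  expect_length(filter_loci(mk(1004, 24L)), 1L)   # retained
  expect_length(filter_loci(mk(900, 24L)), 0L)    # shorter than 950 aa
  expect_length(filter_loci(mk(1100, 24L)), 0L)   # not strictly below 1100 aa
  expect_length(filter_loci(mk(1004, 5L)), 0L)    # boundary: needs > 5 spacers
  expect_length(filter_loci(mk(1004, 6L)), 1L)

  # idempotence and subset property
  loci <- c(mk(1004, 24L), mk(980, 10L), mk(900, 24L))
  once <- filter_loci(loci)
  expect_identical(filter_loci(once), once)
  expect_true(all(vapply(once, `[[`, "", "locus_id") %in%
                    vapply(loci, `[[`, "", "locus_id")))

  # missing protein_length_aa raises an error naming the locus
  bad <- mk(1004, 24L)
  bad[[1]]$cas9$attributes[[1]]$protein_length_aa <- NULL
  expect_error(filter_loci(bad), bad[[1]]$locus_id, fixed = TRUE)
})

test_that("coverage deduplication keeps the deepest intact ortholog", {
  spans <- list(cas9 = c(12500L, 15515L), cas1 = c(16000L, 16900L),
                cas2 = c(17200L, 17500L))
  set.seed(3)
  prot <- rand_seq(400, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  mk1 <- function(contig, protein, coverage) {
    arr <- fake_array(contig, 20000L, 21700L)
    assemble_loci(list(arr),
                  make_locus_features(contig, spans, cas9_aa = nchar(protein),
                                      protein = protein, coverage = coverage))[[1]]
  }
  # identical proteins, different coverage -> highest coverage wins
  l1 <- mk1("cA", prot, 12); l2 <- mk1("cB", prot, 30)
  got <- dedupe_by_coverage(list(l1, l2))
  expect_length(got, 1L)
  expect_equal(got[[1]]$locus_id, l2$locus_id)

  # 10-aa deletion inside a domain span -> discarded despite higher coverage
  deleted <- paste0(substr(prot, 1, 99), substr(prot, 110, 400))
  l3 <- mk1("cC", deleted, 50)
  spans_cfg <- list(sp1 = list(spans = rbind(c(80L, 130L))))
  got2 <- dedupe_by_coverage(list(l1, l3), domain_spans = spans_cfg)
  expect_equal(got2[[1]]$locus_id, l1$locus_id)

  # single-member group returned unconditionally
  expect_equal(dedupe_by_coverage(list(l1))[[1]]$locus_id, l1$locus_id)
})

test_that("greedy clustering matches a dynamic-programming identity oracle", {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(11)
  s1 <- rand_seq(100, aas)
  s2 <- mutate_protein <- s1
  pos <- sample(100, 4)
  for (p in pos) {
    old <- substr(s2, p, p)
    substr(s2, p, p) <- setdiff(aas, old)[1]
  }
  oid <- oracle_nw_identity(s1, s2)
  expect_equal(oid, 0.96)
  recs <- sequence_set(c("a", "b"), c(s1, s2), moltype = "protein")
  cl95 <- cluster_sequences(recs, identity = 0.95, coverage = 0.5)
  expect_length(cl95, 1L)
  cl97 <- cluster_sequences(recs, identity = 0.97, coverage = 0.5)
  expect_length(cl97, 2L)

  # identical pair clusters at 0.95; unrelated random pair does not
  recs2 <- sequence_set(c("a", "b"), c(s1, s1), moltype = "protein")
  expect_length(cluster_sequences(recs2, 0.95, 0.5), 1L)
  recs3 <- sequence_set(c("a", "b"), c(rand_seq(300, aas), rand_seq(300, aas)),
                        moltype = "protein")
  expect_length(cluster_sequences(recs3, 0.95, 0.5), 2L)

  # identity 1.0 -> singletons for distinct sequences; identity ~0 -> one cluster
  expect_length(cluster_sequences(recs, 1.0, 0.5), 2L)
  expect_length(cluster_sequences(recs3, 0.01, 0.01), 1L)
  expect_length(cluster_sequences(recs[0, ], 0.95, 0.5), 0L)
})

test_that("length-outlier exclusion uses population sd below the median", {
  cl <- structure(list(centroid_id = "a",
                       member_ids = c("a", "b", "c", "d", "e"),
                       identity_threshold = 0.7, coverage_threshold = 0.5),
                  class = "sequence_cluster")
  lens <- c(a = 1000, b = 1000, c = 1000, d = 1000, e = 400)
  # arithmetic oracle: median 1000, population sd, threshold = median - 2 sd
  sd_pop <- sqrt(mean((lens - mean(lens))^2))
  expect_equal(sd_pop, 240, tolerance = 1e-10)
  out <- filter_length_outliers(cl, lens)
  expect_setequal(out$member_ids, c("a", "b", "c", "d"))

  # equal lengths: sd 0, nothing below the median
  cl$member_ids <- c("a", "b", "c")
  expect_length(filter_length_outliers(cl, c(a = 5, b = 5, c = 5))$member_ids, 3L)
  # single member unchanged
  cl$member_ids <- "a"
  expect_equal(filter_length_outliers(cl, c(a = 123))$member_ids, "a")
})
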