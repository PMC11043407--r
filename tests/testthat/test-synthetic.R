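test_that("genome generator is deterministic and its truth matches mining", {
  g1 <- make_crispr_genome(n_loci = 2L, seed = 1L)
  g2 <- make_crispr_genome(n_loci = 2L, seed = 1L)
  expect_identical(g1, g2)
  g3 <- make_crispr_genome(n_loci = 2L, seed = 2L)
  expect_false(identical(g1$contigs$sequence, g3$contigs$sequence))

  # truth lists the planted arrays; detection recovers exactly those spans
  for (i in seq_len(2L)) {
    tr <- g1$truth$loci[[i]]
    arr <- detect_crispr_arrays(g1$contigs[g1$contigs$id == tr$contig_id, ])
    expect_length(arr, 1L)
    expect_equal(arr[[1L]]$start, tr$array$start)
    expect_equal(arr[[1L]]$end, tr$array$end)
    expect_equal(arr[[1L]]$n_spacers, tr$array$n_spacers)
    expect_equal(arr[[1L]]$repeat_consensus, tr$array$repeat_seq)
  }

  # a 900-aa cas9 fixture is marked designed-to-fail with the right reason
  gf <- make_crispr_genome(n_loci = 1L, seed = 3L,
                           locus_spec = list(cas9_aa = 900L), n_decoys = 0L)
  expect_false(gf$truth$loci[[1L]]$expected_pass)
  expect_match(gf$truth$loci[[1L]]$fail_reason, "950")
})

test_that("generated files round-trip through the package parsers", {
  g <- make_crispr_genome(n_loci = 1L, seed = 4L)
  d <- withr::local_tempdir()
  write_fasta(g$contigs, file.path(d, "c.fa"))
  back <- read_fasta(file.path(d, "c.fa"))
  expect_equal(back$sequence, g$contigs$sequence)
  write_gff(g$features, file.path(d, "a.gff3"))
  feats <- read_gff(file.path(d, "a.gff3"))
  expect_equal(feats$kind, g$features$kind)
  expect_equal(feats$start, g$features$start)
  expect_equal(vapply(feats$attributes, `[[`, 0, "protein_length_aa"),
               vapply(g$features$attributes, `[[`, 0L, "protein_length_aa"))

  lib <- make_pam_library(pam_library_design(), "NNNNGWNT",
                          n_reads = 2000L, seed = 5L)
  write_fastq(lib$cleaved, file.path(d, "r.fq"))
  expect_equal(read_fastq(file.path(d, "r.fq")), lib$cleaved)
})

test_that("PAM library simulation honors the cleavage model", {
  des <- pam_library_design()
  pats <- builtin_schemes()$cocas9$patterns
  # null model: no enrichment anywhere
  lib0 <- make_pam_library(des, pats,
                           cleavage_model(p_match = 0.5, p_background = 0.49999,
                                          error_rate = 0),
                           n_reads = 20000L, seed = 6L)
  cl <- extract_pams(lib0$cleaved, des)
  co <- extract_pams(lib0$control, des)
  en <- pam_enrichment(cl, co, 5:8)
  expect_lt(max(en$ratio), 2)
  expect_gt(min(en$ratio), 0.5)

  # error rate 0 and background 0: every cleaved PAM matches a pattern
  lib1 <- make_pam_library(des, pats,
                           cleavage_model(p_match = 0.9, p_background = 0,
                                          error_rate = 0),
                           n_reads = 2000L, seed = 7L)
  pams <- substr(lib1$cleaved$sequence, nchar(des$protospacer) + 1L,
                 nchar(des$protospacer) + 8L)
  hits <- Reduce(`|`, lapply(pats, function(p) casforge:::iupac_match(pams, p)))
  expect_true(all(hits))
  expect_equal(lib1$truth$match_fraction, 1)
  expect_error(make_pam_library(des, pats, n_reads = 10L), "1000")
})

test_that("cut-fragment simulation plants offset, geometry and support", {
  fr <- make_cut_fragments(seed = 8L)
  expect_equal(infer_cut_site(fr)$geometry, "blunt")
  expect_equal(infer_cut_site(fr)$offset_bp, 3L)
  fr2 <- make_cut_fragments(geometry = "five_prime", overhang = 1L, seed = 8L)
  expect_equal(infer_cut_site(fr2)$overhang, 1L)
  fr3 <- make_cut_fragments(n = 5L, seed = 8L)
  expect_equal(infer_cut_site(fr3, min_support = 10L)$geometry, "undetermined")
})

test_that("editing-matrix simulation recovers the planted window", {
  m <- make_editing_matrix(window = 4:6, peak = 0.4, off_window = 0.02,
                           n_guides = 10L, noise_sd = 0.03, seed = 9L)
  expect_equal(estimate_window(m)$positions, 4:6)
  # exact boundary with zero noise: >= semantics keeps peak 0.10 positions
  m2 <- make_editing_matrix(window = 4:6, peak = 0.10, off_window = 0.02,
                            noise_sd = 0, seed = 9L)
  expect_equal(estimate_window(m2)$positions, 4:6)
  expect_identical(make_editing_matrix(seed = 10L), make_editing_matrix(seed = 10L))
})

test_that("reference generator plants verdicts and hits its GC target", {
  sch <- builtin_schemes()
  schemes <- list(CoABE8e = sch$cocas9, SaABE8e = sch$sacas9)
  windows <- list(CoABE8e = default_window(), SaABE8e = default_window())
  ref <- make_reference_and_snvs(length = 30000L, n_snv = 40L,
                                 schemes = schemes, windows = windows,
                                 seed = 11L)
  expect_equal(nrow(ref$snvs), 40L)
  expect_true(all(ref$snvs$ref %in% c("G", "C")))
  for (i in seq_len(40L)) {
    ctx <- substr(ref$genome$sequence, ref$snvs$pos[i] - 50L,
                  ref$snvs$pos[i] + 50L)
    for (e in names(schemes)) {
      expect_equal(snv_targetable(ref$snvs[i, ], ctx, schemes[[e]],
                                  windows[[e]])$targetable,
                   ref$truth$intended[i, e],
                   info = paste("snv", i, e))
    }
  }

  # GC content converges to the target (law of large numbers)
  ref2 <- make_reference_and_snvs(length = 1000000L, n_snv = 10L,
                                  gc_content = 0.41,
                                  schemes = schemes[1], windows = windows[1],
                                  seed = 12L)
  gc <- mean(strsplit(ref2$genome$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.41), 0.005)

  # two schemes with disjoint planted-positive sets: solely fractions equal
  # the planted design
  intended <- matrix(FALSE, 40L, 2L, dimnames = list(NULL, names(schemes)))
  intended[1:10, 1L] <- TRUE
  intended[11:25, 2L] <- TRUE
  ref3 <- make_reference_and_snvs(length = 30000L, n_snv = 40L,
                                  schemes = schemes, windows = windows,
                                  seed = 13L, intended = intended)
  verd <- sapply(names(schemes), function(e) {
    vapply(seq_len(40L), function(i) {
      ctx <- substr(ref3$genome$sequence, ref3$snvs$pos[i] - 50L,
                    ref3$snvs$pos[i] + 50L)
      snv_targetable(ref3$snvs[i, ], ctx, schemes[[e]], windows[[e]])$targetable
    }, NA)
  })
  excl <- exclusive_targetability(lapply(as.data.frame(verd),
                                         function(v) ref3$snvs$id[v]), 40L)
  expect_equal(unname(excl$solely_fraction), c(10 / 40, 15 / 40))
  expect_equal(excl$union_fraction, 25 / 40)

  expect_error(make_reference_and_snvs(length = 5000L, schemes = schemes,
                                       windows = windows), "10 kb")
  expect_error(make_reference_and_snvs(length = 12000L, n_snv = 500L,
                                       schemes = schemes, windows = windows),
               "placeable")
})
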