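test_that("fold contract: length, unfoldable input, alphabet and bounds", {
  r <- rna_fold("AAAAAAAAAA", pairmax)
  expect_equal(r$structure, "..........")
  expect_equal(r$mfe, 0)

  set.seed(5)
  seqs <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(20:80, 1), TRUE),
          collapse = "")
  }, character(1))
  out <- rna_fold(seqs, pairmax)
  expect_equal(nchar(out$structure), nchar(seqs))
  expect_equal(out$mfe_per_nt, out$mfe / nchar(seqs))

  expect_error(rna_fold("ACGTACGT", pairmax), "at least 10")
  expect_error(rna_fold("ACGTACGTXZ", pairmax), "alphabet")
})

test_that("a designed perfect stem is fully paired by the fallback engine", {
  p <- make_precursor(20, 4, 0, mature_length = 15, mature_offset = 2)
  f <- rna_fold(p$sequence, pairmax)
  expect_equal(stringr::str_count(f$structure, "\\("), 20L)
  expect_lt(f$mfe, -20)
})

test_that("thermodynamic backend folds a designed hairpin into one stem", {
  set.seed(21)
  p <- make_precursor(30, 6, 0)
  f <- rna_fold(p$sequence, fold_engine("vienna"))
  expect_equal(nchar(f$structure), p$length)
  expect_lt(f$mfe_per_nt, -0.4)
  expect_equal(count_terminal_loops(f$structure), 1L)
})

test_that("terminal loop counting matches the tree-leaf oracle", {
  expect_equal(count_terminal_loops("((((...))))"), 1L)
  expect_equal(count_terminal_loops("((..))..((...))"), 2L)
  expect_equal(count_terminal_loops("....."), 0L)
  expect_error(count_terminal_loops("(()"), "unbalanced")

  set.seed(101)
  for (i in 1:250) {
    db <- random_db(sample(10:200, 1))
    expect_equal(count_terminal_loops(db), bf_terminal_loops(db),
                 info = db)
  }
})

test_that("longest duplex matches the brute-force run scanner", {
  expect_equal(longest_duplex(perfect_hairpin_db(20)), 20L)
  expect_equal(longest_duplex("((((.((((....))))))))"), 9L)
  expect_equal(longest_duplex("........"), 0L)
  expect_error(longest_duplex(")("), "unbalanced")

  set.seed(202)
  for (i in 1:250) {
    db <- random_db(sample(10:200, 1))
    expect_equal(longest_duplex(db), bf_longest_duplex(db), info = db)
  }
})

test_that("pair tables are involutions consistent with the structure", {
  set.seed(303)
  for (i in 1:50) {
    db <- random_db(sample(10:120, 1))
    p <- pair_table(db)
    paired <- which(!is.na(p))
    expect_equal(p[p[paired]], paired)
    expect_true(all(p[paired] != paired))
    expect_equal(substring(db, paired, paired) == "(",
                 p[paired] > paired)
  }
})

test_that("window grids enumerate the documented start/end lattice", {
  cl <- tibble::tibble(id = "c1:+:300-321", chrom = "c1", strand = "+",
                       start = 300L, end = 321L, flank_start = 100L,
                       flank_end = 521L, read_count = 10L)
  w <- enumerate_windows(cl, step = 100L, min_duplex_length = 10L)
  expect_equal(nrow(w), 9L)
  expect_setequal(unique(w$start), c(100L, 200L, 300L))
  expect_setequal(unique(w$end), c(321L, 421L, 521L))

  # degenerate grid: step beyond the flank width gives the anchors only
  w2 <- enumerate_windows(cl, step = 1000L, min_duplex_length = 10L)
  expect_setequal(unique(w2$start), c(100L, 300L))
  expect_setequal(unique(w2$end), c(321L, 521L))

  # windows below 2 x min_duplex_length are skipped
  cl3 <- dplyr::mutate(cl, flank_start = 290L, flank_end = 331L)
  w3 <- enumerate_windows(cl3, step = 10L, min_duplex_length = 20L)
  expect_true(all(w3$end - w3$start >= 40L))
})

test_that("clusters with oversized flank spans are skipped with a warning", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 2000)))
  cl <- tibble::tibble(id = "big", chrom = "c1", strand = "+",
                       start = 100L, end = 3500L, flank_start = 0L,
                       flank_end = 3700L, read_count = 10L)
  expect_warning(out <- enumerate_candidates(cl, g, tiny_config(),
                                             pairmax), "3000")
  expect_equal(nrow(out), 0L)
})

test_that("select_optimal takes the MFE/nt minimum with deterministic ties", {
  cand <- tibble::tibble(
    cluster_id = "x", start = c(0L, 10L, 20L), end = c(100L, 110L, 120L),
    strand = "+", length = 100L, sequence = "N", structure = ".",
    mfe = c(-30, -45, -42), mfe_per_nt = c(-0.30, -0.45, -0.42))
  best <- select_optimal(cand, 0.01)
  expect_equal(best$mfe_per_nt, -0.45)
  expect_true(best$unique_optimum)

  tie <- dplyr::mutate(cand, mfe_per_nt = c(-0.45, -0.45, -0.30))
  best2 <- select_optimal(tie, 0.01)
  expect_equal(best2$start, 0L)        # longer-equal, then smaller start
  expect_false(best2$unique_optimum)

  one <- cand[1, ]
  expect_true(select_optimal(one, 0.01)$unique_optimum)
  expect_equal(nrow(select_optimal(cand[0, ], 0.01)), 0L)
})

test_that("selection equals the exhaustive minimum over the folded grid", {
  set.seed(77)
  g <- build_genome(length = 8000, n_precursors = 1, seed = 77,
                    spacing = 600L)
  cfg <- tiny_config(fold_backend = "pairmax", window_step = 15L,
                     window_refine_step = 0L)
  pre <- g$precursors
  cl <- tibble::tibble(
    id = "t", chrom = pre$chrom, strand = pre$strand,
    start = pre$mature_start, end = pre$mature_end,
    flank_start = pre$mature_start - 150L, flank_end = pre$mature_end + 150L,
    read_count = 10L)
  cand <- enumerate_candidates(cl, g$genome, cfg, pairmax)
  best <- select_optimal(cand, cfg$uniqueness_tolerance)
  expect_equal(best$mfe_per_nt, min(cand$mfe_per_nt))
  expect_equal(best$mfe, best$mfe_per_nt * best$length)
})

test_that("structure filters enforce the three thresholds with reasons", {
  cfg <- tiny_config(preset = "algae")   # mfe/nt <= -0.4, L_ds >= 24
  cand <- tibble::tibble(cluster_id = "x", start = 0L, end = 60L,
                         strand = "+", length = 60L, sequence = "N",
                         structure = perfect_hairpin_db(28),
                         mfe = -27, mfe_per_nt = -0.45,
                         unique_optimum = TRUE, chrom = "c1")
  ok <- apply_structure_filters(cand, cfg)
  expect_true(ok$structure_pass)
  expect_equal(ok$filter_reasons, "")
  expect_equal(ok$l_ds_max, 28L)

  # N_term = 4 fails the strict bound N_term < 4
  four_loops <- paste(rep("((((....))))", 4), collapse = ".")
  c2 <- dplyr::mutate(cand, structure = four_loops,
                      mfe = -0.45 * nchar(four_loops),
                      mfe_per_nt = -0.45, length = nchar(four_loops))
  r2 <- apply_structure_filters(c2, cfg)
  expect_false(r2$structure_pass)
  expect_match(r2$filter_reasons, "hairpin count")

  # borderline energy: -0.45 passes a -0.4 threshold, -0.35 does not
  c3 <- dplyr::mutate(cand, mfe_per_nt = -0.35, mfe = -0.35 * 60)
  r3 <- apply_structure_filters(c3, cfg)
  expect_match(r3$filter_reasons, "mfe_per_nt")
})

test_that("MFE/nt weakly worsens as windows grow past a fixed stem", {
  set.seed(13)
  p <- make_precursor(40, 6, 0)
  pad <- function(n) paste(sample(c("A", "T"), n, TRUE), collapse = "")
  lens <- c(0, 10, 25, 50, 100)
  vals <- vapply(lens, function(n) {
    rna_fold(paste0(p$sequence, pad(n)), pairmax)$mfe_per_nt
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("profiling folds a FASTA into a deterministic feature table", {
  set.seed(31)
  seqs <- c(h1 = make_precursor(30, 5, 0)$sequence,
            h2 = make_precursor(32, 8, 2)$sequence,
            polyA = strrep("A", 40))
  fa <- write_fasta(seqs)
  prof <- profile_precursors(fa, pairmax)
  expect_equal(nrow(prof), 3L)
  expect_equal(prof$name, names(seqs))
  expect_equal(prof$mfe_per_nt[3], 0)
  expect_identical(prof, profile_precursors(fa, pairmax))

  mixed <- write_fasta(c(seqs, bad = "ACGT"))   # too short: skipped
  expect_message(p2 <- profile_precursors(mixed, pairmax), "skipped")
  expect_equal(nrow(p2), 3L)
})
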