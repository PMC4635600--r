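# hairpin with pairs i <-> 59-i (0-based) for i in 5..25
stem60_db <- paste0(strrep(".", 5), strrep("(", 21), strrep(".", 8),
                    strrep(")", 21), strrep(".", 5))
stem60_pt <- pair_table(stem60_db)

test_that("mature loci are sharp stacks above the coverage fraction", {
  cfg <- tiny_config()
  pre <- tibble::tibble(chrom = "c1", strand = "+", start = 1000L,
                        end = 1128L)
  set.seed(3)
  scatter_start <- 1000L + sample(0:100, 10, TRUE)
  reads <- dplyr::bind_rows(
    reads_tbl(rep(1005, 90), rep(1026, 90), chrom = "c1"),
    reads_tbl(scatter_start, scatter_start + 21L, chrom = "c1"))
  loci <- detect_mature_loci(reads, pre, cfg)
  top <- loci[loci$accepted, ]
  expect_equal(nrow(top), 1L)
  expect_equal(top$support_fraction, 0.9)
  expect_equal(c(top$rel_start, top$rel_end), c(5L, 26L))

  # a 19-nt stack fails the duplex length bound
  r19 <- reads_tbl(rep(1005, 50), rep(1024, 50), chrom = "c1")
  l19 <- detect_mature_loci(r19, pre, cfg)
  expect_false(any(l19$accepted))
  expect_equal(l19$reject_reason, "mature length")

  # two disjoint stacks at 45% and 40% both pass min_coverage = 0.10
  reads2 <- dplyr::bind_rows(
    reads_tbl(rep(1005, 45), rep(1026, 45), chrom = "c1"),
    reads_tbl(rep(1100, 40), rep(1121, 40), chrom = "c1"),
    reads_tbl(1000L + sample(0:100, 15, TRUE), 1000L +
                sample(0:100, 15, TRUE) + 21L, chrom = "c1"))
  l2 <- detect_mature_loci(reads2, pre, cfg)
  expect_equal(sum(l2$accepted), 2L)

  expect_equal(nrow(detect_mature_loci(reads[0, ], pre, cfg)), 0L)
})

test_that("overlapping weaker stacks are suppressed, fractions sum below 1", {
  cfg <- tiny_config()
  pre <- tibble::tibble(chrom = "chr1", strand = "+", start = 0L,
                        end = 128L)
  reads <- dplyr::bind_rows(
    reads_tbl(rep(5, 60), rep(26, 60)),
    reads_tbl(rep(7, 25), rep(28, 25)),    # overlaps the stronger stack
    reads_tbl(rep(60, 15), rep(81, 15)))
  loci <- detect_mature_loci(reads, pre, cfg)
  expect_equal(sum(loci$accepted), 2L)
  expect_equal(loci$reject_reason[!loci$accepted], "overlaps stronger locus")
  expect_lte(sum(loci$support_fraction), 1)
})

test_that("raising min_coverage never increases accepted loci", {
  pre <- tibble::tibble(chrom = "chr1", strand = "+", start = 0L,
                        end = 200L)
  set.seed(15)
  stacks <- lapply(c(40, 30, 20, 10), function(d) {
    s <- sample(seq(0, 170, by = 30), 1)
    reads_tbl(rep(s, d), rep(s + 21, d))
  })
  reads <- dplyr::bind_rows(stacks)
  counts <- vapply(c(0.05, 0.1, 0.2, 0.35, 0.6), function(mc) {
    sum(detect_mature_loci(reads, pre,
                           tiny_config(min_coverage = mc))$accepted)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("star computation applies the 2-nt 3' overhang rule", {
  cfg <- tiny_config()
  m <- tibble::tibble(rel_start = 5L, rel_end = 26L, length = 21L)
  st <- compute_star(m, stem60_pt, cfg)
  expect_true(st$ok)
  expect_equal(c(st$star_start, st$star_end), c(36L, 57L))
  expect_equal(st$length, 21L)

  m2 <- tibble::tibble(rel_start = 36L, rel_end = 57L, length = 21L)
  st2 <- compute_star(m2, stem60_pt, cfg)
  expect_equal(c(st2$star_start, st2$star_end), c(5L, 26L))

  # mature spanning the terminal loop: anchors unpaired beyond 3 nt
  loop_m <- tibble::tibble(rel_start = 22L, rel_end = 43L, length = 21L)
  expect_equal(compute_star(loop_m, pair_table(
    paste0(strrep("(", 8), strrep(".", 44), strrep(")", 8))), cfg)$reason,
    "no star")
})

test_that("star involution and overhang geometry hold on perfect stems", {
  cfg <- tiny_config()
  set.seed(404)
  for (i in 1:100) {
    arm <- sample(30:70, 1)
    loop <- sample(3:12, 1)
    pt <- pair_table(perfect_hairpin_db(arm, loop))
    mlen <- sample(20:24, 1)
    m5 <- sample(2:(arm - mlen), 1)
    m <- tibble::tibble(rel_start = m5, rel_end = m5 + mlen, length = mlen)
    st <- compute_star(m, pt, cfg)
    expect_true(st$ok)
    back <- compute_star(tibble::tibble(rel_start = st$star_start,
                                        rel_end = st$star_end,
                                        length = st$length), pt, cfg)
    expect_equal(c(back$star_start, back$star_end),
                 c(m$rel_start, m$rel_end))
    # each 3' end extends 2 nt beyond the partner of the other arm's 5' end
    expect_equal(st$star_end - 1L + 1L, pt[m$rel_start + 1L] + 2L)
    expect_equal(m$rel_end, pt[st$star_start + 1L] + 2L)
  }
})

test_that("duplex checks catch interior and terminal mismatch runs", {
  cfg <- tiny_config()
  m <- tibble::tibble(rel_start = 5L, rel_end = 26L, length = 21L)
  st <- compute_star(m, stem60_pt, cfg)
  v <- validate_duplex(m, st, stem60_pt, cfg)
  expect_true(v$duplex_pass)

  # punch a 4-nt unpaired interior run into the mature (positions 9..12)
  pt4 <- stem60_pt
  mid <- 14:17
  pt4[pt4[mid]] <- NA; pt4[mid] <- NA
  v4 <- validate_duplex(m, st, pt4, cfg)
  expect_false(v4$interior_mismatches_ok)
  # but a 3-nt interior run is allowed
  pt3 <- stem60_pt
  pt3[pt3[14:16]] <- NA; pt3[14:16] <- NA
  expect_true(validate_duplex(m, st, pt3, cfg)$interior_mismatches_ok)

  # 3 adjacent unpaired at the duplex 5' end violate the terminal rule
  ptt <- stem60_pt
  ptt[ptt[6:8]] <- NA; ptt[6:8] <- NA
  vt <- validate_duplex(m, st, ptt, cfg)
  expect_false(vt$terminal_mismatches_ok)
  ptt2 <- stem60_pt
  ptt2[ptt2[6:7]] <- NA; ptt2[6:7] <- NA
  expect_true(validate_duplex(m, st, ptt2, cfg)$terminal_mismatches_ok)

  # disabling the optional rules disables the verdicts
  off <- tiny_config(allow_three_mismatches = FALSE,
                     allow_two_terminal_mismatches = FALSE)
  expect_true(validate_duplex(m, st, pt4, off)$interior_mismatches_ok)
  expect_true(validate_duplex(m, st, ptt, off)$terminal_mismatches_ok)
})

test_that("fold-back matures are rejected", {
  cfg <- tiny_config()
  # structure where the 'mature' region pairs with itself
  db <- paste0(strrep(".", 2), strrep("(", 10), "....",
               strrep(")", 10), strrep(".", 34))
  pt <- pair_table(db)
  m <- tibble::tibble(rel_start = 2L, rel_end = 26L, length = 24L)
  st <- list(ok = TRUE, reason = "", star_start = 30L, star_end = 52L,
             length = 22L)
  v <- validate_duplex(m, st, pt, cfg)
  expect_false(v$no_fold_back)
})

test_that("precursor verification calls clean duplexes, star reads optional", {
  cfg <- tiny_config()
  set.seed(55)
  p <- make_precursor(60, 8, 1)
  cand <- tibble::tibble(cluster_id = "t", chrom = "c1", strand = "+",
                         start = 1000L, end = 1000L + p$length,
                         structure = p$structure)
  mature_reads <- reads_tbl(rep(1000 + p$mature[1], 90),
                            rep(1000 + p$mature[2], 90), chrom = "c1")
  star_reads <- reads_tbl(rep(1000 + p$star[1], 10),
                          rep(1000 + p$star[2], 10), chrom = "c1")

  both <- verify_precursor(cand, dplyr::bind_rows(mature_reads, star_reads),
                           cfg)
  expect_true(both$called)
  expect_equal(nrow(both$duplexes), 1L)
  expect_equal(both$duplexes$mature_rel_start, p$mature[1])
  expect_equal(both$duplexes$star_rel_start, p$star[1])

  # no star expression required
  solo <- verify_precursor(cand, mature_reads, cfg)
  expect_true(solo$called)

  # zero reads: never called
  none <- verify_precursor(cand, mature_reads[0, ], cfg)
  expect_false(none$called)
  expect_equal(none$rejections$reason, "no reads in precursor")

  # a stack sitting in the terminal loop cannot form a duplex
  loop_reads <- reads_tbl(rep(1000 + 50, 30), rep(1000 + 71, 30),
                          chrom = "c1")
  lr <- verify_precursor(cand, loop_reads, cfg)
  expect_false(lr$called)
  expect_true(any(grepl("star|overlaps mature", lr$rejections$reason)))
})

test_that("multi-mature precursors yield one duplex per disjoint stack", {
  cfg <- tiny_config(min_coverage = 0.05)
  # long perfect stem: two disjoint matures on the 5' arm
  arm <- 70L
  db <- perfect_hairpin_db(arm, 8)
  cand <- tibble::tibble(cluster_id = "t", chrom = "chr1", strand = "+",
                         start = 0L, end = nchar(db), structure = db)
  reads <- dplyr::bind_rows(
    reads_tbl(rep(2, 50), rep(23, 50)),
    reads_tbl(rep(26, 40), rep(47, 40)))
  v <- verify_precursor(cand, reads, cfg)
  expect_true(v$called)
  expect_equal(nrow(v$duplexes), 2L)
  # duplex footprints must not overlap
  expect_lte(max(v$duplexes$mature_rel_end),
             min(v$duplexes$star_rel_start))
})
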