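# two precursors, the second with two duplexes, one on the minus strand
make_call_table <- function() {
  tibble::tibble(
    id = c("mirp-c1-1", "mirp-c2-1", "mirp-c2-1"),
    cluster_id = c("a", "b", "b"),
    chrom = c("c1", "c2", "c2"),
    strand = c("-", "+", "+"),
    pre_start = c(800L, 1500L, 1500L),
    pre_end = c(1300L, 1640L, 1640L),
    structure = c("((..))", "((..))", "((..))"),
    mfe = c(-50, -60, -60),
    mfe_per_nt = c(-0.5, -0.43, -0.43),
    p_value = c(0.0099009901, 0.02, 0.02),
    n_term = c(1L, 1L, 1L),
    l_ds_max = c(30L, 25L, 25L),
    unique_optimum = c(TRUE, TRUE, TRUE),
    mature_rel_start = c(5L, 4L, 60L),
    mature_rel_end = c(26L, 25L, 81L),
    mature_length = c(21L, 21L, 21L),
    read_support = c(90L, 50L, 40L),
    support_fraction = c(0.9, 0.5, 0.4),
    star_rel_start = c(100L, 100L, 30L),
    star_rel_end = c(121L, 121L, 51L),
    star_length = c(21L, 21L, 21L),
    arm = c("5p", "5p", "3p"),
    paired_fraction_ok = TRUE, no_fold_back = TRUE,
    interior_mismatches_ok = TRUE, terminal_mismatches_ok = TRUE,
    mature_length_ok = TRUE, star_ok = TRUE, duplex_pass = TRUE,
    mature_start = c(1274L, 1504L, 1560L),
    mature_end = c(1295L, 1525L, 1581L),
    star_start = c(879L, 1600L, 1530L),
    star_end = c(900L, 1621L, 1551L)
  )
}

test_that("BED output has one line per precursor, mature and star", {
  calls <- make_call_table()
  bed <- tempfile(fileext = ".bed")
  write_bed(calls, bed)
  lines <- readLines(bed)
  expect_match(lines[1], "^track")
  body <- lines[-1]
  expect_length(body, 2 + 3 + 3)         # 2 precursors, 3 matures, 3 stars
  fields <- do.call(rbind, strsplit(body, "\t"))
  expect_true(all(fields[, 5] >= 0 & as.integer(fields[, 5]) <= 1000))
  expect_equal(sum(grepl("\\.pre$", fields[, 4])), 2L)
  # minus-strand coordinates stay on the plus-strand axis
  minus <- fields[fields[, 4] == "mirp-c1-1.pre", ]
  expect_equal(as.integer(minus[2:3]), c(800L, 1300L))
  expect_equal(minus[6], "-")

  write_bed(calls[0, ], bed)
  expect_equal(length(readLines(bed)), 1L)   # track header only
})

test_that("GTF output is 1-based inclusive and attribute-complete", {
  calls <- make_call_table()
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(calls, gtf)
  lines <- readLines(gtf)
  expect_length(lines, 2 + 2 * 3)        # 1 per precursor + mature+star each
  f <- do.call(rbind, strsplit(lines, "\t"))
  expect_setequal(unique(f[, 3]), c("precursor", "mature", "star"))
  pre1 <- f[f[, 3] == "precursor" & f[, 1] == "c1", ]
  expect_equal(as.integer(pre1[4:5]), c(801L, 1300L))
  # p-value round-trips at 6 decimals
  p <- as.numeric(sub('.*p_value "([0-9.]+)".*', "\\1", lines[1]))
  expect_equal(p, round(calls$p_value[1], 6))
})

test_that("BED and GTF agree through the established parser", {
  skip_if_not_installed("rtracklayer")
  calls <- make_call_table()
  bed <- tempfile(fileext = ".bed"); gtf <- tempfile(fileext = ".gtf")
  write_bed(calls, bed); write_gtf(calls, gtf)
  gb <- rtracklayer::import(bed)
  gg <- rtracklayer::import(gtf)
  # identical features in both files: GTF start = BED start + 1 handled by
  # the importers, which normalise to 1-based starts
  key <- function(gr) sort(paste(GenomicRanges::seqnames(gr),
                                 GenomicRanges::start(gr),
                                 GenomicRanges::end(gr),
                                 GenomicRanges::strand(gr)))
  expect_equal(key(gb), key(gg))
  expect_equal(sort(as.character(unique(GenomicRanges::strand(gb)))),
               c("+", "-"))
})

test_that("coordinate duality holds line by line between BED and GTF", {
  calls <- make_call_table()
  bed <- tempfile(); gtf <- tempfile()
  write_bed(calls, bed); write_gtf(calls, gtf)
  b <- do.call(rbind, strsplit(readLines(bed)[-1], "\t"))
  g <- do.call(rbind, strsplit(readLines(gtf), "\t"))
  suffix <- c(precursor = "pre", mature = "mature", star = "star")
  bkey <- paste(b[, 1], b[, 4], b[, 2])
  for (i in seq_len(nrow(g))) {
    id <- sub('.*gene_id "([^"]+)".*', "\\1", g[i, 9])
    j <- which(bkey == paste(g[i, 1], paste0(id, ".", suffix[g[i, 3]]),
                             as.integer(g[i, 4]) - 1L))
    expect_length(j, 1L)
    expect_equal(as.integer(g[i, 5]), as.integer(b[j, 3]))
  }
})

test_that("the JSON report round-trips losslessly", {
  calls <- make_call_table()
  rejections <- tibble::tibble(cluster_id = c("x", "y", "z"),
                               reason = c("significance", "no star",
                                          "significance"))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_report(calls, rejections, csv, js)

  got <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(got), nrow(calls))
  expect_equal(names(got), names(calls))

  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$calls$structure, calls$structure)
  expect_equal(parsed$calls$p_value, calls$p_value)
  expect_equal(parsed$rejection_summary$n[parsed$rejection_summary$reason ==
                                            "significance"], 2L)
  # parse -> serialize -> parse is a fixed point
  js2 <- tempfile(fileext = ".json")
  jsonlite::write_json(parsed, js2, digits = NA, dataframe = "rows",
                       na = "null", pretty = TRUE)
  expect_equal(jsonlite::fromJSON(js2), parsed)
})
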