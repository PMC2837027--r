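test_that("the 15-column reader parses fields, header and missing values", {
  d <- toy_dataset()
  expect_s3_class(d, "duplex_dataset")
  expect_equal(nrow(d), 4)
  expect_identical(d$seq1[1], "AAAA")
  expect_identical(d$seq2[1], "TTTT")
  expect_identical(d$duplex_id[1], "toy1")
  expect_identical(d$struct1[1], "((((")
  expect_equal(d$dg_exp[1], -2.0)
  expect_equal(d$temperature[1], 25)
  expect_equal(d$conc_nonself[1], 1e-4)
  expect_equal(d$na_conc[1], 1)
  # "n.r." and empty fields parse as missing, never zero
  expect_true(is.na(d$ds_exp[2]))
  expect_true(is.na(d$dg_err[1]))
  expect_equal(d$dh_exp[2], -40.2)
  # a file without a header parses identically
  no_header <- write_toy_csv(lines = toy_csv_lines()[-1])
  expect_equal(read_duplex_dataset(no_header)$dg_exp, d$dg_exp)
})

test_that("malformed rows are rejected with row and field named", {
  bad_len <- write_toy_csv(lines = c(
    toy_csv_lines()[2],
    "AAAA,TTTT,bad,((((c,)))),-2.0,,,,,,25,,1e-4,1"))
  expect_error(read_duplex_dataset(bad_len), "row 2")
  bad_base <- write_toy_csv(lines =
    "AAXA,TTTT,bad,((((,)))),-2.0,,,,,,25,,1e-4,1")
  expect_error(read_duplex_dataset(bad_base), "non-ACGT")
  bad_fields <- write_toy_csv(lines = "AAAA,TTTT,short_row,-2.0")
  expect_error(read_duplex_dataset(bad_fields), "15")
  bad_num <- write_toy_csv(lines =
    "AAAA,TTTT,bad,((((,)))),minus2,,,,,,25,,1e-4,1")
  expect_error(read_duplex_dataset(bad_num), "dg_exp")
  unbalanced <- write_toy_csv(lines =
    "AAAA,TTTT,bad,((((,.))),-2.0,,,,,,25,,1e-4,1")
  expect_error(read_duplex_dataset(unbalanced), "unbalanced")
})

test_that("exclusion ids are dropped after parsing", {
  d <- read_duplex_dataset(write_toy_csv(), exclude_ids = c("toy2", "toy3"))
  expect_identical(d$duplex_id, c("toy1", "toy4"))
})

test_that("perfect-match detection needs revcomp sequences and full pairing", {
  d <- toy_dataset()
  expect_identical(is_perfect_match(d), c(TRUE, TRUE, FALSE, TRUE))
  # an unpaired position disqualifies even complementary strands
  d2 <- duplex_dataset(data.frame(
    seq1 = "AAAA", seq2 = "TTTT", duplex_id = "x",
    struct1 = "((.(", struct2 = ".)))", dg_exp = -1,
    dg_err = NA, ds_exp = NA, ds_err = NA, dh_exp = NA, dh_err = NA,
    temperature = 25, conc_self = NA, conc_nonself = NA, na_conc = 1))
  expect_false(is_perfect_match(d2))
  # swapping the strands (and the roles of '(' and ')') preserves the flag
  swapped <- d
  swapped$seq1 <- d$seq2; swapped$seq2 <- d$seq1
  swapped$struct1 <- chartr("()", ")(", d$struct2)
  swapped$struct2 <- chartr("()", ")(", d$struct1)
  expect_identical(is_perfect_match(swapped), is_perfect_match(d))
})

test_that("filters subset in order, compose and tolerate empty results", {
  d <- toy_dataset()
  pm <- filter_duplexes(d, perfect_only = TRUE)
  expect_identical(pm$duplex_id, c("toy1", "toy2", "toy4"))
  t25 <- filter_duplexes(d, temperature = 25)
  expect_identical(t25$duplex_id, c("toy1", "toy3"))
  # temperature matching is +/- 0.01 degrees
  expect_equal(nrow(filter_duplexes(d, temperature = 25.005)), 2)
  expect_equal(nrow(filter_duplexes(d, temperature = 24.85)), 0)
  both <- filter_duplexes(d, perfect_only = TRUE, temperature = 25,
                          na_conc = 1)
  expect_identical(both$duplex_id, "toy1")
  # composition is order-independent and always a subset
  alt <- filter_duplexes(filter_duplexes(d, temperature = 25),
                         perfect_only = TRUE, na_conc = 1)
  expect_identical(as.data.frame(both), as.data.frame(alt))
  expect_lte(nrow(both), nrow(d))
  empty <- filter_duplexes(d, na_conc = 99)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(filter_duplexes(empty, perfect_only = TRUE)), 0)
})

test_that("gc_content is the G+C percentage", {
  expect_equal(gc_content(c("ATAT", "GCGC", "ATGC")), c(0, 100, 50))
  expect_error(gc_content(""), "empty")
})

test_that("write/read round-trips every field", {
  d <- generate_duplexes(25, seed = 42)
  path <- tempfile(fileext = ".csv")
  write_duplex_dataset(d, path)
  d2 <- read_duplex_dataset(path)
  for (col in duplex_columns())
    expect_equal(d2[[col]], d[[col]], tolerance = 1e-12, label = col)
  # empty dataset -> header-only file that reads back empty
  write_duplex_dataset(d[0, ], path)
  expect_equal(nrow(read_duplex_dataset(path)), 0)
})

test_that("dataset_summary groups by source with histograms", {
  d <- toy_dataset()
  s <- dataset_summary(d)
  expect_equal(s$total, 4)
  expect_equal(sum(s$groups$n), 4)
  one <- dataset_summary(d[1, ])
  expect_equal(one$total, 1)
  expect_equal(nrow(one$groups), 1)
  expect_equal(one$groups$n, 1)
  # length histogram covers the observed range
  expect_equal(sum(s$length_hist), 4)
  expect_equal(unname(s$length_hist[["4"]]), 3)
  expect_output(print(s), "TOTAL: 4")
})

test_that("out-of-range sequence lengths warn but are kept", {
  lines <- c("ACG,CGT,short,(((,))),-1.0,,,,,,25,,1e-4,1")
  expect_warning(d <- read_duplex_dataset(write_toy_csv(lines = lines)),
                 "4-30")
  expect_equal(nrow(d), 1)
})
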