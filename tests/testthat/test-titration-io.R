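write_log <- function(df, sep = ",", dec = ".", header = c("volume_mL", "pH", "temperature")) {
  path <- tempfile(fileext = ".csv")
  lines <- c(paste(header, collapse = sep),
             apply(df, 1, function(r)
               paste(sub("\\.", dec, formatC(r, digits = 6, format = "g")),
                     collapse = sep)))
  writeLines(lines, path)
  path
}

log_df <- function(n = 60) {
  data.frame(volume_mL = seq(0, 25, length.out = n),
             pH = seq(7.8, 2.6, length.out = n),
             temperature = 25)
}

test_that("delimited logs round-trip through the reader", {
  df <- log_df()
  meta <- list(direction = "acidify", titrant = "HCl", titrant_molarity = 0.5,
               sample_mass = 0.05, diluent_mass = 0.05)
  rec <- read_titration(write_log(df), meta)
  expect_identical(nrow(rec$steps), 60L)
  expect_equal(rec$steps$volume_mL, df$volume_mL, tolerance = 1e-5)
  expect_equal(rec$steps$pH, df$pH, tolerance = 1e-5)

  # semicolon + German decimal comma, and tab, parse identically
  rec2 <- read_titration(write_log(df, sep = ";", dec = ","), meta)
  expect_equal(rec2$steps, rec$steps, tolerance = 1e-9)
  rec3 <- read_titration(write_log(df, sep = "\t"), meta)
  expect_equal(rec3$steps, rec$steps, tolerance = 1e-9)
})

test_that("reader errors are specific: columns, monotonicity, row count", {
  df <- log_df()
  bad_cols <- write_log(df, header = c("foo", "bar", "baz"))
  expect_error(read_titration(bad_cols, list(direction = "acidify")),
               class = "slurrycbc_error_format")
  dfv <- log_df(12)
  dfv$volume_mL[5] <- dfv$volume_mL[6] + 1  # cumulative dose decreases
  expect_error(read_titration(write_log(dfv), list(direction = "acidify")),
               class = "slurrycbc_error_data")
  expect_error(read_titration(write_log(log_df(5)), list(direction = "acidify")),
               class = "slurrycbc_error_insufficient_data")
})

test_that("duplicate volumes keep the final reading; metadata is validated", {
  df <- log_df(20)
  df$volume_mL[8] <- df$volume_mL[7]   # instrument re-read at equilibrium
  rec <- read_titration(write_log(df), list(direction = "acidify"))
  expect_identical(nrow(rec$steps), 19L)
  expect_equal(rec$steps$pH[7], df$pH[8], tolerance = 1e-5)

  expect_error(titration_record(log_df(), direction = "acidify", titrant = "NaOH"),
               class = "slurrycbc_error_parameter")
  expect_error(titration_record(log_df(), direction = "alkalize", titrant = "HCl"),
               class = "slurrycbc_error_parameter")
  expect_error(titration_record(log_df(), direction = "acidify", sample_mass = 0),
               class = "slurrycbc_error_parameter")
})

test_that("amount normalisation is exact, linear, and inverse in sample mass", {
  rec <- make_linear_record(7, 3, total_amount = 0.28, n = 29)
  # 28 mL of 0.5 M on 0.05 kg slurry: 0.28 mol/kg at the top step
  expect_equal(max(rec$steps$volume_mL), 28, tolerance = 1e-9)
  am <- normalize_amount(rec)
  expect_identical(am[1], 0)
  expect_equal(max(am), 0.28, tolerance = 1e-12)
  expect_equal(am, rec$steps$volume_mL / 1000 * 0.5 / 0.05, tolerance = 1e-12)
  # doubling the sample mass halves the amounts
  rec2 <- rec; rec2$sample_mass <- 0.1
  expect_equal(normalize_amount(rec2), am / 2, tolerance = 1e-12)
})

test_that("result tables round-trip through write_results", {
  recs <- list(make_linear_record(8.2, 2.8, total_amount = 0.3, sample_id = "A"),
               make_linear_record(7.9, 2.9, total_amount = 0.25, sample_id = "B"))
  tab <- build_segment_table(recs)
  out <- tempfile()
  paths <- write_results(list(segments = tab, empty = build_segment_table(list())),
                         out)
  expect_true(all(file.exists(file.path(out, c("segments.csv", "empty.csv")))))
  # units land as comment header lines
  expect_match(readLines(file.path(out, "segments.csv"), n = 1), "^# .*mol")
  back <- read_result_table(file.path(out, "segments.csv"))
  expect_identical(nrow(back), 2L)
  for (cc in c("initial_pH", "amount_7_to_5p5", "amount_5p5_to_3"))
    expect_equal(back[[cc]], tab[[cc]], tolerance = 1e-6)
  expect_identical(nrow(read_result_table(file.path(out, "empty.csv"))), 0L)
  expect_error(write_results(list(tab), out), class = "slurrycbc_error_parameter")
})

test_that("a YAML manifest maps log files to validated records", {
  dir <- tempfile(); dir.create(dir)
  f1 <- file.path(dir, "a.csv"); f2 <- file.path(dir, "b.csv")
  file.copy(write_log(log_df()), f1)
  df2 <- data.frame(volume_mL = seq(0, 20, length.out = 50),
                    pH = seq(7.2, 11.8, length.out = 50), temperature = 23)
  file.copy(write_log(df2), f2)
  manifest <- file.path(dir, "batch.yml")
  writeLines(c(
    "- file: a.csv", "  sample_id: s1", "  slurry_type: dairy_cow",
    "  storage: cold", "  week: 2", "  replicate: 1", "  direction: acidify",
    "- file: b.csv", "  sample_id: s2", "  direction: alkalize"), manifest)
  batch <- read_batch(manifest)
  expect_length(batch, 2)
  expect_identical(batch[[1]]$sample_id, "s1")
  expect_identical(batch[[1]]$slurry_type, "dairy_cow")
  expect_identical(batch[[1]]$week, 2L)
  expect_identical(batch[[2]]$direction, "alkalize")
  expect_identical(batch[[2]]$titrant, "NaOH")
})
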