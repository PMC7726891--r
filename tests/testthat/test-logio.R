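lay <- ebb_layout()

sim_pt <- function(seed = 1, n_steps = 3)
  simulate_playthrough(fit_archetype(n_steps = n_steps, seed = seed),
                       player_id = "p1", label = "fit")

test_that("logs round-trip to serialisation precision and validate", {
  pt <- sim_pt()
  path <- tempfile(fileext = ".xml")
  write_log(pt, path)

  xsd <- xml2::read_xml(system.file("extdata", "playthrough.xsd",
                                    package = "ebbmetrics"))
  expect_true(xml2::xml_validate(xml2::read_xml(path), xsd))

  back <- read_log(path, lay)
  expect_lt(max(abs(back$com - pt$com)), 5e-7)   # 6-decimal storage
  expect_lt(abs(back$weight - pt$weight), 5e-7)
  expect_equal(back$player_id, "p1")
  expect_equal(nrow(back$frames), nrow(pt$frames))

  # write-read-write idempotence at fixed precision
  path2 <- tempfile(fileext = ".xml")
  write_log(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("refusing to write an empty playthrough", {
  pt <- sim_pt()
  pt$com <- pt$com[0, , drop = FALSE]
  expect_error(write_log(pt, tempfile()), class = "ebb_validation_error")
})

test_that("corruption modes raise distinct condition classes", {
  pt <- sim_pt()
  path <- tempfile(fileext = ".xml")
  write_log(pt, path)
  txt <- readLines(path)

  # malformed XML
  p1 <- tempfile(fileext = ".xml")
  writeLines(head(txt, length(txt) - 3), p1)
  expect_error(read_log(p1, lay), class = "ebb_parse_error")

  # gap in sample indices
  p2 <- tempfile(fileext = ".xml")
  writeLines(txt[-grep("<s t=\"5\"", txt)[1]], p2)
  expect_error(read_log(p2, lay), class = "ebb_data_failure")

  # truncated sample block (declared n disagrees)
  p3 <- tempfile(fileext = ".xml")
  t3 <- sub("<samples n=\"\\d+\">",
            sprintf("<samples n=\"%d\">", pt$n_com + 7), txt)
  writeLines(t3, p3)
  expect_error(read_log(p3, lay), class = "ebb_data_failure")

  # schema violation: missing player block
  p4 <- tempfile(fileext = ".xml")
  writeLines(txt[-grep("<player ", txt)], p4)
  expect_error(read_log(p4, lay), class = "ebb_validation_error")

  # raw frames that no longer reproduce the stored com
  p5 <- tempfile(fileext = ".xml")
  t5 <- txt
  i <- grep("<f t=\"0\"", t5)[1]
  t5[i] <- sub("v=\"[0-9.]+", "v=\"9999.0", t5[i])
  writeLines(t5, p5)
  expect_error(read_log(p5, lay), class = "ebb_data_failure")
})

test_that("batch ingestion counts exactly the injected corruptions", {
  dir <- tempfile(); dir.create(dir)
  n <- 12; k <- 3
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, sprintf("log%02d.xml", i))
    write_log(sim_pt(seed = i, n_steps = 2), paths[i],
              include_raw = FALSE)
  }
  for (i in seq_len(k)) {  # corrupt the first k
    txt <- readLines(paths[i])
    writeLines(txt[-grep("<s t=\"3\"", txt)[1]], paths[i])
  }
  res <- read_logs(paths, lay)
  expect_equal(res$n_accepted, n - k)
  expect_equal(res$n_discarded, k)
  expect_equal(nrow(res$discards), k)
  expect_true(all(res$discards$class == "ebb_data_failure"))
})

test_that("stored if values can be checked against recomputation", {
  pt <- sim_pt()
  path <- tempfile(fileext = ".xml")
  write_log(pt, path)
  expect_silent(read_log(path, lay, recompute = TRUE))

  txt <- readLines(path)
  i <- grep("<s t=\"2\"", txt)[1]
  txt[i] <- sub("if=\"[0-9.]+\"", "if=\"0.777000\"", txt[i])
  writeLines(txt, path)
  expect_warning(read_log(path, lay, recompute = TRUE), "deviates")
})

test_that("feature tables round-trip through CSV and ARFF", {
  cohort <- simulate_cohort(2, 2, seed = 9)
  tab <- feature_table(cohort)
  tab$step_avg[2] <- NA  # force a missing value through the writers

  csv <- tempfile(fileext = ".csv")
  write_feature_table(tab, csv)
  back <- read_feature_table(csv)
  expect_equal(names(back), names(tab))
  for (f in feature_names())
    expect_equal(back[[f]], tab[[f]], tolerance = 1e-9)

  arff <- tempfile(fileext = ".arff")
  write_feature_table(tab, arff)
  expect_true(any(grepl("\\?", readLines(arff))))  # ARFF missing marker
  back2 <- read_feature_table(arff)
  for (f in feature_names())
    expect_equal(back2[[f]], tab[[f]], tolerance = 1e-9)

  expect_error(write_feature_table(tab[, 1:5], csv), "missing columns")
  expect_error(write_feature_table(tab[0, ], csv), "non-empty")
})
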