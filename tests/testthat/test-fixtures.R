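test_that("packaged targets transcribe the calibration table", {
  tg <- default_targets()
  expect_equal(nrow(tg), 34)
  expect_equal(sum(tg$kind == "prevalence"), 18)
  expect_equal(sum(tg$kind == "incidence"), 12)
  expect_equal(sum(tg$kind == "stage_proportion"), 4)
  # spot checks against the printed cells
  expect_equal(tg$value[tg$kind == "incidence" & tg$age_lo == 65], 636.8)
  expect_equal(tg$value[tg$kind == "prevalence" & tg$label == "SD" &
                          tg$age_lo == 65], 3.84)
  expect_equal(tg$value[tg$kind == "prevalence" & tg$label == "BCH_MD" &
                          tg$age_lo == 40], 13.1)
  # the stage rows are synthetic placeholders, flagged as such
  expect_true(all(tg$source[tg$kind == "stage_proportion"] ==
                    "synthetic_placeholder"))
})

test_that("packaged fixtures round-trip bit-identically through their readers", {
  dir <- withr::local_tempdir()
  write_fixtures(dir)
  for (f in c("table1.json", "table2_targets.csv",
              "life_table_cn2011_approx.csv", "hua_county.yaml", "cixian.yaml")) {
    packaged <- readLines(system.file("extdata", f, package = "esccsim"))
    expect_identical(readLines(file.path(dir, f)), packaged, label = f)
  }
  tg <- default_targets()
  path <- withr::local_tempfile(fileext = ".csv")
  write_targets(tg, path)
  expect_equal(read_targets(path), tg, ignore_attr = TRUE)
})

test_that("synthetic targets converge to the model outputs as n_eff grows", {
  p <- tbl_params(); lt <- tbl_lt()
  defs <- target_definitions()[c(5, 15, 33), ]   # one of each kind
  tg <- make_synthetic_targets(p, lt, defs = defs, n_eff = 1e8, seed = 1)
  mv <- model_values(p, tg, lt)
  expect_true(all(abs(target_proportion(tg) - mv) < 1e-4))
  # fixed seed reproduces the identical target set
  tg2 <- make_synthetic_targets(p, lt, defs = defs, n_eff = 1e8, seed = 1)
  expect_identical(tg$value, tg2$value)
})

test_that("the generating model usually outscores a shifted competitor", {
  p <- tbl_params(); lt <- tbl_lt()
  v <- params_to_vector(p); v["beta0"] <- v["beta0"] + 1
  p_shift <- vector_to_params(v, p)
  defs <- target_definitions()[c(3, 6, 14, 17, 27, 30), ]
  wins <- 0
  for (s in 1:20) {
    tg <- make_synthetic_targets(p, lt, defs = defs, n_eff = 5000, seed = s)
    if (gof(p, tg, lt)$value <= gof(p_shift, tg, lt)$value) wins <- wins + 1
  }
  expect_gte(wins, 19)
})
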