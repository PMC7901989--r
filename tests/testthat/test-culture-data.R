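test_that("culture tables parse, group and sort by time", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# demo culture table",
    "species,condition,mineral,replicate,time_days,cells_per_ml,ethanol_mM,acetate_mM,fe2_total_mM,fe2_soluble_mM",
    "GT1,organotrophic,HFO,r1,4,4e7,12,12,1.9,1.2",
    "GT1,organotrophic,HFO,r1,0,1e6,20,0,0,0",
    "GT1,organotrophic,HFO,r1,2,7e6,16,6,0.9,0.6",
    "GT1,organotrophic,HFO,r2,0,1e6,20,0,0,",
    "GT1,organotrophic,HFO,r2,2,8e6,16,6,1.0,"
  ), f)
  out <- readCultureTable(f)
  expect_length(out, 2)
  s1 <- out[[1]]
  expect_s4_class(s1, "CultureSeries")
  expect_equal(timeDays(s1), c(0, 2, 4))            # re-sorted
  expect_equal(fe2Total(s1), c(0, 0.9, 1.9))
  expect_equal(fe2Soluble(s1), c(0, 0.6, 1.2))
  expect_equal(ethanol(s1), c(20, 16, 12))
  # all-empty optional channel comes back absent, not zero-filled
  expect_length(fe2Soluble(out[[2]]), 0)
})

test_that("schema and parse errors are informative", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,condition,mineral,replicate,time_days,acetate_mM",
               "GT1,organotrophic,HFO,r1,0,0"), f)
  expect_error(readCultureTable(f), "fe2_total_mM")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_days,acetate_mM,fe2_total_mM",
               "0,0,0", "2,abc,0.5"), f2)
  expect_error(readCultureTable(f2), "row 2")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_days,acetate_mM,fe2_total_mM",
               "0,0,0", "0,1,0.5"), f3)
  expect_error(readCultureTable(f3), "duplicate")
})

test_that("write/read round trip reproduces numeric fields bit-for-bit", {
  set.seed(11)
  s <- CultureSeries(
    time_days = cumsum(runif(6, 0.5, 3)),
    acetate_mM = runif(6, 0, 30) + pi * 1e-7,
    fe2_total_mM = sort(runif(6, 0, 2.9)),
    cell_density = 10^runif(6, 6, 8.3),
    ethanol_mM = rev(sort(runif(6, 0, 20))),
    fe2_soluble_mM = numeric(0),
    species_label = "GT1", replicate_id = "r1",
    fe3_initial_mM = 9, culture_volume_mL = 20)
  f <- withr::local_tempfile(fileext = ".csv")
  writeCultureTable(s, f)
  back <- readCultureTable(f)[[1]]
  for (acc in list(timeDays, acetate, fe2Total, cellDensity, ethanol,
                   fe3Initial, cultureVolume))
    expect_identical(acc(back), acc(s))
})

test_that("CultureSeries validity enforces the measurement invariants", {
  expect_error(CultureSeries(time_days = c(0, 2, 2), acetate_mM = 1:3,
                             fe2_total_mM = c(0, 1, 2)),
               "strictly increasing")
  expect_error(CultureSeries(time_days = c(0, 2), acetate_mM = c(0, 1),
                             fe2_total_mM = c(0, 1),
                             fe2_soluble_mM = c(0, 1.2)),
               "fe2_soluble")
  expect_error(CultureSeries(time_days = c(0, 2), acetate_mM = c(0, 1),
                             fe2_total_mM = c(0, 9.5), fe3_initial_mM = 9),
               "fe3_initial")
  # within the 0.05 mM assay tolerance both pass
  expect_s4_class(CultureSeries(time_days = c(0, 2), acetate_mM = c(0, 1),
                                fe2_total_mM = c(0, 1),
                                fe2_soluble_mM = c(0, 1.04)),
                  "CultureSeries")
})

test_that("dialysis series default to the sixfold medium volume", {
  s <- CultureSeries(time_days = c(0, 2), acetate_mM = c(0, 1),
                     fe2_total_mM = c(0, 0.01), condition = "dialysis")
  expect_equal(cultureVolume(s), 120)
})

test_that("concentrationToAmount converts mM x mL to umol and is bilinear", {
  expect_equal(concentrationToAmount(2.9, 20), 58)
  expect_equal(concentrationToAmount(0, 20), 0)
  expect_equal(concentrationToAmount(20, 20), 400)
  for (a in c(0.5, 2)) {
    expect_equal(concentrationToAmount(a * 3.1, 17),
                 a * concentrationToAmount(3.1, 17))
    expect_equal(concentrationToAmount(3.1, a * 17),
                 a * concentrationToAmount(3.1, 17))
  }
  expect_error(concentrationToAmount(-1, 20), ">= 0")
  expect_error(concentrationToAmount(1, 0), "> 0")
})
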