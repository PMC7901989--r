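test_that("presets encode the study conditions", {
  cfg <- cultureConfig("gt1-organo")
  expect_equal(cfg@n0, 1e6)
  expect_equal(cfg@fe3_initial_mM, 9)
  expect_equal(cfg@substrate_mmol, 0.4)      # 20 mM ethanol in 20 mL
  expect_equal(cfg@replicates, 3L)
  expect_equal(cfg@volume_mL, 20)
  litho <- cultureConfig("gt1-litho")
  expect_equal(litho@substrate_mmol, 3.2)    # mmol H2 per bottle
  dial <- cultureConfig("gt1-dialysis")
  expect_equal(dial@volume_mL, 120)
  expect_error(cultureConfig("nope"), "unknown preset")
})

test_that("zero diversion gives acetate = 1.5 x ethanol consumed, exactly", {
  cfg <- cultureConfig(noise_sd = 0, f_div = 0, substrate = "ethanol")
  out <- generateCulture(cfg, seed = 2)
  s <- out$treatment[[1]]
  consumed <- ethanol(s)[1] - ethanol(s)
  expect_equal(acetate(s), 1.5 * consumed, tolerance = 1e-12)
  expect_equal(fe2Total(s), rep(0, length(timeDays(s))))
})

test_that("noiseless generator output conserves electrons exactly", {
  cfg <- cultureConfig("gt1-organo", noise_sd = 0)
  out <- generateCulture(cfg, seed = 4)
  s <- out$treatment[[1]]; ctl <- out$control[[1]]
  vol <- cultureVolume(s)
  deficit_e <- 8 * (concentrationToAmount(acetate(ctl)[8], vol) -
                    concentrationToAmount(acetate(s)[8], vol))
  e_final <- 4 * concentrationToAmount(ethanol(s)[1] - ethanol(s)[8], vol)
  expect_equal(deficit_e, cfg@f_div * e_final, tolerance = 1e-12)
  fe2_e <- concentrationToAmount(finalAccumulation(s, k_last = 1), vol)
  expect_equal(fe2_e, cfg@f_fe * deficit_e, tolerance = 1e-12)
})

test_that("pipeline closure: kinetics + stoichiometry recover the preset truths", {
  cfg <- cultureConfig("gt1-organo", noise_sd = 0)
  out <- generateCulture(cfg, seed = 6)
  s <- out$treatment[[1]]; ctl <- out$control[[1]]
  expect_equal(rateSlope(fe2ProductionRate(s)), 0.47, tolerance = 1e-12)
  expect_equal(finalAccumulation(s), 2.9, tolerance = 1e-12)
  vol <- cultureVolume(s)
  d <- acetateDeficitElectrons(
    concentrationToAmount(acetate(ctl)[8], vol),
    concentrationToAmount(acetate(s)[8], vol))
  expect_equal(as.numeric(d), 248, tolerance = 1e-9)
  expect_equal(diversionEfficiency(
    concentrationToAmount(finalAccumulation(s), vol), as.numeric(d)),
    58 / 248, tolerance = 1e-12)
})

test_that("the dialysis preset plateaus at 0.2% of the Fe(III) input", {
  out <- generateCulture(cultureConfig("gt1-dialysis", noise_sd = 0), seed = 1)
  s <- out$treatment[[1]]
  expect_equal(100 * finalAccumulation(s) / fe3Initial(s), 0.2,
               tolerance = 1e-9)
  expect_equal(cultureVolume(s), 120)
})

test_that("culture generation is deterministic under a fixed seed", {
  cfg <- cultureConfig("sphaeroides-organo", noise_sd = 0.1)
  a <- generateCulture(cfg, seed = 123)
  b <- generateCulture(cfg, seed = 123)
  expect_identical(lapply(a$treatment, fe2Total),
                   lapply(b$treatment, fe2Total))
  expect_identical(lapply(a$control, acetate), lapply(b$control, acetate))
  c2 <- generateCulture(cfg, seed = 124)
  expect_false(identical(fe2Total(a$treatment[[1]]),
                         fe2Total(c2$treatment[[1]])))
})

test_that("generator warns when configured Fe(II) would exceed the Fe input", {
  cfg <- cultureConfig(noise_sd = 0, f_div = 1, f_fe = 1,
                       fe2_rate_mM_day = 10, fe3_initial_mM = 2)
  expect_warning(out <- generateCulture(cfg, seed = 1), "capped")
  expect_lte(max(fe2Total(out$treatment[[1]])), 2)
})

test_that("planted proteomes carry exactly the requested motifs", {
  pr <- generateProteome(20, list(c("CxxCH", 2), c("CxxCK", 3),
                                  c("CxxCH", 0)), seed = 14)
  expect_equal(length(pr$proteome), 23L)
  for (i in which(pr$truth$count > 0)) {
    row <- pr$truth[i, ]
    seqchr <- as.character(pr$proteome[[match(row$protein_id,
                                              names(pr$proteome))]])
    hits <- scanMotifs(seqchr, motifPatterns("with_variants"),
                       overlap_policy = "all_positions")
    expect_equal(nrow(hits), row$count)
    expect_true(all(hits$pattern == row$pattern))
    expect_equal(sort(hits$start),
                 as.integer(strsplit(row$positions, ",")[[1]]))
  }
  # decoys and zero-count plants are motif-free
  for (i in which(pr$truth$count == 0)) {
    seqchr <- as.character(pr$proteome[[match(pr$truth$protein_id[i],
                                              names(pr$proteome))]])
    expect_equal(nrow(scanMotifs(seqchr, motifPatterns("with_variants"),
                                 overlap_policy = "all_positions")), 0)
  }
})

test_that("proteome generation is byte-deterministic and guards infeasibility", {
  a <- generateProteome(5, list(c("CxxCH", 4)), seed = 99)
  b <- generateProteome(5, list(c("CxxCH", 4)), seed = 99)
  expect_identical(as.character(a$proteome), as.character(b$proteome))
  expect_identical(a$truth, b$truth)
  empty <- generateProteome(0, list(), seed = 1)
  expect_equal(length(empty$proteome), 0L)
  expect_error(generateProteome(0, list(c("CxxCH", 30)), seed = 1,
                                planted_length = 60),
               "infeasible|cannot plant")
  expect_error(generateProteome(-1), ">= 0")
})
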