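test_that("degradation rate follows from the half-life anchor", {
  expect_equal(degradation_rate(calibration_anchors()), log(2) / 6)
  expect_equal(degradation_rate(calibration_anchors(insulin_half_life = 4)),
               log(2) / 4)
  # long-half-life limit
  expect_lt(degradation_rate(calibration_anchors(insulin_half_life = 1e9)),
            1e-9)
})

test_that("return fraction combines hepatic extraction and transit decay", {
  anchors <- calibration_anchors()
  d_i <- degradation_rate(anchors)
  expect_equal(return_fraction(anchors, d_i),
               0.5 * exp(-d_i * 25 / 60), tolerance = 1e-12)
  expect_equal(return_fraction(anchors, d_i), 0.4765, tolerance = 1e-4)
  expect_equal(return_fraction(
    calibration_anchors(hepatic_first_pass_extraction = 1), d_i), 0)
  expect_equal(return_fraction(
    calibration_anchors(circulation_time_s = 0), d_i), 0.5)
  # decreasing in degradation rate and in circulation time
  expect_true(all(diff(sapply(c(0.05, 0.1, 0.2),
                              function(d) return_fraction(anchors, d))) < 0))
  expect_true(all(diff(sapply(c(10, 25, 60), function(ct) {
    return_fraction(calibration_anchors(circulation_time_s = ct), d_i)
  })) < 0))
})

test_that("transfer rates follow from the equilibrium anchors", {
  anchors <- calibration_anchors()
  d_i <- degradation_rate(anchors)
  tr <- calibrate_transfer_rates(anchors, d_i)
  expect_equal(tr$k, 3 * d_i)
  expect_equal(tr$k, 0.34657, tolerance = 1e-4)
  expect_equal(tr$c, 0.5 - d_i)
  expect_equal(tr$c, 0.38448, tolerance = 1e-4)
  # equal split means the return coefficient equals the degradation rate
  tr50 <- calibrate_transfer_rates(calibration_anchors(peripheral_share = 0.5),
                                   d_i)
  expect_equal(tr50$k, d_i)
  expect_error(
    calibrate_transfer_rates(
      calibration_anchors(total_monomer_clearance = 0.1), d_i),
    "clearance")
})

test_that("the calibrated share is recovered exactly at equilibrium", {
  for (share in c(0.5, 0.6, 0.75, 0.9)) {
    anchors <- calibration_anchors(peripheral_share = share)
    params <- default_params(anchors)
    eq <- islet_equilibrium(params, 7)
    expect_equal(eq$Ip_pM / eq$total_monomer_pM, share, tolerance = 1e-12)
    expect_equal(new_to_peripheral_ratio(params), (1 - share) / share,
                 tolerance = 1e-12)
  }
})

test_that("default parameter set carries the calibrated values and provenance", {
  params <- default_params()
  expect_equal(params$d_i, log(2) / 6)
  expect_equal(params$q, aggregation_coeff_to_si(7.6e-2))
  expect_equal(params$c + params$d_i, 0.5)
  expect_equal(params$k / params$d_i, 3)
  expect_gt(params$p_hat, params$p)
  expect_equal(hill_rate(16.5, params$hill), 95.7, tolerance = 0.01)
  prov <- param_provenance(params)
  expect_s3_class(prov, "tbl_df")
  expect_setequal(prov$parameter,
                  c("sigma", "alpha", "gamma", "d_i", "c", "k",
                    "p", "p_hat", "q", "q_hat"))
  expect_true(all(nzchar(prov$provenance)))
})

test_that("anchors validate and can be read from a YAML config", {
  expect_error(calibration_anchors(peripheral_share = 1), "share")
  expect_error(calibration_anchors(hepatic_first_pass_extraction = 1.2),
               "extraction")
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("insulin_half_life: 4", "peripheral_share: 0.6"), path)
  anchors <- read_anchors(path)
  expect_equal(anchors$insulin_half_life, 4)
  expect_equal(anchors$peripheral_share, 0.6)
  expect_equal(anchors$circulation_time_s, 25) # untouched default
  writeLines("no_such_field: 1", path)
  expect_error(read_anchors(path), "unknown anchor")
})
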