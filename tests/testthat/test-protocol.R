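test_that("block protocols carry the stated timing and amplitudes", {
  p1 <- situation_protocol(1)
  expect_equal(p1$block_length_s, 48)
  expect_equal(p1$U$onset_s, 8); expect_equal(p1$U$duration_s, 8)
  expect_equal(p1$U$frac_hbo, 0.10); expect_equal(p1$U$frac_hbr, -0.05)
  expect_equal(p1$L$frac_hbo, 0.50); expect_equal(p1$L$frac_hbr, -0.25)
  p2 <- situation_protocol(2)
  expect_equal(p2$block_length_s, 50)
  expect_equal(p2$U$onset_s, 6); expect_equal(p2$U$duration_s, 8)
  expect_equal(p2$L$onset_s, 10); expect_equal(p2$L$duration_s, 12)
  expect_identical(p2$U$frac_hbr, 0)  # scalp HbR stays constant
  expect_error(situation_protocol(3), "1 or 2")
})

test_that("series lengths are 240 s and 250 s at any sampling rate", {
  for (fs in c(2, 10)) {
    cs1 <- concentration_timeseries(situation_protocol(1, sample_rate = fs))
    cs2 <- concentration_timeseries(situation_protocol(2, sample_rate = fs))
    expect_equal(nrow(cs1), 240 * fs)
    expect_equal(nrow(cs2), 250 * fs)
    expect_equal(max(cs1$time_s), 240 - 1 / fs)
    expect_equal(max(cs2$time_s), 250 - 1 / fs)
  }
})

test_that("HRF-convolved unit boxcar is normalised to unit peak", {
  wav <- layernirs:::.block_waveform(8, 8, 48, 10, list())
  expect_equal(max(abs(wav)), 1, tolerance = 1e-9)
  wav2 <- layernirs:::.block_waveform(10, 12, 50, 10, list())
  expect_equal(max(abs(wav2)), 1, tolerance = 1e-9)
})

test_that("peak and trough concentrations equal baseline times the nominal
           change", {
  cs1 <- concentration_timeseries(situation_protocol(1))
  expect_equal(max(cs1$hbo_U), 64.66, tolerance = 0.005 / 64)
  expect_equal(min(cs1$hbr_U), 28.68, tolerance = 0.005 / 28)
  expect_equal(max(cs1$hbo_L), 176.33, tolerance = 0.005 / 176)
  expect_equal(min(cs1$hbr_L), 45.29, tolerance = 0.005 / 45)
  cs2 <- concentration_timeseries(situation_protocol(2))
  expect_equal(min(cs2$hbo_U), 44.08, tolerance = 0.005 / 44)
  expect_equal(max(cs2$hbo_L), 176.33, tolerance = 0.005 / 176)
  # scalp HbR flat in situation 2
  expect_equal(diff(range(cs2$hbr_U)), 0)
})

test_that("a null protocol returns constant baselines", {
  p <- situation_protocol(1)
  p$U$frac_hbo <- 0; p$U$frac_hbr <- 0
  p$L$frac_hbo <- 0; p$L$frac_hbr <- 0
  cs <- concentration_timeseries(p)
  for (col in c("hbo_U", "hbr_U", "hbo_L", "hbr_L"))
    expect_equal(diff(range(cs[[col]])), 0)
})

test_that("proposed scalp and cortex HbO are synchronous in situation 1 and
           anticorrelated in situation 2", {
  cs1 <- concentration_timeseries(situation_protocol(1))
  expect_equal(pearson(cs1$hbo_U - cs1$hbo_U[1], cs1$hbo_L - cs1$hbo_L[1]),
               1, tolerance = 1e-9)
  cs2 <- concentration_timeseries(situation_protocol(2))
  expect_lt(pearson(cs2$hbo_U - cs2$hbo_U[1], cs2$hbo_L - cs2$hbo_L[1]), 0)
})

test_that("intensity noise is reproducible under a fixed seed", {
  hm <- head_model()
  cs <- concentration_timeseries(situation_protocol(1, sample_rate = 0.5,
                                                    n_blocks = 1))
  a1 <- forward_attenuation(cs, hm, mode = "linear", noise_sd = 0.01,
                            seed = 11)
  a2 <- forward_attenuation(cs, hm, mode = "linear", noise_sd = 0.01,
                            seed = 11)
  a3 <- forward_attenuation(cs, hm, mode = "linear", noise_sd = 0.01,
                            seed = 12)
  expect_identical(a1$attenuation, a2$attenuation)
  expect_false(identical(a1$attenuation, a3$attenuation))
  expect_error(forward_attenuation(cs, hm, mode = "linear", noise_sd = 0.01),
               "seed")
})

test_that("baseline timepoint yields zero attenuation on every channel", {
  hm <- head_model()
  cs <- concentration_timeseries(situation_protocol(1, sample_rate = 0.5,
                                                    n_blocks = 1))
  as <- forward_attenuation(cs, hm, mode = "linear")
  first <- as[as$time_s == 0, ]
  expect_equal(first$attenuation, rep(0, nrow(first)))
})
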