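test_that("bundled extinction table reproduces the reference baselines", {
  tab <- default_extinction_table()
  # scalp baseline, 0.018 mm^-1 at the isosbestic point
  expect_equal(unname(mua_to_conc(0.018, tab)), c(58.78, 30.19),
               tolerance = 0.01 / 30)
  # gray matter baseline, 0.036 mm^-1
  expect_equal(unname(mua_to_conc(0.036, tab)), c(117.55, 60.38),
               tolerance = 0.01 / 60)
  expect_equal(unname(mua_to_conc(0, tab)), c(0, 0))
  # invertibility and the isosbestic crossing
  E <- layernirs:::.eps_matrix(tab)
  expect_gt(abs(det(E)), 0)
  expect_gt(tab$eps_hbr[tab$wavelength_nm == 690],
            tab$eps_hbo[tab$wavelength_nm == 690])
  expect_gt(tab$eps_hbo[tab$wavelength_nm == 830],
            tab$eps_hbr[tab$wavelength_nm == 830])
})

test_that("concentrations map to the printed final absorptions", {
  b <- mua_to_conc(0.036)
  hbo_f <- b[["hbo"]] * 1.5
  hbr_f <- b[["hbr"]] * 0.75
  expect_equal(conc_to_mua(hbo_f, hbr_f, 690), 0.0326, tolerance = 5e-5 / 0.03)
  expect_equal(conc_to_mua(hbo_f, hbr_f, 830), 0.0468, tolerance = 5e-5 / 0.04)
  expect_error(conc_to_mua(1, 1, 777), "not in the table")
})

test_that("mua <-> concentration round trip is exact and linear", {
  tab <- default_extinction_table()
  for (x in c(0, 0.005, 0.018, 0.036, 0.1)) {
    cc <- mua_to_conc(x, tab)
    expect_equal(conc_to_mua(cc[["hbo"]], cc[["hbr"]], 690, tab), x,
                 tolerance = 1e-12)
    expect_equal(conc_to_mua(cc[["hbo"]], cc[["hbr"]], 830, tab), x,
                 tolerance = 1e-12)
  }
  # additivity and homogeneity
  expect_equal(conc_to_mua(2 + 5, 1 + 7, 830),
               conc_to_mua(2, 1, 830) + conc_to_mua(5, 7, 830))
  expect_equal(conc_to_mua(3 * 2, 3 * 1, 690), 3 * conc_to_mua(2, 1, 690))
})

test_that("extinction tables survive a text-file round trip", {
  tab <- default_extinction_table()
  f <- tempfile(fileext = ".txt")
  write_extinction_table(tab, f)
  back <- read_extinction_table(f)
  expect_equal(back$eps_hbo, tab$eps_hbo, tolerance = 1e-12)
  expect_equal(back$eps_hbr, tab$eps_hbr, tolerance = 1e-12)
  # decadic declaration converts on read
  f2 <- tempfile(fileext = ".txt")
  writeLines(c("# basis=log10_cm_M",
               "wavelength_nm,eps_hbo,eps_hbr",
               "690,276,2051.96", "830,974,693.04"), f2)
  expect_equal(read_extinction_table(f2)$eps_hbo, tab$eps_hbo,
               tolerance = 1e-12)
  f3 <- tempfile(fileext = ".txt")
  writeLines(c("no header here", "a,b,c"), f3)
  expect_error(read_extinction_table(f3), "basis")
})
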