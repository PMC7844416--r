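make_mre <- function(theta_208, wl = seq(200, 216, by = 0.5)) {
  # flat MRE spectrum pinned at a chosen 208 nm value
  structure(list(wavelength = wl, mre = rep(theta_208, length(wl))),
            class = "mre_spectrum")
}

test_that("mean residue ellipticity implements the normalization formula", {
  wl <- seq(200, 216, by = 0.5)
  s <- cd_spectrum(wl, rep(-23.03, length(wl)), path_cm = 0.1,
                   conc_g_per_ml = 2e-4)
  m <- mre_spectrum(s)
  # independent arithmetic: W_r = 66430.3 / 583 ~ 113.95;
  # MRE = W_r * (theta_mdeg / 1000) / (10 * d * c)
  expected <- (66430.3 / 583) * (-23.03 / 1000) / (10 * 0.1 * 2e-4)
  expect_equal(m$mre[1], expected, tolerance = 1e-12)
  expect_equal(expected, -13121, tolerance = 1e-4)
  # zero in, zero out; and linearity MRE(a * theta) = a * MRE(theta)
  s0 <- cd_spectrum(wl, rep(0, length(wl)), 0.1, 2e-4)
  expect_true(all(mre_spectrum(s0)$mre == 0))
  s3 <- cd_spectrum(wl, rep(-3 * 23.03, length(wl)), 0.1, 2e-4)
  expect_equal(mre_spectrum(s3)$mre, 3 * m$mre)
})

test_that("CD spectrum constructor validates grid and metadata", {
  wl <- seq(200, 216, by = 0.5)
  th <- rep(1, length(wl))
  expect_error(cd_spectrum(wl, th, path_cm = 0, conc_g_per_ml = 2e-4),
               "path")
  expect_error(cd_spectrum(wl, th, path_cm = 0.1, conc_g_per_ml = 0),
               "conc")
  expect_error(cd_spectrum(rev(wl), th, 0.1, 2e-4), "ascending")
  expect_error(cd_spectrum(c(200, 200.5, 201.5), rep(1, 3), 0.1, 2e-4),
               "pitch")
  expect_error(cd_spectrum(seq(180, 200, 0.5),
                           rep(1, 41), 0.1, 2e-4), "190")
})

test_that("helicity estimator is anchored at -4000 (0%) and -33000 (100%)", {
  expect_equal(helicity_from_mre208(make_mre(-4000))$percent, 0)
  expect_equal(helicity_from_mre208(make_mre(-33000))$percent, 100)
  # the natively folded albumin anchor: theta_208 = -20211 -> 55.9%
  h <- helicity_from_mre208(make_mre(-20211))
  expect_equal(h$percent, 55.9, tolerance = 1e-3)
  expect_false(h$out_of_range)
  # outside [0, 100]: reported as-is, flagged, never clamped
  hi <- helicity_from_mre208(make_mre(-40000))
  expect_gt(hi$percent, 100)
  expect_true(hi$out_of_range)
  lo <- helicity_from_mre208(make_mre(-1000))
  expect_lt(lo$percent, 0)
  expect_true(lo$out_of_range)
})

test_that("theta_208 is linearly interpolated at exactly 208 nm", {
  # coarse grid missing 208: neighbours at 207 and 209
  m <- structure(list(wavelength = c(205, 207, 209, 211),
                      mre = c(-10, -100, -300, -400)),
                 class = "mre_spectrum")
  expect_equal(helicity_from_mre208(m)$theta_208, -200)
  out <- structure(list(wavelength = seq(220, 240, 0.5),
                        mre = rep(-1, 41)), class = "mre_spectrum")
  expect_error(helicity_from_mre208(out), "208")
})

test_that("helicity is strictly increasing in -theta_208 and round-trips", {
  vals <- vapply(c(-4000, -10000, -20000, -33000),
                 function(t) helicity_from_mre208(make_mre(t))$percent,
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  for (h in c(0, 25, 50, 75, 100)) {
    s <- gen_cd_spectrum(h, noise_mdeg = 0)
    expect_equal(helicity_from_mre208(mre_spectrum(s))$percent, h,
                 tolerance = 0.1)
  }
})

test_that("difference spectra subtract pointwise on identical grids", {
  a <- gen_cd_spectrum(55.9, noise_mdeg = 0)
  b <- gen_cd_spectrum(34.9, noise_mdeg = 0)
  ma <- mre_spectrum(a)
  mb <- mre_spectrum(b)
  expect_true(all(difference_spectrum(ma, ma)$mre == 0))
  zero <- structure(list(wavelength = ma$wavelength,
                         mre = rep(0, length(ma$mre))),
                    class = "mre_spectrum")
  expect_equal(difference_spectrum(ma, zero)$mre, ma$mre)
  # basis-model closed form at the 208 nm anchor:
  # dMRE(208) = (h1 - h2)/100 * (-33000 + 4000)
  d <- difference_spectrum(ma, mb)
  i208 <- which(d$wavelength == 208)
  expect_equal(d$mre[i208], (55.9 - 34.9) / 100 * (-33000 + 4000),
               tolerance = 1e-9)
  short <- structure(list(wavelength = ma$wavelength[-1],
                          mre = ma$mre[-1]), class = "mre_spectrum")
  expect_error(difference_spectrum(ma, short), "grid")
})

test_that("quench AUC integrates the background-subtracted band", {
  wl <- seq(300, 400, by = 1)
  blank <- emission_spectrum(wl, rep(7, length(wl)))
  # spectrum identical to blank integrates to zero
  expect_equal(quench_auc(emission_spectrum(wl, rep(7, length(wl))),
                          blank)$auc, 0)
  # triangular band, height 2, base 50 nm: trapezoid = triangle area = 50
  tri <- 2 * pmax(0, 1 - abs(wl - 350) / 25)
  q <- quench_auc(emission_spectrum(wl, tri + 7), blank)
  expect_equal(q$auc, 50)
  # self-normalization of the folded control
  expect_equal(quench_auc(emission_spectrum(wl, tri + 7), blank,
                          folded_control_auc = q$auc)$normalized_auc, 1)
  # invariance to a common offset in spectrum and blank
  q2 <- quench_auc(emission_spectrum(wl, tri + 7 + 13),
                   emission_spectrum(wl, rep(7 + 13, length(wl))))
  expect_equal(q2$auc, q$auc)
  expect_error(quench_auc(emission_spectrum(wl, tri), blank,
                          folded_control_auc = 0), "positive")
  expect_error(quench_auc(emission_spectrum(wl, tri),
                          emission_spectrum(wl[-1], tri[-1])), "grid")
})

test_that("synthetic quench spectra scale the normalized AUC by 1 - q", {
  ctrl <- gen_trp_spectrum(0, noise_sd = 0)
  ctrl_auc <- quench_auc(ctrl$spectrum, ctrl$blank)$auc
  for (qf in c(0, 0.3, 1)) {
    s <- gen_trp_spectrum(qf, noise_sd = 0)
    r <- quench_auc(s$spectrum, s$blank, folded_control_auc = ctrl_auc)
    expect_equal(r$normalized_auc, 1 - qf, tolerance = 1e-9)
  }
})
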