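test_that("the analytic blood-suppression weight solves the anchoring condition", {
  ref <- chronic_reference()
  # frozen independent evaluation of the analytic solution at the
  # chronic-MI group means with LGEb = -0.5 Hz
  expect_equal(ref$a_DB, 0.618331531584034, tolerance = 1e-10)
  expect_equal(compute_a_db(ref), ref$a_DB)

  # fixed point: LGEb chosen so R1m R2m / (R1b - LGEb) = R2b gives a_DB = 1
  l1 <- ref$R1b - ref$R1m * ref$R2m / ref$R2b
  ref1 <- tissue_reference(ref$R1m, ref$R2m, ref$R1b, ref$R2b, LGEb = l1)
  expect_equal(ref1$a_DB, 1, tolerance = 1e-10)

  # degenerate references are rejected
  expect_error(tissue_reference(1.5, 20, 2.1, 20), "R2b = R2m")
  expect_error(tissue_reference(1.5, 23, 2.1, 7, LGEb = 2.1), "LGEb")
})

test_that("bright-blood PSIR nulls normal myocardium and is linear in R1", {
  ref <- chronic_reference()
  R1 <- matrix(c(ref$R1m, 1000 / 441, 1000 / 466, NA), 2, 2)
  bb <- calc_bb_psir(R1, ref)
  expect_s3_class(bb, "psir_image")
  expect_equal(bb$values[1, 1], 0)
  # enhancing chronic-MI pixel (frozen hand evaluation)
  expect_equal(bb$values[2, 1], 0.770567708121173, tolerance = 1e-10)
  expect_true(is.na(bb$values[2, 2]))  # unconverged propagates
  # linearity: doubling the R1 offset doubles the signal
  d <- 0.3
  expect_equal(calc_bb_psir(ref$R1m + 2 * d, ref)$values,
               2 * calc_bb_psir(ref$R1m + d, ref)$values)
})

test_that("dark-blood PSIR nulls myocardium, anchors blood at LGEb, equals BB when R2 = R2m", {
  ref <- chronic_reference()
  # null at the myocardial reference point
  expect_equal(calc_db_psir(ref$R1m, ref$R2m, ref)$values, 0, tolerance = 1e-10)
  # anchored at LGEb at the blood operating point
  expect_equal(calc_db_psir(ref$R1b, ref$R2b, ref)$values, -0.5,
               tolerance = 1e-9)
  # chronic-MI pixel (frozen hand evaluation of the DB expression)
  expect_equal(calc_db_psir(1000 / 441, 1000 / 43.8, ref)$values,
               0.740384304053518, tolerance = 1e-10)
  # equivalence with BB wherever R2 == R2m
  R1 <- matrix(seq(1.0, 2.5, length.out = 16), 4, 4)
  R2 <- matrix(ref$R2m, 4, 4)
  expect_equal(calc_db_psir(R1, R2, ref)$values, calc_bb_psir(R1, ref)$values,
               tolerance = 1e-12)
})

test_that("normal-value estimation is the median over converged mask pixels", {
  # phantom-derived maps: remote majority with an MI sector in the mask
  ph <- make_cardiac_phantom("chronic_mi", size = 64L, r_blood = 14,
                             r_epi = 20)
  p <- default_msasha_protocol()
  s <- simulate_series(ph, p, snr = Inf)
  myo <- region_mask(ph, c("remote", "MI"))
  maps <- fit_maps(s, p, mask = myo)
  expect_lt(sum(region_mask(ph, "MI")) / sum(myo), 0.5)
  nv <- estimate_normal_values(maps, myo)
  # median dominated by remote tissue, the rationale for using the median
  expect_equal(unname(nv["T1m"]), 668, tolerance = 1e-3)
  expect_equal(unname(nv["T2m"]), 42.4, tolerance = 1e-3)

  # uniform region returns the exact value; single pixel returns itself
  rem <- region_mask(ph, "remote")
  expect_equal(unname(estimate_normal_values(maps, rem)["T1m"]), 668,
               tolerance = 1e-3)
  one <- matrix(FALSE, 64, 64)
  one[which(rem)[1]] <- TRUE
  expect_equal(unname(estimate_normal_values(maps, one)["T1m"]),
               maps$T1[which(one)])
  expect_error(estimate_normal_values(maps, matrix(FALSE, 64, 64)), "mask")
})

test_that("LGEb sweep anchors the blood level at every setting and includes the default", {
  ref <- chronic_reference()
  ph <- make_cardiac_phantom("chronic_mi", size = 48L, r_blood = 10, r_epi = 16)
  idx <- match(as.vector(ph$label_map), ph$regions$id)
  R1 <- matrix(1000 / ph$regions$T1[idx], 48)
  R2 <- matrix(1000 / ph$regions$T2[idx], 48)
  blood <- region_mask(ph, "blood")

  levels <- c(1, 0.5, 0, -0.25, -0.5)
  sw <- lgeb_sweep(R1, R2, ref, levels)
  expect_length(sw, 5L)
  blood_means <- vapply(sw, function(im) mean(im$values[blood]), numeric(1))
  # blood-region signal equals each LGEb by construction (noise-free maps)
  expect_equal(unname(blood_means), levels, tolerance = 1e-9)
  expect_true(all(diff(blood_means) < 0))
  # endpoint reproduces the default dark-blood computation
  expect_equal(sw[["LGEb=-0.5"]]$values, calc_db_psir(R1, R2, ref)$values)
  # a_DB = 1 fixed point handled inside a sweep
  l1 <- ref$R1b - ref$R1m * ref$R2m / ref$R2b
  sw1 <- lgeb_sweep(R1, R2, ref, l1)
  expect_equal(mean(sw1[[1]]$values[blood]), l1, tolerance = 1e-9)
})

test_that("edema attenuation is 1 at the reference T2 and falls with T2 elevation", {
  remote <- tissue_relaxation(600, 42)
  blood <- tissue_relaxation(400, 150)
  t1g <- seq(300, 550, by = 50)
  t2g <- seq(42, 100, by = 2)
  att <- db_attenuation_curve(t1g, t2g, remote, blood, LGEb = -0.5)
  expect_true(all(is.finite(att)))
  # T2 equal to remote T2 leaves the signal untouched
  expect_equal(unname(att[, 1]), rep(1, length(t1g)), tolerance = 1e-12)
  # strictly decreasing in edema T2 at every fixed T1 below remote T1
  for (i in seq_along(t1g)) expect_true(all(diff(att[i, ]) < 0))
  # undefined where the bright-blood signal is zero (T1 = remote T1)
  att0 <- db_attenuation_curve(600, c(42, 60), remote, blood)
  expect_true(all(is.nan(att0)))
  expect_error(db_attenuation_curve(-300, t2g, remote, blood), "positive")
})
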