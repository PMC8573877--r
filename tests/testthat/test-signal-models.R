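test_that("inversion-recovery PSIR signal has the right null point, bounds and monotonicity", {
  # null point TI = T1 log 2, full inversion at TI = 0
  for (T1 in c(300, 668, 1200)) {
    expect_equal(ir_psir_signal(T1 * log(2), T1), 0, tolerance = 1e-12)
  }
  expect_equal(ir_psir_signal(0, 668), -1)
  # frozen closed-form evaluation at the remote-myocardium operating point
  expect_equal(ir_psir_signal(300, 668), -0.27640225761, tolerance = 1e-10)
  # accepts a tissue_relaxation object
  expect_equal(ir_psir_signal(300, tissue_relaxation(668, 42.4)),
               ir_psir_signal(300, 668))

  # strictly increasing in TI; strictly decreasing in T1 for TI > 0
  ti <- seq(0, 2000, by = 50)
  expect_true(all(diff(ir_psir_signal(ti, 668)) > 0))
  t1s <- seq(200, 2000, by = 50)
  expect_true(all(diff(ir_psir_signal(400, t1s)) < 0))

  expect_error(ir_psir_signal(300, -5), "positive")
  expect_error(ir_psir_signal(-1, 668), "non-negative")
})

test_that("IR-T2 signal reduces to plain IR at TE = 0 and matches its symbolic limits", {
  grid <- expand.grid(TD1 = c(0, 100, 350), TD2 = c(0, 50, 400),
                      T1 = c(300, 668, 1500), T2 = c(40, 142))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(ir_t2_psir_signal(g$TD1, g$TD2, 0, g$T1, g$T2),
                 ir_psir_signal(g$TD1 + g$TD2, g$T1), tolerance = 1e-12)
  }
  # TD1 = TD2 = 0: the inverted magnetization decays through the T2 prep
  # and is read out immediately, so the signal is -exp(-TE/T2) by direct
  # substitution (frozen value)
  expect_equal(ir_t2_psir_signal(0, 0, 55, 668, 42.4),
               -0.273304201945, tolerance = 1e-10)
  expect_equal(ir_t2_psir_signal(0, 0, 55, 668, 42.4),
               -exp(-55 / 42.4), tolerance = 1e-12)
  # long delays: full recovery
  expect_equal(ir_t2_psir_signal(1e7, 1e7, 55, 668, 42.4), 1, tolerance = 1e-9)
  expect_error(ir_t2_psir_signal(100, 100, 55, 668, -1), "T2")
})

test_that("mSASHA signal matches the saturation-recovery closed forms and is bounded", {
  # SR closed form at the protocol operating point (frozen)
  expect_equal(msasha_signal("SR", TS = 300, A = 1, T1 = 668),
               0.361798871195, tolerance = 1e-10)
  # TS -> Inf approaches the full amplitude; anchor approaches A as well
  expect_equal(msasha_signal("SR", TS = 1e8, A = 2.5, T1 = 668), 2.5,
               tolerance = 1e-9)
  # TE_prep = 0 makes the T2-prepped frame equal to the SR frame
  expect_equal(
    msasha_signal("SR+T2prep", TS = 300, TE_prep = 0, A = 1, T1 = 668, T2 = 42.4),
    msasha_signal("SR", TS = 300, A = 1, T1 = 668)
  )
  # anchor recovery duration enters the same exponential
  expect_equal(msasha_signal("anchor", recovery_duration = 3300, A = 1, T1 = 668),
               1 - exp(-3300 / 668), tolerance = 1e-12)

  # bounded in [0, A] across a parameter sweep
  sweep <- expand.grid(TS = c(0, 100, 300, 5000), TE = c(0, 25, 55, 200),
                       T1 = c(250, 668, 2000), T2 = c(35, 142), A = c(0.5, 1, 3))
  for (i in seq_len(nrow(sweep))) {
    s <- sweep[i, ]
    v <- msasha_signal("SR+T2prep", TS = s$TS, TE_prep = s$TE, A = s$A,
                       T1 = s$T1, T2 = s$T2)
    expect_true(v >= 0 && v <= s$A)
  }
  expect_error(msasha_signal("invalid", TS = 300, A = 1, T1 = 668))
})

test_that("gadolinium concentration from T2 shortening matches the relaxivity model", {
  # native arterial blood ~250 ms falling to ~142 ms post contrast
  expect_equal(gd_concentration_from_r2(250, 142, r2 = 5.85), 0.52,
               tolerance = 0.01)
  expect_equal(gd_concentration_from_r2(250, 250), 0)
  # round trip through the forward relaxivity model is the identity
  for (c0 in c(0, 0.1, 0.52, 1.7, 5)) {
    t2p <- t2_post_from_concentration(250, c0, r2 = 5.85)
    expect_equal(gd_concentration_from_r2(250, t2p, r2 = 5.85), c0,
                 tolerance = 1e-12)
  }
  expect_error(gd_concentration_from_r2(142, 250), "negative")
})

test_that("rate/time conversion is reciprocal and reproduces the regional R1 values", {
  expect_equal(round(r1_from_t1(441), 2), 2.27)
  expect_equal(r1_from_t1(668), 1.49, tolerance = 0.01)
  expect_equal(round(r1_from_t1(466), 2), 2.15)
  expect_equal(r1_from_t1(1000), 1)
  t1s <- c(258, 441, 668, 1527)
  expect_equal(t1_from_r1(r1_from_t1(t1s)), t1s, tolerance = 1e-14)
  expect_error(r1_from_t1(0), "positive")
})

test_that("tissue_relaxation enforces positivity and the reciprocal invariant", {
  t <- tissue_relaxation(668, 42.4)
  expect_equal(t$R1 * t$T1, 1000, tolerance = 1e-12)
  expect_equal(t$R2 * t$T2, 1000, tolerance = 1e-12)
  expect_error(tissue_relaxation(-1, 40), "T1")
  expect_error(tissue_relaxation(600, 0), "T2")
})
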