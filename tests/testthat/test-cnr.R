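test_that("ROI statistics are sample mean and sd over the mask", {
  img <- matrix(7, 20, 20)
  m <- matrix(TRUE, 20, 20)
  st <- roi_stats(img, m)
  expect_equal(st$mean, 7)
  expect_equal(st$sd, 0)
  expect_equal(st$n_pixels, 400L)

  # Gaussian field: stats within 3 sampling standard errors
  set.seed(21)
  g <- matrix(stats::rnorm(1e4, mean = 10, sd = 2), 100, 100)
  sg <- roi_stats(g, matrix(TRUE, 100, 100))
  expect_lt(abs(sg$mean - 10), 3 * 2 / sqrt(1e4))
  expect_lt(abs(sg$sd - 2), 3 * 2 / sqrt(2 * 1e4))

  one <- matrix(FALSE, 20, 20); one[3, 3] <- TRUE
  expect_warning(s1 <- roi_stats(img, one), "single-pixel")
  expect_equal(s1$mean, 7); expect_equal(s1$sd, 0)
  expect_error(roi_stats(img, matrix(FALSE, 20, 20)), "empty")
})

test_that("CNR is the mean difference over the reference sd, antisymmetric", {
  mk <- function(m, s) structure(list(region = NA, mean = m, sd = s,
                                      n_pixels = 100L), class = "roi_stats")
  expect_equal(cnr(mk(3, 1), mk(1, 1), mk(0, 0.5)), 4)
  expect_equal(cnr(mk(5, 2), mk(5, 3), mk(0, 1)), 0)
  expect_equal(cnr(mk(2, 1), mk(8, 1), mk(0, 2)),
               -cnr(mk(8, 1), mk(2, 1), mk(0, 2)))
  expect_error(cnr(mk(1, 1), mk(0, 1), mk(0, 0)), "positive")
})

test_that("Monte-Carlo PSIR stats converge to the deterministic values as SNR grows", {
  t <- chronic_tissues()
  tissues <- data.frame(region = c("MI", "remote", "blood"),
                        T1 = c(t$mi$T1, t$remote$T1, t$blood$T1),
                        T2 = c(t$mi$T2, t$remote$T2, t$blood$T2))
  det_ref <- NULL
  sds <- c()
  for (snr in c(20, 80, Inf)) {
    cfg <- mc_config(tissues, snr = snr, n_trials = 400L, seed = 33L,
                     mode = "linearized")
    st <- mc_psir_stats(cfg)
    det <- attr(st, "deterministic")
    if (is.null(det_ref)) det_ref <- det
    mi_bb <- st[st$region == "MI" & st$kind == "BB", ]
    sds <- c(sds, mi_bb$sd)
    if (is.infinite(snr)) {
      expect_equal(mi_bb$sd, 0)
      expect_equal(mi_bb$mean, det[["MI"]][["BB"]], tolerance = 1e-12)
    }
  }
  # noise of the calculated image shrinks as raw SNR increases
  expect_true(all(diff(sds) < 0))
  # deterministic values agree with direct evaluation of the PSIR formulas
  ref <- chronic_reference()
  expect_equal(det_ref[["MI"]][["BB"]], 1000 / 441 - ref$R1m, tolerance = 1e-12)
  expect_equal(det_ref[["blood"]][["DB"]], -0.5, tolerance = 1e-9)
})

test_that("full-fit Monte-Carlo: remote BB is unbiased and DB beats BB on blood CNR", {
  t <- chronic_tissues()
  tissues <- data.frame(region = c("MI", "remote", "blood"),
                        T1 = c(t$mi$T1, t$remote$T1, t$blood$T1),
                        T2 = c(t$mi$T2, t$remote$T2, t$blood$T2))
  cfg <- mc_config(tissues, snr = 40, n_trials = 300L, seed = 9L, mode = "fit")
  st <- mc_psir_stats(cfg)
  expect_true(all(st$n_used >= 0.95 * 300))

  rem <- st[st$region == "remote" & st$kind == "BB", ]
  se <- rem$sd / sqrt(rem$n_used)
  expect_lt(abs(rem$mean - 0), 3 * se)

  # headline ordering: dark-blood gives far better scar-blood contrast
  expect_gt(mc_cnr(st, "DB", "MI", "blood"), mc_cnr(st, "BB", "MI", "blood"))

  # reproducibility under the seed
  st2 <- mc_psir_stats(mc_config(tissues, snr = 40, n_trials = 300L,
                                 seed = 9L, mode = "fit"))
  expect_equal(st$mean, st2$mean)
  expect_equal(st$sd, st2$sd)
})

test_that("linearized and full-fit modes agree at moderate noise", {
  tissues <- data.frame(region = c("MI", "remote", "blood"),
                        T1 = c(441, 668, 466), T2 = c(43.8, 42.4, 142.4))
  st_fit <- mc_psir_stats(mc_config(tissues, snr = 40, n_trials = 400L,
                                    seed = 2L, mode = "fit"))
  st_lin <- mc_psir_stats(mc_config(tissues, snr = 40, n_trials = 4000L,
                                    seed = 2L, mode = "linearized"))
  for (r in c("MI", "remote", "blood")) {
    for (k in c("BB", "DB")) {
      a <- st_fit[st_fit$region == r & st_fit$kind == k, ]
      b <- st_lin[st_lin$region == r & st_lin$kind == k, ]
      expect_equal(a$sd, b$sd, tolerance = 0.25)
      expect_lt(abs(a$mean - b$mean), 4 * a$sd / sqrt(a$n_used) + 0.01)
    }
  }
})
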