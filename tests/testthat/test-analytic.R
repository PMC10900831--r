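test_that("crystallinity factor matches its limits and direct values", {
  expect_equal(crystallinity_factor(0, 0.37), 1)
  expect_equal(crystallinity_factor(0.8, 1), 1)
  expect_equal(crystallinity_factor(0.5, 0.01), 50.5)
  expect_error(crystallinity_factor(0.5, 0), "\\(0,1\\]")
  expect_error(crystallinity_factor(1.1, 0.5), "\\[0,1\\]")
  # F >= 1 always
  for (X in seq(0, 1, 0.25)) for (r in c(1e-3, 0.1, 1))
    expect_gte(crystallinity_factor(X, r), 1)
})

test_that("characteristic times evaluate the closed forms", {
  ct <- characteristic_times(N = 10, K_EG = 1, K_CBHA = 0.25, K_CBHD = 10,
                             K_BGL = 1)
  expect_equal(ct$tau_CBHA, 1)        # 1 / (4 * 1 * 0.25)
  expect_equal(ct$tau_EG, 1 / 16)     # 1 / (2N - 4)
  expect_equal(ct$tau_CBH, ct$tau_CBHA + ct$tau_CBHD)
  ct2 <- characteristic_times(N = 10, K_EG = 1, K_CBHA = 0.25, K_CBHD = 10,
                              K_BGL = 1, X = 0.5, r = 0.01)
  expect_equal(ct2$tau_CBHD, 50.5)    # (10/10) * F
  expect_equal(ct2$tau_CBHA, 1)       # attachment is crystallinity-blind
  expect_error(characteristic_times(N = 2, K_EG = 1, K_CBHA = 1, K_CBHD = 1,
                                    K_BGL = 1), "N must be >= 3")
})

test_that("the limiting step is the largest characteristic time", {
  ct <- characteristic_times(N = 50, K_EG = 100, K_CBHA = 100, K_CBHD = 10,
                             K_BGL = 100)
  ls <- limiting_step(ct)
  expect_equal(ls$limiting, "CBH")
  expect_equal(unname(ls$taus[["CBH"]]), 1 / 400 + 5)
  # EG limiting when its rate collapses
  ct_eg <- characteristic_times(N = 50, K_EG = 1e-6, K_CBHA = 100,
                                K_CBHD = 1e6, K_BGL = 100)
  expect_equal(limiting_step(ct_eg)$limiting, "EG")
  # constructed exact tie
  ct_tie <- ct
  ct_tie$tau_EG <- ct$tau_CBH
  ct_tie$tau_BGL <- ct$tau_CBH
  expect_equal(limiting_step(ct_tie)$limiting, "tie")
})

test_that("EG regime roots reproduce the printed K_R = 1 values", {
  r <- eg_regime_roots(1)
  expect_equal(unname(r$printed["N1"]), 2.53)
  expect_equal(unname(r$printed["N2"]), -0.19)
  expect_equal(r$N1, (14 + sqrt(268)) / 12, tolerance = 1e-12)
  expect_error(eg_regime_roots(0), "K_R must be > 0")
  # two real roots straddling zero for every K_R > 0
  for (k in 10^seq(-3, 3)) {
    rr <- eg_regime_roots(k)
    expect_true(is.finite(rr$N1) && is.finite(rr$N2))
    expect_gt(rr$N1, 0); expect_lt(rr$N2, 0)
    expect_gte(rr$N1, rr$N2)
    # Vieta: product of roots = -3 K_R / 6 < 0
    expect_equal(rr$N1 * rr$N2, -3 * k / 6, tolerance = 1e-9)
  }
})

test_that("printed and derived polynomial variants diverge as documented", {
  # identical at K_R = 1
  expect_equal(eg_regime_roots(1, "printed")$N1, eg_regime_roots(1, "derived")$N1)
  # large K_R: printed N1 grows without bound, derived N1 -> 2
  big <- 1e6
  expect_gt(eg_regime_roots(big, "printed")$N1, 1000)
  expect_equal(eg_regime_roots(big, "derived")$N1, 2, tolerance = 1e-3)
  expect_false(eg_validity(big, 50, "printed"))
  expect_true(eg_validity(big, 50, "derived"))
  rep <- regime_report(parameter_set(K_EG = 1000, K_CBHD = 10))
  expect_true(is.list(rep$roots_printed_variant) && is.list(rep$roots_derived_variant))
})

test_that("EG validity is a root comparison", {
  expect_true(eg_validity(1, 3))    # 3 > 2.53
  expect_false(eg_validity(1, 2))   # 2 < 2.53
})

test_that("BGL threshold cases follow the K_R' algebra", {
  r1 <- bgl_threshold(1)
  expect_equal(r1$case, "threshold")
  expect_equal(r1$N_threshold, 3)   # 3 / (3 - 2)
  expect_true(bgl_validity(1, 4)); expect_false(bgl_validity(1, 3))
  expect_equal(bgl_threshold(0.5)$case, "all_N_ge_3")
  expect_true(bgl_validity(0.5, 3))
  expect_equal(bgl_threshold(2 / 3)$case, "none")
  expect_false(bgl_validity(2 / 3, 1e6))
})

test_that("tau_CBHA sensitivity report matches the 10% / 1% statements", {
  rep <- tau_sensitivity_report()
  n_row <- rep[rep$parameter == "n_CBH0", ]
  k_row <- rep[rep$parameter == "K_CBHA", ]
  expect_equal(n_row$max_rel_change_pct, 10, tolerance = 1e-4)
  expect_equal(k_row$max_rel_change_pct, 1, tolerance = 1e-4)
  expect_equal(n_row$at_value, 10)
  # doubling the range minimum halves the maximum relative change
  rep2 <- tau_sensitivity_report(ranges = list(n_CBH0 = c(20, 100)))
  expect_equal(rep2$max_rel_change_pct, 5, tolerance = 1e-4)
})

test_that("the limiting-step comparison is independent of (X, r)", {
  set.seed(4)
  for (i in 1:20) {
    K <- 10^stats::runif(4, 0, 3)
    n <- stats::runif(3, 1, 50)
    base <- characteristic_times(N = 30, K_EG = K[1], K_CBHA = K[2],
                                 K_CBHD = K[3], K_BGL = K[4],
                                 n_EG0 = n[1], n_CBH0 = n[2], n_BGL0 = n[3])
    r0 <- base$tau_CBHD / base$tau_EG
    for (X in c(0.2, 0.8)) for (r in c(1e-3, 0.1)) {
      ct <- characteristic_times(N = 30, K_EG = K[1], K_CBHA = K[2],
                                 K_CBHD = K[3], K_BGL = K[4],
                                 n_EG0 = n[1], n_CBH0 = n[2], n_BGL0 = n[3],
                                 X = X, r = r)
      expect_equal(ct$tau_CBHD / ct$tau_EG, r0, tolerance = 1e-10)
      expect_equal(ct$tau_CBHD / ct$tau_BGL, base$tau_CBHD / base$tau_BGL,
                   tolerance = 1e-10)
    }
  }
})

test_that("CBH limits across the stated rate ranges (dense sweep)", {
  for (kd in c(10, 30, 100)) for (ke in c(100, 300, 1000)) for (kb in c(100, 300, 1000)) {
    ct <- characteristic_times(N = 50, K_EG = ke, K_CBHA = 500, K_CBHD = kd,
                               K_BGL = kb, n_EG0 = 1, n_CBH0 = 1, n_BGL0 = 1)
    expect_equal(limiting_step(ct)$limiting, "CBH")
  }
})

test_that("the largest-tau enzyme is also the most impactful in simulation", {
  # single-chain substrate; double each enzyme's rate and compare the change
  # in mean completion time with the characteristic-time ranking
  cfg <- bare_chain(40)
  combos <- list(
    list(K_EG = 500, K_CBHA = 500, K_CBHD = 5, K_BGL = 500),   # CBH limits
    list(K_EG = 2, K_CBHA = 500, K_CBHD = 500, K_BGL = 500),   # EG limits
    list(K_EG = 500, K_CBHA = 500, K_CBHD = 500, K_BGL = 2),   # BGL limits
    list(K_EG = 400, K_CBHA = 400, K_CBHD = 8, K_BGL = 400),
    list(K_EG = 3, K_CBHA = 600, K_CBHD = 600, K_BGL = 600)
  )
  n_rep <- 20
  agree <- vapply(combos, function(co) {
    p0 <- plain_params(K_EG = co$K_EG, K_CBHA = co$K_CBHA, K_CBHD = co$K_CBHD,
                       K_BGL = co$K_BGL, n_EG0 = 1, n_CBH0 = 1, n_BGL0 = 1,
                       n_XYL0 = 0)
    ct <- characteristic_times(N = 20, K_EG = co$K_EG, K_CBHA = co$K_CBHA,
                               K_CBHD = co$K_CBHD, K_BGL = co$K_BGL)
    predicted <- limiting_step(ct)$limiting
    mean_t <- function(p) mean(vapply(seq_len(n_rep), function(s)
      completion_time(p, cfg, 7000 + s), numeric(1)))
    t0 <- mean_t(p0)
    deltas <- vapply(c("EG", "CBH", "BGL"), function(enz) {
      p2 <- p0
      if (enz == "EG") p2$K_EG <- p2$K_EG * 2
      if (enz == "CBH") p2$K_CBHD <- p2$K_CBHD * 2
      if (enz == "BGL") p2$K_BGL <- p2$K_BGL * 2
      abs(mean_t(parameter_set(p2)) - t0)
    }, numeric(1))
    names(which.max(deltas)) == predicted
  }, logical(1))
  expect_gte(mean(agree), 0.9 * 5 / 5 - 1e-9) # all five clear-margin cases
})
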