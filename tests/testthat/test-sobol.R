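unit_problem <- function(p, n_base) {
  nm <- paste0("x", seq_len(p))
  ssa_problem(names = nm,
              bounds = data.frame(parameter = nm, low = 0, high = 1,
                                  scale = "linear"),
              n_base = n_base)
}

test_that("the design emits exactly N_base * (p + 2) parameter sets", {
  d19 <- saltelli_sample(ssa_problem(n_base = 1024), seed = 1)
  expect_equal(nrow(d19$params), 21504)
  expect_equal(ncol(d19$params), 19)
  d2 <- saltelli_sample(unit_problem(2, 4), seed = 1)
  expect_equal(nrow(d2$params), 16)
  # AB_i blocks differ from A only in column i
  n <- 4
  A <- d2$unit[1:n, ]; B <- d2$unit[n + 1:n, ]
  AB1 <- d2$unit[2 * n + 1:n, ]; AB2 <- d2$unit[3 * n + 1:n, ]
  expect_equal(AB1[, 2], A[, 2]); expect_equal(AB1[, 1], B[, 1])
  expect_equal(AB2[, 1], A[, 1]); expect_equal(AB2[, 2], B[, 2])
})

test_that("problem validation rejects malformed definitions", {
  expect_error(ssa_problem(n_base = 100), "power of 2")
  expect_error(ssa_problem(names = c("a", "a"), n_base = 4), "unique")
  expect_error(ssa_problem(names = "a",
                           bounds = data.frame(parameter = "a", low = 1,
                                               high = 0, scale = "linear"),
                           n_base = 4), "low < high")
  expect_error(ssa_problem(names = "a",
                           bounds = data.frame(parameter = "a", low = 0,
                                               high = Inf, scale = "linear"),
                           n_base = 4), "finite")
})

test_that("A-block columns are uniform on their bounds", {
  prob <- ssa_problem(n_base = 1024)
  d <- saltelli_sample(prob, seed = 3)
  A <- d$params[1:1024, ]
  # linear-scale parameter: uniform on [0,1]
  ks1 <- stats::ks.test(A$X_cellulose, "punif")$p.value
  expect_gt(ks1, 0.01)
  # log-scale parameter: log10 uniform on its decade
  ks2 <- stats::ks.test(log10(A$K_CBHD), "punif", 1, 2)$p.value
  expect_gt(ks2, 0.01)
  expect_true(all(A$K_CBHD >= 10 & A$K_CBHD <= 100))
})

test_that("the objective measures summed absolute curve differences", {
  g <- 0:8
  ref <- saccharify:::new_time_course(g, rep(100, 9))
  sim0 <- saccharify:::new_time_course(g, rep(0, 9))
  ob <- curve_objective(sim0, ref)
  expect_equal(ob$Y, 900)
  expect_equal(ob$sign_class, "below")
  same <- curve_objective(ref, ref)
  expect_equal(same$Y, 0)
  expect_equal(same$sign_class, "close")
  # just above the threshold with the simulated curve on top
  simhi <- saccharify:::new_time_course(g, rep(100, 9) - 100)
  simup <- saccharify:::new_time_course(g, rep(100 + 150 * 1.01 / 9, 9))
  expect_equal(curve_objective(simup, ref)$sign_class, "above")
  # mismatched grids are rejected unless interpolation is requested
  sim2 <- saccharify:::new_time_course(seq(0, 8, 0.5), rep(50, 17))
  expect_error(curve_objective(sim2, ref), "different grids")
  expect_equal(curve_objective(sim2, ref, interpolate = TRUE)$Y, 450)
})

test_that("Jansen estimator recovers closed-form total indices", {
  d <- saltelli_sample(unit_problem(2, 1024), seed = 7)
  # single-factor function
  st1 <- sobol_total_indices(d$params$x1, d, seed = 1)
  expect_lt(abs(st1$S_T[1] - 1), 0.05)
  expect_lt(abs(st1$S_T[2] - 0), 0.05)
  # additive linear: S_T,i = a_i^2 / sum(a^2)
  a <- c(3, 1)
  Yl <- a[1] * d$params$x1 + a[2] * d$params$x2
  stl <- sobol_total_indices(Yl, d, seed = 1)
  expect_lt(abs(stl$S_T[1] - 9 / 10), 0.05)
  expect_lt(abs(stl$S_T[2] - 1 / 10), 0.05)
  # product interaction: S_T,i = 4/7 for x1 * x2 on U[0,1]^2
  Yp <- d$params$x1 * d$params$x2
  stp <- sobol_total_indices(Yp, d, seed = 1)
  expect_lt(max(abs(stp$S_T - 4 / 7)), 0.05)
  # scale invariance
  st_scaled <- sobol_total_indices(5 * Yp, d, seed = 1)
  expect_equal(st_scaled$S_T, stp$S_T, tolerance = 1e-12)
  # constant output -> explicit zero-variance error
  expect_error(sobol_total_indices(rep(1, nrow(d$params)), d), "zero output variance")
})

test_that("normalisation fixes the reference parameter at 1 and preserves order", {
  d <- saltelli_sample(ssa_problem(names = c("K_CBHD", "X_cellulose"),
                                   n_base = 256), seed = 2)
  Y <- 2 * d$params$X_cellulose + 0.05 * log10(d$params$K_CBHD)
  st <- sobol_total_indices(Y, d, seed = 1)
  nt <- normalise_indices(st, "K_CBHD")
  expect_equal(nt$S_T_norm[nt$parameter == "K_CBHD"], 1)
  expect_equal(order(nt$S_T), order(nt$S_T_norm))
  nt2 <- normalise_indices(nt, "K_CBHD")
  expect_equal(nt2$S_T_norm, nt$S_T_norm)
  expect_error(normalise_indices(st, "nope"), "not in result")
})

test_that("campaign manifests record the full-scale run arithmetic", {
  prob <- ssa_problem(n_base = 1024, replicates = 10)
  m <- campaign_manifest(prob, seed = 1, n_conditions = 6)
  expect_equal(m$sets_per_condition, 21504)
  expect_equal(m$planned_runs, 1290240)
  expect_equal(m$p, 19)
})

test_that("a miniature campaign runs end to end, persists and resumes", {
  ts <- test_sample_config()
  ref <- reference_curve("simulated", params = default_parameters(),
                         structure = ts$structure, n_rep = 2, seed = 50)
  prob <- ssa_problem(names = c("K_CBHD", "X_cellulose", "n_CBH0"),
                      n_base = 8, replicates = 2, reference = ref)
  out <- file.path(tempdir(), "mini_campaign")
  unlink(out, recursive = TRUE)
  res <- run_campaign(prob, ts$structure, seed = 4, out_dir = out)
  expect_equal(nrow(res$table), 8 * 5)
  expect_true(all(is.finite(res$indices$S_T)))
  expect_true(file.exists(file.path(out, "objectives.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  # resuming reuses the persisted rows and reproduces the indices exactly
  res2 <- run_campaign(prob, ts$structure, seed = 4, out_dir = out, resume = TRUE)
  expect_equal(res2$indices$S_T, res$indices$S_T)
  expect_equal(res2$table$Y, res$table$Y)
  unlink(out, recursive = TRUE)
})

test_that("higher crystallinity pushes simulated curves below the reference", {
  ts <- test_sample_config()
  ref <- reference_curve("simulated", params = default_parameters(),
                         structure = ts$structure, n_rep = 2, seed = 60)
  prob <- ssa_problem(n_base = 16, replicates = 2, reference = ref)
  res <- run_campaign(prob, ts$structure, seed = 6)
  tab <- res$table[res$table$Y > prob$threshold_close, ]
  expect_gt(nrow(tab), 50)
  below <- as.integer(tab$class == "below")
  ct <- suppressWarnings(stats::cor.test(tab$X_cellulose, below,
                                         method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})
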