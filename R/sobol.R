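# Variance-based global sensitivity analysis: Saltelli-style radial
# cross-sampling (A / B / AB_i blocks, N_base * (p + 2) model evaluations),
# curve-difference objective, Jansen total-order estimator with bootstrap
# confidence intervals, and per-condition normalisation by a reference
# parameter's index.

#' Define a sensitivity-analysis problem
#'
#' @param names parameter names (must be unique; names present in
#'   [param_registry()] are applied to the simulator, others act as dummy
#'   factors that the model ignores).
#' @param bounds data.frame with columns `parameter`, `low`, `high`, `scale`
#'   (`"linear"` or `"log10"`); defaults to the packaged table for known
#'   names and \[0, 1\] linear for dummies.
#' @param n_base base sample size N (a power of 2; the design emits
#'   `N * (p + 2)` parameter sets).
#' @param replicates stochastic replicates averaged per parameter set.
#' @param reference a `time_course` the objective compares against.
#' @param threshold_close,threshold_spread objective thresholds for the
#'   close/above/below classification and the spread evaluation.
#' @return an `ssa_problem` list.
#' @export
ssa_problem <- function(names = param_registry(), bounds = NULL,
                        n_base = 1024, replicates = 10, reference = NULL,
                        threshold_close = 150, threshold_spread = 75) {
  if (anyDuplicated(names)) stopf("parameter names must be unique")
  if (!is_power_of_two(n_base)) stopf("n_base must be a power of 2")
  tab <- parameter_bounds()
  if (is.null(bounds)) {
    bounds <- do.call(rbind, lapply(names, function(nm) {
      row <- tab[tab$parameter == nm, , drop = FALSE]
      if (nrow(row) == 1) row
      else data.frame(parameter = nm, low = 0, high = 1, scale = "linear")
    }))
  }
  bounds <- bounds[match(names, bounds$parameter), , drop = FALSE]
  if (any(!is.finite(bounds$low)) || any(!is.finite(bounds$high)) ||
      any(bounds$low >= bounds$high))
    stopf("bounds must be finite with low < high")
  if (any(bounds$scale == "log10" & bounds$low <= 0))
    stopf("log10-scaled bounds must be positive")
  structure(list(names = names, p = length(names), bounds = bounds,
                 n_base = as.integer(n_base), replicates = as.integer(replicates),
                 reference = reference, threshold_close = threshold_close,
                 threshold_spread = threshold_spread),
            class = "ssa_problem")
}

scale_unit <- function(u, bounds) {
  out <- u
  for (j in seq_len(ncol(u))) {
    lo <- bounds$low[j]; hi <- bounds$high[j]
    if (bounds$scale[j] == "log10") {
      out[, j] <- 10^(log10(lo) + u[, j] * (log10(hi) - log10(lo)))
    } else {
      out[, j] <- lo + u[, j] * (hi - lo)
    }
  }
  out
}

# one stratified-uniform (Latin hypercube) block: each column is a permuted
# stratified sample of [0,1)
lhs_block <- function(n, p) {
  m <- matrix(0, n, p)
  for (j in seq_len(p)) m[, j] <- (sample.int(n) - stats::runif(n)) / n
  m
}

#' Saltelli-style cross-sampling design
#'
#' Generates the first/total-order radial design: two independent stratified
#' base blocks A and B of size `n_base`, plus for each parameter i a block
#' AB_i equal to A with column i taken from B - `n_base * (p + 2)` rows in
#' total (21,504 at p = 19, N = 1024). No second-order blocks are emitted.
#' Columns are scaled to the problem bounds per their declared scale.
#'
#' @param problem an [ssa_problem()].
#' @param seed integer seed, or `NULL`.
#' @return a `saltelli_design` list: `unit` (unscaled matrix), `params`
#'   (scaled data.frame of parameter sets, one per row), `block` (row
#'   labels "A", "B", "AB1", ...), `problem`.
#' @export
saltelli_sample <- function(problem, seed = NULL) {
  stopifnot(inherits(problem, "ssa_problem"))
  n <- problem$n_base; p <- problem$p
  with_seed(seed, {
    A <- lhs_block(n, p); B <- lhs_block(n, p)
    blocks <- vector("list", p + 2)
    blocks[[1]] <- A; blocks[[2]] <- B
    for (i in seq_len(p)) {
      ABi <- A; ABi[, i] <- B[, i]
      blocks[[i + 2]] <- ABi
    }
    unit <- do.call(rbind, blocks)
    colnames(unit) <- problem$names
    params <- as.data.frame(scale_unit(unit, problem$bounds))
    names(params) <- problem$names
    structure(list(unit = unit, params = params,
                   block = c(rep("A", n), rep("B", n),
                             rep(paste0("AB", seq_len(p)), each = n)),
                   problem = problem),
              class = "saltelli_design")
  })
}

#' Curve-difference objective Y
#'
#' `Y = sum_i |sim(t_i) - ref(t_i)|` over the reference grid points
#' (conversion in percent). The signed sum classifies the set: `close` when
#' Y < threshold, otherwise `above` (simulated curve area exceeds the
#' reference) or `below`. A trapezoidal time-integral variant (units
#' percent x hours) is selectable.
#'
#' @param sim,ref `time_course` objects on a shared grid (or set
#'   `interpolate = TRUE` to interpolate `sim` onto `ref`'s grid).
#' @param threshold_close class threshold (default 150).
#' @param method `"grid_sum"` (default) or `"trapezoid"`.
#' @param interpolate allow linear interpolation of `sim` onto `ref`'s grid.
#' @return list(`Y`, `signed`, `sign_class`).
#' @export
curve_objective <- function(sim, ref, threshold_close = 150,
                            method = c("grid_sum", "trapezoid"),
                            interpolate = FALSE) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(as.numeric(sim$time_h), as.numeric(ref$time_h)))) {
    if (!interpolate) stopf("curves are on different grids; set interpolate = TRUE")
    sim <- new_time_course(ref$time_h,
                           stats::approx(sim$time_h, sim$conversion_pct,
                                         xout = ref$time_h, rule = 2)$y)
  }
  d <- sim$conversion_pct - ref$conversion_pct
  if (method == "grid_sum") {
    Y <- sum(abs(d)); signed <- sum(d)
  } else {
    t <- ref$time_h
    w <- diff(t)
    Y <- sum(w * (abs(d)[-length(d)] + abs(d)[-1]) / 2)
    signed <- sum(w * (d[-length(d)] + d[-1]) / 2)
  }
  cls <- if (Y < threshold_close) "close" else if (signed >= 0) "above" else "below"
  list(Y = Y, signed = signed, sign_class = cls)
}

#' Jansen total-order Sobol indices
#'
#' `S_T,i = mean((Y_A - Y_AB_i)^2) / (2 Var(Y))` with the output variance
#' estimated from the pooled A and B evaluations. Bootstrap percentile
#' confidence intervals resample the base-sample rows.
#'
#' @param Y numeric vector of objective values aligned with the design rows.
#' @param design a `saltelli_design` (defines the A/B/AB layout).
#' @param n_boot bootstrap resamples (default 100).
#' @param conf confidence level.
#' @param seed seed for the bootstrap.
#' @return a `sobol_result` data.frame: `parameter`, `S_T`, `ci_lo`, `ci_hi`.
#' @export
sobol_total_indices <- function(Y, design, n_boot = 100, conf = 0.95, seed = NULL) {
  stopifnot(inherits(design, "saltelli_design"))
  n <- design$problem$n_base; p <- design$problem$p
  if (length(Y) != n * (p + 2)) stopf("Y length does not match the design layout")
  YA <- Y[seq_len(n)]
  YB <- Y[n + seq_len(n)]
  YAB <- matrix(Y[-(1:(2 * n))], nrow = n)
  est <- function(idx) {
    V <- stats::var(c(YA[idx], YB[idx]))
    if (!is.finite(V) || V <= 0) return(rep(NA_real_, p))
    vapply(seq_len(p), function(i) mean((YA[idx] - YAB[idx, i])^2) / (2 * V),
           numeric(1))
  }
  V0 <- stats::var(c(YA, YB))
  if (!is.finite(V0) || V0 <= 0) stopf("zero output variance: Sobol indices undefined")
  ST <- est(seq_len(n))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) est(sample.int(n, n, replace = TRUE)),
           numeric(p))
  })
  if (p == 1) boot <- matrix(boot, nrow = 1)
  a <- (1 - conf) / 2
  res <- data.frame(parameter = design$problem$names, S_T = ST,
                    ci_lo = apply(boot, 1, stats::quantile, probs = a, na.rm = TRUE),
                    ci_hi = apply(boot, 1, stats::quantile, probs = 1 - a, na.rm = TRUE))
  class(res) <- c("sobol_result", "data.frame")
  attr(res, "estimator") <- "jansen_total"
  attr(res, "n_base") <- n
  res
}

#' Normalise Sobol indices by a reference parameter
#'
#' Sobol indices are only comparable within one analysis; each condition's
#' indices are rescaled so the reference parameter (default the CBH
#' processive rate `K_CBHD`) maps to exactly 1. Ordering is preserved;
#' normalising twice is idempotent.
#'
#' @param result a `sobol_result`.
#' @param reference_param name of the reference parameter.
#' @return the result with columns `S_T_norm`, `ci_lo_norm`, `ci_hi_norm`.
#' @export
normalise_indices <- function(result, reference_param = "K_CBHD") {
  i <- match(reference_param, result$parameter)
  if (is.na(i)) stopf("reference parameter '%s' not in result", reference_param)
  s0 <- result$S_T[i]
  if (!is.finite(s0) || s0 == 0) stopf("reference S_T is zero; cannot normalise")
  result$S_T_norm <- result$S_T / s0
  result$ci_lo_norm <- result$ci_lo / s0
  result$ci_hi_norm <- result$ci_hi / s0
  attr(result, "normalised_by") <- reference_param
  result
}

#' Run a full sensitivity campaign
#'
#' Samples the design, simulates each parameter set (replicate-averaged),
#' evaluates the curve-difference objective against the problem's reference,
#' estimates normalised total-order indices, and (optionally) persists
#' everything incrementally under `out_dir` (samples.csv, objectives.csv,
#' sobol_indices.json, manifest.json); an interrupted campaign with the same
#' `out_dir` and `resume = TRUE` restarts after the last completed row
#' (per-row seeds make this bit-reproducible).
#'
#' @param problem an [ssa_problem()] with a non-NULL reference curve.
#' @param structure the [structure_config()] simulated for every set.
#' @param seed campaign master seed. Replicate seeds are derived from the
#'   base-sample row index, shared across the A/B/AB blocks (common random
#'   numbers): the stochastic simulation noise then cancels in the Jansen
#'   differences, and a parameter the simulator ignores gets S_T exactly 0.
#' @param out_dir output directory, or `NULL` for in-memory only.
#' @param resume reuse completed rows found in `out_dir/objectives.csv`.
#' @param normalise_by reference parameter for [normalise_indices()].
#' @return list(`indices` (normalised `sobol_result`), `table` (per-sample
#'   params + Y + class), `manifest`).
#' @export
run_campaign <- function(problem, structure = structure_config(),
                         seed = 1L, out_dir = NULL, resume = TRUE,
                         normalise_by = "K_CBHD") {
  stopifnot(inherits(problem, "ssa_problem"))
  if (is.null(problem$reference)) stopf("problem needs a reference time course")
  design <- saltelli_sample(problem, seed = seed)
  n_rows <- nrow(design$params)
  reps <- problem$replicates
  reg <- param_registry()
  known <- intersect(problem$names, reg)

  obj_path <- if (!is.null(out_dir)) file.path(out_dir, "objectives.csv")
  done <- data.frame()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cbind(row = seq_len(n_rows), block = design$block,
                           design$params),
                     file.path(out_dir, "samples.csv"), row.names = FALSE)
    if (resume && file.exists(obj_path)) {
      done <- tryCatch(utils::read.csv(obj_path), error = function(e) data.frame())
    }
    if (!nrow(done))
      utils::write.table(data.frame(row = integer(0), Y = numeric(0),
                                    signed = numeric(0), class = character(0)),
                         obj_path, sep = ",", row.names = FALSE, col.names = TRUE)
  }

  Y <- numeric(n_rows); signed <- numeric(n_rows); cls <- character(n_rows)
  grid <- problem$reference$time_h
  for (i in seq_len(n_rows)) {
    if (nrow(done) && i %in% done$row) {
      j <- match(i, done$row)
      Y[i] <- done$Y[j]; signed[i] <- done$signed[j]; cls[i] <- done$class[j]
      next
    }
    pv <- as.list(design$params[i, known, drop = FALSE])
    p <- parameter_set(pv)
    j <- (i - 1L) %% problem$n_base # base-sample row: common random numbers
    sim <- simulate_saccharification(p, structure, n_rep = reps,
                                     t_max = max(grid), grid = grid,
                                     seed = seed + j * reps)
    ob <- curve_objective(sim, problem$reference,
                          threshold_close = problem$threshold_close)
    Y[i] <- ob$Y; signed[i] <- ob$signed; cls[i] <- ob$sign_class
    if (!is.null(out_dir))
      utils::write.table(data.frame(row = i, Y = Y[i], signed = signed[i],
                                    class = cls[i]),
                         obj_path, sep = ",", row.names = FALSE,
                         col.names = FALSE, append = TRUE)
  }

  res <- sobol_total_indices(Y, design, seed = seed)
  res <- normalise_indices(res, normalise_by)
  manifest <- campaign_manifest(problem, seed = seed, n_conditions = 1L)
  manifest$completed_runs <- n_rows * reps
  table <- cbind(design$params, Y = Y, signed = signed, class = cls)
  out <- list(indices = res, table = table, manifest = manifest)
  if (!is.null(out_dir)) {
    jsonlite::write_json(as.list(res), file.path(out_dir, "sobol_indices.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Campaign manifest (planning)
#'
#' Records the design arithmetic without running anything: parameter count,
#' sets per condition `n_base * (p + 2)`, and total planned runs
#' `sets * replicates * conditions` (1,290,240 for p = 19, N = 1024, 10
#' replicates, 6 conditions).
#'
#' @param problem an [ssa_problem()].
#' @param seed campaign seed recorded for reproduction.
#' @param n_conditions number of reference conditions.
#' @return manifest list.
#' @export
campaign_manifest <- function(problem, seed = 1L, n_conditions = 1L) {
  sets <- problem$n_base * (problem$p + 2L)
  list(tool = "saccharify",
       version = as.character(utils::packageVersion("saccharify")),
       seed = seed, p = problem$p, n_base = problem$n_base,
       replicates = problem$replicates, n_conditions = n_conditions,
       sets_per_condition = sets,
       planned_runs = sets * problem$replicates * n_conditions,
       threshold_close = problem$threshold_close,
       threshold_spread = problem$threshold_spread,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Spread of well-fitting crystallinity values
#'
#' Width of the central `coverage` interval (default 98%, trimming 1% per
#' tail) of `X_cellulose` among parameter sets whose objective falls below
#' the spread threshold.
#'
#' @param table campaign table (needs `X_cellulose` and `Y` columns).
#' @param threshold objective cutoff (default 75).
#' @param coverage central mass retained.
#' @return list(`spread`, `lo`, `hi`, `n`).
#' @export
crystallinity_spread <- function(table, threshold = 75, coverage = 0.98) {
  x <- table$X_cellulose[table$Y < threshold]
  if (!length(x)) return(list(spread = NA_real_, lo = NA_real_, hi = NA_real_, n = 0L))
  a <- (1 - coverage) / 2
  q <- stats::quantile(x, c(a, 1 - a), names = FALSE)
  list(spread = q[2] - q[1], lo = q[1], hi = q[2], n = length(x))
}
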