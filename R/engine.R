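# Exact SSA driver. ssa_run() calls the compiled engine; ssa_step() /
# apply_event() / ssa_run_r() form an independent pure-R route used as an
# oracle in the test suite (initial propensities must agree exactly, mean
# curves statistically).

new_time_course <- function(time_h, conversion_pct, replicates = 1L, seeds = NA_integer_) {
  tc <- data.frame(time_h = time_h, conversion_pct = conversion_pct)
  class(tc) <- c("time_course", "data.frame")
  attr(tc, "replicates") <- replicates
  attr(tc, "seeds") <- seeds
  tc
}

#' @export
print.time_course <- function(x, ...) {
  cat("<time_course> ", nrow(x), " grid points, t in [",
      min(x$time_h), ", ", max(x$time_h), "] h, final conversion ",
      sprintf("%.2f", x$conversion_pct[nrow(x)]), "% (",
      attr(x, "replicates"), " replicate(s))\n", sep = "")
  invisible(x)
}

flatten_for_engine <- function(state) {
  list(chain_kind = state$kind_id,
       chain_start = state$chains$mono_start - 1L,
       chain_dp = state$chains$dp,
       chain_bond_start = state$chains$bond_start - 1L,
       present = state$present,
       cover = ifelse(is.na(state$cover), -1L, state$cover - 1L),
       intact = state$bond_intact,
       crystalline = state$bond_crystalline,
       bond_m1 = state$bond_m1 - 1L,
       bond_chain = state$bond_chain - 1L)
}

build_state <- function(params, structure, layout = "contiguous_blocks") {
  st <- build_microfibril(structure, seed = 1L)
  spec <- crystallinity_spec(X_cellulose = params$X_cellulose,
                             X_hemicellulose = params$X_hemicellulose,
                             r_cellulose = params$r_cellulose,
                             r_hemicellulose = params$r_hemicellulose,
                             layout = layout)
  assign_crystallinity(st, spec, seed = NULL)
}

#' Run one stochastic saccharification trajectory
#'
#' Builds the microfibril, assigns crystallinity (fractions and ratios taken
#' from `params`), and runs the exact Gillespie simulation until `t_max`
#' hours or an absorbing state (zero total propensity). Glucose conversion is
#' recorded on `grid` by last-event-carried-forward; conversion counts free
#' monomeric glucose as a percentage of the initial cellulose glucose
#' equivalents. Deterministic for a fixed seed.
#'
#' @param params a [parameter_set()].
#' @param structure a [structure_config()].
#' @param t_max simulation horizon in hours (> 0).
#' @param grid time grid (hours) within \[0, t_max\]; default hourly 0-72.
#' @param seed integer seed, or `NULL` to consume the current RNG stream.
#' @param layout crystallinity layout, see [crystallinity_spec()].
#' @param check_mass verify glucose/xylose conservation after every event.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference, slow).
#' @return a `time_course` with attributes `engine_result` (pools, event
#'   counts, initial per-kind propensities, `mass_ok`).
#' @export
ssa_run <- function(params, structure = structure_config(), t_max = 72,
                    grid = seq(0, 72), seed = NULL,
                    layout = "contiguous_blocks", check_mass = TRUE,
                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  validate_parameters(params)
  if (t_max <= 0) stopf("t_max must be > 0")
  if (any(grid < 0) || any(grid > t_max)) stopf("grid must lie within [0, t_max]")
  # substrate construction and the SSA draw stream are seeded independently:
  # trajectories with matched seeds stay comparable across crystallinity
  # layouts (whose assignment consumes a different number of draws)
  st <- with_seed(seed, build_state(params, structure, layout))
  engine_seed <- if (is.null(seed)) NULL else as.integer(seed) + 499979L
  with_seed(engine_seed, {
    if (engine == "r") return(ssa_run_r_state(st, params, t_max, grid))
    fl <- flatten_for_engine(st)
    res <- .ssa_engine_cpp(fl$chain_kind, fl$chain_start, fl$chain_dp,
                           fl$chain_bond_start, fl$present, fl$cover,
                           fl$intact, fl$crystalline, fl$bond_m1, fl$bond_chain,
                           params, t_max, as.numeric(grid),
                           FALSE, check_mass)
    if (check_mass && !res$mass_ok)
      stopf("internal error: mass conservation violated during trajectory")
    tc <- new_time_course(grid, res$conversion_pct, replicates = 1L,
                          seeds = seed %||% NA_integer_)
    attr(tc, "engine_result") <- res
    tc
  })
}

#' Replicate-averaged saccharification curve
#'
#' Runs `n_rep` independent trajectories (seeds `seed + 0:(n_rep-1)`) and
#' returns the pointwise mean conversion on the shared grid; ten replicates
#' per parameter set is the convention for a single simulated curve.
#'
#' @inheritParams ssa_run
#' @param n_rep number of replicates (>= 1).
#' @return a `time_course` with `replicates` and `seeds` attributes.
#' @export
simulate_saccharification <- function(params, structure = structure_config(),
                                      n_rep = 10, t_max = 72, grid = seq(0, 72),
                                      seed = 1L, layout = "contiguous_blocks",
                                      check_mass = FALSE) {
  stopifnot(n_rep >= 1)
  seeds <- seed + seq_len(n_rep) - 1L
  acc <- 0
  for (s in seeds) {
    tc <- ssa_run(params, structure, t_max, grid, seed = s, layout = layout,
                  check_mass = check_mass)
    acc <- acc + tc$conversion_pct
  }
  new_time_course(grid, acc / n_rep, replicates = as.integer(n_rep), seeds = seeds)
}

#' @rdname simulate_saccharification
#' @export
average_runs <- simulate_saccharification

#' One exact-SSA step (reference implementation)
#'
#' Draws the waiting time from Exponential(total propensity), selects a
#' channel with probability proportional to its propensity, applies the event
#' and refreshes exposure. Errors if the state is absorbing (P = 0).
#'
#' @param state a `microfibril`.
#' @param params a [parameter_set()].
#' @param pool optional prepared [enzyme_pool()]; recomputed if missing.
#' @return list(`waiting_time`, `event` (one channel row), `state`).
#' @export
ssa_step <- function(state, params, pool = NULL) {
  if (is.null(pool)) pool <- prepare_pool(state, params)
  ch <- enumerate_channels(state, pool, params)
  P <- total_propensity(ch)
  if (P <= 0) stopf("absorbing state: total propensity is zero")
  wt <- stats::rexp(1, P)
  i <- findInterval(stats::runif(1) * P, cumsum(ch$propensity),
                    rightmost.closed = TRUE) + 1L
  i <- min(i, nrow(ch))
  ev <- ch[i, , drop = FALSE]
  list(waiting_time = wt, event = ev, state = apply_event(state, ev))
}

#' Apply one event to a microfibril state (reference implementation)
#'
#' @param state a `microfibril`.
#' @param event one row of the channel table from [enumerate_channels()].
#' @return the updated state (exposure refreshed).
#' @export
apply_event <- function(state, event) {
  kind <- event$kind
  if (kind == "EG_cut" || kind == "XYL_cut") {
    j <- event$target
    state$bond_intact[j] <- FALSE
    if (kind == "XYL_cut") {
      c <- state$bond_chain[j]
      for (m in c(state$bond_m1[j], state$bond_m1[j] + 1L)) {
        if (isolated_monomer(state, c, m)) {
          state$present[m] <- FALSE
          state$free_xylose <- state$free_xylose + 1
        }
      }
    }
  } else if (kind == "CBH_attach") {
    h <- abs(event$target); dir <- sign(event$target)
    state$attachments <- rbind(state$attachments, data.frame(head = h, dir = dir))
  } else if (kind == "CBH_cleave") {
    k <- event$target
    h <- state$attachments$head[k]; d <- state$attachments$dir[k]
    c <- chain_of_monomer(state, h)
    s <- state$chains$mono_start[c]; b0 <- state$chains$bond_start[c]
    ext <- fragment_extent(state, c, h)
    len <- ext$len
    state$present[c(h, h + d)] <- FALSE
    state$free_cellobiose <- state$free_cellobiose + 1
    state$bond_intact[b0 + ((if (d > 0) h else h - 1L) - s)] <- FALSE
    if (len > 2) state$bond_intact[b0 + ((if (d > 0) h + 1L else h - 2L) - s)] <- FALSE
    if (len - 2 <= 0) {
      state$attachments <- state$attachments[-k, , drop = FALSE]
    } else if (len - 2 == 1) {
      state$present[h + 2L * d] <- FALSE
      state$free_glucose <- state$free_glucose + 1
      state$attachments <- state$attachments[-k, , drop = FALSE]
    } else {
      state$attachments$head[k] <- h + 2L * d
    }
    keep <- state$present[state$attachments$head]
    state$attachments <- state$attachments[keep, , drop = FALSE]
  } else if (kind == "BGL_split") {
    state$free_cellobiose <- state$free_cellobiose - 1
    state$free_glucose <- state$free_glucose + 2
  } else stopf("unknown event kind: %s", kind)
  expose_update(state)
}

isolated_monomer <- function(state, c, m) {
  if (!state$present[m]) return(FALSE)
  s <- state$chains$mono_start[c]; dp <- state$chains$dp[c]
  b0 <- state$chains$bond_start[c]
  left <- m > s && state$present[m - 1L] && state$bond_intact[b0 + (m - 1L - s)]
  right <- m < s + dp - 1L && state$present[m + 1L] && state$bond_intact[b0 + (m - s)]
  !left && !right
}

# pure-R trajectory on a prepared state (oracle; small substrates only)
ssa_run_r_state <- function(state, params, t_max, grid) {
  t <- 0; gi <- 1L; n <- length(grid)
  conv <- numeric(n)
  cv <- function(st) if (st$init_cellulose > 0) 100 * st$free_glucose / st$init_cellulose else 0
  repeat {
    pool <- prepare_pool(state, params)
    ch <- enumerate_channels(state, pool, params)
    P <- total_propensity(ch)
    if (P <= 0) { while (gi <= n) { conv[gi] <- cv(state); gi <- gi + 1L }; break }
    t_new <- t + stats::rexp(1, P)
    if (t_new > t_max) { while (gi <= n) { conv[gi] <- cv(state); gi <- gi + 1L }; break }
    while (gi <= n && grid[gi] < t_new) { conv[gi] <- cv(state); gi <- gi + 1L }
    t <- t_new
    i <- findInterval(stats::runif(1) * P, cumsum(ch$propensity), rightmost.closed = TRUE) + 1L
    i <- min(i, nrow(ch))
    state <- apply_event(state, ch[i, , drop = FALSE])
  }
  tc <- new_time_course(grid, conv)
  attr(tc, "final_state") <- state
  tc
}

#' Frozen-state event counting
#'
#' Draws Gillespie events from the initial state without applying any of
#' them, so each channel group's event count over \[0, t_max\] is Poisson
#' with mean `propensity * t_max`. Used to verify waiting-time exactness.
#'
#' @inheritParams ssa_run
#' @return list with `event_counts` (per kind), `initial_propensity` (per
#'   kind), and `t_max`.
#' @export
frozen_event_counts <- function(params, structure = structure_config(),
                                t_max = 1, seed = NULL,
                                layout = "contiguous_blocks") {
  validate_parameters(params)
  st <- with_seed(seed, build_state(params, structure, layout))
  engine_seed <- if (is.null(seed)) NULL else as.integer(seed) + 499979L
  with_seed(engine_seed, {
    fl <- flatten_for_engine(st)
    res <- .ssa_engine_cpp(fl$chain_kind, fl$chain_start, fl$chain_dp,
                           fl$chain_bond_start, fl$present, fl$cover,
                           fl$intact, fl$crystalline, fl$bond_m1, fl$bond_chain,
                           params, t_max, numeric(0), TRUE, FALSE)
    list(event_counts = res$event_counts,
         initial_propensity = res$initial_propensity, t_max = t_max)
  })
}

#' Scan parameter sets against a reference curve (test-sample experiment)
#'
#' For each parameter set, simulates a replicate-averaged curve on the
#' reference grid, computes the absolute-difference objective Y and
#' classifies the set as `close` (Y below threshold), `above` (simulated
#' curve above the reference) or `below`. With the fully amorphous, pure
#' cellulose test-sample configuration this reproduces the CBH-rate scan.
#'
#' @param params_list list of parameter sets.
#' @param reference a `time_course` reference curve.
#' @param structure a [structure_config()].
#' @param n_rep replicates per set.
#' @param seed base seed; set i uses `seed + (i-1) * n_rep` for its replicates.
#' @param threshold_close objective threshold for the `close` class.
#' @return data.frame with one row per set: `set`, `Y`, `class`, plus the
#'   sampled `K_CBHD`, `omega_CBH_glc`, `n_CBH0`, `X_cellulose` columns.
#' @export
test_sample_scan <- function(params_list, reference,
                             structure = test_sample_config()$structure,
                             n_rep = 3, seed = 1L, threshold_close = 150) {
  rows <- lapply(seq_along(params_list), function(i) {
    p <- params_list[[i]]
    sim <- simulate_saccharification(p, structure, n_rep = n_rep,
                                     t_max = max(reference$time_h),
                                     grid = reference$time_h,
                                     seed = seed + (i - 1L) * n_rep)
    ob <- curve_objective(sim, reference, threshold_close = threshold_close)
    data.frame(set = i, Y = ob$Y, class = ob$sign_class,
               K_CBHD = p$K_CBHD, omega_CBH_glc = p$omega_CBH_glc,
               n_CBH0 = p$n_CBH0, X_cellulose = p$X_cellulose)
  })
  do.call(rbind, rows)
}
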