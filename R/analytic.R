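# Closed-form characteristic-time framework for a pure cellulose chain of
# DP_2N digested by EG + CBH + BGL: crystallinity-weighted times,
# inhibition-corrected times, limiting-step comparison, and the EG/BGL
# regime algebra (quadratic roots in N, validity thresholds).

#' Crystallinity weighting factor
#'
#' A polymer with crystalline fraction X and digestibility ratio r takes
#' `F = 1 + X(1/r - 1)` times longer to digest than its fully amorphous
#' counterpart (weighted sum of crystalline and amorphous characteristic
#' times). F = 1 when X = 0 or r = 1; F >= 1 always. The factor applies to
#' the digestion steps (EG, processive CBH cleavage, BGL) but never to CBH
#' attachment, which does not discriminate bond types.
#'
#' @param X crystallinity fraction in \[0, 1\].
#' @param r digestibility ratio in (0, 1\].
#' @return the factor `1 + X(1/r - 1)`.
#' @export
crystallinity_factor <- function(X, r) {
  if (any(!is.finite(X)) || any(X < 0) || any(X > 1)) stopf("X must be in [0,1]")
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1)) stopf("r must be in (0,1]")
  1 + X * (1 / r - 1)
}

#' Characteristic times of the cellulase reactions
#'
#' For a cellulose chain of DP_2N (2N glucose monomers), with free-glucose
#' inhibition and crystallinity weighting F = `crystallinity_factor(X, r)`:
#' \itemize{
#'   \item `tau_EG  = F / ((2N-4) K_EG n_EG0 g_EG)` - (2N-4) attack points;
#'   \item `tau_CBHA = 1 / (4 K_CBHA n_CBH0 g_CBH)` - two DP_N fragments
#'     expose 4 free ends; attachment is crystallinity-blind;
#'   \item `tau_CBHD = (N / K_CBHD) F` - N processive cellobiose releases;
#'   \item `tau_CBH = tau_CBHA + tau_CBHD`;
#'   \item `tau_BGL = F / (K_BGL n_BGL0 g_BGL)` - N cellobiose splits at N
#'     sites cancel.
#' }
#' where `g_y = 1 - omega_y_glc * n_glc / (n_EG0 + n_CBH0 + n_BGL0 + n_glc)`
#' is the glucose-inhibition factor (free-cellobiose inhibition is dropped:
#' cellobiose does not accumulate when BGL is sufficient). With all omegas 0
#' the times reduce to the uninhibited forms; with X = 0 they reduce to the
#' amorphous-chain times.
#'
#' @param N half the degree of polymerisation (N >= 3, so 2N-4 > 0 ... the
#'   smallest chain on which EG has an attack point in this counting).
#' @param K_EG,K_CBHA,K_CBHD,K_BGL reaction rates (per hour, > 0).
#' @param n_EG0,n_CBH0,n_BGL0 initial enzyme counts (> 0).
#' @param X,r cellulose crystallinity fraction and digestibility ratio.
#' @param n_glc free glucose molecules (inhibition state).
#' @param omega_EG_glc,omega_CBH_glc,omega_BGL_glc glucose inhibition
#'   binding affinities in \[0, 1\].
#' @return a `characteristic_times` list: the five taus plus echoed inputs.
#' @export
characteristic_times <- function(N, K_EG, K_CBHA, K_CBHD, K_BGL,
                                 n_EG0 = 1, n_CBH0 = 1, n_BGL0 = 1,
                                 X = 0, r = 1, n_glc = 0,
                                 omega_EG_glc = 0, omega_CBH_glc = 0,
                                 omega_BGL_glc = 0) {
  if (N < 3) stopf("N must be >= 3 (no EG attack points below DP_6)")
  if (any(c(K_EG, K_CBHA, K_CBHD, K_BGL, n_EG0, n_CBH0, n_BGL0) <= 0))
    stopf("rates and enzyme counts must be > 0")
  FF <- crystallinity_factor(X, r)
  S <- n_EG0 + n_CBH0 + n_BGL0
  g <- function(om) 1 - om * n_glc / (S + n_glc)
  tau_EG <- FF / ((2 * N - 4) * K_EG * n_EG0 * g(omega_EG_glc))
  tau_CBHA <- 1 / (4 * K_CBHA * n_CBH0 * g(omega_CBH_glc))
  tau_CBHD <- (N / K_CBHD) * FF
  tau_BGL <- FF / (K_BGL * n_BGL0 * g(omega_BGL_glc))
  structure(list(
    tau_EG = tau_EG, tau_CBHA = tau_CBHA, tau_CBHD = tau_CBHD,
    tau_CBH = tau_CBHA + tau_CBHD, tau_BGL = tau_BGL,
    inputs = list(N = N, K_EG = K_EG, K_CBHA = K_CBHA, K_CBHD = K_CBHD,
                  K_BGL = K_BGL, n_EG0 = n_EG0, n_CBH0 = n_CBH0,
                  n_BGL0 = n_BGL0, X = X, r = r, n_glc = n_glc,
                  omega_EG_glc = omega_EG_glc, omega_CBH_glc = omega_CBH_glc,
                  omega_BGL_glc = omega_BGL_glc)
  ), class = "characteristic_times")
}

#' @export
print.characteristic_times <- function(x, ...) {
  cat(sprintf("<characteristic_times> N=%g\n", x$inputs$N))
  cat(sprintf("  tau_EG   = %.4g h\n  tau_CBHA = %.4g h\n  tau_CBHD = %.4g h\n",
              x$tau_EG, x$tau_CBHA, x$tau_CBHD))
  cat(sprintf("  tau_CBH  = %.4g h\n  tau_BGL  = %.4g h\n", x$tau_CBH, x$tau_BGL))
  invisible(x)
}

#' Time-limiting enzymatic step
#'
#' The reaction class with the largest characteristic time dominates the
#' saccharification dynamics. Compares `tau_EG`, `tau_CBH`, `tau_BGL`;
#' pairwise ratios are reported as margins. Exact ties return `"tie"`.
#'
#' @param times a [characteristic_times()] object.
#' @return list(`limiting` in EG/CBH/BGL/tie, `taus`, `margins`).
#' @export
limiting_step <- function(times) {
  stopifnot(inherits(times, "characteristic_times"))
  taus <- c(EG = times$tau_EG, CBH = times$tau_CBH, BGL = times$tau_BGL)
  mx <- max(taus)
  winners <- names(taus)[taus == mx]
  lim <- if (length(winners) > 1) "tie" else winners
  margins <- mx / taus
  list(limiting = lim, taus = taus, margins = margins)
}

#' Roots of the EG-regime quadratic
#'
#' Validity of "CBH cleavage slower than EG" in the most constrained
#' inhibition case reduces to `P(N) > 0` with
#' `P(N) = 6 N^2 - N (12 + 2 K_R) - 3 K_R`, `K_R = K_EG / K_CBHD`
#' (`variant = "printed"`). Independent re-derivation of the same inequality
#' gives `P(N) = 6 N^2 - N (12 + 2/K_R) - 3/K_R` (`variant = "derived"`,
#' i.e. the printed polynomial with K_R inverted); the two agree at K_R = 1
#' but have opposite large-K_R limits - both are provided and the
#' discrepancy is surfaced by [regime_report()]. The discriminant is
#' positive for all K_R > 0, and the root product is negative, so the roots
#' always straddle zero.
#'
#' @param K_R rate ratio `K_EG / K_CBHD` (> 0).
#' @param variant `"printed"` (default) or `"derived"`.
#' @return list(`N1`, `N2` (exact, N1 >= N2), `printed` = roots truncated
#'   toward zero to 2 decimals - the reporting convention of the reference
#'   values - `K_R`, `variant`).
#' @export
eg_regime_roots <- function(K_R, variant = c("printed", "derived")) {
  variant <- match.arg(variant)
  if (!is.finite(K_R) || K_R <= 0) stopf("K_R must be > 0")
  k <- if (variant == "printed") K_R else 1 / K_R
  b <- 12 + 2 * k
  disc <- b^2 + 72 * k
  N1 <- (b + sqrt(disc)) / 12
  N2 <- (b - sqrt(disc)) / 12
  list(N1 = N1, N2 = N2,
       printed = c(N1 = trunc_toward_zero(N1), N2 = trunc_toward_zero(N2)),
       K_R = K_R, variant = variant)
}

#' EG-regime validity at a given chain size
#'
#' TRUE iff `P(N) > 0`, i.e. N exceeds the larger root N1 (the smaller root
#' is negative, so for physical N >= 3 only N1 matters).
#'
#' @inheritParams eg_regime_roots
#' @param N half-DP (>= 3 for the physical regime; smaller N allowed for
#'   root comparison).
#' @return logical.
#' @export
eg_validity <- function(K_R, N, variant = c("printed", "derived")) {
  roots <- eg_regime_roots(K_R, variant)
  N > roots$N1
}

#' BGL-regime validity rule
#'
#' "CBH cleavage slower than BGL" in the most constrained case requires
#' `N > 3 / (3 K_R' - 2)` with `K_R' = K_BGL / K_CBHD`. Three cases:
#' K_R' < 2/3 - valid for all N >= 3 (negative threshold); K_R' = 2/3 -
#' invalid for all N (threshold diverges); K_R' > 2/3 - valid iff N exceeds
#' the threshold.
#'
#' @param K_R_prime rate ratio `K_BGL / K_CBHD` (> 0).
#' @return list(`case` in all_N_ge_3/none/threshold, `N_threshold`
#'   (NA unless case == "threshold"), `K_R_prime`).
#' @export
bgl_threshold <- function(K_R_prime) {
  if (!is.finite(K_R_prime) || K_R_prime <= 0) stopf("K_R_prime must be > 0")
  d <- 3 * K_R_prime - 2
  if (d < 0) list(case = "all_N_ge_3", N_threshold = NA_real_, K_R_prime = K_R_prime)
  else if (d == 0) list(case = "none", N_threshold = Inf, K_R_prime = K_R_prime)
  else list(case = "threshold", N_threshold = 3 / d, K_R_prime = K_R_prime)
}

#' @rdname bgl_threshold
#' @param N half-DP (>= 3).
#' @return `bgl_validity`: logical, whether CBH dominates BGL at this N.
#' @export
bgl_validity <- function(K_R_prime, N) {
  rule <- bgl_threshold(K_R_prime)
  switch(rule$case,
         all_N_ge_3 = N >= 3,
         none = FALSE,
         threshold = N > rule$N_threshold)
}

#' Sensitivity of the CBH attachment time to its parameters
#'
#' `tau_CBHA = 1 / (4 n_CBH K_CBHA)` depends symmetrically on the CBH count
#' and attachment rate, but their typical ranges differ by an order of
#' magnitude. For each parameter this reports the maximum over its range of
#' the relative change of tau_CBHA per unit parameter change,
#' `|d tau / d p| / tau` (computed by central finite differences on a dense
#' grid; analytically 1/p, maximised at the range minimum). A unit deviation
#' in n_CBH0 over \[10, 100\] changes tau_CBHA by up to 10%; the same
#' deviation in K_CBHA over \[100, 1000\] by at most 1%.
#'
#' @param ranges named list of c(low, high) ranges; default the stated
#'   n_CBH0 and K_CBHA ranges.
#' @param n_grid grid resolution per range.
#' @return data.frame: `parameter`, `low`, `high`, `max_rel_change_pct`,
#'   `at_value`.
#' @export
tau_sensitivity_report <- function(ranges = list(n_CBH0 = c(10, 100),
                                                 K_CBHA = c(100, 1000)),
                                   n_grid = 1001) {
  tau <- function(n, K) 1 / (4 * n * K)
  rows <- lapply(names(ranges), function(nm) {
    rg <- ranges[[nm]]
    xs <- seq(rg[1], rg[2], length.out = n_grid)
    h <- 1e-6 * rg[1]
    rel <- vapply(xs, function(x) {
      f <- function(v) if (nm == "n_CBH0") tau(v, 500) else tau(30, v)
      abs((f(x + h) - f(x - h)) / (2 * h)) / f(x)
    }, numeric(1))
    i <- which.max(rel)
    data.frame(parameter = nm, low = rg[1], high = rg[2],
               max_rel_change_pct = 100 * rel[i], at_value = xs[i])
  })
  do.call(rbind, rows)
}

#' Full analytic regime report
#'
#' Characteristic times, rate ratios, quadratic roots (both polynomial
#' variants), regime validity classification and the limiting enzyme for a
#' parameter set at chain half-length N. Serialisable to JSON for the
#' `analytic` CLI subcommand.
#'
#' @param params a [parameter_set()].
#' @param N half-DP (>= 3).
#' @param n_glc free-glucose inhibition state (default 0).
#' @return nested list; note `roots_printed_variant` and
#'   `roots_derived_variant` disagree away from K_R = 1 (documented
#'   internal inconsistency of the source algebra).
#' @export
regime_report <- function(params, N = 50, n_glc = 0) {
  ct <- characteristic_times(N, params$K_EG, params$K_CBHA, params$K_CBHD,
                             params$K_BGL, params$n_EG0, params$n_CBH0,
                             params$n_BGL0, X = params$X_cellulose,
                             r = params$r_cellulose, n_glc = n_glc,
                             omega_EG_glc = params$omega_EG_glc,
                             omega_CBH_glc = params$omega_CBH_glc,
                             omega_BGL_glc = params$omega_BGL_glc)
  K_R <- params$K_EG / params$K_CBHD
  K_Rp <- params$K_BGL / params$K_CBHD
  rp <- eg_regime_roots(K_R, "printed")
  rd <- eg_regime_roots(K_R, "derived")
  ls <- limiting_step(ct)
  list(N = N, taus = ls$taus, tau_CBHA = ct$tau_CBHA, tau_CBHD = ct$tau_CBHD,
       limiting_enzyme = ls$limiting, margins = as.list(ls$margins),
       K_R = K_R, K_R_prime = K_Rp,
       roots_printed_variant = rp[c("N1", "N2", "printed")],
       roots_derived_variant = rd[c("N1", "N2", "printed")],
       eg_valid_printed = eg_validity(K_R, N, "printed"),
       eg_valid_derived = eg_validity(K_R, N, "derived"),
       bgl_rule = bgl_threshold(K_Rp),
       bgl_valid = bgl_validity(K_Rp, N))
}
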