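# Enzyme cocktail kinetics: the 19-parameter registry, effective enzymes
# under end-product inhibition, lignin sequestration, and the reference
# (pure-R) channel enumeration used to cross-check the compiled engine.

#' The 19-parameter sensitivity registry
#'
#' Five reaction rates, four initial enzyme counts, two crystallinity
#' fractions, two digestibility ratios, the lignin adhesion rate, and five
#' inhibition binding affinities (glucose on EG/CBH/BGL, cellobiose on EG/CBH;
#' cellobiose inhibition of BGL is excluded since cellobiose is BGL's
#' substrate).
#'
#' @return character vector of the 19 parameter names.
#' @export
param_registry <- function() {
  c("K_EG", "K_CBHA", "K_CBHD", "K_BGL", "K_XYL",
    "n_EG0", "n_CBH0", "n_BGL0", "n_XYL0",
    "X_cellulose", "X_hemicellulose", "r_cellulose", "r_hemicellulose",
    "L_adh",
    "omega_EG_glc", "omega_CBH_glc", "omega_BGL_glc",
    "omega_EG_cbs", "omega_CBH_cbs")
}

#' Default parameter set
#'
#' Mid-range values inside the stated bounds, used as the reference-curve
#' generator for the desk-scale campaigns: processive CBH rate 45/h (the
#' best-fit region of the test-sample scan), attachment and diffusive rates
#' 300/h, 30 enzymes of each species, cellulose crystallinity 0.45 with
#' digestibility ratio 5e-3, strong glucose-CBH inhibition.
#'
#' @return named list of the 19 parameters.
#' @export
default_parameters <- function() {
  list(K_EG = 300, K_CBHA = 300, K_CBHD = 45, K_BGL = 300, K_XYL = 300,
       n_EG0 = 30, n_CBH0 = 30, n_BGL0 = 30, n_XYL0 = 30,
       X_cellulose = 0.45, X_hemicellulose = 0.30,
       r_cellulose = 0.005, r_hemicellulose = 0.005,
       L_adh = 10,
       omega_EG_glc = 0.5, omega_CBH_glc = 0.8, omega_BGL_glc = 0.5,
       omega_EG_cbs = 0.2, omega_CBH_cbs = 0.2)
}

#' Construct and validate a parameter set
#'
#' Starts from [default_parameters()] and overrides named entries. Rates and
#' counts must be >= 0, crystallinity fractions in \[0,1\], digestibility
#' ratios in (0,1\], inhibition affinities in \[0,1\]; the registry holds
#' exactly 19 uniquely named scalars. `L_adh = 0` disables lignin adsorption.
#'
#' @param ... named scalar overrides, or a single named list.
#' @return validated named list of the 19 parameters.
#' @export
parameter_set <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) over <- over[[1]]
  if (length(over) == 1 && !is.null(names(over)) && names(over)[1] == "" && is.list(over[[1]]))
    over <- over[[1]]
  p <- default_parameters()
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stopf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  validate_parameters(p)
  p
}

#' @rdname parameter_set
#' @param params named list to validate.
#' @export
validate_parameters <- function(params) {
  reg <- param_registry()
  if (!setequal(names(params), reg) || length(params) != 19L || anyDuplicated(names(params)))
    stopf("parameter set must contain exactly the 19 registry parameters")
  num <- vapply(params, function(v) is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))
  if (!all(num)) stopf("all parameters must be finite scalars")
  for (nm in c("K_EG", "K_CBHA", "K_CBHD", "K_BGL", "K_XYL",
               "n_EG0", "n_CBH0", "n_BGL0", "n_XYL0", "L_adh"))
    if (params[[nm]] < 0) stopf("%s must be >= 0", nm)
  for (nm in c("X_cellulose", "X_hemicellulose"))
    if (params[[nm]] < 0 || params[[nm]] > 1) stopf("%s must be in [0,1]", nm)
  for (nm in c("r_cellulose", "r_hemicellulose"))
    if (params[[nm]] <= 0 || params[[nm]] > 1) stopf("%s must be in (0,1]", nm)
  for (nm in grep("^omega_", reg, value = TRUE))
    if (params[[nm]] < 0 || params[[nm]] > 1) stopf("%s must be in [0,1]", nm)
  invisible(params)
}

#' Sampling bounds for the sensitivity parameters
#'
#' The packaged bounds table: enzyme kinetic rates and counts on a log10
#' scale over their stated typical ranges (K_CBHD in \[10,100\], K_EG, K_BGL,
#' K_CBHA, K_XYL in \[100,1000\], enzyme counts in \[10,100\], digestibility
#' ratios in \[1e-3,1e-2\]); crystallinity fractions and inhibition
#' affinities uniform on \[0,1\]; lignin adhesion rate in \[1,100\].
#'
#' @return data.frame with columns `parameter`, `low`, `high`, `scale`.
#' @export
parameter_bounds <- function() {
  path <- system.file("extdata", "parameter_bounds.csv", package = "saccharify")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Enzyme pool
#'
#' Per-species availability bookkeeping: initial counts `n0`, the
#' inhibition-reduced effective counts `n_effective` (possibly fractional),
#' and the lignin-sequestered counts `n_lignin_bound`.
#'
#' @param params a parameter set.
#' @return an `enzyme_pool` list.
#' @export
enzyme_pool <- function(params) {
  species <- c("EG", "CBH", "BGL", "XYL")
  n0 <- c(params$n_EG0, params$n_CBH0, params$n_BGL0, params$n_XYL0)
  structure(list(species = species, n0 = stats::setNames(n0, species),
                 n_effective = stats::setNames(n0, species),
                 n_lignin_bound = stats::setNames(rep(0, 4), species)),
            class = "enzyme_pool")
}

#' Effective enzyme numbers under end-product inhibition
#'
#' Free glucose and cellobiose bind cellulase catalytic sites and reduce the
#' effective enzyme numbers:
#' `n_y = n_y0 * (1 - sum_x omega_y^x * n_x / (sum_y n_y0 + n_x))`,
#' where x ranges over glucose and cellobiose, y over the cellulases
#' (EG, CBH, BGL; xylanase is not inhibited) and `sum_y n_y0` is the total
#' initial cellulase count. Clamped below at zero; recomputed whenever the
#' free-sugar pools change.
#'
#' @param pool an [enzyme_pool()].
#' @param free_glucose,free_cellobiose inhibitor molecule counts (>= 0).
#' @param params a parameter set (the omegas and initial counts).
#' @return the pool with `n_effective` updated.
#' @export
effective_enzymes <- function(pool, free_glucose, free_cellobiose, params) {
  stopifnot(free_glucose >= 0, free_cellobiose >= 0)
  S <- params$n_EG0 + params$n_CBH0 + params$n_BGL0
  term <- function(om_g, om_c) {
    tg <- if (free_glucose > 0) om_g * free_glucose / (S + free_glucose) else 0
    tc <- if (free_cellobiose > 0) om_c * free_cellobiose / (S + free_cellobiose) else 0
    tg + tc
  }
  f <- c(EG = 1 - term(params$omega_EG_glc, params$omega_EG_cbs),
         CBH = 1 - term(params$omega_CBH_glc, params$omega_CBH_cbs),
         BGL = 1 - term(params$omega_BGL_glc, 0),
         XYL = 1)
  ne <- pool$n0 * pmax(f, 0)
  ne[ne < 0] <- 0
  pool$n_effective <- stats::setNames(as.numeric(ne), pool$species)
  pool
}

#' Non-productive enzyme adsorption on lignin
#'
#' Exposed monolignols sequester enzymes statically: `L_adh` monolignols bind
#' one enzyme, so at most `floor(exposed_monolignols / L_adh)` enzymes are
#' sequestered in total, allocated in fixed species order EG, CBH, BGL, XYL
#' and clamped by each species' availability. `L_adh = 0` disables
#' adsorption. Sequestered enzymes return only if the shielding lignin is
#' consumed (never, in the current cocktail, which has no ligninase).
#'
#' @param pool an [enzyme_pool()] (after [effective_enzymes()]).
#' @param state a `microfibril` (supplies the exposed monolignol count).
#' @param params a parameter set.
#' @return the pool with `n_lignin_bound` filled in.
#' @export
lignin_adsorb <- function(pool, state, params) {
  exposed <- if (inherits(state, "microfibril")) state$n_monolignols else as.numeric(state)
  cap <- if (params$L_adh > 0) floor(exposed / params$L_adh) else 0
  bound <- stats::setNames(rep(0, 4), pool$species)
  for (sp in pool$species) {
    take <- min(pool$n_effective[[sp]] - bound[[sp]], cap)
    take <- max(take, 0)
    bound[[sp]] <- take
    cap <- cap - take
  }
  pool$n_lignin_bound <- bound
  pool
}

# availability after inhibition + sequestration
pool_available <- function(pool) {
  v <- pool$n_effective - pool$n_lignin_bound
  v[v < 0] <- 0
  v
}

#' Enumerate event channels (reference implementation)
#'
#' Builds the explicit channel list for the current state in stable order
#' (chain id, bond index, kind): EG channels for every exposed, intact,
#' non-terminal cellulose bond (the two outermost bonds at each fragment end
#' are excluded); CBH attachment channels for every exposed, unoccupied
#' fragment end (fragments of >= 2 monomers); CBH cleavage channels for every
#' attached CBH (rate scaled by r if the bond being hydrolysed is
#' crystalline); one BGL channel per free cellobiose; XYL channels for every
#' exposed hemicellulose bond. Crystalline digestion channels carry the
#' factor r relative to their amorphous counterparts.
#'
#' This pure-R path is the oracle against which the compiled engine's
#' propensities are checked; [ssa_run()] uses the compiled engine.
#'
#' @param state a `microfibril`.
#' @param pool an [enzyme_pool()], already passed through
#'   [effective_enzymes()] and [lignin_adsorb()] (see [prepare_pool()]).
#' @param params a parameter set.
#' @return data.frame with columns `kind`, `chain`, `target`, `propensity`;
#'   zero rows signal an absorbing state.
#' @export
enumerate_channels <- function(state, pool, params) {
  state <- expose_update(state)
  avail <- pool_available(pool)
  frags <- chain_fragments(state)
  kind <- character(0); chain <- integer(0); target <- integer(0); prop <- numeric(0)

  occupied <- rep(FALSE, length(state$present))
  if (nrow(state$attachments)) occupied[state$attachments$head] <- TRUE
  n_free_cbh <- max(0, avail[["CBH"]] - nrow(state$attachments))

  for (i in seq_len(nrow(frags))) {
    c <- frags$chain[i]; a <- frags$start_m[i]; b <- frags$end_m[i]
    ck <- state$kind_id[c]
    s <- state$chains$mono_start[c]; b0 <- state$chains$bond_start[c]
    if (ck == 1L) {
      if (b - a + 1L >= 2L) {
        for (endm in c(a, b)) {
          dir <- if (endm == a) 1L else -1L
          if (state$mono_exposed[endm] && !occupied[endm]) {
            kind <- c(kind, "CBH_attach"); chain <- c(chain, c)
            target <- c(target, endm * dir)
            prop <- c(prop, params$K_CBHA * n_free_cbh)
          }
        }
      }
      if (a + 2L <= b - 3L) for (m in seq.int(a + 2L, b - 3L, by = 1L)) {
        j <- b0 + (m - s)
        if (state$bond_exposed[j]) {
          kind <- c(kind, "EG_cut"); chain <- c(chain, c); target <- c(target, j)
          prop <- c(prop, params$K_EG * avail[["EG"]] *
                      (if (state$bond_crystalline[j]) params$r_cellulose else 1))
        }
      }
    } else if (ck == 2L && b > a) {
      for (m in a:(b - 1L)) {
        j <- b0 + (m - s)
        if (state$bond_exposed[j]) {
          kind <- c(kind, "XYL_cut"); chain <- c(chain, c); target <- c(target, j)
          prop <- c(prop, params$K_XYL * avail[["XYL"]] *
                      (if (state$bond_crystalline[j]) params$r_hemicellulose else 1))
        }
      }
    }
  }

  if (nrow(state$attachments)) {
    for (k in seq_len(nrow(state$attachments))) {
      h <- state$attachments$head[k]; d <- state$attachments$dir[k]
      c <- chain_of_monomer(state, h)
      ext <- fragment_extent(state, c, h)
      len <- ext$len
      s <- state$chains$mono_start[c]; b0 <- state$chains$bond_start[c]
      jb <- if (len == 2) b0 + ((if (d > 0) h else h - 1L) - s)
            else b0 + ((if (d > 0) h + 1L else h - 2L) - s)
      kind <- c(kind, "CBH_cleave"); chain <- c(chain, c); target <- c(target, k)
      prop <- c(prop, params$K_CBHD *
                  (if (state$bond_crystalline[jb]) params$r_cellulose else 1))
    }
  }

  if (state$free_cellobiose > 0) {
    n <- state$free_cellobiose
    kind <- c(kind, rep("BGL_split", n)); chain <- c(chain, rep(NA_integer_, n))
    target <- c(target, seq_len(n))
    prop <- c(prop, rep(params$K_BGL * avail[["BGL"]], n))
  }

  data.frame(kind = kind, chain = chain, target = target, propensity = prop)
}

chain_of_monomer <- function(state, m) {
  findInterval(m, state$chains$mono_start)
}

# fragment containing monomer m on chain c: walk both ways along intact bonds
fragment_extent <- function(state, c, m) {
  s <- state$chains$mono_start[c]; dp <- state$chains$dp[c]
  b0 <- state$chains$bond_start[c]
  connected <- function(mm) { # mm and mm+1
    mm >= s && mm + 1L < s + dp + 1L && mm + 1L <= s + dp - 1L &&
      state$present[mm] && state$present[mm + 1L] && state$bond_intact[b0 + (mm - s)]
  }
  a <- m; while (a > s && connected(a - 1L)) a <- a - 1L
  b <- m; while (b < s + dp - 1L && connected(b)) b <- b + 1L
  list(start_m = a, end_m = b, len = b - a + 1L)
}

#' Convenience: inhibition + lignin adsorption in one call
#'
#' @inheritParams enumerate_channels
#' @return a ready-to-use [enzyme_pool()].
#' @export
prepare_pool <- function(state, params) {
  pool <- enzyme_pool(params)
  pool <- effective_enzymes(pool, state$free_glucose, state$free_cellobiose, params)
  lignin_adsorb(pool, state, params)
}

#' Total propensity of a channel list
#'
#' Sum of per-channel propensities; grouping by enzyme species reproduces
#' `p_y = K_y n_y N_y` with `N_y` the (crystallinity-weighted) channel count.
#'
#' @param channels data.frame from [enumerate_channels()].
#' @return non-negative rate (events per hour).
#' @export
total_propensity <- function(channels) {
  if (is.null(channels) || nrow(channels) == 0) return(0)
  sum(channels$propensity)
}
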