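# Coarse-grained microfibril substrate: cellulose core chains in concentric
# rings, an optional hemicellulose sheath, an outer lignin layer. Resolved at
# monomer level (glucose / xylose / monolignol); bonds carry an
# amorphous/crystalline label and a cleaved flag.

#' Microfibril structure configuration
#'
#' Geometry of the simulated microfibril. Cellulose chains sit in concentric
#' rings (innermost first); hemicellulose chains form the next layer out and
#' lignin chains the outermost layer. Exposure follows column shielding: a
#' monomer is covered by the monomer with the same axial index on its covering
#' chain in the next layer; outermost-layer monomers are always exposed.
#'
#' @param cellulose_rings integer vector, number of cellulose chains per ring,
#'   innermost first. Default `c(3, 9)`: a 12-chain desk-scale fibril.
#' @param dp_cellulose degree of polymerisation of each cellulose chain
#'   (glucose monomers per chain, >= 4 so that endoglucanase and
#'   cellobiohydrolase both have at least one site).
#' @param hemicellulose_chains number of hemicellulose (xylan) chains in the
#'   sheath layer (0 = pre-treated substrate with hemicellulose removed).
#' @param dp_hemicellulose xylose monomers per hemicellulose chain.
#' @param lignin_chains number of lignin chains in the outermost layer.
#' @param dp_lignin monolignols per lignin chain.
#' @param pretreated if `TRUE`, hemicellulose and lignin are stripped
#'   (acid-type pre-treatment removes nearly all hemicellulose).
#' @return a `structure_config` list.
#' @export
structure_config <- function(cellulose_rings = c(3, 9), dp_cellulose = 100,
                             hemicellulose_chains = 0, dp_hemicellulose = 50,
                             lignin_chains = 0, dp_lignin = 50,
                             pretreated = FALSE) {
  cellulose_rings <- as.integer(cellulose_rings)
  if (length(cellulose_rings) < 1 || any(cellulose_rings < 1) || sum(cellulose_rings) < 1)
    stopf("at least one cellulose chain is required")
  if (dp_cellulose < 4)
    stopf("dp_cellulose must be >= 4 (EG needs a non-terminal bond, CBH needs ends)")
  if (hemicellulose_chains < 0 || lignin_chains < 0)
    stopf("layer contents must be >= 0")
  if (hemicellulose_chains > 0 && dp_hemicellulose < 2)
    stopf("dp_hemicellulose must be >= 2")
  if (isTRUE(pretreated)) {
    hemicellulose_chains <- 0L
    lignin_chains <- 0L
  }
  structure(list(
    cellulose_rings = cellulose_rings,
    dp_cellulose = as.integer(dp_cellulose),
    hemicellulose_chains = as.integer(hemicellulose_chains),
    dp_hemicellulose = as.integer(dp_hemicellulose),
    lignin_chains = as.integer(lignin_chains),
    dp_lignin = as.integer(dp_lignin)
  ), class = "structure_config")
}

#' Crystallinity specification
#'
#' Requested crystalline-bond fractions and digestibility ratios. The realised
#' crystalline-bond count per polymer type is exactly
#' `round_half_away(X * total bonds of that type)`, distributed per `layout`.
#' Lignin bonds are always amorphous.
#'
#' @param X_cellulose,X_hemicellulose crystallinity fractions in \[0, 1\]
#'   (crystalline bonds / total bonds of that type).
#' @param r_cellulose,r_hemicellulose digestibility ratios in (0, 1\]: the
#'   crystalline-to-amorphous digestion propensity ratio (r = 1: bonds
#'   indistinguishable; typical values 1e-3 to 1e-2).
#' @param layout `"contiguous_blocks"` (one crystalline block per chain,
#'   default, matching the banded crystalline regions of real microfibrils) or
#'   `"random"`.
#' @return a `crystallinity_spec` list.
#' @export
crystallinity_spec <- function(X_cellulose = 0, X_hemicellulose = 0,
                               r_cellulose = 1, r_hemicellulose = 1,
                               layout = c("contiguous_blocks", "random")) {
  layout <- match.arg(layout)
  for (X in c(X_cellulose, X_hemicellulose))
    if (!is.finite(X) || X < 0 || X > 1) stopf("crystallinity fraction X must be in [0,1]")
  for (r in c(r_cellulose, r_hemicellulose))
    if (!is.finite(r) || r <= 0 || r > 1) stopf("digestibility ratio r must be in (0,1]")
  structure(list(X_cellulose = X_cellulose, X_hemicellulose = X_hemicellulose,
                 r_cellulose = r_cellulose, r_hemicellulose = r_hemicellulose,
                 layout = layout),
            class = "crystallinity_spec")
}

#' Build a microfibril state
#'
#' Constructs the layered substrate: all bonds intact and amorphous, free
#' sugar pools empty, no enzymes attached. Deterministic for a fixed
#' `(config, seed)`; layer placement obeys core-hemicellulose-lignin ordering.
#' Use [assign_crystallinity()] afterwards to label crystalline bonds.
#'
#' @param config a [structure_config()].
#' @param seed integer seed (placement is currently deterministic, the seed is
#'   recorded for provenance and future randomised layouts).
#' @return a `microfibril` state object.
#' @export
build_microfibril <- function(config, seed = 1L) {
  stopifnot(inherits(config, "structure_config"))
  kinds <- integer(0); layers <- integer(0); rings <- integer(0); dps <- integer(0)
  layer <- 0L
  layer_sizes <- integer(0)
  for (nring in config$cellulose_rings) {
    kinds <- c(kinds, rep(1L, nring)); layers <- c(layers, rep(layer, nring))
    rings <- c(rings, seq_len(nring) - 1L); dps <- c(dps, rep(config$dp_cellulose, nring))
    layer_sizes <- c(layer_sizes, nring); layer <- layer + 1L
  }
  if (config$hemicellulose_chains > 0) {
    n <- config$hemicellulose_chains
    kinds <- c(kinds, rep(2L, n)); layers <- c(layers, rep(layer, n))
    rings <- c(rings, seq_len(n) - 1L); dps <- c(dps, rep(config$dp_hemicellulose, n))
    layer_sizes <- c(layer_sizes, n); layer <- layer + 1L
  }
  if (config$lignin_chains > 0) {
    n <- config$lignin_chains
    kinds <- c(kinds, rep(3L, n)); layers <- c(layers, rep(layer, n))
    rings <- c(rings, seq_len(n) - 1L); dps <- c(dps, rep(config$dp_lignin, n))
    layer_sizes <- c(layer_sizes, n); layer <- layer + 1L
  }
  n_chain <- length(kinds)
  mono_start <- cumsum(c(1L, dps))[seq_len(n_chain)]
  bond_start <- cumsum(c(1L, pmax(dps - 1L, 0L)))[seq_len(n_chain)]
  n_mono <- sum(dps); n_bond <- sum(pmax(dps - 1L, 0L))

  # cover chain: same ring position scaled into the next (non-empty) layer out
  cover_chain <- rep(NA_integer_, n_chain)
  n_layers <- layer
  for (l in seq_len(n_layers - 1L)) { # layers 0 .. n_layers-2 get covered
    this <- which(layers == l - 1L)
    nxt <- which(layers == l)
    j <- rings[this]
    cover_chain[this] <- nxt[floor(j * length(nxt) / length(this)) + 1L]
  }

  # per-monomer cover index (same axial position on the covering chain)
  cover <- rep(NA_integer_, n_mono)
  bond_m1 <- integer(n_bond); bond_chain <- integer(n_bond)
  for (c in seq_len(n_chain)) {
    idx <- mono_start[c]:(mono_start[c] + dps[c] - 1L)
    cc <- cover_chain[c]
    if (!is.na(cc)) {
      ax <- seq_len(dps[c])
      ok <- ax <= dps[cc]
      cover[idx[ok]] <- mono_start[cc] + ax[ok] - 1L
    }
    if (dps[c] > 1) {
      bidx <- bond_start[c]:(bond_start[c] + dps[c] - 2L)
      bond_m1[bidx] <- idx[-length(idx)]
      bond_chain[bidx] <- c
    }
  }

  chains <- data.frame(
    id = seq_len(n_chain),
    kind = c("cellulose", "hemicellulose", "lignin")[kinds],
    layer = layers, ring_pos = rings, axial_offset = 0L,
    cover_chain = cover_chain, dp = dps,
    mono_start = mono_start, bond_start = bond_start
  )
  state <- structure(list(
    chains = chains,
    kind_id = kinds,
    present = rep(TRUE, n_mono),
    cover = cover,
    bond_intact = rep(TRUE, n_bond),
    bond_crystalline = rep(FALSE, n_bond),
    bond_m1 = bond_m1,
    bond_chain = bond_chain,
    free_glucose = 0, free_cellobiose = 0, free_xylose = 0,
    attachments = data.frame(head = integer(0), dir = integer(0)),
    init_cellulose = sum(dps[kinds == 1L]),
    init_hemicellulose = sum(dps[kinds == 2L]),
    n_monolignols = sum(dps[kinds == 3L]),
    crystallinity = crystallinity_spec(),
    config = config, seed = as.integer(seed)
  ), class = "microfibril")
  expose_update(state)
}

#' @export
print.microfibril <- function(x, ...) {
  k <- table(x$chains$kind)
  cat("<microfibril> ", nrow(x$chains), " chains (",
      paste(names(k), as.integer(k), sep = ":", collapse = ", "), ")\n", sep = "")
  cat("  glucose equivalents:", x$init_cellulose,
      " xylose:", x$init_hemicellulose, " monolignols:", x$n_monolignols, "\n")
  cat("  bonds intact:", sum(x$bond_intact), "/", length(x$bond_intact),
      " crystalline:", sum(x$bond_crystalline), "\n")
  cat("  pools: glc", x$free_glucose, " cbs", x$free_cellobiose,
      " xyl", x$free_xylose, "  CBH attached:", nrow(x$attachments), "\n")
  invisible(x)
}

#' Assign crystalline labels to bonds
#'
#' Labels exactly `round_half_away(X * n_bonds)` bonds of each polymer type
#' (cellulose, hemicellulose) crystalline; the pooled count is split across
#' chains by cumulative rounding and placed as one contiguous block per chain
#' (`layout = "contiguous_blocks"`) or uniformly at random (`"random"`).
#' Must be called on a freshly built state (no cleaved bonds); cleaving never
#' changes crystallinity labels afterwards.
#'
#' @param state a `microfibril` from [build_microfibril()].
#' @param spec a [crystallinity_spec()].
#' @param seed integer seed (block positions / random draws), or `NULL` to
#'   consume the current RNG stream.
#' @return the state with `bond_crystalline` set and the spec recorded.
#' @export
assign_crystallinity <- function(state, spec, seed = NULL) {
  stopifnot(inherits(state, "microfibril"), inherits(spec, "crystallinity_spec"))
  if (!all(state$bond_intact)) stopf("assign_crystallinity requires a freshly built state")
  with_seed(seed, {
    cry <- rep(FALSE, length(state$bond_intact))
    for (kid in c(1L, 2L)) {
      X <- if (kid == 1L) spec$X_cellulose else spec$X_hemicellulose
      cidx <- which(state$kind_id == kid & state$chains$dp > 1)
      if (length(cidx) == 0 || X == 0) next
      nb <- state$chains$dp[cidx] - 1L
      total <- sum(nb)
      k <- round_half_away(X * total)
      if (k == 0) next
      if (spec$layout == "random") {
        pool <- unlist(lapply(cidx, function(c)
          state$chains$bond_start[c]:(state$chains$bond_start[c] + state$chains$dp[c] - 2L)))
        cry[sample(pool, k)] <- TRUE
      } else {
        alloc <- diff(c(0, round(cumsum(nb) * k / total)))
        # fix any overflow from cumulative rounding
        over <- alloc - nb
        if (any(over > 0)) {
          excess <- sum(pmax(over, 0)); alloc <- pmin(alloc, nb)
          room <- nb - alloc
          for (i in seq_along(alloc)) {
            take <- min(room[i], excess)
            alloc[i] <- alloc[i] + take; excess <- excess - take
            if (excess == 0) break
          }
        }
        for (i in seq_along(cidx)) {
          a <- alloc[i]
          if (a == 0) next
          b0 <- state$chains$bond_start[cidx[i]]
          start <- sample.int(nb[i] - a + 1L, 1L)
          cry[b0 + start - 1L + seq_len(a) - 1L] <- TRUE
        }
      }
    }
    state$bond_crystalline <- cry
    state$crystallinity <- spec
    state
  })
}

monomer_exposed <- function(state) {
  is.na(state$cover) | !state$present[ifelse(is.na(state$cover), 1L, state$cover)]
}

#' Recompute the exposure bookkeeping
#'
#' A bond is exposed iff the covering monomers of both its endpoints (same
#' axial index, next layer out) have been removed; outermost-layer material is
#' always exposed. Exposure is monotone: once a covering monomer is gone it
#' never returns. Called automatically by accessors; exported for the
#' incremental-update contract after an applied event.
#'
#' @param state a `microfibril`.
#' @return the state with `$mono_exposed` and `$bond_exposed` caches refreshed.
#' @export
expose_update <- function(state) {
  me <- monomer_exposed(state)
  state$mono_exposed <- me
  state$bond_exposed <- me[state$bond_m1] & me[state$bond_m1 + 1L]
  state
}

#' Currently attackable bonds
#'
#' @param state a `microfibril`.
#' @return data.frame of exposed, intact bonds with both monomers present:
#'   columns `bond`, `chain`, `kind`, `crystalline`.
#' @export
exposed_bonds <- function(state) {
  state <- expose_update(state)
  ok <- state$bond_intact & state$bond_exposed &
    state$present[state$bond_m1] & state$present[state$bond_m1 + 1L]
  idx <- which(ok)
  data.frame(bond = idx, chain = state$bond_chain[idx],
             kind = state$chains$kind[state$bond_chain[idx]],
             crystalline = state$bond_crystalline[idx])
}

# Maximal runs of present monomers connected by intact bonds, per digestible
# chain. Returns data.frame(chain, start_m, end_m, len) in stable order.
chain_fragments <- function(state) {
  out_chain <- integer(0); out_a <- integer(0); out_b <- integer(0)
  for (c in seq_len(nrow(state$chains))) {
    if (state$kind_id[c] == 3L) next
    s <- state$chains$mono_start[c]; dp <- state$chains$dp[c]
    b0 <- state$chains$bond_start[c]
    pres <- state$present[s:(s + dp - 1L)]
    conn <- if (dp > 1) state$bond_intact[b0:(b0 + dp - 2L)] &
      pres[-dp] & pres[-1] else logical(0)
    m <- 1L
    while (m <= dp) {
      if (!pres[m]) { m <- m + 1L; next }
      a <- m
      while (m < dp && conn[m]) m <- m + 1L
      out_chain <- c(out_chain, c); out_a <- c(out_a, s + a - 1L); out_b <- c(out_b, s + m - 1L)
      m <- m + 1L
    }
  }
  data.frame(chain = out_chain, start_m = out_a, end_m = out_b, len = out_b - out_a + 1L)
}

#' Glucose / xylose equivalent bookkeeping
#'
#' Conservation diagnostics: monomers still in chains plus the free pools must
#' equal the initial totals at every step of a trajectory.
#'
#' @param state a `microfibril`.
#' @return list with per-type tallies and logical `conserved`.
#' @export
mass_balance <- function(state) {
  cel <- sum(state$present[unlist(mapply(function(s, d) s:(s + d - 1L),
    state$chains$mono_start[state$kind_id == 1L], state$chains$dp[state$kind_id == 1L],
    SIMPLIFY = FALSE))])
  hem_idx <- which(state$kind_id == 2L)
  hem <- if (length(hem_idx)) sum(state$present[unlist(mapply(function(s, d) s:(s + d - 1L),
    state$chains$mono_start[hem_idx], state$chains$dp[hem_idx], SIMPLIFY = FALSE))]) else 0L
  list(
    cellulose_in_chains = cel, hemicellulose_in_chains = hem,
    glucose_equivalents = cel + 2 * state$free_cellobiose + state$free_glucose,
    xylose_equivalents = hem + state$free_xylose,
    conserved = (cel + 2 * state$free_cellobiose + state$free_glucose == state$init_cellulose) &&
      (hem + state$free_xylose == state$init_hemicellulose)
  )
}

#' Export a state snapshot to JSON
#'
#' Debug/fixture serialisation of the chain list, bond states and pools.
#'
#' @param state a `microfibril`.
#' @param path file path, or `NULL` to return the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
fibril_to_json <- function(state, path = NULL) {
  obj <- list(
    chains = state$chains,
    present = state$present,
    bond_intact = state$bond_intact,
    bond_crystalline = state$bond_crystalline,
    pools = list(glucose = state$free_glucose, cellobiose = state$free_cellobiose,
                 xylose = state$free_xylose),
    crystallinity = unclass(state$crystallinity),
    config = unclass(state$config), seed = state$seed
  )
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
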