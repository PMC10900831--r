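// Exact stochastic simulation (Gillespie direct method) of enzymatic
// saccharification of a layered microfibril.
//
// State is passed in flattened form from R (see build_microfibril()):
//   - monomers: present flag, covering monomer index (-1 = outermost layer)
//   - bonds: intact flag, crystalline flag, left-monomer index, owning chain
// Chain kinds: 1 = cellulose, 2 = hemicellulose, 3 = lignin.
//
// Event kinds: 1 EG cut, 2 CBH attach, 3 CBH cleave, 4 BGL split, 5 XYL cut.
// Lignin adsorption is a deterministic (static) sequestration recomputed each
// step, not a stochastic channel. Inhibition (effective enzymes) is
// recomputed each step from the free glucose/cellobiose pools.
//
// Per-event target choice uses a single weighted scan over a stable ordering
// (chain id, bond index), so trajectories with matched seeds are invariant to
// the crystallinity layout when r = 1 (all weights equal).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Attachment {
  int head;  // flat monomer index the CBH currently sits on (fragment end)
  int dir;   // +1 eat rightwards, -1 leftwards
};

// [[Rcpp::export(name = ".ssa_engine_cpp")]]
List ssa_engine_cpp(IntegerVector chain_kind,
                    IntegerVector chain_start,   // 0-based first monomer
                    IntegerVector chain_dp,
                    IntegerVector chain_bond_start, // 0-based first bond
                    LogicalVector present_in,
                    IntegerVector cover,         // 0-based, -1 = uncovered
                    LogicalVector intact_in,
                    LogicalVector crystalline,
                    IntegerVector bond_m1,       // 0-based left monomer
                    IntegerVector bond_chain,    // 0-based owning chain
                    List par,
                    double t_max,
                    NumericVector grid,
                    bool freeze = false,
                    bool check_mass = true,
                    double max_events = 5e7) {
  const int n_chain = chain_kind.size();
  const int n_mono = present_in.size();
  const int n_bond = intact_in.size();

  std::vector<char> present(n_mono), intact(n_bond);
  for (int i = 0; i < n_mono; ++i) present[i] = present_in[i];
  for (int i = 0; i < n_bond; ++i) intact[i] = intact_in[i];

  const double K_EG   = as<double>(par["K_EG"]);
  const double K_CBHA = as<double>(par["K_CBHA"]);
  const double K_CBHD = as<double>(par["K_CBHD"]);
  const double K_BGL  = as<double>(par["K_BGL"]);
  const double K_XYL  = as<double>(par["K_XYL"]);
  const double n_EG0  = as<double>(par["n_EG0"]);
  const double n_CBH0 = as<double>(par["n_CBH0"]);
  const double n_BGL0 = as<double>(par["n_BGL0"]);
  const double n_XYL0 = as<double>(par["n_XYL0"]);
  const double r_cel  = as<double>(par["r_cellulose"]);
  const double r_hem  = as<double>(par["r_hemicellulose"]);
  const double L_adh  = as<double>(par["L_adh"]);
  const double om_EG_g  = as<double>(par["omega_EG_glc"]);
  const double om_CBH_g = as<double>(par["omega_CBH_glc"]);
  const double om_BGL_g = as<double>(par["omega_BGL_glc"]);
  const double om_EG_c  = as<double>(par["omega_EG_cbs"]);
  const double om_CBH_c = as<double>(par["omega_CBH_cbs"]);

  // initial pools / totals
  long long init_cel = 0, init_hem = 0, lig_mono = 0;
  for (int c = 0; c < n_chain; ++c) {
    for (int m = chain_start[c]; m < chain_start[c] + chain_dp[c]; ++m) {
      if (!present[m]) continue;
      if (chain_kind[c] == 1) init_cel++;
      else if (chain_kind[c] == 2) init_hem++;
      else lig_mono++;
    }
  }
  long long cel_present = init_cel, hem_present = init_hem;
  long long glc = 0, cbs = 0, xyl = 0;

  std::vector<Attachment> att;
  std::vector<char> occupied(n_mono, 0);

  // scratch: per-step channel lists
  std::vector<int> eg_bonds, xyl_bonds, site_mono, site_dir;
  std::vector<double> att_w;

  auto mono_exposed = [&](int m) -> bool {
    int cm = cover[m];
    return cm < 0 || !present[cm];
  };
  auto bond_exposed = [&](int j) -> bool {
    int m = bond_m1[j];
    return mono_exposed(m) && mono_exposed(m + 1);
  };
  // bond between monomers m and m+1 (same chain) -> global bond index
  auto bond_at = [&](int c, int m) -> int {
    return chain_bond_start[c] + (m - chain_start[c]);
  };
  auto connected = [&](int c, int m) -> bool { // m and m+1 connected?
    if (m < chain_start[c] || m + 1 >= chain_start[c] + chain_dp[c]) return false;
    return present[m] && present[m + 1] && intact[bond_at(c, m)];
  };

  const double sum_n0 = n_EG0 + n_CBH0 + n_BGL0;
  auto inhib_factor = [&](double om_g, double om_c) -> double {
    double term = 0.0;
    if (glc > 0 && sum_n0 + glc > 0) term += om_g * (double)glc / (sum_n0 + glc);
    if (cbs > 0 && sum_n0 + cbs > 0) term += om_c * (double)cbs / (sum_n0 + cbs);
    double f = 1.0 - term;
    return f < 0.0 ? 0.0 : f;
  };

  double p_EG = 0, p_ATT = 0, p_CLV = 0, p_BGL = 0, p_XYL = 0;
  double W_EG = 0, W_XYL = 0;

  auto recompute = [&]() {
    eg_bonds.clear(); xyl_bonds.clear();
    site_mono.clear(); site_dir.clear(); att_w.clear();
    std::fill(occupied.begin(), occupied.end(), 0);
    for (size_t k = 0; k < att.size(); ++k) occupied[att[k].head] = 1;

    W_EG = 0; W_XYL = 0;
    for (int c = 0; c < n_chain; ++c) {
      int kind = chain_kind[c];
      if (kind == 3) continue; // lignin: never digested
      int s = chain_start[c], e = s + chain_dp[c]; // [s, e)
      int m = s;
      while (m < e) {
        if (!present[m]) { ++m; continue; }
        int a = m; // fragment start
        while (m + 1 < e && connected(c, m)) ++m;
        int b = m; // fragment end (inclusive)
        int len = b - a + 1;
        if (kind == 1) {
          if (len >= 2) {
            if (mono_exposed(a) && !occupied[a]) { site_mono.push_back(a); site_dir.push_back(+1); }
            if (mono_exposed(b) && !occupied[b]) { site_mono.push_back(b); site_dir.push_back(-1); }
          }
          // EG: exclude the two outermost bonds at each fragment end
          for (int mm = a + 2; mm <= b - 3; ++mm) {
            int j = bond_at(c, mm);
            if (bond_exposed(j)) {
              eg_bonds.push_back(j);
              W_EG += crystalline[j] ? r_cel : 1.0;
            }
          }
        } else { // hemicellulose: all exposed fragment bonds
          for (int mm = a; mm <= b - 1; ++mm) {
            int j = bond_at(c, mm);
            if (bond_exposed(j)) {
              xyl_bonds.push_back(j);
              W_XYL += crystalline[j] ? r_hem : 1.0;
            }
          }
        }
        ++m;
      }
    }

    // CBH cleave weights: crystallinity of the bond being hydrolysed
    for (size_t k = 0; k < att.size(); ++k) {
      int h = att[k].head, d = att[k].dir;
      int c = -1;
      // find chain by binary search over chain_start
      {
        int lo = 0, hi = n_chain - 1;
        while (lo <= hi) {
          int mid = (lo + hi) / 2;
          if (h < chain_start[mid]) hi = mid - 1;
          else if (h >= chain_start[mid] + chain_dp[mid]) lo = mid + 1;
          else { c = mid; break; }
        }
      }
      int len = 1, mm = h;
      while (connected(c, d > 0 ? mm : mm - 1)) { mm += d; ++len; }
      int jb;
      if (len == 2) jb = bond_at(c, d > 0 ? h : h - 1);           // internal bond
      else          jb = bond_at(c, d > 0 ? h + 1 : h - 2);       // bond ahead
      att_w.push_back(crystalline[jb] ? r_cel : 1.0);
    }

    // effective enzymes (inhibition), then lignin sequestration
    double avail_EG  = n_EG0  * inhib_factor(om_EG_g,  om_EG_c);
    double avail_CBH = n_CBH0 * inhib_factor(om_CBH_g, om_CBH_c);
    double avail_BGL = n_BGL0 * inhib_factor(om_BGL_g, 0.0);
    double avail_XYL = n_XYL0;
    double cap = (L_adh > 0) ? std::floor((double)lig_mono / L_adh) : 0.0;
    double take;
    take = std::min(avail_EG,  cap); avail_EG  -= take; cap -= take;
    take = std::min(avail_CBH, cap); avail_CBH -= take; cap -= take;
    take = std::min(avail_BGL, cap); avail_BGL -= take; cap -= take;
    take = std::min(avail_XYL, cap); avail_XYL -= take; cap -= take;

    double n_free_cbh = avail_CBH - (double)att.size();
    if (n_free_cbh < 0) n_free_cbh = 0;
    double w_clv = 0; for (double w : att_w) w_clv += w;

    p_EG  = K_EG * avail_EG * W_EG;
    p_ATT = K_CBHA * n_free_cbh * (double)site_mono.size();
    p_CLV = K_CBHD * w_clv;
    p_BGL = K_BGL * avail_BGL * (double)cbs;
    p_XYL = K_XYL * avail_XYL * W_XYL;
  };

  // --- run loop ---
  int n_grid = grid.size();
  NumericVector conv(n_grid);
  NumericVector glc_grid(n_grid), cbs_grid(n_grid), xyl_grid(n_grid);
  int gi = 0;
  auto flush_grid = [&](double upto, bool strict) {
    double cv = init_cel > 0 ? 100.0 * (double)glc / (double)init_cel : 0.0;
    while (gi < n_grid && (strict ? grid[gi] < upto : grid[gi] <= upto)) {
      conv[gi] = cv;
      glc_grid[gi] = (double)glc; cbs_grid[gi] = (double)cbs; xyl_grid[gi] = (double)xyl;
      ++gi;
    }
  };

  double t = 0.0;
  long long n_events = 0;
  NumericVector counts(5);        // per kind
  NumericVector p0(5);            // initial propensities (diagnostic)
  bool mass_ok = true;
  bool first = true;

  recompute();
  p0[0] = p_EG; p0[1] = p_ATT; p0[2] = p_CLV; p0[3] = p_BGL; p0[4] = p_XYL;

  while (true) {
    if (n_events >= (long long)max_events) break;
    double P = p_EG + p_ATT + p_CLV + p_BGL + p_XYL;
    if (P <= 0.0) { flush_grid(t_max, false); break; } // absorbing state
    double dt = R::exp_rand() / P;
    double t_new = t + dt;
    if (t_new > t_max) { flush_grid(t_max, false); break; }
    flush_grid(t_new, true); // last-event-carried-forward
    t = t_new;

    double u = unif_rand() * P;
    int kind;
    if      (u < p_EG)                              kind = 1;
    else if (u < p_EG + p_ATT)                      kind = 2;
    else if (u < p_EG + p_ATT + p_CLV)              kind = 3;
    else if (u < p_EG + p_ATT + p_CLV + p_BGL)      kind = 4;
    else                                            kind = 5;
    counts[kind - 1] += 1;
    ++n_events;
    if (n_events % 4096 == 0) Rcpp::checkUserInterrupt();
    if (freeze) { t = t_new; continue; }

    if (kind == 1) { // EG cut
      double v = unif_rand() * W_EG, acc = 0.0;
      int j = eg_bonds.back();
      for (int jb : eg_bonds) {
        acc += crystalline[jb] ? r_cel : 1.0;
        if (v <= acc) { j = jb; break; }
      }
      intact[j] = 0;
    } else if (kind == 2) { // CBH attach
      int i = (int)(unif_rand() * (double)site_mono.size());
      if (i >= (int)site_mono.size()) i = (int)site_mono.size() - 1;
      Attachment a; a.head = site_mono[i]; a.dir = site_dir[i];
      att.push_back(a);
    } else if (kind == 3) { // CBH cleave
      double w_tot = 0; for (double w : att_w) w_tot += w;
      double v = unif_rand() * w_tot, acc = 0.0;
      int k = (int)att.size() - 1;
      for (size_t kk = 0; kk < att_w.size(); ++kk) {
        acc += att_w[kk];
        if (v <= acc) { k = (int)kk; break; }
      }
      int h = att[k].head, d = att[k].dir;
      // chain of h
      int c = bond_chain[0];
      { int lo = 0, hi = n_chain - 1;
        while (lo <= hi) { int mid = (lo + hi) / 2;
          if (h < chain_start[mid]) hi = mid - 1;
          else if (h >= chain_start[mid] + chain_dp[mid]) lo = mid + 1;
          else { c = mid; break; } } }
      int len = 1, mm = h;
      while (connected(c, d > 0 ? mm : mm - 1)) { mm += d; ++len; }
      // release cellobiose: monomers h and h+d
      present[h] = 0; present[h + d] = 0;
      cel_present -= 2; cbs += 1;
      intact[bond_at(c, d > 0 ? h : h - 1)] = 0;
      if (len > 2) intact[bond_at(c, d > 0 ? h + 1 : h - 2)] = 0;
      if (len - 2 <= 0) {
        att.erase(att.begin() + k);
      } else if (len - 2 == 1) { // lone remainder released as glucose
        present[h + 2 * d] = 0; cel_present -= 1; glc += 1;
        att.erase(att.begin() + k);
      } else {
        att[k].head = h + 2 * d;
      }
      // drop attachments whose end monomer vanished (converging CBHs)
      for (int kk = (int)att.size() - 1; kk >= 0; --kk)
        if (!present[att[kk].head]) att.erase(att.begin() + kk);
    } else if (kind == 4) { // BGL split
      cbs -= 1; glc += 2;
    } else { // XYL cut
      double v = unif_rand() * W_XYL, acc = 0.0;
      int j = xyl_bonds.back();
      for (int jb : xyl_bonds) {
        acc += crystalline[jb] ? r_hem : 1.0;
        if (v <= acc) { j = jb; break; }
      }
      intact[j] = 0;
      int c = bond_chain[j];
      int m1 = bond_m1[j];
      for (int m : {m1, m1 + 1}) {
        bool left  = m > chain_start[c] && present[m - 1] && intact[bond_at(c, m - 1)];
        bool right = m + 1 < chain_start[c] + chain_dp[c] && present[m + 1] && intact[bond_at(c, m)];
        if (!left && !right && present[m]) {
          present[m] = 0; hem_present -= 1; xyl += 1;
        }
      }
    }

    if (check_mass) {
      long long cel_n = 0, hem_n = 0;
      for (int c = 0; c < n_chain; ++c) {
        if (chain_kind[c] == 3) continue;
        for (int m = chain_start[c]; m < chain_start[c] + chain_dp[c]; ++m)
          if (present[m]) { if (chain_kind[c] == 1) cel_n++; else hem_n++; }
      }
      if (cel_n != cel_present || hem_n != hem_present ||
          cel_n + 2 * cbs + glc != init_cel || hem_n + xyl != init_hem)
        mass_ok = false;
    }
    recompute();
    (void)first;
  }

  counts.names() = CharacterVector::create("EG_cut", "CBH_attach", "CBH_cleave", "BGL_split", "XYL_cut");
  p0.names() = CharacterVector::create("EG_cut", "CBH_attach", "CBH_cleave", "BGL_split", "XYL_cut");
  LogicalVector present_out(n_mono), intact_out(n_bond);
  for (int i = 0; i < n_mono; ++i) present_out[i] = present[i];
  for (int i = 0; i < n_bond; ++i) intact_out[i] = intact[i];
  return List::create(
    _["time_h"] = grid, _["conversion_pct"] = conv,
    _["free_glucose"] = (double)glc, _["free_cellobiose"] = (double)cbs,
    _["free_xylose"] = (double)xyl,
    _["glucose_grid"] = glc_grid, _["cellobiose_grid"] = cbs_grid,
    _["xylose_grid"] = xyl_grid,
    _["event_counts"] = counts, _["initial_propensity"] = p0,
    _["n_events"] = (double)n_events, _["t_end"] = t,
    _["mass_ok"] = mass_ok,
    _["present"] = present_out, _["intact"] = intact_out,
    _["n_attached"] = (double)att.size());
}
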