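// Discrete-time 1D lattice engine for SMC loop extrusion.
//
// Species codes: 1 condensin_I, 2 condensin_II, 3 cohesin_extrusive,
//                4 cohesin_cohesive (immobile obstacle), 5 ctcf_barrier.
// Outcome codes: 0 bypass, 1 stall, 2 unload_obstacle, 3 push_obstacle,
//                4 unload_self.
//
// All randomness goes through R's RNG so set.seed() on the R side gives
// bit-reproducible trajectories.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

const int OUT_BYPASS = 0;
const int OUT_STALL = 1;
const int OUT_UNLOAD_OBS = 2;
const int OUT_PUSH = 3;
const int OUT_UNLOAD_SELF = 4;

struct Engine {
  int L;
  // extruders
  std::vector<int> sp, l, r;
  std::vector<bool> stall_l, stall_r, alive;
  std::vector<double> transloc;
  // immobile point obstacles (cohesive cohesin)
  std::vector<int> ob_sp, ob_pos;
  std::vector<bool> ob_alive;
  // CTCF barrier sites: blocks_dir = +1 blocks rightward legs, -1 leftward
  std::vector<int> ctcf_pos, ctcf_dir;
  std::vector<bool> ctcf_alive;
  std::vector<int> ctcf_at; // site -> ctcf index or -1
  // occupancy: occ_id >= 0 with occ_kind 0 (extruder) / 1 (obstacle)
  std::vector<int> occ_id, occ_kind;
  // policy[mover-1][obstacle-1], movers 1..3, obstacles 1..4
  int policy[4][5];
  bool push_cohesive;
  // audit: counts[mover-1][obstacle-1][outcome]
  std::vector<int> audit;

  void audit_add(int mov, int obs, int out) {
    audit[((mov - 1) * 5 + (obs - 1)) * 5 + out]++;
  }

  bool partner_shares_site(int e, int site) {
    return l[e] == r[e] && l[e] == site;
  }
  void clear_leg(int e, int site) {
    if (!partner_shares_site(e, site)) {
      occ_id[site] = -1;
      occ_kind[site] = -1;
    }
  }
  void set_leg(int e, int site) {
    occ_id[site] = e;
    occ_kind[site] = 0;
  }
  int occupant_species(int site) {
    if (occ_kind[site] == 0) return sp[occ_id[site]];
    return ob_sp[occ_id[site]];
  }

  void unload_extruder(int e) {
    if (!alive[e]) return;
    int a = l[e], b = r[e];
    occ_id[a] = -1; occ_kind[a] = -1;
    occ_id[b] = -1; occ_kind[b] = -1;
    alive[e] = false;
  }
  void unload_obstacle(int o) {
    if (!ob_alive[o]) return;
    occ_id[ob_pos[o]] = -1;
    occ_kind[ob_pos[o]] = -1;
    ob_alive[o] = false;
  }

  bool ctcf_blocks(int site, int spc, int dir) {
    // Only extrusive cohesin respects CTCF; anchored at the barrier site.
    if (spc != 3) return false;
    int ci = ctcf_at[site];
    return ci >= 0 && ctcf_alive[ci] && ctcf_dir[ci] == dir;
  }

  void move_leg_to(int e, int dir, int from, int to) {
    clear_leg(e, from);
    set_leg(e, to);
    if (dir < 0) l[e] = to; else r[e] = to;
    transloc[e] += std::abs(to - from);
    if (dir < 0) stall_l[e] = false; else stall_r[e] = false;
  }

  void set_stalled(int e, int dir) {
    if (dir < 0) stall_l[e] = true; else stall_r[e] = true;
  }

  // push the contiguous chain of occupants starting at tgt; returns success
  bool try_push(int e, int dir, int tgt) {
    int j = tgt;
    while (j >= 0 && j < L && occ_id[j] != -1) {
      int s2 = occupant_species(j);
      bool pushable = policy[sp[e] - 1][s2 - 1] == OUT_PUSH &&
                      (s2 != 4 || push_cohesive);
      if (!pushable) return false;
      j += dir;
    }
    if (j < 0 || j >= L) return false; // push against chromosome end
    // shift chain far -> near
    for (int k = j - dir; k != tgt - dir; k -= dir) {
      int id = occ_id[k], kind = occ_kind[k];
      occ_id[k + dir] = id; occ_kind[k + dir] = kind;
      occ_id[k] = -1; occ_kind[k] = -1;
      if (kind == 1) {
        ob_pos[id] = k + dir;
      } else {
        if (l[id] == k && r[id] == k) { l[id] = k + dir; r[id] = k + dir; }
        else if (l[id] == k) l[id] = k + dir;
        else r[id] = k + dir;
      }
    }
    return true;
  }

  // one attempted unit move of one leg; returns true if the leg advanced
  bool attempt_move(int e, int dir) {
    int cur = dir < 0 ? l[e] : r[e];
    // anchored at a matching CTCF barrier site
    if (ctcf_blocks(cur, sp[e], dir)) { set_stalled(e, dir); return false; }
    int tgt = cur + dir;
    if (tgt < 0 || tgt >= L) { set_stalled(e, dir); return false; }
    if (occ_id[tgt] == -1) {
      move_leg_to(e, dir, cur, tgt);
      return true;
    }
    int s2 = occupant_species(tgt);
    int out = policy[sp[e] - 1][s2 - 1];
    audit_add(sp[e], s2, out);
    if (out == OUT_STALL) { set_stalled(e, dir); return false; }
    if (out == OUT_UNLOAD_SELF) { unload_extruder(e); return false; }
    if (out == OUT_UNLOAD_OBS) {
      if (occ_kind[tgt] == 0) unload_extruder(occ_id[tgt]);
      else unload_obstacle(occ_id[tgt]);
      move_leg_to(e, dir, cur, tgt);
      return true;
    }
    if (out == OUT_PUSH) {
      bool ok = (s2 != 4 || push_cohesive) && try_push(e, dir, tgt);
      if (!ok) { set_stalled(e, dir); return false; }
      move_leg_to(e, dir, cur, tgt);
      return true;
    }
    // bypass: land past the run of contiguous bypassable occupants
    int j = tgt;
    while (j >= 0 && j < L && occ_id[j] != -1) {
      int s3 = occupant_species(j);
      if (policy[sp[e] - 1][s3 - 1] != OUT_BYPASS) {
        set_stalled(e, dir);
        return false;
      }
      j += dir;
    }
    if (j < 0 || j >= L) { set_stalled(e, dir); return false; }
    move_leg_to(e, dir, cur, j);
    return true;
  }

  double coverage() {
    std::vector<std::pair<int, int> > iv;
    for (size_t e = 0; e < sp.size(); ++e)
      if (alive[e] && r[e] > l[e]) iv.push_back(std::make_pair(l[e], r[e]));
    if (iv.empty()) return 0.0;
    std::sort(iv.begin(), iv.end());
    long covered = 0;
    int cl = iv[0].first, cr = iv[0].second;
    for (size_t i = 1; i < iv.size(); ++i) {
      if (iv[i].first <= cr) cr = std::max(cr, iv[i].second);
      else { covered += cr - cl; cl = iv[i].first; cr = iv[i].second; }
    }
    covered += cr - cl;
    return (double)covered / (double)L;
  }
};

int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

} // namespace

// [[Rcpp::export]]
List engine_run_cpp(int L,
                    IntegerVector ex_species, IntegerVector ex_l,
                    IntegerVector ex_r, LogicalVector ex_stall_l,
                    LogicalVector ex_stall_r, NumericVector ex_transloc,
                    IntegerVector ob_species, IntegerVector ob_pos,
                    IntegerVector ctcf_pos, IntegerVector ctcf_dir,
                    IntegerMatrix policy, NumericVector move_prob,
                    IntegerVector move_sites, NumericVector unload_prob,
                    NumericVector load_prob, double ctcf_loss_prob,
                    bool push_cohesive, bool protect_anchored,
                    int n_steps, int t0,
                    IntegerVector record_at, int stats_every,
                    double coverage_target) {
  Engine en;
  en.L = L;
  en.push_cohesive = push_cohesive;
  en.occ_id.assign(L, -1);
  en.occ_kind.assign(L, -1);
  en.ctcf_at.assign(L, -1);
  en.audit.assign(4 * 5 * 5, 0);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 5; ++j) en.policy[i][j] = policy(i, j);

  int n0 = ex_species.size();
  for (int e = 0; e < n0; ++e) {
    en.sp.push_back(ex_species[e]);
    en.l.push_back(ex_l[e]);
    en.r.push_back(ex_r[e]);
    en.stall_l.push_back(ex_stall_l[e]);
    en.stall_r.push_back(ex_stall_r[e]);
    en.transloc.push_back(ex_transloc[e]);
    en.alive.push_back(true);
    en.set_leg(e, ex_l[e]);
    en.set_leg(e, ex_r[e]);
  }
  for (int o = 0; o < ob_species.size(); ++o) {
    en.ob_sp.push_back(ob_species[o]);
    en.ob_pos.push_back(ob_pos[o]);
    en.ob_alive.push_back(true);
    en.occ_id[ob_pos[o]] = o;
    en.occ_kind[ob_pos[o]] = 1;
  }
  for (int c = 0; c < ctcf_pos.size(); ++c) {
    en.ctcf_pos.push_back(ctcf_pos[c]);
    en.ctcf_dir.push_back(ctcf_dir[c]);
    en.ctcf_alive.push_back(true);
    en.ctcf_at[ctcf_pos[c]] = c;
  }

  List frames;
  std::vector<double> st_time, st_nb, st_cov, st_mean_loop, st_tot_tr,
      st_nob, st_nctcf, st_anch;
  double coverage_time = NA_REAL;
  int rec_i = 0;

  RNGScope scope;

  for (int step = 0; step < n_steps; ++step) {
    int t = t0 + step + 1;
    // ---- movement: all mobile legs in random order -------------------
    std::vector<std::pair<int, int> > legs; // (extruder, dir)
    for (size_t e = 0; e < en.sp.size(); ++e) {
      if (!en.alive[e]) continue;
      int s = en.sp[e];
      if (move_prob[s - 1] <= 0 && move_sites[s - 1] <= 0) continue;
      legs.push_back(std::make_pair((int)e, -1));
      legs.push_back(std::make_pair((int)e, +1));
    }
    for (int i = (int)legs.size() - 1; i > 0; --i)
      std::swap(legs[i], legs[runif_int(i + 1)]);
    for (size_t i = 0; i < legs.size(); ++i) {
      int e = legs[i].first, dir = legs[i].second;
      if (!en.alive[e]) continue;
      int s = en.sp[e];
      int n_moves = move_sites[s - 1];
      if (unif_rand() < move_prob[s - 1]) n_moves += 1;
      for (int m = 0; m < n_moves; ++m) {
        if (!en.alive[e]) break;
        if (!en.attempt_move(e, dir)) break;
      }
    }
    // ---- unloading ---------------------------------------------------
    // CTCF-stabilized cohesin: a loop with both legs anchored at matching
    // barrier sites (a formed dot) is protected from stochastic unloading
    for (size_t e = 0; e < en.sp.size(); ++e) {
      if (!en.alive[e]) continue;
      double u = unload_prob[en.sp[e] - 1];
      if (u <= 0) continue;
      if (protect_anchored && en.sp[e] == 3) {
        int cl = en.ctcf_at[en.l[e]], cr = en.ctcf_at[en.r[e]];
        bool la = cl >= 0 && en.ctcf_alive[cl] && en.ctcf_dir[cl] == -1;
        bool ra = cr >= 0 && en.ctcf_alive[cr] && en.ctcf_dir[cr] == 1;
        if (la && ra) continue;
      }
      if (unif_rand() < u) en.unload_extruder((int)e);
    }
    for (size_t o = 0; o < en.ob_sp.size(); ++o) {
      if (!en.ob_alive[o]) continue;
      double u = unload_prob[en.ob_sp[o] - 1];
      if (u > 0 && unif_rand() < u) en.unload_obstacle((int)o);
    }
    if (ctcf_loss_prob > 0) {
      for (size_t c = 0; c < en.ctcf_pos.size(); ++c) {
        if (en.ctcf_alive[c] && unif_rand() < ctcf_loss_prob) {
          en.ctcf_alive[c] = false;
          en.ctcf_at[en.ctcf_pos[c]] = -1;
        }
      }
    }
    // ---- loading: extruder species with nonzero rate -----------------
    for (int s = 1; s <= 3; ++s) {
      double p = load_prob[s - 1];
      if (p <= 0) continue;
      int k = (int)R::rbinom((double)L, p);
      for (int a = 0; a < k; ++a) {
        int site = runif_int(L);
        if (en.occ_id[site] != -1) continue;
        int e = (int)en.sp.size();
        en.sp.push_back(s);
        en.l.push_back(site);
        en.r.push_back(site);
        en.stall_l.push_back(false);
        en.stall_r.push_back(false);
        en.transloc.push_back(0.0);
        en.alive.push_back(true);
        en.set_leg(e, site);
      }
    }
    // ---- bookkeeping -------------------------------------------------
    bool want_cov = coverage_target > 0 && !R_finite(coverage_time);
    double cov = NA_REAL;
    if (want_cov || (stats_every > 0 && t % stats_every == 0))
      cov = en.coverage();
    if (want_cov && cov >= coverage_target) coverage_time = t;
    if (stats_every > 0 && t % stats_every == 0) {
      int nb = 0, nloop = 0, nanch = 0;
      double mloop = 0, tot = 0;
      for (size_t e = 0; e < en.sp.size(); ++e) {
        if (!en.alive[e]) continue;
        nb++;
        tot += en.transloc[e];
        if (en.r[e] > en.l[e]) { nloop++; mloop += en.r[e] - en.l[e]; }
        bool anch = en.ctcf_at[en.l[e]] >= 0 || en.ctcf_at[en.r[e]] >= 0;
        if (anch) nanch++;
      }
      int nob = 0, nct = 0;
      for (size_t o = 0; o < en.ob_sp.size(); ++o) if (en.ob_alive[o]) nob++;
      for (size_t c = 0; c < en.ctcf_pos.size(); ++c)
        if (en.ctcf_alive[c]) nct++;
      st_time.push_back(t);
      st_nb.push_back(nb);
      st_cov.push_back(cov);
      st_mean_loop.push_back(nloop ? mloop / nloop : NA_REAL);
      st_tot_tr.push_back(tot);
      st_nob.push_back(nob);
      st_nctcf.push_back(nct);
      st_anch.push_back(nanch);
    }
    if (rec_i < record_at.size() && t == record_at[rec_i]) {
      int na = 0;
      for (size_t e = 0; e < en.sp.size(); ++e) if (en.alive[e]) na++;
      IntegerMatrix fx(na, 3);
      LogicalMatrix fs(na, 2);
      NumericVector ftr(na);
      int row = 0;
      for (size_t e = 0; e < en.sp.size(); ++e) {
        if (!en.alive[e]) continue;
        fx(row, 0) = en.sp[e]; fx(row, 1) = en.l[e]; fx(row, 2) = en.r[e];
        fs(row, 0) = en.stall_l[e]; fs(row, 1) = en.stall_r[e];
        ftr[row] = en.transloc[e];
        row++;
      }
      std::vector<int> obp, obs;
      for (size_t o = 0; o < en.ob_sp.size(); ++o)
        if (en.ob_alive[o]) { obp.push_back(en.ob_pos[o]); obs.push_back(en.ob_sp[o]); }
      std::vector<int> ctp, ctd;
      for (size_t c = 0; c < en.ctcf_pos.size(); ++c)
        if (en.ctcf_alive[c]) { ctp.push_back(en.ctcf_pos[c]); ctd.push_back(en.ctcf_dir[c]); }
      frames.push_back(List::create(
          _["time"] = t, _["extruders"] = fx, _["stalled"] = fs,
          _["translocated"] = ftr, _["obstacle_pos"] = wrap(obp),
          _["obstacle_species"] = wrap(obs), _["ctcf_pos"] = wrap(ctp),
          _["ctcf_dir"] = wrap(ctd)));
      rec_i++;
    }
  }

  // final state
  int na = 0;
  for (size_t e = 0; e < en.sp.size(); ++e) if (en.alive[e]) na++;
  IntegerVector fsp(na), fl(na), fr(na);
  LogicalVector fsl(na), fsr(na);
  NumericVector ftr(na);
  int row = 0;
  for (size_t e = 0; e < en.sp.size(); ++e) {
    if (!en.alive[e]) continue;
    fsp[row] = en.sp[e]; fl[row] = en.l[e]; fr[row] = en.r[e];
    fsl[row] = en.stall_l[e]; fsr[row] = en.stall_r[e];
    ftr[row] = en.transloc[e];
    row++;
  }
  std::vector<int> obp, obs;
  for (size_t o = 0; o < en.ob_sp.size(); ++o)
    if (en.ob_alive[o]) { obp.push_back(en.ob_pos[o]); obs.push_back(en.ob_sp[o]); }
  std::vector<int> ctp, ctd;
  for (size_t c = 0; c < en.ctcf_pos.size(); ++c)
    if (en.ctcf_alive[c]) { ctp.push_back(en.ctcf_pos[c]); ctd.push_back(en.ctcf_dir[c]); }

  NumericMatrix stats((int)st_time.size(), 8);
  for (size_t i = 0; i < st_time.size(); ++i) {
    stats(i, 0) = st_time[i]; stats(i, 1) = st_nb[i]; stats(i, 2) = st_cov[i];
    stats(i, 3) = st_mean_loop[i]; stats(i, 4) = st_tot_tr[i];
    stats(i, 5) = st_nob[i]; stats(i, 6) = st_nctcf[i]; stats(i, 7) = st_anch[i];
  }
  colnames(stats) = CharacterVector::create(
      "time", "n_bound", "coverage", "mean_loop_sites", "total_translocated",
      "n_obstacles", "n_ctcf", "n_anchored");

  return List::create(
      _["species"] = fsp, _["l"] = fl, _["r"] = fr, _["stall_l"] = fsl,
      _["stall_r"] = fsr, _["translocated"] = ftr,
      _["obstacle_pos"] = wrap(obp), _["obstacle_species"] = wrap(obs),
      _["ctcf_pos"] = wrap(ctp), _["ctcf_dir"] = wrap(ctd),
      _["time"] = t0 + n_steps, _["frames"] = frames, _["stats"] = stats,
      _["coverage_time"] = coverage_time, _["audit"] = wrap(en.audit));
}
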