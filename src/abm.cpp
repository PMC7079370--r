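// Discrete-time stochastic agent engine for the osteoblast
// mechanotransduction network.
//
// One step = apply_load -> move_agents -> apply_bindings -> fire_timers ->
// record_counts.  All randomness goes through R's RNG (unif_rand/norm_rand)
// so a set.seed() in R makes a run bit-reproducible.  Binding uses a uniform
// cell list of cell size R_inter; a brute-force O(n^2) path is kept behind a
// flag as the correctness oracle for the spatial hash.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Agent {
  int sp;            // species index
  bool act;          // activation state
  int partner;       // index of bound partner agent, -1 if free
  double x, y, z;
  bool is_static;
  bool alive;
  int ttype;         // -1 none, 0 state rule, 1 complex channel
  int tid;           // rule/channel index
  double trem;       // remaining timer, seconds
};

inline double runif01() { return unif_rand(); }

// positive modulo without fmod (keeps the shared object free of
// glibc >= 2.38 symbol versions)
inline double mod_pos(double a, double p) {
  double r = a - std::floor(a / p) * p;
  if (r < 0) r += p;
  if (r >= p) r -= p;
  return r;
}

// uniform point in spherical shell [rmin, rmax]
inline void shell_point(double rmin, double rmax, double &x, double &y,
                        double &z, bool surface) {
  double nx, ny, nz, n2;
  do {
    nx = norm_rand(); ny = norm_rand(); nz = norm_rand();
    n2 = nx * nx + ny * ny + nz * nz;
  } while (n2 < 1e-12);
  double inv = 1.0 / std::sqrt(n2);
  double r;
  if (surface) {
    r = rmax;
  } else {
    double u = runif01();
    r = std::cbrt(rmin * rmin * rmin +
                  u * (rmax * rmax * rmax - rmin * rmin * rmin));
  }
  x = nx * inv * r; y = ny * inv * r; z = nz * inv * r;
}

// radial reflection into [rmin, rmax]
inline void reflect_shell(double rmin, double rmax, double &x, double &y,
                          double &z) {
  double r = std::sqrt(x * x + y * y + z * z);
  if (r < 1e-12) {
    if (rmin > 0) { x = rmin; y = 0; z = 0; }
    return;
  }
  double rn = r;
  for (int it = 0; it < 8; ++it) {
    if (rn > rmax) rn = 2 * rmax - rn;
    else if (rn < rmin) rn = 2 * rmin - rn;
    else break;
  }
  if (rn > rmax) rn = rmax;          // very thin shells: clamp
  if (rn < rmin) rn = rmin;
  double f = rn / r;
  x *= f; y *= f; z *= f;
}

}  // namespace

// [[Rcpp::export(name = ".abm_run_cpp")]]
List abm_run_cpp(List conf) {
  // --- unpack configuration -------------------------------------------------
  const int n_steps = as<int>(conf["n_steps"]);
  const double dt = as<double>(conf["dt"]);
  IntegerVector sp_count = conf["sp_count"];
  IntegerVector sp_init_act = conf["sp_init_active"];
  IntegerVector sp_comp = conf["sp_comp_class"];   // 0 nuc,1 cyt,2 nuc+cyt,3 extra,4 membrane
  IntegerVector sp_static = conf["sp_static"];
  NumericVector sp_rmin = conf["sp_rmin"];
  NumericVector sp_rmax = conf["sp_rmax"];
  CharacterVector sp_names = conf["sp_names"];
  const int S = sp_count.size();

  const double rn_ = as<double>(conf["rn"]);
  const double rc_ = as<double>(conf["rc"]);
  const double rx_ = as<double>(conf["rx"]);
  const double M = as<double>(conf["M"]);
  const double P = as<double>(conf["P"]);
  const double phase = as<double>(conf["phase"]);
  const double m0 = as<double>(conf["m0"]);
  const double k_act = as<double>(conf["k_act"]);
  const double M_ref = as<double>(conf["M_ref"]);
  const double R_inter = as<double>(conf["R_inter"]);
  const double dstep = as<double>(conf["diff_step"]);
  const int receptor_sp = as<int>(conf["receptor_sp"]);
  const bool brute = as<bool>(conf["brute_force"]);
  const bool ret_agents = as<bool>(conf["return_agents"]);

  IntegerMatrix bind = conf["bind"];  // a_sp a_act b_sp b_act complex a_after b_after
  const int NB = bind.nrow();
  IntegerVector ch_rule = conf["ch_rule"];
  NumericVector ch_lo = conf["ch_lo"], ch_hi = conf["ch_hi"];
  IntegerVector ch_aout = conf["ch_aout"], ch_bout = conf["ch_bout"];
  IntegerVector ch_prod = conf["ch_prod"];
  IntegerVector ch_stage = conf["ch_stage"];
  IntegerVector ch_dissoc = conf["ch_dissoc"];
  const int NC = ch_rule.size();
  IntegerVector sr_sp = conf["sr_sp"];
  IntegerVector sr_act = conf["sr_act"];
  NumericVector sr_lo = conf["sr_lo"], sr_hi = conf["sr_hi"];
  IntegerVector sr_aout = conf["sr_aout"], sr_prod = conf["sr_prod"];
  IntegerVector sr_gate = conf["sr_gate"], sr_die = conf["sr_die"];
  IntegerVector sr_become = conf["sr_become"];
  const int NS = sr_sp.size();

  // lookups: state rule per (species, act); binding rules per (species, act)
  std::vector<int> sridx(2 * S, -1);
  for (int s = 0; s < NS; ++s) sridx[2 * sr_sp[s] + sr_act[s]] = s;
  // seek[(sp,act)] = list of (rule, side) where side 0 = agent is reactant A
  std::vector<std::vector<std::pair<int, int> > > seek(2 * S);
  for (int r = 0; r < NB; ++r) {
    seek[2 * bind(r, 0) + bind(r, 1)].push_back(std::make_pair(r, 0));
    seek[2 * bind(r, 2) + bind(r, 3)].push_back(std::make_pair(r, 1));
  }
  // channels grouped by (bind rule, stage); competing timers race within a
  // stage, a non-dissociating winner advances the complex to the next stage
  int max_stage = 0;
  for (int c = 0; c < NC; ++c) max_stage = std::max(max_stage, (int)ch_stage[c]);
  std::vector<std::vector<std::vector<int> > > rule_chans(
      NB, std::vector<std::vector<int> >(max_stage + 1));
  for (int c = 0; c < NC; ++c)
    rule_chans[ch_rule[c]][ch_stage[c]].push_back(c);

  // --- init agents ----------------------------------------------------------
  std::vector<Agent> ag;
  ag.reserve(sum(sp_count) + 64);
  for (int s = 0; s < S; ++s) {
    for (int k = 0; k < sp_count[s]; ++k) {
      Agent a;
      a.sp = s; a.act = (k < sp_init_act[s]); a.partner = -1;
      a.is_static = sp_static[s] != 0; a.alive = true;
      a.ttype = -1; a.tid = -1; a.trem = 0;
      shell_point(sp_rmin[s], sp_rmax[s], a.x, a.y, a.z, sp_comp[s] == 4);
      ag.push_back(a);
    }
  }
  auto set_state_timer = [&](Agent &a) {
    a.ttype = -1; a.tid = -1;
    int s = sridx[2 * a.sp + (a.act ? 1 : 0)];
    if (s >= 0) {
      a.ttype = 0; a.tid = s;
      a.trem = sr_lo[s] + runif01() * (sr_hi[s] - sr_lo[s]);
    }
  };
  for (size_t i = 0; i < ag.size(); ++i) set_state_timer(ag[i]);

  // carrier holds the earliest of the competing channel timers of a stage
  auto draw_channel = [&](Agent &a, int rule, int stage) {
    a.ttype = -1; a.tid = -1;
    double best = R_PosInf;
    const std::vector<int> &chs = rule_chans[rule][stage];
    for (size_t c = 0; c < chs.size(); ++c) {
      double u = ch_lo[chs[c]] + runif01() * (ch_hi[chs[c]] - ch_lo[chs[c]]);
      if (u < best) { best = u; a.ttype = 1; a.tid = chs[c]; }
    }
    a.trem = best;
  };

  auto comp_of = [&](const Agent &a) -> int {
    if (sp_comp[a.sp] == 4) return 2;  // membrane
    double r = std::sqrt(a.x * a.x + a.y * a.y + a.z * a.z);
    if (r < rn_) return 0;
    if (r < rc_) return 1;
    return 3;
  };
  auto spawn = [&](int sp, double x, double y, double z) {
    Agent a;
    a.sp = sp; a.act = false; a.partner = -1;
    a.is_static = sp_static[sp] != 0; a.alive = true;
    a.x = x; a.y = y; a.z = z;
    reflect_shell(sp_rmin[sp], sp_rmax[sp], a.x, a.y, a.z);
    a.ttype = -1; a.tid = -1; a.trem = 0;
    set_state_timer(a);
    ag.push_back(a);
  };

  // --- label bookkeeping ----------------------------------------------------
  std::unordered_map<int64_t, int> colmap;
  std::vector<int64_t> colkeys;
  std::vector<std::vector<int> > rows;
  rows.reserve(n_steps + 1);
  auto label_key = [&](const Agent &a) -> int64_t {
    int psp = a.partner >= 0 ? ag[a.partner].sp : -1;
    return (((int64_t)a.sp * 2 + (a.act ? 1 : 0)) * (S + 1) + (psp + 1)) * 4 +
           comp_of(a);
  };
  std::vector<int> productions(n_steps + 1, 0), degradations(n_steps + 1, 0);
  NumericVector loads(n_steps + 1);

  auto record = [&](int row) {
    std::vector<int> cnt(colmap.size(), 0);
    for (size_t i = 0; i < ag.size(); ++i) {
      if (!ag[i].alive) continue;
      int64_t k = label_key(ag[i]);
      std::unordered_map<int64_t, int>::iterator it = colmap.find(k);
      int col;
      if (it == colmap.end()) {
        col = (int)colmap.size();
        colmap[k] = col;
        colkeys.push_back(k);
        cnt.push_back(0);
      } else col = it->second;
      cnt[col] += 1;
    }
    rows.push_back(cnt);
    (void)row;
  };

  // --- spatial grid ---------------------------------------------------------
  // cell size >= R_inter keeps the +/-1 neighbour ring sufficient; the
  // lower bound caps the grid at ~100^3 cells for tiny interaction ranges
  const double cell = std::max(R_inter, 2 * rx_ / 100);
  const double orig = -rx_ - cell;
  const int ng = (int)std::ceil((2 * (rx_ + cell)) / cell) + 1;
  std::vector<int> head, nxt;
  if (NB > 0 && !brute) head.assign((size_t)ng * ng * ng, -1);
  auto cell_ix = [&](double v) {
    int i = (int)std::floor((v - orig) / cell);
    if (i < 0) i = 0;
    if (i >= ng) i = ng - 1;
    return i;
  };

  std::vector<int> perm;
  std::vector<char> claimed;

  record(0);
  loads[0] = (mod_pos(0.0 - phase, P) < P / 2) ? M : m0;

  // --- main loop ------------------------------------------------------------
  for (int step = 1; step <= n_steps; ++step) {
    const size_t N0 = ag.size();
    const double t = (step - 1) * dt;
    const double tm = mod_pos(t - phase, P);
    const double load = (tm < P / 2) ? M : m0;
    loads[step] = load;

    // 1. load: inactive free membrane receptors activate with probability
    //    linear in (load - baseline)
    if (receptor_sp >= 0 && load > m0) {
      double p = k_act * (load - m0) / (M_ref - m0);
      if (p > 1) p = 1;
      if (p > 0) {
        for (size_t i = 0; i < N0; ++i) {
          Agent &a = ag[i];
          if (a.alive && a.sp == receptor_sp && !a.act && a.partner < 0 &&
              runif01() < p) {
            a.act = true;
            set_state_timer(a);
          }
        }
      }
    }

    // 2. move: Gaussian step, radial reflection; complexes move as one
    //    (carrier = timer holder); static and non-carrier bound agents skip
    if (dstep > 0) {
      for (size_t i = 0; i < N0; ++i) {
        Agent &a = ag[i];
        if (!a.alive || a.is_static) continue;
        if (a.partner >= 0 && a.ttype != 1) continue;  // follows carrier
        a.x += norm_rand() * dstep;
        a.y += norm_rand() * dstep;
        a.z += norm_rand() * dstep;
        // a complex is confined to the intersection of both partners' domains
        double rlo = sp_rmin[a.sp], rhi = sp_rmax[a.sp];
        if (a.partner >= 0) {
          rlo = std::max(rlo, sp_rmin[ag[a.partner].sp]);
          rhi = std::min(rhi, sp_rmax[ag[a.partner].sp]);
        }
        reflect_shell(rlo, rhi, a.x, a.y, a.z);
        if (a.partner >= 0) {
          ag[a.partner].x = a.x; ag[a.partner].y = a.y; ag[a.partner].z = a.z;
        }
      }
    }

    // 3. bindings: seeded random permutation; nearest eligible partner
    //    within R_inter; at most one binding per agent per step
    if (NB > 0) {
      perm.resize(N0);
      for (size_t i = 0; i < N0; ++i) perm[i] = (int)i;
      for (size_t i = N0; i > 1; --i) {   // Fisher-Yates via R RNG
        size_t j = (size_t)(runif01() * i);
        if (j >= i) j = i - 1;
        std::swap(perm[i - 1], perm[j]);
      }
      claimed.assign(N0, 0);
      if (!brute) {
        std::fill(head.begin(), head.end(), -1);
        nxt.assign(N0, -1);
        for (size_t i = 0; i < N0; ++i) {
          const Agent &a = ag[i];
          if (!a.alive || a.partner >= 0) continue;
          size_t c = ((size_t)cell_ix(a.x) * ng + cell_ix(a.y)) * ng +
                     cell_ix(a.z);
          nxt[i] = head[c];
          head[c] = (int)i;
        }
      }
      const double R2 = R_inter * R_inter;
      for (size_t pi = 0; pi < N0; ++pi) {
        const int i = perm[pi];
        Agent &a = ag[i];
        if (!a.alive || a.partner >= 0 || claimed[i]) continue;
        const std::vector<std::pair<int, int> > &cand =
            seek[2 * a.sp + (a.act ? 1 : 0)];
        if (cand.empty()) continue;
        double bd2 = R2 * (1 + 1e-12);
        int bj = -1, brule = -1, bside = -1;
        for (size_t q = 0; q < cand.size(); ++q) {
          const int r = cand[q].first, side = cand[q].second;
          const int tsp = side == 0 ? bind(r, 2) : bind(r, 0);
          const int tact = side == 0 ? bind(r, 3) : bind(r, 1);
          auto consider = [&](int j) {
            if (j == i) return;
            const Agent &b = ag[j];
            if (!b.alive || b.partner >= 0 || claimed[j]) return;
            if (b.sp != tsp || (b.act ? 1 : 0) != tact) return;
            double dx = a.x - b.x, dy = a.y - b.y, dz = a.z - b.z;
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < bd2 - 1e-300 ||
                (d2 == bd2 && (bj < 0 || j < bj))) {
              if (d2 <= R2) { bd2 = d2; bj = j; brule = r; bside = side; }
            }
          };
          if (brute) {
            for (size_t j = 0; j < N0; ++j) consider((int)j);
          } else {
            int cx = cell_ix(a.x), cy = cell_ix(a.y), cz = cell_ix(a.z);
            for (int ddx = -1; ddx <= 1; ++ddx)
              for (int ddy = -1; ddy <= 1; ++ddy)
                for (int ddz = -1; ddz <= 1; ++ddz) {
                  int ux = cx + ddx, uy = cy + ddy, uz = cz + ddz;
                  if (ux < 0 || uy < 0 || uz < 0 || ux >= ng || uy >= ng ||
                      uz >= ng)
                    continue;
                  for (int j = head[((size_t)ux * ng + uy) * ng + uz]; j >= 0;
                       j = nxt[j])
                    consider(j);
                }
          }
        }
        if (bj < 0) continue;
        const int r = brule;
        const int ai = bside == 0 ? i : bj;
        const int bi = bside == 0 ? bj : i;
        claimed[i] = claimed[bj] = 1;
        Agent &A = ag[ai];
        Agent &B = ag[bi];
        if (bind(r, 4)) {            // complex formation
          A.partner = bi; B.partner = ai;
          A.act = bind(r, 5) != 0; B.act = bind(r, 6) != 0;
          B.ttype = -1; B.tid = -1;
          draw_channel(A, r, 0);
        } else {                     // messenger transfer: state changes only
          bool na = bind(r, 5) != 0, nb = bind(r, 6) != 0;
          if (A.act != na) { A.act = na; set_state_timer(A); }
          if (B.act != nb) { B.act = nb; set_state_timer(B); }
        }
      }
    }

    // 4. timers: decrement all, then fire expired ones
    for (size_t i = 0; i < N0; ++i)
      if (ag[i].alive && ag[i].ttype >= 0) ag[i].trem -= dt;
    for (size_t i = 0; i < N0; ++i) {
      Agent &a = ag[i];
      if (!a.alive || a.ttype < 0 || a.trem > 1e-9) continue;
      if (a.ttype == 1) {            // complex channel
        const int c = a.tid;
        const int j = a.partner;
        const int rule = ch_rule[c];
        const int stage = ch_stage[c];
        bool dissoc = ch_dissoc[c] != 0 ||
                      stage >= (int)rule_chans[rule].size() - 1 ||
                      rule_chans[rule][stage + 1].empty();
        a.act = ch_aout[c] != 0;
        if (j >= 0) ag[j].act = ch_bout[c] != 0;
        if (dissoc) {
          a.ttype = -1; a.tid = -1; a.partner = -1;
          set_state_timer(a);
          if (j >= 0) {
            ag[j].partner = -1;
            set_state_timer(ag[j]);
          }
        } else {
          draw_channel(a, rule, stage + 1);
        }
        if (ch_prod[c] >= 0) {
          spawn(ch_prod[c], a.x, a.y, a.z);
          productions[step] += 1;
        }
      } else {                       // single-agent state rule
        const int s = a.tid;
        a.ttype = -1; a.tid = -1;
        if (sr_die[s]) {
          a.alive = false;
          degradations[step] += 1;
          continue;
        }
        bool gate_ok = sr_gate[s] < 0 || comp_of(a) == sr_gate[s];
        if (sr_become[s] >= 0) {
          a.sp = sr_become[s];
          a.act = false;
          a.is_static = sp_static[a.sp] != 0;
          reflect_shell(sp_rmin[a.sp], sp_rmax[a.sp], a.x, a.y, a.z);
          set_state_timer(a);
        } else {
          a.act = sr_aout[s] != 0;
          set_state_timer(a);
        }
        if (sr_prod[s] >= 0 && gate_ok) {
          spawn(sr_prod[s], a.x, a.y, a.z);
          productions[step] += 1;
        }
      }
    }

    record(step);
  }

  // --- assemble results -----------------------------------------------------
  const int ncol = (int)colmap.size();
  IntegerMatrix counts(n_steps + 1, ncol);
  for (int i = 0; i <= n_steps; ++i)
    for (size_t j = 0; j < rows[i].size(); ++j) counts(i, j) = rows[i][j];
  CharacterVector cn(ncol);
  const char *compn[4] = {"nucleus", "cytoplasm", "membrane", "extracellular"};
  for (int j = 0; j < ncol; ++j) {
    int64_t k = colkeys[j];
    int comp = (int)(k % 4); k /= 4;
    int pp = (int)(k % (S + 1)) - 1; k /= (S + 1);
    int act = (int)(k % 2); k /= 2;
    int sp = (int)k;
    std::string lab = std::string(CHAR(STRING_ELT(sp_names, sp))) + "." +
                      (act ? "active" : "inactive") + "." +
                      (pp >= 0 ? std::string(CHAR(STRING_ELT(sp_names, pp)))
                               : std::string("none")) +
                      "." + compn[comp];
    cn[j] = lab;
  }
  NumericVector times(n_steps + 1);
  for (int i = 0; i <= n_steps; ++i) times[i] = i * dt;

  List out = List::create(
      _["times"] = times, _["counts"] = counts, _["labels"] = cn,
      _["productions"] = wrap(productions),
      _["degradations"] = wrap(degradations), _["loads"] = loads);
  if (ret_agents) {
    const size_t N = ag.size();
    CharacterVector asp(N);
    LogicalVector aact(N), astat(N), aal(N);
    IntegerVector apart(N);
    NumericVector ax(N), ay(N), az(N), atim(N);
    for (size_t i = 0; i < N; ++i) {
      asp[i] = sp_names[ag[i].sp];
      aact[i] = ag[i].act;
      astat[i] = ag[i].is_static;
      aal[i] = ag[i].alive;
      apart[i] = ag[i].partner >= 0 ? (int)(ag[i].partner + 1) : NA_INTEGER;
      ax[i] = ag[i].x; ay[i] = ag[i].y; az[i] = ag[i].z;
      atim[i] = ag[i].ttype >= 0 ? ag[i].trem : NA_REAL;
    }
    out["agents"] = DataFrame::create(
        _["species"] = asp, _["active"] = aact, _["partner"] = apart,
        _["x"] = ax, _["y"] = ay, _["z"] = az, _["static"] = astat,
        _["alive"] = aal, _["timer"] = atim);
  }
  return out;
}
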