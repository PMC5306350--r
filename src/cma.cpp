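// Cooperative motion algorithm kernel on a fully occupied triangular lattice.
//
// Site indexing: s = a + L*b + L*L*layer with axial coordinates (a, b) in
// [0, L) and layer in {0, 1}.  The Cartesian embedding is x = a + b/2,
// y = b*sqrt(3)/2, z = layer, so all six in-layer neighbour vectors have
// unit length and the periodic cell is a rhombus spanned by L*(1,0) and
// L*(1/2, sqrt(3)/2).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <climits>
#include <cstdint>

using namespace Rcpp;

namespace {

// xoshiro256** seeded through splitmix64: deterministic and portable,
// independent of R's RNG stream.
struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

const int UV[6][2] = {{1,0},{-1,0},{0,1},{0,-1},{1,-1},{-1,1}};
const double SQ32 = 0.8660254037844386467637231707529362; // sqrt(3)/2
const int HIST_MAX = 512;

// ascending eigenvalues of a symmetric 3x3 matrix (trigonometric method)
void eig_sym3(double xx, double yy, double zz,
              double xy, double xz, double yz, double lam[3]) {
  double p1 = xy*xy + xz*xz + yz*yz;
  if (p1 < 1e-28) {
    lam[0] = xx; lam[1] = yy; lam[2] = zz;
    std::sort(lam, lam + 3);
    return;
  }
  double q = (xx + yy + zz) / 3.0;
  double p2 = (xx-q)*(xx-q) + (yy-q)*(yy-q) + (zz-q)*(zz-q) + 2.0*p1;
  double p = std::sqrt(p2 / 6.0);
  double bxx = (xx-q)/p, byy = (yy-q)/p, bzz = (zz-q)/p;
  double bxy = xy/p, bxz = xz/p, byz = yz/p;
  double r = (bxx*(byy*bzz - byz*byz)
            - bxy*(bxy*bzz - byz*bxz)
            + bxz*(bxy*byz - byy*bxz)) / 2.0;
  r = std::max(-1.0, std::min(1.0, r));
  double phi = std::acos(r) / 3.0;
  lam[2] = q + 2.0*p*std::cos(phi);
  lam[0] = q + 2.0*p*std::cos(phi + 2.0*M_PI/3.0);
  lam[1] = 3.0*q - lam[0] - lam[2];
  std::sort(lam, lam + 3);
}

struct Sim {
  int L, layers, nsites, N, nchains, coordnum, maxlen;
  std::vector<int> nbr;        // nsites x 7 neighbour table
  std::vector<int> occ_chain;  // per site: chain id or -1 (solvent)
  std::vector<int> occ_bead;   // per site: bead index or -1
  std::vector<int> chain_site; // nchains*N: site of each bead
  std::vector<int> stamp; int stampc;
  std::vector<int> walk, oldc, oldb;
  RNG rng;

  double attempts, accepted, closed_loops, displacements;
  long long disp_since, timestep;
  std::vector<double> loophist;

  // measurement buffers
  std::vector<double> m_t, m_rg2, m_ree2, m_l1, m_l2, m_l3, m_d2, m_s2;
  std::vector<double> gamma_counts;
  double gamma_samples;

  Sim(const IntegerMatrix& beads, int L_, int layers_, int N_, int nchains_,
      uint64_t seed, int maxlen_, long long timestep0)
    : L(L_), layers(layers_), nsites(L_*L_*layers_), N(N_), nchains(nchains_),
      coordnum(layers_ == 2 ? 7 : 6), maxlen(maxlen_), rng(seed),
      attempts(0), accepted(0), closed_loops(0), displacements(0),
      disp_since(0), timestep(timestep0), gamma_samples(0) {
    nbr.assign((size_t)nsites * 7, -1);
    for (int l = 0; l < layers; ++l)
      for (int b = 0; b < L; ++b)
        for (int a = 0; a < L; ++a) {
          int s = a + L*b + L*L*l;
          for (int d = 0; d < 6; ++d) {
            int na = (a + UV[d][0] + L) % L;
            int nb = (b + UV[d][1] + L) % L;
            nbr[(size_t)s*7 + d] = na + L*nb + L*L*l;
          }
          if (layers == 2) nbr[(size_t)s*7 + 6] = a + L*b + L*L*(1 - l);
        }
    occ_chain.assign(nsites, -1);
    occ_bead.assign(nsites, -1);
    chain_site.assign((size_t)nchains * N, -1);
    for (int c = 0; c < nchains; ++c)
      for (int i = 0; i < N; ++i) {
        int r = c*N + i;
        int s = beads(r, 0) + L*beads(r, 1) + L*L*beads(r, 2);
        chain_site[(size_t)c*N + i] = s;
        occ_chain[s] = c;
        occ_bead[s] = i;
      }
    stamp.assign(nsites, 0); stampc = 0;
    loophist.assign(HIST_MAX + 1, 0.0);
    gamma_counts.assign((size_t)L*L + 2, 0.0);
  }

  inline void decode(int s, int& a, int& b, int& l) const {
    a = s % L; b = (s / L) % L; l = s / (L*L);
  }
  inline int reduce1(int d) const {
    d %= L; if (d < 0) d += L; if (d > L/2) d -= L; return d;
  }
  inline bool is_neighbor(int s1, int s2) const {
    int a1,b1,l1,a2,b2,l2;
    decode(s1, a1, b1, l1); decode(s2, a2, b2, l2);
    if (l1 != l2) return a1 == a2 && b1 == b2;
    int da = reduce1(a2 - a1), db = reduce1(b2 - b1);
    for (int d = 0; d < 6; ++d)
      if (da == UV[d][0] && db == UV[d][1]) return true;
    return false;
  }
  // minimum-image squared distance; exactly an integer on this lattice
  inline int min_image_r2(int s1, int s2) const {
    int a1,b1,l1,a2,b2,l2;
    decode(s1, a1, b1, l1); decode(s2, a2, b2, l2);
    int da0 = (a2 - a1) % L; if (da0 < 0) da0 += L;
    int db0 = (b2 - b1) % L; if (db0 < 0) db0 += L;
    int best = INT_MAX;
    for (int m = -1; m <= 1; ++m)
      for (int n = -1; n <= 1; ++n) {
        int da = da0 + m*L, db = db0 + n*L;
        int q = da*da + da*db + db*db;
        if (q < best) best = q;
      }
    int dz = l2 - l1;
    return best + dz*dz;
  }

  // Displacement random walk: each step tentatively moves the element at
  // the current site onto a uniformly chosen neighbour; the displaced
  // element continues the walk.  Closure onto the start site completes a
  // cooperative loop (zero net displacement by construction).  Walks that
  // self-intersect, exceed maxlen sites, or close with fewer than 3 sites
  // are rejected.  Every tentative step counts towards simulation time.
  bool propose() {
    walk.clear();
    int s0 = rng.below(nsites);
    walk.push_back(s0);
    ++stampc; stamp[s0] = stampc;
    int cur = s0;
    int wa = 0, wb = 0, wl = 0;  // raw displacement sum (detects winding)
    for (;;) {
      int d = rng.below(coordnum);
      int nxt = nbr[(size_t)cur*7 + d];
      if (d < 6) { wa += UV[d][0]; wb += UV[d][1]; }
      else wl += 1 - 2 * (cur / (L*L));
      displacements += 1.0; ++disp_since;
      if (nxt == s0) {
        // loops that wind around the torus have a non-zero displacement
        // sum and violate the continuity condition: reject
        return (int)walk.size() >= 3 && wa == 0 && wb == 0 && wl == 0;
      }
      if (stamp[nxt] == stampc) return false;
      if ((int)walk.size() >= maxlen) return false;
      stamp[nxt] = stampc;
      walk.push_back(nxt);
      cur = nxt;
    }
  }

  // Cyclically permute the elements along the closed walk, then accept iff
  // every bond of every affected chain is still a nearest-neighbour pair.
  bool apply_walk() {
    int k = (int)walk.size();
    oldc.resize(k); oldb.resize(k);
    for (int i = 0; i < k; ++i) {
      oldc[i] = occ_chain[walk[i]];
      oldb[i] = occ_bead[walk[i]];
    }
    for (int i = 0; i < k; ++i) {
      int j = (i + 1) % k;
      occ_chain[walk[j]] = oldc[i];
      occ_bead[walk[j]] = oldb[i];
      if (oldc[i] >= 0) chain_site[(size_t)oldc[i]*N + oldb[i]] = walk[j];
    }
    bool ok = true;
    for (int i = 0; i < k && ok; ++i) {
      int c = oldc[i];
      if (c < 0) continue;
      int b = oldb[i];
      int s = chain_site[(size_t)c*N + b];
      if (b > 0 && !is_neighbor(s, chain_site[(size_t)c*N + b - 1])) ok = false;
      if (ok && b < N - 1 && !is_neighbor(s, chain_site[(size_t)c*N + b + 1])) ok = false;
    }
    if (!ok) {
      for (int i = 0; i < k; ++i) {
        occ_chain[walk[i]] = oldc[i];
        occ_bead[walk[i]] = oldb[i];
        if (oldc[i] >= 0) chain_site[(size_t)oldc[i]*N + oldb[i]] = walk[i];
      }
    }
    return ok;
  }

  void unwrap(int c, std::vector<double>& X, std::vector<double>& Y,
              std::vector<double>& Z) const {
    int a, b, l;
    decode(chain_site[(size_t)c*N], a, b, l);
    double ua = a, ub = b, ul = l;
    X[0] = ua + 0.5*ub; Y[0] = SQ32*ub; Z[0] = ul;
    for (int i = 1; i < N; ++i) {
      int a2,b2,l2,pa,pb,pl;
      decode(chain_site[(size_t)c*N + i], a2, b2, l2);
      decode(chain_site[(size_t)c*N + i - 1], pa, pb, pl);
      ua += reduce1(a2 - pa); ub += reduce1(b2 - pb); ul += (l2 - pl);
      X[i] = ua + 0.5*ub; Y[i] = SQ32*ub; Z[i] = ul;
    }
  }

  // per-chain rg2, ree2 and ascending gyration-tensor eigenvalues
  void chain_metric(int c, std::vector<double>& X, std::vector<double>& Y,
                    std::vector<double>& Z, double out[6]) const {
    unwrap(c, X, Y, Z);
    double mx = 0, my = 0, mz = 0;
    for (int i = 0; i < N; ++i) { mx += X[i]; my += Y[i]; mz += Z[i]; }
    mx /= N; my /= N; mz /= N;
    double xx = 0, yy = 0, zz = 0, xy = 0, xz = 0, yz = 0;
    for (int i = 0; i < N; ++i) {
      double dx = X[i]-mx, dy = Y[i]-my, dz = Z[i]-mz;
      xx += dx*dx; yy += dy*dy; zz += dz*dz;
      xy += dx*dy; xz += dx*dz; yz += dy*dz;
    }
    xx /= N; yy /= N; zz /= N; xy /= N; xz /= N; yz /= N;
    double rg2 = xx + yy + zz;
    double ex = X[N-1]-X[0], ey = Y[N-1]-Y[0], ez = Z[N-1]-Z[0];
    double ree2 = ex*ex + ey*ey + ez*ez;
    double l1, l2, l3;
    if (layers == 1) {
      double tr = xx + yy, det = xx*yy - xy*xy;
      double disc = std::sqrt(std::max(0.0, tr*tr - 4.0*det));
      l1 = (tr - disc) / 2.0; l2 = (tr + disc) / 2.0; l3 = 0.0;
    } else {
      double lam[3];
      eig_sym3(xx, yy, zz, xy, xz, yz, lam);
      l1 = lam[0]; l2 = lam[1]; l3 = lam[2];
    }
    out[0] = rg2; out[1] = ree2; out[2] = l1; out[3] = l2; out[4] = l3;
    out[5] = 0.0;
  }

  void measure(std::vector<double>& X, std::vector<double>& Y,
               std::vector<double>& Z) {
    double rg2 = 0, ree2 = 0, sl1 = 0, sl2 = 0, sl3 = 0, d2 = 0, s2 = 0;
    double out[6];
    for (int c = 0; c < nchains; ++c) {
      chain_metric(c, X, Y, Z, out);
      rg2 += out[0]; ree2 += out[1];
      double l1, l2;  // two dominant eigenvalues for the asphericity
      if (layers == 1) { l1 = out[2]; l2 = out[3]; }
      else             { l1 = out[3]; l2 = out[4]; }
      sl1 += l1; sl2 += l2; sl3 += out[4];
      d2 += (l2 - l1)*(l2 - l1);
      s2 += (l2 + l1)*(l2 + l1);
    }
    double n = (double)nchains;
    m_t.push_back((double)timestep);
    m_rg2.push_back(rg2/n);  m_ree2.push_back(ree2/n);
    m_l1.push_back(sl1/n);   m_l2.push_back(sl2/n);  m_l3.push_back(sl3/n);
    m_d2.push_back(d2);      m_s2.push_back(s2);
  }

  void accumulate_gamma() {
    for (int c = 0; c < nchains; ++c) {
      gamma_counts[0] += N;  // self pairs
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) {
          int r2 = min_image_r2(chain_site[(size_t)c*N + i],
                                chain_site[(size_t)c*N + j]);
          gamma_counts[r2] += 2.0;  // ordered pairs
        }
    }
    gamma_samples += nchains;
  }

  IntegerMatrix beads_out() const {
    IntegerMatrix out(nchains * N, 3);
    for (int c = 0; c < nchains; ++c)
      for (int i = 0; i < N; ++i) {
        int a, b, l;
        decode(chain_site[(size_t)c*N + i], a, b, l);
        int r = c*N + i;
        out(r, 0) = a; out(r, 1) = b; out(r, 2) = l;
      }
    return out;
  }
};

} // namespace

// [[Rcpp::export]]
List cma_run_cpp(IntegerMatrix beads, int L, int layers, int N, int n_chains,
                 double seed, double n_timesteps, int max_len,
                 int measure_every, int gamma_every, bool collect_gamma,
                 double timestep0) {
  Sim sim(beads, L, layers, N, n_chains, (uint64_t)seed, max_len,
          (long long)timestep0);
  std::vector<double> X(N > 0 ? N : 1), Y(N > 0 ? N : 1), Z(N > 0 ? N : 1);
  long long t_end = sim.timestep + (long long)n_timesteps;
  long long meas_count = 0;
  while (sim.timestep < t_end) {
    sim.attempts += 1.0;
    if (sim.propose()) {
      sim.closed_loops += 1.0;
      int k = std::min((int)sim.walk.size(), HIST_MAX);
      sim.loophist[k] += 1.0;
      if (sim.apply_walk()) sim.accepted += 1.0;
    }
    while (sim.disp_since >= sim.nsites && sim.timestep < t_end) {
      sim.disp_since -= sim.nsites;
      sim.timestep += 1;
      if (measure_every > 0 && n_chains > 0 &&
          sim.timestep % measure_every == 0) {
        sim.measure(X, Y, Z);
        ++meas_count;
        if (collect_gamma && gamma_every > 0 && meas_count % gamma_every == 0)
          sim.accumulate_gamma();
      }
    }
  }
  int nm = (int)sim.m_t.size();
  NumericMatrix meas(nm, 8);
  for (int i = 0; i < nm; ++i) {
    meas(i,0) = sim.m_t[i];   meas(i,1) = sim.m_rg2[i];
    meas(i,2) = sim.m_ree2[i]; meas(i,3) = sim.m_l1[i];
    meas(i,4) = sim.m_l2[i];  meas(i,5) = sim.m_l3[i];
    meas(i,6) = sim.m_d2[i];  meas(i,7) = sim.m_s2[i];
  }
  colnames(meas) = CharacterVector::create("timestep", "rg2_mean", "ree2_mean",
    "lambda1_mean", "lambda2_mean", "lambda3_mean", "sum_dlambda_sq",
    "sum_slambda_sq");
  return List::create(
    _["beads"] = sim.beads_out(),
    _["measurements"] = meas,
    _["gamma_counts"] = NumericVector(sim.gamma_counts.begin(),
                                      sim.gamma_counts.end()),
    _["gamma_samples"] = sim.gamma_samples,
    _["timestep"] = (double)sim.timestep,
    _["attempts"] = sim.attempts,
    _["closed_loops"] = sim.closed_loops,
    _["accepted"] = sim.accepted,
    _["displacements"] = sim.displacements,
    _["loop_hist"] = NumericVector(sim.loophist.begin(), sim.loophist.end()));
}

// [[Rcpp::export]]
NumericMatrix chain_metrics_cpp(IntegerMatrix beads, int L, int layers,
                                int N, int n_chains) {
  Sim sim(beads, L, layers, N, n_chains, 1ULL, 100, 0);
  std::vector<double> X(N), Y(N), Z(N);
  NumericMatrix out(n_chains, 5);
  double m[6];
  for (int c = 0; c < n_chains; ++c) {
    sim.chain_metric(c, X, Y, Z, m);
    for (int k = 0; k < 5; ++k) out(c, k) = m[k];
  }
  colnames(out) = CharacterVector::create("rg2", "ree2", "lambda1", "lambda2",
                                          "lambda3");
  return out;
}

// [[Rcpp::export]]
List gamma_counts_cpp(IntegerMatrix beads, int L, int layers, int N,
                      int n_chains) {
  Sim sim(beads, L, layers, N, n_chains, 1ULL, 100, 0);
  sim.accumulate_gamma();
  return List::create(
    _["counts"] = NumericVector(sim.gamma_counts.begin(),
                                sim.gamma_counts.end()),
    _["samples"] = sim.gamma_samples);
}

// [[Rcpp::export]]
int min_image_r2_cpp(int a1, int b1, int l1, int a2, int b2, int l2, int L) {
  int da0 = (a2 - a1) % L; if (da0 < 0) da0 += L;
  int db0 = (b2 - b1) % L; if (db0 < 0) db0 += L;
  int best = INT_MAX;
  for (int m = -1; m <= 1; ++m)
    for (int n = -1; n <= 1; ++n) {
      int da = da0 + m*L, db = db0 + n*L;
      int q = da*da + da*db + db*db;
      if (q < best) best = q;
    }
  int dz = l2 - l1;
  return best + dz*dz;
}

// Randomised Hamiltonian path on the L x L triangular torus via backbite
// moves, started from the boustrophedon path.  Cutting the returned site
// order into consecutive N-bead segments gives an exact full packing of
// chains with disordered, random-walk-like conformations.
// [[Rcpp::export]]
IntegerMatrix backbite_path_cpp(int L, double n_moves, double seed) {
  RNG rng((uint64_t)seed);
  int M = L * L;
  std::vector<int> path(M), pos_in_path(M);
  // boustrophedon start
  for (int b = 0; b < L; ++b)
    for (int i = 0; i < L; ++i) {
      int a = (b % 2 == 0) ? i : (L - 1 - i);
      path[(size_t)b * L + i] = a + L * b;
    }
  for (int i = 0; i < M; ++i) pos_in_path[path[i]] = i;
  long long moves = (long long)n_moves;
  for (long long m = 0; m < moves; ++m) {
    bool head = (rng.next() & 1ULL) != 0;
    if (!head) { // operate on the tail by reversing the whole path view
      std::reverse(path.begin(), path.end());
      for (int i = 0; i < M; ++i) pos_in_path[path[i]] = i;
    }
    int h = path[0];
    int a = h % L, b = h / L;
    int d = rng.below(6);
    int v = ((a + UV[d][0] + L) % L) + L * ((b + UV[d][1] + L) % L);
    int j = pos_in_path[v];
    if (j <= 1) continue;  // current neighbour or self: no-op
    std::reverse(path.begin(), path.begin() + j);
    for (int i = 0; i < j; ++i) pos_in_path[path[i]] = i;
  }
  IntegerMatrix out(M, 3);
  for (int i = 0; i < M; ++i) {
    out(i, 0) = path[i] % L;
    out(i, 1) = path[i] / L;
    out(i, 2) = 0;
  }
  return out;
}

namespace {

struct SawEnum {
  int nbeads;
  std::vector<int> steps;          // current step sequence
  std::vector<int> pa, pb;         // positions (axial)
  std::vector<char> visited;       // grid of size (2n+1)^2
  int span;
  std::vector<int> all_steps;      // flattened results
  std::vector<double> ree2, rg2;

  explicit SawEnum(int n) : nbeads(n), span(2*n + 1) {
    visited.assign((size_t)span * span, 0);
    pa.assign(n, 0); pb.assign(n, 0);
    steps.assign(n - 1, 0);
  }
  inline size_t gidx(int a, int b) const {
    return (size_t)(a + nbeads) * span + (b + nbeads);
  }
  void record() {
    for (int i = 0; i < nbeads - 1; ++i) all_steps.push_back(steps[i]);
    double sx = 0, sy = 0;
    std::vector<double> X(nbeads), Y(nbeads);
    for (int i = 0; i < nbeads; ++i) {
      X[i] = pa[i] + 0.5*pb[i];
      Y[i] = SQ32*pb[i];
      sx += X[i]; sy += Y[i];
    }
    sx /= nbeads; sy /= nbeads;
    double g = 0;
    for (int i = 0; i < nbeads; ++i)
      g += (X[i]-sx)*(X[i]-sx) + (Y[i]-sy)*(Y[i]-sy);
    rg2.push_back(g / nbeads);
    double ex = X[nbeads-1] - X[0], ey = Y[nbeads-1] - Y[0];
    ree2.push_back(ex*ex + ey*ey);
  }
  void dfs(int depth) {
    if (depth == nbeads) { record(); return; }
    for (int d = 0; d < 6; ++d) {
      int na = pa[depth-1] + UV[d][0], nb = pb[depth-1] + UV[d][1];
      size_t g = gidx(na, nb);
      if (visited[g]) continue;
      visited[g] = 1;
      pa[depth] = na; pb[depth] = nb; steps[depth-1] = d;
      dfs(depth + 1);
      visited[g] = 0;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List saw_enumerate_cpp(int nbeads) {
  SawEnum e(nbeads);
  e.visited[e.gidx(0, 0)] = 1;
  e.dfs(1);
  int count = (int)e.rg2.size();
  IntegerMatrix walks(count, nbeads - 1);
  for (int w = 0; w < count; ++w)
    for (int i = 0; i < nbeads - 1; ++i)
      walks(w, i) = e.all_steps[(size_t)w*(nbeads-1) + i] + 1; // 1-based dir
  return List::create(
    _["count"] = count,
    _["steps"] = walks,
    _["ree2"] = NumericVector(e.ree2.begin(), e.ree2.end()),
    _["rg2"] = NumericVector(e.rg2.begin(), e.rg2.end()));
}
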