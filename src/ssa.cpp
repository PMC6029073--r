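// Exact stochastic simulation of the two-stage HOG transcriptional
// activation network:
//   R1  Hog1 -> Hog1P                (k_basal + activity_scale*c_active*stress) * Hog1
//   R2  Hog1P -> Hog1                k_dephos * Hog1P
//   R3  gene + TF <-> gene.TF        c_tfon * TFfree  /  k_off_tf
//   R4  gene.TF + Hog1P <-> gene.TF.Hog                c_hogon * Hog1P  /  k_off_hog
//   R5  + remodeler <-> ...          remodeling_scale * c_remon * Remfree / k_off_rem
//   R6  + polymerase <-> active gene c_polon * Polfree / k_off_pol
//   R7  active gene -> + mRNA        k_tx
//   R8  gene-bound Hog1P dephosphorylated (k_dephos): complex disassembles
//       to gene.TF, bound remodeler/polymerase are released, Hog1 returns
//       unphosphorylated
//   R9  mRNA -> 0                    k_deg_mrna
//   R10 mRNA -> mRNA + protein       k_tl   (protein never degrades)
//
// The engine is Anderson's modified next-reaction method (exact; random
// time-change representation): every reaction channel owns an
// independent unit-rate internal clock driven by its own random
// substream derived from (seed, cell, channel). Besides exactness, this
// gives strong pathwise coupling across parameter values: rescaling one
// rate constant perturbs only that channel's firing times, so
// populations simulated at neighbouring parameter fractions under the
// same seed share almost their whole realisation - the common-random-
// number structure the parameter sweeps rely on.
//
// Cells are independent; cell i's trajectory depends only on (seed, i).
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  Rng() : s(0) {}
  Rng(uint64_t seed, uint64_t stream) {
    // decorrelate (seed, stream) pairs before use
    s = seed * 0x9E3779B97F4A7C15ULL + (stream + 1) * 0xD1B54A32D192ED03ULL;
    for (int i = 0; i < 4; ++i) next();
  }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0,1), never exactly 0 or 1
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double rexp1() { return -std::log(unif()); }
};

// exact Poisson draw by the multiplication method, in chunks small enough
// that the running product cannot underflow; the sum of independent
// Poisson chunks is Poisson of the summed mean
double rpois_exact(Rng& rng, double lambda) {
  double total = 0.0;
  while (lambda > 0.0) {
    double l = lambda < 25.0 ? lambda : 25.0;
    lambda -= l;
    const double L = std::exp(-l);
    double p = rng.unif();
    int k = 0;
    while (p > L) { p *= rng.unif(); ++k; }
    total += k;
  }
  return total;
}

struct Pars {
  double hog1_total, tf_total, remodeler_total, polymerase_total;
  int gene_copies;
  double k_basal, c_active, stress, k_dephos;
  double c_tfon, c_hogon, c_remon, c_polon;
  double k_off_tf, k_off_hog, k_off_rem, k_off_pol;
  double k_tx, k_deg_mrna, k_tl, t_end;
  double activity_scale, remodeling_scale;
};

Pars read_pars(const List& p) {
  Pars q;
  q.hog1_total = as<double>(p["hog1_total"]);
  q.tf_total = as<double>(p["tf_total"]);
  q.remodeler_total = as<double>(p["remodeler_total"]);
  q.polymerase_total = as<double>(p["polymerase_total"]);
  q.gene_copies = as<int>(p["gene_copies"]);
  q.k_basal = as<double>(p["k_basal"]);
  q.c_active = as<double>(p["c_active"]);
  q.stress = as<double>(p["stress"]);
  q.k_dephos = as<double>(p["k_dephos"]);
  q.c_tfon = as<double>(p["c_tfon"]);
  q.c_hogon = as<double>(p["c_hogon"]);
  q.c_remon = as<double>(p["c_remon"]);
  q.c_polon = as<double>(p["c_polon"]);
  q.k_off_tf = as<double>(p["k_off_tf"]);
  q.k_off_hog = as<double>(p["k_off_hog"]);
  q.k_off_rem = as<double>(p["k_off_rem"]);
  q.k_off_pol = as<double>(p["k_off_pol"]);
  q.k_tx = as<double>(p["k_tx"]);
  q.k_deg_mrna = as<double>(p["k_deg_mrna"]);
  q.k_tl = as<double>(p["k_tl"]);
  q.t_end = as<double>(p["t_end"]);
  q.activity_scale = as<double>(p["activity_scale"]);
  q.remodeling_scale = as<double>(p["remodeling_scale"]);
  return q;
}

struct CellState {
  double H, Hp, TFf, Rf, Pf;  // free pools (counts)
  std::vector<int> g;         // per-copy gene state 0..4
  double M, P;                // mRNA, protein
};

// channel layout: 4 global channels, then 10 per gene copy
enum GlobalCh { PHOS = 0, DEPHOS = 1, DEG = 2, TL = 3 };
enum CopyCh { TF_ON = 0, TF_OFF, HOG_ON, HOG_OFF, REM_ON, REM_OFF,
              POL_ON, POL_OFF, R8, TX };

// one exact trajectory; if `rec` is non-null every event is appended and
// translation fires as explicit events; otherwise the reporter count is
// drawn at the end as Poisson(k_tl * integral of mRNA dt), which has
// exactly the end-point law because protein feeds back on no propensity
void run_cell(const Pars& q, uint64_t seed, int cell, CellState& st,
              std::vector<double>* rec) {
  const double k_act = q.k_basal + q.activity_scale * q.c_active * q.stress;
  const double c_rem = q.remodeling_scale * q.c_remon;
  const bool event_translation = (rec != nullptr);
  const int nc = q.gene_copies;
  const int nch = 4 + 10 * nc;

  st.H = q.hog1_total; st.Hp = 0;
  st.TFf = q.tf_total; st.Rf = q.remodeler_total; st.Pf = q.polymerase_total;
  st.g.assign(nc, 0);
  st.M = 0; st.P = 0;

  std::vector<Rng> rng(nch);
  std::vector<double> nextP(nch), intA(nch), a(nch);
  for (int j = 0; j < nch; ++j) {
    rng[j] = Rng(seed, (uint64_t)cell * 64ULL + (uint64_t)j);
    nextP[j] = rng[j].rexp1();
    intA[j] = 0.0;
  }

  double t = 0.0, intM = 0.0;

  auto record = [&](double tt) {
    if (!rec) return;
    rec->push_back(tt);
    rec->push_back(st.H); rec->push_back(st.Hp);
    rec->push_back(st.TFf); rec->push_back(st.Rf); rec->push_back(st.Pf);
    double gsum = 0; for (int c = 0; c < nc; ++c) gsum += st.g[c];
    rec->push_back(nc == 1 ? st.g[0] : gsum);
    rec->push_back(st.M); rec->push_back(st.P);
  };
  record(0.0);

  while (true) {
    a[PHOS] = k_act * st.H;
    a[DEPHOS] = q.k_dephos * st.Hp;
    a[DEG] = q.k_deg_mrna * st.M;
    a[TL] = event_translation ? q.k_tl * st.M : 0.0;
    for (int c = 0; c < nc; ++c) {
      double* ac = &a[4 + 10 * c];
      for (int j = 0; j < 10; ++j) ac[j] = 0.0;
      switch (st.g[c]) {
        case 0: ac[TF_ON] = q.c_tfon * st.TFf; break;
        case 1: ac[TF_OFF] = q.k_off_tf;
                ac[HOG_ON] = q.c_hogon * st.Hp; break;
        case 2: ac[HOG_OFF] = q.k_off_hog;
                ac[REM_ON] = c_rem * st.Rf;
                ac[R8] = q.k_dephos; break;
        case 3: ac[REM_OFF] = q.k_off_rem;
                ac[POL_ON] = q.c_polon * st.Pf;
                ac[R8] = q.k_dephos; break;
        case 4: ac[POL_OFF] = q.k_off_pol;
                ac[TX] = q.k_tx;
                ac[R8] = q.k_dephos; break;
      }
    }
    // next channel to fire: smallest (remaining internal time) / rate
    int jmin = -1;
    double dt = R_PosInf;
    for (int j = 0; j < nch; ++j) {
      if (a[j] > 0.0) {
        double d = (nextP[j] - intA[j]) / a[j];
        if (d < dt) { dt = d; jmin = j; }
      }
    }
    if (jmin < 0 || t + dt >= q.t_end) {
      double rest = q.t_end - t;
      intM += st.M * rest;
      t = q.t_end;
      break;
    }
    for (int j = 0; j < nch; ++j) intA[j] += a[j] * dt;
    intM += st.M * dt;
    t += dt;
    nextP[jmin] += rng[jmin].rexp1();

    if (jmin < 4) {
      switch (jmin) {
        case PHOS: st.H -= 1; st.Hp += 1; break;
        case DEPHOS: st.Hp -= 1; st.H += 1; break;
        case DEG: st.M -= 1; break;
        case TL: st.P += 1; break;
      }
    } else {
      int c = (jmin - 4) / 10, kind = (jmin - 4) % 10;
      int& g = st.g[c];
      switch (kind) {
        case TF_ON: st.TFf -= 1; g = 1; break;
        case TF_OFF: st.TFf += 1; g = 0; break;
        case HOG_ON: st.Hp -= 1; g = 2; break;
        case HOG_OFF: st.Hp += 1; g = 1; break;
        case REM_ON: st.Rf -= 1; g = 3; break;
        case REM_OFF: st.Rf += 1; g = 2; break;
        case POL_ON: st.Pf -= 1; g = 4; break;
        case POL_OFF: st.Pf += 1; g = 3; break;
        case TX: st.M += 1; break;
        case R8:
          if (g == 3) st.Rf += 1;
          if (g == 4) { st.Rf += 1; st.Pf += 1; }
          st.H += 1; g = 1;
          break;
      }
    }
    record(t);
  }
  if (!event_translation) {
    Rng prng(seed, (uint64_t)cell * 64ULL + 63ULL);
    st.P = rpois_exact(prng, q.k_tl * intM);
  }
  record(q.t_end);
}

}  // namespace

// [[Rcpp::export]]
List ssa_population_cpp(List pars, int n_cells, double seed) {
  Pars q = read_pars(pars);
  IntegerVector protein(n_cells), mrna(n_cells);
  uint64_t s = (uint64_t)((int64_t)seed);
  CellState st;
  for (int i = 0; i < n_cells; ++i) {
    run_cell(q, s, i, st, nullptr);
    protein[i] = (int)st.P;
    mrna[i] = (int)st.M;
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["protein"] = protein, _["mrna"] = mrna);
}

// Full event record of a single cell's trajectory (for conservation and
// monotonicity checks). Columns: t, hog1, hog1p, tf_free, rem_free,
// pol_free, gene_state, mrna, protein.
// [[Rcpp::export]]
NumericMatrix ssa_trajectory_cpp(List pars, int cell_index, double seed) {
  Pars q = read_pars(pars);
  std::vector<double> rec;
  CellState st;
  run_cell(q, (uint64_t)((int64_t)seed), cell_index, st, &rec);
  int ncol = 9, nrow = (int)(rec.size() / ncol);
  NumericMatrix out(nrow, ncol);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < ncol; ++j) out(i, j) = rec[i * ncol + j];
  colnames(out) = CharacterVector::create(
    "t", "hog1", "hog1p", "tf_free", "rem_free", "pol_free",
    "gene_state", "mrna", "protein");
  return out;
}
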