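// Tick-loop core of the whole-cell translation engine.
//
// Each mRNA is a one-dimensional codon lattice carrying ribosomes with a
// physical footprint of s codons (exclusion, no overtaking). Dynamics are
// deterministic count-down timers whose durations are set, at state
// transitions, from the live supply-demand ratios: RSDR for initiation and
// the per-codon ESDR for A-site tRNA waits. Randomness enters only through
// the per-tick mRNA visiting order, the wobble choice among decoding tRNA
// species, and nothing else; all draws come from R's RNG so set.seed()
// makes runs bit-reproducible.
//
// Demand counters (mRNAs awaiting initiation, codons awaiting a tRNA, and
// the alpha-weighted per-species demand D_j) are maintained incrementally
// on every state transition, never by rescanning.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rib {
  int id;      // monotone placement id (order/no-overtaking checks)
  int pos;     // 1-based A-site codon
  int state;   // 0 = AWAIT_TRNA, 1 = ELONGATING (translocation pending)
  int timer;   // remaining ticks; 0 = ready to act (retries every tick)
  int cur;     // tRNA bound at the current codon (-1 none)
  int prev;    // tRNA one codon behind (released at next translocation)
};

}  // namespace

// [[Rcpp::export]]
List engine_run_cpp(List codon_seqs, IntegerVector gene_of,
                    NumericVector init_times, NumericMatrix alpha,
                    List decoders, NumericVector H_tot_per, double G_tot,
                    NumericVector exponent, List cfg, int ticks,
                    bool record_positions = false) {
  const int nL = codon_seqs.size();
  const int nT = H_tot_per.size();
  const int nC = alpha.nrow();

  const double dt = as<double>(cfg["dt"]);
  const int s = as<int>(cfg["s"]);
  const int transloc = std::max(1, as<int>(cfg["transloc_ticks"]));
  const double scale_e = as<double>(cfg["scale_elong"]);
  const double rsdr_ref = as<double>(cfg["rsdr_ref"]);
  const double eps = as<double>(cfg["sdr_floor"]);
  const double warn_wait = as<double>(cfg["warn_wait"]);

  std::vector<std::vector<int> > seqs(nL);
  int maxL = 0, n_genes = 0;
  for (int i = 0; i < nL; i++) {
    IntegerVector v = codon_seqs[i];
    if (v.size() < 1) stop("empty lattice");
    seqs[i].assign(v.begin(), v.end());
    for (size_t k = 0; k < seqs[i].size(); k++) seqs[i][k] -= 1;
    if ((int)seqs[i].size() > maxL) maxL = seqs[i].size();
    if (gene_of[i] > n_genes) n_genes = gene_of[i];
  }
  std::vector<std::vector<int> > dec(nC);
  for (int c = 0; c < nC; c++) {
    IntegerVector v = decoders[c];
    dec[c].assign(v.begin(), v.end());
    for (size_t k = 0; k < dec[c].size(); k++) dec[c][k] -= 1;
  }

  std::vector<double> Hfree(H_tot_per.begin(), H_tot_per.end());
  std::vector<double> boundT(nT, 0.0);
  double Gfree = G_tot, boundR = 0;
  double init_demand = 0;
  std::vector<double> cod_demand(nC, 0.0);
  std::vector<double> D(nT, 0.0);  // alpha-weighted demand per species

  std::vector<std::vector<Rib> > ribs(nL);   // ascending A-site position
  std::vector<int> init_state(nL, 0), init_timer(nL, 0);
  int next_id = 0;
  double warn_count = 0, inits = 0;

  NumericVector traj_G(ticks), traj_bR(ticks), traj_Hf(ticks), traj_bT(ticks);
  IntegerVector traj_term(ticks), traj_init(ticks);
  std::vector<std::vector<int> > term(n_genes);
  NumericMatrix occ(n_genes, maxL);
  NumericVector esdr_sum(nC);
  List pos_log(record_positions ? ticks : 0);

  std::vector<int> order(nL);
  for (int i = 0; i < nL; i++) order[i] = i;

  auto demand_add = [&](int c, double delta) {
    cod_demand[c] += delta;
    const std::vector<int> &dc = dec[c];
    for (size_t k = 0; k < dc.size(); k++)
      D[dc[k]] += alpha(c, dc[k]) * delta;
  };

  auto esdr_of = [&](int c) -> double {
    double total = 0.0;
    const double e = exponent[c];
    const std::vector<int> &dc = dec[c];
    for (size_t k = 0; k < dc.size(); k++) {
      int j = dc[k];
      double d = D[j] > 1.0 ? D[j] : 1.0;
      total += alpha(c, j) * Hfree[j] / std::pow(d, e);
    }
    return total;
  };

  auto sdr_ticks = [&](double T) -> int {
    if (T > warn_wait) warn_count += 1;
    int k = (int)std::lround(T / dt);
    return k < 1 ? 1 : k;
  };

  auto elong_ticks = [&](int c) -> int {
    double sdr = esdr_of(c);
    return sdr_ticks(scale_e / (sdr > eps ? sdr : eps));
  };

  auto release = [&](int j) {
    Hfree[j] += 1;
    boundT[j] -= 1;
    if (boundT[j] < 0) stop("accounting error: bound tRNA underflow");
  };

  for (int t = 1; t <= ticks; t++) {
    // fresh uniform visiting order (Fisher-Yates on R's RNG)
    for (int i = nL - 1; i > 0; i--) {
      int k = (int)(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(order[i], order[k]);
    }
    int n_term_tick = 0, n_init_tick = 0;

    for (int oi = 0; oi < nL; oi++) {
      const int li = order[oi];
      std::vector<Rib> &R = ribs[li];
      const std::vector<int> &sq = seqs[li];
      const int L = (int)sq.size();

      // --- initiation state machine ---
      if (init_state[li] == 0) {  // IDLE -> AWAIT_RIBOSOME
        init_state[li] = 1;
        init_demand += 1;
        double rs = Gfree / (init_demand > 1.0 ? init_demand : 1.0);
        init_timer[li] =
            sdr_ticks(init_times[li] * rsdr_ref / (rs > eps ? rs : eps));
      } else {
        if (init_timer[li] > 0) init_timer[li] -= 1;
        if (init_timer[li] == 0) {
          bool clear = R.empty() || R.front().pos > s;
          if (Gfree > 0 && clear) {
            Gfree -= 1;
            boundR += 1;
            init_demand -= 1;
            inits += 1;
            n_init_tick += 1;
            Rib r;
            r.id = next_id++;
            r.pos = 1;
            r.state = 0;
            r.cur = -1;
            r.prev = -1;
            demand_add(sq[0], +1);
            r.timer = elong_ticks(sq[0]);
            R.insert(R.begin(), r);
            init_state[li] = 0;  // back to IDLE; re-arms next tick
          }
          // else: conditions unmet at expiry -> delayed one tick (retry)
        }
      }

      // --- elongation: leading ribosome first (descending position) ---
      for (int i = (int)R.size() - 1; i >= 0; i--) {
        Rib &r = R[i];
        if (r.timer > 0) r.timer -= 1;
        if (r.timer > 0) continue;
        if (r.state == 0) {  // AWAIT_TRNA: attempt allocation
          const int c = sq[r.pos - 1];
          const std::vector<int> &dc = dec[c];
          int navail = 0, only = -1;
          double total = 0.0;
          for (size_t k = 0; k < dc.size(); k++) {
            if (Hfree[dc[k]] > 0) {
              navail++;
              only = dc[k];
              total += alpha(c, dc[k]) * Hfree[dc[k]];
            }
          }
          if (navail == 0) continue;  // starved: retry next tick
          int j = only;
          if (navail > 1) {  // wobble choice ~ alpha * H_free
            double u = unif_rand() * total, acc = 0.0;
            for (size_t k = 0; k < dc.size(); k++) {
              if (Hfree[dc[k]] > 0) {
                acc += alpha(c, dc[k]) * Hfree[dc[k]];
                if (u <= acc) { j = dc[k]; break; }
              }
            }
          }
          Hfree[j] -= 1;
          boundT[j] += 1;
          demand_add(c, -1);
          r.cur = j;
          r.state = 1;
          r.timer = transloc;
        } else {  // ELONGATING: translocate or terminate
          if (r.pos == L) {
            if (r.prev >= 0) release(r.prev);
            if (r.cur >= 0) release(r.cur);
            Gfree += 1;
            boundR -= 1;
            term[gene_of[li] - 1].push_back(t);
            n_term_tick += 1;
            R.erase(R.begin() + i);
            continue;
          }
          bool can = (i == (int)R.size() - 1) ||
                     (R[i + 1].pos - (r.pos + 1) >= s);
          if (!can) continue;  // BLOCKED: retry every tick
          if (r.prev >= 0) release(r.prev);
          r.prev = r.cur;
          r.cur = -1;
          r.pos += 1;
          const int c2 = sq[r.pos - 1];
          demand_add(c2, +1);
          r.state = 0;
          r.timer = elong_ticks(c2);
        }
      }
    }

    // --- end-of-tick accounting ---
    double Hf = 0, bT = 0;
    for (int j = 0; j < nT; j++) { Hf += Hfree[j]; bT += boundT[j]; }
    traj_G[t - 1] = Gfree;
    traj_bR[t - 1] = boundR;
    traj_Hf[t - 1] = Hf;
    traj_bT[t - 1] = bT;
    traj_term[t - 1] = n_term_tick;
    traj_init[t - 1] = n_init_tick;
    for (int li = 0; li < nL; li++) {
      const int g = gene_of[li] - 1;
      for (size_t k = 0; k < ribs[li].size(); k++)
        occ(g, ribs[li][k].pos - 1) += 1;
    }
    for (int c = 0; c < nC; c++) esdr_sum[c] += esdr_of(c);
    if (record_positions) {
      int n = 0;
      for (int li = 0; li < nL; li++) n += (int)ribs[li].size();
      IntegerMatrix pm(n, 3);
      int row = 0;
      for (int li = 0; li < nL; li++)
        for (size_t k = 0; k < ribs[li].size(); k++) {
          pm(row, 0) = li + 1;
          pm(row, 1) = ribs[li][k].id;
          pm(row, 2) = ribs[li][k].pos;
          row++;
        }
      pos_log[t - 1] = pm;
    }
  }

  List term_out(n_genes);
  for (int g = 0; g < n_genes; g++)
    term_out[g] = IntegerVector(term[g].begin(), term[g].end());
  List rib_out(nL);
  for (int li = 0; li < nL; li++) {
    const std::vector<Rib> &R = ribs[li];
    IntegerMatrix m((int)R.size(), 6);
    for (size_t k = 0; k < R.size(); k++) {
      m(k, 0) = R[k].id;
      m(k, 1) = R[k].pos;
      m(k, 2) = R[k].state;
      m(k, 3) = R[k].timer;
      m(k, 4) = R[k].cur + 1;   // 1-based, 0 = none
      m(k, 5) = R[k].prev + 1;
    }
    colnames(m) = CharacterVector::create("id", "pos", "state", "timer",
                                          "cur_trna", "prev_trna");
    rib_out[li] = m;
  }

  return List::create(
      _["traj"] = DataFrame::create(
          _["tick"] = seq_len(ticks), _["G_free"] = traj_G,
          _["bound_ribo"] = traj_bR, _["H_free_total"] = traj_Hf,
          _["bound_trna_total"] = traj_bT, _["n_init"] = traj_init,
          _["n_term"] = traj_term),
      _["term_ticks"] = term_out, _["occupancy"] = occ,
      _["esdr_mean"] = NumericVector(esdr_sum / (double)ticks),
      _["inits"] = inits, _["warn_count"] = warn_count,
      _["final"] = List::create(
          _["G_free"] = Gfree, _["bound_ribo"] = boundR,
          _["H_free"] = NumericVector(Hfree.begin(), Hfree.end()),
          _["bound_trna"] = NumericVector(boundT.begin(), boundT.end()),
          _["init_demand"] = init_demand,
          _["codon_demand"] = NumericVector(cod_demand.begin(),
                                            cod_demand.end()),
          _["init_state"] = IntegerVector(init_state.begin(),
                                          init_state.end()),
          _["init_timer"] = IntegerVector(init_timer.begin(),
                                          init_timer.end()),
          _["ribosomes"] = rib_out),
      _["positions"] = pos_log);
}
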