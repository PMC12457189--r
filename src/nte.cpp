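// Neural-surrogate-guided tree exploration: DUCB scoring, stochastic
// expansion, conditional selection, and local backpropagation over a
// persistent visitation table keyed by exact grid indices. Surrogate values
// are either computed directly from the in-memory conv net (fast path) or
// through an R callback (pluggable surrogates, used heavily in tests).
#include "net.h"
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef std::vector<int> Cand;  // 0-based grid indices, length d

static std::string cand_key(const Cand &c) {
  return std::string(reinterpret_cast<const char *>(c.data()),
                     c.size() * sizeof(int));
}

struct Trace {
  std::unordered_map<std::string, int> index;
  std::vector<Cand> cands;
  std::vector<int> visits;
  std::vector<double> preds;
  std::vector<char> touched;  // entry seen during this search call

  int lookup(const Cand &c) {
    std::string k = cand_key(c);
    auto it = index.find(k);
    if (it != index.end()) return it->second;
    int id = (int)cands.size();
    index.emplace(std::move(k), id);
    cands.push_back(c);
    visits.push_back(0);
    preds.push_back(NA_REAL);
    touched.push_back(0);
    return id;
  }
};

struct Predictor {
  Net *net = nullptr;
  Rcpp::Function *rfun = nullptr;
  const std::vector<arma::vec> *levels = nullptr;  // grid values per dim
  const std::vector<int> *nlev = nullptr;
  long n_evals = 0;

  // candidates -> standardized internal-convention values
  arma::vec eval(const std::vector<Cand> &cs) {
    int n = (int)cs.size();
    if (n == 0) return arma::vec();
    n_evals += n;
    int d = (int)cs[0].size();
    if (net) {
      arma::mat X(n, d);
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < d; ++j) {
          int m = (*nlev)[j];
          X(i, j) = m > 1 ? (double)cs[i][j] / (double)(m - 1) : 0.0;
        }
      }
      return net_predict(net, X);
    }
    IntegerMatrix idx(n, d);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < d; ++j) idx(i, j) = cs[i][j] + 1;  // 1-based for R
    }
    NumericVector out = (*rfun)(idx);
    return arma::vec(out.begin(), out.size());
  }
};

static double ducb_score(double v, double c0, double c_rho, int N, int n) {
  return v + c0 * c_rho * std::sqrt(2.0 * std::log((double)N) / (n + 1.0));
}

// One leaf proposal; returns true on success (leaf != root).
static bool propose_leaf(const Cand &root, Cand &leaf,
                         const std::vector<int> &nlev,
                         const std::vector<int> &mut_pos,
                         const NumericVector &mode_probs,
                         double frac_lo, double frac_hi,
                         int expand_kind, double p_fresh, int max_mut,
                         std::mt19937 &rng) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  leaf = root;
  int np = (int)mut_pos.size();
  auto rand_pos = [&]() { return mut_pos[(int)(U(rng) * np) % np]; };
  auto resample = [&](int j) {
    int m = nlev[j];
    int v;
    do { v = (int)(U(rng) * m) % m; } while (m > 1 && v == leaf[j]);
    leaf[j] = v;
  };

  if (expand_kind == 1) {  // sequence spaces: point mutations or fresh draw
    if (U(rng) < p_fresh) {
      for (int j : mut_pos) leaf[j] = (int)(U(rng) * nlev[j]) % nlev[j];
    } else {
      int m = 1 + (int)(U(rng) * max_mut) % std::max(max_mut, 1);
      for (int t = 0; t < m; ++t) resample(rand_pos());
    }
    return leaf != root;
  }

  double u = U(rng);
  if (u < mode_probs[0]) {  // one-step move
    int j = rand_pos();
    int dir = U(rng) < 0.5 ? -1 : 1;
    int v = root[j] + dir;
    if (v < 0 || v >= nlev[j]) v = root[j] - dir;
    if (v < 0 || v >= nlev[j]) return false;
    leaf[j] = v;
  } else if (u < mode_probs[0] + mode_probs[1]) {  // single mutation
    resample(rand_pos());
  } else {  // scaled random mutation
    double frac = frac_lo + U(rng) * (frac_hi - frac_lo);
    int m = std::max(1, (int)std::lround(frac * np));
    // sample m distinct positions (partial Fisher-Yates)
    std::vector<int> pool = mut_pos;
    for (int t = 0; t < m; ++t) {
      int r = t + (int)(U(rng) * (np - t)) % (np - t);
      std::swap(pool[t], pool[r]);
      resample(pool[t]);
    }
  }
  return leaf != root;
}

// [[Rcpp::export]]
List nte_search_cpp(SEXP net_ptr, SEXP r_predict, SEXP r_constraint,
                    IntegerVector n_levels, List level_values,
                    IntegerMatrix roots, int budget,
                    double c0, double c_rho,
                    NumericVector mode_probs, NumericVector frac_range,
                    bool cond_sel, bool local_bp,
                    int retry, double seed,
                    IntegerMatrix prev_cands, IntegerVector prev_visits,
                    IntegerVector mutable_pos, int trace_cap,
                    int expand_kind, double p_fresh, int max_mut) {
  int d = n_levels.size();
  std::vector<int> nlev(n_levels.begin(), n_levels.end());
  std::vector<arma::vec> levels(d);
  for (int j = 0; j < d; ++j) {
    NumericVector lv = level_values[j];
    levels[j] = arma::vec(lv.begin(), lv.size());
  }
  std::vector<int> mut_pos;
  for (int i = 0; i < mutable_pos.size(); ++i) mut_pos.push_back(mutable_pos[i] - 1);
  if (mut_pos.empty()) stop("no mutable positions: degenerate space");

  Predictor pred;
  std::unique_ptr<Rcpp::Function> rfun;
  if (!Rf_isNull(net_ptr)) {
    Rcpp::XPtr<Net> p(net_ptr);
    pred.net = p.get();
  } else {
    if (Rf_isNull(r_predict)) stop("need a surrogate");
    rfun.reset(new Rcpp::Function(r_predict));
    pred.rfun = rfun.get();
  }
  pred.levels = &levels;
  pred.nlev = &nlev;

  bool has_constraint = !Rf_isNull(r_constraint);
  std::unique_ptr<Rcpp::Function> cfun;
  if (has_constraint) cfun.reset(new Rcpp::Function(r_constraint));
  auto feasible = [&](const Cand &c) -> bool {
    if (!has_constraint) return true;
    IntegerVector idx(d);
    for (int j = 0; j < d; ++j) idx[j] = c[j] + 1;
    LogicalVector ok = (*cfun)(idx);
    return ok[0] == TRUE;
  };

  std::mt19937 rng((unsigned long)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  Trace tr;
  for (int i = 0; i < prev_cands.nrow(); ++i) {
    Cand c(d);
    for (int j = 0; j < d; ++j) c[j] = prev_cands(i, j) - 1;
    int id = tr.lookup(c);
    tr.visits[id] = prev_visits[i];
  }

  int n_roots = roots.nrow();
  if (n_roots == 0) stop("need at least one root");
  int per_root = budget / std::max(n_roots, 1);
  std::vector<int> root_log;  // trace id of root after each rollout
  int rollouts_done = 0;

  for (int r = 0; r < n_roots; ++r) {
    Cand root(d);
    for (int j = 0; j < d; ++j) root[j] = roots(r, j) - 1;
    int root_id = tr.lookup(root);
    tr.touched[root_id] = 1;
    if (tr.visits[root_id] < 1) tr.visits[root_id] = 1;  // roots start visited
    if (!std::isfinite(tr.preds[root_id]) || ISNA(tr.preds[root_id])) {
      arma::vec v = pred.eval({root});
      tr.preds[root_id] = v(0);
    }
    int n_roll = (r == n_roots - 1) ? budget - per_root * (n_roots - 1) : per_root;

    for (int it = 0; it < n_roll; ++it) {
      // --- stochastic expansion: d leaves ---
      std::vector<int> leaf_ids;
      leaf_ids.reserve(d);
      for (int j = 0; j < d; ++j) {
        Cand leaf;
        bool ok = false;
        for (int att = 0; att < retry; ++att) {
          if (propose_leaf(root, leaf, nlev, mut_pos, mode_probs,
                           frac_range[0], frac_range[1],
                           expand_kind, p_fresh, max_mut, rng) &&
              feasible(leaf)) {
            ok = true;
            break;
          }
        }
        if (ok) leaf_ids.push_back(tr.lookup(leaf));
      }
      if (leaf_ids.empty()) { ++rollouts_done; root_log.push_back(root_id); continue; }

      // --- surrogate scores (cached within this search call) ---
      std::vector<Cand> need;
      std::vector<int> need_ids;
      for (int id : leaf_ids) {
        if (ISNA(tr.preds[id]) || !std::isfinite(tr.preds[id])) {
          need.push_back(tr.cands[id]);
          need_ids.push_back(id);
        }
      }
      if (!need.empty()) {
        arma::vec v = pred.eval(need);
        for (size_t i = 0; i < need_ids.size(); ++i) tr.preds[need_ids[i]] = v(i);
      }
      for (int id : leaf_ids) tr.touched[id] = 1;

      // --- DUCB + conditional selection ---
      int N = tr.visits[root_id];
      double root_ducb = ducb_score(tr.preds[root_id], c0, c_rho, N, N);
      double best = -arma::datum::inf;
      std::vector<int> argmax;
      for (int id : leaf_ids) {
        double pv = tr.preds[id];
        if (!std::isfinite(pv)) continue;  // non-finite scores never win
        double s = ducb_score(pv, c0, c_rho, N, tr.visits[id]);
        if (s > best + 1e-12) {
          best = s;
          argmax.clear();
          argmax.push_back(id);
        } else if (std::abs(s - best) <= 1e-12) {
          argmax.push_back(id);
        }
      }
      int selected;
      if (argmax.empty()) {
        selected = root_id;
      } else {
        int pick = argmax[(int)(U(rng) * argmax.size()) % argmax.size()];
        if (cond_sel) {
          selected = (best > root_ducb + 1e-12) ? pick : root_id;
        } else {
          selected = pick;  // ablation: always move to the max-DUCB leaf
        }
      }

      // --- local backpropagation ---
      if (local_bp) {
        tr.visits[root_id] += 1;
        if (selected != root_id) tr.visits[selected] += 1;
        tr.touched[root_id] = 1;
        tr.touched[selected] = 1;
      }

      if (selected != root_id) {
        root = tr.cands[selected];
        root_id = selected;
        if (local_bp && tr.visits[root_id] < 1) tr.visits[root_id] = 1;
      }
      root_log.push_back(root_id);
      ++rollouts_done;
    }
  }

  // --- assemble output ---
  // trace rows: entries touched during THIS call (visited ones plus the
  // best-scored unvisited up to the cap); the full visitation table is
  // returned separately for persistence across calls
  int n_all = (int)tr.cands.size();
  std::vector<int> keep;
  std::vector<int> scored_only;
  for (int i = 0; i < n_all; ++i) {
    if (!tr.touched[i]) continue;
    if (tr.visits[i] > 0) keep.push_back(i);
    else if (std::isfinite(tr.preds[i])) scored_only.push_back(i);
  }
  if ((int)scored_only.size() > trace_cap) {
    std::nth_element(scored_only.begin(), scored_only.begin() + trace_cap,
                     scored_only.end(), [&](int a, int b) {
                       return tr.preds[a] > tr.preds[b];
                     });
    scored_only.resize(trace_cap);
  }
  keep.insert(keep.end(), scored_only.begin(), scored_only.end());

  int n_out = (int)keep.size();
  IntegerMatrix out_cands(n_out, d);
  IntegerVector out_visits(n_out);
  NumericVector out_preds(n_out);
  for (int i = 0; i < n_out; ++i) {
    const Cand &c = tr.cands[keep[i]];
    for (int j = 0; j < d; ++j) out_cands(i, j) = c[j] + 1;
    out_visits[i] = tr.visits[keep[i]];
    out_preds[i] = tr.preds[keep[i]];
  }

  IntegerVector out_root_log(root_log.size());
  for (size_t i = 0; i < root_log.size(); ++i) {
    // report 1-based position in the kept set when present, NA otherwise
    out_root_log[i] = NA_INTEGER;
  }
  std::unordered_map<int, int> keep_pos;
  for (int i = 0; i < n_out; ++i) keep_pos[keep[i]] = i + 1;
  for (size_t i = 0; i < root_log.size(); ++i) {
    auto it = keep_pos.find(root_log[i]);
    if (it != keep_pos.end()) out_root_log[i] = it->second;
  }

  // persistent visitation table: every entry ever visited
  int n_tab = 0;
  for (int i = 0; i < n_all; ++i) if (tr.visits[i] > 0) ++n_tab;
  IntegerMatrix tab_cands(n_tab, d);
  IntegerVector tab_visits(n_tab);
  int r2 = 0;
  for (int i = 0; i < n_all; ++i) {
    if (tr.visits[i] > 0) {
      for (int j = 0; j < d; ++j) tab_cands(r2, j) = tr.cands[i][j] + 1;
      tab_visits[r2] = tr.visits[i];
      ++r2;
    }
  }

  return List::create(
      _["cands"] = out_cands,
      _["visits"] = out_visits,
      _["preds"] = out_preds,
      _["table_cands"] = tab_cands,
      _["table_visits"] = tab_visits,
      _["root_log"] = out_root_log,
      _["n_evals"] = (double)pred.n_evals,
      _["rollouts"] = rollouts_done);
}
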