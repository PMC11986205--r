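// Scaled event-based model core: joint state is a balanced partition of
// biomarkers into K clusters of fixed size plus a permutation of the
// clusters (the event order). The data enter only through per-subject,
// per-biomarker log densities under the "normal" and "abnormal" mixture
// components, precomputed in R. A subject at stage s has all biomarkers in
// clusters at order positions <= s abnormal, the rest normal; the stage is
// marginalised under a uniform prior over 0..K.
//
// All randomness uses R's RNG (unif_rand) so results are reproducible
// under set.seed().
#include <Rcpp.h>
#include <cmath>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

struct EbmData {
  int n, b, k;
  std::vector<double> diff;  // n x b, logA - logN
  std::vector<double> totN;  // n, rowSums(logN)
};

// cluster "delta" matrix: n x k, column c = sum over biomarkers assigned
// to cluster c of (logA - logN)
void compute_delta(const EbmData& dat, const std::vector<int>& assign,
                   std::vector<double>& delta) {
  std::fill(delta.begin(), delta.end(), 0.0);
  for (int j = 0; j < dat.b; ++j) {
    const int c = assign[j];
    for (int i = 0; i < dat.n; ++i) {
      delta[static_cast<size_t>(c) * dat.n + i] +=
        dat.diff[static_cast<size_t>(j) * dat.n + i];
    }
  }
}

// total log-likelihood given cluster deltas and an order over clusters
double loglik_from_delta(const EbmData& dat, const std::vector<double>& delta,
                         const std::vector<int>& order) {
  const int k = dat.k;
  const double logprior = -std::log(static_cast<double>(k + 1));
  double total = 0.0;
  std::vector<double> stage_ll(k + 1);
  for (int i = 0; i < dat.n; ++i) {
    double acc = dat.totN[i];
    stage_ll[0] = acc;
    double best = acc;
    for (int p = 0; p < k; ++p) {
      acc += delta[static_cast<size_t>(order[p]) * dat.n + i];
      stage_ll[p + 1] = acc;
      if (acc > best) best = acc;
    }
    double s = 0.0;
    for (int st = 0; st <= k; ++st) s += std::exp(stage_ll[st] - best);
    total += best + std::log(s) + logprior;
  }
  return total;
}

double eval_state(const EbmData& dat, const std::vector<int>& assign,
                  const std::vector<int>& order,
                  std::vector<double>& delta_buf) {
  compute_delta(dat, assign, delta_buf);
  return loglik_from_delta(dat, delta_buf, order);
}

int rand_int(int n) {  // uniform on 0..n-1 via R's RNG
  int r;
  do {
    r = static_cast<int>(unif_rand() * n);
  } while (r >= n);
  return r;
}

void shuffle_vec(std::vector<int>& v) {
  for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
    const int j = rand_int(i + 1);
    std::swap(v[i], v[j]);
  }
}

EbmData make_data(const NumericMatrix& logN, const NumericMatrix& logA,
                  int k) {
  EbmData dat;
  dat.n = logN.nrow();
  dat.b = logN.ncol();
  dat.k = k;
  dat.diff.resize(static_cast<size_t>(dat.n) * dat.b);
  dat.totN.assign(dat.n, 0.0);
  for (int j = 0; j < dat.b; ++j) {
    for (int i = 0; i < dat.n; ++i) {
      dat.diff[static_cast<size_t>(j) * dat.n + i] = logA(i, j) - logN(i, j);
      dat.totN[i] += logN(i, j);
    }
  }
  return dat;
}

}  // namespace

// [[Rcpp::export]]
double ebm_loglik_cpp(NumericMatrix logN, NumericMatrix logA,
                      IntegerVector assign, IntegerVector order) {
  const int k = order.size();
  EbmData dat = make_data(logN, logA, k);
  std::vector<int> a(assign.begin(), assign.end());
  std::vector<int> o(order.begin(), order.end());
  for (auto& v : a) --v;  // to 0-based
  for (auto& v : o) --v;
  std::vector<double> delta(static_cast<size_t>(dat.n) * k);
  return eval_state(dat, a, o, delta);
}

// Greedy search: for each random start, repeatedly propose a sampled set
// of candidate moves (order swaps / cross-cluster biomarker swaps), take
// the best candidate, accept only if it improves the likelihood.
// [[Rcpp::export]]
List ebm_greedy_cpp(NumericMatrix logN, NumericMatrix logA, int k,
                    int cluster_size, int n_starts, int n_iter,
                    int n_candidates) {
  EbmData dat = make_data(logN, logA, k);
  const int b = dat.b;
  std::vector<double> delta(static_cast<size_t>(dat.n) * k);

  std::vector<int> best_assign, best_order;
  double best_ll = R_NegInf;

  for (int s = 0; s < n_starts; ++s) {
    std::vector<int> perm(b);
    for (int j = 0; j < b; ++j) perm[j] = j;
    shuffle_vec(perm);
    std::vector<int> assign(b);
    for (int j = 0; j < b; ++j) assign[perm[j]] = j / cluster_size;
    std::vector<int> order(k);
    for (int c = 0; c < k; ++c) order[c] = c;
    shuffle_vec(order);
    double ll = eval_state(dat, assign, order, delta);

    for (int it = 0; it < n_iter; ++it) {
      double cand_best_ll = R_NegInf;
      std::vector<int> cand_assign, cand_order;
      for (int c = 0; c < n_candidates; ++c) {
        std::vector<int> a2 = assign, o2 = order;
        if (unif_rand() < 0.5 && k >= 2) {
          int p1 = rand_int(k), p2 = rand_int(k);
          while (p2 == p1) p2 = rand_int(k);
          std::swap(o2[p1], o2[p2]);
        } else {
          int j1 = rand_int(b), j2 = rand_int(b);
          while (a2[j2] == a2[j1]) j2 = rand_int(b);
          std::swap(a2[j1], a2[j2]);
        }
        const double l2 = eval_state(dat, a2, o2, delta);
        if (l2 > cand_best_ll) {
          cand_best_ll = l2;
          cand_assign = a2;
          cand_order = o2;
        }
      }
      if (cand_best_ll > ll) {
        ll = cand_best_ll;
        assign = cand_assign;
        order = cand_order;
      }
    }
    if (ll > best_ll) {
      best_ll = ll;
      best_assign = assign;
      best_order = order;
    }
  }
  IntegerVector a_out(best_assign.begin(), best_assign.end());
  IntegerVector o_out(best_order.begin(), best_order.end());
  for (auto& v : a_out) v += 1;
  for (auto& v : o_out) v += 1;
  return List::create(_["assign"] = a_out, _["order"] = o_out,
                      _["loglik"] = best_ll);
}

// Metropolis MCMC with symmetric proposals (50/50 order swap vs
// cross-cluster biomarker swap). Returns retained post-burn-in samples,
// the modal state (most frequent; ties broken by likelihood), positional
// counts and the acceptance rate.
// [[Rcpp::export]]
List ebm_mcmc_cpp(NumericMatrix logN, NumericMatrix logA,
                  IntegerVector assign0, IntegerVector order0,
                  int n_iter, int burn_in) {
  const int k = order0.size();
  EbmData dat = make_data(logN, logA, k);
  const int b = dat.b;
  std::vector<double> delta(static_cast<size_t>(dat.n) * k);

  std::vector<int> assign(assign0.begin(), assign0.end());
  std::vector<int> order(order0.begin(), order0.end());
  for (auto& v : assign) --v;
  for (auto& v : order) --v;
  double ll = eval_state(dat, assign, order, delta);

  const int n_keep = n_iter - burn_in;
  IntegerMatrix order_samples(n_keep, k);
  IntegerMatrix assign_samples(n_keep, b);
  NumericVector ll_samples(n_keep);
  // positional counts: cluster c observed at position p (post burn-in)
  IntegerMatrix pos_counts(k, k);          // clusters x positions
  IntegerMatrix bm_pos_counts(b, k);       // biomarkers x positions

  std::map<std::string, int> state_count;
  std::map<std::string, double> state_ll;
  long accepted = 0;

  for (int it = 0; it < n_iter; ++it) {
    std::vector<int> a2 = assign, o2 = order;
    if (unif_rand() < 0.5 && k >= 2) {
      int p1 = rand_int(k), p2 = rand_int(k);
      while (p2 == p1) p2 = rand_int(k);
      std::swap(o2[p1], o2[p2]);
    } else {
      int j1 = rand_int(b), j2 = rand_int(b);
      while (a2[j2] == a2[j1]) j2 = rand_int(b);
      std::swap(a2[j1], a2[j2]);
    }
    const double l2 = eval_state(dat, a2, o2, delta);
    if (l2 >= ll || unif_rand() < std::exp(l2 - ll)) {
      assign = a2;
      order = o2;
      ll = l2;
      ++accepted;
    }
    if (it >= burn_in) {
      const int row = it - burn_in;
      std::string key;
      key.reserve(2 * (k + b));
      std::vector<int> pos_of_cluster(k);
      for (int p = 0; p < k; ++p) {
        order_samples(row, p) = order[p] + 1;
        pos_counts(order[p], p) += 1;
        pos_of_cluster[order[p]] = p;
        key += static_cast<char>('A' + order[p]);
      }
      key += '|';
      for (int j = 0; j < b; ++j) {
        assign_samples(row, j) = assign[j] + 1;
        bm_pos_counts(j, pos_of_cluster[assign[j]]) += 1;
        key += static_cast<char>('A' + assign[j]);
      }
      ll_samples[row] = ll;
      auto& cnt = state_count[key];
      cnt += 1;
      auto fit = state_ll.find(key);
      if (fit == state_ll.end() || ll > fit->second) state_ll[key] = ll;
    }
  }

  // modal state: highest count, ties -> higher likelihood
  std::string best_key;
  int best_cnt = -1;
  double best_state_ll = R_NegInf;
  for (const auto& kv : state_count) {
    const double sll = state_ll[kv.first];
    if (kv.second > best_cnt ||
        (kv.second == best_cnt && sll > best_state_ll)) {
      best_cnt = kv.second;
      best_state_ll = sll;
      best_key = kv.first;
    }
  }
  IntegerVector modal_order(k), modal_assign(b);
  for (int p = 0; p < k; ++p) modal_order[p] = best_key[p] - 'A' + 1;
  for (int j = 0; j < b; ++j) modal_assign[j] = best_key[k + 1 + j] - 'A' + 1;

  return List::create(
    _["order_samples"] = order_samples,
    _["assign_samples"] = assign_samples,
    _["loglik_samples"] = ll_samples,
    _["modal_order"] = modal_order,
    _["modal_assign"] = modal_assign,
    _["modal_count"] = best_cnt,
    _["modal_loglik"] = best_state_ll,
    _["pos_counts"] = pos_counts,
    _["biomarker_pos_counts"] = bm_pos_counts,
    _["acceptance_rate"] = static_cast<double>(accepted) / n_iter);
}
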