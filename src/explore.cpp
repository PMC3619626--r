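// Exploration engine: simulates one agent exploring a CMC, maintaining its
// Bayesian posterior-mean model, per-row one-step utilities, and the
// missing-information learning curve.  The R-level functions in R/ define
// (and unit-test) each component in isolation; this loop exists so that
// batch experiments over hundreds of worlds and thousands of steps run in
// seconds.  All randomness comes from R's RNG stream, so runs are
// reproducible with set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double log2d(double x) { return std::log(x) / M_LN2; }

namespace {

// strategy codes (keep in sync with R/strategies.R)
enum Strategy { RANDOM = 0, UNEMBODIED = 1, GREEDY = 2, VI = 3,
                LTA = 4, CB = 5, PEIGQ = 6 };
enum Utility { PIG = 0, PMC = 1, PLC = 2 };
enum Prior { DIRICHLET = 0, ONETWOTHREE = 1 };

struct Engine {
  int N, M;
  const double* theta;          // truth, idx (a*N + s)*N + sp
  int prior;                    // Prior enum
  double alpha;
  const double* alpha_t;        // optional per-row concentration tensor
  std::vector<double> alpha_rowsum;
  std::vector<int> counts;      // (a*N+s)*N + sp
  std::vector<int> rowtot;      // a*N + s
  std::vector<double> that;     // model, same layout as theta

  Engine(int N_, int M_, const double* th, int prior_, double alpha_,
         const double* alpha_t_)
      : N(N_), M(M_), theta(th), prior(prior_), alpha(alpha_),
        alpha_t(alpha_t_),
        counts(M_ * N_ * N_, 0), rowtot(M_ * N_, 0), that(M_ * N_ * N_, 0.0) {
    if (alpha_t) {
      alpha_rowsum.assign(M * N, 0.0);
      for (int r = 0; r < M * N; ++r)
        for (int i = 0; i < N; ++i) alpha_rowsum[r] += alpha_t[r * N + i];
    }
    for (int a = 0; a < M; ++a)
      for (int s = 0; s < N; ++s) posterior_row(a, s, &that[(a * N + s) * N]);
  }

  // posterior-mean row, optionally with one extra hypothetical count
  void posterior_row(int a, int s, double* out, int extra = -1) const {
    const int* c = &counts[(a * N + s) * N];
    if (prior == DIRICHLET) {
      double tot = rowtot[a * N + s] + (extra >= 0 ? 1 : 0);
      if (alpha_t) {
        const double* al = &alpha_t[(a * N + s) * N];
        double denom = tot + alpha_rowsum[a * N + s];
        for (int i = 0; i < N; ++i)
          out[i] = (c[i] + (i == extra ? 1 : 0) + al[i]) / denom;
        return;
      }
      double denom = tot + N * alpha;
      for (int i = 0; i < N; ++i)
        out[i] = (c[i] + (i == extra ? 1 : 0) + alpha) / denom;
    } else {
      int a_label = a + 1;                  // support size equals label
      int k = 0;
      std::vector<char> obs(N, 0);
      for (int i = 0; i < N; ++i)
        if (c[i] > 0 || i == extra) { obs[i] = 1; ++k; }
      double p_unobs = (k >= a_label) ? 0.0
                       : double(a_label - k) / (double(a_label) * (N - k));
      for (int i = 0; i < N; ++i)
        out[i] = obs[i] ? 1.0 / a_label : p_unobs;
    }
  }

  // one-step predicted change of row (a, s) under the current model
  double util_row(int a, int s, int utility) const {
    const double* cur = &that[(a * N + s) * N];
    std::vector<double> hyp(N);
    double total = 0.0;
    for (int sstar = 0; sstar < N; ++sstar) {
      double w = cur[sstar];
      if (w <= 0.0) continue;               // impossible outcome
      if (prior == ONETWOTHREE && counts[(a * N + s) * N + sstar] > 0)
        continue;                           // re-observation changes nothing
      posterior_row(a, s, hyp.data(), sstar);
      double d = 0.0;
      if (utility == PIG) {
        for (int i = 0; i < N; ++i)
          if (hyp[i] > 0.0) d += hyp[i] * log2d(hyp[i] / cur[i]);
      } else if (utility == PMC) {
        double mh = 0.0, mc = 0.0;
        for (int i = 0; i < N; ++i) {
          if (hyp[i] > mh) mh = hyp[i];
          if (cur[i] > mc) mc = cur[i];
        }
        d = mh - mc;
      } else {                              // PLC
        for (int i = 0; i < N; ++i) d += std::fabs(hyp[i] - cur[i]);
        d /= N;
      }
      total += w * d;
    }
    return total;
  }

  // KL(truth row || model row), bits
  double row_kl_truth(int a, int s) const {
    const double* t = &theta[(a * N + s) * N];
    const double* m = &that[(a * N + s) * N];
    double d = 0.0;
    for (int i = 0; i < N; ++i)
      if (t[i] > 0.0) d += t[i] * log2d(t[i] / m[i]);
    return d;
  }
};

int sample_row(const double* p, int n) {
  double u = unif_rand(), cum = 0.0;
  int last = 0;
  for (int i = 0; i < n; ++i) {
    if (p[i] <= 0.0) continue;
    cum += p[i];
    last = i;
    if (u <= cum) return i;
  }
  return last;
}

int argmax_tie(const double* x, int n) {
  double best = x[0];
  for (int i = 1; i < n; ++i) if (x[i] > best) best = x[i];
  int ties = 0;
  for (int i = 0; i < n; ++i) if (x[i] == best) ++ties;
  if (ties == 1) {
    for (int i = 0; i < n; ++i) if (x[i] == best) return i;
  }
  int pick = (int)(unif_rand() * ties);
  if (pick >= ties) pick = ties - 1;
  for (int i = 0; i < n; ++i)
    if (x[i] == best && pick-- == 0) return i;
  return n - 1;
}

// finite-horizon value iteration: Q = U, then `horizon` backups of
// Q(a,s) <- U(a,s) + gamma * sum_sp K(a,s,sp) * max_a' Q(a',sp)
void value_iterate_q(const std::vector<double>& U, const double* K,
                     int N, int M, double gamma, int horizon,
                     std::vector<double>& Q, std::vector<double>& vmax) {
  Q = U;
  for (int it = 0; it < horizon; ++it) {
    for (int s = 0; s < N; ++s) {
      double b = Q[s];
      for (int a = 1; a < M; ++a) b = std::max(b, Q[a * N + s]);
      vmax[s] = b;
    }
    for (int a = 0; a < M; ++a)
      for (int s = 0; s < N; ++s) {
        const double* k = &K[(a * N + s) * N];
        double acc = 0.0;
        for (int sp = 0; sp < N; ++sp) acc += k[sp] * vmax[sp];
        Q[a * N + s] = U[a * N + s] + gamma * acc;
      }
  }
}

}  // namespace

// [[Rcpp::export]]
List explore_core(NumericVector theta_flat, int N, int M,
                  int n_steps, int eval_every,
                  int strategy, int utility,
                  int prior_family, double alpha, NumericVector alpha_flat,
                  bool vi_true_kernel, double gamma, int horizon,
                  double lr, double epsilon,
                  int s0) {
  const double* alpha_t =
      (alpha_flat.size() == theta_flat.size()) ? alpha_flat.begin() : nullptr;
  Engine eng(N, M, theta_flat.begin(), prior_family, alpha, alpha_t);

  const bool uses_util = (strategy == UNEMBODIED || strategy == GREEDY ||
                          strategy == VI);
  const int util_kind = (strategy == UNEMBODIED) ? PIG : utility;

  std::vector<double> util(M * N, 0.0);
  if (uses_util)
    for (int a = 0; a < M; ++a)
      for (int s = 0; s < N; ++s)
        util[a * N + s] = eng.util_row(a, s, util_kind);

  std::vector<double> rowkl(M * N);
  double im = 0.0;
  for (int a = 0; a < M; ++a)
    for (int s = 0; s < N; ++s) {
      rowkl[a * N + s] = eng.row_kl_truth(a, s);
      im += rowkl[a * N + s];
    }

  std::vector<int> acount;                       // LTA
  if (strategy == LTA) acount.assign(M * N, 0);
  std::vector<double> cbcount;                   // CB state-visit counts
  if (strategy == CB) { cbcount.assign(N, 0.0); cbcount[s0] = 1.0; }
  std::vector<double> q;                         // PEIG(Q)
  if (strategy == PEIGQ) q.assign(M * N, 0.0);

  std::vector<double> Q, vmax, avals(M), oldrow;
  if (strategy == VI) { Q.resize(M * N); vmax.resize(N); }
  if (strategy == PEIGQ) oldrow.resize(N);

  IntegerVector states(n_steps + 1), actions(std::max(n_steps, 0)),
      origins(std::max(n_steps, 0));
  std::vector<int> eval_steps;
  std::vector<double> im_curve;
  int s = s0;
  states[0] = s + 1;
  eval_steps.push_back(0);
  im_curve.push_back(im);

  for (int t = 1; t <= n_steps; ++t) {
    int a = 0;
    switch (strategy) {
      case RANDOM: {
        a = (int)(unif_rand() * M);
        if (a >= M) a = M - 1;
        break;
      }
      case UNEMBODIED: {                        // teleport to global argmax
        int idx = argmax_tie(util.data(), M * N);
        a = idx / N;
        s = idx % N;
        break;
      }
      case GREEDY: {
        for (int aa = 0; aa < M; ++aa) avals[aa] = util[aa * N + s];
        a = argmax_tie(avals.data(), M);
        break;
      }
      case VI: {
        const double* K = vi_true_kernel ? theta_flat.begin() : eng.that.data();
        value_iterate_q(util, K, N, M, gamma, horizon, Q, vmax);
        for (int aa = 0; aa < M; ++aa) avals[aa] = Q[aa * N + s];
        a = argmax_tie(avals.data(), M);
        break;
      }
      case LTA: {
        for (int aa = 0; aa < M; ++aa) avals[aa] = -double(acount[aa * N + s]);
        a = argmax_tie(avals.data(), M);
        acount[a * N + s] += 1;
        break;
      }
      case CB: {
        for (int aa = 0; aa < M; ++aa) {
          const double* row = &eng.that[(aa * N + s) * N];
          double e = 0.0;
          for (int sp = 0; sp < N; ++sp) e += row[sp] * cbcount[sp];
          avals[aa] = -e;
        }
        a = argmax_tie(avals.data(), M);
        break;
      }
      case PEIGQ: {
        if (unif_rand() < epsilon) {
          a = (int)(unif_rand() * M);
          if (a >= M) a = M - 1;
        } else {
          for (int aa = 0; aa < M; ++aa) avals[aa] = q[aa * N + s];
          a = argmax_tie(avals.data(), M);
        }
        break;
      }
    }

    const int sp = sample_row(&theta_flat[(a * N + s) * N], N);

    if (strategy == PEIGQ)
      std::copy(&eng.that[(a * N + s) * N], &eng.that[(a * N + s) * N] + N,
                oldrow.begin());

    eng.counts[(a * N + s) * N + sp] += 1;
    eng.rowtot[a * N + s] += 1;
    eng.posterior_row(a, s, &eng.that[(a * N + s) * N]);

    if (uses_util) util[a * N + s] = eng.util_row(a, s, util_kind);

    if (strategy == PEIGQ) {
      const double* nr = &eng.that[(a * N + s) * N];
      double r = 0.0;                           // PEIG = KL(new || old)
      for (int i = 0; i < N; ++i)
        if (nr[i] > 0.0) r += nr[i] * log2d(nr[i] / oldrow[i]);
      double qn = q[sp];                        // max_a' q(a', sp)
      for (int aa = 1; aa < M; ++aa) qn = std::max(qn, q[aa * N + sp]);
      q[a * N + s] = (1.0 - lr) * q[a * N + s] + lr * (r + gamma * qn);
    }

    double kl_new = eng.row_kl_truth(a, s);
    im += kl_new - rowkl[a * N + s];
    rowkl[a * N + s] = kl_new;

    if (strategy == CB) cbcount[sp] += 1.0;

    actions[t - 1] = a + 1;
    origins[t - 1] = s + 1;             // teleports make this != states[t-1]
    states[t] = sp + 1;
    s = sp;

    if (t % eval_every == 0 || t == n_steps) {
      eval_steps.push_back(t);
      im_curve.push_back(std::max(im, 0.0));  // guard float drift at ~1e-13
    }
  }

  return List::create(
      _["states"] = states,
      _["actions"] = actions,
      _["origins"] = origins,
      _["eval_steps"] = wrap(eval_steps),
      _["missing_info"] = wrap(im_curve),
      _["theta_hat"] = wrap(eng.that),
      _["counts"] = wrap(eng.counts));
}
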