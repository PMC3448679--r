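#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward pass for one sequence. Returns log-likelihood and, if
// alpha_out != nullptr, the filtered state distributions (rows = time).
static double forward_seq(const IntegerVector &obs,
                          const NumericVector &init,
                          const NumericMatrix &trans,
                          const NumericMatrix &emis,
                          NumericMatrix *alpha_out) {
  const int T = obs.size();
  const int K = init.size();
  std::vector<double> alpha(K), tmp(K);
  double ll = 0.0;

  for (int k = 0; k < K; ++k) alpha[k] = init[k] * emis(k, obs[0]);
  double c = 0.0;
  for (int k = 0; k < K; ++k) c += alpha[k];
  if (c <= 0) return R_NegInf;
  for (int k = 0; k < K; ++k) alpha[k] /= c;
  ll += std::log(c);
  if (alpha_out) for (int k = 0; k < K; ++k) (*alpha_out)(0, k) = alpha[k];

  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha[i] * trans(i, j);
      tmp[j] = s * emis(j, obs[t]);
    }
    c = 0.0;
    for (int k = 0; k < K; ++k) c += tmp[k];
    if (c <= 0) return R_NegInf;
    for (int k = 0; k < K; ++k) alpha[k] = tmp[k] / c;
    ll += std::log(c);
    if (alpha_out) for (int k = 0; k < K; ++k) (*alpha_out)(t, k) = alpha[k];
  }
  return ll;
}

// [[Rcpp::export]]
double hmm_loglik_cpp(List seqs, NumericVector init, NumericMatrix trans,
                      NumericMatrix emis) {
  double ll = 0.0;
  for (int s = 0; s < seqs.size(); ++s) {
    IntegerVector obs = seqs[s];
    ll += forward_seq(obs, init, trans, emis, nullptr);
  }
  return ll;
}

// Filtered state distributions after each prefix of one sequence.
// [[Rcpp::export]]
NumericMatrix hmm_filter_cpp(IntegerVector obs, NumericVector init,
                             NumericMatrix trans, NumericMatrix emis) {
  NumericMatrix alpha(obs.size(), init.size());
  forward_seq(obs, init, trans, emis, &alpha);
  return alpha;
}

// Baum-Welch EM for discrete-emission HMMs over a list of 0-based
// integer sequences. Parameters are kept in flat row-major arrays and
// all per-sequence buffers are allocated once, outside the EM loop.
// Emission rows are re-estimated with a small Dirichlet pseudo-count
// ('smooth') so held-out symbols never hit an exact zero;
// transition/initial rows get a miniscule floor purely to guard against
// 0/0 on states that lose all occupancy.
// [[Rcpp::export]]
List baum_welch_cpp(List seqs, NumericVector init0, NumericMatrix trans0,
                    NumericMatrix emis0, int max_iter, double tol,
                    double smooth) {
  const int K = init0.size();
  const int M = emis0.ncol();
  const int S = seqs.size();

  // flat row-major copies: trans[i*K+j], emis[i*M+m]
  std::vector<double> init(K), trans(K * K), emis(K * M);
  for (int k = 0; k < K; ++k) init[k] = init0[k];
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) trans[i * K + j] = trans0(i, j);
  for (int i = 0; i < K; ++i)
    for (int m = 0; m < M; ++m) emis[i * M + m] = emis0(i, m);

  // cache sequences and the longest length
  std::vector<std::vector<int>> obs_all(S);
  int Tmax = 1;
  for (int s = 0; s < S; ++s) {
    IntegerVector o = seqs[s];
    obs_all[s].assign(o.begin(), o.end());
    if ((int)o.size() > Tmax) Tmax = o.size();
  }

  std::vector<double> alpha(Tmax * K), beta(Tmax * K), cvec(Tmax);
  std::vector<double> init_acc(K), trans_acc(K * K), emis_acc(K * M);
  std::vector<double> ll_trace;
  double prev_ll = R_NegInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(init_acc.begin(), init_acc.end(), 0.0);
    std::fill(trans_acc.begin(), trans_acc.end(), 0.0);
    std::fill(emis_acc.begin(), emis_acc.end(), 0.0);
    double ll = 0.0;

    for (int s = 0; s < S; ++s) {
      const std::vector<int> &obs = obs_all[s];
      const int T = obs.size();

      // scaled forward
      double c = 0.0;
      for (int k = 0; k < K; ++k) {
        alpha[k] = init[k] * emis[k * M + obs[0]];
        c += alpha[k];
      }
      cvec[0] = c;
      for (int k = 0; k < K; ++k) alpha[k] /= c;
      for (int t = 1; t < T; ++t) {
        double *at = &alpha[t * K];
        const double *ap = &alpha[(t - 1) * K];
        c = 0.0;
        for (int j = 0; j < K; ++j) {
          double acc = 0.0;
          for (int i = 0; i < K; ++i) acc += ap[i] * trans[i * K + j];
          at[j] = acc * emis[j * M + obs[t]];
          c += at[j];
        }
        cvec[t] = c;
        for (int j = 0; j < K; ++j) at[j] /= c;
      }
      for (int t = 0; t < T; ++t) ll += std::log(cvec[t]);

      // scaled backward
      for (int k = 0; k < K; ++k) beta[(T - 1) * K + k] = 1.0;
      for (int t = T - 2; t >= 0; --t) {
        double *bt = &beta[t * K];
        const double *bn = &beta[(t + 1) * K];
        const double inv_c = 1.0 / cvec[t + 1];
        for (int i = 0; i < K; ++i) {
          double acc = 0.0;
          const double *tr = &trans[i * K];
          for (int j = 0; j < K; ++j)
            acc += tr[j] * emis[j * M + obs[t + 1]] * bn[j];
          bt[i] = acc * inv_c;
        }
      }

      // expected counts
      for (int t = 0; t < T; ++t) {
        const double *at = &alpha[t * K];
        const double *bt = &beta[t * K];
        const int o = obs[t];
        for (int k = 0; k < K; ++k) {
          double g = at[k] * bt[k];
          emis_acc[k * M + o] += g;
          if (t == 0) init_acc[k] += g;
        }
      }
      for (int t = 0; t < T - 1; ++t) {
        const double *at = &alpha[t * K];
        const double *bn = &beta[(t + 1) * K];
        const int o = obs[t + 1];
        const double inv_c = 1.0 / cvec[t + 1];
        for (int i = 0; i < K; ++i) {
          const double ai = at[i] * inv_c;
          if (ai == 0) continue;
          const double *tr = &trans[i * K];
          double *ta = &trans_acc[i * K];
          for (int j = 0; j < K; ++j)
            ta[j] += ai * tr[j] * emis[j * M + o] * bn[j];
        }
      }
    }

    ll_trace.push_back(ll);

    // M-step
    double init_sum = 0.0;
    for (int k = 0; k < K; ++k) init_sum += init_acc[k] + 1e-12;
    for (int k = 0; k < K; ++k) init[k] = (init_acc[k] + 1e-12) / init_sum;
    for (int i = 0; i < K; ++i) {
      double rs = 0.0;
      for (int j = 0; j < K; ++j) rs += trans_acc[i * K + j] + 1e-12;
      for (int j = 0; j < K; ++j)
        trans[i * K + j] = (trans_acc[i * K + j] + 1e-12) / rs;
      double es = 0.0;
      for (int m = 0; m < M; ++m) es += emis_acc[i * M + m] + smooth;
      for (int m = 0; m < M; ++m)
        emis[i * M + m] = (emis_acc[i * M + m] + smooth) / es;
    }

    if (iter > 0) {
      double rel = std::fabs(ll - prev_ll) / (1.0 + std::fabs(ll));
      if (rel < tol) { prev_ll = ll; break; }
    }
    prev_ll = ll;
  }

  NumericVector init_out(K);
  NumericMatrix trans_out(K, K), emis_out(K, M);
  for (int k = 0; k < K; ++k) init_out[k] = init[k];
  for (int i = 0; i < K; ++i) {
    for (int j = 0; j < K; ++j) trans_out(i, j) = trans[i * K + j];
    for (int m = 0; m < M; ++m) emis_out(i, m) = emis[i * M + m];
  }

  // log-likelihood of the final parameters (one extra forward pass)
  double final_ll = 0.0;
  for (int s = 0; s < S; ++s) {
    IntegerVector obs = seqs[s];
    final_ll += forward_seq(obs, init_out, trans_out, emis_out, nullptr);
  }

  return List::create(_["initial"] = init_out, _["transition"] = trans_out,
                      _["emission"] = emis_out,
                      _["loglik"] = final_ll,
                      _["loglik_trace"] = NumericVector(ll_trace.begin(),
                                                        ll_trace.end()),
                      _["n_iter"] = (int)ll_trace.size());
}

// One-step-ahead argmax prediction error over a list of sequences:
// positions t >= 2 are scored, prediction = argmax of the one-step
// predictive distribution given the true prefix (first index wins ties,
// matching the canonical category order).
// [[Rcpp::export]]
List holdout_error_cpp(List seqs, NumericVector init, NumericMatrix trans,
                       NumericMatrix emis) {
  const int K = init.size();
  const int M = emis.ncol();
  long scored = 0, wrong = 0;
  double logloss = 0.0;
  std::vector<double> alpha(K), tmp(K), pred(M);

  for (int s = 0; s < seqs.size(); ++s) {
    IntegerVector obs = seqs[s];
    const int T = obs.size();
    if (T < 2) continue;
    for (int k = 0; k < K; ++k) alpha[k] = init[k] * emis(k, obs[0]);
    double c = 0.0;
    for (int k = 0; k < K; ++k) c += alpha[k];
    for (int k = 0; k < K; ++k) alpha[k] /= c;

    for (int t = 1; t < T; ++t) {
      // predictive state distribution, then observable distribution
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        for (int i = 0; i < K; ++i) acc += alpha[i] * trans(i, j);
        tmp[j] = acc;
      }
      int best = 0;
      double bestp = -1.0;
      for (int m = 0; m < M; ++m) {
        double p = 0.0;
        for (int j = 0; j < K; ++j) p += tmp[j] * emis(j, m);
        pred[m] = p;
        if (p > bestp) { bestp = p; best = m; }
      }
      ++scored;
      if (best != obs[t]) ++wrong;
      logloss += -std::log(std::max(pred[obs[t]], 1e-300));

      // filter update with the true symbol
      c = 0.0;
      for (int j = 0; j < K; ++j) {
        alpha[j] = tmp[j] * emis(j, obs[t]);
        c += alpha[j];
      }
      for (int j = 0; j < K; ++j) alpha[j] /= c;
    }
  }

  return List::create(_["n_scored"] = (double)scored,
                      _["n_wrong"] = (double)wrong,
                      _["error"] = scored ? (double)wrong / scored : NA_REAL,
                      _["mean_logloss"] = scored ? logloss / scored : NA_REAL);
}
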