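#include <Rcpp.h>
using namespace Rcpp;

// Adjacency is CSR: neighbours of node v (0-based) are adj[offsets[v] .. offsets[v+1]-1].
// cumw holds, per node slice, the running sum of neighbour-selection weights
// (fitness, edge weight, or their product, prepared in R), so one uniform draw
// plus a binary search samples a neighbour in O(log k).

static inline int sample_neighbour(const IntegerVector& adj,
                                   const IntegerVector& offsets,
                                   const NumericVector& cumw,
                                   int v) {
  int lo = offsets[v], hi = offsets[v + 1] - 1;
  double u = unif_rand() * cumw[hi];
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cumw[mid] >= u) hi = mid; else lo = mid + 1;
  }
  return adj[lo];
}

// One elementary update applied `n_steps` times, recording the per-opinion
// population fraction q and weighted fraction qf every `record_every` steps
// (including step 0). qf uses per-node weights w_v = k_v * f_v, normalised.
// media_opinion is 1-based, 0 = no media.
// [[Rcpp::export]]
List run_dynamics_cpp(IntegerVector adj, IntegerVector offsets,
                      NumericVector cumw, IntegerVector opinions0,
                      LogicalVector committed, int n_opinions,
                      int media_opinion, double media_p,
                      NumericVector qf_weight,
                      double n_steps, double record_every) {
  const int N = opinions0.size();
  IntegerVector op = clone(opinions0);

  std::vector<double> qcount(n_opinions, 0.0), qfsum(n_opinions, 0.0);
  double wtot = 0.0;
  for (int v = 0; v < N; ++v) {
    qcount[op[v] - 1] += 1.0;
    qfsum[op[v] - 1] += qf_weight[v];
    wtot += qf_weight[v];
  }

  long long steps = (long long)(n_steps + 0.5);
  long long rec = (long long)(record_every + 0.5);
  if (rec < 1) rec = 1;
  int n_rec = (int)(steps / rec) + 1;
  NumericMatrix q_out(n_rec, n_opinions), qf_out(n_rec, n_opinions);
  NumericVector t_out(n_rec);

  int row = 0;
  for (int i = 0; i < n_opinions; ++i) {
    q_out(row, i) = qcount[i] / N;
    qf_out(row, i) = qfsum[i] / wtot;
  }
  t_out[row] = 0.0;
  ++row;

  for (long long t = 1; t <= steps; ++t) {
    int v = (int)(unif_rand() * N);
    if (v == N) v = N - 1;
    if (!committed[v]) {
      int newop;
      if (media_p > 0.0 && unif_rand() < media_p) {
        newop = media_opinion;
      } else {
        newop = op[sample_neighbour(adj, offsets, cumw, v)];
      }
      int oldop = op[v];
      if (newop != oldop) {
        op[v] = newop;
        qcount[oldop - 1] -= 1.0;  qcount[newop - 1] += 1.0;
        qfsum[oldop - 1] -= qf_weight[v];  qfsum[newop - 1] += qf_weight[v];
      }
    }
    if (t % rec == 0) {
      for (int i = 0; i < n_opinions; ++i) {
        q_out(row, i) = qcount[i] / N;
        qf_out(row, i) = qfsum[i] / wtot;
      }
      t_out[row] = (double)t;
      ++row;
    }
  }

  return List::create(_["steps"] = t_out, _["q"] = q_out, _["qf"] = qf_out,
                      _["opinions"] = op);
}

// Iterate until every node holds one opinion (no committed nodes, no media).
// Returns the winning opinion and the number of elementary steps taken.
// [[Rcpp::export]]
List run_fixation_cpp(IntegerVector adj, IntegerVector offsets,
                      NumericVector cumw, IntegerVector opinions0,
                      int n_opinions, double max_steps) {
  const int N = opinions0.size();
  IntegerVector op = clone(opinions0);
  std::vector<int> qcount(n_opinions, 0);
  for (int v = 0; v < N; ++v) qcount[op[v] - 1]++;

  int leader = 0;
  for (int i = 1; i < n_opinions; ++i) if (qcount[i] > qcount[leader]) leader = i;
  if (qcount[leader] == N) {
    return List::create(_["opinion"] = leader + 1, _["steps"] = 0.0);
  }

  long long limit = (long long)max_steps;
  for (long long t = 1; t <= limit; ++t) {
    int v = (int)(unif_rand() * N);
    if (v == N) v = N - 1;
    int newop = op[sample_neighbour(adj, offsets, cumw, v)];
    int oldop = op[v];
    if (newop != oldop) {
      op[v] = newop;
      qcount[oldop - 1]--;
      if (++qcount[newop - 1] == N) {
        return List::create(_["opinion"] = newop, _["steps"] = (double)t);
      }
    }
  }
  stop("fixation not reached within max_steps");
}
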