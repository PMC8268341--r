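#include <Rcpp.h>
using namespace Rcpp;

// Exact minimum-hypergeometric (mHG) enrichment over a ranked list.
//
// A set of K member sites sits somewhere in a ranked list of N sites. For
// every prefix length t the hypergeometric upper tail P(X >= k_t) measures
// the surprise of seeing k_t members in the top t. The mHG statistic is the
// minimum tail over all prefixes; because that minimum scans N cutoffs, its
// null probability is computed exactly by a dynamic program over the
// (prefix, member-count) lattice rather than by a Bonferroni bound.

// upper-tail table: tail(t, k) = P(X >= k) for X ~ Hypergeom(N, K, t),
// t = 1..N (rows), k = 0..K (cols). O(N*K) using log-factorials.
static NumericMatrix tail_table(int N, int K) {
    std::vector<double> lf(N + 1);
    lf[0] = 0.0;
    for (int i = 1; i <= N; ++i) lf[i] = lf[i - 1] + std::log((double)i);
    NumericMatrix tail(N, K + 1);
    for (int t = 1; t <= N; ++t) {
        int kmax = std::min(t, K);
        int kmin = std::max(0, K - (N - t));   // at least this many members drawn
        double acc = 0.0;
        for (int k = K; k >= 0; --k) {
            if (k <= kmax && k >= kmin) {
                // log pmf = log C(K,k) + log C(N-K, t-k) - log C(N,t)
                double lp = lf[K] - lf[k] - lf[K - k]
                          + lf[N - K] - lf[t - k] - lf[N - K - (t - k)]
                          - (lf[N] - lf[t] - lf[N - t]);
                acc += std::exp(lp);
                if (acc > 1.0) acc = 1.0;
            }
            tail(t - 1, k) = (k == 0) ? 1.0 : acc;
        }
    }
    return tail;
}

// statistic: min over t of tail(t, k_t); with k fixed the tail grows with t,
// so the minimum is attained right after a member enters the prefix.
static void mhg_statistic(const IntegerVector& ranks, const NumericMatrix& tail,
                          double& stat, int& t_star) {
    stat = 1.0;
    t_star = 0;
    for (int i = 0; i < ranks.size(); ++i) {
        int t = ranks[i];          // 1-based rank of the (i+1)-th member
        double v = tail(t - 1, i + 1);
        if (v < stat) { stat = v; t_star = t; }
    }
}

// exact null probability P(mHG <= s): probability that the hypergeometric
// lattice walk (revealing the ranked list one position at a time) ever
// enters a cell whose tail value is <= s. Complement counted by a walk that
// zeroes out entered cells; all placements are equiprobable.
static double mhg_pvalue(int N, int K, double s, const NumericMatrix& tail) {
    const double thr = s * (1.0 + 1e-12) + 1e-300;
    std::vector<double> m(K + 1, 0.0);
    m[0] = 1.0;
    for (int t = 1; t <= N; ++t) {
        int kmax = std::min(t, K);
        double rem = (double)(N - t + 1);      // elements left before step t
        for (int k = kmax; k >= 0; --k) {
            double stay = m[k] * (1.0 - (double)(K - k) / rem);
            double step = (k > 0) ? m[k - 1] * ((double)(K - k + 1) / rem) : 0.0;
            m[k] = stay + step;
            if (k >= 1 && tail(t - 1, k) <= thr) m[k] = 0.0;
        }
    }
    double p = 1.0 - m[K];
    if (p < 0.0) p = 0.0;
    if (p > 1.0) p = 1.0;
    return p;
}

//' @name mhg_exact
//' @title Exact mHG test of a ranked member placement (internal)
//' @param member_ranks 1-based ranks of the set members, sorted ascending
//' @param N length of the ranked list
//' @return list with elements stat, p, t_star
//' @keywords internal
// [[Rcpp::export]]
List mhg_exact(IntegerVector member_ranks, int N) {
    int K = member_ranks.size();
    if (K < 1) stop("member_ranks must contain at least one rank");
    if (N < K) stop("N must be >= number of members");
    for (int i = 0; i < K; ++i) {
        if (member_ranks[i] < 1 || member_ranks[i] > N)
            stop("member ranks must lie in 1..N");
        if (i > 0 && member_ranks[i] <= member_ranks[i - 1])
            stop("member ranks must be strictly increasing");
    }
    NumericMatrix tail = tail_table(N, K);
    double stat; int t_star;
    mhg_statistic(member_ranks, tail, stat, t_star);
    double p = mhg_pvalue(N, K, stat, tail);
    return List::create(_["stat"] = stat, _["p"] = p, _["t_star"] = t_star);
}

//' @name mhg_exact_batch
//' @title Exact mHG p-values for many placements sharing (N, K) (internal)
//' @param ranks_mat K x B integer matrix; each column a sorted rank placement
//' @param N length of the ranked list
//' @return numeric vector of B exact p-values
//' @keywords internal
// [[Rcpp::export]]
NumericVector mhg_exact_batch(IntegerMatrix ranks_mat, int N) {
    int K = ranks_mat.nrow(), B = ranks_mat.ncol();
    if (K < 1) stop("ranks_mat must have at least one row");
    NumericMatrix tail = tail_table(N, K);
    NumericVector out(B);
    for (int b = 0; b < B; ++b) {
        IntegerVector ranks = ranks_mat(_, b);
        double stat; int t_star;
        mhg_statistic(ranks, tail, stat, t_star);
        out[b] = mhg_pvalue(N, K, stat, tail);
    }
    return out;
}
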