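#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Median of a small buffer (sorts in place). Odd length: middle order
// statistic; even length: midpoint of the two central order statistics.
static double median_inplace(std::vector<double>& v) {
    std::sort(v.begin(), v.end());
    const size_t k = v.size();
    if (k % 2 == 1) return v[k / 2];
    return 0.5 * (v[k / 2 - 1] + v[k / 2]);
}

// Steady iff no drawable action can change anything (tie-break independent:
// the rewiring candidate set depends only on the maximal discrepancy value).
static bool state_steady(const std::vector<double>& x,
                         const std::vector<int>& src,
                         double beta, int n, int k,
                         std::vector<double>& buf) {
    for (int i = 0; i < n; ++i) {
        const double xi = x[i];
        const int* si = &src[(size_t)i * k];
        if (beta < 1.0) {
            buf.assign(k, 0.0);
            for (int j = 0; j < k; ++j) buf[j] = x[si[j]];
            if (xi != median_inplace(buf)) return false;
        }
        if (beta > 0.0) {
            double dmax = 0.0;
            for (int j = 0; j < k; ++j) {
                const double d = std::fabs(xi - x[si[j]]);
                if (d > dmax) dmax = d;
            }
            if (dmax > 0.0) {
                for (int l = 0; l < n; ++l) {
                    if (l == i) continue;
                    if (std::fabs(xi - x[l]) < dmax) {
                        bool is_source = false;
                        for (int j = 0; j < k; ++j)
                            if (si[j] == l) { is_source = true; break; }
                        if (!is_source) return false;
                    }
                }
            }
        }
    }
    return true;
}

static List make_snapshot(const std::vector<double>& x,
                          const std::vector<int>& src, int n, int k) {
    NumericVector xs(x.begin(), x.end());
    IntegerMatrix ss(n, k);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < k; ++j)
            ss(i, j) = src[(size_t)i * k + j] + 1;
    return List::create(_["opinions"] = xs, _["sources"] = ss);
}

// Run the round dynamics to steady state (or the round cap). Uses R's global
// RNG so results are reproducible under set.seed(). sources are 1-based on
// the R side. traj_rounds < 0 disables snapshot recording.
// [[Rcpp::export]]
List sim_engine(NumericVector x0, IntegerMatrix src0, double beta,
                int max_rounds, int traj_rounds) {
    const int n = x0.size();
    const int k = src0.ncol();
    std::vector<double> x(x0.begin(), x0.end());
    std::vector<int> src((size_t)n * k);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < k; ++j)
            src[(size_t)i * k + j] = src0(i, j) - 1;

    std::vector<double> buf(k);
    std::vector<char> is_src(n, 0);
    std::vector<int> perm(n), worst;
    worst.reserve(k);
    for (int i = 0; i < n; ++i) perm[i] = i;

    List traj(traj_rounds >= 0 ? traj_rounds + 1 : 0);
    int n_snapshots = 0;
    if (traj_rounds >= 0) {
        traj[0] = make_snapshot(x, src, n, k);
        n_snapshots = 1;
    }

    int round = 0;
    bool steady = state_steady(x, src, beta, n, k, buf);
    while (!steady && round < max_rounds) {
        // fresh uniform permutation (Fisher-Yates)
        for (int i = n - 1; i > 0; --i) {
            int j = (int)(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(perm[i], perm[j]);
        }
        for (int t = 0; t < n; ++t) {
            const int i = perm[t];
            int* si = &src[(size_t)i * k];
            if (unif_rand() < beta) {
                // selective exposure
                const double xi = x[i];
                double dmax = 0.0;
                for (int j = 0; j < k; ++j) {
                    const double d = std::fabs(xi - x[si[j]]);
                    if (d > dmax) dmax = d;
                }
                if (dmax == 0.0) continue;
                worst.clear();
                for (int j = 0; j < k; ++j)
                    if (std::fabs(xi - x[si[j]]) == dmax) worst.push_back(j);
                int slot = worst[0];
                if (worst.size() > 1) {
                    int w = (int)(unif_rand() * worst.size());
                    if (w >= (int)worst.size()) w = (int)worst.size() - 1;
                    slot = worst[w];
                }
                for (int j = 0; j < k; ++j) is_src[si[j]] = 1;
                int count = 0;
                for (int l = 0; l < n; ++l)
                    if (l != i && !is_src[l] && std::fabs(xi - x[l]) < dmax)
                        ++count;
                if (count > 0) {
                    int pick = (int)(unif_rand() * count);
                    if (pick >= count) pick = count - 1;
                    int chosen = -1, c = 0;
                    for (int l = 0; l < n; ++l) {
                        if (l != i && !is_src[l] && std::fabs(xi - x[l]) < dmax) {
                            if (c == pick) { chosen = l; break; }
                            ++c;
                        }
                    }
                    for (int j = 0; j < k; ++j) is_src[si[j]] = 0;
                    si[slot] = chosen;
                } else {
                    for (int j = 0; j < k; ++j) is_src[si[j]] = 0;
                }
            } else {
                // naive learning: adopt the source median
                for (int j = 0; j < k; ++j) buf[j] = x[si[j]];
                x[i] = median_inplace(buf);
            }
        }
        ++round;
        if (traj_rounds >= 0 && round <= traj_rounds) {
            traj[round] = make_snapshot(x, src, n, k);
            n_snapshots = round + 1;
        }
        steady = state_steady(x, src, beta, n, k, buf);
    }

    IntegerMatrix src_out(n, k);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < k; ++j)
            src_out(i, j) = src[(size_t)i * k + j] + 1;
    return List::create(
        _["opinions"] = NumericVector(x.begin(), x.end()),
        _["sources"] = src_out,
        _["rounds"] = round,
        _["converged"] = steady,
        _["trajectory"] = traj,
        _["n_snapshots"] = n_snapshots);
}
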