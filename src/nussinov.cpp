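#include <Rcpp.h>
#include <vector>
#include <string>
#include <cctype>
using namespace Rcpp;

// Pair weights: GC=3, AU=2, GU=1. T plays U so DNA and RNA input fold alike.
static inline int pair_weight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
    bool au = (a == 'A' && (b == 'T' || b == 'U')) ||
              ((a == 'T' || a == 'U') && b == 'A');
    if (au) return 2;
    bool gu = (a == 'G' && (b == 'T' || b == 'U')) ||
              ((a == 'T' || a == 'U') && b == 'G');
    if (gu) return 1;
    return 0;
}

// Maximum-weight non-crossing pairing with a minimum hairpin loop of
// min_loop unpaired bases.  Traceback is fully deterministic: at each
// subproblem the leftmost base pairs the largest partner that attains the
// optimum; if none does, it is left unpaired (bifurcations therefore occur
// at the smallest admissible split point).
// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, int min_loop = 3) {
    int n = (int) seq.size();
    if (n == 0) stop("empty sequence");
    for (size_t t = 0; t < seq.size(); ++t)
        seq[t] = (char) std::toupper((unsigned char) seq[t]);

    std::string db(n, '.');
    if (n < min_loop + 2) {
        return List::create(_["structure"] = db, _["energy"] = 0.0);
    }

    size_t N = (size_t) n;
    std::vector<int> W(N * N, 0);   // row-major W[i*N+j]
    std::vector<int> WC(N * N, 0);  // column-major mirror WC[j*N+i]

    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            const int *row_i1 = &W[(size_t)(i + 1) * N];
            const int *col_j = &WC[(size_t) j * N];
            int best = row_i1[j];
            for (int k = i + min_loop + 1; k <= j; ++k) {
                int w = pair_weight(seq[i], seq[k]);
                if (!w) continue;
                int v = w;
                if (k - 1 >= i + 1) v += row_i1[k - 1];
                if (k + 1 <= j)     v += col_j[k + 1];
                if (v > best) best = v;
            }
            W[(size_t) i * N + j] = best;
            WC[(size_t) j * N + i] = best;
        }
    }

    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first;
        int j = stack.back().second;
        stack.pop_back();
        if (j - i < min_loop + 1) continue;
        int cur = W[(size_t) i * N + j];
        if (cur == 0) continue;
        int chosen = -1;
        for (int k = j; k >= i + min_loop + 1; --k) {
            int w = pair_weight(seq[i], seq[k]);
            if (!w) continue;
            int v = w;
            if (k - 1 >= i + 1) v += W[(size_t)(i + 1) * N + (k - 1)];
            if (k + 1 <= j)     v += W[(size_t)(k + 1) * N + j];
            if (v == cur) { chosen = k; break; }
        }
        if (chosen >= 0) {
            db[i] = '(';
            db[chosen] = ')';
            if (chosen - 1 - (i + 1) >= min_loop + 1)
                stack.push_back(std::make_pair(i + 1, chosen - 1));
            if (j - (chosen + 1) >= min_loop + 1)
                stack.push_back(std::make_pair(chosen + 1, j));
        } else {
            stack.push_back(std::make_pair(i + 1, j));
        }
    }

    double energy = -(double) W[0 * N + (n - 1)];
    return List::create(_["structure"] = db, _["energy"] = energy);
}
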