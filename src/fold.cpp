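#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Maximum-pairing secondary structure under three constraints that keep the
// prediction conservative: pairs may span at most max_span bases, every
// helix must stack at least min_helix consecutive pairs, and hairpin loops
// must hold at least min_loop unpaired bases. Watson-Crick plus G:U wobble
// pairing; T is treated as U.

static inline bool canpair(char a, char b) {
    if (a == 'T') a = 'U';
    if (b == 'T') b = 'U';
    return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// longest helix starting with pair (i, j), respecting min_loop
static int run_len(const std::string &s, int i, int j, int min_loop) {
    int t = 0;
    while (i + t < j - t && (j - t) - (i + t) - 1 >= min_loop &&
           canpair(s[i + t], s[j - t]))
        ++t;
    return t;
}

struct FoldDP {
    const std::string &s;
    int n, L, min_helix, min_loop;
    std::vector<int> M;          // window DP: M[i * (L + 1) + d], d = j - i
    std::vector<int> S;          // suffix DP
    std::vector<int> partner;    // 0-based partner, -1 if unpaired

    FoldDP(const std::string &seq, int max_span, int mh, int ml)
        : s(seq), n((int)seq.size()), L(max_span), min_helix(mh), min_loop(ml),
          M((size_t)(n > 0 ? n : 1) * (L + 1), 0), S(n + 2, 0),
          partner(n, -1) {}

    inline int m(int i, int d) const {
        if (d <= 0) return 0;
        return M[(size_t)i * (L + 1) + d];
    }

    void fill() {
        for (int i = n - 1; i >= 0; --i) {
            int dmax = std::min(L, n - 1 - i);
            for (int d = 1; d <= dmax; ++d) {
                int j = i + d;
                int best = m(i + 1, d - 1);           // i unpaired
                int r = run_len(s, i, j, min_loop);   // helix closing (i, j)
                for (int t = min_helix; t <= r; ++t) {
                    int v = t + m(i + t, d - 2 * t);
                    if (v > best) best = v;
                }
                for (int k = i + 1; k < j; ++k) {     // bifurcation
                    int v = m(i, k - i) + m(k + 1, j - k - 1);
                    if (v > best) best = v;
                }
                M[(size_t)i * (L + 1) + d] = best;
            }
        }
        for (int i = n - 1; i >= 0; --i) {
            int best = S[i + 1];
            int jmax = std::min(n - 1, i + L);
            for (int j = i + min_loop + 1; j <= jmax; ++j) {
                int r = run_len(s, i, j, min_loop);
                for (int t = min_helix; t <= r; ++t) {
                    int v = t + m(i + t, (j - t) - (i + t)) + S[j + 1];
                    if (v > best) best = v;
                }
            }
            S[i] = best;
        }
    }

    void place_helix(int i, int j, int t) {
        for (int k = 0; k < t; ++k) {
            partner[i + k] = j - k;
            partner[j - k] = i + k;
        }
    }

    void trace_window(int i, int j) {
        while (i < j) {
            int d = j - i;
            int val = m(i, d);
            if (val == 0) return;
            if (val == m(i + 1, d - 1)) { ++i; continue; }
            int r = run_len(s, i, j, min_loop);
            int chosen_t = -1;
            for (int t = r; t >= min_helix; --t) {
                if (t + m(i + t, d - 2 * t) == val) { chosen_t = t; break; }
            }
            if (chosen_t > 0) {
                place_helix(i, j, chosen_t);
                i += chosen_t; j -= chosen_t;
                continue;
            }
            for (int k = i + 1; k < j; ++k) {
                if (m(i, k - i) + m(k + 1, j - k - 1) == val) {
                    trace_window(i, k);
                    i = k + 1;
                    break;
                }
            }
        }
    }

    void trace_suffix() {
        int i = 0;
        while (i < n) {
            if (S[i] == S[i + 1]) { ++i; continue; }
            int jmax = std::min(n - 1, i + L);
            bool placed = false;
            for (int j = i + min_loop + 1; j <= jmax && !placed; ++j) {
                int r = run_len(s, i, j, min_loop);
                for (int t = r; t >= min_helix; --t) {
                    if (t + m(i + t, (j - t) - (i + t)) + S[j + 1] == S[i]) {
                        place_helix(i, j, t);
                        trace_window(i + t, j - t);
                        i = j + 1;
                        placed = true;
                        break;
                    }
                }
            }
            if (!placed) ++i;   // defensive; should not happen
        }
    }
};

// [[Rcpp::export(name = ".nussinov_pairing")]]
IntegerVector nussinov_pairing(std::string seq, int max_span, int min_helix,
                               int min_loop) {
    int n = (int)seq.size();
    IntegerVector out(n, 0);
    if (n < 2 || min_helix < 1) return out;
    FoldDP dp(seq, max_span, min_helix, min_loop);
    dp.fill();
    dp.trace_suffix();
    for (int i = 0; i < n; ++i)
        out[i] = dp.partner[i] >= 0 ? dp.partner[i] + 1 : 0;
    return out;
}
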