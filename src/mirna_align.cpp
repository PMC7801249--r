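#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Plant miRNA-target alignment with penalty scoring.
//
// The miRNA (5'->3') is aligned antiparallel to a target window; the
// window is passed REVERSED so that w[0] is the target base pairing
// miRNA position 1.  Penalties: mismatch pm, G:U wobble pg, bulged
// nucleotide pb, each multiplied by `mult` for miRNA positions r1..r2
// (1-based).  At most one bulge event per side, each of 1..maxb
// nucleotides.  Target bulges are internal only (a terminal unpaired
// target base would just shift or shrink the site).

static const double INF = std::numeric_limits<double>::infinity();

static inline int pairClass(char a, char b) {
    // 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch (DNA alphabet)
    switch (a) {
    case 'A': return b == 'T' ? 2 : 0;
    case 'C': return b == 'G' ? 2 : 0;
    case 'G': return b == 'C' ? 2 : (b == 'T' ? 1 : 0);
    case 'T': return b == 'A' ? 2 : (b == 'G' ? 1 : 0);
    default: return 0;
    }
}

struct AlnParams {
    double pm, pg, pb, mult;
    int r1, r2, maxb;
    double posMult(int i) const {  // i = 1-based miRNA position
        return (i >= r1 && i <= r2) ? mult : 1.0;
    }
    double pairPen(char a, char b, int i) const {
        int c = pairClass(a, b);
        double base = (c == 2) ? 0.0 : (c == 1 ? pg : pm);
        return base * posMult(i);
    }
};

// dp indexed [i][j][s]; s bit0 = target-bulge event used, bit1 = miRNA-
// bulge event used.
static void fillDP(const char *m, int M, const char *w, int W,
                   const AlnParams &P, std::vector<double> &dp) {
    const int S = 4;
    dp.assign((size_t)(M + 1) * (W + 1) * S, INF);
    auto at = [&](int i, int j, int s) -> double & {
        return dp[((size_t)i * (W + 1) + j) * S + s];
    };
    at(0, 0, 0) = 0.0;
    for (int i = 0; i <= M; ++i) {
        for (int j = 0; j <= W; ++j) {
            for (int s = 0; s < S; ++s) {
                double best = (i == 0 && j == 0 && s == 0) ? 0.0 : INF;
                if (i > 0 && j > 0) {
                    double d = at(i - 1, j - 1, s);
                    if (d < INF)
                        best = std::min(best,
                                        d + P.pairPen(m[i - 1], w[j - 1], i));
                }
                if (s & 2) {  // miRNA bulge event ends exactly at (i, j)
                    double pen = 0.0;
                    for (int L = 1; L <= P.maxb && i - L >= 0; ++L) {
                        pen += P.pb * P.posMult(i - L + 1);
                        double d = at(i - L, j, s & ~2);
                        if (d < INF) best = std::min(best, d + pen);
                    }
                }
                if ((s & 1) && i >= 1 && i < M) {  // internal target bulge
                    double unit = P.pb * P.posMult(std::min(i + 1, M));
                    for (int L = 1; L <= P.maxb && j - L >= 0; ++L) {
                        double d = at(i, j - L, s & ~1);
                        if (d < INF) best = std::min(best, d + L * unit);
                    }
                }
                at(i, j, s) = std::min(at(i, j, s), best);
            }
        }
    }
}

// traceback from (i, j, s); returns pairing string (one char per
// alignment column, miRNA 5'->3'): '|' WC, 'o' G:U, 'x' mismatch,
// '-' bulged nucleotide on either side.
static std::string traceback(const char *m, int M, const char *w, int W,
                             const AlnParams &P,
                             const std::vector<double> &dp,
                             int i, int j, int s) {
    const int S = 4;
    auto at = [&](int i2, int j2, int s2) -> double {
        return dp[((size_t)i2 * (W + 1) + j2) * S + s2];
    };
    std::string out;
    const double eps = 1e-9;
    while (i > 0 || j > 0) {
        double cur = at(i, j, s);
        bool moved = false;
        if (i > 0 && j > 0) {
            double d = at(i - 1, j - 1, s);
            if (d < INF &&
                std::abs(d + P.pairPen(m[i - 1], w[j - 1], i) - cur) < eps) {
                int c = pairClass(m[i - 1], w[j - 1]);
                out.push_back(c == 2 ? '|' : (c == 1 ? 'o' : 'x'));
                --i; --j; moved = true;
            }
        }
        if (!moved && (s & 2)) {
            double pen = 0.0;
            for (int L = 1; L <= P.maxb && i - L >= 0 && !moved; ++L) {
                pen += P.pb * P.posMult(i - L + 1);
                double d = at(i - L, j, s & ~2);
                if (d < INF && std::abs(d + pen - cur) < eps) {
                    for (int t = 0; t < L; ++t) out.push_back('-');
                    i -= L; s &= ~2; moved = true;
                }
            }
        }
        if (!moved && (s & 1) && i >= 1 && i < M) {
            double unit = P.pb * P.posMult(std::min(i + 1, M));
            for (int L = 1; L <= P.maxb && j - L >= 0 && !moved; ++L) {
                double d = at(i, j - L, s & ~1);
                if (d < INF && std::abs(d + L * unit - cur) < eps) {
                    for (int t = 0; t < L; ++t) out.push_back('-');
                    j -= L; s &= ~1; moved = true;
                }
            }
        }
        if (!moved) break;  // defensive; should not happen
    }
    std::reverse(out.begin(), out.end());
    return out;
}

// [[Rcpp::export(name = ".cppMirnaAlign")]]
List cppMirnaAlign(std::string mir, std::string win, bool global,
                   double pm, double pg, double pb, double mult,
                   int r1, int r2, int maxb) {
    AlnParams P{pm, pg, pb, mult, r1, r2, maxb};
    int M = (int)mir.size(), W = (int)win.size();
    std::vector<double> dp;
    fillDP(mir.c_str(), M, win.c_str(), W, P, dp);
    const int S = 4;
    auto at = [&](int i, int j, int s) -> double {
        return dp[((size_t)i * (W + 1) + j) * S + s];
    };
    double best = INF;
    int bj = W, bs = 0;
    if (global) {
        for (int s = 0; s < S; ++s)
            if (at(M, W, s) < best) { best = at(M, W, s); bs = s; }
        bj = W;
    } else {
        for (int j = 0; j <= W; ++j)
            for (int s = 0; s < S; ++s)
                if (at(M, j, s) < best) { best = at(M, j, s); bj = j; bs = s; }
    }
    std::string pairing;
    if (best < INF)
        pairing = traceback(mir.c_str(), M, win.c_str(), W, P, dp, M, bj, bs);
    return List::create(_["score"] = best, _["site_len"] = bj,
                        _["pairing"] = pairing);
}

// Scan a target for cleavage-type sites: for every site end q (target
// base pairing miRNA position 1), align and report scores below the
// cutoff.  Returns a matrix with columns (end, site_len, score).
// [[Rcpp::export(name = ".cppScanTarget")]]
NumericMatrix cppScanTarget(std::string mir, std::string target,
                            double cutoff, double pm, double pg, double pb,
                            double mult, int r1, int r2, int maxb) {
    AlnParams P{pm, pg, pb, mult, r1, r2, maxb};
    int M = (int)mir.size();
    int N = (int)target.size();
    int Wmax = M + maxb;
    std::vector<double> dp;
    std::vector<double> ends;
    std::vector<double> lens;
    std::vector<double> scores;
    std::string win;
    for (int q = M - maxb; q <= N; ++q) {
        if (q < 1) continue;
        int W = std::min(Wmax, q);
        win.assign(W, 'N');
        for (int t = 0; t < W; ++t) win[t] = target[q - 1 - t];
        fillDP(mir.c_str(), M, win.c_str(), W, P, dp);
        const int S = 4;
        double best = INF;
        int bj = 0;
        for (int j = 0; j <= W; ++j)
            for (int s = 0; s < S; ++s) {
                double v = dp[((size_t)M * (W + 1) + j) * S + s];
                if (v < best) { best = v; bj = j; }
            }
        if (best < cutoff) {
            ends.push_back(q);
            lens.push_back(bj);
            scores.push_back(best);
        }
    }
    NumericMatrix out((int)ends.size(), 3);
    for (int k = 0; k < (int)ends.size(); ++k) {
        out(k, 0) = ends[k];
        out(k, 1) = lens[k];
        out(k, 2) = scores[k];
    }
    colnames(out) = CharacterVector::create("end", "site_len", "score");
    return out;
}
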