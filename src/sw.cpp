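#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gap penalties (Gotoh).
// A gap of length k costs gap_open + k * gap_ext (both negative). 'N'
// never scores as a match. Intended for short queries (reads, flank
// probes) against subjects of a few kilobases; full DP matrices are kept.
// Returns the single best local alignment with 1-based inclusive
// coordinates on query and subject, identity count and alignment length.

// [[Rcpp::export]]
List sw_best_cpp(std::string query, std::string subject,
                 double match, double mismatch,
                 double gap_open, double gap_ext) {
    const int m = (int) query.size();
    const int n = (int) subject.size();
    if (m == 0 || n == 0)
        stop("empty sequence in local alignment");

    const double NEG = -1e18;
    const size_t W = (size_t) n + 1;
    std::vector<double> H((size_t)(m + 1) * W, 0.0);
    std::vector<double> E((size_t)(m + 1) * W, NEG); // gap in query (left)
    std::vector<double> F((size_t)(m + 1) * W, NEG); // gap in subject (up)

    double best = 0.0;
    int bi = 0, bj = 0;

    for (int i = 1; i <= m; ++i) {
        const char qc = query[i - 1];
        const size_t r = (size_t) i * W, p = (size_t)(i - 1) * W;
        for (int j = 1; j <= n; ++j) {
            double e = std::max(H[r + j - 1] + gap_open + gap_ext,
                                E[r + j - 1] + gap_ext);
            double f = std::max(H[p + j] + gap_open + gap_ext,
                                F[p + j] + gap_ext);
            const char sc = subject[j - 1];
            double sub = (qc == sc && qc != 'N') ? match : mismatch;
            double h = H[p + j - 1] + sub;
            if (e > h) h = e;
            if (f > h) h = f;
            if (h < 0.0) h = 0.0;
            E[r + j] = e;
            F[r + j] = f;
            H[r + j] = h;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }

    if (best <= 0.0)
        return List::create(_["score"] = 0.0);

    // Traceback from (bi, bj) following the recurrence until H == 0.
    int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
    int qs = bi, ss = bj, nident = 0, alen = 0;
    const double eps = 1e-9;
    while (i > 0 && j > 0) {
        const size_t r = (size_t) i * W, p = (size_t)(i - 1) * W;
        if (state == 0) {
            double h = H[r + j];
            if (h <= eps) break;
            double sub = (query[i - 1] == subject[j - 1] &&
                          query[i - 1] != 'N') ? match : mismatch;
            if (std::abs(h - (H[p + j - 1] + sub)) < eps) {
                if (sub == match) ++nident;
                ++alen; qs = i; ss = j; --i; --j;
            } else if (std::abs(h - E[r + j]) < eps) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) {
            // gap consuming subject
            double e = E[r + j];
            ++alen; ss = j;
            if (std::abs(e - (E[r + j - 1] + gap_ext)) < eps &&
                E[r + j - 1] > NEG / 2) {
                --j;
            } else {
                --j; state = 0;
            }
        } else {
            double f = F[r + j];
            ++alen; qs = i;
            if (std::abs(f - (F[p + j] + gap_ext)) < eps &&
                F[p + j] > NEG / 2) {
                --i;
            } else {
                --i; state = 0;
            }
        }
    }

    return List::create(_["score"] = best,
                        _["q_start"] = qs, _["q_end"] = bi,
                        _["s_start"] = ss, _["s_end"] = bj,
                        _["n_ident"] = nident, _["aln_len"] = alen);
}
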