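#include <Rcpp.h>
#include <string>
#include <cmath>
using namespace Rcpp;

// Per-base sequencing-error model for simulated reads. err_profile gives
// the substitution probability at each read position (a linear ramp by
// default). Each base carries a Phred quality reflecting its position's
// error rate; bases that actually receive an error have their recorded
// quality lowered by 10 (floored at 2). Uses R's RNG so a set.seed()
// call makes the output reproducible.

static inline char phred_char(int q, int offset) {
    if (q < 2) q = 2;
    if (q > 41) q = 41;
    return (char) (q + offset);
}

// [[Rcpp::export]]
List inject_errors_cpp(CharacterVector seqs, NumericVector err_profile,
                       int qual_offset) {
    const R_xlen_t n = seqs.size();
    const int L = err_profile.size();
    static const char BASES[4] = {'A', 'C', 'G', 'T'};
    // position qualities from the error profile
    std::string qtemplate(L, '!');
    std::vector<int> phred(L);
    for (int j = 0; j < L; ++j) {
        double p = err_profile[j];
        int q = (p <= 0) ? 41 : (int) std::round(-10.0 * std::log10(p));
        phred[j] = q;
        qtemplate[j] = phred_char(q, qual_offset);
    }
    CharacterVector out_seq(n), out_qual(n);
    GetRNGstate();
    for (R_xlen_t k = 0; k < n; ++k) {
        std::string s(CHAR(STRING_ELT(seqs, k)));
        if ((int) s.size() != L)
            stop("read %d has length %d, expected %d", (int)(k + 1),
                 (int) s.size(), L);
        std::string q = qtemplate;
        for (int j = 0; j < L; ++j) {
            if (unif_rand() < err_profile[j]) {
                char cur = s[j];
                char nb = cur;
                while (nb == cur)
                    nb = BASES[(int) std::floor(unif_rand() * 4.0) % 4];
                s[j] = nb;
                q[j] = phred_char(phred[j] - 10, qual_offset);
            }
        }
        out_seq[k] = s;
        out_qual[k] = q;
    }
    PutRNGstate();
    return List::create(_["seq"] = out_seq, _["qual"] = out_qual);
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
    const R_xlen_t n = seqs.size();
    CharacterVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        std::string s(CHAR(STRING_ELT(seqs, k)));
        const size_t L = s.size();
        std::string r(L, 'N');
        for (size_t i = 0; i < L; ++i) {
            char c = s[L - 1 - i];
            switch (c) {
            case 'A': r[i] = 'T'; break;
            case 'C': r[i] = 'G'; break;
            case 'G': r[i] = 'C'; break;
            case 'T': r[i] = 'A'; break;
            default:  r[i] = 'N';
            }
        }
        out[k] = r;
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector reverse_str_cpp(CharacterVector strs) {
    const R_xlen_t n = strs.size();
    CharacterVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        std::string s(CHAR(STRING_ELT(strs, k)));
        std::reverse(s.begin(), s.end());
        out[k] = s;
    }
    return out;
}
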