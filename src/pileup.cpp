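#include <Rcpp.h>
#include <map>
#include <string>
#include <cstdlib>
using namespace Rcpp;

static inline int base_idx(char c) {
    switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
    }
}

// Accumulate a pileup for one chromosome from mapped reads.
// pos is the 1-based leftmost mapping coordinate; cigars use M/I/D/S.
// Bases with quality below min_baseq (Phred, ASCII offset qual_offset)
// are ignored for depth and allele counts. Soft clips never contribute.
// Insertions are registered at the reference position of the preceding
// aligned base (anchor), deletions likewise with their length.
//
// Returns depth (integer vector over the chromosome), optionally a
// ref_len x 4 matrix of A/C/G/T counts, and indel evidence tables.

// [[Rcpp::export]]
List pileup_chrom_cpp(IntegerVector pos, CharacterVector cigar,
                      CharacterVector seq, CharacterVector qual,
                      int ref_len, int min_baseq, int qual_offset,
                      bool want_counts) {
    const R_xlen_t nread = pos.size();
    if (cigar.size() != nread || seq.size() != nread || qual.size() != nread)
        stop("pileup inputs must have equal length");
    IntegerVector depth(ref_len, 0);
    IntegerMatrix counts = want_counts ? IntegerMatrix(ref_len, 4)
                                       : IntegerMatrix(0, 0);
    std::map<std::pair<int, std::string>, int> ins;
    std::map<std::pair<int, int>, int> del;

    for (R_xlen_t k = 0; k < nread; ++k) {
        const char *cg = CHAR(STRING_ELT(cigar, k));
        const char *sq = CHAR(STRING_ELT(seq, k));
        const char *ql = CHAR(STRING_ELT(qual, k));
        int rpos = pos[k] - 1;   // 0-based reference cursor
        int qpos = 0;            // 0-based query cursor
        int anchor = -1;         // last aligned reference position
        const char *p = cg;
        while (*p) {
            long len = 0;
            const char *d = p;
            while (*p >= '0' && *p <= '9') { len = len * 10 + (*p - '0'); ++p; }
            if (p == d || len <= 0 || *p == '\0')
                stop("malformed CIGAR '%s' in read %d", cg, (int)(k + 1));
            char op = *p;
            ++p;
            if (op == 'M') {
                for (long t = 0; t < len; ++t) {
                    if (rpos >= 0 && rpos < ref_len) {
                        int q = (int) ql[qpos] - qual_offset;
                        if (q >= min_baseq) {
                            depth[rpos] += 1;
                            if (want_counts) {
                                int b = base_idx(sq[qpos]);
                                if (b >= 0) counts(rpos, b) += 1;
                            }
                        }
                    }
                    ++rpos; ++qpos;
                }
                anchor = rpos - 1;
            } else if (op == 'I') {
                if (anchor >= 0 && anchor < ref_len) {
                    std::string allele(sq + qpos, (size_t) len);
                    ins[std::make_pair(anchor, allele)] += 1;
                }
                qpos += (int) len;
            } else if (op == 'D') {
                if (anchor >= 0 && anchor < ref_len)
                    del[std::make_pair(anchor, (int) len)] += 1;
                rpos += (int) len;
                anchor = rpos - 1;
            } else if (op == 'S') {
                qpos += (int) len;
            } else {
                stop("unsupported CIGAR op '%c' in '%s'", op, cg);
            }
        }
    }

    // flatten indel maps (positions reported 1-based)
    const int ni = (int) ins.size(), nd = (int) del.size();
    IntegerVector ipos(ni), icnt(ni);
    CharacterVector iseq(ni);
    int t = 0;
    for (auto &kv : ins) {
        ipos[t] = kv.first.first + 1;
        iseq[t] = kv.first.second;
        icnt[t] = kv.second;
        ++t;
    }
    IntegerVector dpos(nd), dlen(nd), dcnt(nd);
    t = 0;
    for (auto &kv : del) {
        dpos[t] = kv.first.first + 1;
        dlen[t] = kv.first.second;
        dcnt[t] = kv.second;
        ++t;
    }
    return List::create(
        _["depth"] = depth,
        _["counts"] = want_counts ? (SEXP) counts : R_NilValue,
        _["ins"] = DataFrame::create(_["pos"] = ipos, _["allele"] = iseq,
                                     _["count"] = icnt,
                                     _["stringsAsFactors"] = false),
        _["del"] = DataFrame::create(_["pos"] = dpos, _["len"] = dlen,
                                     _["count"] = dcnt));
}
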