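#include <Rcpp.h>
#include <unordered_map>
#include <cstring>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Canonical k-mer histogram with a rolling 2-bit encoding (A=0, C=1, G=2,
// T=3). k <= 31 so a k-mer fits in one 64-bit word. Windows containing a
// non-ACGT character are skipped; the rolling state resets after one.
//
// Returns list(depth, count, n_instances, n_short) where depth/count is the
// histogram (number of distinct canonical k-mers per depth) and n_instances
// is the total number of k-mer windows counted.
// [[Rcpp::export(name = ".kmer_histogram_cpp")]]
List kmer_histogram_cpp(CharacterVector reads, int k) {
    if (k < 2 || k > 31)
        stop("k must be in [2, 31]");
    std::unordered_map<uint64_t, uint32_t> counts;
    const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
    const int shift_hi = 2 * (k - 1);
    double n_instances = 0.0;
    R_xlen_t n_short = 0;

    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        SEXP el = STRING_ELT(reads, i);
        if (el == NA_STRING) continue;
        const char *s = CHAR(el);
        const int n = (int) std::strlen(s);
        if (n < k) { ++n_short; continue; }
        uint64_t fwd = 0, rev = 0;
        int valid = 0;
        for (int j = 0; j < n; ++j) {
            int c;
            switch (s[j]) {
                case 'A': case 'a': c = 0; break;
                case 'C': case 'c': c = 1; break;
                case 'G': case 'g': c = 2; break;
                case 'T': case 't': c = 3; break;
                default: c = -1;
            }
            if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t) c) & mask;
            rev = (rev >> 2) | ((uint64_t) (3 - c) << shift_hi);
            if (++valid >= k) {
                const uint64_t canon = fwd < rev ? fwd : rev;
                ++counts[canon];
                n_instances += 1.0;
            }
        }
    }

    std::unordered_map<uint32_t, double> hist;
    for (const auto &p : counts) hist[p.second] += 1.0;
    std::vector<uint32_t> depths;
    depths.reserve(hist.size());
    for (const auto &p : hist) depths.push_back(p.first);
    std::sort(depths.begin(), depths.end());

    IntegerVector depth(depths.size());
    NumericVector count(depths.size());
    for (size_t i = 0; i < depths.size(); ++i) {
        depth[i] = (int) depths[i];
        count[i] = hist[depths[i]];
    }
    return List::create(_["depth"] = depth, _["count"] = count,
                        _["n_instances"] = n_instances,
                        _["n_short"] = (double) n_short);
}
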