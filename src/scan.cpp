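#include <Rcpp.h>
using namespace Rcpp;

static inline bool is_base(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Pigeonhole seed-and-verify Hamming scan of a short ACGT pattern over a
// DNA subject. With a budget of k mismatches the pattern is split into k+1
// near-equal segments; any window within budget must carry at least one
// segment exactly, so exact segment matches anchor candidate windows which
// are then fully verified. Windows containing a non-ACGT character are
// skipped and tallied, never reported.
//
// Returns 0-based window starts, per-window mismatch counts, 1-based
// mismatch offsets within the pattern, and the skipped-window tally.
// [[Rcpp::export]]
List cpp_scan_hamming(std::string text, std::string pat, int budget) {
    const int n = (int) text.size();
    const int L = (int) pat.size();
    if (L <= 0) stop("empty pattern");
    if (budget < 0) stop("negative budget");

    std::vector<int> starts, counts;
    std::vector< std::vector<int> > positions;
    int skipped = 0;

    const int nw = n - L + 1;
    if (nw <= 0) {
        return List::create(_["start"] = IntegerVector(0),
                            _["mismatch_count"] = IntegerVector(0),
                            _["mismatch_offsets"] = List(0),
                            _["skipped_windows"] = 0);
    }

    // prefix counts of non-ACGT characters -> skipped-window tally
    std::vector<int> badpref(n + 1, 0);
    for (int i = 0; i < n; ++i)
        badpref[i + 1] = badpref[i] + (is_base(text[i]) ? 0 : 1);
    for (int w = 0; w < nw; ++w)
        if (badpref[w + L] - badpref[w] > 0) ++skipped;

    // candidate windows anchored by exact segment matches
    std::vector<char> cand(nw, 0);
    const int nseg = budget + 1;
    for (int s = 0; s < nseg; ++s) {
        const int off = (int) ((long long) s * L / nseg);
        const int len = (int) ((long long) (s + 1) * L / nseg) - off;
        const char *seg = pat.c_str() + off;
        const int last = n - len;
        for (int p = 0; p <= last; ++p) {
            int j = 0;
            while (j < len && text[p + j] == seg[j]) ++j;
            if (j == len) {
                const int w = p - off;
                if (w >= 0 && w < nw) cand[w] = 1;
            }
        }
    }

    // full verification of candidates
    for (int w = 0; w < nw; ++w) {
        if (!cand[w]) continue;
        if (badpref[w + L] - badpref[w] > 0) continue;
        int mm = 0;
        std::vector<int> pos;
        for (int j = 0; j < L && mm <= budget; ++j) {
            if (text[w + j] != pat[j]) {
                ++mm;
                if (mm <= budget) pos.push_back(j + 1);
            }
        }
        if (mm <= budget) {
            starts.push_back(w);
            counts.push_back(mm);
            positions.push_back(pos);
        }
    }

    List poslist(positions.size());
    for (size_t i = 0; i < positions.size(); ++i)
        poslist[i] = wrap(positions[i]);
    return List::create(_["start"] = wrap(starts),
                        _["mismatch_count"] = wrap(counts),
                        _["mismatch_offsets"] = poslist,
                        _["skipped_windows"] = skipped);
}
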