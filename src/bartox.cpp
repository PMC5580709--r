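#include <Rcpp.h>
using namespace Rcpp;

static inline int hamming(const char* a, const char* b, int len, int stop_at) {
    // early exit once distance exceeds stop_at (caller's pruning bound)
    int d = 0;
    for (int i = 0; i < len; ++i) {
        if (a[i] != b[i]) {
            if (++d > stop_at) return d;
        }
    }
    return d;
}

// Greedy prefix filter: accept candidate rows (strings, equal length) that
// are at Hamming distance >= min_dist from every previously accepted row.
// Returns 1-based indices of accepted candidates, at most n_needed.
// [[Rcpp::export(name = ".cpp_greedy_min_dist")]]
IntegerVector cpp_greedy_min_dist(CharacterVector candidates, int min_dist,
                                  int n_needed) {
    int n = candidates.size();
    std::vector<const char*> kept;
    std::vector<int> idx;
    kept.reserve(n_needed);
    idx.reserve(n_needed);
    int len = n > 0 ? LENGTH(STRING_ELT(candidates, 0)) : 0;
    for (int i = 0; i < n && (int)idx.size() < n_needed; ++i) {
        const char* s = CHAR(STRING_ELT(candidates, i));
        if ((int)LENGTH(STRING_ELT(candidates, i)) != len)
            stop("candidate barcodes must all have the same length");
        bool ok = true;
        for (size_t j = 0; j < kept.size(); ++j) {
            if (hamming(s, kept[j], len, min_dist - 1) < min_dist) {
                ok = false;
                break;
            }
        }
        if (ok) {
            kept.push_back(s);
            idx.push_back(i + 1);
        }
    }
    return wrap(idx);
}

// Minimum pairwise Hamming distance among equal-length strings.
// [[Rcpp::export(name = ".cpp_min_pairwise_hamming")]]
int cpp_min_pairwise_hamming(CharacterVector seqs) {
    int n = seqs.size();
    if (n < 2) return NA_INTEGER;
    int len = LENGTH(STRING_ELT(seqs, 0));
    int best = len + 1;
    for (int i = 0; i < n - 1; ++i) {
        const char* a = CHAR(STRING_ELT(seqs, i));
        for (int j = i + 1; j < n; ++j) {
            const char* b = CHAR(STRING_ELT(seqs, j));
            int d = hamming(a, b, len, best - 1);
            if (d < best) {
                best = d;
                if (best == 0) return 0;
            }
        }
    }
    return best;
}

// Nearest-neighbour Hamming search of each probe against a reference set.
// Returns an integer matrix with columns:
//   [,1] best_index (1-based; 0 if best distance > max_mm)
//   [,2] best_dist  (distance to nearest reference, capped at len+1 meaning
//                    "worse than any bound considered")
//   [,3] n_best     (number of references attaining best_dist)
// Probes whose length differs from the reference length get best_index 0,
// best_dist len+1, n_best 0.
// [[Rcpp::export(name = ".cpp_best_hamming")]]
IntegerMatrix cpp_best_hamming(CharacterVector probes, CharacterVector refs,
                               int max_mm) {
    int np = probes.size(), nr = refs.size();
    int len = nr > 0 ? LENGTH(STRING_ELT(refs, 0)) : 0;
    IntegerMatrix out(np, 3);
    for (int i = 0; i < np; ++i) {
        const char* p = CHAR(STRING_ELT(probes, i));
        if ((int)LENGTH(STRING_ELT(probes, i)) != len || nr == 0) {
            out(i, 0) = 0; out(i, 1) = len + 1; out(i, 2) = 0;
            continue;
        }
        int best = len + 1, nbest = 0, bidx = 0;
        for (int j = 0; j < nr; ++j) {
            const char* r = CHAR(STRING_ELT(refs, j));
            int d = hamming(p, r, len, best);
            if (d < best) {
                best = d; nbest = 1; bidx = j + 1;
                if (best == 0) break;
            } else if (d == best && best <= len) {
                ++nbest;
            }
        }
        out(i, 1) = best;
        out(i, 2) = nbest;
        out(i, 0) = (best <= max_mm && nbest == 1) ? bidx : 0;
        if (best <= max_mm && nbest > 1) out(i, 0) = -1;  // ambiguous
    }
    return out;
}
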