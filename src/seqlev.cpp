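#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Sequence-Levenshtein distance between two barcodes a and b:
// the minimum over the last row and last column of the unit-cost
// Levenshtein dynamic-programming matrix D of size (|a|+1) x (|b|+1).
// This models barcodes embedded at the start of a longer read, where an
// indel shifts the downstream frame, so the cheapest alignment may stop
// before either word is fully consumed.
//
// If `cap >= 0`, computation is abandoned as soon as the distance is
// provably > cap, returning cap + 1. Valid because the row minimum of the
// Levenshtein DP matrix is non-decreasing from row to row.
static int sl_dist_core(const char* a, int na, const char* b, int nb, int cap) {
    std::vector<int> prev(nb + 1), cur(nb + 1);
    for (int j = 0; j <= nb; ++j) prev[j] = j;
    int min_last_col = nb;  // D[0][nb]
    for (int i = 1; i <= na; ++i) {
        cur[0] = i;
        int row_min = i;
        for (int j = 1; j <= nb; ++j) {
            int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
            int v = std::min(prev[j - 1] + cost,
                             std::min(prev[j] + 1, cur[j - 1] + 1));
            cur[j] = v;
            if (v < row_min) row_min = v;
        }
        if (cur[nb] < min_last_col) min_last_col = cur[nb];
        if (cap >= 0 && row_min > cap && min_last_col > cap) return cap + 1;
        std::swap(prev, cur);
    }
    int min_last_row = *std::min_element(prev.begin(), prev.end());
    return std::min(min_last_row, min_last_col);
}

// Plain Levenshtein distance (full-word), for invariants d_SL <= d_Lev.
static int lev_dist_core(const char* a, int na, const char* b, int nb) {
    std::vector<int> prev(nb + 1), cur(nb + 1);
    for (int j = 0; j <= nb; ++j) prev[j] = j;
    for (int i = 1; i <= na; ++i) {
        cur[0] = i;
        for (int j = 1; j <= nb; ++j) {
            int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
            cur[j] = std::min(prev[j - 1] + cost,
                              std::min(prev[j] + 1, cur[j - 1] + 1));
        }
        std::swap(prev, cur);
    }
    return prev[nb];
}

// [[Rcpp::export(name = ".sl_dist_cpp")]]
IntegerVector sl_dist_cpp(CharacterVector a, CharacterVector b) {
    int n = a.size();
    if (b.size() != n) stop("a and b must have equal length");
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        const char* sa = CHAR(STRING_ELT(a, i));
        const char* sb = CHAR(STRING_ELT(b, i));
        out[i] = sl_dist_core(sa, std::strlen(sa), sb, std::strlen(sb), -1);
    }
    return out;
}

// [[Rcpp::export(name = ".lev_dist_cpp")]]
IntegerVector lev_dist_cpp(CharacterVector a, CharacterVector b) {
    int n = a.size();
    if (b.size() != n) stop("a and b must have equal length");
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        const char* sa = CHAR(STRING_ELT(a, i));
        const char* sb = CHAR(STRING_ELT(b, i));
        out[i] = lev_dist_core(sa, std::strlen(sa), sb, std::strlen(sb));
    }
    return out;
}

// Minimum pairwise SL distance over a set, with the offending pair.
// [[Rcpp::export(name = ".sl_min_pairwise_cpp")]]
List sl_min_pairwise_cpp(CharacterVector seqs) {
    int n = seqs.size();
    if (n < 2) return List::create(_["min"] = NA_INTEGER,
                                   _["i"] = NA_INTEGER, _["j"] = NA_INTEGER);
    std::vector<const char*> s(n);
    std::vector<int> len(n);
    for (int i = 0; i < n; ++i) {
        s[i] = CHAR(STRING_ELT(seqs, i));
        len[i] = std::strlen(s[i]);
    }
    int best = INT_MAX, bi = 0, bj = 1;
    for (int i = 0; i < n - 1; ++i) {
        for (int j = i + 1; j < n; ++j) {
            int cap = (best == INT_MAX) ? -1 : best - 1;
            int d = sl_dist_core(s[i], len[i], s[j], len[j], cap);
            if (d < best) { best = d; bi = i; bj = j; }
            if (best == 0) {
                return List::create(_["min"] = 0, _["i"] = bi + 1,
                                    _["j"] = bj + 1);
            }
        }
        Rcpp::checkUserInterrupt();
    }
    return List::create(_["min"] = best, _["i"] = bi + 1, _["j"] = bj + 1);
}

// Full pairwise SL distance matrix (small sets; oracle/tests).
// [[Rcpp::export(name = ".sl_pairwise_matrix_cpp")]]
IntegerMatrix sl_pairwise_matrix_cpp(CharacterVector seqs) {
    int n = seqs.size();
    IntegerMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        const char* si = CHAR(STRING_ELT(seqs, i));
        int li = std::strlen(si);
        for (int j = i + 1; j < n; ++j) {
            const char* sj = CHAR(STRING_ELT(seqs, j));
            int d = sl_dist_core(si, li, sj, std::strlen(sj), -1);
            out(i, j) = d;
            out(j, i) = d;
        }
    }
    return out;
}

// Greedy closure growth: examine candidates in order, accept a candidate iff
// its SL distance to every already-accepted sequence (including
// `accepted` passed in) is >= min_dist. Stops early once `target` total
// accepted sequences exist. Returns a logical acceptance flag per candidate.
// [[Rcpp::export(name = ".sl_greedy_accept_cpp")]]
LogicalVector sl_greedy_accept_cpp(CharacterVector accepted,
                                   CharacterVector cand,
                                   int min_dist, int target) {
    std::vector<std::string> acc;
    acc.reserve(accepted.size() + cand.size());
    for (int i = 0; i < accepted.size(); ++i)
        acc.push_back(std::string(CHAR(STRING_ELT(accepted, i))));
    int n = cand.size();
    LogicalVector keep(n);
    int cap = min_dist - 1;
    for (int i = 0; i < n; ++i) {
        if ((int)acc.size() >= target) { keep[i] = false; continue; }
        const char* c = CHAR(STRING_ELT(cand, i));
        int lc = std::strlen(c);
        bool ok = true;
        for (size_t k = 0; k < acc.size(); ++k) {
            int d = sl_dist_core(acc[k].c_str(), acc[k].size(), c, lc, cap);
            if (d < min_dist) { ok = false; break; }
        }
        keep[i] = ok;
        if (ok) acc.push_back(std::string(c));
        if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    return keep;
}

// Decode an observed window against a barcode set. For barcode b and window
// w the decoding distance is min_j Lev(b, w[1..j]) (the barcode must be
// fully consumed; the window may be consumed only partially because the UMI
// and downstream sequence follow it). The consumed length is the argmin j,
// ties broken toward |j - |b|| smallest, then smaller j.
// Returns a 3-column matrix: barcode index (1-based, 0 = no decode),
// distance, consumed window length (NA when no decode).
// [[Rcpp::export(name = ".sl_decode_cpp")]]
IntegerMatrix sl_decode_cpp(CharacterVector windows, CharacterVector barcodes,
                            int max_dist) {
    int nb = barcodes.size();
    std::vector<const char*> bs(nb);
    std::vector<int> bl(nb);
    for (int i = 0; i < nb; ++i) {
        bs[i] = CHAR(STRING_ELT(barcodes, i));
        bl[i] = std::strlen(bs[i]);
    }
    int nw = windows.size();
    IntegerMatrix out(nw, 3);
    std::vector<int> prev, cur;
    for (int w = 0; w < nw; ++w) {
        const char* ws = CHAR(STRING_ELT(windows, w));
        int wl = std::strlen(ws);
        int best_d = max_dist + 1, best_b = -1, best_j = -1;
        bool tie = false;
        for (int b = 0; b < nb; ++b) {
            int L = bl[b];
            prev.assign(wl + 1, 0);
            cur.assign(wl + 1, 0);
            for (int j = 0; j <= wl; ++j) prev[j] = j;
            bool abandoned = false;
            for (int i = 1; i <= L; ++i) {
                cur[0] = i;
                int row_min = i;
                for (int j = 1; j <= wl; ++j) {
                    int cost = (bs[b][i - 1] == ws[j - 1]) ? 0 : 1;
                    int v = std::min(prev[j - 1] + cost,
                                     std::min(prev[j] + 1, cur[j - 1] + 1));
                    cur[j] = v;
                    if (v < row_min) row_min = v;
                }
                if (row_min > max_dist) { abandoned = true; break; }
                std::swap(prev, cur);
            }
            if (abandoned) continue;
            // prev = last row: Lev(b, w[1..j]) for each consumed prefix j
            int d = max_dist + 1, cj = -1;
            for (int j = 0; j <= wl; ++j) {
                if (prev[j] < d) { d = prev[j]; cj = j; }
                else if (prev[j] == d && cj >= 0 &&
                         std::abs(j - L) < std::abs(cj - L)) cj = j;
            }
            if (d < best_d) { best_d = d; best_b = b; best_j = cj; tie = false; }
            else if (d == best_d && best_b >= 0 && b != best_b) tie = true;
        }
        if (best_d <= max_dist && !tie) {
            out(w, 0) = best_b + 1;
            out(w, 1) = best_d;
            out(w, 2) = best_j;
        } else {
            out(w, 0) = 0;
            out(w, 1) = NA_INTEGER;
            out(w, 2) = NA_INTEGER;
        }
        if ((w & 255) == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}
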