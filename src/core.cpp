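#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exact k-mer anchor pairs between two code vectors (codes >= 0; negative =
// ambiguous, windows containing one are skipped). `alpha` is the alphabet
// size used for rolling hashes; k * log2(alpha) must fit in 63 bits, which is
// checked on the R side. Returns a 2-column 0-based matrix (ref_pos, qry_pos)
// with one row per exact match, all occurrences kept (--maxmatch semantics).
// [[Rcpp::export]]
IntegerMatrix anchor_pairs_cpp(IntegerVector ref, IntegerVector qry, int k, int alpha) {
    const int nr = ref.size(), nq = qry.size();
    std::vector<int> rpos_out, qpos_out;
    if (nr < k || nq < k) return IntegerMatrix(0, 2);

    std::unordered_map<uint64_t, std::vector<int> > index;
    index.reserve(nr * 2);

    uint64_t key = 0, top = 1;
    for (int i = 0; i < k - 1; ++i) top *= (uint64_t)alpha;
    int valid = 0; // length of current run of unambiguous codes
    for (int i = 0; i < nr; ++i) {
        int c = ref[i];
        if (c < 0) { valid = 0; key = 0; continue; }
        if (valid >= k) key -= top * (uint64_t)ref[i - k];
        key = key * (uint64_t)alpha + (uint64_t)c;
        ++valid;
        if (valid > k) valid = k;
        if (valid == k) index[key].push_back(i - k + 1);
    }

    key = 0; valid = 0;
    for (int j = 0; j < nq; ++j) {
        int c = qry[j];
        if (c < 0) { valid = 0; key = 0; continue; }
        if (valid >= k) key -= top * (uint64_t)qry[j - k];
        key = key * (uint64_t)alpha + (uint64_t)c;
        ++valid;
        if (valid > k) valid = k;
        if (valid == k) {
            auto it = index.find(key);
            if (it != index.end()) {
                for (int p : it->second) {
                    rpos_out.push_back(p);
                    qpos_out.push_back(j - k + 1);
                }
            }
        }
    }

    IntegerMatrix out(rpos_out.size(), 2);
    for (size_t i = 0; i < rpos_out.size(); ++i) {
        out(i, 0) = rpos_out[i];
        out(i, 1) = qpos_out[i];
    }
    return out;
}

// Banded global alignment of code vectors a (reference span) and b (query
// span), unit mismatch/gap costs, cells restricted to diagonals d = i - j in
// [lo, hi]. Returns c(matches, columns, edits) for one optimal path
// (ties broken deletion > mismatch/match > insertion, deterministically).
// Codes < 0 never match anything.
// [[Rcpp::export]]
IntegerVector banded_stats_cpp(IntegerVector a, IntegerVector b, int lo, int hi) {
    const int n = a.size(), m = b.size();
    if (lo > hi) stop("empty band");
    // The corner cells (0,0) and (n,m) must be inside the band.
    if (0 < lo || 0 > hi || (n - m) < lo || (n - m) > hi)
        stop("band excludes alignment endpoints");
    const int W = hi - lo + 1;
    const int BIG = n + m + 10;
    // dp[i * W + (d - lo)] where d = i - j
    std::vector<int> dp((size_t)(n + 1) * W, BIG);
    std::vector<signed char> bt((size_t)(n + 1) * W, 0); // 1=diag 2=up(del a) 3=left(ins b)
    auto at = [&](int i, int d) -> size_t { return (size_t)i * W + (d - lo); };

    dp[at(0, 0)] = 0;
    for (int i = 0; i <= n; ++i) {
        int dmin = std::max(lo, i - m), dmax = std::min(hi, i);
        // descending d: the in-row transition (gap in a) reads (i, d + 1)
        for (int d = dmax; d >= dmin; --d) {
            if (i == 0 && d == 0) continue;
            int j = i - d;
            int best = BIG; signed char dir = 0;
            if (i > 0 && j > 0 && d >= lo && d <= hi) { // diagonal
                int cost = dp[at(i - 1, d)];
                if (cost < BIG) {
                    bool match = a[i - 1] >= 0 && a[i - 1] == b[j - 1];
                    cost += match ? 0 : 1;
                    if (cost < best) { best = cost; dir = 1; }
                }
            }
            if (i > 0 && d - 1 >= lo) { // consume a[i-1], gap in b
                int cost = dp[at(i - 1, d - 1)];
                if (cost < BIG && cost + 1 < best) { best = cost + 1; dir = 2; }
            }
            if (j > 0 && d + 1 <= hi) { // consume b[j-1], gap in a
                int cost = dp[at(i, d + 1)];
                if (cost < BIG && cost + 1 < best) { best = cost + 1; dir = 3; }
            }
            dp[at(i, d)] = best;
            bt[at(i, d)] = dir;
        }
    }

    int i = n, d = n - m;
    if (dp[at(i, d)] >= BIG) stop("no alignment within band");
    int matches = 0, columns = 0;
    const int edits = dp[at(i, d)];
    while (i > 0 || d != 0) {
        signed char dir = bt[at(i, d)];
        if (dir == 1) {
            int j = i - d;
            if (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ++matches;
            --i; ++columns;
        } else if (dir == 2) {
            --i; --d; ++columns;
        } else if (dir == 3) {
            ++d; ++columns;
        } else {
            stop("traceback failed");
        }
    }
    return IntegerVector::create(matches, columns, edits);
}

// Length of the longest proper border (prefix that is also a suffix) of s,
// via the KMP failure function. Codes < 0 match nothing, not even themselves.
// [[Rcpp::export]]
int kmp_border_cpp(IntegerVector s) {
    const int n = s.size();
    if (n == 0) return 0;
    std::vector<int> f(n, 0);
    for (int i = 1; i < n; ++i) {
        int j = f[i - 1];
        while (j > 0 && !(s[i] >= 0 && s[i] == s[j])) j = f[j - 1];
        if (s[i] >= 0 && s[i] == s[j]) ++j;
        f[i] = j;
    }
    return f[n - 1];
}
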