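#include <Rcpp.h>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Column conventions (sequences are uppercase, equal length, '-' = alignment gap):
//   both '-'                      -> ignored, transparent for indel-run contiguity
//   either side not in {ACGT,-}   -> excluded from all difference counting,
//                                    transparent for runs, blocks inversion windows
//   exactly one '-', other a base -> indel column
//   both bases                    -> match or substitution column

inline bool isBase(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

inline char compBase(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'T': return 'A';
    case 'C': return 'G';
    case 'G': return 'C';
    default:  return '\0';
    }
}

// Maximal gap-free reverse-complement intervals of length >= minLen that
// contain at least one mismatching column (palindrome guard), chosen greedily
// left-to-right with a longest-first tie-break. 0-based inclusive intervals.
static std::vector<std::pair<int, int>> invIntervals(const std::string& a,
                                                     const std::string& b,
                                                     int minLen) {
    const int L = (int)a.size();
    std::vector<char> clean(L);
    std::vector<int> mism;
    for (int i = 0; i < L; ++i) {
        clean[i] = isBase(a[i]) && isBase(b[i]);
        if (clean[i] && a[i] != b[i]) mism.push_back(i);
    }
    std::set<std::pair<int, int>> cand;
    if (mism.empty()) return {};

    // match(x) on anti-diagonal d: interval columns x pair with columns d-x
    auto ok = [&](int x, int d) {
        const int y = d - x;
        if (x < 0 || x >= L || y < 0 || y >= L) return false;
        if (!clean[x] || !clean[y]) return false;
        return b[x] == compBase(a[y]);
    };

    for (int m : mism) {
        const char target = compBase(b[m]); // anchor partner: a[y] == comp(b[m])
        for (int y = 0; y < L; ++y) {
            if (a[y] != target || !clean[y]) continue;
            const int d = m + y;
            if (!ok(m, d)) continue;
            int x1 = m, x2 = m;
            while (ok(x1 - 1, d)) --x1;
            while (ok(x2 + 1, d)) ++x2;
            const int i0 = std::max(x1, d - x2);
            const int j0 = d - i0;
            if (j0 - i0 + 1 < minLen) continue;
            bool hasMismatch = false;
            for (int x = i0; x <= j0 && !hasMismatch; ++x)
                if (clean[x] && a[x] != b[x]) hasMismatch = true;
            if (hasMismatch) cand.insert(std::make_pair(i0, j0));
        }
    }

    std::vector<std::pair<int, int>> v(cand.begin(), cand.end());
    std::sort(v.begin(), v.end(), [](const std::pair<int, int>& p,
                                     const std::pair<int, int>& q) {
        if (p.first != q.first) return p.first < q.first;
        return (p.second - p.first) > (q.second - q.first);
    });
    std::vector<std::pair<int, int>> out;
    int lastEnd = -1;
    for (const auto& p : v) {
        if (p.first > lastEnd) {
            out.push_back(p);
            lastEnd = p.second;
        }
    }
    return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_detect_inversions(std::string a, std::string b, int min_inversion_len) {
    std::vector<std::pair<int, int>> iv = invIntervals(a, b, min_inversion_len);
    IntegerMatrix out((int)iv.size(), 2);
    for (int i = 0; i < (int)iv.size(); ++i) {
        out(i, 0) = iv[i].first;   // 0-based inclusive
        out(i, 1) = iv[i].second;
    }
    return out;
}

static IntegerVector unitCounts(const std::string& a, const std::string& b,
                                int minInvLen) {
    const int L = (int)a.size();
    std::vector<std::pair<int, int>> iv = invIntervals(a, b, minInvLen);
    std::vector<char> inInv(L, 0);
    for (const auto& p : iv)
        for (int x = p.first; x <= p.second; ++x) inInv[x] = 1;

    int subs = 0, indelEvents = 0, indelSites = 0;
    bool inRun = false;
    for (int i = 0; i < L; ++i) {
        const char ca = a[i], cb = b[i];
        const bool ba = isBase(ca), bb = isBase(cb);
        const bool ga = (ca == '-'), gb = (cb == '-');
        if (ga && gb) continue;              // transparent
        if ((!ba && !ga) || (!bb && !gb)) continue; // ambiguity: excluded, transparent
        if ((ga && bb) || (gb && ba)) {
            ++indelSites;
            if (!inRun) { ++indelEvents; inRun = true; }
            continue;
        }
        inRun = false;                       // both bases
        if (ca != cb && !inInv[i]) ++subs;
    }
    return IntegerVector::create(
        _["substitutions"] = subs,
        _["indel_events"] = indelEvents,
        _["indel_sites"] = indelSites,
        _["inversion_events"] = (int)iv.size());
}

// [[Rcpp::export]]
IntegerVector cpp_pairwise_units(std::string a, std::string b, int min_inversion_len) {
    return unitCounts(a, b, min_inversion_len);
}

// Total difference units for every pair of sequences; indel contribution is
// one unit per maximal run ("event" mode) or per gap column ("site" mode).
// [[Rcpp::export]]
IntegerMatrix cpp_units_matrix(CharacterVector seqs, int min_inversion_len,
                               bool site_mode) {
    const int n = seqs.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    IntegerMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            IntegerVector u = unitCounts(s[i], s[j], min_inversion_len);
            int indel = site_mode ? u["indel_sites"] : u["indel_events"];
            int tot = u["substitutions"] + indel + u["inversion_events"];
            out(i, j) = tot;
            out(j, i) = tot;
        }
    }
    return out;
}
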