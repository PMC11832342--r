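#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ungapped (Hamming) scan of short queries against one subject
// strand. Desk-scale by design: every offset is examined, so the contract is
// directly checkable against an independent brute-force oracle.
//
// Returns parallel vectors (qidx 1-based, start 0-based, nmm, del = 0-based
// subject offset of a deleted reference base or -1, mmpos = comma-separated
// 0-based query offsets of mismatches).

struct HitAcc {
    std::vector<int> qidx, start, nmm, del;
    std::vector<std::string> mmpos;
};

static std::string join_pos(const std::vector<int>& v) {
    std::string s;
    for (size_t i = 0; i < v.size(); ++i) {
        if (i) s.push_back(',');
        s += std::to_string(v[i]);
    }
    return s;
}

static void scan_one_ungapped(const std::string& subj, const std::string& q,
                              int qi, int max_mm, HitAcc& acc) {
    const int S = (int)subj.size(), L = (int)q.size();
    if (L == 0 || L > S) return;
    std::vector<int> pos;
    for (int st = 0; st + L <= S; ++st) {
        int mm = 0;
        pos.clear();
        for (int i = 0; i < L; ++i) {
            if (subj[st + i] != q[i]) {
                if (++mm > max_mm) break;
                pos.push_back(i);
            }
        }
        if (mm <= max_mm) {
            acc.qidx.push_back(qi);
            acc.start.push_back(st);
            acc.nmm.push_back(mm);
            acc.del.push_back(-1);
            acc.mmpos.push_back(join_pos(pos));
        }
    }
}

// One-deletion scan: the query matches subject[st, st+L+1) with exactly one
// internal subject base skipped (the Mn2+ reverse-transcription signature).
// Per start, only the best placement (fewest mismatches, then leftmost
// deletion) is reported, which normalizes homopolymer ambiguity.
static void scan_one_del(const std::string& subj, const std::string& q,
                         int qi, int max_mm, HitAcc& acc) {
    const int S = (int)subj.size(), L = (int)q.size();
    if (L < 2 || L + 1 > S) return;
    std::vector<int> pref(L + 1), suff(L + 1);
    for (int st = 0; st + L + 1 <= S; ++st) {
        // prefix mismatches, stopping once the budget is exhausted: a
        // feasible deletion offset d needs pref[d] <= max_mm
        pref[0] = 0;
        int dmax = L - 1;
        for (int i = 0; i < L; ++i) {
            pref[i + 1] = pref[i] + (subj[st + i] != q[i] ? 1 : 0);
            if (pref[i + 1] > max_mm) { dmax = i; break; }
        }
        if (dmax < 1) continue;
        // suffix mismatches from the right, stopping likewise: feasible d
        // also needs suff[d] <= max_mm
        suff[L] = 0;
        int dmin = 1;
        for (int j = L - 1; j >= 1; --j) {
            suff[j] = suff[j + 1] + (subj[st + j + 1] != q[j] ? 1 : 0);
            if (suff[j] > max_mm) { dmin = j + 1; break; }
            if (j == 1) dmin = 1;
        }
        if (dmin > dmax) continue;
        int best_mm = max_mm + 1, best_d = -1;
        for (int d = dmin; d <= dmax; ++d) {  // internal deletions only
            int mm = pref[d] + suff[d];
            if (mm < best_mm) { best_mm = mm; best_d = d; }
        }
        if (best_d >= 0 && best_mm <= max_mm) {
            std::vector<int> pos;
            for (int i = 0; i < best_d; ++i)
                if (subj[st + i] != q[i]) pos.push_back(i);
            for (int j = best_d; j < L; ++j)
                if (subj[st + j + 1] != q[j]) pos.push_back(j);
            acc.qidx.push_back(qi);
            acc.start.push_back(st);
            acc.nmm.push_back(best_mm);
            acc.del.push_back(st + best_d);
            acc.mmpos.push_back(join_pos(pos));
        }
    }
}

// [[Rcpp::export(name = ".scan_queries_cpp")]]
List scan_queries_cpp(std::string subject, CharacterVector queries,
                      int max_mm, bool with_deletion) {
    HitAcc acc;
    for (int qi = 0; qi < queries.size(); ++qi) {
        std::string q = as<std::string>(queries[qi]);
        scan_one_ungapped(subject, q, qi + 1, max_mm, acc);
        if (with_deletion) scan_one_del(subject, q, qi + 1, max_mm, acc);
    }
    return List::create(_["qidx"] = wrap(acc.qidx),
                        _["start"] = wrap(acc.start),
                        _["nmm"] = wrap(acc.nmm),
                        _["del"] = wrap(acc.del),
                        _["mmpos"] = wrap(acc.mmpos));
}
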