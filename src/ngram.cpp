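// Core 2-bit-packed n-gram machinery: encoding, extraction, posting-list
// construction, per-genome score accumulation and per-read assignment.
// n-grams are packed 2 bits per base (A=00, C=01, G=10, T=11, MSB-first)
// into uint64_t internally; values cross the R boundary as doubles, which
// are exact for n <= 26 (4^26 < 2^53).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int baseCode(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t rcKmer(uint64_t v, int n) {
    uint64_t r = 0;
    for (int i = 0; i < n; i++) {
        r = (r << 2) | (3ULL - (v & 3ULL));
        v >>= 2;
    }
    return r;
}

// Rolling extraction of all valid n-gram windows of one sequence.
// Windows containing a non-ACGT character are skipped (and counted).
static void extractInto(const char* s, size_t L, int n, bool canonical,
                        std::vector<uint64_t>& out,
                        double* total, double* skipped) {
    uint64_t mask = (n >= 32) ? ~0ULL : ((1ULL << (2 * n)) - 1ULL);
    int shift = 2 * (n - 1);
    double tot = (L >= (size_t)n) ? (double)(L - n + 1) : 0.0;
    *total += tot;
    double emitted = 0;
    uint64_t val = 0, rc = 0;
    int run = 0;
    for (size_t i = 0; i < L; i++) {
        int c = baseCode(s[i]);
        if (c < 0) { run = 0; val = 0; rc = 0; continue; }
        val = ((val << 2) | (uint64_t)c) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
        if (++run >= n) {
            emitted += 1;
            out.push_back(canonical ? std::min(val, rc) : val);
        }
    }
    *skipped += tot - emitted;
}

// [[Rcpp::export]]
NumericVector cpp_encode(CharacterVector windows) {
    R_xlen_t N = windows.size();
    NumericVector out(N);
    for (R_xlen_t i = 0; i < N; i++) {
        const char* s = CHAR(STRING_ELT(windows, i));
        size_t L = LENGTH(STRING_ELT(windows, i));
        uint64_t v = 0;
        for (size_t j = 0; j < L; j++) {
            int c = baseCode(s[j]);
            if (c < 0)
                stop("invalid-alphabet: character '%c' is not one of A, C, G, T",
                     s[j]);
            v = (v << 2) | (uint64_t)c;
        }
        out[i] = (double)v;
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode(NumericVector values, int n) {
    R_xlen_t N = values.size();
    double lim = std::pow(4.0, n);
    CharacterVector out(N);
    std::vector<char> buf(n + 1);
    buf[n] = '\0';
    for (R_xlen_t i = 0; i < N; i++) {
        double d = values[i];
        if (!(d >= 0) || d >= lim || d != std::floor(d))
            stop("invalid-encoding: value must be an integer in [0, 4^n)");
        uint64_t v = (uint64_t)d;
        for (int j = n - 1; j >= 0; j--) {
            buf[j] = BASES[v & 3ULL];
            v >>= 2;
        }
        out[i] = std::string(buf.data());
    }
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_revcomp(NumericVector values, int n) {
    R_xlen_t N = values.size();
    double lim = std::pow(4.0, n);
    NumericVector out(N);
    for (R_xlen_t i = 0; i < N; i++) {
        double d = values[i];
        if (!(d >= 0) || d >= lim || d != std::floor(d))
            stop("invalid-encoding: value must be an integer in [0, 4^n)");
        out[i] = (double)rcKmer((uint64_t)d, n);
    }
    return out;
}

// Extraction for one sequence, preserving emission order; `distinct`
// deduplicates keeping first occurrence.
// [[Rcpp::export]]
List cpp_extract(std::string seq, int n, bool distinct, bool canonical) {
    std::vector<uint64_t> v;
    double total = 0, skipped = 0;
    extractInto(seq.c_str(), seq.size(), n, canonical, v, &total, &skipped);
    if (distinct) {
        std::unordered_set<uint64_t> seen;
        seen.reserve(v.size() * 2 + 16);
        std::vector<uint64_t> keep;
        keep.reserve(v.size());
        for (uint64_t x : v)
            if (seen.insert(x).second) keep.push_back(x);
        v.swap(keep);
    }
    NumericVector out(v.size());
    for (size_t i = 0; i < v.size(); i++) out[i] = (double)v[i];
    return List::create(_["ngrams"] = out,
                        _["windows_total"] = total,
                        _["windows_skipped"] = skipped);
}

// Sorted distinct n-gram set over a collection of sequences (the records of
// one genome, or all reads of a sample).
// [[Rcpp::export]]
NumericVector cpp_collect_distinct(CharacterVector seqs, int n, bool canonical) {
    std::unordered_set<uint64_t> set;
    std::vector<uint64_t> buf;
    double total = 0, skipped = 0;
    for (R_xlen_t i = 0; i < seqs.size(); i++) {
        buf.clear();
        const char* s = CHAR(STRING_ELT(seqs, i));
        size_t L = LENGTH(STRING_ELT(seqs, i));
        extractInto(s, L, n, canonical, buf, &total, &skipped);
        set.insert(buf.begin(), buf.end());
    }
    std::vector<uint64_t> v(set.begin(), set.end());
    std::sort(v.begin(), v.end());
    NumericVector out(v.size());
    for (size_t i = 0; i < v.size(); i++) out[i] = (double)v[i];
    return out;
}

// Merge per-genome sorted distinct sets into a CSR posting index:
// kmers (sorted distinct union), m (genomes containing), postings
// (concatenated 0-based genome ordinals, ascending within each kmer).
// [[Rcpp::export]]
List cpp_merge_postings(List sets) {
    int G = sets.size();
    size_t P = 0;
    for (int g = 0; g < G; g++) P += ((NumericVector)sets[g]).size();
    std::vector<std::pair<uint64_t, int> > pairs;
    pairs.reserve(P);
    for (int g = 0; g < G; g++) {
        NumericVector s = sets[g];
        for (R_xlen_t i = 0; i < s.size(); i++)
            pairs.push_back(std::make_pair((uint64_t)s[i], g));
    }
    std::sort(pairs.begin(), pairs.end());
    size_t K = 0;
    for (size_t i = 0; i < pairs.size(); i++)
        if (i == 0 || pairs[i].first != pairs[i - 1].first) K++;
    NumericVector kmers(K);
    IntegerVector m(K);
    IntegerVector postings(pairs.size());
    size_t k = (size_t)-1;
    for (size_t i = 0; i < pairs.size(); i++) {
        if (i == 0 || pairs[i].first != pairs[i - 1].first) {
            k++;
            kmers[k] = (double)pairs[i].first;
            m[k] = 0;
        }
        m[k]++;
        postings[i] = pairs[i].second;
    }
    return List::create(_["kmers"] = kmers, _["m"] = m,
                        _["postings"] = postings);
}

// n-gram size survey: for each n, the distinct / unique / common counts over
// a genome set. Works internally on uint64, so n up to 31 is supported even
// though such values are never exported to R.
// [[Rcpp::export]]
NumericMatrix cpp_survey(List genomes, IntegerVector ns, bool canonical) {
    int G = genomes.size();
    NumericMatrix out(ns.size(), 3);
    for (R_xlen_t t = 0; t < ns.size(); t++) {
        int n = ns[t];
        std::vector<std::pair<uint64_t, int> > pairs;
        for (int g = 0; g < G; g++) {
            CharacterVector recs = genomes[g];
            std::unordered_set<uint64_t> set;
            std::vector<uint64_t> buf;
            double total = 0, skipped = 0;
            for (R_xlen_t i = 0; i < recs.size(); i++) {
                buf.clear();
                const char* s = CHAR(STRING_ELT(recs, i));
                size_t L = LENGTH(STRING_ELT(recs, i));
                extractInto(s, L, n, canonical, buf, &total, &skipped);
                set.insert(buf.begin(), buf.end());
            }
            for (uint64_t x : set) pairs.push_back(std::make_pair(x, g));
        }
        std::sort(pairs.begin(), pairs.end());
        double distinct = 0, unique = 0;
        size_t i = 0;
        while (i < pairs.size()) {
            size_t j = i;
            while (j < pairs.size() && pairs[j].first == pairs[i].first) j++;
            distinct += 1;
            if (j - i == 1) unique += 1;
            i = j;
        }
        out(t, 0) = distinct;
        out(t, 1) = unique;
        out(t, 2) = distinct - unique;
    }
    return out;
}

static inline std::vector<double> weightTable(int C) {
    std::vector<double> w(C + 1, 0.0);
    double lc = std::log((double)C);
    for (int m = 1; m <= C; m++) {
        double r = std::log((double)C / (double)m) / lc;
        w[m] = r * r;
    }
    return w;
}

// Accumulate S_g and n_c per genome over a sorted sample n-gram set, via a
// two-pointer merge against the sorted model kmer vector.
// [[Rcpp::export]]
List cpp_score_sample(NumericVector sample, NumericVector modelKmers,
                      IntegerVector m, IntegerVector postings, int nGenomes) {
    std::vector<double> wt = weightTable(nGenomes);
    std::vector<size_t> off(modelKmers.size() + 1, 0);
    for (R_xlen_t i = 0; i < m.size(); i++) off[i + 1] = off[i] + m[i];
    NumericVector S(nGenomes);
    IntegerVector nc(nGenomes);
    R_xlen_t i = 0, j = 0, NS = sample.size(), NK = modelKmers.size();
    while (i < NS && j < NK) {
        double a = sample[i], b = modelKmers[j];
        if (a < b) i++;
        else if (a > b) j++;
        else {
            double w = wt[m[j]];
            for (size_t p = off[j]; p < off[j + 1]; p++) {
                int g = postings[p];
                S[g] += w;
                nc[g]++;
            }
            i++; j++;
        }
    }
    return List::create(_["S"] = S, _["nc"] = nc);
}

// ---- read assignment ----

struct AssignModel {
    const NumericVector& kmers;
    const IntegerVector& m;
    const IntegerVector& postings;
    std::vector<size_t> off;
    std::vector<int> slot;      // genome ordinal -> predicted slot or -1
    std::vector<int> predOrd;   // slot -> genome ordinal
    std::vector<double> wt;
    AssignModel(const NumericVector& k, const IntegerVector& mm,
                const IntegerVector& p, const IntegerVector& predicted,
                int nGenomes)
        : kmers(k), m(mm), postings(p), slot(nGenomes, -1) {
        off.resize(k.size() + 1, 0);
        for (R_xlen_t i = 0; i < mm.size(); i++) off[i + 1] = off[i] + mm[i];
        for (int i = 0; i < predicted.size(); i++) {
            slot[predicted[i]] = i;
            predOrd.push_back(predicted[i]);
        }
        wt = weightTable(nGenomes);
    }
};

// Rules: (1) most unique n-grams of a predicted genome; tie -> rule 2 over
// the tied genomes; (2) argmax of summed shared n-gram weights (R_jg); tie
// -> smallest genome ordinal, flagged; (3) no match to any predicted genome
// -> unassigned. Genome ordinals follow genome_id ascending order, so
// smallest ordinal == genome_id ascending.
static void assignOne(const std::vector<uint64_t>& kset, const AssignModel& M,
                      std::vector<double>& wsum, std::vector<int>& ucnt,
                      int* assigned, int* rule, bool* tie) {
    size_t np = M.predOrd.size();
    std::fill(wsum.begin(), wsum.end(), 0.0);
    std::fill(ucnt.begin(), ucnt.end(), 0);
    bool any = false;
    for (uint64_t x : kset) {
        double dx = (double)x;
        const double* begin = REAL(M.kmers);
        const double* end = begin + M.kmers.size();
        const double* it = std::lower_bound(begin, end, dx);
        if (it == end || *it != dx) continue;
        size_t j = (size_t)(it - begin);
        double w = M.wt[M.m[j]];
        for (size_t p = M.off[j]; p < M.off[j + 1]; p++) {
            int s = M.slot[M.postings[p]];
            if (s < 0) continue;
            any = true;
            wsum[s] += w;
            if (M.m[j] == 1) ucnt[s]++;
        }
    }
    if (!any) { *assigned = -1; *rule = 0; *tie = false; return; }
    int maxU = 0;
    for (size_t s = 0; s < np; s++) maxU = std::max(maxU, ucnt[s]);
    std::vector<size_t> cand;
    if (maxU > 0) {
        for (size_t s = 0; s < np; s++)
            if (ucnt[s] == maxU) cand.push_back(s);
        if (cand.size() == 1) {
            *assigned = M.predOrd[cand[0]];
            *rule = 1; *tie = false;
            return;
        }
    } else {
        for (size_t s = 0; s < np; s++) cand.push_back(s);
    }
    double maxW = -1.0;
    for (size_t s : cand) maxW = std::max(maxW, wsum[s]);
    std::vector<size_t> best;
    for (size_t s : cand)
        if (wsum[s] == maxW) best.push_back(s);
    *assigned = M.predOrd[*std::min_element(best.begin(), best.end())];
    *rule = 2;
    *tie = best.size() > 1;
}

// [[Rcpp::export]]
List cpp_assign_reads(CharacterVector reads, int n, bool canonical,
                      NumericVector modelKmers, IntegerVector m,
                      IntegerVector postings, IntegerVector predicted,
                      int nGenomes) {
    AssignModel M(modelKmers, m, postings, predicted, nGenomes);
    size_t np = M.predOrd.size();
    std::vector<double> wsum(np);
    std::vector<int> ucnt(np);
    R_xlen_t N = reads.size();
    IntegerVector assigned(N), rule(N);
    LogicalVector tie(N);
    std::vector<uint64_t> buf;
    for (R_xlen_t r = 0; r < N; r++) {
        buf.clear();
        double total = 0, skipped = 0;
        const char* s = CHAR(STRING_ELT(reads, r));
        size_t L = LENGTH(STRING_ELT(reads, r));
        extractInto(s, L, n, canonical, buf, &total, &skipped);
        std::sort(buf.begin(), buf.end());
        buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
        int a, ru; bool t;
        assignOne(buf, M, wsum, ucnt, &a, &ru, &t);
        assigned[r] = a; rule[r] = ru; tie[r] = t;
    }
    return List::create(_["assigned"] = assigned, _["rule"] = rule,
                        _["tie"] = tie);
}

// Assignment of pre-extracted distinct n-gram sets (one NumericVector each).
// [[Rcpp::export]]
List cpp_assign_kmer_sets(List kmerSets, NumericVector modelKmers,
                          IntegerVector m, IntegerVector postings,
                          IntegerVector predicted, int nGenomes) {
    AssignModel M(modelKmers, m, postings, predicted, nGenomes);
    size_t np = M.predOrd.size();
    std::vector<double> wsum(np);
    std::vector<int> ucnt(np);
    R_xlen_t N = kmerSets.size();
    IntegerVector assigned(N), rule(N);
    LogicalVector tie(N);
    for (R_xlen_t r = 0; r < N; r++) {
        NumericVector ks = kmerSets[r];
        std::vector<uint64_t> buf;
        buf.reserve(ks.size());
        for (R_xlen_t i = 0; i < ks.size(); i++)
            buf.push_back((uint64_t)ks[i]);
        std::sort(buf.begin(), buf.end());
        buf.erase(std::unique(buf.begin(), buf.end()), buf.end());
        int a, ru; bool t;
        assignOne(buf, M, wsum, ucnt, &a, &ru, &t);
        assigned[r] = a; rule[r] = ru; tie[r] = t;
    }
    return List::create(_["assigned"] = assigned, _["rule"] = rule,
                        _["tie"] = tie);
}

// i.i.d. substitution errors using R's RNG (respects set.seed()).
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector reads, double rate) {
    R_xlen_t N = reads.size();
    CharacterVector out(N);
    std::string buf;
    for (R_xlen_t r = 0; r < N; r++) {
        const char* s = CHAR(STRING_ELT(reads, r));
        size_t L = LENGTH(STRING_ELT(reads, r));
        buf.assign(s, L);
        for (size_t i = 0; i < L; i++) {
            if (unif_rand() < rate) {
                int c = baseCode(buf[i]);
                if (c < 0) continue;
                int nc = (c + 1 + (int)(unif_rand() * 3.0)) & 3;
                buf[i] = BASES[nc];
            }
        }
        out[r] = buf;
    }
    return out;
}

// Parse the postings section of a serialized model: a vector of u32 words
// (arriving as R signed integers) laid out as
// [kmer_lo, kmer_hi, m, delta-encoded ordinals ...] per distinct n-gram.
// [[Rcpp::export]]
List cpp_parse_postings(IntegerVector u) {
    std::vector<double> kmers;
    std::vector<int> mv;
    std::vector<int> post;
    R_xlen_t i = 0, N = u.size();
    while (i < N) {
        if (i + 3 > N) stop("corrupt-model: truncated posting record");
        uint32_t lo = (uint32_t)u[i];
        uint32_t hi = (uint32_t)u[i + 1];
        uint32_t mm = (uint32_t)u[i + 2];
        i += 3;
        if (mm == 0 || i + (R_xlen_t)mm > N)
            stop("corrupt-model: truncated posting record");
        kmers.push_back((double)(((uint64_t)hi << 32) | (uint64_t)lo));
        mv.push_back((int)mm);
        uint32_t acc = 0;
        for (uint32_t k = 0; k < mm; k++) {
            uint32_t d = (uint32_t)u[i + k];
            acc = (k == 0) ? d : acc + d;
            post.push_back((int)acc);
        }
        i += mm;
    }
    return List::create(_["kmers"] = NumericVector(kmers.begin(), kmers.end()),
                        _["m"] = IntegerVector(mv.begin(), mv.end()),
                        _["postings"] = IntegerVector(post.begin(), post.end()));
}
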