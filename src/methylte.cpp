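#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---- small sequence utilities -------------------------------------------

static inline char comp_base(char b) {
    switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) c = comp_base(c);
    return r;
}

// mode 0: C->T, mode 1: G->A
static std::string convert_seq(const std::string &s, int mode) {
    std::string out(s);
    if (mode == 0) {
        for (char &c : out) if (c == 'C') c = 'T';
    } else {
        for (char &c : out) if (c == 'G') c = 'A';
    }
    return out;
}

static inline int base_code(char b) {
    switch (b) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

// ---- bisulfite read simulation ------------------------------------------
//
// Fragments of length 2*read_length; mate1 is the first read_length bases of
// the bisulfite-converted template strand (5'->3'), mate2 the reverse
// complement of the last read_length bases (directional library).
// Methylation state of each templated cytosine is an independent Bernoulli
// draw under its true probability; draws use R's RNG so set.seed() governs.

// [[Rcpp::export]]
List cpp_simulate_read_pairs(CharacterVector chrom_seqs,
                             List p_plus, List p_minus,
                             IntegerVector chrom_idx, IntegerVector start0,
                             CharacterVector strand,
                             int read_length,
                             double conversion_rate, double meth_protection,
                             double seq_error) {
    int n = chrom_idx.size();
    int frag = 2 * read_length;
    CharacterVector m1(n), m2(n);
    std::vector<std::string> seqs;
    for (int i = 0; i < chrom_seqs.size(); ++i)
        seqs.push_back(as<std::string>(chrom_seqs[i]));
    const char *bases = "ACGT";

    for (int i = 0; i < n; ++i) {
        int ci = chrom_idx[i] - 1;
        int s = start0[i];
        bool plus = (as<std::string>(strand[i]) == "+");
        const std::string &g = seqs[ci];
        NumericVector pp = p_plus[ci];
        NumericVector pm = p_minus[ci];
        std::string tmpl(frag, 'N');
        if (plus) {
            for (int j = 0; j < frag; ++j) {
                char b = g[s + j];
                if (b == 'C') {
                    bool meth = (R::unif_rand() < pp[s + j]);
                    double pC = meth ? meth_protection : (1.0 - conversion_rate);
                    tmpl[j] = (R::unif_rand() < pC) ? 'C' : 'T';
                } else tmpl[j] = b;
            }
        } else {
            // template runs 5'->3' on the minus strand: plus coords s+frag-1 .. s
            for (int j = 0; j < frag; ++j) {
                int pos = s + frag - 1 - j;
                char b = comp_base(g[pos]);
                if (b == 'C') {  // genomic G on plus strand
                    bool meth = (R::unif_rand() < pm[pos]);
                    double pC = meth ? meth_protection : (1.0 - conversion_rate);
                    tmpl[j] = (R::unif_rand() < pC) ? 'C' : 'T';
                } else tmpl[j] = b;
            }
        }
        std::string r1 = tmpl.substr(0, read_length);
        std::string r2 = revcomp(tmpl.substr(read_length, read_length));
        if (seq_error > 0) {
            for (char &c : r1)
                if (R::unif_rand() < seq_error) {
                    char nb;
                    do { nb = bases[(int)(R::unif_rand() * 4) & 3]; } while (nb == c);
                    c = nb;
                }
            for (char &c : r2)
                if (R::unif_rand() < seq_error) {
                    char nb;
                    do { nb = bases[(int)(R::unif_rand() * 4) & 3]; } while (nb == c);
                    c = nb;
                }
        }
        m1[i] = r1;
        m2[i] = r2;
    }
    return List::create(_["mate1"] = m1, _["mate2"] = m2);
}

// ---- three-letter aligner ------------------------------------------------
//
// Seed-and-extend over a k-mer hash of the converted genome. Reads are
// searched under both template-strand hypotheses; ungapped end-to-end
// placement, up to max_mm mismatches, up to max_hits equally good hits
// (one chosen by a uniform draw from R's RNG); otherwise the read is
// discarded. Three seeds partition the read so that with <=2 mismatches at
// least one seed is exact (pigeonhole), guaranteeing all valid placements
// are found when k <= floor(read_length/3).

struct KmerIndex {
    std::unordered_map<uint64_t, std::vector<uint64_t>> map;  // kmer -> (chrom<<32)|pos
    int k;
};

static void build_index(const std::vector<std::string> &seqs, int k, KmerIndex &idx) {
    idx.k = k;
    uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    for (size_t ci = 0; ci < seqs.size(); ++ci) {
        const std::string &s = seqs[ci];
        if ((int)s.size() < k) continue;
        uint64_t kmer = 0;
        int valid = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int c = base_code(s[i]);
            if (c < 0) { valid = 0; kmer = 0; continue; }
            kmer = ((kmer << 2) | (uint64_t)c) & mask;
            if (++valid >= k) {
                uint64_t pos = i + 1 - k;
                idx.map[kmer].push_back(((uint64_t)ci << 32) | pos);
            }
        }
    }
}

static bool encode_kmer(const std::string &s, int off, int k, uint64_t &out) {
    uint64_t kmer = 0;
    for (int i = 0; i < k; ++i) {
        int c = base_code(s[off + i]);
        if (c < 0) return false;
        kmer = (kmer << 2) | (uint64_t)c;
    }
    out = kmer;
    return true;
}

struct Hit {
    int chrom, pos, mm;
    char tmpl;    // '+' or '-': template strand
    int orient;   // 0: read as given, 1: reverse complement
    bool operator<(const Hit &o) const {
        if (chrom != o.chrom) return chrom < o.chrom;
        if (pos != o.pos) return pos < o.pos;
        if (tmpl != o.tmpl) return tmpl < o.tmpl;
        return orient < o.orient;
    }
    bool operator==(const Hit &o) const {
        return chrom == o.chrom && pos == o.pos && tmpl == o.tmpl && orient == o.orient;
    }
};

static void search_combo(const std::string &query, const std::vector<std::string> &genome,
                         const KmerIndex &idx, int max_mm, char tmpl, int orient,
                         std::vector<Hit> &hits) {
    int L = query.size();
    int k = idx.k;
    if (L < k) return;
    int b1 = L / 3, b2 = (2 * L) / 3;
    int offs[3] = {0, b1, b2};
    std::vector<std::pair<int,int>> seen;
    for (int si = 0; si < 3; ++si) {
        int off = offs[si];
        if (off + k > L) continue;
        uint64_t kmer;
        if (!encode_kmer(query, off, k, kmer)) continue;
        auto it = idx.map.find(kmer);
        if (it == idx.map.end()) continue;
        for (uint64_t packed : it->second) {
            int ci = (int)(packed >> 32);
            int pos = (int)(packed & 0xffffffffULL);
            int start = pos - off;
            if (start < 0 || start + L > (int)genome[ci].size()) continue;
            std::pair<int,int> key(ci, start);
            if (std::find(seen.begin(), seen.end(), key) != seen.end()) continue;
            seen.push_back(key);
            const std::string &g = genome[ci];
            int mm = 0;
            for (int j = 0; j < L; ++j) {
                if (query[j] != g[start + j]) { if (++mm > max_mm) break; }
            }
            if (mm <= max_mm) {
                Hit h; h.chrom = ci; h.pos = start; h.mm = mm;
                h.tmpl = tmpl; h.orient = orient;
                hits.push_back(h);
            }
        }
    }
}

// mates: 1 (template-strand read), 2 (complementary read), 0 (search all four combos)
// [[Rcpp::export]]
DataFrame cpp_align_reads(CharacterVector genome_ct, CharacterVector genome_ga,
                          CharacterVector reads, IntegerVector mates,
                          int k, int max_mm, int max_hits) {
    std::vector<std::string> gct, gga;
    for (int i = 0; i < genome_ct.size(); ++i) gct.push_back(as<std::string>(genome_ct[i]));
    for (int i = 0; i < genome_ga.size(); ++i) gga.push_back(as<std::string>(genome_ga[i]));
    KmerIndex idx_ct, idx_ga;
    build_index(gct, k, idx_ct);
    build_index(gga, k, idx_ga);

    int n = reads.size();
    std::vector<int> out_read, out_chrom, out_pos, out_mm, out_mult, out_orient, out_status;
    // status: 0 aligned, 1 no hit, 2 too many hits, 3 too short
    std::vector<char> out_tmpl;
    out_status.resize(n, 1);

    for (int i = 0; i < n; ++i) {
        std::string rd = as<std::string>(reads[i]);
        if ((int)rd.size() < k) { out_status[i] = 3; continue; }
        int mate = mates[i];
        std::string rc = revcomp(rd);
        std::vector<Hit> hits;
        if (mate == 1 || mate == 0) {
            search_combo(convert_seq(rd, 0), gct, idx_ct, max_mm, '+', 0, hits);
            search_combo(convert_seq(rc, 1), gga, idx_ga, max_mm, '-', 1, hits);
        }
        if (mate == 2 || mate == 0) {
            search_combo(convert_seq(rc, 0), gct, idx_ct, max_mm, '+', 1, hits);
            search_combo(convert_seq(rd, 1), gga, idx_ga, max_mm, '-', 0, hits);
        }
        if (hits.empty()) { out_status[i] = 1; continue; }
        int best = max_mm + 1;
        for (const Hit &h : hits) best = std::min(best, h.mm);
        std::vector<Hit> top;
        for (const Hit &h : hits) if (h.mm == best) top.push_back(h);
        std::sort(top.begin(), top.end());
        top.erase(std::unique(top.begin(), top.end()), top.end());
        if ((int)top.size() > max_hits) { out_status[i] = 2; continue; }
        int pick = (int)(R::unif_rand() * top.size());
        if (pick >= (int)top.size()) pick = top.size() - 1;
        const Hit &h = top[pick];
        out_status[i] = 0;
        out_read.push_back(i + 1);
        out_chrom.push_back(h.chrom + 1);
        out_pos.push_back(h.pos);
        out_mm.push_back(h.mm);
        out_mult.push_back((int)top.size());
        out_orient.push_back(h.orient);
        out_tmpl.push_back(h.tmpl);
    }

    CharacterVector tmpl_out(out_tmpl.size());
    for (size_t i = 0; i < out_tmpl.size(); ++i)
        tmpl_out[i] = std::string(1, out_tmpl[i]);
    DataFrame hits_df = DataFrame::create(
        _["read"] = wrap(out_read), _["chrom_idx"] = wrap(out_chrom),
        _["pos0"] = wrap(out_pos), _["strand"] = tmpl_out,
        _["orient"] = wrap(out_orient), _["mismatches"] = wrap(out_mm),
        _["multiplicity"] = wrap(out_mult),
        _["stringsAsFactors"] = false);
    hits_df.attr("status") = wrap(out_status);
    return hits_df;
}

// ---- per-cytosine pileup -------------------------------------------------
//
// Counts evidence from the ORIGINAL (unconverted) read bases at genomic
// cytosines of the template strand the read aligned to. Overlapping bases of
// the two mates of a pair at the same position are counted once (mate 1 wins).
// Rows must be ordered so that mate 1 of a pair precedes mate 2.

// [[Rcpp::export]]
List cpp_pileup(CharacterVector chrom_seqs,
                IntegerVector chrom_idx, IntegerVector pos0,
                CharacterVector strand, IntegerVector orient,
                CharacterVector read_seqs,
                IntegerVector pair_id, IntegerVector mate) {
    int nchrom = chrom_seqs.size();
    std::vector<std::string> seqs;
    for (int i = 0; i < nchrom; ++i) seqs.push_back(as<std::string>(chrom_seqs[i]));
    std::vector<std::vector<int>> nCp(nchrom), nTp(nchrom), nCm(nchrom), nTm(nchrom);
    for (int i = 0; i < nchrom; ++i) {
        size_t L = seqs[i].size();
        nCp[i].assign(L, 0); nTp[i].assign(L, 0);
        nCm[i].assign(L, 0); nTm[i].assign(L, 0);
    }
    std::unordered_map<int, std::tuple<int,int,int,char>> mate1_span;  // pair -> chrom,start,end,tmpl

    int n = chrom_idx.size();
    for (int i = 0; i < n; ++i) {
        int ci = chrom_idx[i] - 1;
        int s = pos0[i];
        char tm = as<std::string>(strand[i])[0];
        std::string rd = as<std::string>(read_seqs[i]);
        if (orient[i] == 1) rd = revcomp(rd);
        int L = rd.size();
        int skip_lo = -1, skip_hi = -1;
        if (mate[i] == 1) {
            mate1_span[pair_id[i]] = std::make_tuple(ci, s, s + L, tm);
        } else {
            auto it = mate1_span.find(pair_id[i]);
            if (it != mate1_span.end()) {
                int mc, ms, me; char mt;
                std::tie(mc, ms, me, mt) = it->second;
                if (mc == ci && mt == tm) { skip_lo = ms; skip_hi = me; }
            }
        }
        const std::string &g = seqs[ci];
        for (int j = 0; j < L; ++j) {
            int gp = s + j;
            if (gp >= skip_lo && gp < skip_hi) continue;
            char gb = g[gp], rb = rd[j];
            if (tm == '+') {
                if (gb == 'C') {
                    if (rb == 'C') nCp[ci][gp]++;
                    else if (rb == 'T') nTp[ci][gp]++;
                }
            } else {
                if (gb == 'G') {
                    if (rb == 'G') nCm[ci][gp]++;
                    else if (rb == 'A') nTm[ci][gp]++;
                }
            }
        }
    }
    List out(nchrom);
    for (int i = 0; i < nchrom; ++i)
        out[i] = List::create(_["nC_plus"] = wrap(nCp[i]), _["nT_plus"] = wrap(nTp[i]),
                              _["nC_minus"] = wrap(nCm[i]), _["nT_minus"] = wrap(nTm[i]));
    return out;
}
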