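// Seeded short-tag aligner: exact k-mer index over the forward genome,
// pigeonhole segment seeding for <= max_mismatch substitutions, full
// Hamming verification. Minus-strand hits come from querying the
// reverse complement against the forward index.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N or invalid: never indexed, never seeds
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

struct GenomeIndex {
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  int k;
  // packed k-mer -> positions, position packed as (chrom << 40) | offset
  std::unordered_map<uint64_t, std::vector<uint64_t>> kmers;
};

// [[Rcpp::export(name = ".build_index_cpp")]]
SEXP build_index_cpp(CharacterVector names, CharacterVector seqs, int k) {
  if (seqs.size() == 0) stop("empty genome: no sequences to index");
  if (k < 1 || k > 15) stop("seed length k must be in 1..15");
  GenomeIndex* gi = new GenomeIndex();
  gi->k = k;
  uint64_t total = 0;
  for (int c = 0; c < seqs.size(); ++c) {
    std::string s = as<std::string>(seqs[c]);
    for (size_t i = 0; i < s.size(); ++i) {
      char up = std::toupper((unsigned char)s[i]);
      if (up != 'A' && up != 'C' && up != 'G' && up != 'T' && up != 'N')
        stop("non-ACGTN character '%c' in sequence '%s' at position %d",
             s[i], as<std::string>(names[c]).c_str(), (int)(i + 1));
      s[i] = up;
    }
    total += s.size();
    gi->names.push_back(as<std::string>(names[c]));
    gi->seqs.push_back(s);
  }
  if (total == 0) { delete gi; stop("empty genome: all sequences have length 0"); }
  // rolling 2-bit encoding; restart after any non-ACGT base
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t c = 0; c < gi->seqs.size(); ++c) {
    const std::string& s = gi->seqs[c];
    if ((int)s.size() < k) continue;
    uint64_t code = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t pos = ((uint64_t)c << 40) | (uint64_t)(i + 1 - k);
        gi->kmers[code].push_back(pos);
      }
    }
  }
  XPtr<GenomeIndex> ptr(gi, true);
  return ptr;
}

// [[Rcpp::export(name = ".index_info_cpp")]]
List index_info_cpp(SEXP xp) {
  XPtr<GenomeIndex> gi(xp);
  IntegerVector lens(gi->names.size());
  CharacterVector nms(gi->names.size());
  for (size_t i = 0; i < gi->names.size(); ++i) {
    nms[i] = gi->names[i];
    lens[i] = (int)gi->seqs[i].size();
  }
  return List::create(_["names"] = nms, _["lengths"] = lens, _["k"] = gi->k,
                      _["n_kmers"] = (double)gi->kmers.size());
}

// [[Rcpp::export(name = ".index_lookup_cpp")]]
DataFrame index_lookup_cpp(SEXP xp, std::string kmer) {
  XPtr<GenomeIndex> gi(xp);
  if ((int)kmer.size() != gi->k)
    stop("query length %d does not match index seed length %d",
         (int)kmer.size(), gi->k);
  uint64_t code = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int b = base2bits(std::toupper((unsigned char)kmer[i]));
    if (b < 0) stop("query k-mer contains a non-ACGT character");
    code = (code << 2) | (uint64_t)b;
  }
  std::vector<int> chroms, offs;
  auto it = gi->kmers.find(code);
  if (it != gi->kmers.end()) {
    for (uint64_t p : it->second) {
      chroms.push_back((int)(p >> 40) + 1);
      offs.push_back((int)(p & ((1ULL << 40) - 1)));
    }
  }
  return DataFrame::create(_["chrom"] = chroms, _["offset"] = offs);
}

// Hamming distance with N-mismatch rule; early exit above budget.
static inline int window_mm(const std::string& g, int start,
                            const std::string& q, int budget) {
  int mm = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    char a = q[i], b = g[start + i];
    if (a != b || a == 'N' || b == 'N') {
      if (++mm > budget) return mm;
    }
  }
  return mm;
}

struct Hit { int chrom; int start; char strand; int mm; };

static void collect_hits(const GenomeIndex* gi, const std::string& q,
                         char strand, int max_mm,
                         std::vector<Hit>& hits) {
  const int L = (int)q.size();
  const int k = gi->k;
  const int nseg = max_mm + 1;
  const int seg = L / nseg;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::vector<uint64_t> cand;  // (chrom << 40) | start
  for (int i = 0; i < nseg; ++i) {
    int off = i * seg;
    uint64_t code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(q[off + j]);
      if (b < 0) { ok = false; break; }
      code = ((code << 2) | (uint64_t)b) & mask;
    }
    if (!ok) continue;  // seed spans an N: cannot be an exact segment
    auto it = gi->kmers.find(code);
    if (it == gi->kmers.end()) continue;
    for (uint64_t p : it->second) {
      int c = (int)(p >> 40);
      long long st = (long long)(p & ((1ULL << 40) - 1)) - off;
      if (st < 0 || st + L > (long long)gi->seqs[c].size()) continue;
      cand.push_back(((uint64_t)c << 40) | (uint64_t)st);
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (uint64_t p : cand) {
    int c = (int)(p >> 40);
    int st = (int)(p & ((1ULL << 40) - 1));
    int mm = window_mm(gi->seqs[c], st, q, max_mm);
    if (mm <= max_mm) hits.push_back(Hit{c, st, strand, mm});
  }
}

// [[Rcpp::export(name = ".align_tags_cpp")]]
List align_tags_cpp(SEXP xp, CharacterVector tags, int max_mismatch,
                    int max_store) {
  XPtr<GenomeIndex> gi(xp);
  const int n = tags.size();
  CharacterVector stratum(n);
  IntegerVector n_best(n);
  LogicalVector too_short(n);
  std::vector<int> p_tag, p_chrom, p_start, p_mm;
  std::vector<char> p_strand;
  const char* level_u[3] = {"U0", "U1", "U2"};
  for (int t = 0; t < n; ++t) {
    std::string fwd = as<std::string>(tags[t]);
    for (auto& ch : fwd) ch = std::toupper((unsigned char)ch);
    const int L = (int)fwd.size();
    const int seg = L / (max_mismatch + 1);
    if (seg < gi->k) {
      stratum[t] = "NM";
      n_best[t] = 0;
      too_short[t] = true;
      continue;
    }
    std::string rev(fwd.rbegin(), fwd.rend());
    for (auto& ch : rev) ch = comp(ch);
    std::vector<Hit> hits;
    collect_hits(gi, fwd, '+', max_mismatch, hits);
    collect_hits(gi, rev, '-', max_mismatch, hits);
    int counts[3] = {0, 0, 0};
    for (const Hit& h : hits) counts[h.mm]++;
    int best = -1;
    for (int lv = 0; lv <= max_mismatch; ++lv)
      if (counts[lv] > 0) { best = lv; break; }
    if (best < 0) {
      stratum[t] = "NM";
      n_best[t] = 0;
      continue;
    }
    n_best[t] = counts[best];
    stratum[t] = (counts[best] == 1) ? level_u[best] : "R";
    int stored = 0;
    for (const Hit& h : hits) {
      if (h.mm != best) continue;
      if (stored >= max_store) break;
      p_tag.push_back(t + 1);
      p_chrom.push_back(h.chrom + 1);
      p_start.push_back(h.start);
      p_strand.push_back(h.strand);
      p_mm.push_back(h.mm);
      ++stored;
    }
  }
  CharacterVector strand_out(p_strand.size());
  for (size_t i = 0; i < p_strand.size(); ++i)
    strand_out[i] = std::string(1, p_strand[i]);
  return List::create(
      _["stratum"] = stratum, _["n_best"] = n_best,
      _["too_short"] = too_short,
      _["placements"] = List::create(
          _["tag_id"] = wrap(p_tag), _["chrom_id"] = wrap(p_chrom),
          _["start"] = wrap(p_start), _["strand"] = strand_out,
          _["mismatches"] = wrap(p_mm)));
}
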