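// Seeded short-read alignment against small genomes.
//
// A 2-bit k-mer hash over the reference drives a seed-and-extend search.
// End-to-end mode verifies full-length placements under a mismatch budget;
// local mode extends exact seeds with an X-drop heuristic and soft-clips
// unextendable ends. Mismatch positions inside matched blocks are reported
// so pileup construction does not have to re-compare sequences in R.
//
// cpp_align_fragments is a fused simulate-and-align entry point for the
// deep-coverage pipeline: reads are constructed from fragment coordinates
// and an edit list in a stack buffer (no R strings), aligned with the same
// core routine, and reduced on the fly to per-strand coverage and
// mismatch tallies.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  }
  return 'N';
}

static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct Hit {
  int32_t chrom;  // 0-based
  int32_t pos;    // 0-based offset of k-mer start
};

struct SeedIndex {
  int k;
  uint64_t kmask;
  std::vector<std::string> seqs;   // uppercase reference, one per chromosome
  std::vector<std::string> names;
  std::vector<uint64_t> keys;      // open-addressed hash, linear probing
  std::vector<int32_t> hchrom;
  std::vector<int32_t> hpos;
  std::vector<uint8_t> state;      // 0 empty, 1 unique, 2 in dups
  uint64_t mask;
  std::unordered_map<uint64_t, std::vector<Hit>> dups;

  void insert(uint64_t key, int32_t c, int32_t p) {
    uint64_t h = mix64(key) & mask;
    while (state[h] != 0 && keys[h] != key) h = (h + 1) & mask;
    if (state[h] == 0) {
      keys[h] = key; hchrom[h] = c; hpos[h] = p; state[h] = 1;
    } else if (state[h] == 1) {
      std::vector<Hit>& v = dups[key];
      v.push_back(Hit{hchrom[h], hpos[h]});
      v.push_back(Hit{c, p});
      state[h] = 2;
    } else {
      dups[key].push_back(Hit{c, p});
    }
  }

  int lookup(uint64_t key, std::vector<Hit>& out) const {
    uint64_t h = mix64(key) & mask;
    while (state[h] != 0) {
      if (keys[h] == key) {
        if (state[h] == 1) { out.push_back(Hit{hchrom[h], hpos[h]}); return 1; }
        const std::vector<Hit>& v = dups.at(key);
        out.insert(out.end(), v.begin(), v.end());
        return (int)v.size();
      }
      h = (h + 1) & mask;
    }
    return 0;
  }
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  idx->kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  size_t total = 0;
  for (int i = 0; i < seqs.size(); ++i) {
    idx->seqs.push_back(std::string(CHAR(STRING_ELT(seqs, i))));
    idx->names.push_back(std::string(CHAR(STRING_ELT(names, i))));
    size_t len = idx->seqs.back().size();
    if (len >= (size_t)k) total += len - k + 1;
  }
  uint64_t cap = 64;
  while (cap < 2 * total + 1) cap <<= 1;
  idx->keys.assign(cap, 0);
  idx->hchrom.assign(cap, 0);
  idx->hpos.assign(cap, 0);
  idx->state.assign(cap, 0);
  idx->mask = cap - 1;
  for (size_t c = 0; c < idx->seqs.size(); ++c) {
    const std::string& s = idx->seqs[c];
    uint64_t kmer = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int code = base_code(s[i]);
      if (code < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)code) & idx->kmask;
      if (++valid >= k) idx->insert(kmer, (int32_t)c, (int32_t)(i - k + 1));
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal index k");
  uint64_t key = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int code = base_code(kmer[i]);
    if (code < 0) return List::create(_["chrom"] = IntegerVector(0),
                                      _["pos"] = IntegerVector(0));
    key = (key << 2) | (uint64_t)code;
  }
  std::vector<Hit> hits;
  idx->lookup(key, hits);
  IntegerVector chrom(hits.size()), pos(hits.size());
  for (size_t i = 0; i < hits.size(); ++i) {
    chrom[i] = hits[i].chrom + 1;
    pos[i] = hits[i].pos + 1;
  }
  return List::create(_["chrom"] = chrom, _["pos"] = pos);
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  IntegerVector lens(idx->seqs.size());
  CharacterVector nm(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) {
    lens[i] = (int)idx->seqs[i].size();
    nm[i] = idx->names[i];
  }
  return List::create(_["k"] = idx->k, _["names"] = nm, _["lengths"] = lens);
}

struct Cand {
  int32_t chrom;
  int32_t gstart;   // e2e: genome start; local: diagonal
  int8_t strand;    // 0 fwd, 1 rev
  int32_t ql, qr;   // 0-based matched block on the oriented read
  int32_t gl;       // 0-based genome offset of matched block start
  int score;        // e2e: -mismatches; local: matches - 3*mismatches
  int nmm;
};

static bool cand_better(const Cand& a, const Cand& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.chrom != b.chrom) return a.chrom < b.chrom;
  if (a.gl != b.gl) return a.gl < b.gl;
  return a.strand < b.strand;
}

static int count_mm(const std::string& str, int q0, int q1,
                    const std::string& g, int g0, int cap) {
  int mm = 0;
  for (int q = q0, gg = g0; q <= q1; ++q, ++gg) {
    if (str[(size_t)q] != g[(size_t)gg] && ++mm > cap) return mm;
  }
  return mm;
}

struct AlnOut {
  bool mapped;
  int chrom;        // 0-based
  int gl;           // 0-based matched-block start
  int strand;
  int clipL, matchL, clipR;
  int nmm, nhits, mapq;
};

// Core seed-and-extend for one read. fwd/rev are the two orientations of
// the read; on success the winning candidate is written to `out` and the
// mismatch read offsets (on the oriented read) are appended to mm_q.
struct Aligner {
  const SeedIndex* idx;
  int mode;         // 0 end_to_end, 1 local
  int max_mm, min_block, max_hits, xdrop;
  std::vector<Hit> hits;
  std::vector<Cand> cands;
  std::string rev;

  void align(const std::string& fwd, AlnOut& out,
             std::vector<int>* mm_goff, std::vector<char>* mm_base) {
    const int k = idx->k;
    const int L = (int)fwd.size();
    out.mapped = false;
    out.nhits = 0;
    if (L < k) return;
    rev.resize((size_t)L);
    for (int i = 0; i < L; ++i)
      rev[(size_t)(L - 1 - i)] = comp_base(fwd[(size_t)i]);
    cands.clear();

    if (mode == 0) {
      // offsets outer, strands inner: after offset 0 on both strands an
      // exact full-length placement is provably complete (any 0-mismatch
      // location shares the read's first k-mer), so seeding stops early.
      // Reads long enough for max_mm+1 disjoint seed windows get the full
      // pigeonhole guarantee; shorter reads fall back to denser,
      // overlapping seeds (best effort).
      int step = k;
      if (L < (max_mm + 1) * k && max_mm > 0)
        step = std::max(1, (L - k) / max_mm);
      bool stop_seeding = false;
      for (int off = 0; off <= L - k && !stop_seeding; ) {
        for (int strand = 0; strand < 2; ++strand) {
          const std::string& str = strand ? rev : fwd;
          uint64_t key = 0;
          bool ok = true;
          for (int i = 0; i < k; ++i) {
            int code = base_code(str[(size_t)(off + i)]);
            if (code < 0) { ok = false; break; }
            key = (key << 2) | (uint64_t)code;
          }
          if (!ok) continue;
          hits.clear();
          idx->lookup(key, hits);
          for (size_t h = 0; h < hits.size(); ++h) {
            const std::string& g = idx->seqs[(size_t)hits[h].chrom];
            int gstart = hits[h].pos - off;
            if (gstart < 0 || gstart + L > (int)g.size()) continue;
            bool seen = false;
            for (size_t c = 0; c < cands.size(); ++c)
              if (cands[c].chrom == hits[h].chrom &&
                  cands[c].gstart == gstart &&
                  cands[c].strand == strand) { seen = true; break; }
            if (seen) continue;
            int mm = count_mm(str, 0, L - 1, g, gstart, max_mm);
            if (mm > max_mm) continue;
            Cand cd;
            cd.chrom = hits[h].chrom; cd.gstart = gstart;
            cd.strand = (int8_t)strand;
            cd.ql = 0; cd.qr = L - 1; cd.gl = gstart;
            cd.score = -mm; cd.nmm = mm;
            cands.push_back(cd);
          }
        }
        if (off == 0) {
          for (size_t c = 0; c < cands.size(); ++c)
            if (cands[c].nmm == 0) { stop_seeding = true; break; }
        }
        if (off == L - k) break;
        off += step;
        if (off > L - k) off = L - k;  // final window flush against the end
      }
    } else {
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& str = strand ? rev : fwd;
        for (int off = 0; off <= L - k; ) {
          uint64_t key = 0;
          bool ok = true;
          for (int i = 0; i < k; ++i) {
            int code = base_code(str[(size_t)(off + i)]);
            if (code < 0) { ok = false; break; }
            key = (key << 2) | (uint64_t)code;
          }
          if (ok) {
            hits.clear();
            idx->lookup(key, hits);
            for (size_t h = 0; h < hits.size(); ++h) {
              const std::string& g = idx->seqs[(size_t)hits[h].chrom];
              int diag = hits[h].pos - off;  // X-drop from the exact seed
              bool seen = false;
              for (size_t c = 0; c < cands.size(); ++c)
                if (cands[c].chrom == hits[h].chrom &&
                    (cands[c].gl - cands[c].ql) == diag &&
                    cands[c].strand == strand) { seen = true; break; }
              if (seen) continue;
              int glen = (int)g.size();
              int qi = off + k, gi = hits[h].pos + k;
              int sc = 0, best = 0, bq = off + k - 1;
              while (qi < L && gi < glen) {
                sc += (str[(size_t)qi] == g[(size_t)gi]) ? 1 : -3;
                if (sc > best) { best = sc; bq = qi; }
                else if (best - sc > xdrop) break;
                ++qi; ++gi;
              }
              int qr = bq;
              qi = off - 1; gi = hits[h].pos - 1;
              sc = 0; best = 0; int bql = off;
              while (qi >= 0 && gi >= 0) {
                sc += (str[(size_t)qi] == g[(size_t)gi]) ? 1 : -3;
                if (sc > best) { best = sc; bql = qi; }
                else if (best - sc > xdrop) break;
                --qi; --gi;
              }
              int ql = bql;
              int gl = hits[h].pos - (off - ql);
              int mm = count_mm(str, ql, qr, g, gl, L);
              Cand cd;
              cd.chrom = hits[h].chrom; cd.gstart = diag;
              cd.strand = (int8_t)strand;
              cd.ql = ql; cd.qr = qr; cd.gl = gl;
              cd.score = (qr - ql + 1 - mm) - 3 * mm; cd.nmm = mm;
              if (qr - ql + 1 >= min_block) cands.push_back(cd);
            }
          }
          if (off == L - k) break;
          off += k;
          if (off > L - k) off = L - k;
        }
      }
    }

    if (cands.empty()) return;
    int bi = 0;
    for (size_t c = 1; c < cands.size(); ++c)
      if (cand_better(cands[c], cands[(size_t)bi])) bi = (int)c;
    int nbest = 0;
    for (size_t c = 0; c < cands.size(); ++c)
      if (cands[c].score == cands[(size_t)bi].score) ++nbest;
    out.nhits = nbest;
    if (nbest > max_hits) return;  // multi-mapping beyond cap -> unmapped
    const Cand& b = cands[(size_t)bi];
    const std::string& str = b.strand ? rev : fwd;
    const std::string& g = idx->seqs[(size_t)b.chrom];
    out.mapped = true;
    out.chrom = b.chrom;
    out.gl = b.gl;
    out.strand = b.strand;
    out.clipL = b.ql;
    out.matchL = b.qr - b.ql + 1;
    out.clipR = L - 1 - b.qr;
    out.nmm = b.nmm;
    out.mapq = (nbest == 1) ? 42 : 3;
    if (b.nmm > 0 && mm_goff != nullptr) {
      for (int q = b.ql, gg = b.gl; q <= b.qr; ++q, ++gg) {
        char rb = str[(size_t)q];
        if (rb != g[(size_t)gg]) {
          mm_goff->push_back(gg);
          mm_base->push_back(rb);
        }
      }
    }
  }
};

// [[Rcpp::export]]
List cpp_align(SEXP xp, CharacterVector reads, int mode, int max_mm,
               int min_block, int max_hits, int xdrop) {
  XPtr<SeedIndex> idx(xp);
  Aligner al;
  al.idx = idx.get();
  al.mode = mode; al.max_mm = max_mm; al.min_block = min_block;
  al.max_hits = max_hits; al.xdrop = xdrop;
  const int n = reads.size();
  IntegerVector out_chrom(n, NA_INTEGER), out_pos(n, NA_INTEGER),
      out_strand(n, NA_INTEGER), out_clipL(n, NA_INTEGER),
      out_matchL(n, NA_INTEGER), out_clipR(n, NA_INTEGER),
      out_nmm(n, NA_INTEGER), out_nhits(n, 0), out_mapq(n, 0);
  LogicalVector out_mapped(n, false);
  std::vector<int> mm_read, mm_pos, mm_chrom;
  std::vector<char> mm_base;
  std::vector<int> goff;
  std::vector<char> gb;
  std::string fwd;
  AlnOut res;
  for (int r = 0; r < n; ++r) {
    fwd.assign(CHAR(STRING_ELT(reads, r)));
    goff.clear(); gb.clear();
    al.align(fwd, res, &goff, &gb);
    out_nhits[r] = res.nhits;
    if (!res.mapped) continue;
    out_mapped[r] = true;
    out_chrom[r] = res.chrom + 1;
    out_pos[r] = res.gl + 1;
    out_strand[r] = res.strand;
    out_clipL[r] = res.clipL;
    out_matchL[r] = res.matchL;
    out_clipR[r] = res.clipR;
    out_nmm[r] = res.nmm;
    out_mapq[r] = res.mapq;
    for (size_t i = 0; i < goff.size(); ++i) {
      mm_read.push_back(r + 1);
      mm_chrom.push_back(res.chrom + 1);
      mm_pos.push_back(goff[i] + 1);
      mm_base.push_back(gb[i]);
    }
  }
  CharacterVector mmb(mm_base.size());
  for (size_t i = 0; i < mm_base.size(); ++i) {
    char s[2] = {mm_base[i], 0};
    mmb[i] = s;
  }
  return List::create(
      _["mapped"] = out_mapped, _["chrom"] = out_chrom, _["pos"] = out_pos,
      _["strand"] = out_strand, _["clipL"] = out_clipL,
      _["matchL"] = out_matchL, _["clipR"] = out_clipR, _["nmm"] = out_nmm,
      _["nhits"] = out_nhits, _["mapq"] = out_mapq,
      _["mm_read"] = IntegerVector(mm_read.begin(), mm_read.end()),
      _["mm_chrom"] = IntegerVector(mm_chrom.begin(), mm_chrom.end()),
      _["mm_pos"] = IntegerVector(mm_pos.begin(), mm_pos.end()),
      _["mm_base"] = mmb);
}

// Fused simulate-align-reduce for paired fragments at deep coverage.
// Fragments are given by chromosome/start/length; reads are the first
// read_len bases (mate 1) and the reverse complement of the last
// read_len bases (mate 2). Edits (genomic position, replacement base,
// fragment id; sorted by fragment id) encode haplotype alleles and
// sequencing errors. Reads are aligned end-to-end; per-strand coverage
// increment/decrement tallies (diff arrays, length len+1 per chromosome)
// and mismatch tallies are accumulated for records with
// mapq >= min_mapq.
// [[Rcpp::export]]
List cpp_align_fragments(SEXP xp, IntegerVector frag_chrom,
                         IntegerVector frag_start, IntegerVector frag_len,
                         int read_len,
                         IntegerVector edit_frag, IntegerVector edit_pos,
                         CharacterVector edit_base,
                         int max_mm, int max_hits, int min_mapq) {
  XPtr<SeedIndex> idx(xp);
  Aligner al;
  al.idx = idx.get();
  al.mode = 0; al.max_mm = max_mm; al.min_block = 0;
  al.max_hits = max_hits; al.xdrop = 12;
  const int nf = frag_chrom.size();
  const int nc = (int)idx->seqs.size();
  std::vector<std::vector<int>> inc_f(nc), dec_f(nc), inc_r(nc), dec_r(nc);
  for (int c = 0; c < nc; ++c) {
    size_t L = idx->seqs[(size_t)c].size() + 2;
    inc_f[c].assign(L, 0); dec_f[c].assign(L, 0);
    inc_r[c].assign(L, 0); dec_r[c].assign(L, 0);
  }
  // mismatch tally: key = chrom<<42 | pos<<10 | base<<2 | strand
  std::unordered_map<uint64_t, int> mmtab;
  std::string r1, r2;
  r1.resize((size_t)read_len);
  r2.resize((size_t)read_len);
  AlnOut res;
  std::vector<int> goff;
  std::vector<char> gb;
  int ei = 0;
  const int ne = edit_frag.size();
  long long mapped_reads = 0, aligned_bases = 0;
  for (int f = 0; f < nf; ++f) {
    int c = frag_chrom[f] - 1;
    const std::string& g = idx->seqs[(size_t)c];
    int st = frag_start[f] - 1;
    int L = frag_len[f];
    if (st < 0 || st + L > (int)g.size()) stop("fragment outside chromosome");
    if (L < read_len) stop("fragment shorter than read length");
    // mate 1: fragment head, forward
    std::copy(g.begin() + st, g.begin() + st + read_len, r1.begin());
    // mate 2: reverse complement of fragment tail
    int t0 = st + L - read_len;
    for (int i = 0; i < read_len; ++i)
      r2[(size_t)(read_len - 1 - i)] = comp_base(g[(size_t)(t0 + i)]);
    while (ei < ne && edit_frag[ei] == f + 1) {
      int p = edit_pos[ei] - 1;          // 0-based genomic position
      char b = CHAR(STRING_ELT(edit_base, ei))[0];
      int o1 = p - st;
      if (o1 >= 0 && o1 < read_len) r1[(size_t)o1] = b;
      int o2 = (st + L - 1) - p;         // offset from fragment end
      if (o2 >= 0 && o2 < read_len) r2[(size_t)o2] = comp_base(b);
      ++ei;
    }
    for (int mate = 0; mate < 2; ++mate) {
      const std::string& rd = mate ? r2 : r1;
      goff.clear(); gb.clear();
      al.align(rd, res, &goff, &gb);
      if (!res.mapped || res.mapq < min_mapq) continue;
      ++mapped_reads;
      aligned_bases += res.matchL;
      std::vector<int>& inc = res.strand ? inc_r[res.chrom] : inc_f[res.chrom];
      std::vector<int>& dec = res.strand ? dec_r[res.chrom] : dec_f[res.chrom];
      ++inc[(size_t)res.gl];
      ++dec[(size_t)(res.gl + res.matchL)];
      for (size_t i = 0; i < goff.size(); ++i) {
        int code = base_code(gb[i]);
        uint64_t key = ((uint64_t)res.chrom << 42) |
          ((uint64_t)goff[i] << 10) |
          ((uint64_t)(code < 0 ? 4 : code) << 2) | (uint64_t)res.strand;
        ++mmtab[key];
      }
    }
  }
  if (ei < ne) stop("edit list not sorted by fragment id");
  // export mismatch tallies
  size_t nm = mmtab.size();
  IntegerVector mchrom(nm), mpos(nm), mcount(nm), mstrand(nm);
  CharacterVector mbase(nm);
  const char* bs[5] = {"A", "C", "G", "T", "N"};
  size_t i = 0;
  for (auto& kv : mmtab) {
    mchrom[i] = (int)(kv.first >> 42) + 1;
    mpos[i] = (int)((kv.first >> 10) & 0xFFFFFFFFULL) + 1;
    mbase[i] = bs[(kv.first >> 2) & 7];
    mstrand[i] = (int)(kv.first & 3);
    mcount[i] = kv.second;
    ++i;
  }
  List covf(nc), covr(nc);
  for (int c = 0; c < nc; ++c) {
    size_t L = idx->seqs[(size_t)c].size();
    IntegerVector cf(L), cr(L);
    int acc = 0;
    for (size_t p = 0; p < L; ++p) {
      acc += inc_f[c][p] - dec_f[c][p];
      cf[p] = acc;
    }
    acc = 0;
    for (size_t p = 0; p < L; ++p) {
      acc += inc_r[c][p] - dec_r[c][p];
      cr[p] = acc;
    }
    covf[c] = cf; covr[c] = cr;
  }
  return List::create(_["cov_fwd"] = covf, _["cov_rev"] = covr,
                      _["mm_chrom"] = mchrom, _["mm_pos"] = mpos,
                      _["mm_base"] = mbase, _["mm_strand"] = mstrand,
                      _["mm_count"] = mcount,
                      _["mapped_reads"] = (double)mapped_reads,
                      _["aligned_bases"] = (double)aligned_bases);
}

// Extract read sequences (optionally reverse-complemented) from reference
// fragments; used by the read simulator.
// [[Rcpp::export]]
CharacterVector cpp_extract_reads(CharacterVector seqs, IntegerVector chrom,
                                  IntegerVector start, IntegerVector len,
                                  LogicalVector rc) {
  std::vector<std::string> g;
  for (int i = 0; i < seqs.size(); ++i)
    g.push_back(std::string(CHAR(STRING_ELT(seqs, i))));
  int n = chrom.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const std::string& s = g[(size_t)(chrom[i] - 1)];
    int st = start[i] - 1, L = len[i];
    if (st < 0 || st + L > (int)s.size()) stop("fragment outside chromosome");
    if (rc[i]) {
      buf.resize((size_t)L);
      for (int j = 0; j < L; ++j)
        buf[(size_t)(L - 1 - j)] = comp_base(s[(size_t)(st + j)]);
      SET_STRING_ELT(out, i, Rf_mkCharLen(buf.data(), L));
    } else {
      SET_STRING_ELT(out, i, Rf_mkCharLen(s.data() + st, L));
    }
  }
  return out;
}

// fast "prefix_i" identifier generation
// [[Rcpp::export]]
CharacterVector cpp_make_ids(std::string prefix, int n) {
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    buf = prefix;
    buf.push_back('_');
    buf += std::to_string(i + 1);
    SET_STRING_ELT(out, i, Rf_mkCharLen(buf.data(), (int)buf.size()));
  }
  return out;
}

// CIGAR strings from clip/match lengths, sharing CHARSXPs across reads
// [[Rcpp::export]]
CharacterVector cpp_make_cigars(IntegerVector clipL, IntegerVector matchL,
                                IntegerVector clipR, LogicalVector mapped) {
  int n = clipL.size();
  CharacterVector out(n);
  std::unordered_map<uint64_t, SEXP> cache;
  SEXP star = Rf_mkChar("*");
  std::string buf;
  for (int i = 0; i < n; ++i) {
    if (!mapped[i]) { SET_STRING_ELT(out, i, star); continue; }
    uint64_t key = ((uint64_t)clipL[i] << 40) | ((uint64_t)matchL[i] << 20) |
      (uint64_t)clipR[i];
    auto it = cache.find(key);
    if (it == cache.end()) {
      buf.clear();
      if (clipL[i] > 0) { buf += std::to_string(clipL[i]); buf.push_back('S'); }
      buf += std::to_string(matchL[i]); buf.push_back('M');
      if (clipR[i] > 0) { buf += std::to_string(clipR[i]); buf.push_back('S'); }
      SEXP cs = Rf_mkCharLen(buf.data(), (int)buf.size());
      it = cache.emplace(key, cs).first;
    }
    SET_STRING_ELT(out, i, it->second);
  }
  return out;
}
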