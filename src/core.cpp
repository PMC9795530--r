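#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

static inline bool valid_base(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': case 'C': case 'G': case 'T': case 'N': return true;
  }
  return false;
}

// Run-length ("homopolymer") compression of one nucleotide sequence.
// Runs are defined case-insensitively; the first character of each run is kept.
// If a quality string is supplied, the maximum quality within each run is kept.
// [[Rcpp::export(name = ".hpc_compress_one")]]
List hpc_compress_one(std::string seq, Nullable<CharacterVector> qual = R_NilValue) {
  const size_t n = seq.size();
  std::string cseq, cq, q;
  bool has_q = qual.isNotNull();
  if (has_q) {
    q = as<std::string>(CharacterVector(qual)[0]);
    if (q.size() != n)
      stop("quality string length (%d) differs from sequence length (%d)",
           (int)q.size(), (int)n);
  }
  cseq.reserve(n);
  std::vector<int> rl;
  rl.reserve(n / 2 + 1);
  size_t i = 0;
  while (i < n) {
    const char c = seq[i];
    if (!valid_base(c))
      stop("invalid nucleotide '%c' at position %d (expected A/C/G/T/N)",
           c, (int)(i + 1));
    const char cu = std::toupper(static_cast<unsigned char>(c));
    char qm = has_q ? q[i] : 0;
    size_t j = i + 1;
    while (j < n && std::toupper(static_cast<unsigned char>(seq[j])) == cu) {
      if (has_q && q[j] > qm) qm = q[j];
      ++j;
    }
    cseq.push_back(c);
    rl.push_back((int)(j - i));
    if (has_q) cq.push_back(qm);
    i = j;
  }
  List out = List::create(_["seq"] = cseq,
                          _["run_lengths"] = IntegerVector(rl.begin(), rl.end()));
  if (has_q) out["qual"] = cq;
  return out;
}

// Batch version for reads: compress sequences and (optionally) qualities.
// [[Rcpp::export(name = ".hpc_compress_batch")]]
List hpc_compress_batch(CharacterVector seqs, Nullable<CharacterVector> quals = R_NilValue) {
  const int n = seqs.size();
  CharacterVector cs(n), cq(n);
  bool has_q = quals.isNotNull();
  CharacterVector qv;
  if (has_q) {
    qv = CharacterVector(quals);
    if (qv.size() != n) stop("sequence and quality vectors differ in length");
  }
  for (int r = 0; r < n; ++r) {
    std::string s = std::string(CHAR(STRING_ELT(seqs, r)));
    List one;
    if (has_q)
      one = hpc_compress_one(s, CharacterVector::create(qv[r]));
    else
      one = hpc_compress_one(s, R_NilValue);
    cs[r] = as<std::string>(one["seq"]);
    if (has_q) cq[r] = as<std::string>(one["qual"]);
  }
  List out = List::create(_["seq"] = cs);
  if (has_q) out["qual"] = cq;
  return out;
}

struct CigOp { char op; int len; };

static void parse_cigar(const char* cg, std::vector<CigOp>& ops) {
  ops.clear();
  int num = 0;
  for (const char* p = cg; *p; ++p) {
    if (*p >= '0' && *p <= '9') {
      num = num * 10 + (*p - '0');
    } else {
      if (num <= 0) stop("malformed CIGAR '%s'", cg);
      ops.push_back({*p, num});
      num = 0;
    }
  }
  if (num != 0) stop("malformed CIGAR '%s'", cg);
}

// reference/read widths implied by CIGAR strings
// [[Rcpp::export(name = ".cigar_widths")]]
IntegerMatrix cigar_widths(CharacterVector cigar) {
  const int n = cigar.size();
  IntegerMatrix out(n, 2);
  colnames(out) = CharacterVector::create("ref_width", "read_width");
  std::vector<CigOp> ops;
  for (int r = 0; r < n; ++r) {
    parse_cigar(CHAR(STRING_ELT(cigar, r)), ops);
    int rw = 0, qw = 0;
    for (const CigOp& o : ops) {
      switch (o.op) {
        case 'M': case '=': case 'X': rw += o.len; qw += o.len; break;
        case 'D': case 'N': rw += o.len; break;
        case 'I': case 'S': qw += o.len; break;
        case 'H': case 'P': break;
        default: stop("unsupported CIGAR op '%c'", o.op);
      }
    }
    out(r, 0) = rw;
    out(r, 1) = qw;
  }
  return out;
}

// Walk every alignment's CIGAR and pull the read base over each haplotype site
// falling inside its reference span; score +1/-1/0 against the two phased
// alleles (per-site score of the read against haplotype A / haplotype B).
//
//   pos       0-based leftmost reference position per alignment
//   site_pos  0-based sorted site coordinates (one chromosome / phase set)
//   allele_a, allele_b  one character per site
//
// Returns flat parallel vectors grouped by read (read index non-decreasing),
// bases as a raw vector ('-' for sites under deletions), plus per-read ok
// flags (FALSE when CIGAR read-length != seq length) and reference widths.
// [[Rcpp::export(name = ".score_alignments_cpp")]]
List score_alignments_cpp(IntegerVector pos, CharacterVector cigar, CharacterVector seq,
                          IntegerVector site_pos, std::string allele_a, std::string allele_b) {
  const int n = pos.size();
  const int ns = site_pos.size();
  if ((int)allele_a.size() != ns || (int)allele_b.size() != ns)
    stop("allele strings must have one character per site");
  std::vector<int> v_read, v_site, v_score;
  std::vector<char> v_base;
  LogicalVector ok(n, true);
  IntegerVector refw(n);
  std::vector<CigOp> ops;
  const int* sp0 = INTEGER(site_pos);
  for (int r = 0; r < n; ++r) {
    const char* cg = CHAR(STRING_ELT(cigar, r));
    const char* sq = CHAR(STRING_ELT(seq, r));
    const int slen = (int)LENGTH(STRING_ELT(seq, r));
    parse_cigar(cg, ops);
    int rw = 0, qw = 0;
    for (const CigOp& o : ops) {
      if (o.op == 'M' || o.op == '=' || o.op == 'X') { rw += o.len; qw += o.len; }
      else if (o.op == 'D' || o.op == 'N') rw += o.len;
      else if (o.op == 'I' || o.op == 'S') qw += o.len;
    }
    refw[r] = rw;
    if (qw != slen) { ok[r] = false; continue; }
    int ref = pos[r], rd = 0;
    // first site at or beyond the alignment start
    int si = (int)(std::lower_bound(sp0, sp0 + ns, ref) - sp0);
    for (const CigOp& o : ops) {
      if (si >= ns) break;
      if (o.op == 'M' || o.op == '=' || o.op == 'X') {
        const int end = ref + o.len;
        while (si < ns && sp0[si] < end) {
          const char b = sq[rd + (sp0[si] - ref)];
          const char bu = std::toupper(static_cast<unsigned char>(b));
          int sc = 0;
          if (bu == allele_a[si]) sc = 1;
          else if (bu == allele_b[si]) sc = -1;
          v_read.push_back(r + 1);
          v_site.push_back(si + 1);
          v_score.push_back(sc);
          v_base.push_back(bu);
          ++si;
        }
        ref = end; rd += o.len;
      } else if (o.op == 'D' || o.op == 'N') {
        const int end = ref + o.len;
        while (si < ns && sp0[si] < end) {
          v_read.push_back(r + 1);
          v_site.push_back(si + 1);
          v_score.push_back(0);
          v_base.push_back('-');
          ++si;
        }
        ref = end;
      } else if (o.op == 'I' || o.op == 'S') {
        rd += o.len;
      }
    }
  }
  RawVector base(v_base.size());
  for (size_t i = 0; i < v_base.size(); ++i) base[i] = (Rbyte)v_base[i];
  return List::create(_["read"] = IntegerVector(v_read.begin(), v_read.end()),
                      _["site"] = IntegerVector(v_site.begin(), v_site.end()),
                      _["score"] = IntegerVector(v_score.begin(), v_score.end()),
                      _["base"] = base,
                      _["ok"] = ok,
                      _["ref_width"] = refw);
}

// Synthetic gamete-pool read batch in compressed coordinate space.
// Each read copies hapA/hapB (switching at offset bp when bp >= 0; b_first
// says which haplotype supplies the 5' side), injecting substitutions,
// single-base insertions and deletions.  Indel probabilities are multiplied
// by hp_mult at positions flagged as original homopolymer runs (hp_flag).
// Uses R's RNG.  Returns sequences, CIGARs and (possibly shifted) 0-based
// positions after trimming alignment-leading/trailing deletions.
// [[Rcpp::export(name = ".sim_read_batch")]]
List sim_read_batch(std::string hapA, std::string hapB, LogicalVector hp_flag,
                    IntegerVector start, IntegerVector len, IntegerVector bp,
                    LogicalVector b_first,
                    double p_sub, double p_ins, double p_del, double hp_mult) {
  const int nr = start.size();
  const int gl = (int)hapA.size();
  if ((int)hapB.size() != gl || hp_flag.size() != gl)
    stop("haplotype sequences and homopolymer flags must have equal length");
  CharacterVector seqs(nr), cigars(nr);
  IntegerVector out_pos(nr);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string read, cig;
  std::vector<CigOp> ops;
  char buf[16];
  for (int r = 0; r < nr; ++r) {
    const int s = start[r], L = len[r], b = bp[r];
    if (s < 0 || s + L > gl) stop("read %d outside genome bounds", r + 1);
    read.clear(); cig.clear(); ops.clear();
    read.reserve(L + L / 8 + 8);
    auto push_op = [&](char op, int m) {
      if (m <= 0) return;
      if (!ops.empty() && ops.back().op == op) ops.back().len += m;
      else ops.push_back({op, m});
    };
    const bool bf = b_first[r];
    for (int k = 0; k < L; ++k) {
      const int g = s + k;
      const bool hp = hp_flag[g];
      const bool second = (b >= 0 && k >= b);
      const char ref = second ? (bf ? hapA[g] : hapB[g]) : (bf ? hapB[g] : hapA[g]);
      const double pd = hp ? p_del * hp_mult : p_del;
      const double u = unif_rand();
      if (u < pd) {
        push_op('D', 1);
      } else if (u < pd + p_sub) {
        int t = (int)(unif_rand() * 3.0); if (t > 2) t = 2;
        const char ru = std::toupper(static_cast<unsigned char>(ref));
        char c = 'A'; int seen = 0;
        for (int bi = 0; bi < 4; ++bi) {
          if (bases[bi] != ru) { if (seen == t) { c = bases[bi]; break; } ++seen; }
        }
        read.push_back(c);
        push_op('M', 1);
      } else {
        read.push_back(ref);
        push_op('M', 1);
      }
      if (k < L - 1) {
        const double pi = hp ? p_ins * hp_mult : p_ins;
        if (unif_rand() < pi) {
          int t = (int)(unif_rand() * 4.0); if (t > 3) t = 3;
          read.push_back(bases[t]);
          push_op('I', 1);
        }
      }
    }
    int lead = 0;
    size_t o0 = 0, o1 = ops.size();
    while (o0 < o1 && ops[o0].op == 'D') { lead += ops[o0].len; ++o0; }
    while (o1 > o0 && ops[o1 - 1].op == 'D') --o1;
    for (size_t i = o0; i < o1; ++i) {
      snprintf(buf, sizeof(buf), "%d%c", ops[i].len, ops[i].op);
      cig += buf;
    }
    seqs[r] = read;
    cigars[r] = cig;
    out_pos[r] = s + lead;
  }
  return List::create(_["seq"] = seqs, _["cigar"] = cigars, _["pos"] = out_pos);
}
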