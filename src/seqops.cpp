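#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// status codes shared with R/preprocess.R (keep in sync)
enum TrimStatus { TRIMMED = 0, UNTRIMMED = 1, TOO_SHORT = 2, TOO_LONG = 3,
                  LOW_QUALITY = 4, HAS_N = 5, BAD_ALPHABET = 6,
                  NO_ADAPTER = 7 };

// 3' adapter removal: the leftmost suffix-anchored alignment of the adapter
// prefix is removed together with everything downstream of it.  The
// alignment overlap is min(read_len - i, adapter_len); it must be at least
// min_overlap and carry a mismatch rate <= max_mm_rate.
// [[Rcpp::export]]
List trim_reads_cpp(CharacterVector seqs, CharacterVector quals,
                    std::string adapter, int min_overlap,
                    double max_mm_rate, int min_len, int max_len,
                    double min_qual, bool require_adapter) {
  int n = seqs.size();
  CharacterVector out(n);
  IntegerVector status(n);
  int alen = (int) adapter.size();
  bool have_adapter = alen > 0;

  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int L = (int) s.size();
    bool bad = false;
    for (int i = 0; i < L; ++i) {
      char c = s[i];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'N') {
        bad = true; break;
      }
    }
    if (bad) { out[r] = s; status[r] = BAD_ALPHABET; continue; }

    int cut = -1;
    if (have_adapter) {
      for (int i = 0; i <= L - min_overlap; ++i) {
        int ov = std::min(L - i, alen);
        if (ov < min_overlap) break;
        int mm = 0, allowed = (int) std::floor(max_mm_rate * ov);
        for (int k = 0; k < ov; ++k) {
          if (s[i + k] != adapter[k]) {
            if (++mm > allowed) break;
          }
        }
        if (mm <= allowed) { cut = i; break; }
      }
    }
    std::string t;
    bool trimmed = cut >= 0;
    if (trimmed) t = s.substr(0, cut);
    else t = s;
    if (!trimmed && require_adapter && have_adapter) {
      out[r] = s; status[r] = NO_ADAPTER; continue;
    }
    int TL = (int) t.size();
    if (TL < min_len) { out[r] = t; status[r] = TOO_SHORT; continue; }
    if (TL > max_len) { out[r] = t; status[r] = TOO_LONG; continue; }
    if (t.find('N') != std::string::npos) {
      out[r] = t; status[r] = HAS_N; continue;
    }
    if (min_qual > 0 && r < quals.size() && quals[r] != NA_STRING) {
      std::string q = as<std::string>(quals[r]);
      if ((int) q.size() >= TL && TL > 0) {
        double mean = 0.0;
        for (int k = 0; k < TL; ++k) mean += (double) (q[k] - 33);
        mean /= TL;
        if (mean < min_qual) { out[r] = t; status[r] = LOW_QUALITY; continue; }
      }
    }
    out[r] = t;
    status[r] = trimmed ? TRIMMED : UNTRIMMED;
  }
  return List::create(_["sequence"] = out, _["status"] = status);
}

// First library entry containing each read as an exact substring.
// Returns 1-based ref index (0 = none) and the 0-based start offset.
// [[Rcpp::export]]
List substring_assign_cpp(CharacterVector reads, CharacterVector refs) {
  int n = reads.size(), m = refs.size();
  std::vector<std::string> R(m);
  for (int j = 0; j < m; ++j) R[j] = as<std::string>(refs[j]);
  IntegerVector hit(n, 0), pos(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    for (int j = 0; j < m; ++j) {
      size_t p = R[j].find(s);
      if (p != std::string::npos) {
        hit[i] = j + 1;
        pos[i] = (int) p;
        break;
      }
    }
  }
  return List::create(_["ref"] = hit, _["pos"] = pos);
}

// IsomiR-tolerant matcher: read vs mature sequences allowing a 5' offset in
// [-max_off, max_off], <= max_clip soft-clipped 3' bases and <= max_mm
// internal mismatches in the aligned core.  Read position t aligns to
// mature position off + t (0-based).  Bases with off + t < 0 (read starts
// upstream of the mature 5' end) are left unchecked here and resolved
// against the precursor downstream.  Score = mismatches + clip + |offset|;
// the lowest score wins, ties go to the earliest ref in input order with an
// ambiguity flag.
// [[Rcpp::export]]
DataFrame isomir_match_cpp(CharacterVector reads, CharacterVector matures,
                           int max_mm, int max_clip, int max_off,
                           int min_core) {
  int n = reads.size(), m = matures.size();
  std::vector<std::string> M(m);
  for (int j = 0; j < m; ++j) M[j] = as<std::string>(matures[j]);
  IntegerVector ref(n, 0), off(n, NA_INTEGER), clip(n, NA_INTEGER),
    nmm(n, NA_INTEGER), mmpos(n, NA_INTEGER);
  CharacterVector mmread(n, NA_STRING), mmref(n, NA_STRING);
  LogicalVector ambiguous(n, false);

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    int L = (int) s.size();
    int bestScore = 1 << 30;
    for (int j = 0; j < m; ++j) {
      const std::string& mat = M[j];
      int ML = (int) mat.size();
      for (int d = -max_off; d <= max_off; ++d) {
        int lead = d < 0 ? -d : 0;
        // minimal clip so the core stays inside the mature sequence
        int cmin = std::max(0, L + d - ML);
        for (int c = cmin; c <= max_clip; ++c) {
          int coreEnd = L - c;           // exclusive, read coords
          int coreLen = coreEnd - lead;
          if (coreLen < min_core) continue;
          int mm = 0, mp = -1;
          for (int t = lead; t < coreEnd; ++t) {
            if (s[t] != mat[d + t]) {
              if (++mm > max_mm) break;
              mp = t;
            }
          }
          if (mm > max_mm) continue;
          int score = mm + c + (d < 0 ? -d : d);
          if (score < bestScore) {
            bestScore = score;
            ref[i] = j + 1;
            off[i] = d;
            clip[i] = c;
            nmm[i] = mm;
            ambiguous[i] = false;
            if (mm > 0) {
              mmpos[i] = mp;
              mmread[i] = std::string(1, s[mp]);
              mmref[i] = std::string(1, mat[d + mp]);
            } else {
              mmpos[i] = NA_INTEGER;
              mmread[i] = NA_STRING;
              mmref[i] = NA_STRING;
            }
          } else if (score == bestScore && ref[i] != j + 1 && ref[i] > 0) {
            ambiguous[i] = true;
          }
        }
      }
    }
  }
  return DataFrame::create(_["ref"] = ref, _["offset"] = off,
                           _["clip"] = clip, _["n_mismatch"] = nmm,
                           _["mm_pos"] = mmpos, _["mm_read"] = mmread,
                           _["mm_ref"] = mmref, _["ambiguous"] = ambiguous,
                           _["stringsAsFactors"] = false);
}

// All exact occurrences (0-based starts) of each pattern in one subject.
// [[Rcpp::export]]
List find_occurrences_cpp(CharacterVector patterns, std::string subject) {
  int n = patterns.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::string p = as<std::string>(patterns[i]);
    std::vector<int> hits;
    if (!p.empty()) {
      size_t at = subject.find(p, 0);
      while (at != std::string::npos) {
        hits.push_back((int) at);
        at = subject.find(p, at + 1);
      }
    }
    out[i] = wrap(hits);
  }
  return out;
}
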