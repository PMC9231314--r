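#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

// Seed-and-extend ungapped translated search kernel.
//
// frame_aa:  one translated reading frame (amino acids, may contain '*'/'X')
// proteins:  protein database sequences
// score_mat: square substitution matrix (e.g. BLOSUM62)
// letters:   row/column alphabet of score_mat, as a single string
// k:         exact-match seed length (amino acids)
// x_drop:    ungapped X-drop extension threshold
// min_score, min_len: hit reporting thresholds
//
// Returns one row per extended seed surviving the thresholds, with 0-based
// half-open amino-acid coordinates on the frame (q_*) and subject (s_*).
// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string frame_aa, CharacterVector proteins,
                          IntegerMatrix score_mat, std::string letters,
                          int k, double x_drop, double min_score,
                          int min_len) {
  const int n_letters = letters.size();
  std::vector<int> code(256, -1);
  for (int i = 0; i < n_letters; ++i) {
    code[(unsigned char) letters[i]] = i;
  }
  // seeds are restricted to the 20 standard residues
  const std::string std_aa = "ARNDCQEGHILKMFPSTWYV";
  std::vector<bool> seedable(256, false);
  for (size_t i = 0; i < std_aa.size(); ++i) {
    seedable[(unsigned char) std_aa[i]] = true;
  }

  const int np = proteins.size();
  std::vector<std::string> prot(np);
  for (int j = 0; j < np; ++j) prot[j] = as<std::string>(proteins[j]);

  // k-mer index over all proteins: code -> (protein, position)
  std::unordered_map<long long, std::vector<std::pair<int, int> > > index;
  for (int j = 0; j < np; ++j) {
    const std::string &p = prot[j];
    if ((int) p.size() < k) continue;
    for (int pos = 0; pos + k <= (int) p.size(); ++pos) {
      long long h = 0;
      bool ok = true;
      for (int t = 0; t < k; ++t) {
        unsigned char c = p[pos + t];
        if (!seedable[c] || code[c] < 0) { ok = false; break; }
        h = h * 32 + code[c];
      }
      if (ok) index[h].push_back(std::make_pair(j, pos));
    }
  }

  const int qn = frame_aa.size();
  auto sc = [&](unsigned char a, unsigned char b) -> int {
    int ia = code[a], ib = code[b];
    if (ia < 0 || ib < 0) return -4;
    return score_mat(ia, ib);
  };

  // per (protein, diagonal) rightmost query end already covered
  std::unordered_map<long long, int> reach;

  std::vector<int> out_subj, out_qs, out_qe, out_ss, out_se, out_len,
      out_match;
  std::vector<double> out_score;

  for (int i = 0; i + k <= qn; ++i) {
    long long h = 0;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      unsigned char c = frame_aa[i + t];
      if (!seedable[c] || code[c] < 0) { ok = false; break; }
      h = h * 32 + code[c];
    }
    if (!ok) continue;
    auto it = index.find(h);
    if (it == index.end()) continue;
    for (size_t m = 0; m < it->second.size(); ++m) {
      int j = it->second[m].first;
      int pos = it->second[m].second;
      long long dkey = (long long) j * 2000003LL + (i - pos) + 1000000LL;
      auto r = reach.find(dkey);
      if (r != reach.end() && r->second >= i) continue;  // inside prior hit
      const std::string &p = prot[j];
      // seed score
      double s0 = 0;
      for (int t = 0; t < k; ++t) s0 += sc(frame_aa[i + t], p[pos + t]);
      // extend right
      double best_r = 0, run = 0;
      int ext_r = 0;
      for (int t = 0; i + k + t < qn && pos + k + t < (int) p.size(); ++t) {
        run += sc(frame_aa[i + k + t], p[pos + k + t]);
        if (run > best_r) { best_r = run; ext_r = t + 1; }
        if (best_r - run > x_drop) break;
      }
      // extend left
      double best_l = 0;
      int ext_l = 0;
      run = 0;
      for (int t = 1; i - t >= 0 && pos - t >= 0; ++t) {
        run += sc(frame_aa[i - t], p[pos - t]);
        if (run > best_l) { best_l = run; ext_l = t; }
        if (best_l - run > x_drop) break;
      }
      int qs = i - ext_l, qe = i + k + ext_r;
      int ss = pos - ext_l, se = pos + k + ext_r;
      double total = s0 + best_r + best_l;
      reach[dkey] = qe - 1;
      int len = qe - qs;
      if (total < min_score || len < min_len) continue;
      int nmatch = 0;
      for (int t = 0; t < len; ++t) {
        if (frame_aa[qs + t] == p[ss + t]) ++nmatch;
      }
      out_subj.push_back(j + 1);
      out_qs.push_back(qs);
      out_qe.push_back(qe);
      out_ss.push_back(ss);
      out_se.push_back(se);
      out_score.push_back(total);
      out_match.push_back(nmatch);
      out_len.push_back(len);
    }
  }

  return DataFrame::create(
      Named("subject") = out_subj, Named("q_start_aa") = out_qs,
      Named("q_end_aa") = out_qe, Named("s_start_aa") = out_ss,
      Named("s_end_aa") = out_se, Named("score") = out_score,
      Named("n_match") = out_match, Named("aln_len_aa") = out_len);
}
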