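#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ungapped minimal-mismatch scan of each read against every
// offset of every reference. Reads and references are expected to be in the
// same symbol space (for bisulfite alignment both are C->T collapsed before
// the call). Returns all champion alignments per read: every reference
// achieving the global minimum mismatch count (<= max_mismatch), at its
// leftmost best offset. Early termination keeps the inner loop cheap once a
// good champion exists.
//
// [[Rcpp::export]]
DataFrame cpp_scan_align(CharacterVector reads, CharacterVector refs,
                         int max_mismatch) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::string> F(nf);
  for (int f = 0; f < nf; ++f) F[f] = as<std::string>(refs[f]);

  std::vector<int> out_read, out_ref, out_start, out_mm;

  for (int r = 0; r < nr; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    const int l = (int)rd.size();
    int best = max_mismatch + 1;
    std::vector<int> bref, bstart;

    for (int f = 0; f < nf; ++f) {
      const std::string &rf = F[f];
      const int L = (int)rf.size();
      if (l > L) continue;
      bool f_added = false;
      for (int s = 0; s + l <= L; ++s) {
        int mm = 0;
        const char *a = rd.data(), *b = rf.data() + s;
        for (int i = 0; i < l; ++i) {
          if (a[i] != b[i] && ++mm > best) break;
        }
        if (mm > max_mismatch || mm > best) continue;
        if (mm < best) {
          best = mm;
          bref.clear(); bstart.clear();
          bref.push_back(f); bstart.push_back(s + 1);
          f_added = true;
          if (best == 0 && f_added) {
            // cannot improve within this reference; leftmost 0-mm kept
            break;
          }
        } else if (!f_added) {  // mm == best, first (leftmost) hit in this ref
          bref.push_back(f); bstart.push_back(s + 1);
          f_added = true;
          if (best == 0) break;
        }
      }
    }
    for (size_t k = 0; k < bref.size(); ++k) {
      out_read.push_back(r + 1);
      out_ref.push_back(bref[k] + 1);
      out_start.push_back(bstart[k]);
      out_mm.push_back(best);
    }
  }
  return DataFrame::create(_["read_idx"] = out_read,
                           _["ref_idx"] = out_ref,
                           _["start"] = out_start,
                           _["mismatches"] = out_mm);
}
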