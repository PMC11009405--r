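#include <Rcpp.h>
using namespace Rcpp;

// Connected components (4-connectivity) over a freq x time grid of
// suprathreshold bins; returns the summed statistic per cluster.
// Values are laid out column-major: bin (f, t) at index f + t*nf.
static void cluster_scan(const double* tval, int nf, int nt, double thresh,
                         bool negative, std::vector<double>& masses,
                         std::vector<int>* labels) {
  int nb = nf * nt;
  std::vector<int> lab(nb, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < nb; ++s) {
    bool supra = negative ? (tval[s] < thresh) : (tval[s] > thresh);
    if (!supra || lab[s]) continue;
    ++next;
    double mass = 0.0;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      mass += tval[c];
      int f = c % nf, t = c / nf;
      int nb4[4] = {f > 0 ? c - 1 : -1, f < nf - 1 ? c + 1 : -1,
                    t > 0 ? c - nf : -1, t < nt - 1 ? c + nf : -1};
      for (int k = 0; k < 4; ++k) {
        int q = nb4[k];
        if (q >= 0) {
          bool qs = negative ? (tval[q] < thresh) : (tval[q] > thresh);
          if (qs && !lab[q]) {
            lab[q] = next;
            stack.push_back(q);
          }
        }
      }
    }
    masses.push_back(mass);
  }
  if (labels) *labels = lab;
}

// [[Rcpp::export]]
List c_cluster_masses(NumericMatrix tmap, double thresh, bool negative) {
  std::vector<double> masses;
  std::vector<int> labels;
  cluster_scan(&tmap(0, 0), tmap.nrow(), tmap.ncol(), thresh, negative,
               masses, &labels);
  IntegerMatrix lab(tmap.nrow(), tmap.ncol());
  for (int i = 0; i < (int)labels.size(); ++i) lab[i] = labels[i];
  return List::create(_["masses"] = wrap(masses), _["labels"] = lab);
}

// Null distribution of the maximal |cluster mass| under within-subject
// sign flips. diffs: n_subj x (nf*nt) matrix of per-subject condition
// differences; signs: n_perm x n_subj matrix of +/-1.
// [[Rcpp::export]]
NumericVector c_perm_max_mass(NumericMatrix diffs, int nf, int nt,
                              double thresh, bool negative,
                              IntegerMatrix signs) {
  int n = diffs.nrow(), nb = diffs.ncol(), P = signs.nrow();
  if (nb != nf * nt) stop("grid dimensions do not match");
  std::vector<double> ss(nb, 0.0);
  for (int j = 0; j < nb; ++j)
    for (int i = 0; i < n; ++i) ss[j] += diffs(i, j) * diffs(i, j);
  NumericVector out(P);
  std::vector<double> tval(nb);
  for (int p = 0; p < P; ++p) {
    for (int j = 0; j < nb; ++j) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += signs(p, i) * diffs(i, j);
      m /= n;
      double v = (ss[j] - n * m * m) / (n - 1);
      tval[j] = v > 0 ? m / std::sqrt(v / n) : 0.0;
    }
    std::vector<double> masses;
    cluster_scan(tval.data(), nf, nt, thresh, negative, masses, nullptr);
    double mx = 0.0;
    for (double ms : masses) mx = std::max(mx, std::fabs(ms));
    out[p] = mx;
  }
  return out;
}
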