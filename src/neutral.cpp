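#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// log(exp(a) + exp(b)) without overflow
static inline double logadd(double a, double b) {
    if (a == R_NegInf) return b;
    if (b == R_NegInf) return a;
    double m = a > b ? a : b;
    return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Log-scale K(D,A) coefficients of the Etienne sampling formula.
// Per species with abundance n the coefficient polynomial over a = 1..n has
// coefficients s1(n,a) * (a-1)! / (n-1)!  (s1 = unsigned Stirling, first kind);
// K(D,A) is the coefficient of x^A in the product over species. Everything is
// kept in log space; the returned vector covers degrees A = S..J.
// [[Rcpp::export]]
NumericVector logK_cpp(IntegerVector n) {
    int S = n.size();
    if (S == 0) stop("empty abundance configuration");
    int maxn = 0;
    for (int i = 0; i < S; i++) {
        if (n[i] < 1) stop("abundances must be positive integers");
        if (n[i] > maxn) maxn = n[i];
    }

    // log unsigned Stirling rows, recurrence s1(m,k) = s1(m-1,k-1) + (m-1) s1(m-1,k);
    // only rows for abundance values present in D are retained.
    std::vector<bool> need(maxn + 1, false);
    for (int i = 0; i < S; i++) need[n[i]] = true;
    std::map<int, std::vector<double> > rows;
    std::vector<double> prev(1, 0.0); // row m=1: s1(1,1) = 1
    if (need[1]) rows[1] = prev;
    for (int m = 2; m <= maxn; m++) {
        std::vector<double> cur(m);
        double lm1 = std::log((double)(m - 1));
        cur[0] = lm1 + prev[0];
        for (int k = 2; k < m; k++)
            cur[k - 1] = logadd(prev[k - 2], lm1 + prev[k - 1]);
        cur[m - 1] = 0.0;
        if (need[m]) rows[m] = cur;
        prev.swap(cur);
    }

    // sequential log-space polynomial convolution
    std::vector<double> res;
    bool first = true;
    for (int i = 0; i < S; i++) {
        int ni = n[i];
        std::vector<double> &sr = rows[ni];
        std::vector<double> c(ni);
        double lgn = R::lgammafn((double)ni);
        for (int a = 1; a <= ni; a++)
            c[a - 1] = sr[a - 1] + R::lgammafn((double)a) - lgn;
        if (first) { res = c; first = false; continue; }
        int L = (int)res.size(), M = ni;
        std::vector<double> out(L + M - 1, R_NegInf);
        for (int t = 0; t < L + M - 1; t++) {
            int jlo = t - M + 1 < 0 ? 0 : t - M + 1;
            int jhi = t < L - 1 ? t : L - 1;
            double mx = R_NegInf;
            for (int j = jlo; j <= jhi; j++) {
                double v = res[j] + c[t - j];
                if (v > mx) mx = v;
            }
            if (mx == R_NegInf) { out[t] = R_NegInf; continue; }
            double s2 = 0.0;
            for (int j = jlo; j <= jhi; j++)
                s2 += std::exp(res[j] + c[t - j] - mx);
            out[t] = mx + std::log(s2);
        }
        res.swap(out);
    }
    return wrap(res);
}

// Sequential two-level urn construction of neutral local communities.
// Individual k of a community is a new immigrant ancestor with probability
// I/(I + k - 1), otherwise it copies a uniformly chosen earlier individual of
// the same community. Ancestor a takes a new metacommunity species with
// probability theta/(theta + a - 1), otherwise copies a uniformly chosen
// earlier ancestor. The ancestor (metacommunity) urn is shared across
// communities when `shared` is true. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix urn_sim_cpp(int n_comm, int J, double theta, NumericVector I,
                          bool shared) {
    if (n_comm < 1 || J < 1) stop("n_communities and J must be >= 1");
    if (!(theta > 0)) stop("theta must be > 0");
    std::vector<int> anc_species;
    int n_species = 0;
    std::vector< std::vector<int> > comm_counts(n_comm);
    std::vector<int> indiv;
    indiv.reserve(J);

    for (int c = 0; c < n_comm; c++) {
        if (!shared) anc_species.clear();
        double Ic = I[c % I.size()];
        if (!(Ic > 0)) stop("I must be > 0");
        indiv.clear();
        for (int k = 1; k <= J; k++) {
            bool immigrant;
            if (!R_finite(Ic)) immigrant = true;
            else immigrant = (unif_rand() * (Ic + k - 1.0) < Ic);
            int sp;
            if (immigrant) {
                int a = (int)anc_species.size() + 1;
                bool newsp = (unif_rand() * (theta + a - 1.0) < theta);
                if (newsp) {
                    sp = n_species++;
                } else {
                    int idx = (int)(unif_rand() * (a - 1));
                    if (idx > a - 2) idx = a - 2;
                    sp = anc_species[idx];
                }
                anc_species.push_back(sp);
            } else {
                int m = (int)indiv.size();
                int idx = (int)(unif_rand() * m);
                if (idx > m - 1) idx = m - 1;
                sp = indiv[idx];
            }
            indiv.push_back(sp);
        }
        std::vector<int> &cc = comm_counts[c];
        for (int t = 0; t < J; t++) {
            int sp = indiv[t];
            if ((int)cc.size() <= sp) cc.resize(sp + 1, 0);
            cc[sp]++;
        }
    }

    IntegerMatrix out(n_comm, n_species);
    for (int c = 0; c < n_comm; c++)
        for (int s = 0; s < (int)comm_counts[c].size(); s++)
            out(c, s) = comm_counts[c][s];
    return out;
}
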