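#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sequences arrive as integer codes 0..3 (A,C,G,T); 4 marks N/masked bases.
// A window containing any masked base is unusable and carries no likelihood.

static inline void windowScores(const std::vector<int>& c,
                                const std::vector<double>& lo, // 4 x W, col-major
                                int W, std::vector<double>& out) {
    int L = (int)c.size();
    int nw = L - W + 1;
    if (nw < 0) nw = 0;
    out.assign(nw, NA_REAL);
    for (int w = 0; w < nw; ++w) {
        double s = 0.0;
        bool ok = true;
        for (int j = 0; j < W; ++j) {
            int b = c[w + j];
            if (b > 3) { ok = false; break; }
            s += lo[4 * j + b];
        }
        if (ok) out[w] = s;
    }
}

static std::vector<std::vector<int> > asCodes(const List& seqs) {
    std::vector<std::vector<int> > out(seqs.size());
    for (int i = 0; i < seqs.size(); ++i) {
        IntegerVector v = seqs[i];
        out[i].assign(v.begin(), v.end());
    }
    return out;
}

// One E-step over all sequences for the current log-odds matrix.
// Fills per-sequence window responsibilities (zoops/oops) and returns the
// total log-likelihood ratio against the background-only model.
struct EStep {
    double llr;
    std::vector<std::vector<double> > zf, zr; // responsibilities per window
    std::vector<double> sitep;                // P(site present) per sequence
};

static void estep(const std::vector<std::vector<int> >& fwd,
                  const std::vector<std::vector<int> >& rev,
                  const std::vector<double>& lo, int W,
                  double gamma, bool oops, EStep& E) {
    int n = (int)fwd.size();
    bool both = !rev.empty();
    E.llr = 0.0;
    E.zf.assign(n, std::vector<double>());
    E.zr.assign(n, std::vector<double>());
    E.sitep.assign(n, 0.0);
    std::vector<double> sf, sr;
    for (int i = 0; i < n; ++i) {
        windowScores(fwd[i], lo, W, sf);
        if (both) windowScores(rev[i], lo, W, sr); else sr.clear();
        int m = 0;
        double M = R_NegInf;
        for (size_t w = 0; w < sf.size(); ++w)
            if (!ISNA(sf[w])) { ++m; if (sf[w] > M) M = sf[w]; }
        for (size_t w = 0; w < sr.size(); ++w)
            if (!ISNA(sr[w])) { ++m; if (sr[w] > M) M = sr[w]; }
        E.zf[i].assign(sf.size(), 0.0);
        E.zr[i].assign(sr.size(), 0.0);
        if (m == 0) {
            // no usable window: background-only sequence
            if (!oops) E.llr += std::log(1.0 - gamma);
            continue;
        }
        double A = 0.0;
        for (size_t w = 0; w < sf.size(); ++w)
            if (!ISNA(sf[w])) A += std::exp(sf[w] - M);
        for (size_t w = 0; w < sr.size(); ++w)
            if (!ISNA(sr[w])) A += std::exp(sr[w] - M);
        double denom, lli;
        if (oops) {
            denom = A;
            lli = M + std::log(A) - std::log((double)m);
            E.sitep[i] = 1.0;
        } else {
            double noSite = (1.0 - gamma) * std::exp(-M);
            denom = noSite + (gamma / m) * A;
            lli = M + std::log(denom);
            E.sitep[i] = (gamma / m) * A / denom;
        }
        E.llr += lli;
        double zf0 = oops ? (1.0 / denom) : ((gamma / m) / denom);
        for (size_t w = 0; w < sf.size(); ++w)
            if (!ISNA(sf[w])) E.zf[i][w] = zf0 * std::exp(sf[w] - M);
        for (size_t w = 0; w < sr.size(); ++w)
            if (!ISNA(sr[w])) E.zr[i][w] = zf0 * std::exp(sr[w] - M);
    }
}

static void logOdds(const NumericMatrix& p, const NumericVector& bg,
                    std::vector<double>& lo) {
    int W = p.ncol();
    lo.assign(4 * W, 0.0);
    for (int j = 0; j < W; ++j)
        for (int b = 0; b < 4; ++b)
            lo[4 * j + b] = std::log(p(b, j)) - std::log(bg[b]);
}

// [[Rcpp::export(name = ".cpp_em_run")]]
List cpp_em_run(List fwdSeqs, List revSeqs, NumericMatrix p0, NumericVector bg,
                double gamma, bool oops, int maxIter, double tol,
                double pseudocount) {
    std::vector<std::vector<int> > fwd = asCodes(fwdSeqs);
    std::vector<std::vector<int> > rev = asCodes(revSeqs);
    int W = p0.ncol();
    int n = (int)fwd.size();
    NumericMatrix p = clone(p0);
    std::vector<double> lo;
    std::vector<double> trace, objTrace;
    EStep E;
    double prev = R_NegInf;
    for (int it = 0; it < maxIter; ++it) {
        logOdds(p, bg, lo);
        estep(fwd, rev, lo, W, gamma, oops, E);
        trace.push_back(E.llr);
        // MAP-EM objective: llr plus the Dirichlet(pc+1) log-prior of the
        // motif columns; this, not the raw llr, is the monotone quantity
        double prior = 0.0;
        if (pseudocount > 0.0)
            for (int j = 0; j < W; ++j)
                for (int b = 0; b < 4; ++b)
                    prior += pseudocount * std::log(p(b, j));
        double obj = E.llr + prior;
        objTrace.push_back(obj);
        if (it > 0 && obj - prev < tol) break;
        prev = obj;
        // M-step: expected base counts per motif column
        NumericMatrix cnt(4, W);
        std::fill(cnt.begin(), cnt.end(), pseudocount);
        for (int i = 0; i < n; ++i) {
            for (size_t w = 0; w < E.zf[i].size(); ++w) {
                double z = E.zf[i][w];
                if (z <= 0.0) continue;
                for (int j = 0; j < W; ++j) cnt(fwd[i][w + j], j) += z;
            }
            for (size_t w = 0; w < E.zr[i].size(); ++w) {
                double z = E.zr[i][w];
                if (z <= 0.0) continue;
                for (int j = 0; j < W; ++j) cnt(rev[i][w + j], j) += z;
            }
        }
        for (int j = 0; j < W; ++j) {
            double s = cnt(0, j) + cnt(1, j) + cnt(2, j) + cnt(3, j);
            for (int b = 0; b < 4; ++b) p(b, j) = cnt(b, j) / s;
        }
    }
    // occurrences from the final responsibilities (consistent with trace tail)
    IntegerVector bestStart(n, NA_INTEGER), bestStrand(n, NA_INTEGER);
    NumericVector bestZ(n, 0.0), sitep(n);
    for (int i = 0; i < n; ++i) {
        sitep[i] = E.sitep[i];
        double zb = -1.0;
        for (size_t w = 0; w < E.zf[i].size(); ++w)
            if (E.zf[i][w] > zb) { zb = E.zf[i][w]; bestStart[i] = (int)w + 1; bestStrand[i] = 1; }
        for (size_t w = 0; w < E.zr[i].size(); ++w)
            if (E.zr[i][w] > zb) { zb = E.zr[i][w]; bestStart[i] = (int)w + 1; bestStrand[i] = 2; }
        bestZ[i] = zb;
    }
    return List::create(_["p"] = p,
                        _["trace"] = NumericVector(trace.begin(), trace.end()),
                        _["objTrace"] = NumericVector(objTrace.begin(),
                                                      objTrace.end()),
                        _["obj"] = objTrace.back(),
                        _["llr"] = trace.back(),
                        _["bestStart"] = bestStart,
                        _["bestStrand"] = bestStrand,
                        _["bestZ"] = bestZ,
                        _["sitep"] = sitep);
}

// Log-likelihood ratio of each near-indicator seed model (one E-step, no
// update); used to shortlist starting points before full EM.
// [[Rcpp::export(name = ".cpp_seed_ll")]]
NumericVector cpp_seed_ll(List fwdSeqs, List revSeqs, IntegerMatrix seeds,
                          NumericVector bg, double gamma, bool oops,
                          double pMatch) {
    std::vector<std::vector<int> > fwd = asCodes(fwdSeqs);
    std::vector<std::vector<int> > rev = asCodes(revSeqs);
    int W = seeds.ncol();
    int ns = seeds.nrow();
    NumericVector out(ns);
    double pOther = (1.0 - pMatch) / 3.0;
    std::vector<double> lo(4 * W);
    EStep E;
    for (int s = 0; s < ns; ++s) {
        for (int j = 0; j < W; ++j)
            for (int b = 0; b < 4; ++b)
                lo[4 * j + b] = std::log(b == seeds(s, j) ? pMatch : pOther)
                    - std::log(bg[b]);
        estep(fwd, rev, lo, W, gamma, oops, E);
        out[s] = E.llr;
    }
    return out;
}

// Lattice window scores for PWM scanning: integer scores, NA for windows
// containing unknown bases.
// [[Rcpp::export(name = ".cpp_window_lattice")]]
NumericVector cpp_window_lattice(IntegerVector codes, NumericMatrix lat) {
    int W = lat.ncol();
    int L = codes.size();
    int nw = L - W + 1;
    if (nw < 0) nw = 0;
    NumericVector out(nw);
    for (int w = 0; w < nw; ++w) {
        double s = 0.0;
        bool ok = true;
        for (int j = 0; j < W; ++j) {
            int b = codes[w + j];
            if (b == NA_INTEGER || b > 3) { ok = false; break; }
            s += lat(b, j);
        }
        out[w] = ok ? s : NA_REAL;
    }
    return out;
}
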