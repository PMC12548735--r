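#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dynamic programming core for local (Smith-Waterman-style entry/exit)
// profile-HMM alignment. Everything is in natural-log odds against the
// background null; insert states are background-tied so their emission
// log-odds is 0. Entry is uniform over match states (-log M), exit from
// any match state is free. Conversion to bits happens in R.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
    if (a == NEG_INF) return b;
    if (b == NEG_INF) return a;
    double m = a > b ? a : b;
    return m + log1p(exp((a < b ? a : b) - m));
}

// lod: M x n matrix of match emission log-odds, lod(j-1, i-1) = log(e_j(x_i)/bg(x_i))
// transition vectors have length M-1 (log probabilities), indexed by the
// source column j = 1..M-1 (0-based j-1).
// [[Rcpp::export]]
List phmm_viterbi_cpp(NumericMatrix lod,
                      NumericVector tMM, NumericVector tMI, NumericVector tMD,
                      NumericVector tIM, NumericVector tII,
                      NumericVector tDM, NumericVector tDD) {
    const int M = lod.nrow(), n = lod.ncol();
    const double entry = -std::log((double)M);

    NumericMatrix VM(n + 1, M + 1), VI(n + 1, M + 1), VD(n + 1, M + 1);
    IntegerMatrix BM(n + 1, M + 1), BI(n + 1, M + 1), BD(n + 1, M + 1);
    std::fill(VM.begin(), VM.end(), NEG_INF);
    std::fill(VI.begin(), VI.end(), NEG_INF);
    std::fill(VD.begin(), VD.end(), NEG_INF);

    double best = NEG_INF; int bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= M; ++j) {
            // match state
            double sc = entry; int bp = 0; // 0 = fresh entry
            if (j > 1) {
                double v = VM(i - 1, j - 1) + tMM[j - 2];
                if (v > sc) { sc = v; bp = 1; }
                v = VI(i - 1, j - 1) + tIM[j - 2];
                if (v > sc) { sc = v; bp = 2; }
                v = VD(i - 1, j - 1) + tDM[j - 2];
                if (v > sc) { sc = v; bp = 3; }
            }
            VM(i, j) = lod(j - 1, i - 1) + sc;
            BM(i, j) = bp;
            if (VM(i, j) > best) { best = VM(i, j); bi = i; bj = j; }
            // insert state I_j exists for j = 1..M-1; emission log-odds 0
            if (j < M) {
                double vi = VM(i - 1, j) + tMI[j - 1]; int bpi = 1;
                double v2 = VI(i - 1, j) + tII[j - 1];
                if (v2 > vi) { vi = v2; bpi = 2; }
                VI(i, j) = vi; BI(i, j) = bpi;
            }
            // delete state (no emission, same i)
            if (j > 1) {
                double vd = VM(i, j - 1) + tMD[j - 2]; int bpd = 1;
                double v2 = VD(i, j - 1) + tDD[j - 2];
                if (v2 > vd) { vd = v2; bpd = 3; }
                VD(i, j) = vd; BD(i, j) = bpd;
            }
        }
    }

    // traceback from best-scoring match cell to the entry point
    IntegerVector path(M, 0); // residue index (1-based) aligned to match j, 0 = none
    int i = bi, j = bj, state = 1; // 1 = M, 2 = I, 3 = D
    int env_start = bi, env_end = bi;
    while (i > 0 && j > 0) {
        if (state == 1) {
            path[j - 1] = i;
            env_start = i;
            int bp = BM(i, j);
            if (bp == 0) break;
            state = bp; --i; --j;
        } else if (state == 2) {
            int bp = BI(i, j);
            state = bp; --i;
        } else {
            int bp = BD(i, j);
            state = bp; --j;
        }
    }

    return List::create(_["score_nats"] = best,
                        _["env_start"] = env_start,
                        _["env_end"] = env_end,
                        _["match_path"] = path);
}

// [[Rcpp::export]]
double phmm_forward_cpp(NumericMatrix lod,
                        NumericVector tMM, NumericVector tMI, NumericVector tMD,
                        NumericVector tIM, NumericVector tII,
                        NumericVector tDM, NumericVector tDD) {
    const int M = lod.nrow(), n = lod.ncol();
    const double entry = -std::log((double)M);

    NumericMatrix FM(n + 1, M + 1), FI(n + 1, M + 1), FD(n + 1, M + 1);
    std::fill(FM.begin(), FM.end(), NEG_INF);
    std::fill(FI.begin(), FI.end(), NEG_INF);
    std::fill(FD.begin(), FD.end(), NEG_INF);

    double total = NEG_INF;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= M; ++j) {
            double sc = entry;
            if (j > 1) {
                sc = lse2(sc, FM(i - 1, j - 1) + tMM[j - 2]);
                sc = lse2(sc, FI(i - 1, j - 1) + tIM[j - 2]);
                sc = lse2(sc, FD(i - 1, j - 1) + tDM[j - 2]);
            }
            FM(i, j) = lod(j - 1, i - 1) + sc;
            total = lse2(total, FM(i, j)); // free exit from every match cell
            if (j < M)
                FI(i, j) = lse2(FM(i - 1, j) + tMI[j - 1], FI(i - 1, j) + tII[j - 1]);
            if (j > 1)
                FD(i, j) = lse2(FM(i, j - 1) + tMD[j - 2], FD(i, j - 1) + tDD[j - 2]);
        }
    }
    return total;
}
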