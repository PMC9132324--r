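#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fisher-LDA separation statistic (mu1 - mu2)^2 / (s1^2 + s2^2) for one
// labeling. X is n x d (already reduced to a full-rank coordinate set),
// grp is 0/1. The discriminant direction uses a pseudo-inverse of the
// pooled within-group covariance so rank-deficient genes (more isoforms
// than samples) are still projectable. Group variances are unbiased.
static double lda_stat_one(const mat& X, const uvec& idx1, const uvec& idx2) {
    const mat X1 = X.rows(idx1);
    const mat X2 = X.rows(idx2);
    const rowvec m1 = mean(X1, 0);
    const rowvec m2 = mean(X2, 0);
    const double n1 = (double)X1.n_rows, n2 = (double)X2.n_rows;

    mat C1 = X1.each_row() - m1;
    mat C2 = X2.each_row() - m2;
    mat Sw = (C1.t() * C1 + C2.t() * C2) / (n1 + n2 - 2.0);

    vec d = (m1 - m2).t();
    vec w;
    if (accu(abs(Sw)) < 1e-300) {
        // no within-group scatter at all: project straight onto the
        // mean-difference axis
        w = d;
    } else {
        mat Swinv;
        if (!pinv(Swinv, Sw)) {
            w = d;
        } else {
            w = Swinv * d;
            if (accu(abs(w)) < 1e-300) w = d;
        }
    }
    vec p1 = X1 * w;
    vec p2 = X2 * w;
    double mu1 = mean(p1), mu2 = mean(p2);
    double v1 = (n1 > 1) ? var(p1) : 0.0;  // arma::var is unbiased (n-1)
    double v2 = (n2 > 1) ? var(p2) : 0.0;
    double denom = v1 + v2;
    double delta = mu1 - mu2;
    if (denom <= 0.0) {
        return (std::abs(delta) <= 0.0) ? 0.0 : R_PosInf;
    }
    return delta * delta / denom;
}

// [[Rcpp::export]]
double lda_stat_cpp(const arma::mat& X, const arma::ivec& grp) {
    uvec idx1 = find(grp == 0);
    uvec idx2 = find(grp == 1);
    return lda_stat_one(X, idx1, idx2);
}

// Statistic for each column of `perms`, a n x B matrix of 0/1 labelings
// (each column one relabeling of the samples).
// [[Rcpp::export]]
arma::vec lda_perm_stats_cpp(const arma::mat& X, const arma::imat& perms) {
    const uword B = perms.n_cols;
    vec out(B);
    for (uword b = 0; b < B; ++b) {
        ivec g = perms.col(b);
        uvec idx1 = find(g == 0);
        uvec idx2 = find(g == 1);
        out(b) = lda_stat_one(X, idx1, idx2);
    }
    return out;
}
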