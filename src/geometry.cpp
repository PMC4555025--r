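// Geometric kernels: ellipsoid separation (matrix-pencil criterion),
// point/triangle distance, ray-parity inside tests, ellipsoid-mesh
// intersection, and the Metropolis relocation chain for the hard-core
// null model.  All coordinates in nm.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// ---------------------------------------------------------------------------
// Ellipsoid pencil separation
// ---------------------------------------------------------------------------

// homogeneous 4x4 quadric matrix; interior satisfies X' M X < 0
static mat44 quadric4(const vec3& c, const vec3& r, const mat33& R)
{
    mat33 Q = R * diagmat(1.0 / square(r)) * R.t();
    mat44 M;
    M.submat(0, 0, 2, 2) = Q;
    vec3 Qc = Q * c;
    M(0, 3) = -Qc(0); M(1, 3) = -Qc(1); M(2, 3) = -Qc(2);
    M(3, 0) = -Qc(0); M(3, 1) = -Qc(1); M(3, 2) = -Qc(2);
    M(3, 3) = dot(c, Qc) - 1.0;
    return M;
}

// true iff the closed ellipsoids share a point.  Separation criterion:
// det(lambda*A + B) = 0 has two distinct positive real roots iff the
// ellipsoids are disjoint; a positive double root means external tangency
// (treated as overlap of the closed sets).
static bool overlap_core(const vec3& c1, const vec3& r1, const mat33& R1,
                         const vec3& c2, const vec3& r2, const mat33& R2)
{
    // bounding-sphere prechecks (inscribed / circumscribed spheres)
    double d = norm(c1 - c2);
    if (d > r1.max() + r2.max()) return false;
    if (d < r1.min() + r2.min()) return true;

    mat44 A = quadric4(c1, r1, R1);
    mat44 B = quadric4(c2, r2, R2);
    cx_vec ev;
    mat44 nA = -A;
    if (!eig_pair(ev, conv_to<mat>::from(B), conv_to<mat>::from(nA))) {
        // numerically degenerate pencil: fall back to conservative overlap
        return true;
    }
    // collect distinct real positive roots
    double p1 = datum::nan, p2 = datum::nan;
    int npos = 0;
    for (uword i = 0; i < ev.n_elem; ++i) {
        double re = ev(i).real(), im = ev(i).imag();
        if (std::abs(im) > 1e-8 * (1.0 + std::abs(re))) continue;
        if (re <= 1e-12) continue;
        if (npos == 0) p1 = re; else p2 = re;
        ++npos;
    }
    if (npos != 2) return true;
    // distinct?
    if (std::abs(p1 - p2) <= 1e-9 * (std::abs(p1) + std::abs(p2))) return true;
    return false;
}

// [[Rcpp::export]]
bool cpp_ellipsoids_overlap(const arma::vec& c1, const arma::vec& r1,
                            const arma::mat& R1, const arma::vec& c2,
                            const arma::vec& r2, const arma::mat& R2,
                            double margin)
{
    vec3 rr1 = r1 + margin / 2.0;
    vec3 rr2 = r2 + margin / 2.0;
    return overlap_core(c1, rr1, R1, c2, rr2, R2);
}

// ---------------------------------------------------------------------------
// Point / triangle distance (Ericson, Real-Time Collision Detection ch. 5)
// ---------------------------------------------------------------------------

static vec3 closest_point_triangle(const vec3& p, const vec3& a,
                                   const vec3& b, const vec3& c)
{
    vec3 ab = b - a, ac = c - a, ap = p - a;
    double d1 = dot(ab, ap), d2 = dot(ac, ap);
    if (d1 <= 0.0 && d2 <= 0.0) return a;

    vec3 bp = p - b;
    double d3 = dot(ab, bp), d4 = dot(ac, bp);
    if (d3 >= 0.0 && d4 <= d3) return b;

    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        return a + v * ab;
    }

    vec3 cp = p - c;
    double d5 = dot(ab, cp), d6 = dot(ac, cp);
    if (d6 >= 0.0 && d5 <= d6) return c;

    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
        double w = d2 / (d2 - d6);
        return a + w * ac;
    }

    double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
        double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        return b + w * (c - b);
    }

    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    return a + ab * v + ac * w;
}

// [[Rcpp::export]]
Rcpp::List cpp_mesh_closest(const arma::mat& P, const arma::mat& V,
                            const arma::imat& F)
{
    const uword n = P.n_rows, m = F.n_rows;
    vec dist(n);
    mat nearest(n, 3);
    ivec tri(n);
    for (uword i = 0; i < n; ++i) {
        vec3 p = P.row(i).t();
        double best = datum::inf;
        vec3 bq = {0, 0, 0};
        uword bj = 0;
        for (uword j = 0; j < m; ++j) {
            vec3 a = V.row(F(j, 0)).t();
            vec3 b = V.row(F(j, 1)).t();
            vec3 c = V.row(F(j, 2)).t();
            vec3 q = closest_point_triangle(p, a, b, c);
            double d2 = dot(p - q, p - q);
            if (d2 < best) { best = d2; bq = q; bj = j; }
        }
        dist(i) = std::sqrt(best);
        nearest.row(i) = bq.t();
        tri(i) = (sword)bj;
    }
    return Rcpp::List::create(Rcpp::Named("distance") = dist,
                              Rcpp::Named("nearest") = nearest,
                              Rcpp::Named("triangle") = tri);
}

// distance only, no bookkeeping: used for voxel grids
// [[Rcpp::export]]
arma::vec cpp_mesh_dist(const arma::mat& P, const arma::mat& V,
                        const arma::imat& F)
{
    const uword n = P.n_rows, m = F.n_rows;
    // per-triangle centroid + radius for pruning
    mat cen(m, 3);
    vec rad(m);
    for (uword j = 0; j < m; ++j) {
        vec3 a = V.row(F(j, 0)).t();
        vec3 b = V.row(F(j, 1)).t();
        vec3 c = V.row(F(j, 2)).t();
        vec3 g = (a + b + c) / 3.0;
        cen.row(j) = g.t();
        rad(j) = std::max({norm(a - g), norm(b - g), norm(c - g)});
    }
    vec dist(n);
    for (uword i = 0; i < n; ++i) {
        vec3 p = P.row(i).t();
        double best = datum::inf;
        for (uword j = 0; j < m; ++j) {
            double lb = norm(p - cen.row(j).t()) - rad(j);
            if (lb * lb >= best && lb > 0) continue;
            vec3 a = V.row(F(j, 0)).t();
            vec3 b = V.row(F(j, 1)).t();
            vec3 c = V.row(F(j, 2)).t();
            vec3 q = closest_point_triangle(p, a, b, c);
            double d2 = dot(p - q, p - q);
            if (d2 < best) best = d2;
        }
        dist(i) = std::sqrt(best);
    }
    return dist;
}

// ---------------------------------------------------------------------------
// Ray-parity inside test (watertight meshes; disjoint unions allowed)
// ---------------------------------------------------------------------------

// fixed "irrational" ray direction avoids hitting edges of axis-aligned
// meshes for points on regular lattices
static const vec3 RAY_DIR = {0.2938712331, 0.5972618317, 0.7458342117};

static bool ray_hits_triangle(const vec3& o, const vec3& d, const vec3& a,
                              const vec3& b, const vec3& c)
{
    const double eps = 1e-12;
    vec3 e1 = b - a, e2 = c - a;
    vec3 pv = cross(d, e2);
    double det = dot(e1, pv);
    if (std::abs(det) < eps) return false;
    double inv = 1.0 / det;
    vec3 tv = o - a;
    double u = dot(tv, pv) * inv;
    if (u < 0.0 || u > 1.0) return false;
    vec3 qv = cross(tv, e1);
    double v = dot(d, qv) * inv;
    if (v < 0.0 || u + v > 1.0) return false;
    double t = dot(e2, qv) * inv;
    return t > eps;
}

static bool inside_one(const vec3& p, const mat& V, const imat& F)
{
    int crossings = 0;
    for (uword j = 0; j < F.n_rows; ++j) {
        vec3 a = V.row(F(j, 0)).t();
        vec3 b = V.row(F(j, 1)).t();
        vec3 c = V.row(F(j, 2)).t();
        if (ray_hits_triangle(p, RAY_DIR, a, b, c)) ++crossings;
    }
    return (crossings % 2) == 1;
}

// [[Rcpp::export]]
Rcpp::LogicalVector cpp_inside_mesh(const arma::mat& P, const arma::mat& V,
                                    const arma::imat& F)
{
    const uword n = P.n_rows;
    Rcpp::LogicalVector out(n);
    for (uword i = 0; i < n; ++i)
        out[i] = inside_one(P.row(i).t(), V, F);
    return out;
}

// ---------------------------------------------------------------------------
// Ellipsoid vs. triangle mesh
// ---------------------------------------------------------------------------

// true iff any triangle meets the closed ellipsoid with radii already
// including any safety margin.  Exact via the affine map sending the
// ellipsoid to the unit ball.
static bool ellipsoid_mesh_core(const vec3& c, const vec3& r, const mat33& R,
                                const mat& V, const imat& F)
{
    mat33 S = diagmat(1.0 / r) * R.t();
    for (uword j = 0; j < F.n_rows; ++j) {
        vec3 a = S * (V.row(F(j, 0)).t() - c);
        vec3 b = S * (V.row(F(j, 1)).t() - c);
        vec3 d = S * (V.row(F(j, 2)).t() - c);
        // cheap reject: all vertices farther than 1 + triangle span
        double la = norm(a);
        double span = std::max(norm(b - a), norm(d - a));
        if (la > 1.0 + span) continue;
        vec3 q = closest_point_triangle({0, 0, 0}, a, b, d);
        if (dot(q, q) <= 1.0) return true;
    }
    return false;
}

// [[Rcpp::export]]
bool cpp_ellipsoid_mesh_intersect(const arma::vec& c, const arma::vec& r,
                                  const arma::mat& R, const arma::mat& V,
                                  const arma::imat& F, double margin)
{
    vec3 rr = r + margin;
    return ellipsoid_mesh_core(c, rr, R, V, F);
}

// ---------------------------------------------------------------------------
// Configuration feasibility + Metropolis relocation chain
// ---------------------------------------------------------------------------

struct World {
    const mat& memV; const imat& memF;
    const mat& obsV; const imat& obsF;
    double margin;
    bool has_obstacles() const { return obsF.n_rows > 0; }
};

// feasibility of ellipsoid (c,r,R) at index self against the domain and
// all other vesicles (self = -1 for a fresh candidate)
static bool feasible_one(const vec3& c, const vec3& r, const mat33& R,
                         int self, const mat& centers, const mat& radii,
                         const cube& axes, const World& w)
{
    if (!inside_one(c, w.memV, w.memF)) return false;
    if (ellipsoid_mesh_core(c, r + w.margin, R, w.memV, w.memF)) return false;
    if (w.has_obstacles()) {
        if (inside_one(c, w.obsV, w.obsF)) return false;
        if (ellipsoid_mesh_core(c, r + w.margin, R, w.obsV, w.obsF))
            return false;
    }
    const double m2 = w.margin / 2.0;
    vec3 ri = r + m2;
    for (uword j = 0; j < centers.n_rows; ++j) {
        if ((int)j == self) continue;
        vec3 cj = centers.row(j).t();
        vec3 rj = radii.row(j).t() + m2;
        double d = norm(c - cj);
        if (d > ri.max() + rj.max()) continue;
        if (d < ri.min() + rj.min()) return false;
        if (overlap_core(c, ri, R, cj, rj, axes.slice(j))) return false;
    }
    return true;
}

// [[Rcpp::export]]
bool cpp_candidate_feasible(const arma::vec& c, const arma::vec& r,
                            const arma::mat& R, const arma::mat& centers,
                            const arma::mat& radii, const arma::cube& axes,
                            const arma::mat& memV, const arma::imat& memF,
                            const arma::mat& obsV, const arma::imat& obsF,
                            double margin)
{
    World w{memV, memF, obsV, obsF, margin};
    return feasible_one(c, r, R, -1, centers, radii, axes, w);
}

// pairwise overlap violations in a configuration (1-based index pairs)
// [[Rcpp::export]]
arma::imat cpp_pair_violations(const arma::mat& centers, const arma::mat& radii,
                               const arma::cube& axes, double margin)
{
    std::vector<sword> rows;
    const double m2 = margin / 2.0;
    for (uword i = 0; i + 1 < centers.n_rows; ++i) {
        vec3 ci = centers.row(i).t();
        vec3 ri = radii.row(i).t() + m2;
        for (uword j = i + 1; j < centers.n_rows; ++j) {
            vec3 cj = centers.row(j).t();
            vec3 rj = radii.row(j).t() + m2;
            if (overlap_core(ci, ri, axes.slice(i), cj, rj, axes.slice(j))) {
                rows.push_back(i + 1);
                rows.push_back(j + 1);
            }
        }
    }
    imat out(rows.size() / 2, 2);
    for (uword k = 0; k < out.n_rows; ++k) {
        out(k, 0) = rows[2 * k];
        out(k, 1) = rows[2 * k + 1];
    }
    return out;
}

// uniform random rotation via normalized quaternion drawn from R's RNG
static mat33 random_rotation()
{
    double q0 = norm_rand(), q1 = norm_rand(), q2 = norm_rand(),
           q3 = norm_rand();
    double s = std::sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3);
    q0 /= s; q1 /= s; q2 /= s; q3 /= s;
    mat33 R;
    R(0, 0) = 1 - 2 * (q2 * q2 + q3 * q3);
    R(0, 1) = 2 * (q1 * q2 - q0 * q3);
    R(0, 2) = 2 * (q1 * q3 + q0 * q2);
    R(1, 0) = 2 * (q1 * q2 + q0 * q3);
    R(1, 1) = 1 - 2 * (q1 * q1 + q3 * q3);
    R(1, 2) = 2 * (q2 * q3 - q0 * q1);
    R(2, 0) = 2 * (q1 * q3 - q0 * q2);
    R(2, 1) = 2 * (q2 * q3 + q0 * q1);
    R(2, 2) = 1 - 2 * (q1 * q1 + q2 * q2);
    return R;
}

// Metropolis relocation chain with fixed N and fixed radii.  Proposal:
// pick a vesicle uniformly; new center uniform in the bounding box when
// proposal_sd <= 0, otherwise an isotropic Gaussian step; optionally a
// fresh uniform rotation.  Accept iff all hard-core constraints hold, so
// the stationary law is uniform over feasible configurations.
// [[Rcpp::export]]
Rcpp::List cpp_run_chain(arma::mat centers, const arma::mat& radii,
                         arma::cube axes, const arma::mat& memV,
                         const arma::imat& memF, const arma::mat& obsV,
                         const arma::imat& obsF, const arma::vec& bbox_lo,
                         const arma::vec& bbox_hi, double margin,
                         int n_samples, int moves_per_sample, int burn_in,
                         bool reorient, double proposal_sd)
{
    World w{memV, memF, obsV, obsF, margin};
    const int N = (int)centers.n_rows;
    cube out_centers(N, 3, n_samples);
    cube out_axes(3, 3 * N, n_samples);
    long accepted = 0;
    const long total = (long)burn_in + (long)n_samples * moves_per_sample;
    long done = 0;
    int emitted = 0;
    vec3 lo = bbox_lo, hi = bbox_hi;

    while (done < total) {
        int i = (int)std::floor(unif_rand() * N);
        if (i == N) i = N - 1;
        vec3 cnew;
        if (proposal_sd > 0) {
            vec3 ci = centers.row(i).t();
            cnew = {ci(0) + proposal_sd * norm_rand(),
                    ci(1) + proposal_sd * norm_rand(),
                    ci(2) + proposal_sd * norm_rand()};
        } else {
            cnew = {lo(0) + unif_rand() * (hi(0) - lo(0)),
                    lo(1) + unif_rand() * (hi(1) - lo(1)),
                    lo(2) + unif_rand() * (hi(2) - lo(2))};
        }
        mat33 Rnew = reorient ? random_rotation() * axes.slice(i)
                              : mat33(axes.slice(i));
        bool ok = cnew(0) >= lo(0) && cnew(0) <= hi(0) && cnew(1) >= lo(1) &&
                  cnew(1) <= hi(1) && cnew(2) >= lo(2) && cnew(2) <= hi(2);
        if (ok)
            ok = feasible_one(cnew, radii.row(i).t(), Rnew, i, centers,
                               radii, axes, w);
        if (ok) {
            centers.row(i) = cnew.t();
            axes.slice(i) = Rnew;
            ++accepted;
        }
        ++done;
        if (done > burn_in && (done - burn_in) % moves_per_sample == 0 &&
            emitted < n_samples) {
            out_centers.slice(emitted) = centers;
            for (int k = 0; k < N; ++k)
                out_axes.slice(emitted).cols(3 * k, 3 * k + 2) =
                    axes.slice(k);
            ++emitted;
        }
        if (done % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    return Rcpp::List::create(
        Rcpp::Named("centers") = out_centers,
        Rcpp::Named("axes") = out_axes,
        Rcpp::Named("accepted") = (double)accepted,
        Rcpp::Named("proposals") = (double)total);
}
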