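#include <Rcpp.h>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Quality-guided region-growing phase unwrapping on a 6-connected lattice.
// Voxels are admitted to the unwrapped region in decreasing quality order;
// each new voxel is unwrapped against the already-unwrapped neighbour it was
// reached from, so 2*pi errors cannot silently propagate through low-quality
// regions before high-quality ones are consumed.

struct QNode {
    double q;
    int idx;
    int ref;
};

struct QLess {
    bool operator()(const QNode &a, const QNode &b) const { return a.q < b.q; }
};

// [[Rcpp::export(name = ".unwrap_rg_cpp")]]
NumericVector unwrap_rg_cpp(NumericVector wrapped, NumericVector quality,
                            LogicalVector mask, IntegerVector dims,
                            int seedIdx) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double TWOPI = 2.0 * M_PI;
    const R_xlen_t n = wrapped.size();
    NumericVector out(clone(wrapped));
    std::vector<char> done(n, 0);
    std::priority_queue<QNode, std::vector<QNode>, QLess> pq;

    if (seedIdx < 0 || seedIdx >= n || !mask[seedIdx])
        stop("seed voxel outside the mask");

    done[seedIdx] = 1;
    const int offs[6] = {1, -1, nx, -nx, nx * ny, -nx * ny};

    auto pushNeighbours = [&](int idx) {
        int x = idx % nx, rem = idx / nx;
        int y = rem % ny, z = rem / ny;
        for (int d = 0; d < 6; ++d) {
            if (d == 0 && x == nx - 1) continue;
            if (d == 1 && x == 0) continue;
            if (d == 2 && y == ny - 1) continue;
            if (d == 3 && y == 0) continue;
            if (d == 4 && z == nz - 1) continue;
            if (d == 5 && z == 0) continue;
            int nb = idx + offs[d];
            if (!mask[nb] || done[nb]) continue;
            pq.push({quality[nb], nb, idx});
        }
    };

    pushNeighbours(seedIdx);
    while (!pq.empty()) {
        QNode nd = pq.top();
        pq.pop();
        if (done[nd.idx]) continue;
        double ref = out[nd.ref];
        out[nd.idx] = wrapped[nd.idx] -
            TWOPI * std::round((wrapped[nd.idx] - ref) / TWOPI);
        done[nd.idx] = 1;
        pushNeighbours(nd.idx);
    }
    return out;
}

// Successive over-relaxation solver for the Laplace boundary-value problem:
// u is fixed (Dirichlet) wherever `interior` is FALSE and relaxed towards
// the 6-neighbour average on interior voxels. Returns the harmonic field.
// Convergence: relative Laplacian residual over the interior below `tol`.

// [[Rcpp::export(name = ".lbv_sor_cpp")]]
List lbv_sor_cpp(NumericVector field, LogicalVector interior,
                 IntegerVector dims, double omega, double tol, int maxIter) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    NumericVector u(clone(field));
    std::vector<int> idxs;
    idxs.reserve(field.size() / 2);
    for (int z = 1; z < nz - 1; ++z)
        for (int y = 1; y < ny - 1; ++y)
            for (int x = 1; x < nx - 1; ++x) {
                int idx = x + nx * (y + ny * z);
                if (interior[idx]) idxs.push_back(idx);
            }
    if (idxs.empty()) stop("empty interior for the Laplace solve");

    double scale = 0.0;
    for (int idx : idxs) scale += field[idx] * field[idx];
    scale = std::sqrt(scale / idxs.size());
    if (scale == 0.0) scale = 1.0;

    const int oxy = nx * ny;
    double rel = R_PosInf;
    int it = 0;
    for (it = 1; it <= maxIter; ++it) {
        for (int idx : idxs) {
            double avg = (u[idx + 1] + u[idx - 1] + u[idx + nx] + u[idx - nx] +
                          u[idx + oxy] + u[idx - oxy]) / 6.0;
            u[idx] += omega * (avg - u[idx]);
        }
        if (it % 25 == 0 || it == maxIter) {
            double rss = 0.0;
            for (int idx : idxs) {
                double r = (u[idx + 1] + u[idx - 1] + u[idx + nx] + u[idx - nx] +
                            u[idx + oxy] + u[idx - oxy]) / 6.0 - u[idx];
                rss += r * r;
            }
            rel = std::sqrt(rss / idxs.size()) / scale;
            if (rel < tol) break;
        }
    }
    return List::create(_["u"] = u, _["iterations"] = it,
                        _["residual"] = rel, _["converged"] = rel < tol);
}
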