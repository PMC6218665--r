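#include <Rcpp.h>
using namespace Rcpp;

// Semi-implicit right-hand side plus forward-Euler gating sweep, fused so
// each quadrature point is visited once per step. Element matrices are
// group-indexed: structured box meshes have at most 8 distinct element
// shapes, so per-element storage of condensed blocks is unnecessary.
//
// rhs[A] = sum_e { p_u^e - (L^T Kalpha^-1) p_alpha^e } scattered to global
// dofs, i.e. the right-hand side of A u_{n+1} = rhs (the negative of the
// b_n convention used by assemble_rhs()).
//
// conn and egroup are 0-based. Ce has dim (nn, 3, ngroups), wdetg
// (ngroups, nq). stim is either (nel, nq) or 0 x 0 when no source is
// active. ion = (c1, c2, alpha, b, gamma, mu1, mu2); tau converts the
// dimensionless kinetics to per-ms rates. Hot loops use raw column-major
// pointers.
// [[Rcpp::export]]
List si_rhs_gating_cpp(NumericVector u, NumericMatrix alpha, NumericMatrix r,
                       IntegerMatrix conn, IntegerVector egroup,
                       NumericMatrix Nval, NumericMatrix Wval,
                       NumericMatrix wdetg, NumericVector Ce,
                       NumericMatrix stim, double dt, double tau,
                       NumericVector ion, int ndof)
{
    const int nn = Nval.nrow(), nq = Nval.ncol(), nel = conn.nrow();
    const int nc = Wval.nrow();
    const int ng = wdetg.nrow();
    const bool has_stim = stim.nrow() == nel;
    const double c1 = ion[0], c2 = ion[1], aa = ion[2], bb = ion[3],
                 gam = ion[4], mu1 = ion[5], mu2 = ion[6];
    const double dtm = dt / tau, idt = 1.0 / dt, itau = 1.0 / tau;

    NumericVector rhs(ndof);
    NumericMatrix pa(nc > 0 ? nel : 0, nc > 0 ? 3 : 0);
    NumericMatrix rnew(nel, nq);

    const double *pu_in = REAL(u), *pal = nc > 0 ? REAL(alpha) : nullptr;
    const double *pr = REAL(r), *pN = REAL(Nval), *pW = REAL(Wval);
    const double *pwd = REAL(wdetg), *pC = REAL(Ce);
    const double *pst = has_stim ? REAL(stim) : nullptr;
    const int *pconn = INTEGER(conn), *pg = INTEGER(egroup);
    double *prhs = REAL(rhs), *ppa = nc > 0 ? REAL(pa) : nullptr;
    double *prn = REAL(rnew);

    std::vector<double> ue(nn), pu(nn);
    double pae[3];

    for (int e = 0; e < nel; ++e) {
        const int g = pg[e];
        for (int a = 0; a < nn; ++a) {
            ue[a] = pu_in[pconn[e + nel * a]];
            pu[a] = 0.0;
        }
        pae[0] = pae[1] = pae[2] = 0.0;
        for (int q = 0; q < nq; ++q) {
            const double *Nq = pN + nn * q;
            double phi = 0.0;
            for (int a = 0; a < nn; ++a) phi += Nq[a] * ue[a];
            if (nc > 0) {
                const double *Wq = pW + 3 * q;
                for (int c = 0; c < 3; ++c)
                    phi += Wq[c] * pal[e + nel * c];
            }
            const double rq = pr[e + nel * q];
            const double f = c1 * phi * (phi - aa) * (1.0 - phi) - c2 * rq * phi;
            const double g2 = (gam + mu1 * rq / (mu2 + phi)) *
                              (-rq - c2 * phi * (phi - bb - 1.0));
            prn[e + nel * q] = rq + dtm * g2;
            double s = phi * idt + f * itau;
            if (has_stim) s += pst[e + nel * q];
            s *= pwd[g + ng * q];
            for (int a = 0; a < nn; ++a) pu[a] += Nq[a] * s;
            if (nc > 0) {
                const double *Wq = pW + 3 * q;
                for (int c = 0; c < 3; ++c) pae[c] += Wq[c] * s;
            }
        }
        if (nc > 0) {
            for (int a = 0; a < nn; ++a) {
                double v = pu[a];
                for (int c = 0; c < 3; ++c)
                    v -= pC[a + nn * (c + 3 * g)] * pae[c];
                prhs[pconn[e + nel * a]] += v;
            }
            for (int c = 0; c < 3; ++c) ppa[e + nel * c] = pae[c];
        } else {
            for (int a = 0; a < nn; ++a)
                prhs[pconn[e + nel * a]] += pu[a];
        }
    }
    return List::create(_["rhs"] = rhs, _["p_alpha"] = pa, _["r_new"] = rnew);
}

// Element-level recovery of the incompatible-mode coefficients once the
// nodal update is known: alpha_{n+1} = Kalpha^-1 p_alpha - Kalpha^-1 L u_{n+1}.
// Kai has dim (3, 3, ngroups), KaiL (3, nn, ngroups).
// [[Rcpp::export]]
NumericMatrix nc_alpha_update_cpp(NumericVector unew, NumericMatrix pa,
                                  IntegerMatrix conn, IntegerVector egroup,
                                  NumericVector Kai, NumericVector KaiL)
{
    const int nel = conn.nrow(), nn = conn.ncol();
    NumericMatrix alpha(nel, 3);
    const double *pu = REAL(unew), *ppa = REAL(pa);
    const double *pKai = REAL(Kai), *pKaiL = REAL(KaiL);
    const int *pconn = INTEGER(conn), *pg = INTEGER(egroup);
    double *pal = REAL(alpha);
    for (int e = 0; e < nel; ++e) {
        const int g = pg[e];
        for (int c = 0; c < 3; ++c) {
            double v = 0.0;
            for (int d = 0; d < 3; ++d)
                v += pKai[c + 3 * (d + 3 * g)] * ppa[e + nel * d];
            for (int a = 0; a < nn; ++a)
                v -= pKaiL[c + 3 * (a + nn * g)] * pu[pconn[e + nel * a]];
            pal[e + nel * c] = v;
        }
    }
    return alpha;
}
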