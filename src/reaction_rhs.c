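/* Right-hand side of the community reaction ODEs, evaluated for all cells
 * of the column at once (a batch reactor is one cell). State layout is
 * column-major: nsp*ncell species concentrations followed by ncomm*ncell
 * biomass values, each grouped by cell.
 *
 * Rate law per community: mu_max * X * Monod(donor) * Monod(acceptor)
 * * I/(C_inh + I) (inhibited communities only), tapered by a smooth
 * cutoff C/(C + eps) for every reactant approaching zero; decay b*X
 * removes biomass only.
 */
#include <R.h>
#include <Rinternals.h>
#include <string.h>
#include <math.h>

SEXP C_reaction_rhs(SEXP sy, SEXP sdims, SEXP sstoich, SEXP sdon, SEXP sacc,
                    SEXP sinh_sp, SEXP spar, SEXP sinhibited, SEXP sfrozen,
                    SEXP scutoff)
{
    const int nsp = INTEGER(sdims)[0];
    const int ncomm = INTEGER(sdims)[1];
    const int ncell = INTEGER(sdims)[2];
    const double *y = REAL(sy);
    const double *st = REAL(sstoich);       /* nsp x ncomm, column-major */
    const int *don = INTEGER(sdon);         /* 0-based species index */
    const int *acc = INTEGER(sacc);
    const int inh_sp = INTEGER(sinh_sp)[0]; /* inhibitor species index */
    const double *par = REAL(spar);         /* 5 x ncomm: mu,Kd,Ka,I,b */
    const int *inhibited = INTEGER(sinhibited);
    const int frozen = INTEGER(sfrozen)[0];
    const double eps = REAL(scutoff)[0];

    SEXP sdy = PROTECT(allocVector(REALSXP, (R_xlen_t)(nsp + ncomm) * ncell));
    double *dy = REAL(sdy);
    memset(dy, 0, sizeof(double) * (size_t)(nsp + ncomm) * ncell);

    const double *X = y + (R_xlen_t)nsp * ncell;
    double *dX = dy + (R_xlen_t)nsp * ncell;

    for (int c = 0; c < ncell; c++) {
        const double *conc = y + (R_xlen_t)c * nsp;
        double *dconc = dy + (R_xlen_t)c * nsp;
        double ci = conc[inh_sp] > 0 ? conc[inh_sp] : 0;
        for (int j = 0; j < ncomm; j++) {
            const double mu = par[5 * j], Kd = par[5 * j + 1],
                         Ka = par[5 * j + 2], I = par[5 * j + 3],
                         b = par[5 * j + 4];
            const double Xjc = X[(R_xlen_t)c * ncomm + j];
            double cd = conc[don[j]] > 0 ? conc[don[j]] : 0;
            double ca = conc[acc[j]] > 0 ? conc[acc[j]] : 0;
            double g = mu * Xjc * cd / (cd + Kd) * ca / (ca + Ka);
            if (inhibited[j] && isfinite(I))
                g *= I / (ci + I);
            const double *nu = st + (R_xlen_t)j * nsp;
            for (int s = 0; s < nsp; s++) {
                if (nu[s] < 0) {
                    double cs = conc[s] > 0 ? conc[s] : 0;
                    g *= cs / (cs + eps);
                }
            }
            for (int s = 0; s < nsp; s++)
                if (nu[s] != 0)
                    dconc[s] += nu[s] * g;
            if (!frozen)
                dX[(R_xlen_t)c * ncomm + j] = g - b * Xjc;
        }
    }
    UNPROTECT(1);
    return sdy;
}
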