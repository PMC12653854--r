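/* Whole-body perfusion-limited PBPK right-hand side for deSolve.
 *
 * Up to three compounds integrated simultaneously.  Per compound:
 * oral depot -> liver (portal inflow), 12 perfusion-limited tissues
 * with Kp-based back-partitioning, venous/arterial blood, hepatic
 * elimination on unbound liver concentration with dynamic competitive
 * CYP inhibition from co-simulated compounds, additional systemic and
 * renal clearance on venous plasma, and mole-converted parent ->
 * metabolite formation into the metabolite's liver compartment.
 *
 * Parameter vector (padded to MAXPAR in R):
 *  p[0] n_comp, p[1] n_tissues (= 12)
 *  p[2..13]   tissue volumes V (L)           [adipose bone brain gut
 *  p[14..25]  tissue blood flows Q (L/h)      heart kidney liver lung
 *  p[26] venous blood volume                  muscle skin spleen
 *  p[27] arterial blood volume                pancreas]
 *  then per compound (37 doubles):
 *   0 MW  1 B/P  2 fu,p  3 ka  4 CL_additional  5 CL_renal
 *   6 metabolite link (1-based compound index, 0 = none)
 *   7 link fraction
 *   8..19 Kp (plasma-referenced, scalar included)
 *   20..27 per-isoform unbound intrinsic clearance (L/h)
 *          [1A2 2B6 2C8 2C9 2C19 2D6 3A4 3A5]
 *   28 non-inhibitable residual intrinsic clearance (L/h)
 *   29..36 competitive ki per isoform (uM; <= 0 means not inhibiting)
 *
 * Flow conventions: Q[liver] is the hepatic artery; the portal vein
 * carries gut + spleen + pancreas outflow; Q[lung] is the cardiac
 * output and must equal the sum of the other eleven flows.
 *
 * States per compound (17): depot, 12 tissue amounts, venous,
 * arterial, cumulative eliminated, cumulative formed (mg).
 */
#include <R.h>
#include <math.h>

#define NTIS 12
#define NISO 8
#define NSC 17
#define NCP 37
#define PHYS 2
#define CBLK (PHYS + 2 * NTIS + 2)
#define MAXPAR (CBLK + 3 * NCP)

#define T_GUT 3
#define T_LIV 6
#define T_LUN 7
#define T_SPL 10
#define T_PAN 11

static double p[MAXPAR];

void pbpk_init(void (*odeparms)(int *, double *))
{
    int N = MAXPAR;
    odeparms(&N, p);
}

void pbpk_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int ncomp = (int) p[0];
    const double *V = p + PHYS;
    const double *Q = p + PHYS + NTIS;
    double Vven = p[PHYS + 2 * NTIS];
    double Vart = p[PHYS + 2 * NTIS + 1];
    double CO = Q[T_LUN];
    double Qpv = Q[T_GUT] + Q[T_SPL] + Q[T_PAN];
    double Qh = Q[T_LIV] + Qpv;

    double culiv[3] = {0, 0, 0};
    double eform[3] = {0, 0, 0};
    double fac[NISO];
    int c, j, ti;

    for (c = 0; c < ncomp; c++) {
        const double *cp = p + CBLK + c * NCP;
        const double *yc = y + c * NSC;
        double cl = (yc[1 + T_LIV] / V[T_LIV]) / cp[8 + T_LIV];
        culiv[c] = cp[2] * (cl > 0 ? cl : 0);
    }
    /* summed competitive occupancy I_u/ki per isoform; a compound's
     * own contribution is excluded from the factor applied to its own
     * clearance (auto-inhibition is already encoded empirically in the
     * regimen-dependent clearance anchors) */
    double occ[NISO][3];
    for (j = 0; j < NISO; j++) {
        double s = 0;
        for (c = 0; c < ncomp; c++) {
            const double *cp = p + CBLK + c * NCP;
            double ki = cp[29 + j];
            occ[j][c] = (ki > 0) ? (culiv[c] * 1000.0 / cp[0]) / ki : 0;
            s += occ[j][c];
        }
        fac[j] = s; /* store the sum; per-target factor built below */
    }
    for (c = 0; c < ncomp; c++) {
        const double *cp = p + CBLK + c * NCP;
        const double *Kp = cp + 8;
        const double *yc = y + c * NSC;
        double *dc = ydot + c * NSC;
        double BP = cp[1], ka = cp[3];
        double Cab = yc[14] / Vart;
        double Cvb = yc[13] / Vven;
        double Cv[NTIS];
        double clint_inh = 0, Ehep, sysel, vensum = 0;

        for (ti = 0; ti < NTIS; ti++)
            Cv[ti] = (yc[1 + ti] / V[ti]) * BP / Kp[ti];
        for (j = 0; j < NISO; j++)
            clint_inh += cp[20 + j] / (1.0 + fac[j] - occ[j][c]);
        Ehep = (clint_inh + cp[28]) * culiv[c];
        eform[c] = clint_inh * culiv[c] * cp[7];

        dc[0] = -ka * yc[0];
        for (ti = 0; ti < NTIS; ti++) {
            if (ti == T_LIV || ti == T_LUN) continue;
            dc[1 + ti] = Q[ti] * (Cab - Cv[ti]);
            if (ti != T_GUT && ti != T_SPL && ti != T_PAN)
                vensum += Q[ti] * Cv[ti];
        }
        dc[1 + T_LIV] = Q[T_LIV] * Cab + Q[T_GUT] * Cv[T_GUT] +
            Q[T_SPL] * Cv[T_SPL] + Q[T_PAN] * Cv[T_PAN] +
            ka * yc[0] - Qh * Cv[T_LIV] - Ehep;
        dc[1 + T_LUN] = CO * (Cvb - Cv[T_LUN]);
        dc[14] = CO * (Cv[T_LUN] - Cab);
        sysel = (cp[4] + cp[5]) * Cvb / BP;
        dc[13] = vensum + Qh * Cv[T_LIV] - CO * Cvb - sysel;
        dc[15] = Ehep + sysel;
        dc[16] = 0.0;
    }
    for (c = 0; c < ncomp; c++) {
        const double *cp = p + CBLK + c * NCP;
        int m = (int) cp[6];
        if (m > 0 && eform[c] != 0) {
            const double *mp = p + CBLK + (m - 1) * NCP;
            double flux = eform[c] * mp[0] / cp[0];
            ydot[(m - 1) * NSC + 1 + T_LIV] += flux;
            ydot[(m - 1) * NSC + 16] += flux;
        }
    }
}
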