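/* Compiled right-hand side of the two-population mESC bioprocess model,
 * used through deSolve's compiled-model interface. Mirrors culture_rhs()
 * in R/rates.R; the R version is the reference the tests compare against.
 *
 * State order: x_u, x_d, glc, gln, lac, amm, rex1, fgf5, dppa3.
 * Parameter vector: the 29 model parameters in canonical order, then
 * n_bead, dilution rate, inlet (GLC, GLN, LAC, AMM), Rex1 reference.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define N_PARMS 36

static double parms[N_PARMS];

#define mu_max_U   parms[0]
#define mu_max_D   parms[1]
#define Kglc_U     parms[2]
#define Kglc_D     parms[3]
#define mud_max_U  parms[4]
#define mud_max_D  parms[5]
#define Kdlac_U    parms[6]
#define Kdlac_D    parms[7]
#define K_GLC_MAX  parms[8]
#define K_GLN_MAX  parms[9]
#define Kx_GLC     parms[10]
#define Kx_GLN     parms[11]
#define Y_LACGLC   parms[12]
#define Y_AMMGLN   parms[13]
#define GLC_MIN    parms[14]
#define K_Diff     parms[15]
#define K_D_GLN    parms[16]
#define b_REX1     parms[17]
#define a_REX      parms[18]
#define b_FGF      parms[19]
#define alpha_FGF  parms[20]
#define b_DPPA     parms[21]
#define alpha_DPPA parms[22]
#define LAC_MIN    parms[23]
#define K_LAC_REX  parms[24]
#define K_FGF      parms[25]
#define K_LAC_FGF  parms[26]
#define AMM_MIN    parms[27]
#define K_AMM_DPPA parms[28]
#define N_BEAD     parms[29]
#define DIL        parms[30]
#define IN_GLC     parms[31]
#define IN_GLN     parms[32]
#define IN_LAC     parms[33]
#define IN_AMM     parms[34]
#define REX_REF    parms[35]

/* Hill exponent of the inhibitory metabolite-stress terms. */
#define STRESS_HILL_N 2.0

void mesc_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void mesc_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    /* Solver iterates may undershoot zero by round-off; rates are
     * evaluated on the nonnegative part so trajectories stay physical. */
    double xu  = fmax(y[0], 0.0), xd  = fmax(y[1], 0.0);
    double glc = fmax(y[2], 0.0), gln = fmax(y[3], 0.0);
    double lac = fmax(y[4], 0.0), amm = fmax(y[5], 0.0);
    double rex = fmax(y[6], 0.0), fgf = fmax(y[7], 0.0);
    double dppa = fmax(y[8], 0.0);
    double xv = xu + xd;

    double mu_u  = mu_max_U * glc / (Kglc_U + glc);
    double mu_d  = mu_max_D * glc / (Kglc_D + glc);
    double mud_u = mud_max_U * lac / (Kdlac_U + lac);
    double mud_d = mud_max_D * lac / (Kdlac_D + lac);

    double r = K_Diff * fabs(REX_REF - rex);
    double flux = (rex < REX_REF) ? r * xu : -r * xd;

    double s_glc = fmax(glc - GLC_MIN, 0.0);
    double q_glc = K_GLC_MAX * s_glc / (Kx_GLC + s_glc) * xv * N_BEAD;
    double q_gln = K_GLN_MAX * gln / (Kx_GLN + gln) * xv * N_BEAD;

    double s_lac = fmax(lac - LAC_MIN, 0.0);
    double s_amm = fmax(amm - AMM_MIN, 0.0);

    ydot[0] = (mu_u - mud_u) * xu - flux;
    ydot[1] = (mu_d - mud_d) * xd + flux;
    ydot[2] = -q_glc + DIL * (IN_GLC - glc);
    ydot[3] = -q_gln - K_D_GLN * gln + DIL * (IN_GLN - gln);
    ydot[4] = Y_LACGLC * q_glc + DIL * (IN_LAC - lac);
    ydot[5] = Y_AMMGLN * q_gln + DIL * (IN_AMM - amm);
    ydot[6] = b_REX1 / (1.0 + pow(s_lac / K_LAC_REX, STRESS_HILL_N)) -
              a_REX * rex;
    ydot[7] = b_FGF * (s_lac / (K_LAC_FGF + s_lac)) * (fgf / (K_FGF + fgf)) -
              alpha_FGF * fgf;
    ydot[8] = b_DPPA / (1.0 + pow(s_amm / K_AMM_DPPA, STRESS_HILL_N)) -
              alpha_DPPA * dppa;
}

/* Root function: crossing of Rex1 through its reference level, where the
 * transfer flux reverses direction. The solver restarts there. */
void mesc_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *out, int *ip)
{
    gout[0] = y[6] - REX_REF;
}
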