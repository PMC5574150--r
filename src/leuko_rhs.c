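/* Compiled right-hand side of the 17-state leukopoiesis / AML model for
 * deSolve.  The R reference implementation lives in R/model.R
 * (leuko_derivatives()); the two are kept term-for-term identical and are
 * cross-checked in the test suite.
 *
 * Parameter vector layout (must match .pack_parms() in R/model.R):
 *   [0..50]  the 51 named model parameters in roster order
 *   [51]     sMc   cancer maturation rate (alias of source lineage)
 *   [52]     chemo_start (day)
 *   [53]     chemo_end (day)
 *   [54]     chemo_inf  (drug units/day; 0 disables chemotherapy)
 *   [55..57] scopeN, scopeL, scopeM (0/1 lineage scope flags)
 *   [58..74] kill mask for the 17 states (0/1)
 */
#include <R.h>
#include <math.h>

#define N_PARMS 75
static double parms[N_PARMS];

/* named accessors, roster order */
#define aS     parms[0]
#define mrS    parms[1]
#define fN     parms[2]
#define fL     parms[3]
#define kS     parms[4]
#define kBM    parms[5]
#define dS     parms[6]
#define aN2    parms[7]
#define mrN2   parms[8]
#define sN2    parms[9]
#define kN     parms[10]
#define mbN    parms[11]
#define rN     parms[12]
#define mgN    parms[13]
#define dmN    parms[14]
#define kmovN  parms[15]
#define aL2    parms[16]
#define mrL2   parms[17]
#define sL2    parms[18]
#define kL     parms[19]
#define mbL    parms[20]
#define rL     parms[21]
#define kmovL  parms[22]
#define aM2    parms[23]
#define mrM2   parms[24]
#define sM2    parms[25]
#define kM     parms[26]
#define mbM    parms[27]
#define rM     parms[28]
#define mgM    parms[29]
#define dmM    parms[30]
#define kmovM  parms[31]
#define actMAC parms[32]
#define prMAC  parms[33]
#define kA     parms[34]
#define kMAC   parms[35]
#define clA    parms[36]
#define kkill  parms[37]
#define kel    parms[38]
#define Kbm    parms[39]
#define dMc    parms[40]
#define aMc2   parms[41]
#define mrMc2  parms[42]
#define mbMc   parms[43]
#define d2     parms[44]
#define dN     parms[45]
#define dL3    parms[46]
#define dL3pb  parms[47]
#define dM     parms[48]
#define dMpb   parms[49]
#define dMAC   parms[50]
#define sMc        parms[51]
#define chemo_t0   parms[52]
#define chemo_t1   parms[53]
#define chemo_inf  parms[54]
#define scopeN     parms[55]
#define scopeL     parms[56]
#define scopeM     parms[57]
#define KILLMASK(i) parms[58 + (i)]

void leuko_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* one-compartment PK: constant-rate infusion on [t0, t1], first-order
 * elimination at rate kel; continuous in t */
static double chemo_level(double t)
{
    double plateau, at_end;
    if (chemo_inf <= 0.0 || t <= chemo_t0)
        return 0.0;
    plateau = chemo_inf / kel;
    if (t <= chemo_t1)
        return plateau * (1.0 - exp(-kel * (t - chemo_t0)));
    at_end = plateau * (1.0 - exp(-kel * (chemo_t1 - chemo_t0)));
    return at_end * exp(-kel * (t - chemo_t1));
}

void leuko_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    /* clamp sub-tolerance negative excursions for feedback evaluation */
    double x[17];
    int i;
    for (i = 0; i < 17; i++)
        x[i] = y[i] > 0.0 ? y[i] : 0.0;

    double S    = x[0];
    double N2   = x[1], Nbm = x[2], Npb = x[3], Nmp = x[4];
    double L2   = x[5], L3  = x[6], L3pb = x[7];
    double M2   = x[8], Mbm = x[9], Mpb = x[10], Mmp = x[11];
    double MAC  = x[12], A  = x[13];
    double Mc2  = x[14], Mcbm = x[15], Mcpb = x[16];

    double chemo = chemo_level(*t);
    double kill[17];
    double debris_in = 0.0;
    for (i = 0; i < 17; i++) {
        kill[i] = kkill * chemo * KILLMASK(i) * x[i];
        debris_in += kill[i];
    }

    /* live bone-marrow / tissue occupancy (debris excluded) */
    double BM = S + N2 + Nbm + L2 + L3 + M2 + Mbm + MAC + Mc2 + Mcbm;

    /* stem cells: self-renewal inhibited by stem concentration and by
     * marrow occupancy relative to capacity */
    double aSe  = aS * (kS / (kS + S)) * (kBM / (kBM + BM / Kbm));
    double outS = 2.0 * (1.0 - aSe) * mrS * S;
    ydot[0] = (2.0 * aSe - 1.0) * mrS * S - dS * S - kill[0];

    double fM = 1.0 - fN - fL;
    double recMAC = MAC / (kMAC + MAC); /* macrophage-assisted recruitment */

    /* neutrophil lineage */
    double aNe  = aN2 * (kN / (kN + Npb));
    double matN = 2.0 * (1.0 - aNe) * mrN2 * N2 + sN2 * N2;
    double FmobN = mbN * (kmovN / (kmovN + Npb)) * Nbm;
    double FrecN = rN * recMAC * (kmovN / (kmovN + Nbm)) * Npb;
    double FmgN  = mgN * (kmovN / (kmovN + Nmp)) * Npb;
    double FdmN  = dmN * (kmovN / (kmovN + Npb)) * Nmp;
    ydot[1] = scopeN * fN * outS + (2.0 * aNe - 1.0) * mrN2 * N2
              - sN2 * N2 - d2 * N2 - kill[1];
    ydot[2] = matN - FmobN + FrecN - dN * Nbm - kill[2];
    ydot[3] = FmobN + FdmN - FmgN - FrecN - dN * Npb - kill[3];
    ydot[4] = FmgN - FdmN - dN * Nmp - kill[4];

    /* lymphocyte lineage (no marginal pool) */
    double aLe  = aL2 * (kL / (kL + L3pb));
    double matL = 2.0 * (1.0 - aLe) * mrL2 * L2 + sL2 * L2;
    double FmobL = mbL * (kmovL / (kmovL + L3pb)) * L3;
    double FrecL = rL * recMAC * (kmovL / (kmovL + L3)) * L3pb;
    ydot[5] = scopeL * fL * outS + (2.0 * aLe - 1.0) * mrL2 * L2
              - sL2 * L2 - d2 * L2 - kill[5];
    ydot[6] = matL - FmobL + FrecL - dL3 * L3 - kill[6];
    ydot[7] = FmobL - FrecL - dL3pb * L3pb - kill[7];

    /* monocyte lineage */
    double aMe  = aM2 * (kM / (kM + Mpb));
    double matM = 2.0 * (1.0 - aMe) * mrM2 * M2 + sM2 * M2;
    double FmobM = mbM * (kmovM / (kmovM + Mpb)) * Mbm;
    double FrecM = rM * recMAC * (kmovM / (kmovM + Mbm)) * Mpb;
    double FmgM  = mgM * (kmovM / (kmovM + Mmp)) * Mpb;
    double FdmM  = dmM * (kmovM / (kmovM + Mpb)) * Mmp;
    double Fact  = actMAC * Mpb;
    ydot[8]  = scopeM * fM * outS + (2.0 * aMe - 1.0) * mrM2 * M2
               - sM2 * M2 - d2 * M2 - kill[8];
    ydot[9]  = matM - FmobM + FrecM - dM * Mbm - kill[9];
    ydot[10] = FmobM + FdmM - FmgM - FrecM - Fact - dMpb * Mpb - kill[10];
    ydot[11] = FmgM - FdmM - dMpb * Mmp - kill[11];

    /* activated macrophages: monocyte activation + debris-driven
     * proliferation; not targeted by chemotherapy */
    ydot[12] = Fact + prMAC * (A / (kA + A)) * MAC - dMAC * MAC;

    /* apoptotic debris: chemotherapy kills accumulate, macrophages clear */
    ydot[13] = debris_in - clA * (MAC / (kMAC + MAC)) * A;

    /* leukemic clone: monocyte-form equations with all homeostatic feedback
     * removed (including any capacity gate on division) and no recruitment
     * back; growth ends at the marrow's maximal density because the patient
     * dies there (root function below) */
    ydot[14] = (2.0 * aMc2 - 1.0) * mrMc2 * Mc2
               - sMc * Mc2 - dMc * Mc2 - kill[14];
    ydot[15] = 2.0 * (1.0 - aMc2) * mrMc2 * Mc2 + sMc * Mc2
               - mbMc * Mcbm - dMc * Mcbm - kill[15];
    ydot[16] = mbMc * Mcbm - dMc * Mcpb - kill[16];
}

/* root: total leukemic burden far beyond the lethal marrow density; used to
 * halt AML simulations once every clinical endpoint has been crossed */
void leuko_root(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip)
{
    gout[0] = 20.0 * Kbm - (y[14] + y[15] + y[16]);
}
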