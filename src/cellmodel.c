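/* Compact spontaneously active cardiomyocyte membrane model.
 *
 * Right-hand side, root function (upstroke detector at the -20 mV
 * up-crossing) and event function (per-cycle homeostasis update of the
 * Na/K-pump and Na/Ca-exchanger correction factors) in the compiled-code
 * style used by deSolve.  The R level mirrors every formula here
 * (R/gating.R, R/currents.R, R/state.R); a consistency test asserts the
 * two agree to machine precision.
 *
 * Units: mV, ms, pA, nS, pF, mM, pL; fluxes fmol/ms; total cell Ca amol.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_STATE 21
#define N_PARMS 54
#define N_CURR  11

/* state indices */
#define iV    0
#define iM    1
#define iH    2
#define iD    3
#define iF    4
#define iY    5
#define iPA   6
#define iN    7
#define iRUR  8
#define iSUR  9
#define iRTO  10
#define iQTO  11
#define iNAI  12
#define iKI   13
#define iCAJ  14
#define iCAI  15
#define iCAB  16
#define iCAU  17
#define iCAR  18
#define iCFNK 19
#define iCFNX 20

/* parameter indices (kept in lock step with .parm_order in R/params.R) */
#define pCM      0
#define pGNA     1
#define pGCAL    2
#define pGHA     3
#define pGK1     4
#define pGKR     5
#define pGKS     6
#define pGKUR    7
#define pGKTO    8
#define pGBNSC   9
#define pMAXNAK  10
#define pMAXNCX  11
#define pECAL    12
#define pEHA     13
#define pEBNSC   14
#define pNAO     15
#define pKO      16
#define pCAO     17
#define pVJNC    18
#define pVIZ     19
#define pVBLK    20
#define pVSRUP   21
#define pVSRRL   22
#define pBJNC    23
#define pKDJNC   24
#define pBIZ     25
#define pKDIZ    26
#define pBBLK    27
#define pKDBLK   28
#define pBSRRL   29
#define pKDSRRL  30
#define pKLCAL   31
#define pPUP     32
#define pKUP     33
#define pPREL    34
#define pKMRYR   35
#define pGTR     36
#define pGDJI    37
#define pGDIB    38
#define pKMNANAK 39
#define pKMKNAK  40
#define pKMNANCX 41
#define pKMCANCX 42
#define pKSATNCX 43
#define pGAMNCX  44
#define pSTDNAI  45
#define pSTDCAT  46
#define pGCRFNAK 47
#define pGCRFNCX 48
#define pCRFFLR  49
#define pFHANA   50
#define pFBNSCNA 51
#define pHOMEO   52
#define pROOTV   53

#define RTF  26.7139      /* RT/F at 310 K, mV */
#define FDAY 96485.332    /* C/mol */

static double parms[N_PARMS];

void pf_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* guarded exponential: keeps the RHS finite for absurd voltages so that
 * pathological parameter sets surface as penalty MSE, not solver aborts */
static double sexp(double x)
{
    if (x > 50.0) x = 50.0;
    if (x < -50.0) x = -50.0;
    return exp(x);
}

/* rapid-buffer approximation: free Ca from total Ca for one buffer pool */
static double free_ca(double catot, double B, double Kd)
{
    double b = B + Kd - catot;
    double fr = 0.5 * (-b + sqrt(b * b + 4.0 * Kd * catot));
    return fr > 0.0 ? fr : 0.0;
}

/* voltage-dependent opening/closing rates, alpha = xinf/tau, beta = (1-xinf)/tau.
 * scheme ids: 0 m, 1 h, 2 d, 3 f, 4 y, 5 pa, 6 n, 7 rur, 8 sur, 9 rto, 10 qto */
static void gate_rates(int scheme, double v, double *alpha, double *beta)
{
    double xinf = 0.0, tau = 1.0;
    switch (scheme) {
    case 0: /* Na activation m */
        xinf = 1.0 / (1.0 + sexp(-(v + 40.0) / 6.0));
        tau  = 0.12 + 0.4 / (1.0 + sexp((v + 40.0) / 8.0));
        break;
    case 1: /* Na inactivation h */
        xinf = 1.0 / (1.0 + sexp((v + 64.0) / 4.5));
        tau  = 1.0 + 30.0 / (1.0 + sexp((v + 40.0) / 6.0));
        break;
    case 2: /* CaL activation d */
        xinf = 1.0 / (1.0 + sexp(-(v + 18.0) / 6.0));
        tau  = 0.6 + 1.8 / (1.0 + sexp((v + 30.0) / 8.0));
        break;
    case 3: /* CaL voltage inactivation f */
        xinf = 1.0 / (1.0 + sexp((v + 35.0) / 4.5));
        tau  = 100.0 + 200.0 / (1.0 + sexp((v + 25.0) / 6.0));
        break;
    case 4: /* hyperpolarization-activated y */
        xinf = 1.0 / (1.0 + sexp((v + 78.0) / 9.0));
        tau  = 250.0;
        break;
    case 5: /* Kr activation pa */
        xinf = 1.0 / (1.0 + sexp(-(v + 10.0) / 7.0));
        tau  = 80.0 + 250.0 / (1.0 + sexp((v + 35.0) / 8.0));
        break;
    case 6: /* Ks activation n */
        xinf = 1.0 / (1.0 + sexp(-(v - 2.0) / 13.0));
        tau  = 400.0;
        break;
    case 7: /* Kur activation */
        xinf = 1.0 / (1.0 + sexp(-(v + 6.0) / 9.0));
        tau  = 8.0;
        break;
    case 8: /* Kur inactivation */
        xinf = 1.0 / (1.0 + sexp((v + 30.0) / 10.0));
        tau  = 800.0;
        break;
    case 9: /* Kto activation */
        xinf = 1.0 / (1.0 + sexp(-(v + 14.0) / 9.0));
        tau  = 4.0;
        break;
    case 10: /* Kto inactivation */
        xinf = 1.0 / (1.0 + sexp((v + 42.0) / 6.0));
        tau  = 35.0;
        break;
    }
    *alpha = xinf / tau;
    *beta  = (1.0 - xinf) / tau;
}

/* currents[]: Na CaL ha K1 Kr Ks Kur Kto bNSC NaK NCX (roster order) */
static void compute_rhs(double t, double *y, double *ydot, double *currents)
{
    double v = y[iV];
    double nai = y[iNAI], ki = y[iKI];
    double caJ = free_ca(y[iCAJ], parms[pBJNC], parms[pKDJNC]);
    double caI = free_ca(y[iCAI], parms[pBIZ], parms[pKDIZ]);
    double caB = free_ca(y[iCAB], parms[pBBLK], parms[pKDBLK]);
    double caU = y[iCAU]; /* network SR unbuffered */
    double caR = free_ca(y[iCAR], parms[pBSRRL], parms[pKDSRRL]);

    if (nai < 1e-6) nai = 1e-6;
    if (ki < 1e-6) ki = 1e-6;

    double ena = RTF * log(parms[pNAO] / nai);
    double ek  = RTF * log(parms[pKO] / ki);

    /* open probabilities */
    double poNa  = y[iM] * y[iM] * y[iM] * y[iH];
    double fca   = parms[pKLCAL] / (parms[pKLCAL] + caJ);
    double poCaL = y[iD] * y[iF] * fca;
    double poHa  = y[iY];
    double poK1  = 1.0 / (1.0 + sexp((v - ek - 8.0) / 10.0));
    double poKr  = y[iPA] / (1.0 + sexp((v + 10.0) / 12.0));
    double poKs  = y[iN] * y[iN];
    double poKur = y[iRUR] * y[iSUR];
    double poKto = y[iRTO] * y[iQTO];

    double iNa   = parms[pGNA] * poNa * (v - ena);
    double iCaL  = parms[pGCAL] * poCaL * (v - parms[pECAL]);
    double iHa   = parms[pGHA] * poHa * (v - parms[pEHA]);
    double iK1   = parms[pGK1] * poK1 * (v - ek);
    double iKr   = parms[pGKR] * poKr * (v - ek);
    double iKs   = parms[pGKS] * poKs * (v - ek);
    double iKur  = parms[pGKUR] * poKur * (v - ek);
    double iKto  = parms[pGKTO] * poKto * (v - ek);
    double iBnsc = parms[pGBNSC] * 1.0 * (v - parms[pEBNSC]);

    double fnak = 1.0 / (1.0 + 0.1245 * sexp(-0.1 * v / RTF) +
                         0.0353 * sexp(-v / RTF));
    double rna = nai / (nai + parms[pKMNANAK]);
    double iNaK = y[iCFNK] * parms[pMAXNAK] * rna * rna * rna *
                  (parms[pKO] / (parms[pKO] + parms[pKMKNAK])) * fnak;

    double g = parms[pGAMNCX];
    double e1 = sexp(g * v / RTF), e2 = sexp((g - 1.0) * v / RTF);
    double nao3 = parms[pNAO] * parms[pNAO] * parms[pNAO];
    double kmna3 = parms[pKMNANCX] * parms[pKMNANCX] * parms[pKMNANCX];
    double iNCX = y[iCFNX] * parms[pMAXNCX] *
                  (e1 * nai * nai * nai * parms[pCAO] - e2 * nao3 * caB) /
                  ((kmna3 + nao3) * (parms[pKMCANCX] + parms[pCAO]) *
                   (1.0 + parms[pKSATNCX] * e2));

    double itot = iNa + iCaL + iHa + iK1 + iKr + iKs + iKur + iKto +
                  iBnsc + iNaK + iNCX;

    if (currents) {
        currents[0] = iNa;  currents[1] = iCaL; currents[2] = iHa;
        currents[3] = iK1;  currents[4] = iKr;  currents[5] = iKs;
        currents[6] = iKur; currents[7] = iKto; currents[8] = iBnsc;
        currents[9] = iNaK; currents[10] = iNCX;
    }
    if (!ydot) return;

    ydot[iV] = -itot / parms[pCM];

    double a, b;
    gate_rates(0, v, &a, &b);  ydot[iM]   = a * (1.0 - y[iM]) - b * y[iM];
    gate_rates(1, v, &a, &b);  ydot[iH]   = a * (1.0 - y[iH]) - b * y[iH];
    gate_rates(2, v, &a, &b);  ydot[iD]   = a * (1.0 - y[iD]) - b * y[iD];
    gate_rates(3, v, &a, &b);  ydot[iF]   = a * (1.0 - y[iF]) - b * y[iF];
    gate_rates(4, v, &a, &b);  ydot[iY]   = a * (1.0 - y[iY]) - b * y[iY];
    gate_rates(5, v, &a, &b);  ydot[iPA]  = a * (1.0 - y[iPA]) - b * y[iPA];
    gate_rates(6, v, &a, &b);  ydot[iN]   = a * (1.0 - y[iN]) - b * y[iN];
    gate_rates(7, v, &a, &b);  ydot[iRUR] = a * (1.0 - y[iRUR]) - b * y[iRUR];
    gate_rates(8, v, &a, &b);  ydot[iSUR] = a * (1.0 - y[iSUR]) - b * y[iSUR];
    gate_rates(9, v, &a, &b);  ydot[iRTO] = a * (1.0 - y[iRTO]) - b * y[iRTO];
    gate_rates(10, v, &a, &b); ydot[iQTO] = a * (1.0 - y[iQTO]) - b * y[iQTO];

    /* ion bookkeeping; channel fluxes fmol/ms = pA / (z F) */
    double volCyt = parms[pVJNC] + parms[pVIZ] + parms[pVBLK];
    double jNaCh = iNa + parms[pFHANA] * iHa + parms[pFBNSCNA] * iBnsc;
    double jKCh  = iK1 + iKr + iKs + iKur + iKto +
                   (1.0 - parms[pFHANA]) * iHa +
                   (1.0 - parms[pFBNSCNA]) * iBnsc;
    ydot[iNAI] = -(jNaCh + 3.0 * iNaK + 3.0 * iNCX) / (FDAY * volCyt);
    ydot[iKI]  = -(jKCh - 2.0 * iNaK) / (FDAY * volCyt);

    /* Ca subsystem fluxes, fmol/ms */
    double poRyr = caJ * caJ / (caJ * caJ + parms[pKMRYR] * parms[pKMRYR]);
    double jRel = parms[pPREL] * poRyr * (caR - caJ);
    double jUp  = parms[pPUP] * caB * caB /
                  (caB * caB + parms[pKUP] * parms[pKUP]);
    double jTr  = parms[pGTR] * (caU - caR);
    double jJI  = parms[pGDJI] * (caJ - caI);
    double jIB  = parms[pGDIB] * (caI - caB);

    ydot[iCAJ] = (-iCaL / (2.0 * FDAY) + jRel - jJI) / parms[pVJNC];
    ydot[iCAI] = (jJI - jIB) / parms[pVIZ];
    ydot[iCAB] = (jIB - jUp + iNCX / FDAY) / parms[pVBLK];
    ydot[iCAU] = (jUp - jTr) / parms[pVSRUP];
    ydot[iCAR] = (jTr - jRel) / parms[pVSRRL];

    /* correction factors are piecewise constant between cycle events */
    ydot[iCFNK] = 0.0;
    ydot[iCFNX] = 0.0;
}

void pf_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    compute_rhs(*t, y, ydot, NULL);
}

/* root: candidate cycle boundary at the -20 mV crossing */
void pf_root(int *neq, double *t, double *y, int *ng, double *gout,
             double *out, int *ip)
{
    gout[0] = y[iV] - parms[pROOTV];
}

/* per-cycle homeostasis increments, applied at upward crossings only */
void pf_event(int *n, double *t, double *y)
{
    double ydot[N_STATE];
    compute_rhs(*t, y, ydot, NULL);
    if (ydot[iV] <= 0.0 || parms[pHOMEO] == 0.0) return;

    double catot = 1000.0 * (y[iCAJ] * parms[pVJNC] + y[iCAI] * parms[pVIZ] +
                             y[iCAB] * parms[pVBLK] + y[iCAU] * parms[pVSRUP] +
                             y[iCAR] * parms[pVSRRL]); /* amol */
    y[iCFNK] += -(parms[pSTDNAI] - y[iNAI]) * parms[pGCRFNAK];
    y[iCFNX] += -(parms[pSTDCAT] - catot) * parms[pGCRFNCX];
    if (y[iCFNK] < parms[pCRFFLR]) y[iCFNK] = parms[pCRFFLR];
    if (y[iCFNX] < parms[pCRFFLR]) y[iCFNX] = parms[pCRFFLR];
}

/* ---- .Call interface used by the R mirrors and tests ---- */

SEXP pf_rhs_call(SEXP y_, SEXP p_)
{
    if (LENGTH(y_) != N_STATE) error("state vector must have %d elements", N_STATE);
    if (LENGTH(p_) != N_PARMS) error("parameter vector must have %d elements", N_PARMS);
    double save[N_PARMS];
    memcpy(save, parms, sizeof(parms));
    memcpy(parms, REAL(p_), sizeof(parms));

    SEXP dy = PROTECT(allocVector(REALSXP, N_STATE));
    SEXP cur = PROTECT(allocVector(REALSXP, N_CURR));
    compute_rhs(0.0, REAL(y_), REAL(dy), REAL(cur));
    memcpy(parms, save, sizeof(parms));

    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, dy);
    SET_VECTOR_ELT(out, 1, cur);
    SEXP nm = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, mkChar("deriv"));
    SET_STRING_ELT(nm, 1, mkChar("currents"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(4);
    return out;
}

SEXP pf_gate_rates_call(SEXP scheme_, SEXP v_)
{
    int s = asInteger(scheme_);
    if (s < 0 || s > 10) error("unknown gating scheme id %d", s);
    int nv = LENGTH(v_);
    SEXP out = PROTECT(allocMatrix(REALSXP, nv, 2));
    for (int i = 0; i < nv; i++) {
        double a, b;
        gate_rates(s, REAL(v_)[i], &a, &b);
        REAL(out)[i] = a;
        REAL(out)[i + nv] = b;
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef callMethods[] = {
    {"pf_rhs_call", (DL_FUNC) &pf_rhs_call, 2},
    {"pf_gate_rates_call", (DL_FUNC) &pf_gate_rates_call, 2},
    {NULL, NULL, 0}
};

void R_init_pacefit(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
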