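/* Right-hand side of the temperature-entrainment circadian model.
 *
 * State (11 per cell): TS1, TS2, actHSF1, indHSP, PerCry_mRNA, PERCRY,
 * nucPERCRY, Bmal1_mRNA, BMAL1, nucBMAL1, CLOCKBMAL1.
 *
 * Parameters are passed through deSolve as a flat numeric vector:
 *   [ n_cells, T, Tavg, <41 parameters for cell 1>, <41 for cell 2>, ... ]
 * Temperature is piecewise constant; the integrator is restarted at every
 * schedule discontinuity, so T and Tavg are plain parameters here.
 * Any number of cells can be stacked into one uncoupled system.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* parameter indices within one cell's 41-slot block (canonical order) */
#define VACT0_TS1  0
#define VACT1_TS1  1
#define VINA_TS1   2
#define VB_TS2     3
#define KB_TS2     4
#define HILL_N     5
#define VD_TS2     6
#define KT_SMALL   7
#define KT_BIG     8
#define VACT_HSF1  9
#define HSF1TOT   10
#define VINA_HSF1 11
#define VB_HSP    12
#define VD_HSP    13
#define KHSF1     14
#define KHSF1_BIG 15
#define KHSF1_CI  16
#define V1B       17
#define C_ACT     18
#define K1B       19
#define K1I       20
#define HILL_P    21
#define K1D       22
#define K2B       23
#define HILL_Q    24
#define K2D       25
#define K2T       26
#define K3T       27
#define K3D       28
#define V4B       29
#define K4B       30
#define HILL_R    31
#define K4D       32
#define K5B       33
#define K5D       34
#define K5T       35
#define K6T       36
#define K6D       37
#define K6A       38
#define K7A       39
#define K7D       40

#define NSTATE 11
#define NPAR   41

static double *pp = NULL;

void clock_init(void (*odeparms)(int *, double *))
{
    static SEXP (*get_gparms)(void) = NULL;
    if (get_gparms == NULL)
        get_gparms = (SEXP (*)(void)) R_GetCCallable("deSolve",
                                                     "get_deSolve_gparms");
    pp = REAL(get_gparms());
}

/* Hill inputs are clipped at 0 so that transient sub-zero probes of the
 * error-controlled integrator cannot produce NaN from fractional powers;
 * the solution itself is positivity-checked on output in R. */
static inline double pos(double x) { return x > 0.0 ? x : 0.0; }

void clock_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const int ncell = (int) pp[0];
    const double T = pp[1], Tavg = pp[2];

    for (int c = 0; c < ncell; c++) {
        const double *q = pp + 3 + NPAR * c;
        const double *s = y + NSTATE * c;
        double *d = ydot + NSTATE * c;

        const double TS1  = s[0], TS2  = s[1], aH = s[2], hsp = s[3];
        const double PCm  = s[4], PC   = s[5], nPC = s[6];
        const double Bm   = s[7], B    = s[8], nB  = s[9], CB = s[10];

        /* thermosensing cascade */
        const double ts1n = pow(pos(TS1), q[HILL_N]);
        const double kbn  = pow(q[KB_TS2], q[HILL_N]);
        d[0] = q[VACT0_TS1] * Tavg + q[VACT1_TS1] * (T - Tavg)
               - q[VINA_TS1] * TS1;
        d[1] = q[VB_TS2] * ts1n / (kbn + ts1n) - q[VD_TS2] * TS2;

        /* HSF1/HSP heat-shock-response module */
        const double stim = 1.0 + q[KT_SMALL] * TS2 / (q[KT_BIG] + TS2);
        d[2] = q[VACT_HSF1] * (q[HSF1TOT] - aH) / hsp * stim
               - q[VINA_HSF1] * aH;
        d[3] = q[VB_HSP] * aH / hsp - q[VD_HSP] * hsp;

        /* clock gene network; active HSF1 multiplies the CLOCK/BMAL1-driven
         * transcription, saturably, with HSP competing against CLOCK/BMAL1
         * stabilisation in the denominator */
        const double ent = 1.0 + q[KHSF1] * aH
            / (q[KHSF1_BIG] + aH + q[KHSF1_CI] * hsp / CB);
        const double inhib = pow(pos(nPC) / q[K1I], q[HILL_P]);
        d[4] = q[V1B] * (CB + q[C_ACT])
               / (q[K1B] * (1.0 + inhib) + CB + q[C_ACT]) * ent
               - q[K1D] * PCm;
        d[5] = q[K2B] * pow(pos(PCm), q[HILL_Q]) - q[K2D] * PC
               - q[K2T] * PC + q[K3T] * nPC;
        d[6] = q[K2T] * PC - q[K3T] * nPC - q[K3D] * nPC;

        const double npcr = pow(pos(nPC), q[HILL_R]);
        const double k4br = pow(q[K4B], q[HILL_R]);
        d[7] = q[V4B] * npcr / (k4br + npcr) - q[K4D] * Bm;
        d[8] = q[K5B] * Bm - q[K5D] * B - q[K5T] * B + q[K6T] * nB;
        d[9] = q[K5T] * B - q[K6T] * nB - q[K6D] * nB + q[K7A] * CB
               - q[K6A] * nB;
        d[10] = q[K6A] * nB - q[K7A] * CB - q[K7D] * CB;
    }
}
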