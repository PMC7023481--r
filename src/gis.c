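/* Compiled right-hand side of the six-state gastrointestinal
 * dissolution-and-transit model, in the form deSolve expects.
 *
 * States (amounts, ug):
 *   y[0] stomach solid        y[1] duodenum solid   y[2] duodenum dissolved
 *   y[3] jejunum solid        y[4] jejunum dissolved y[5] plasma
 *   y[6] cumulative eliminated y[7] cumulative distal solid transit
 *
 * Forcings (only read when plus > 0.5): saturation solubility Cs (ug/mL)
 * in duodenum and jejunum, interpolated from the subject's pH series.
 */
#include <R.h>
#include <math.h>

static double parms[9];
#define plusflag  parms[0]
#define Kempt     parms[1]
#define K_TD      parms[2]
#define K_TJ      parms[3]
#define Ka        parms[4]
#define Kel       parms[5]
#define V1        parms[6]
#define V2        parms[7]
#define KD        parms[8]

static double forc[2];
#define cs_duo forc[0]
#define cs_jej forc[1]

void gis_initmod(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

void gis_initforc(void (*odeforcs)(int *, double *))
{
    int n = 2;
    odeforcs(&n, forc);
}

void gis_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double r_duo, r_jej;
    if (plusflag > 0.5) {
        double drive_d = cs_duo - y[2] / V1;
        double drive_j = cs_jej - y[4] / V2;
        r_duo = KD * y[1] * (drive_d > 0 ? drive_d : 0);
        r_jej = KD * y[3] * (drive_j > 0 ? drive_j : 0);
    } else {
        r_duo = KD * y[1];
        r_jej = KD * y[3];
    }
    ydot[0] = -Kempt * y[0];
    ydot[1] = Kempt * y[0] - K_TD * y[1] - r_duo;
    ydot[2] = r_duo - Ka * y[2];
    ydot[3] = K_TD * y[1] - K_TJ * y[3] - r_jej;
    ydot[4] = r_jej - Ka * y[4];
    ydot[5] = Ka * (y[2] + y[4]) - Kel * y[5];
    ydot[6] = Kel * y[5];
    ydot[7] = K_TJ * y[3];
}
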