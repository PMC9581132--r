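/* Reduced human Purkinje action-potential model.
 *
 * Hodgkin-Huxley-style formulation with the 12 ionic currents that dominate
 * Purkinje electrophysiology: INa, INaL, ICaL, ICaT, Ito, Isus, IKr, IKs,
 * If, IK1, INCX, INaK.  Membrane capacitance is normalised to 1, so currents
 * are in pA/pF (= mV/ms on dV/dt) and conductances absorb the scaling.
 * Intracellular concentrations are held fixed; INCX and INaK are static
 * voltage-dependent currents.  Reversal potentials are constants.
 *
 * State vector (15): V, m, h, j, mL, hL, d, f, dT, fT, r, s, xr, xs, y
 * Parameters (13): the 12 maximal conductances (already multiplied by any
 * population scaling and drug block) followed by the stimulus current.
 */

#include <R.h>
#include <math.h>

static double parms[13];
#define gNa   parms[0]
#define gNaL  parms[1]
#define gCaL  parms[2]
#define gCaT  parms[3]
#define gto   parms[4]
#define gsus  parms[5]
#define gKr   parms[6]
#define gKs   parms[7]
#define gf    parms[8]
#define gK1   parms[9]
#define gNCX  parms[10]
#define gNaK  parms[11]
#define istim parms[12]

static const double ENa =  27.0;   /* mV */
static const double EK  = -91.0;   /* mV */
static const double ECa =  60.0;   /* mV, effective for the reduced model */
static const double Ef  = -30.0;   /* mV, mixed Na/K funny-current reversal */

void purkinje_init(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, parms);
}

static double sigm(double v, double vh, double k)
{
    return 1.0 / (1.0 + exp(-(v - vh) / k));
}

void purkinje_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double V  = y[0];
    double m  = y[1],  h  = y[2],  j  = y[3];
    double mL = y[4],  hL = y[5];
    double d  = y[6],  f  = y[7];
    double dT = y[8],  fT = y[9];
    double r  = y[10], s  = y[11];
    double xr = y[12], xs = y[13];
    double yf = y[14];

    /* --- currents ------------------------------------------------------ */
    double INa  = gNa  * m * m * m * h * j * (V - ENa);
    double INaL = gNaL * mL * hL * (V - ENa);
    double ICaL = gCaL * d * f * (V - ECa);
    double ICaT = gCaT * dT * fT * (V - ECa);
    double Ito  = gto  * r * s * (V - EK);
    double Isus = gsus * sigm(V, 12.0, 14.0) * (V - EK);
    double rkr  = 1.0 / (1.0 + exp((V + 20.0) / 20.0));
    double IKr  = gKr * xr * rkr * (V - EK);
    double IKs  = gKs * xs * xs * (V - EK);
    double If   = gf * yf * (V - Ef);
    double IK1  = gK1 * (V - EK) / (1.0 + exp((V + 70.0) / 8.0));
    double INCX = -gNCX / (1.0 + exp((V + 25.0) / 12.0));
    double INaK = gNaK / (1.0 + exp(-(V + 65.0) / 25.0));

    double Iion = INa + INaL + ICaL + ICaT + Ito + Isus + IKr + IKs +
                  If + IK1 + INCX + INaK;

    ydot[0] = -Iion + istim;

    /* --- gating kinetics ----------------------------------------------- */
    /* INa activation/inactivation; j is the slow recovery gate that sets
     * the rate dependence of dV/dtMax. */
    double minf = sigm(V, -47.0, 5.5);
    double taum = 0.10 + 0.12 * exp(-pow((V + 45.0) / 15.0, 2.0));
    double hinf = 1.0 / (1.0 + exp((V + 75.0) / 6.5));
    double tauh = 0.30 + 6.0 * exp(-pow((V + 70.0) / 12.0, 2.0));
    double jinf = hinf;
    double tauj = 35.0 + 280.0 * exp(-pow((V + 75.0) / 15.0, 2.0));

    double mLinf = sigm(V, -47.0, 5.5);
    double taumL = 0.5;
    double hLinf = 0.05 + 0.95 / (1.0 + exp((V + 87.0) / 7.0));
    double tauhL = 200.0;

    /* ICaL: slow, voltage-dependent tau_f gives the window-current
     * reactivation responsible for EADs under strong IKr block. */
    double dinf = sigm(V, -20.0, 6.5);
    double taud = 0.5 + 2.5 * exp(-pow((V + 15.0) / 20.0, 2.0));
    double finf = 1.0 / (1.0 + exp((V + 28.0) / 7.0));
    double tauf = 25.0 + 600.0 * exp(-pow((V - 25.0) / 30.0, 2.0));

    double dTinf = sigm(V, -50.0, 5.0);
    double taudT = 2.0;
    double fTinf = 1.0 / (1.0 + exp((V + 72.0) / 5.0));
    double taufT = 25.0;

    double rinf = sigm(V, 5.0, 13.0);
    double taur = 1.5;
    double sinf = 1.0 / (1.0 + exp((V + 40.0) / 5.0));
    double taus = 15.0 + 60.0 * exp(-pow((V + 55.0) / 20.0, 2.0));

    double xrinf  = sigm(V, -20.0, 8.0);
    double tauxr  = 300.0 + 500.0 / (1.0 + exp((V + 45.0) / 8.0));
    double xsinf  = sigm(V, -12.0, 14.0);
    double tauxs  = 1500.0 + 1500.0 * exp(-pow(V / 40.0, 2.0));

    /* If activation (y) drives the slow diastolic depolarisation that makes
     * the take-off potential rate dependent. */
    double yinf = 1.0 / (1.0 + exp((V + 87.0) / 6.0));
    double tauy = 700.0 + 1800.0 * exp(-pow((V + 85.0) / 25.0, 2.0));

    ydot[1]  = (minf  - m)  / taum;
    ydot[2]  = (hinf  - h)  / tauh;
    ydot[3]  = (jinf  - j)  / tauj;
    ydot[4]  = (mLinf - mL) / taumL;
    ydot[5]  = (hLinf - hL) / tauhL;
    ydot[6]  = (dinf  - d)  / taud;
    ydot[7]  = (finf  - f)  / tauf;
    ydot[8]  = (dTinf - dT) / taudT;
    ydot[9]  = (fTinf - fT) / taufT;
    ydot[10] = (rinf  - r)  / taur;
    ydot[11] = (sinf  - s)  / taus;
    ydot[12] = (xrinf - xr) / tauxr;
    ydot[13] = (xsinf - xs) / tauxs;
    ydot[14] = (yinf  - yf) / tauy;
}
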