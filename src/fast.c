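/* Fast double-precision evaluation of the GPC density and CDF for the
 * regression loss, simulation studies and trajectory export.  Same series
 * as the extended-precision engines; at the sample times used in fitting
 * (minutes to days after dosing with beta of tens of seconds) the terms
 * carry no destructive cancellation, so ~13 significant digits survive.
 * Falls back to the extended-precision long-t engine when e^{bt} would
 * overflow a double.
 */
#include "gpconv.h"
#include <Rmath.h>

/* B_z(P,-alpha) direct series in doubles (z <= 0.75) */
static double betainc_d(double z, double P, double alpha)
{
    double s = 0.0, c = 1.0;
    for (int k = 0; k < 100000; k++) {
        s += c / (P + k);
        c *= (1.0 + alpha + k) * z / (k + 1);
        if (fabs(c / (P + k + 1)) < 1e-18 * (fabs(s) + 1e-300) && k > 2)
            break;
    }
    return pow(z, P) * s;
}

static int koff_fast(int kind)
{
    static const int o[4] = { 0, 1, 2, -1 };
    return o[kind];
}

static double short_fast(int kind, double t, double a, double b,
                         double alpha, double beta)
{
    double z = 1.0 - beta / t;
    double bt = b * t;
    int off = koff_fast(kind);
    double pref = pow(b, a) * alpha * pow(beta, alpha) / tgamma(a)
        * pow(t, a - alpha - 1.0 + off);
    double s = 0.0, c = 1.0, amax = 0.0;
    for (int n = 0; n < 100000; n++) {
        double P = a + n + off;
        double coeff = 1.0;
        if (kind == GPC_CDF) coeff = 1.0 / (a + n);
        else if (kind == GPC_SUPER) coeff = 1.0 / ((a + n) * (1.0 + a + n));
        else if (kind == GPC_DERIV) coeff = a + n - 1.0;
        double term;
        if (kind == GPC_DERIV && coeff == 0.0)
            term = c;                            /* limit z^0 */
        else
            term = c * coeff * betainc_d(z, P, alpha);
        s += term;
        if (fabs(term) > amax) amax = fabs(term);
        if (n > 2 && fabs(term) < 1e-18 * amax) break;
        c *= -bt / (n + 1);
    }
    return pref * s;
}

/* regularized 1F1(A,B;x) for x > 0 via the entire series sum (doubles) */
static double f1reg_pos_d(double A, double B, double x)
{
    double c = 1.0 / tgamma(B), s = 0.0, amax = 0.0;
    long jstart = 0;
    if (B < 0.5 && fabs(B - round(B)) < 1e-12) {
        jstart = (long) (-round(B)) + 1;
        c = 1.0;
        for (long j = 0; j < jstart; j++)
            c *= (A + j) * x / (j + 1);
        c /= tgamma(B + jstart);
    }
    for (long j = jstart; j < 1000000; j++) {
        s += c;
        if (fabs(c) > amax) amax = fabs(c);
        if (j > 2 + (long) x && fabs(c) < 1e-18 * amax) break;
        c *= (A + j) * x / ((B + j) * (j + 1));
    }
    return s;
}

/* terminating 1F1(A, A-k; x) for x < 0 (times e^x applied by caller) */
static double f1term_d(double B, double bt, long k)
{
    /* 1F1(-k, B; bt) */
    double s = 0.0, c = 1.0;
    for (long j = 0; j <= k; j++) {
        s += c;
        if (j == k) break;
        c *= (double)(j - k) * bt / ((B + j) * (j + 1));
    }
    return s;
}

static double long_fast(int kind, double t, double a, double b,
                        double alpha, double beta)
{
    double bt = b * t;
    double w = beta / t;
    double cscpa = M_PI / sin(M_PI * alpha);
    double ba = pow(b, a);
    double galpha = tgamma(alpha);
    double embt = exp(-bt);
    double closed, spre;
    if (kind == GPC_PDF) {
        closed = ba / tgamma(a) * embt * pow(t, a - 1.0);
        double f1 = embt * f1reg_pos_d(-alpha, a - alpha, bt);
        closed -= cscpa * ba * pow(beta, alpha) / galpha
            * pow(t, a - alpha - 1.0) * f1;
        spre = -alpha * ba / tgamma(a) * pow(t, a - 1.0);
    } else {                                     /* CDF */
        double Q = pgamma(bt, a, 1.0, 0, 0);
        double f1 = embt * f1reg_pos_d(-alpha + 1.0, a - alpha + 1.0, bt);
        closed = 1.0 - Q - cscpa * ba * pow(beta, alpha) / galpha
            * pow(t, a - alpha) * f1;
        spre = -alpha * ba / (a * tgamma(a)) * pow(t, a);
    }
    double s = 0.0, wk = w, poch = (kind == GPC_PDF) ? 1.0 - a : -a;
    double kfact = 1.0;
    for (long k = 1; k < 100000; k++) {
        long deg = (kind == GPC_PDF) ? k : k - 1;
        double term = wk * poch / (kfact * ((double) k - alpha))
            * embt * f1term_d(a - (double) deg, bt, deg);
        s += term;
        if (fabs(spre * term) < 1e-22 * (fabs(closed) + fabs(spre * s)) && k > 1)
            break;
        wk *= w;
        poch *= (kind == GPC_PDF) ? ((double) k + 1.0 - a) : ((double) k - a);
        kfact *= (double) (k + 1);
    }
    return closed + spre * s;
}

double gpc_fast1(int kind, double t, double a, double b, double alpha,
                 double beta)
{
    if (t <= beta) return 0.0;
    if (t < 4.0 * beta) return short_fast(kind, t, a, b, alpha, beta);
    if (b * t <= 650.0 && (kind == GPC_PDF || kind == GPC_CDF))
        return long_fast(kind, t, a, b, alpha, beta);
    /* e^{bt} exceeds double range: use the extended-precision engine */
    gpc_policy pol = { 20, 10, -40, 1000000 };
    gpc_diag diag;
    mpfr_t r;
    mpfr_init2(r, gpc_bits(30));
    if (fabs(a - round(a)) < 1e-10) {
        gpc_eval_short(r, kind, t, a, b, alpha, beta, &pol, &diag);
    } else {
        gpc_eval_long(r, kind, t, a, b, alpha, beta, &pol, &diag);
    }
    double v = mpfr_get_d(r, MPFR_RNDN);
    mpfr_clear(r);
    return v;
}
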