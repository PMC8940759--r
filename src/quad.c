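/* High-precision tanh-sinh (double-exponential) quadrature oracles over
 * (beta, t), independent of the series engines:
 *   which = 0 : GD(t - tau) PD(tau)                      -> density
 *   which = 1 : PD(v) P(a, b (t - v))                    -> CDF
 *   which = 2 : PD(v) [(t-v) P(a,b(t-v)) - a/b P(a+1,b(t-v))] -> super-cum.
 * The change of variable tau = c + d tanh((pi/2) sinh u) handles the
 * algebraic endpoint singularity of the gamma kernel at tau -> t (a < 1).
 * Endpoint distances are computed as 2d/(1+e^{±2y}) to avoid cancellation.
 */
#include "gpconv.h"

typedef struct {
    double t, a, b, alpha, beta;
    int which;
    mpfr_t ga;           /* Gamma(a) */
} quad_ctx;

/* integrand evaluated from the distances to the endpoints:
 * dl = tau - beta, dr = t - tau (both > 0, high precision) */
static void integrand(mpfr_t rop, quad_ctx *cx, mpfr_t dl, mpfr_t dr,
                      mpfr_prec_t prec)
{
    mpfr_t tau, x, tmp, tmp2;
    mpfr_inits2(prec, tau, x, tmp, tmp2, (mpfr_ptr) 0);
    mpfr_add_d(tau, dl, cx->beta, MPFR_RNDN);       /* tau = beta + dl */
    /* PD(tau) = (alpha/tau) (beta/tau)^alpha */
    mpfr_set_d(tmp, cx->beta, MPFR_RNDN);
    mpfr_div(tmp, tmp, tau, MPFR_RNDN);
    mpfr_set_d(tmp2, cx->alpha, MPFR_RNDN);
    mpfr_pow(tmp, tmp, tmp2, MPFR_RNDN);
    mpfr_mul_d(tmp, tmp, cx->alpha, MPFR_RNDN);
    mpfr_div(rop, tmp, tau, MPFR_RNDN);

    mpfr_set(x, dr, MPFR_RNDN);                     /* x = t - tau */
    if (cx->which == 0) {
        /* GD(x) = e^{-bx} (bx)^a / (x Gamma(a)) */
        mpfr_mul_d(tmp, x, cx->b, MPFR_RNDN);       /* bx */
        mpfr_set_d(tmp2, cx->a, MPFR_RNDN);
        mpfr_pow(tmp2, tmp, tmp2, MPFR_RNDN);       /* (bx)^a */
        mpfr_neg(tmp, tmp, MPFR_RNDN);
        mpfr_exp(tmp, tmp, MPFR_RNDN);              /* e^{-bx} */
        mpfr_mul(tmp, tmp, tmp2, MPFR_RNDN);
        mpfr_div(tmp, tmp, x, MPFR_RNDN);
        mpfr_div(tmp, tmp, cx->ga, MPFR_RNDN);
        mpfr_mul(rop, rop, tmp, MPFR_RNDN);
    } else {
        mpfr_t bx, P1;
        mpfr_inits2(prec, bx, P1, (mpfr_ptr) 0);
        mpfr_mul_d(bx, x, cx->b, MPFR_RNDN);
        mpfr_set_d(tmp, cx->a, MPFR_RNDN);
        gamma_regP(P1, tmp, bx, prec);              /* P(a, bx) */
        if (cx->which == 1) {
            mpfr_mul(rop, rop, P1, MPFR_RNDN);
        } else {
            mpfr_t P2;
            mpfr_init2(P2, prec);
            mpfr_set_d(tmp, cx->a, MPFR_RNDN);
            mpfr_add_ui(tmp, tmp, 1, MPFR_RNDN);
            gamma_regP(P2, tmp, bx, prec);          /* P(a+1, bx) */
            mpfr_mul(P1, P1, x, MPFR_RNDN);
            mpfr_mul_d(P2, P2, cx->a, MPFR_RNDN);
            mpfr_div_d(P2, P2, cx->b, MPFR_RNDN);   /* * a/b */
            mpfr_sub(P1, P1, P2, MPFR_RNDN);
            mpfr_mul(rop, rop, P1, MPFR_RNDN);
            mpfr_clear(P2);
        }
        mpfr_clears(bx, P1, (mpfr_ptr) 0);
    }
    mpfr_clears(tau, x, tmp, tmp2, (mpfr_ptr) 0);
}

/* weighted contribution at abscissa u (plus u and, symmetrically, -u) */
static void nodes_at(mpfr_t acc, quad_ctx *cx, mpfr_t d, double u,
                     mpfr_prec_t prec, int both)
{
    mpfr_t mu, y, e2y, dl, dr, wgt, f, tmp;
    mpfr_inits2(prec, mu, y, e2y, dl, dr, wgt, f, tmp, (mpfr_ptr) 0);
    for (int sgn = 0; sgn < (both ? 2 : 1); sgn++) {
        double uu = sgn ? -u : u;
        mpfr_set_d(mu, uu, MPFR_RNDN);
        mpfr_sinh(y, mu, MPFR_RNDN);
        mpfr_const_pi(tmp, MPFR_RNDN);
        mpfr_mul(y, y, tmp, MPFR_RNDN);
        mpfr_div_ui(y, y, 2, MPFR_RNDN);            /* y = pi/2 sinh u */
        /* right distance: d * 2/(1+e^{2y}); left: d * 2/(1+e^{-2y}) */
        mpfr_mul_ui(e2y, y, 2, MPFR_RNDN);
        mpfr_exp(e2y, e2y, MPFR_RNDN);
        mpfr_add_ui(tmp, e2y, 1, MPFR_RNDN);
        mpfr_ui_div(dr, 2, tmp, MPFR_RNDN);
        mpfr_mul(dr, dr, d, MPFR_RNDN);
        mpfr_mul_ui(tmp, y, 2, MPFR_RNDN);
        mpfr_neg(tmp, tmp, MPFR_RNDN);
        mpfr_exp(tmp, tmp, MPFR_RNDN);
        mpfr_add_ui(tmp, tmp, 1, MPFR_RNDN);
        mpfr_ui_div(dl, 2, tmp, MPFR_RNDN);
        mpfr_mul(dl, dl, d, MPFR_RNDN);
        /* weight = d (pi/2) cosh u / cosh^2 y */
        mpfr_cosh(wgt, mu, MPFR_RNDN);
        mpfr_const_pi(tmp, MPFR_RNDN);
        mpfr_mul(wgt, wgt, tmp, MPFR_RNDN);
        mpfr_div_ui(wgt, wgt, 2, MPFR_RNDN);
        mpfr_mul(wgt, wgt, d, MPFR_RNDN);
        mpfr_cosh(tmp, y, MPFR_RNDN);
        mpfr_sqr(tmp, tmp, MPFR_RNDN);
        mpfr_div(wgt, wgt, tmp, MPFR_RNDN);
        integrand(f, cx, dl, dr, prec);
        mpfr_mul(f, f, wgt, MPFR_RNDN);
        mpfr_add(acc, acc, f, MPFR_RNDN);
    }
    mpfr_clears(mu, y, e2y, dl, dr, wgt, f, tmp, (mpfr_ptr) 0);
}

SEXP C_conv_quad(SEXP st, SEXP sa, SEXP sb, SEXP salpha, SEXP sbeta,
                 SEXP sdigits, SEXP swhich)
{
    double t = REAL(st)[0];
    quad_ctx cx;
    cx.t = t; cx.a = REAL(sa)[0]; cx.b = REAL(sb)[0];
    cx.alpha = REAL(salpha)[0]; cx.beta = REAL(sbeta)[0];
    cx.which = INTEGER(swhich)[0];
    long digits = (long) REAL(sdigits)[0];
    if (t <= cx.beta) {
        SEXP out = PROTECT(allocVector(VECSXP, 2));
        mpfr_t z; mpfr_init2(z, 64); mpfr_set_zero(z, 1);
        SET_VECTOR_ELT(out, 0, gpc_mkstring(z, digits));
        SET_VECTOR_ELT(out, 1, ScalarReal(R_PosInf));
        mpfr_clear(z);
        UNPROTECT(1);
        return out;
    }
    mpfr_prec_t prec = gpc_bits(digits + 15);
    mpfr_init2(cx.ga, prec);
    mpfr_t tmp;
    mpfr_init2(tmp, prec);
    mpfr_set_d(tmp, cx.a, MPFR_RNDN);
    mpfr_gamma(cx.ga, tmp, MPFR_RNDN);

    mpfr_t d, S, Sprev, acc, athr;
    mpfr_inits2(prec, d, S, Sprev, acc, athr, (mpfr_ptr) 0);
    mpfr_set_d(d, t, MPFR_RNDN);
    mpfr_sub_d(d, d, cx.beta, MPFR_RNDN);
    mpfr_div_ui(d, d, 2, MPFR_RNDN);            /* (t - beta)/2, exact inputs */

    const double umax = 6.56;   /* tanh((pi/2) sinh 6.56) saturates far past need */
    double h = 1.0;
    /* level 0: trapezoid at spacing 1 */
    mpfr_set_zero(acc, 1);
    nodes_at(acc, &cx, d, 0.0, prec, 0);
    for (double u = h; u <= umax; u += h)
        nodes_at(acc, &cx, d, u, prec, 1);
    mpfr_mul_d(S, acc, h, MPFR_RNDN);

    double est_digits = 0.0;
    int level;
    for (level = 1; level <= 12; level++) {
        h /= 2.0;
        mpfr_set(Sprev, S, MPFR_RNDN);
        mpfr_set_zero(acc, 1);
        for (double u = h; u <= umax; u += 2.0 * h)
            nodes_at(acc, &cx, d, u, prec, 1);
        mpfr_mul_d(acc, acc, h, MPFR_RNDN);
        mpfr_div_ui(S, Sprev, 2, MPFR_RNDN);
        mpfr_add(S, S, acc, MPFR_RNDN);
        /* relative change */
        mpfr_sub(athr, S, Sprev, MPFR_RNDN);
        if (mpfr_zero_p(athr)) { est_digits = (double) digits + 15; break; }
        mpfr_abs(athr, athr, MPFR_RNDN);
        mpfr_abs(acc, S, MPFR_RNDN);
        mpfr_div(athr, athr, acc, MPFR_RNDN);
        long e;
        double m = fabs(mpfr_get_d_2exp(&e, athr, MPFR_RNDN));
        double relchange = (double) e * 0.30102999566398120 + log10(m);
        est_digits = -relchange;
        /* the d.e. rule roughly squares accuracy per level: stop once the
         * last refinement already met the request */
        if (level >= 3 && est_digits > (double) digits + 2) break;
    }
    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, gpc_mkstring(S, digits));
    SET_VECTOR_ELT(out, 1, ScalarReal(est_digits));
    UNPROTECT(1);
    mpfr_clears(d, S, Sprev, acc, athr, tmp, (mpfr_ptr) 0);
    mpfr_clear(cx.ga);
    return out;
}
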