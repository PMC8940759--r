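/* Short-t branch: the primary alternating series for the GPC density, CDF,
 * super-cumulative and derivative.
 *
 * Pass 1 scans the summand in machine-precision signed-log arithmetic to find
 * the number of terms (stop once past the magnitude peak and below the
 * absolute threshold 10^stop_exp) and the largest term magnitude.  Pass 2
 * recomputes and sums every term at round(log10 max|term|) + target digits.
 * Stored terms include the constant prefactor b^a alpha beta^alpha / Gamma(a)
 * times the power of t, matching the diagnostic conventions used for the
 * reported term magnitudes.
 */
#include "gpconv.h"

/* offsets of the incomplete-beta first argument and the t-power by kind */
static const int koff[4] = { 0, 1, 2, -1 };

/* signed log representation: (sign, log|x|) */
typedef struct { double s; double l; } slog;

static slog slog_add(slog x, slog y)
{
    slog r;
    if (x.l == -HUGE_VAL) return y;
    if (y.l == -HUGE_VAL) return x;
    if (x.l < y.l) { slog t = x; x = y; y = t; }
    double v = x.s + y.s * exp(y.l - x.l);
    if (v == 0.0) { r.s = 0; r.l = -HUGE_VAL; return r; }
    r.s = v > 0 ? 1 : -1;
    r.l = x.l + log(fabs(v));
    return r;
}

/* log|B_z(P, -alpha)| in doubles; z = 1 - beta/t */
static slog scan_logbeta(double z, double P, double alpha)
{
    slog out;
    if (z <= 0.75) {
        /* direct series: B_z(P,Q=-alpha) = z^P sum_k (1+alpha)_k z^k/(k!(P+k)) */
        double s = 0.0, c = 1.0;
        int k;
        for (k = 0; k < 100000; k++) {
            double term = c / (P + k);
            s += term;
            c *= (1.0 + alpha + k) * z / (k + 1);
            if (fabs(c / (P + k + 1)) < 1e-18 * (fabs(s) + 1e-300) && k > 2)
                break;
        }
        out.s = s >= 0 ? 1 : -1;
        out.l = P * log(z) + log(fabs(s));
        return out;
    }
    /* reflection: B(P,-alpha) - B_w(-alpha, P), w = 1-z */
    double w = 1.0 - z;
    int sg_p, sg_pa;
    double lg_p = lgamma_r(P, &sg_p);
    double lg_pa = lgamma_r(P - alpha, &sg_pa);
    /* Gamma(-alpha) = Gamma(1-alpha)/(-alpha): log magnitude, sign negative
     * for alpha in (0,1); in general sign of Gamma(-alpha) */
    int sg_ma;
    double lg_ma = lgamma_r(-alpha, &sg_ma);
    slog complete;
    complete.s = (double) (sg_p * sg_ma * sg_pa);
    complete.l = lg_p + lg_ma - lg_pa;
    /* series piece: w^{-alpha} sum_k (1-P)_k w^k / (k!(k-alpha)) */
    double s = 0.0, c = 1.0;
    int k;
    for (k = 0; k < 100000; k++) {
        s += c / (k - alpha);
        c *= (1.0 - P + k) * w / (k + 1);
        if (fabs(c / (k + 1 - alpha)) < 1e-18 * (fabs(s) + 1e-300) && k > 2)
            break;
    }
    slog piece2;
    if (s == 0.0) { piece2.s = 0; piece2.l = -HUGE_VAL; }
    else {
        piece2.s = s > 0 ? -1 : 1;      /* minus sign of the subtraction */
        piece2.l = -alpha * log(w) + log(fabs(s));
    }
    out = slog_add(complete, piece2);
    return out;
}

int gpc_scan_short(int kind, double t, double a, double b, double alpha,
                   double beta, const gpc_policy *pol,
                   long *n_terms, double *max_log10)
{
    double z = 1.0 - beta / t;
    double lbt = log(b * t);
    int off = koff[kind];
    double pw = a - alpha - 1.0 + off;
    double lpref = a * log(b) + log(alpha) + alpha * log(beta) - lgamma(a)
        + pw * log(t);
    double maxl = -HUGE_VAL;
    long argmax = -1, n;
    int seen = 0;
    const double l10 = log(10.0);

    for (n = 0; n < pol->max_terms; n++) {
        double P = a + n + off;
        double lcoeff = 0.0;
        int degenerate = 0;
        if (kind == GPC_CDF) lcoeff = -log(a + n);
        else if (kind == GPC_SUPER) lcoeff = -log(a + n) - log(1.0 + a + n);
        else if (kind == GPC_DERIV) {
            double cf = a + n - 1.0;
            if (cf == 0.0) degenerate = 1;
            else lcoeff = log(fabs(cf));
        }
        double lT;
        if (degenerate) {
            /* limit of (a+n-1) B_z(a+n-1,-alpha) as the argument -> 0 is z^0 */
            lT = n * lbt - lgamma(n + 1.0) + lpref;
        } else {
            slog lb = scan_logbeta(z, P, alpha);
            if (lb.s == 0) lT = -HUGE_VAL;
            else lT = n * lbt - lgamma(n + 1.0) + lcoeff + lb.l + lpref;
        }
        double lT10 = lT / l10;
        if (lT10 > -HUGE_VAL) {
            if (lT10 > maxl) { maxl = lT10; argmax = n; }
            seen = 1;
        }
        if (seen && n > argmax && lT10 < (double) pol->stop_exp) {
            *n_terms = n + 1;
            *max_log10 = maxl;
            return 0;
        }
    }
    return 1;   /* term cap exceeded */
}

void gpc_eval_short(mpfr_t rop, int kind, double t, double a, double b,
                    double alpha, double beta, const gpc_policy *pol,
                    gpc_diag *diag)
{
    diag->branch = 0;
    if (t <= beta) {
        diag->n_terms = 0;
        diag->has_maxlog = 0;
        diag->max_term_log10 = 0;
        diag->working_digits = pol->target_digits + pol->guard_digits;
        mpfr_set_zero(rop, 1);
        return;
    }
    long N;
    double maxl;
    if (gpc_scan_short(kind, t, a, b, alpha, beta, pol, &N, &maxl))
        error("short-t series exceeded the term cap (%ld terms)", pol->max_terms);

    long wd = pol->target_digits + pol->guard_digits;
    long lift = (long) llround(maxl);
    if (lift > 0 && lift + pol->target_digits > wd)
        wd = lift + pol->target_digits;
    if (wd > 1000000)
        error("working precision guard: %ld digits required (cap 10^6)", wd);
    /* wd is the reported decimal working precision (largest-term exponent
     * plus the target); internally a few guard digits absorb the rounding
     * accumulated over the N summed terms */
    mpfr_prec_t prec = gpc_bits(wd + 8 + (long) ceil(log10((double) N + 1)));

    int off = koff[kind];
    double z = 1.0 - beta / t;
    int use_direct = (z <= 0.75);

    mpfr_t sum, c, term, Bz, mz, mw, mP, mPA, man, mQ, tmp, tmp2;
    mpfr_t gP, gPA, gMA, piece;
    mpfr_inits2(prec, sum, c, term, Bz, mz, mw, mP, mPA, man, mQ, tmp, tmp2,
                gP, gPA, gMA, piece, (mpfr_ptr) 0);

    /* all composites of the inputs are formed at working precision */
    mpfr_set_d(tmp, beta, MPFR_RNDN);
    mpfr_set_d(tmp2, t, MPFR_RNDN);
    mpfr_div(mw, tmp, tmp2, MPFR_RNDN);         /* w = beta/t */
    mpfr_ui_sub(mz, 1, mw, MPFR_RNDN);          /* z = 1 - beta/t */
    mpfr_set_d(mQ, alpha, MPFR_RNDN);
    mpfr_neg(mQ, mQ, MPFR_RNDN);                /* -alpha */
    mpfr_set_d(man, a, MPFR_RNDN);              /* a + n */
    mpfr_add_si(mP, man, off, MPFR_RNDN);       /* P_n = a + n + off */
    mpfr_add(mPA, mP, mQ, MPFR_RNDN);           /* P_n - alpha */

    mpfr_t wQ, zP, Bcur;
    mpfr_inits2(prec, wQ, zP, Bcur, (mpfr_ptr) 0);
    mpfr_pow(wQ, mw, mQ, MPFR_RNDN);            /* (1-z)^{-alpha} */
    if (!use_direct)
        mpfr_gamma(gMA, mQ, MPFR_RNDN);         /* Gamma(-alpha) */

    /* prefactor b^a alpha beta^alpha / Gamma(a) * t^(a-alpha-1+off), folded
     * into the summand so the summed terms carry the magnitudes the scan
     * reported; the t-exponent is formed at working precision */
    mpfr_t pref, mbt;
    mpfr_inits2(prec, pref, mbt, (mpfr_ptr) 0);
    mpfr_set_d(tmp, b, MPFR_RNDN);
    mpfr_set_d(tmp2, a, MPFR_RNDN);
    mpfr_pow(pref, tmp, tmp2, MPFR_RNDN);
    mpfr_mul_d(pref, pref, alpha, MPFR_RNDN);
    mpfr_set_d(tmp, beta, MPFR_RNDN);
    mpfr_set_d(tmp2, alpha, MPFR_RNDN);
    mpfr_pow(tmp, tmp, tmp2, MPFR_RNDN);
    mpfr_mul(pref, pref, tmp, MPFR_RNDN);
    mpfr_set_d(tmp, a, MPFR_RNDN);
    mpfr_gamma(tmp, tmp, MPFR_RNDN);
    mpfr_div(pref, pref, tmp, MPFR_RNDN);
    mpfr_set_d(tmp, a, MPFR_RNDN);
    mpfr_add(tmp2, tmp, mQ, MPFR_RNDN);         /* a - alpha */
    mpfr_add_si(tmp2, tmp2, off - 1, MPFR_RNDN);
    mpfr_set_d(tmp, t, MPFR_RNDN);
    mpfr_pow(tmp, tmp, tmp2, MPFR_RNDN);
    mpfr_mul(pref, pref, tmp, MPFR_RNDN);

    mpfr_set_zero(sum, 1);
    mpfr_set(c, pref, MPFR_RNDN);               /* pref * (-bt)^n / n! */
    mpfr_set_d(tmp, b, MPFR_RNDN);
    mpfr_set_d(tmp2, t, MPFR_RNDN);
    mpfr_mul(mbt, tmp, tmp2, MPFR_RNDN);
    mpfr_neg(mbt, mbt, MPFR_RNDN);              /* -bt */

    /* B_z(P_n, -alpha) advances over n through the integration-by-parts
     * identity B_z(P+1,B) = P/(P+B) B_z(P,B) - z^P (1-z)^B/(P+B), seeded by
     * one full series (or reflection) evaluation; this makes the summation
     * O(1) per term.  The identity is benign here: the multiplier exceeds 1
     * only by alpha/P and the subtracted term is small against B_z. */
    int have_B = 0;
    for (long n = 0; n < N; n++) {
        int degenerate = (kind == GPC_DERIV && a + n - 1.0 == 0.0);
        if (degenerate) {
            /* coeff * B -> z^0 = 1 in the limit; the recurrence cannot
             * cross the P = 0 pole, so it is reseeded afterwards */
            mpfr_set(term, c, MPFR_RNDN);
            have_B = 0;
        } else {
            if (!have_B) {
                /* the reflection route needs Gamma(P - alpha) off its
                 * poles; when a - alpha sits on an integer fall back to
                 * the direct series (term cap guards the z -> 1 cost) */
                double pa = a + n + off - alpha;
                int pa_pole = (pa < 0.5 && fabs(pa - round(pa)) < 1e-6);
                if (use_direct || pa_pole) {
                    beta_inc_series(Bcur, mz, mP, mQ, prec, pol->max_terms);
                } else {
                    /* complete beta Gamma(P)Gamma(-alpha)/Gamma(P-alpha) */
                    mpfr_gamma(gP, mP, MPFR_RNDN);
                    mpfr_gamma(gPA, mPA, MPFR_RNDN);
                    mpfr_mul(Bcur, gP, gMA, MPFR_RNDN);
                    mpfr_div(Bcur, Bcur, gPA, MPFR_RNDN);
                    beta_inc_series_scaled(piece, mw, mQ, mP, wQ, prec,
                                           pol->max_terms);
                    mpfr_sub(Bcur, Bcur, piece, MPFR_RNDN);
                }
                mpfr_pow(zP, mz, mP, MPFR_RNDN);    /* z^{P_n} */
                have_B = 1;
            }
            mpfr_mul(term, c, Bcur, MPFR_RNDN);
            if (kind == GPC_CDF) {
                mpfr_div(term, term, man, MPFR_RNDN);
            } else if (kind == GPC_SUPER) {
                mpfr_div(term, term, man, MPFR_RNDN);
                mpfr_add_ui(tmp, man, 1, MPFR_RNDN);
                mpfr_div(term, term, tmp, MPFR_RNDN);
            } else if (kind == GPC_DERIV) {
                mpfr_mul(term, term, mP, MPFR_RNDN);    /* P = a+n-1 */
            }
        }
        mpfr_add(sum, sum, term, MPFR_RNDN);
        /* advance: c, the ibp recurrence for B, and the counters */
        mpfr_mul(c, c, mbt, MPFR_RNDN);
        mpfr_div_si(c, c, n + 1, MPFR_RNDN);
        if (have_B && n + 1 < N) {
            /* B_z(P+1,-alpha) = [P B_z(P,-alpha) - z^P w^{-alpha}] / (P-alpha);
             * the identity degenerates when P - alpha ~ 0, in which case the
             * next term is reseeded by a full evaluation instead */
            if (fabs(a + n + off - alpha) < 1e-6) {
                have_B = 0;
            } else {
                mpfr_mul(Bcur, Bcur, mP, MPFR_RNDN);
                mpfr_mul(tmp, zP, wQ, MPFR_RNDN);
                mpfr_sub(Bcur, Bcur, tmp, MPFR_RNDN);
                mpfr_div(Bcur, Bcur, mPA, MPFR_RNDN);
                mpfr_mul(zP, zP, mz, MPFR_RNDN);
            }
        }
        mpfr_add_ui(man, man, 1, MPFR_RNDN);
        mpfr_add_ui(mP, mP, 1, MPFR_RNDN);
        mpfr_add_ui(mPA, mPA, 1, MPFR_RNDN);
    }

    mpfr_set(rop, sum, MPFR_RNDN);

    diag->n_terms = N;
    diag->has_maxlog = 1;
    diag->max_term_log10 = (long) llround(maxl);
    diag->working_digits = wd;

    mpfr_clears(sum, c, term, Bz, mz, mw, mP, mPA, man, mQ, tmp, tmp2,
                gP, gPA, gMA, piece, (mpfr_ptr) 0);
    mpfr_clears(mbt, pref, wQ, zP, Bcur, (mpfr_ptr) 0);
}
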