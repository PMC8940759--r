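/* Arbitrary-precision special-function building blocks:
 * incomplete beta (negative second parameter allowed), Kummer 1F1 and its
 * regularised form, regularised incomplete gamma Q/P, Pochhammer.
 *
 * Everything is a plain power series with explicit stopping rules; MPFR only
 * supplies arithmetic, Gamma, exp/log and trigonometry.
 */
#include "gpconv.h"

/* B_w(P,Q) = w^P * sum_k (1-Q)_k w^k / (k! (P+k)),  0 < w < 1.
 * Valid for any real P not a nonpositive integer.  Relative stopping rule.
 * beta_inc_series_scaled takes a precomputed w^P factor (hoisted out of the
 * short-t reflection loop, where P stays fixed while Q advances). */
void beta_inc_series_scaled(mpfr_t rop, const mpfr_t w, const mpfr_t P,
                            const mpfr_t Q, const mpfr_t wP,
                            mpfr_prec_t prec, long max_terms)
{
    mpfr_t s, c, term, den, eps, as, at;
    long k;
    mpfr_inits2(prec, s, c, term, den, eps, as, at, (mpfr_ptr) 0);
    mpfr_set_zero(s, 1);
    mpfr_set_ui(c, 1, MPFR_RNDN);               /* c = (1-Q)_k w^k / k! */
    mpfr_set_ui_2exp(eps, 1, -(mpfr_exp_t) prec - 8, MPFR_RNDN);
    for (k = 0; ; k++) {
        mpfr_add_si(den, P, k, MPFR_RNDN);      /* P + k */
        mpfr_div(term, c, den, MPFR_RNDN);
        mpfr_add(s, s, term, MPFR_RNDN);
        /* c <- c * (1-Q+k) * w / (k+1) */
        mpfr_ui_sub(den, 1, Q, MPFR_RNDN);
        mpfr_add_si(den, den, k, MPFR_RNDN);
        mpfr_mul(c, c, den, MPFR_RNDN);
        mpfr_mul(c, c, w, MPFR_RNDN);
        mpfr_div_si(c, c, k + 1, MPFR_RNDN);
        mpfr_abs(at, term, MPFR_RNDN);
        mpfr_abs(as, s, MPFR_RNDN);
        mpfr_mul(as, as, eps, MPFR_RNDN);
        if (k > 1 && mpfr_cmp(at, as) < 0) break;
        if (k >= max_terms)
            error("incomplete beta series did not converge within %ld terms",
                  max_terms);
    }
    mpfr_mul(rop, s, wP, MPFR_RNDN);
    mpfr_clears(s, c, term, den, eps, as, at, (mpfr_ptr) 0);
}

void beta_inc_series(mpfr_t rop, const mpfr_t w, const mpfr_t P, const mpfr_t Q,
                     mpfr_prec_t prec, long max_terms)
{
    mpfr_t wP;
    mpfr_init2(wP, prec);
    mpfr_pow(wP, w, P, MPFR_RNDN);
    beta_inc_series_scaled(rop, w, P, Q, wP, prec, max_terms);
    mpfr_clear(wP);
}

static int near_nonpos_int(const mpfr_t x, double tol)
{
    double v = mpfr_get_d(x, MPFR_RNDN);
    return v < 0.5 && fabs(v - round(v)) < tol;
}

/* complete beta B(A,B) = Gamma(A)Gamma(B)/Gamma(A+B) */
static void beta_complete(mpfr_t rop, const mpfr_t A, const mpfr_t B,
                          mpfr_prec_t prec)
{
    mpfr_t ga, gb, gab;
    mpfr_inits2(prec, ga, gb, gab, (mpfr_ptr) 0);
    mpfr_gamma(ga, A, MPFR_RNDN);
    mpfr_gamma(gb, B, MPFR_RNDN);
    mpfr_add(gab, A, B, MPFR_RNDN);
    mpfr_gamma(gab, gab, MPFR_RNDN);
    mpfr_mul(rop, ga, gb, MPFR_RNDN);
    mpfr_div(rop, rop, gab, MPFR_RNDN);
    mpfr_clears(ga, gb, gab, (mpfr_ptr) 0);
}

/* B_z(A,B); route 0 = auto (series for z<=0.75, reflection otherwise),
 * 1 = force direct series, 2 = force reflection */
void beta_inc_core(mpfr_t rop, const mpfr_t z, const mpfr_t A, const mpfr_t B,
                   mpfr_prec_t prec, long max_terms, int route)
{
    if (mpfr_zero_p(z)) { mpfr_set_zero(rop, 1); return; }
    if (near_nonpos_int(A, 1e-12))
        error("incomplete beta pole: first parameter is a nonpositive integer");
    if (mpfr_cmp_ui(z, 1) == 0) {
        if (near_nonpos_int(B, 1e-8))
            error("incomplete beta pole: complete beta with nonpositive-integer second parameter");
        if (mpfr_sgn(B) <= 0 && !near_nonpos_int(B, 1e-8)) {
            /* B negative non-integer: B_1(A,B) = Gamma(A)Gamma(B)/Gamma(A+B) */
        } else if (mpfr_sgn(B) <= 0) {
            error("incomplete beta pole at z = 1");
        }
        beta_complete(rop, A, B, prec);
        return;
    }
    int use_series = (route == 1) ||
        (route == 0 && mpfr_cmp_d(z, 0.75) <= 0);
    if (use_series) {
        beta_inc_series(rop, z, A, B, prec, max_terms);
    } else {
        if (near_nonpos_int(B, 1e-8))
            error("reflection route needs non-integer second parameter");
        mpfr_t comp, w, tail;
        mpfr_inits2(prec, comp, w, tail, (mpfr_ptr) 0);
        beta_complete(comp, A, B, prec);
        mpfr_ui_sub(w, 1, z, MPFR_RNDN);
        beta_inc_series(tail, w, B, A, prec, max_terms);
        mpfr_sub(rop, comp, tail, MPFR_RNDN);
        mpfr_clears(comp, w, tail, (mpfr_ptr) 0);
    }
}

/* 1F1(A,B;x) (regularized: /Gamma(B)) summed directly; intended for x >= 0
 * where the tail is single-signed, or as the brute-force oracle route at
 * elevated precision for x < 0.  Handles B at nonpositive integers in the
 * regularized case by starting past the Gamma poles.  The binary exponent
 * of the largest summed term is left in hyp1f1_last_max_exp so callers can
 * estimate the cancellation they just paid. */
static mpfr_exp_t hyp1f1_last_max_exp = 0;

void hyp1f1_possum(mpfr_t rop, const mpfr_t A, const mpfr_t B, const mpfr_t x,
                   mpfr_prec_t prec, long max_terms, int regularized)
{
    mpfr_t s, c, den, eps, smax, at;
    long j, jstart = 0;
    mpfr_inits2(prec, s, c, den, eps, smax, at, (mpfr_ptr) 0);

    double bd = mpfr_get_d(B, MPFR_RNDN);
    if (regularized && bd < 0.5 && fabs(bd - round(bd)) < 1e-12)
        jstart = (long) (-round(bd)) + 1;   /* 1/Gamma(B+j) = 0 for j <= -B */
    else if (!regularized && bd < 0.5 && fabs(bd - round(bd)) < 1e-12)
        error("1F1 pole: second parameter is a nonpositive integer");

    /* c_j = (A)_j x^j / j! [/ Gamma(B+jstart) folded below]; start at jstart */
    mpfr_set_ui(c, 1, MPFR_RNDN);
    for (j = 0; j < jstart; j++) {          /* build (A)_jstart x^jstart/jstart! */
        mpfr_add_si(den, A, j, MPFR_RNDN);
        mpfr_mul(c, c, den, MPFR_RNDN);
        mpfr_mul(c, c, x, MPFR_RNDN);
        mpfr_div_si(c, c, j + 1, MPFR_RNDN);
    }
    mpfr_set_zero(s, 1);
    mpfr_set_zero(smax, 1);
    mpfr_set_ui_2exp(eps, 1, -(mpfr_exp_t) prec - 8, MPFR_RNDN);

    mpfr_t invg, bj, term;
    mpfr_inits2(prec, invg, bj, term, (mpfr_ptr) 0);
    if (regularized) {
        mpfr_add_si(bj, B, jstart, MPFR_RNDN);
        mpfr_gamma(invg, bj, MPFR_RNDN);
        mpfr_ui_div(invg, 1, invg, MPFR_RNDN);   /* 1/Gamma(B+jstart) */
    } else {
        mpfr_set_ui(invg, 1, MPFR_RNDN);
    }
    for (j = jstart; ; j++) {
        mpfr_mul(term, c, invg, MPFR_RNDN);
        mpfr_add(s, s, term, MPFR_RNDN);
        mpfr_abs(at, term, MPFR_RNDN);
        if (mpfr_cmp(at, smax) > 0) mpfr_set(smax, at, MPFR_RNDN);
        /* stop when |term| < eps * max(|s|, smax) and past j ~ |x| */
        mpfr_abs(den, s, MPFR_RNDN);
        if (mpfr_cmp(den, smax) < 0) mpfr_set(den, smax, MPFR_RNDN);
        mpfr_mul(den, den, eps, MPFR_RNDN);
        double xd = fabs(mpfr_get_d(x, MPFR_RNDN));
        if (j > 2 + (long) xd && mpfr_cmp(at, den) < 0) break;
        if (j - jstart >= max_terms)
            error("1F1 series did not converge within %ld terms", max_terms);
        /* c <- c * (A+j) x / (j+1); invg <- invg / (B+j) (regularized)
         * or fold (B+j) into c denominator (plain) */
        mpfr_add_si(den, A, j, MPFR_RNDN);
        mpfr_mul(c, c, den, MPFR_RNDN);
        mpfr_mul(c, c, x, MPFR_RNDN);
        mpfr_div_si(c, c, j + 1, MPFR_RNDN);
        mpfr_add_si(bj, B, j, MPFR_RNDN);
        if (regularized) mpfr_div(invg, invg, bj, MPFR_RNDN);
        else             mpfr_div(c, c, bj, MPFR_RNDN);
    }
    hyp1f1_last_max_exp = mpfr_zero_p(smax) ? 0 : mpfr_get_exp(smax);
    mpfr_set(rop, s, MPFR_RNDN);
    mpfr_clears(s, c, den, eps, smax, at, invg, bj, term, (mpfr_ptr) 0);
}

/* terminating Kummer route: 1F1(A,B;x) with B-A = -k (k >= 0 integer), x<0:
 * 1F1(A,B;x) = e^x 1F1(-k, B; -x), a (k+1)-term polynomial */
void hyp1f1_terminating(mpfr_t rop, const mpfr_t A, const mpfr_t B,
                        const mpfr_t x, long k, mpfr_prec_t prec)
{
    mpfr_t s, c, mx, den;
    long j;
    (void) A;
    mpfr_inits2(prec, s, c, mx, den, (mpfr_ptr) 0);
    mpfr_neg(mx, x, MPFR_RNDN);                 /* -x > 0 */
    mpfr_set_zero(s, 1);
    mpfr_set_ui(c, 1, MPFR_RNDN);
    for (j = 0; j <= k; j++) {
        mpfr_add(s, s, c, MPFR_RNDN);
        if (j == k) break;
        /* c <- c * (-k+j)(-x) / ((B+j)(j+1)) */
        mpfr_mul_si(c, c, j - k, MPFR_RNDN);
        mpfr_mul(c, c, mx, MPFR_RNDN);
        mpfr_add_si(den, B, j, MPFR_RNDN);
        mpfr_div(c, c, den, MPFR_RNDN);
        mpfr_div_si(c, c, j + 1, MPFR_RNDN);
    }
    mpfr_exp(c, x, MPFR_RNDN);
    mpfr_mul(rop, s, c, MPFR_RNDN);
    mpfr_clears(s, c, mx, den, (mpfr_ptr) 0);
}

/* general 1F1 dispatcher.  For x < 0: terminating Kummer when B-A is a
 * nonpositive integer, else Kummer transform to the positive-argument
 * single-signed series.  force_direct = brute-force direct series at x<0
 * with precision elevated by |x| log10 e digits (test oracle route). */
void hyp1f1_core(mpfr_t rop, const mpfr_t A, const mpfr_t B, const mpfr_t x,
                 mpfr_prec_t prec, long max_terms, int regularized,
                 int force_direct)
{
    if (mpfr_zero_p(x)) {
        if (regularized) {
            mpfr_t g; mpfr_init2(g, prec);
            mpfr_gamma(g, B, MPFR_RNDN);
            mpfr_ui_div(rop, 1, g, MPFR_RNDN);
            mpfr_clear(g);
        } else
            mpfr_set_ui(rop, 1, MPFR_RNDN);
        return;
    }
    if (force_direct || mpfr_sgn(x) > 0) {
        /* the alternating series cancels by max-term/result, which can
         * exceed e^{|x|} when the value itself is exponentially small;
         * re-elevate until enough digits survive the cancellation */
        mpfr_prec_t p2 = prec;
        if (mpfr_sgn(x) < 0) {
            double xd = fabs(mpfr_get_d(x, MPFR_RNDN));
            p2 = prec + (mpfr_prec_t) (xd * 1.4427) + 32;
        }
        for (int attempt = 0; ; attempt++) {
            mpfr_t A2, B2, x2, r2;
            mpfr_inits2(p2, A2, B2, x2, r2, (mpfr_ptr) 0);
            mpfr_set(A2, A, MPFR_RNDN);
            mpfr_set(B2, B, MPFR_RNDN);
            mpfr_set(x2, x, MPFR_RNDN);
            hyp1f1_possum(r2, A2, B2, x2, p2, max_terms, regularized);
            /* cancellation in bits: exponent of max term minus result */
            long cancel = 0;
            if (!mpfr_zero_p(r2)) {
                mpfr_exp_t er = mpfr_get_exp(r2);
                mpfr_exp_t em = hyp1f1_last_max_exp;
                if (em > er) cancel = (long) (em - er);
            }
            if (mpfr_zero_p(r2) ||
                (long) p2 - cancel >= (long) prec + 8 || attempt >= 3) {
                mpfr_set(rop, r2, MPFR_RNDN);
                mpfr_clears(A2, B2, x2, r2, (mpfr_ptr) 0);
                return;
            }
            p2 = prec + (mpfr_prec_t) cancel + 32;
            mpfr_clears(A2, B2, x2, r2, (mpfr_ptr) 0);
        }
    }
    /* x < 0 */
    mpfr_t d;
    mpfr_init2(d, prec);
    mpfr_sub(d, B, A, MPFR_RNDN);
    double dd = mpfr_get_d(d, MPFR_RNDN);
    if (dd < 0.5 && fabs(dd - round(dd)) < 1e-12 && !regularized) {
        long k = (long) (-round(dd));
        hyp1f1_terminating(rop, A, B, x, k, prec);
    } else {
        /* Kummer transform: 1F1(A,B;x) = e^x 1F1(B-A,B;-x) (also regularized) */
        mpfr_t mx, r, ex;
        mpfr_inits2(prec, mx, r, ex, (mpfr_ptr) 0);
        mpfr_neg(mx, x, MPFR_RNDN);
        hyp1f1_possum(r, d, B, mx, prec, max_terms, regularized);
        mpfr_exp(ex, x, MPFR_RNDN);
        mpfr_mul(rop, r, ex, MPFR_RNDN);
        mpfr_clears(mx, r, ex, (mpfr_ptr) 0);
    }
    mpfr_clear(d);
}

/* lower regularized incomplete gamma P(a,x) by power series (x < a+1) */
static void gammaP_series(mpfr_t rop, const mpfr_t a, const mpfr_t x,
                          mpfr_prec_t prec)
{
    mpfr_t s, c, den, eps, at, as;
    long n;
    mpfr_inits2(prec, s, c, den, eps, at, as, (mpfr_ptr) 0);
    /* sum_n x^n / (a(a+1)...(a+n)), times x^a e^{-x} / Gamma(a) */
    mpfr_ui_div(c, 1, a, MPFR_RNDN);
    mpfr_set(s, c, MPFR_RNDN);
    mpfr_set_ui_2exp(eps, 1, -(mpfr_exp_t) prec - 8, MPFR_RNDN);
    for (n = 1; ; n++) {
        mpfr_add_si(den, a, n, MPFR_RNDN);
        mpfr_mul(c, c, x, MPFR_RNDN);
        mpfr_div(c, c, den, MPFR_RNDN);
        mpfr_add(s, s, c, MPFR_RNDN);
        mpfr_abs(at, c, MPFR_RNDN);
        mpfr_abs(as, s, MPFR_RNDN);
        mpfr_mul(as, as, eps, MPFR_RNDN);
        if (mpfr_cmp(at, as) < 0) break;
        if (n > 1000000) error("P(a,x) series did not converge");
    }
    /* x^a e^{-x} / Gamma(a) */
    mpfr_t f, g;
    mpfr_inits2(prec, f, g, (mpfr_ptr) 0);
    mpfr_pow(f, x, a, MPFR_RNDN);
    mpfr_neg(g, x, MPFR_RNDN);
    mpfr_exp(g, g, MPFR_RNDN);
    mpfr_mul(f, f, g, MPFR_RNDN);
    mpfr_gamma(g, a, MPFR_RNDN);
    mpfr_div(f, f, g, MPFR_RNDN);
    mpfr_mul(rop, s, f, MPFR_RNDN);
    mpfr_clears(s, c, den, eps, at, as, f, g, (mpfr_ptr) 0);
}

/* upper regularized Q(a,x) by modified Lentz continued fraction (x >= a+1) */
static void gammaQ_cf(mpfr_t rop, const mpfr_t a, const mpfr_t x,
                      mpfr_prec_t prec)
{
    mpfr_t tiny, f, C, D, delta, an, bn, eps, tmp;
    long i;
    mpfr_inits2(prec, tiny, f, C, D, delta, an, bn, eps, tmp, (mpfr_ptr) 0);
    mpfr_set_ui_2exp(tiny, 1, -(mpfr_exp_t) prec - 60, MPFR_RNDN);
    mpfr_set_ui_2exp(eps, 1, -(mpfr_exp_t) prec - 4, MPFR_RNDN);
    /* CF: Q = x^a e^-x/Gamma(a) * 1/(x+1-a- 1(1-a)/(x+3-a- 2(2-a)/(x+5-a-...))) */
    mpfr_sub(bn, x, a, MPFR_RNDN);
    mpfr_add_ui(bn, bn, 1, MPFR_RNDN);          /* b0 = x+1-a */
    mpfr_set(f, bn, MPFR_RNDN);
    if (mpfr_zero_p(f)) mpfr_set(f, tiny, MPFR_RNDN);
    mpfr_set(C, f, MPFR_RNDN);
    mpfr_set_zero(D, 1);
    for (i = 1; i <= 1000000; i++) {
        /* a_i = -i (i - a); b_i = b_{i-1} + 2 */
        mpfr_sub_si(an, a, i, MPFR_RNDN);
        mpfr_mul_si(an, an, i, MPFR_RNDN);      /* i (a - i) = -i(i-a) */
        mpfr_add_ui(bn, bn, 2, MPFR_RNDN);
        /* D = 1/(b + a_i D); C = b + a_i / C */
        mpfr_mul(tmp, an, D, MPFR_RNDN);
        mpfr_add(tmp, tmp, bn, MPFR_RNDN);
        if (mpfr_zero_p(tmp)) mpfr_set(tmp, tiny, MPFR_RNDN);
        mpfr_ui_div(D, 1, tmp, MPFR_RNDN);
        mpfr_div(tmp, an, C, MPFR_RNDN);
        mpfr_add(C, bn, tmp, MPFR_RNDN);
        if (mpfr_zero_p(C)) mpfr_set(C, tiny, MPFR_RNDN);
        mpfr_mul(delta, C, D, MPFR_RNDN);
        mpfr_mul(f, f, delta, MPFR_RNDN);
        mpfr_sub_ui(delta, delta, 1, MPFR_RNDN);
        mpfr_abs(delta, delta, MPFR_RNDN);
        if (mpfr_cmp(delta, eps) < 0) break;
    }
    if (i > 1000000) error("Q(a,x) continued fraction did not converge");
    mpfr_t pre, g;
    mpfr_inits2(prec, pre, g, (mpfr_ptr) 0);
    mpfr_pow(pre, x, a, MPFR_RNDN);
    mpfr_neg(g, x, MPFR_RNDN);
    mpfr_exp(g, g, MPFR_RNDN);
    mpfr_mul(pre, pre, g, MPFR_RNDN);
    mpfr_gamma(g, a, MPFR_RNDN);
    mpfr_div(pre, pre, g, MPFR_RNDN);
    mpfr_div(rop, pre, f, MPFR_RNDN);
    mpfr_clears(tiny, f, C, D, delta, an, bn, eps, tmp, pre, g, (mpfr_ptr) 0);
}

void gamma_regQ(mpfr_t rop, const mpfr_t a, const mpfr_t x, mpfr_prec_t prec)
{
    if (mpfr_zero_p(x)) { mpfr_set_ui(rop, 1, MPFR_RNDN); return; }
    mpfr_t ap1;
    mpfr_init2(ap1, prec);
    mpfr_add_ui(ap1, a, 1, MPFR_RNDN);
    if (mpfr_cmp(x, ap1) < 0) {
        gammaP_series(rop, a, x, prec);
        mpfr_ui_sub(rop, 1, rop, MPFR_RNDN);
    } else {
        gammaQ_cf(rop, a, x, prec);
    }
    mpfr_clear(ap1);
}

void gamma_regP(mpfr_t rop, const mpfr_t a, const mpfr_t x, mpfr_prec_t prec)
{
    if (mpfr_zero_p(x)) { mpfr_set_zero(rop, 1); return; }
    mpfr_t ap1;
    mpfr_init2(ap1, prec);
    mpfr_add_ui(ap1, a, 1, MPFR_RNDN);
    if (mpfr_cmp(x, ap1) < 0) {
        gammaP_series(rop, a, x, prec);
    } else {
        gammaQ_cf(rop, a, x, prec);
        mpfr_ui_sub(rop, 1, rop, MPFR_RNDN);
    }
    mpfr_clear(ap1);
}

/* ---------------- .Call wrappers ---------------- */

static double dbl_arg(SEXP s) { return REAL(s)[0]; }

SEXP C_beta_inc(SEXP sz, SEXP sA, SEXP sB, SEXP spolicy, SEXP sroute)
{
    gpc_policy pol;
    gpc_read_policy(spolicy, &pol);
    mpfr_prec_t prec = gpc_bits(pol.target_digits + pol.guard_digits);
    mpfr_t z, A, B, r;
    mpfr_inits2(prec, z, A, B, r, (mpfr_ptr) 0);
    mpfr_set_d(z, dbl_arg(sz), MPFR_RNDN);
    mpfr_set_d(A, dbl_arg(sA), MPFR_RNDN);
    mpfr_set_d(B, dbl_arg(sB), MPFR_RNDN);
    beta_inc_core(r, z, A, B, prec, pol.max_terms, INTEGER(sroute)[0]);
    SEXP out = gpc_mkstring(r, pol.target_digits);
    mpfr_clears(z, A, B, r, (mpfr_ptr) 0);
    return out;
}

/* integration-by-parts reduction: B_z(A+1,B) =
 *   A/(A+B) B_z(A,B) - z^A (1-z)^B / (A+B)  */
SEXP C_beta_ibp(SEXP sz, SEXP sA, SEXP sB, SEXP spolicy)
{
    gpc_policy pol;
    gpc_read_policy(spolicy, &pol);
    mpfr_prec_t prec = gpc_bits(pol.target_digits + pol.guard_digits);
    mpfr_t z, A, B, r, apb, t1, t2;
    mpfr_inits2(prec, z, A, B, r, apb, t1, t2, (mpfr_ptr) 0);
    mpfr_set_d(z, dbl_arg(sz), MPFR_RNDN);
    mpfr_set_d(A, dbl_arg(sA), MPFR_RNDN);
    mpfr_set_d(B, dbl_arg(sB), MPFR_RNDN);
    mpfr_add(apb, A, B, MPFR_RNDN);
    if (fabs(mpfr_get_d(apb, MPFR_RNDN)) < 1e-12) {
        mpfr_clears(z, A, B, r, apb, t1, t2, (mpfr_ptr) 0);
        error("A + B is (near) zero: identity undefined");
    }
    beta_inc_core(r, z, A, B, prec, pol.max_terms, 0);
    mpfr_mul(r, r, A, MPFR_RNDN);
    mpfr_div(r, r, apb, MPFR_RNDN);
    mpfr_pow(t1, z, A, MPFR_RNDN);
    mpfr_ui_sub(t2, 1, z, MPFR_RNDN);
    mpfr_pow(t2, t2, B, MPFR_RNDN);
    mpfr_mul(t1, t1, t2, MPFR_RNDN);
    mpfr_div(t1, t1, apb, MPFR_RNDN);
    mpfr_sub(r, r, t1, MPFR_RNDN);
    SEXP out = gpc_mkstring(r, pol.target_digits);
    mpfr_clears(z, A, B, r, apb, t1, t2, (mpfr_ptr) 0);
    return out;
}

SEXP C_hyp1f1(SEXP sA, SEXP sB, SEXP sx, SEXP spolicy, SEXP sreg, SEXP sdirect)
{
    gpc_policy pol;
    gpc_read_policy(spolicy, &pol);
    mpfr_prec_t prec = gpc_bits(pol.target_digits + pol.guard_digits);
    mpfr_t A, B, x, r;
    mpfr_inits2(prec, A, B, x, r, (mpfr_ptr) 0);
    mpfr_set_d(A, dbl_arg(sA), MPFR_RNDN);
    mpfr_set_d(B, dbl_arg(sB), MPFR_RNDN);
    mpfr_set_d(x, dbl_arg(sx), MPFR_RNDN);
    hyp1f1_core(r, A, B, x, prec, pol.max_terms,
                INTEGER(sreg)[0], INTEGER(sdirect)[0]);
    SEXP out = gpc_mkstring(r, pol.target_digits);
    mpfr_clears(A, B, x, r, (mpfr_ptr) 0);
    return out;
}

SEXP C_gamma_regQ(SEXP sa, SEXP sx, SEXP spolicy)
{
    gpc_policy pol;
    gpc_read_policy(spolicy, &pol);
    mpfr_prec_t prec = gpc_bits(pol.target_digits + pol.guard_digits);
    mpfr_t a, x, r;
    mpfr_inits2(prec, a, x, r, (mpfr_ptr) 0);
    mpfr_set_d(a, dbl_arg(sa), MPFR_RNDN);
    mpfr_set_d(x, dbl_arg(sx), MPFR_RNDN);
    gamma_regQ(r, a, x, prec);
    SEXP out = gpc_mkstring(r, pol.target_digits);
    mpfr_clears(a, x, r, (mpfr_ptr) 0);
    return out;
}

SEXP C_pochhammer(SEXP sx, SEXP sk, SEXP sdigits)
{
    long digits = (long) REAL(sdigits)[0];
    long k = (long) REAL(sk)[0], i;
    mpfr_prec_t prec = gpc_bits(digits + 10);
    mpfr_t r, f;
    mpfr_inits2(prec, r, f, (mpfr_ptr) 0);
    mpfr_set_ui(r, 1, MPFR_RNDN);
    for (i = 0; i < k; i++) {
        mpfr_set_d(f, REAL(sx)[0], MPFR_RNDN);
        mpfr_add_si(f, f, i, MPFR_RNDN);
        mpfr_mul(r, r, f, MPFR_RNDN);
    }
    SEXP out = gpc_mkstring(r, digits);
    mpfr_clears(r, f, (mpfr_ptr) 0);
    return out;
}
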