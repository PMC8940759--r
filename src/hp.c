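/* high-precision value plumbing: digits<->bits, decimal-string I/O,
 * digit-agreement metric and elementary arithmetic on decimal strings */
#include "gpconv.h"

mpfr_prec_t gpc_bits(long digits)
{
    double b = (double) digits * 3.3219280948873626 + 24.0;
    if (b < 64.0) b = 64.0;
    return (mpfr_prec_t) b;
}

/* format as d.ddd...e±xx with `digits` significant digits */
SEXP gpc_mkstring(mpfr_t x, long digits)
{
    char *buf = NULL;
    SEXP out;
    if (digits < 2) digits = 2;
    if (mpfr_asprintf(&buf, "%.*Re", (int)(digits - 1), x) < 0)
        error("mpfr formatting failed");
    out = mkString(buf);
    mpfr_free_str(buf);
    return out;
}

void gpc_read_policy(SEXP spolicy, gpc_policy *p)
{
    p->target_digits = (long) REAL(VECTOR_ELT(spolicy, 0))[0];
    p->guard_digits  = (long) REAL(VECTOR_ELT(spolicy, 1))[0];
    p->stop_exp      = (long) REAL(VECTOR_ELT(spolicy, 2))[0];
    p->max_terms     = (long) REAL(VECTOR_ELT(spolicy, 3))[0];
}

static void set_from_string(mpfr_t x, const char *s)
{
    if (mpfr_set_str(x, s, 10, MPFR_RNDN) != 0 && mpfr_nan_p(x))
        error("cannot parse '%s' as a high-precision number", s);
}

/* number of matching leading significant digits = floor(-log10 relative diff);
 * Inf (encoded as R_PosInf) when identical at parse precision */
SEXP C_hp_digits_agree(SEXP sx, SEXP sy)
{
    R_xlen_t n = XLENGTH(sx), i;
    SEXP out = PROTECT(allocVector(REALSXP, n));
    for (i = 0; i < n; i++) {
        const char *xs = CHAR(STRING_ELT(sx, i));
        const char *ys = CHAR(STRING_ELT(sy, i));
        size_t len = strlen(xs) + strlen(ys);
        mpfr_prec_t prec = gpc_bits((long)len + 32);
        mpfr_t x, y, d;
        mpfr_inits2(prec, x, y, d, (mpfr_ptr) 0);
        set_from_string(x, xs);
        set_from_string(y, ys);
        mpfr_sub(d, x, y, MPFR_RNDN);
        if (mpfr_zero_p(d)) {
            REAL(out)[i] = R_PosInf;
        } else if (mpfr_zero_p(x) || mpfr_zero_p(y)) {
            REAL(out)[i] = 0.0;
        } else {
            mpfr_t ax;
            mpfr_init2(ax, prec);
            mpfr_abs(ax, x, MPFR_RNDN);
            mpfr_abs(d, d, MPFR_RNDN);
            mpfr_div(d, d, ax, MPFR_RNDN);
            mpfr_log10(d, d, MPFR_RNDN);
            REAL(out)[i] = floor(-mpfr_get_d(d, MPFR_RNDN));
            mpfr_clear(ax);
        }
        mpfr_clears(x, y, d, (mpfr_ptr) 0);
    }
    UNPROTECT(1);
    return out;
}

/* elementwise arithmetic on decimal strings; op: 1 add 2 sub 3 mul 4 div */
SEXP C_hp_arith(SEXP sop, SEXP sx, SEXP sy, SEXP sdigits)
{
    int op = INTEGER(sop)[0];
    long digits = (long) REAL(sdigits)[0];
    R_xlen_t nx = XLENGTH(sx), ny = XLENGTH(sy);
    R_xlen_t n = nx > ny ? nx : ny, i;
    mpfr_prec_t prec = gpc_bits(digits + 10);
    SEXP out = PROTECT(allocVector(STRSXP, n));
    mpfr_t x, y, r;
    mpfr_inits2(prec, x, y, r, (mpfr_ptr) 0);
    for (i = 0; i < n; i++) {
        set_from_string(x, CHAR(STRING_ELT(sx, i % nx)));
        set_from_string(y, CHAR(STRING_ELT(sy, i % ny)));
        switch (op) {
        case 1: mpfr_add(r, x, y, MPFR_RNDN); break;
        case 2: mpfr_sub(r, x, y, MPFR_RNDN); break;
        case 3: mpfr_mul(r, x, y, MPFR_RNDN); break;
        case 4: mpfr_div(r, x, y, MPFR_RNDN); break;
        default: error("unknown op");
        }
        SET_STRING_ELT(out, i, STRING_ELT(gpc_mkstring(r, digits), 0));
    }
    mpfr_clears(x, y, r, (mpfr_ptr) 0);
    UNPROTECT(1);
    return out;
}

/* sum of a character vector of decimal strings at `digits` working digits */
SEXP C_hp_sum(SEXP sx, SEXP sdigits)
{
    long digits = (long) REAL(sdigits)[0];
    mpfr_prec_t prec = gpc_bits(digits + 10);
    R_xlen_t n = XLENGTH(sx), i;
    mpfr_t s, x;
    mpfr_inits2(prec, s, x, (mpfr_ptr) 0);
    mpfr_set_zero(s, 1);
    for (i = 0; i < n; i++) {
        set_from_string(x, CHAR(STRING_ELT(sx, i)));
        mpfr_add(s, s, x, MPFR_RNDN);
    }
    SEXP out = gpc_mkstring(s, digits);
    mpfr_clears(s, x, (mpfr_ptr) 0);
    return out;
}
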