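#include "gpconv.h"
#include <R_ext/Rdynload.h>

/* ---- engine wrappers ---- */

SEXP C_gpc_eval(SEXP skind, SEXP st, SEXP sa, SEXP sb, SEXP salpha,
                SEXP sbeta, SEXP spolicy, SEXP sbranch)
{
    gpc_policy pol;
    gpc_read_policy(spolicy, &pol);
    int kind = INTEGER(skind)[0];
    int branch = INTEGER(sbranch)[0];   /* 1 short, 2 long */
    double t = REAL(st)[0], a = REAL(sa)[0], b = REAL(sb)[0];
    double alpha = REAL(salpha)[0], beta = REAL(sbeta)[0];
    gpc_diag diag;
    /* the engines work internally at whatever precision the two-pass or
     * adaptive schemes require; the result needs only target+guard digits */
    mpfr_t r;
    mpfr_init2(r, gpc_bits(pol.target_digits + pol.guard_digits));
    if (branch == 2 && t > beta)
        gpc_eval_long(r, kind, t, a, b, alpha, beta, &pol, &diag);
    else
        gpc_eval_short(r, kind, t, a, b, alpha, beta, &pol, &diag);
    const char *nm[] = { "value", "branch", "n_terms", "max_term_log10",
                         "working_digits", "" };
    SEXP out = PROTECT(Rf_mkNamed(VECSXP, nm));
    SET_VECTOR_ELT(out, 0, gpc_mkstring(r, pol.target_digits));
    SET_VECTOR_ELT(out, 1, mkString(diag.branch == 0 ? "short" : "long"));
    SET_VECTOR_ELT(out, 2, ScalarReal((double) diag.n_terms));
    SET_VECTOR_ELT(out, 3, diag.has_maxlog
                   ? ScalarReal((double) diag.max_term_log10)
                   : ScalarReal(NA_REAL));
    SET_VECTOR_ELT(out, 4, ScalarReal((double) diag.working_digits));
    UNPROTECT(1);
    mpfr_clear(r);
    return out;
}

SEXP C_gpc_scan_short(SEXP skind, SEXP st, SEXP sa, SEXP sb, SEXP salpha,
                      SEXP sbeta, SEXP spolicy)
{
    gpc_policy pol;
    gpc_read_policy(spolicy, &pol);
    long nt;
    double maxl;
    if (gpc_scan_short(INTEGER(skind)[0], REAL(st)[0], REAL(sa)[0],
                       REAL(sb)[0], REAL(salpha)[0], REAL(sbeta)[0],
                       &pol, &nt, &maxl))
        error("short-t series exceeded the term cap (%ld terms)", pol.max_terms);
    const char *nm[] = { "n_terms", "max_term_log10", "" };
    SEXP out = PROTECT(Rf_mkNamed(VECSXP, nm));
    SET_VECTOR_ELT(out, 0, ScalarReal((double) nt));
    SET_VECTOR_ELT(out, 1, ScalarReal((double) llround(maxl)));
    UNPROTECT(1);
    return out;
}

SEXP C_gpc_asym_pdf(SEXP st, SEXP sa, SEXP sb, SEXP salpha, SEXP sbeta,
                    SEXP spolicy)
{
    gpc_policy pol;
    gpc_read_policy(spolicy, &pol);
    mpfr_prec_t prec = gpc_bits(pol.target_digits + pol.guard_digits);
    mpfr_t r;
    mpfr_init2(r, prec);
    gpc_asymptote_pdf(r, REAL(st)[0], REAL(sa)[0], REAL(sb)[0],
                      REAL(salpha)[0], REAL(sbeta)[0], prec, pol.max_terms);
    SEXP out = gpc_mkstring(r, pol.target_digits);
    mpfr_clear(r);
    return out;
}

/* |T_{k+1}/T_k| of the simplified long-t density terms */
SEXP C_long_term_ratio(SEXP sk, SEXP st, SEXP sa, SEXP sb, SEXP salpha,
                       SEXP sbeta)
{
    long k = (long) REAL(sk)[0];
    double t = REAL(st)[0], a = REAL(sa)[0], b = REAL(sb)[0];
    double alpha = REAL(salpha)[0], beta = REAL(sbeta)[0];
    mpfr_prec_t prec = gpc_bits(40);
    mpfr_t T[2], w, X1, A1, B1, f1, poch, kfact, tmp;
    mpfr_inits2(prec, T[0], T[1], w, X1, A1, B1, f1, poch, kfact, tmp,
                (mpfr_ptr) 0);
    mpfr_set_d(w, beta / t, MPFR_RNDN);
    mpfr_set_d(X1, -b * t, MPFR_RNDN);
    for (int i = 0; i < 2; i++) {
        long kk = k + i;
        mpfr_set_d(A1, a, MPFR_RNDN);
        mpfr_set_d(B1, a - (double) kk, MPFR_RNDN);
        hyp1f1_terminating(f1, A1, B1, X1, kk, prec);
        /* (beta/t)^kk (1-a)_kk / (kk! (kk-alpha)) */
        mpfr_set_ui(poch, 1, MPFR_RNDN);
        mpfr_set_ui(kfact, 1, MPFR_RNDN);
        for (long j = 0; j < kk; j++) {
            mpfr_set_d(tmp, 1.0 - a + j, MPFR_RNDN);
            mpfr_mul(poch, poch, tmp, MPFR_RNDN);
            mpfr_mul_si(kfact, kfact, j + 1, MPFR_RNDN);
        }
        mpfr_pow_si(T[i], w, kk, MPFR_RNDN);
        mpfr_mul(T[i], T[i], poch, MPFR_RNDN);
        mpfr_div(T[i], T[i], kfact, MPFR_RNDN);
        mpfr_div_d(T[i], T[i], (double) kk - alpha, MPFR_RNDN);
        mpfr_mul(T[i], T[i], f1, MPFR_RNDN);
    }
    mpfr_div(tmp, T[1], T[0], MPFR_RNDN);
    mpfr_abs(tmp, tmp, MPFR_RNDN);
    double ratio = mpfr_get_d(tmp, MPFR_RNDN);
    mpfr_clears(T[0], T[1], w, X1, A1, B1, f1, poch, kfact, tmp, (mpfr_ptr) 0);
    return ScalarReal(ratio);
}

SEXP C_gpc_fast(SEXP skind, SEXP st, SEXP sa, SEXP sb, SEXP salpha, SEXP sbeta)
{
    int kind = INTEGER(skind)[0];
    R_xlen_t n = XLENGTH(st), i;
    double a = REAL(sa)[0], b = REAL(sb)[0];
    double alpha = REAL(salpha)[0], beta = REAL(sbeta)[0];
    SEXP out = PROTECT(allocVector(REALSXP, n));
    for (i = 0; i < n; i++)
        REAL(out)[i] = gpc_fast1(kind, REAL(st)[i], a, b, alpha, beta);
    UNPROTECT(1);
    return out;
}

/* ---- registration ---- */

SEXP C_hp_digits_agree(SEXP, SEXP);
SEXP C_hp_arith(SEXP, SEXP, SEXP, SEXP);
SEXP C_hp_sum(SEXP, SEXP);
SEXP C_beta_inc(SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_beta_ibp(SEXP, SEXP, SEXP, SEXP);
SEXP C_hyp1f1(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_gamma_regQ(SEXP, SEXP, SEXP);
SEXP C_pochhammer(SEXP, SEXP, SEXP);
SEXP C_conv_quad(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef callMethods[] = {
    { "C_hp_digits_agree", (DL_FUNC) &C_hp_digits_agree, 2 },
    { "C_hp_arith",        (DL_FUNC) &C_hp_arith,        4 },
    { "C_hp_sum",          (DL_FUNC) &C_hp_sum,          2 },
    { "C_beta_inc",        (DL_FUNC) &C_beta_inc,        5 },
    { "C_beta_ibp",        (DL_FUNC) &C_beta_ibp,        4 },
    { "C_hyp1f1",          (DL_FUNC) &C_hyp1f1,          6 },
    { "C_gamma_regQ",      (DL_FUNC) &C_gamma_regQ,      3 },
    { "C_pochhammer",      (DL_FUNC) &C_pochhammer,      3 },
    { "C_gpc_eval",        (DL_FUNC) &C_gpc_eval,        8 },
    { "C_gpc_scan_short",  (DL_FUNC) &C_gpc_scan_short,  7 },
    { "C_gpc_asym_pdf",    (DL_FUNC) &C_gpc_asym_pdf,    6 },
    { "C_long_term_ratio", (DL_FUNC) &C_long_term_ratio, 6 },
    { "C_gpc_fast",        (DL_FUNC) &C_gpc_fast,        6 },
    { "C_conv_quad",       (DL_FUNC) &C_conv_quad,       7 },
    { NULL, NULL, 0 }
};

void R_init_gpconv(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
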