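#ifndef GPCONV_H
#define GPCONV_H

#include <stdlib.h>
#include <string.h>
#include <math.h>
#include <mpfr.h>
#include <R.h>
#include <Rinternals.h>

/* evaluation policy mirrored from the R side */
typedef struct {
    long target_digits;   /* significant decimal digits in results      */
    long guard_digits;    /* extra working digits                       */
    long stop_exp;        /* outer sums stop when |term| < 10^stop_exp  */
    long max_terms;       /* hard cap on summed terms                   */
} gpc_policy;

/* function selector: order matches the R-side FunctionKind levels */
enum gpc_kind { GPC_PDF = 0, GPC_CDF = 1, GPC_SUPER = 2, GPC_DERIV = 3 };

/* diagnostics filled in by the series engines */
typedef struct {
    int branch;            /* 0 short, 1 long */
    long n_terms;
    int has_maxlog;
    long max_term_log10;
    long working_digits;
} gpc_diag;

mpfr_prec_t gpc_bits(long digits);
SEXP gpc_mkstring(mpfr_t x, long digits);
void gpc_read_policy(SEXP spolicy, gpc_policy *p);

/* special.c */
void beta_inc_series(mpfr_t rop, const mpfr_t w, const mpfr_t P, const mpfr_t Q,
                     mpfr_prec_t prec, long max_terms);
void beta_inc_series_scaled(mpfr_t rop, const mpfr_t w, const mpfr_t P,
                            const mpfr_t Q, const mpfr_t wP,
                            mpfr_prec_t prec, long max_terms);
void beta_inc_core(mpfr_t rop, const mpfr_t z, const mpfr_t A, const mpfr_t B,
                   mpfr_prec_t prec, long max_terms, int route);
void hyp1f1_possum(mpfr_t rop, const mpfr_t A, const mpfr_t B, const mpfr_t x,
                   mpfr_prec_t prec, long max_terms, int regularized);
void hyp1f1_terminating(mpfr_t rop, const mpfr_t A, const mpfr_t B,
                        const mpfr_t x, long k, mpfr_prec_t prec);
void hyp1f1_core(mpfr_t rop, const mpfr_t A, const mpfr_t B, const mpfr_t x,
                 mpfr_prec_t prec, long max_terms, int regularized, int force_direct);
void gamma_regQ(mpfr_t rop, const mpfr_t a, const mpfr_t x, mpfr_prec_t prec);
void gamma_regP(mpfr_t rop, const mpfr_t a, const mpfr_t x, mpfr_prec_t prec);

/* shortt.c */
int gpc_scan_short(int kind, double t, double a, double b, double alpha,
                   double beta, const gpc_policy *pol,
                   long *n_terms, double *max_log10);
void gpc_eval_short(mpfr_t rop, int kind, double t, double a, double b,
                    double alpha, double beta, const gpc_policy *pol,
                    gpc_diag *diag);

/* longt.c */
void gpc_eval_long(mpfr_t rop, int kind, double t, double a, double b,
                   double alpha, double beta, const gpc_policy *pol,
                   gpc_diag *diag);
void gpc_asymptote_pdf(mpfr_t rop, double t, double a, double b, double alpha,
                       double beta, mpfr_prec_t prec, long max_terms);

/* fast.c */
double gpc_fast1(int kind, double t, double a, double b, double alpha, double beta);

#endif
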