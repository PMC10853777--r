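#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_h5_read_kallisto(SEXP path_);
SEXP C_h5_write_kallisto(SEXP path_, SEXP ids_, SEXP lengths_, SEXP eff_,
                         SEXP est_, SEXP boots_);

static const R_CallMethodDef CallEntries[] = {
    {"C_h5_read_kallisto", (DL_FUNC) &C_h5_read_kallisto, 1},
    {"C_h5_write_kallisto", (DL_FUNC) &C_h5_write_kallisto, 6},
    {NULL, NULL, 0}
};

void R_init_rtadte(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
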