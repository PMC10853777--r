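/* Minimal HDF5 I/O for the kallisto abundance.h5 dialect.
 *
 * Reads/writes the datasets kallisto emits: /est_counts, /aux/ids,
 * /aux/lengths, /aux/eff_lengths, /aux/num_bootstrap and /bootstrap/bs{0..B-1}.
 * String datasets are read whether stored variable- or fixed-length;
 * the writer emits variable-length strings.
 */
#include <stdlib.h>
#include <string.h>
#include <hdf5.h>
#include <R.h>
#include <Rinternals.h>

static void h5err(hid_t file, const char *what, const char *path)
{
    if (file >= 0) H5Fclose(file);
    error("HDF5: %s (%s)", what, path ? path : "");
}

static int dset_exists(hid_t file, const char *name)
{
    return H5Lexists(file, name, H5P_DEFAULT) > 0;
}

static hsize_t dset_len(hid_t dset)
{
    hid_t space = H5Dget_space(dset);
    hsize_t n = (hsize_t) H5Sget_simple_extent_npoints(space);
    H5Sclose(space);
    return n;
}

static SEXP read_double_dset(hid_t file, const char *name)
{
    hid_t dset = H5Dopen2(file, name, H5P_DEFAULT);
    if (dset < 0) h5err(file, "cannot open dataset", name);
    hsize_t n = dset_len(dset);
    SEXP out = PROTECT(allocVector(REALSXP, (R_xlen_t) n));
    if (H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                REAL(out)) < 0) {
        H5Dclose(dset);
        h5err(file, "read failed", name);
    }
    H5Dclose(dset);
    UNPROTECT(1);
    return out;
}

static int read_int_scalar(hid_t file, const char *name)
{
    hid_t dset = H5Dopen2(file, name, H5P_DEFAULT);
    if (dset < 0) h5err(file, "cannot open dataset", name);
    int val = 0;
    if (H5Dread(dset, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                &val) < 0) {
        H5Dclose(dset);
        h5err(file, "read failed", name);
    }
    H5Dclose(dset);
    return val;
}

static SEXP read_string_dset(hid_t file, const char *name)
{
    hid_t dset = H5Dopen2(file, name, H5P_DEFAULT);
    if (dset < 0) h5err(file, "cannot open dataset", name);
    hsize_t n = dset_len(dset);
    hid_t ftype = H5Dget_type(dset);
    SEXP out = PROTECT(allocVector(STRSXP, (R_xlen_t) n));
    if (H5Tis_variable_str(ftype) > 0) {
        char **buf = (char **) R_alloc((size_t) n, sizeof(char *));
        hid_t mtype = H5Tcopy(H5T_C_S1);
        H5Tset_size(mtype, H5T_VARIABLE);
        H5Tset_cset(mtype, H5T_CSET_UTF8);
        if (H5Dread(dset, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf) < 0) {
            H5Tclose(mtype); H5Tclose(ftype); H5Dclose(dset);
            h5err(file, "read failed", name);
        }
        for (hsize_t i = 0; i < n; i++)
            SET_STRING_ELT(out, (R_xlen_t) i,
                           mkChar(buf[i] ? buf[i] : ""));
        hid_t space = H5Dget_space(dset);
        H5Dvlen_reclaim(mtype, space, H5P_DEFAULT, buf);
        H5Sclose(space);
        H5Tclose(mtype);
    } else {
        size_t sz = H5Tget_size(ftype);
        char *buf = (char *) R_alloc((size_t) n, sz + 1);
        hid_t mtype = H5Tcopy(H5T_C_S1);
        H5Tset_size(mtype, sz);
        if (H5Dread(dset, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf) < 0) {
            H5Tclose(mtype); H5Tclose(ftype); H5Dclose(dset);
            h5err(file, "read failed", name);
        }
        char *tmp = (char *) R_alloc(1, sz + 1);
        for (hsize_t i = 0; i < n; i++) {
            memcpy(tmp, buf + i * sz, sz);
            tmp[sz] = '\0';
            SET_STRING_ELT(out, (R_xlen_t) i, mkChar(tmp));
        }
        H5Tclose(mtype);
    }
    H5Tclose(ftype);
    H5Dclose(dset);
    UNPROTECT(1);
    return out;
}

/* Read an abundance.h5 file. Returns list(ids, lengths, eff_lengths,
 * est_counts, num_bootstrap, bootstraps) with bootstraps a T x B matrix. */
SEXP C_h5_read_kallisto(SEXP path_)
{
    const char *path = CHAR(STRING_ELT(path_, 0));
    hid_t file = H5Fopen(path, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) error("HDF5: cannot open file %s", path);

    const char *need[] = {"/est_counts", "/aux/ids", "/aux/eff_lengths",
                          "/aux/lengths", "/aux/num_bootstrap"};
    for (int i = 0; i < 5; i++)
        if (!dset_exists(file, need[i]))
            h5err(file, "missing dataset", need[i]);

    SEXP est = PROTECT(read_double_dset(file, "/est_counts"));
    SEXP ids = PROTECT(read_string_dset(file, "/aux/ids"));
    SEXP eff = PROTECT(read_double_dset(file, "/aux/eff_lengths"));
    SEXP len = PROTECT(read_double_dset(file, "/aux/lengths"));
    int nboot = read_int_scalar(file, "/aux/num_bootstrap");
    R_xlen_t T = XLENGTH(est);

    /* count the bs* datasets actually present */
    int nbs = 0;
    char name[64];
    for (;;) {
        snprintf(name, sizeof(name), "/bootstrap/bs%d", nbs);
        if (H5Lexists(file, "/bootstrap", H5P_DEFAULT) <= 0 ||
            !dset_exists(file, name))
            break;
        nbs++;
    }
    if (nbs != nboot) {
        H5Fclose(file);
        error("HDF5: /aux/num_bootstrap declares %d resamples but %d "
              "bootstrap datasets are present (%s)", nboot, nbs, path);
    }

    SEXP boots = PROTECT(allocMatrix(REALSXP, T, nboot));
    for (int b = 0; b < nboot; b++) {
        snprintf(name, sizeof(name), "/bootstrap/bs%d", b);
        hid_t dset = H5Dopen2(file, name, H5P_DEFAULT);
        if (dset < 0) h5err(file, "cannot open dataset", name);
        if ((R_xlen_t) dset_len(dset) != T) {
            H5Dclose(dset);
            h5err(file, "bootstrap dataset length mismatch", name);
        }
        if (H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                    REAL(boots) + (R_xlen_t) b * T) < 0) {
            H5Dclose(dset);
            h5err(file, "read failed", name);
        }
        H5Dclose(dset);
    }
    H5Fclose(file);

    SEXP out = PROTECT(allocVector(VECSXP, 6));
    SEXP nms = PROTECT(allocVector(STRSXP, 6));
    const char *onames[] = {"ids", "lengths", "eff_lengths", "est_counts",
                            "num_bootstrap", "bootstraps"};
    for (int i = 0; i < 6; i++) SET_STRING_ELT(nms, i, mkChar(onames[i]));
    SET_VECTOR_ELT(out, 0, ids);
    SET_VECTOR_ELT(out, 1, len);
    SET_VECTOR_ELT(out, 2, eff);
    SET_VECTOR_ELT(out, 3, est);
    SET_VECTOR_ELT(out, 4, ScalarInteger(nboot));
    SET_VECTOR_ELT(out, 5, boots);
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(7);
    return out;
}

static void write_double_dset(hid_t file, const char *name, const double *x,
                              hsize_t n)
{
    hid_t space = H5Screate_simple(1, &n, NULL);
    hid_t dset = H5Dcreate2(file, name, H5T_NATIVE_DOUBLE, space,
                            H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    if (dset < 0) h5err(file, "cannot create dataset", name);
    if (H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                 x) < 0)
        h5err(file, "write failed", name);
    H5Dclose(dset);
    H5Sclose(space);
}

SEXP C_h5_write_kallisto(SEXP path_, SEXP ids_, SEXP lengths_, SEXP eff_,
                         SEXP est_, SEXP boots_)
{
    const char *path = CHAR(STRING_ELT(path_, 0));
    R_xlen_t T = XLENGTH(est_);
    hid_t file = H5Fcreate(path, H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
    if (file < 0) error("HDF5: cannot create file %s", path);
    hid_t aux = H5Gcreate2(file, "/aux", H5P_DEFAULT, H5P_DEFAULT,
                           H5P_DEFAULT);
    H5Gclose(aux);

    write_double_dset(file, "/est_counts", REAL(est_), (hsize_t) T);
    write_double_dset(file, "/aux/eff_lengths", REAL(eff_), (hsize_t) T);
    write_double_dset(file, "/aux/lengths", REAL(lengths_), (hsize_t) T);

    /* ids as variable-length strings */
    {
        hsize_t n = (hsize_t) T;
        hid_t space = H5Screate_simple(1, &n, NULL);
        hid_t type = H5Tcopy(H5T_C_S1);
        H5Tset_size(type, H5T_VARIABLE);
        H5Tset_cset(type, H5T_CSET_UTF8);
        hid_t dset = H5Dcreate2(file, "/aux/ids", type, space, H5P_DEFAULT,
                                H5P_DEFAULT, H5P_DEFAULT);
        if (dset < 0) h5err(file, "cannot create dataset", "/aux/ids");
        const char **buf = (const char **) R_alloc((size_t) T,
                                                   sizeof(char *));
        for (R_xlen_t i = 0; i < T; i++)
            buf[i] = CHAR(STRING_ELT(ids_, i));
        if (H5Dwrite(dset, type, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf) < 0)
            h5err(file, "write failed", "/aux/ids");
        H5Dclose(dset);
        H5Tclose(type);
        H5Sclose(space);
    }

    int nboot = isMatrix(boots_) ? Rf_ncols(boots_) : 0;
    {
        hsize_t one = 1;
        hid_t space = H5Screate_simple(1, &one, NULL);
        hid_t dset = H5Dcreate2(file, "/aux/num_bootstrap", H5T_NATIVE_INT,
                                space, H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
        if (H5Dwrite(dset, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                     &nboot) < 0)
            h5err(file, "write failed", "/aux/num_bootstrap");
        H5Dclose(dset);
        H5Sclose(space);
    }
    if (nboot > 0) {
        hid_t grp = H5Gcreate2(file, "/bootstrap", H5P_DEFAULT, H5P_DEFAULT,
                               H5P_DEFAULT);
        H5Gclose(grp);
        char name[64];
        for (int b = 0; b < nboot; b++) {
            snprintf(name, sizeof(name), "/bootstrap/bs%d", b);
            write_double_dset(file, name, REAL(boots_) + (R_xlen_t) b * T,
                              (hsize_t) T);
        }
    }
    H5Fclose(file);
    return R_NilValue;
}
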