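/* Minimal HDF5 binding for fluorescence-lifetime image cubes.
 *
 * One 3-D double dataset (C-order dims: time, row, col) plus attributes:
 * "period_ns" (scalar), "bin_centers_ns" (vector), and "meta:<key>" string
 * attributes for free-form provenance.  Axis remapping for third-party
 * layouts is done on the R side.
 */
#include <stdlib.h>
#include <string.h>
#include <hdf5.h>
#include <R.h>
#include <Rinternals.h>

#define MAX_ATTRS 256
#define MAX_ANAME 255

static void write_attr_double(hid_t loc, const char *name, const double *val,
                              hsize_t n)
{
    hid_t sp = (n == 1) ? H5Screate(H5S_SCALAR)
                        : H5Screate_simple(1, &n, NULL);
    hid_t at = H5Acreate2(loc, name, H5T_NATIVE_DOUBLE, sp, H5P_DEFAULT,
                          H5P_DEFAULT);
    if (at >= 0) {
        H5Awrite(at, H5T_NATIVE_DOUBLE, val);
        H5Aclose(at);
    }
    H5Sclose(sp);
}

static void write_attr_string(hid_t loc, const char *name, const char *val)
{
    hid_t tp = H5Tcopy(H5T_C_S1);
    H5Tset_size(tp, strlen(val) + 1);
    H5Tset_strpad(tp, H5T_STR_NULLTERM);
    hid_t sp = H5Screate(H5S_SCALAR);
    hid_t at = H5Acreate2(loc, name, tp, sp, H5P_DEFAULT, H5P_DEFAULT);
    if (at >= 0) {
        H5Awrite(at, tp, val);
        H5Aclose(at);
    }
    H5Sclose(sp);
    H5Tclose(tp);
}

SEXP C_h5_write(SEXP path, SEXP dset_name, SEXP data, SEXP dims,
                SEXP period_ns, SEXP centers, SEXP meta_names, SEXP meta_vals)
{
    const char *fpath = CHAR(STRING_ELT(path, 0));
    const char *dname = CHAR(STRING_ELT(dset_name, 0));

    hid_t file = H5Fcreate(fpath, H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
    if (file < 0)
        Rf_error("cannot create HDF5 file '%s'", fpath);

    hsize_t d[3];
    for (int i = 0; i < 3; i++)
        d[i] = (hsize_t) INTEGER(dims)[i];

    hid_t sp = H5Screate_simple(3, d, NULL);
    hid_t lcpl = H5Pcreate(H5P_LINK_CREATE);
    H5Pset_create_intermediate_group(lcpl, 1);
    hid_t ds = H5Dcreate2(file, dname, H5T_NATIVE_DOUBLE, sp, lcpl,
                          H5P_DEFAULT, H5P_DEFAULT);
    H5Pclose(lcpl);
    if (ds < 0) {
        H5Sclose(sp);
        H5Fclose(file);
        Rf_error("cannot create dataset '%s' in '%s'", dname, fpath);
    }
    H5Dwrite(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
             REAL(data));

    if (period_ns != R_NilValue)
        write_attr_double(ds, "period_ns", REAL(period_ns), 1);
    if (centers != R_NilValue)
        write_attr_double(ds, "bin_centers_ns", REAL(centers),
                          (hsize_t) XLENGTH(centers));
    for (R_xlen_t i = 0; i < XLENGTH(meta_names); i++) {
        char nm[MAX_ANAME + 1];
        snprintf(nm, sizeof nm, "meta:%s", CHAR(STRING_ELT(meta_names, i)));
        write_attr_string(ds, nm, CHAR(STRING_ELT(meta_vals, i)));
    }

    H5Dclose(ds);
    H5Sclose(sp);
    H5Fclose(file);
    return path;
}

struct attr_list {
    int n;
    char names[MAX_ATTRS][MAX_ANAME + 1];
};

static herr_t collect_attr(hid_t loc, const char *name,
                           const H5A_info_t *info, void *op_data)
{
    struct attr_list *al = (struct attr_list *) op_data;
    (void) loc; (void) info;
    if (al->n < MAX_ATTRS) {
        strncpy(al->names[al->n], name, MAX_ANAME);
        al->names[al->n][MAX_ANAME] = '\0';
        al->n++;
    }
    return 0;
}

static SEXP read_one_attr(hid_t ds, const char *name)
{
    hid_t at = H5Aopen(ds, name, H5P_DEFAULT);
    if (at < 0)
        return R_NilValue;
    hid_t tp = H5Aget_type(at);
    hid_t sp = H5Aget_space(at);
    hssize_t n = H5Sget_simple_extent_npoints(sp);
    H5T_class_t cls = H5Tget_class(tp);
    SEXP out = R_NilValue;

    if (cls == H5T_FLOAT || cls == H5T_INTEGER) {
        out = PROTECT(Rf_allocVector(REALSXP, (R_xlen_t) n));
        H5Aread(at, H5T_NATIVE_DOUBLE, REAL(out));
        UNPROTECT(1);
    } else if (cls == H5T_STRING && n == 1) {
        if (H5Tis_variable_str(tp)) {
            char *buf = NULL;
            hid_t mt = H5Tcopy(H5T_C_S1);
            H5Tset_size(mt, H5T_VARIABLE);
            if (H5Aread(at, mt, &buf) >= 0 && buf != NULL) {
                out = Rf_mkString(buf);
                H5free_memory(buf);
            }
            H5Tclose(mt);
        } else {
            size_t sz = H5Tget_size(tp);
            char *buf = (char *) calloc(sz + 1, 1);
            hid_t mt = H5Tcopy(H5T_C_S1);
            H5Tset_size(mt, sz + 1);
            H5Tset_strpad(mt, H5T_STR_NULLTERM);
            if (H5Aread(at, mt, buf) >= 0)
                out = Rf_mkString(buf);
            free(buf);
            H5Tclose(mt);
        }
    }
    H5Sclose(sp);
    H5Tclose(tp);
    H5Aclose(at);
    return out;
}

SEXP C_h5_read(SEXP path, SEXP dset_name)
{
    const char *fpath = CHAR(STRING_ELT(path, 0));
    const char *dname = CHAR(STRING_ELT(dset_name, 0));

    hid_t file = H5Fopen(fpath, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0)
        Rf_error("cannot open HDF5 file '%s'", fpath);
    hid_t ds = H5Dopen2(file, dname, H5P_DEFAULT);
    if (ds < 0) {
        H5Fclose(file);
        Rf_error("dataset '%s' not found in '%s'", dname, fpath);
    }

    hid_t sp = H5Dget_space(ds);
    int rank = H5Sget_simple_extent_ndims(sp);
    if (rank < 1 || rank > 3) {
        H5Sclose(sp); H5Dclose(ds); H5Fclose(file);
        Rf_error("dataset '%s' has rank %d; expected 1-3", dname, rank);
    }
    hsize_t d[3] = {1, 1, 1};
    H5Sget_simple_extent_dims(sp, d, NULL);
    R_xlen_t ntot = 1;
    for (int i = 0; i < rank; i++)
        ntot *= (R_xlen_t) d[i];

    SEXP data = PROTECT(Rf_allocVector(REALSXP, ntot));
    H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(data));

    SEXP dims = PROTECT(Rf_allocVector(INTSXP, rank));
    for (int i = 0; i < rank; i++)
        INTEGER(dims)[i] = (int) d[i];

    struct attr_list al;
    al.n = 0;
    hsize_t idx = 0;
    H5Aiterate2(ds, H5_INDEX_NAME, H5_ITER_NATIVE, &idx, collect_attr, &al);

    SEXP anames = PROTECT(Rf_allocVector(STRSXP, al.n));
    SEXP avals = PROTECT(Rf_allocVector(VECSXP, al.n));
    for (int i = 0; i < al.n; i++) {
        SET_STRING_ELT(anames, i, Rf_mkChar(al.names[i]));
        SET_VECTOR_ELT(avals, i, read_one_attr(ds, al.names[i]));
    }

    H5Sclose(sp);
    H5Dclose(ds);
    H5Fclose(file);

    SEXP out = PROTECT(Rf_allocVector(VECSXP, 4));
    SET_VECTOR_ELT(out, 0, data);
    SET_VECTOR_ELT(out, 1, dims);
    SET_VECTOR_ELT(out, 2, anames);
    SET_VECTOR_ELT(out, 3, avals);
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, 4));
    SET_STRING_ELT(nm, 0, Rf_mkChar("data"));
    SET_STRING_ELT(nm, 1, Rf_mkChar("dims"));
    SET_STRING_ELT(nm, 2, Rf_mkChar("attr_names"));
    SET_STRING_ELT(nm, 3, Rf_mkChar("attr_values"));
    Rf_setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(6);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_h5_write", (DL_FUNC) &C_h5_write, 8},
    {"C_h5_read",  (DL_FUNC) &C_h5_read,  2},
    {NULL, NULL, 0}
};

void R_init_fliphasor(DllInfo *dll)
{
    /* route HDF5 failures through R errors, not stderr dumps */
    H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
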