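/* Raw-deflate compression and CRC32 via zlib, for writing zip containers. */
#include <R.h>
#include <Rinternals.h>
#include <zlib.h>
#include <string.h>

/* CRC32 of a raw vector, returned as a double (fits 2^32 exactly). */
SEXP C_crc32(SEXP raw)
{
    if (TYPEOF(raw) != RAWSXP) error("raw vector expected");
    uLong crc = crc32(0L, Z_NULL, 0);
    crc = crc32(crc, RAW(raw), (uInt) XLENGTH(raw));
    return ScalarReal((double) crc);
}

/* Raw deflate stream (windowBits = -15), suitable for zip method 8. */
SEXP C_deflate_raw(SEXP raw, SEXP level)
{
    if (TYPEOF(raw) != RAWSXP) error("raw vector expected");
    int lev = asInteger(level);
    z_stream strm;
    memset(&strm, 0, sizeof strm);
    int ret = deflateInit2(&strm, lev, Z_DEFLATED, -15, 8, Z_DEFAULT_STRATEGY);
    if (ret != Z_OK) error("deflateInit2 failed (%d)", ret);

    uLong bound = deflateBound(&strm, (uLong) XLENGTH(raw));
    SEXP out = PROTECT(allocVector(RAWSXP, (R_xlen_t) bound));
    strm.next_in = RAW(raw);
    strm.avail_in = (uInt) XLENGTH(raw);
    strm.next_out = RAW(out);
    strm.avail_out = (uInt) bound;
    ret = deflate(&strm, Z_FINISH);
    if (ret != Z_STREAM_END) {
        deflateEnd(&strm);
        UNPROTECT(1);
        error("deflate failed (%d)", ret);
    }
    R_xlen_t n = (R_xlen_t) strm.total_out;
    deflateEnd(&strm);
    SEXP trimmed = PROTECT(allocVector(RAWSXP, n));
    memcpy(RAW(trimmed), RAW(out), (size_t) n);
    UNPROTECT(2);
    return trimmed;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_crc32",       (DL_FUNC) &C_crc32,       1},
    {"C_deflate_raw", (DL_FUNC) &C_deflate_raw, 2},
    {NULL, NULL, 0}
};

void R_init_ampmelt(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
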