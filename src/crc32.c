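/* CRC-32 (IEEE 802.3 polynomial, reflected), as required by the ZIP
 * local-file and central-directory headers. */
#include <R.h>
#include <Rinternals.h>
#include <stdint.h>

static uint32_t table[256];
static int table_ready = 0;

static void init_table(void)
{
    for (uint32_t n = 0; n < 256; n++) {
        uint32_t c = n;
        for (int k = 0; k < 8; k++)
            c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
        table[n] = c;
    }
    table_ready = 1;
}

SEXP ada3d_crc32(SEXP bytes)
{
    if (TYPEOF(bytes) != RAWSXP)
        error("crc32 expects a raw vector");
    if (!table_ready)
        init_table();
    const unsigned char *p = RAW(bytes);
    R_xlen_t n = XLENGTH(bytes);
    uint32_t c = 0xFFFFFFFFu;
    for (R_xlen_t i = 0; i < n; i++)
        c = table[(c ^ p[i]) & 0xFFu] ^ (c >> 8);
    c ^= 0xFFFFFFFFu;
    return ScalarReal((double) c);
}

static const R_CallMethodDef callMethods[] = {
    {"ada3d_crc32", (DL_FUNC) &ada3d_crc32, 1},
    {NULL, NULL, 0}
};

void R_init_ada3d(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
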