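# Atomic property tables used as autocorrelation / matrix weightings.
# Columns: Z, mass, vdW volume (A^3, from Bondi radii), Sanderson EN,
# Pauling EN, Allred-Rochow EN, polarizability (A^3), first ionization
# potential (eV), principal quantum number L, valence electron count Zv,
# McGowan volume increment (cm^3/mol / 100).
# Elements outside this table yield NA descriptor contributions, which the
# missing-value pipeline handles downstream.

.atom_props_df <- function() {
  m <- rbind(
    #        Z    mass     rvdw    se     pe    are     p       i    L  Zv  mcgowan
    H  = c(  1,  1.008,  1.20, 2.592, 2.20, 2.20, 0.667, 13.598, 1, 1, 0.0871),
    B  = c(  5, 10.811,  1.92, 2.275, 2.04, 2.01, 3.030,  8.298, 2, 3, 0.1832),
    C  = c(  6, 12.011,  1.70, 2.746, 2.55, 2.50, 1.760, 11.260, 2, 4, 0.1635),
    N  = c(  7, 14.007,  1.55, 3.194, 3.04, 3.07, 1.100, 14.534, 2, 5, 0.1439),
    O  = c(  8, 15.999,  1.52, 3.654, 3.44, 3.50, 0.802, 13.618, 2, 6, 0.1243),
    F  = c(  9, 18.998,  1.47, 4.000, 3.98, 4.10, 0.557, 17.423, 2, 7, 0.1048),
    Si = c( 14, 28.086,  2.10, 2.138, 1.90, 1.74, 5.380,  8.152, 3, 4, 0.2683),
    P  = c( 15, 30.974,  1.80, 2.515, 2.19, 2.06, 3.630, 10.487, 3, 5, 0.2487),
    S  = c( 16, 32.066,  1.80, 2.957, 2.58, 2.44, 2.900, 10.360, 3, 6, 0.2291),
    Cl = c( 17, 35.453,  1.75, 3.475, 3.16, 2.83, 2.180, 12.968, 3, 7, 0.2095),
    As = c( 33, 74.922,  1.85, 2.816, 2.18, 2.20, 4.310,  9.815, 4, 5, 0.2942),
    Se = c( 34, 78.960,  1.90, 3.014, 2.55, 2.48, 3.770,  9.752, 4, 6, 0.2781),
    Br = c( 35, 79.904,  1.85, 3.219, 2.96, 2.74, 3.050, 11.814, 4, 7, 0.2621),
    I  = c( 53, 126.904, 1.98, 2.778, 2.66, 2.21, 5.350, 10.451, 5, 7, 0.3453)
  )
  colnames(m) <- c("Z", "m", "rvdw", "se", "pe", "are", "p", "i", "L", "Zv", "mcgowan")
  df <- as.data.frame(m)
  # vdW volume from the Bondi radius
  df$v <- 4 / 3 * pi * df$rvdw^3
  df
}

.ATOM_PROPS <- .atom_props_df()

# The 12 atomic weightings of the autocorrelation/Barysz/Burden families.
# c  Gasteiger partial charge        dv Kier-Hall valence delta
# d  sigma degree (heavy neighbours) s  intrinsic state
# Z/m/v/se/pe/are/p/i: tabulated atomic properties above.
.WEIGHT_CODES <- c("c", "dv", "d", "s", "Z", "m", "v", "se", "pe", "are", "p", "i")

atom_prop <- function(elem, code) {
  idx <- match(elem, rownames(.ATOM_PROPS))
  .ATOM_PROPS[idx, code]
}
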