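# Per-element property tables used by descriptor weighting schemes.
# Values: atomic number, atomic mass (u), van der Waals radius (A, Bondi),
# Sanderson electronegativity, static dipole polarizability (A^3),
# first ionization energy (eV) and covalent radius (A).  Elements outside the
# common organic set fall back to carbon-like defaults with a warning upstream.

.atom_table <- local({
  tab <- rbind(
    #        Z     mass    rvdw   eneg   polar   ion     rcov
    H  = c(  1,   1.008,  1.20,  2.592,  0.667, 13.598, 0.31),
    B  = c(  5,  10.811,  1.92,  2.275,  3.030,  8.298, 0.84),
    C  = c(  6,  12.011,  1.70,  2.746,  1.760, 11.260, 0.76),
    N  = c(  7,  14.007,  1.55,  3.194,  1.100, 14.534, 0.71),
    O  = c(  8,  15.999,  1.52,  3.654,  0.802, 13.618, 0.66),
    F  = c(  9,  18.998,  1.47,  4.000,  0.557, 17.423, 0.57),
    Si = c( 14,  28.086,  2.10,  2.138,  5.380,  8.152, 1.11),
    P  = c( 15,  30.974,  1.80,  2.515,  3.630, 10.487, 1.07),
    S  = c( 16,  32.066,  1.80,  2.957,  2.900, 10.360, 1.05),
    Cl = c( 17,  35.453,  1.75,  3.475,  2.180, 12.968, 1.02),
    Se = c( 34,  78.971,  1.90,  2.957,  3.770,  9.752, 1.20),
    Br = c( 35,  79.904,  1.85,  3.219,  3.050, 11.814, 1.20),
    I  = c( 53, 126.904,  1.98,  2.778,  5.350, 10.451, 1.39)
  )
  colnames(tab) <- c("Z", "mass", "rvdw", "eneg", "polar", "ion", "rcov")
  tab
})

atom_prop <- function(elem, prop) {
  idx <- match(elem, rownames(.atom_table))
  idx[is.na(idx)] <- match("C", rownames(.atom_table))  # carbon fallback
  .atom_table[idx, prop]
}

#' Atomic numbers of element symbols
#' @param elem character vector of element symbols.
#' @return integer-valued numeric vector (carbon fallback for rare elements).
#' @export
atomic_number <- function(elem) atom_prop(elem, "Z")

# van der Waals volume from the vdW radius
atom_vdw_volume <- function(elem) (4 / 3) * pi * atom_prop(elem, "rvdw")^3

# Descriptor weights relative to carbon (Todeschini-style convention).
atom_weight <- function(elem, scheme) {
  switch(scheme,
    u = rep(1, length(elem)),
    m = atom_prop(elem, "mass") / atom_prop("C", "mass"),
    v = atom_vdw_volume(elem) / atom_vdw_volume("C"),
    e = atom_prop(elem, "eneg") / atom_prop("C", "eneg"),
    p = atom_prop(elem, "polar") / atom_prop("C", "polar"),
    i = atom_prop(elem, "ion") / atom_prop("C", "ion"),
    r = atom_prop(elem, "rcov") / atom_prop("C", "rcov"),
    stop("unknown weighting scheme: ", scheme)
  )
}

# Coarse additive atomic contributions for octanol/water logP and molar
# refractivity used only to weight voxel grids.  This is the package's own
# element/ring-state scheme (hydrophobic carbons positive, polar heteroatoms
# negative), not a reimplementation of any published fragment system.
atom_logp_contrib <- function(elem, in_ring) {
  base <- c(H = 0.12, C = 0.20, N = -0.60, O = -0.45, F = 0.25, Cl = 0.65,
            Br = 0.85, I = 1.05, S = 0.25, P = -0.40, B = 0.00, Si = 0.20,
            Se = 0.30)
  v <- base[elem]
  v[is.na(v)] <- 0
  unname(v + ifelse(in_ring & elem == "C", 0.09, 0))
}

atom_mr_contrib <- function(elem, in_ring) {
  base <- c(H = 1.03, C = 2.75, N = 2.50, O = 1.60, F = 0.90, Cl = 5.85,
            Br = 8.75, I = 13.90, S = 7.35, P = 6.90, B = 3.50, Si = 7.00,
            Se = 9.50)
  v <- base[elem]
  v[is.na(v)] <- 2.75
  unname(v + ifelse(in_ring & elem == "C", 0.35, 0))
}
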