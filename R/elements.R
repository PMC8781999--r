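# Element-level constants used by the 3D embedding and the descriptor
# weighting schemes. All weights are expressed relative to carbon, the
# convention of the WHIM / RDF / Burden descriptor families.

# single-bond covalent radii (Angstrom)
.R_COV <- c(H = 0.32, B = 0.82, C = 0.77, N = 0.75, O = 0.73, F = 0.71,
            Si = 1.11, P = 1.06, S = 1.02, Cl = 0.99, Se = 1.17,
            Br = 1.14, I = 1.33)

# Bondi van der Waals radii (Angstrom)
.R_VDW <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
            Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Se = 1.90,
            Br = 1.85, I = 1.98)

# standard atomic weights
.MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
           F = 18.998, Si = 28.086, P = 30.974, S = 32.066, Cl = 35.453,
           Se = 78.971, Br = 79.904, I = 126.904)

# Sanderson electronegativities
.EN_SANDERSON <- c(H = 2.592, B = 2.275, C = 2.746, N = 3.194, O = 3.654,
                   F = 4.000, Si = 2.138, P = 2.515, S = 2.957,
                   Cl = 3.475, Se = 3.014, Br = 3.219, I = 2.778)

# first ionization energies (eV)
.IONIZATION <- c(H = 13.598, B = 8.298, C = 11.260, N = 14.534, O = 13.618,
                 F = 17.423, Si = 8.152, P = 10.487, S = 10.360,
                 Cl = 12.968, Se = 9.752, Br = 11.814, I = 10.451)

# valence electron counts (for Kier-Hall intrinsic state)
.N_VALENCE <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5,
                S = 6, Cl = 7, Se = 6, Br = 7, I = 7)

# principal quantum number of the valence shell
.PQN <- c(H = 1, B = 2, C = 2, N = 2, O = 2, F = 2, Si = 3, P = 3, S = 3,
          Cl = 3, Se = 4, Br = 4, I = 5)

.elem_lookup <- function(table, elem, default = NA_real_) {
  v <- unname(table[elem])
  v[is.na(v)] <- default
  v
}

# relative atom weights for the descriptor weighting schemes
.atom_weights <- function(elem, scheme = c("unweighted", "mass",
                                           "sanderson_en", "ionization",
                                           "vdw_volume")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    unweighted = rep(1, length(elem)),
    mass = .elem_lookup(.MASS, elem, 12.011) / .MASS[["C"]],
    sanderson_en = .elem_lookup(.EN_SANDERSON, elem, 2.746) / .EN_SANDERSON[["C"]],
    ionization = .elem_lookup(.IONIZATION, elem, 11.26) / .IONIZATION[["C"]],
    vdw_volume = (.elem_lookup(.R_VDW, elem, 1.70) / .R_VDW[["C"]])^3
  )
}

# Kier-Hall intrinsic state: ((2/L)^2 * deltav + 1) / delta, with
# deltav = valence electrons - attached hydrogens, delta = heavy-atom
# degree, L the principal quantum number.
.intrinsic_state <- function(elem, n_h, degree) {
  L <- .elem_lookup(.PQN, elem, 2)
  dv <- .elem_lookup(.N_VALENCE, elem, 4) - n_h
  d <- pmax(degree, 1)
  ((2 / L)^2 * dv + 1) / d
}
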