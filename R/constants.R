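# Physical constants. Internal units throughout the package are Angstrom,
# femtosecond, kcal/mol and amu; conversions happen only at file boundaries.

# Boltzmann constant, kcal mol^-1 K^-1
KB <- 0.0019872041

# hbar in (kcal/mol) fs
HBAR <- 1.054571817e-34 * 6.02214076e23 / 4184 * 1e15

# multiply an amu mass by this to make 1/2 m v^2 (v in A/fs) come out in kcal/mol
MASSFAC <- 1e7 / 4184

# speed of light in cm/fs (wavenumber axis: nu~ = f / C_CMFS)
C_CMFS <- 2.99792458e-5

# file-boundary conversions (CPMD TRAJECTORY dialect)
BOHR2ANG <- 0.52917721
AUT2FS <- 0.02418884

HARTREE2KCAL <- 627.5095
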