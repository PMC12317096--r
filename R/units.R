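# Internal unit system: length Angstrom, time fs, mass amu, energy kcal/mol.
# Frequencies are reported in wavenumbers (cm^-1); phase integrals use rad/fs.

# speed of light in cm/fs
.c_cm_fs <- 2.99792458e-5
# Boltzmann constant, kcal/mol/K
.kB_kcal <- 1.9872041e-3
# 1 kcal/mol expressed in amu * A^2 / fs^2 (converts force to acceleration)
.kcal_to_internal <- 4.184e-4
# Coulomb constant, kcal A / (mol e^2)
.coulomb_kcal <- 332.0637

#' Unit conversions for vibrational frequencies and diffusion coefficients
#'
#' The package works internally in Angstrom / fs / amu and reports
#' frequencies in wavenumbers.  `cm1_to_radfs()` converts a wavenumber to an
#' angular frequency in rad/fs (`omega = 2 pi c nu~`); `radfs_to_cm1()` is
#' its inverse.  `diffusion_A2fs_to_SI()` converts a diffusion coefficient
#' from A^2/fs to the reporting unit 1e-10 m^2/s (1 A^2/fs = 1e5 in those
#' units); `diffusion_SI_to_A2fs()` inverts it.
#'
#' @param cm1,radfs,D_A2fs,D_1e10 numeric vectors in the unit the name states.
#' @return numeric vector in the converted unit.
#' @examples
#' cm1_to_radfs(3500)            # ~0.66 rad/fs
#' diffusion_A2fs_to_SI(1e-5)    # 1 A^2/ps  ->  100 x 1e-10 m^2/s
#' @export
cm1_to_radfs <- function(cm1) 2 * pi * .c_cm_fs * cm1

#' @rdname cm1_to_radfs
#' @export
radfs_to_cm1 <- function(radfs) radfs / (2 * pi * .c_cm_fs)

#' @rdname cm1_to_radfs
#' @export
diffusion_A2fs_to_SI <- function(D_A2fs) D_A2fs * 1e5

#' @rdname cm1_to_radfs
#' @export
diffusion_SI_to_A2fs <- function(D_1e10) D_1e10 * 1e-5

# frequency (cycles/fs) to cm^-1
.freqfs_to_cm1 <- function(nu) nu / .c_cm_fs

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
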