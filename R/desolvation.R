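#' Ion specification
#'
#' Builds an ion description, either from the built-in table of the four
#' species the method was developed for (Ca2+, Mg2+, Zn2+, Cl-) or from an
#' explicit valence. The effective radius enters the Born desolvation
#' penalty; the clash radius enters the steric filter. Both default to 2.0 A
#' for all species (a single effective radius is used for cations and anions
#' alike, for computational efficiency).
#'
#' @param species One of `"CA2"`, `"MG2"`, `"ZN2"`, `"CL1"`, or any label
#'   when `valence` is given explicitly.
#' @param valence Signed integer charge of the ion in units of e; taken from
#'   the built-in table when missing.
#' @param effective_radius Born radius r0 in Angstrom (default 2.0).
#' @param clash_radius Steric radius R_ion in Angstrom (defaults to
#'   `effective_radius`).
#' @return An object of class `"ion_spec"` with fields `species`, `valence`,
#'   `effective_radius`, `clash_radius`.
#' @examples
#' ion_spec("CL1")              # chloride, z = -1
#' ion_spec("NA1", valence = 1) # a custom monovalent cation
#' @export
ion_spec <- function(species, valence = NULL, effective_radius = 2.0,
                     clash_radius = effective_radius) {
  builtin <- c(CA2 = 2L, MG2 = 2L, ZN2 = 2L, CL1 = -1L)
  species <- toupper(species)
  if (is.null(valence)) {
    if (!species %in% names(builtin))
      stop(sprintf("unknown ion species '%s'; built-in species are %s (or give valence= explicitly)",
                   species, paste(names(builtin), collapse = ", ")),
           call. = FALSE)
    valence <- builtin[[species]]
  }
  valence <- as.integer(valence)
  stopifnot(valence != 0L, effective_radius > 0, clash_radius > 0)
  structure(list(species = species, valence = valence,
                 effective_radius = effective_radius,
                 clash_radius = clash_radius),
            class = "ion_spec")
}

#' @export
print.ion_spec <- function(x, ...) {
  cat(sprintf("ion %s: z = %+d, r0 = %g A (Born), R_ion = %g A (clash)\n",
              x$species, x$valence, x$effective_radius, x$clash_radius))
  invisible(x)
}

#' Born desolvation penalty of an ion
#'
#' The energy cost for an ion to move from bulk water (permittivity `eps_w`)
#' into a region of local permittivity `eps_local`:
#' \deqn{\Delta G_{solv} = \frac{N_A z^2 e^2}{8\pi\epsilon_0 r_0}
#'       \left(\frac{1}{\epsilon_r} - \frac{1}{\epsilon_w}\right)}
#' i.e. `(coulomb_kcal / (2 r0)) * z^2 * (1/eps_local - 1/eps_w)` kcal/mol.
#' It is zero in bulk and grows as the ion approaches the low-dielectric
#' solute interior; it scales exactly as z^2.
#'
#' @param ion An `"ion_spec"`.
#' @param eps_local Local dielectric value(s), >= 1.
#' @param eps_w Bulk water dielectric (default 80).
#' @return Penalty in kcal/mol (vectorised over `eps_local`), >= 0 whenever
#'   `eps_local <= eps_w`.
#' @examples
#' desolvation_penalty(ion_spec("CL1"), eps_local = 2)   # ~40.5 kcal/mol
#' @export
desolvation_penalty <- function(ion, eps_local, eps_w = 80) {
  stopifnot(inherits(ion, "ion_spec"))
  if (any(eps_local < 1))
    stop("eps_local must be >= 1", call. = FALSE)
  ion_constants()$coulomb_kcal / (2 * ion$effective_radius) *
    ion$valence^2 * (1 / eps_local - 1 / eps_w)
}
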