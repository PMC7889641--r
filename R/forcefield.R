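#' Debye screening length
#'
#' Computes the Debye length kappa^-1 = sqrt(eps0 * eps_r * kB * T /
#' (2 * NA * e^2 * I)) for a 1:1 electrolyte of ionic strength `I`.
#' Returns `Inf` at zero ionic strength (unscreened Coulomb limit).
#'
#' @param ionic_strength mol/L (>= 0).
#' @param temperature K.
#' @param rel_permittivity Relative permittivity (default 80, water).
#' @return Debye length in nm.
#' @examples
#' debye_length(0.15, 298, 80)  # ~0.78 nm (physiological saline)
#' @export
debye_length <- function(ionic_strength, temperature = 298,
                         rel_permittivity = 80) {
  if (any(ionic_strength < 0)) stop("ionic strength must be >= 0")
  kB_J <- 1.380649e-23
  I_m3 <- ionic_strength * 1000 * .NA_CONST      # ions per m^3 (per species)
  lam_m <- sqrt(.EPS0 * rel_permittivity * kB_J * temperature /
                  (2 * .E_CHARGE^2 * pmax(I_m3, 0)))
  ifelse(ionic_strength == 0, Inf, lam_m * 1e9)
}

#' Salt-regime interaction scaling
#'
#' The knobs that emulate the salt regime in the coarse-grained model:
#' `chi` multiplies the screened Coulomb term, `hydro_scale` multiplies
#' pair hydrophobicities (lambda_ij), `cation_pi_eps` is the depth
#' (kJ/mol) of an extra short-range well on {R,K} x {F,W,Y} pairs (0
#' disables it), `debye_length` (nm, `Inf` allowed) sets the screening
#' length, `rel_permittivity` and `temperature` complete the
#' electrostatic description.
#'
#' @param chi Dimensionless Coulomb multiplier (>= 0).
#' @param hydro_scale Dimensionless multiplier on pair hydrophobicity (> 0).
#' @param cation_pi_eps Extra well depth for cation-aromatic pairs, kJ/mol.
#' @param debye_length Screening length, nm (> 0 or Inf).
#' @param rel_permittivity Relative permittivity.
#' @param temperature K.
#' @param eps_ah Ashbaugh-Hatch energy scale, kJ/mol (default 0.2 kcal/mol).
#' @param cutoff_hydro Hydrophobic/cation-pi cutoff, nm.
#' @param cutoff_elec_factor Electrostatic cutoff as a multiple of the
#'   Debye length; the cutoff is capped at `cutoff_elec_max`.
#' @param cutoff_elec_max Cap on the electrostatic cutoff, nm.
#' @return An `interaction_scaling` list.
#' @export
interaction_scaling <- function(chi = 1, hydro_scale = 1, cation_pi_eps = 0,
                                debye_length = 1.0, rel_permittivity = 80,
                                temperature = 300, eps_ah = 0.8368,
                                cutoff_hydro = 2.0, cutoff_elec_factor = 3.5,
                                cutoff_elec_max = 3.5) {
  if (chi < 0) stop("chi must be >= 0")
  if (hydro_scale <= 0) stop("hydro_scale must be > 0")
  if (cation_pi_eps < 0) stop("cation_pi_eps must be >= 0")
  if (!(debye_length > 0)) stop("debye_length must be > 0 (Inf allowed)")
  cutoff_elec <- min(cutoff_elec_factor * debye_length, cutoff_elec_max)
  structure(list(chi = chi, hydro_scale = hydro_scale,
                 cation_pi_eps = cation_pi_eps, debye_length = debye_length,
                 rel_permittivity = rel_permittivity,
                 temperature = temperature, eps_ah = eps_ah,
                 cutoff_hydro = cutoff_hydro, cutoff_elec = cutoff_elec),
            class = "interaction_scaling")
}

#' Salt-regime presets
#'
#' Maps the three experimental salt regimes onto interaction scalings:
#' low salt uses chi = 4 with the cation-pi enhancement switched on;
#' moderate salt (reduced electrostatics) uses chi = 2 with cation-pi
#' off; high salt uses chi = 1 with the hydrophobic contribution
#' up-scaled by 10% for FUS-like proteins or 30% for PR25-like
#' arginine-rich peptides (the high-salt cation-pi attraction is
#' subsumed by this up-scaling).
#'
#' @param regime One of `"low"`, `"moderate"`, `"high"`.
#' @param protein_class One of `"fus_like"`, `"pr_like"`.
#' @param temperature K, stored in the scaling.
#' @param cation_pi_eps Well depth used when the regime enables
#'   cation-pi (default 6 kJ/mol).
#' @param ... Further overrides passed to [interaction_scaling()].
#' @return An `interaction_scaling`.
#' @export
apply_regime <- function(regime = c("low", "moderate", "high"),
                         protein_class = c("fus_like", "pr_like"),
                         temperature = 300, cation_pi_eps = 6.0, ...) {
  regime <- match.arg(regime)
  protein_class <- match.arg(protein_class)
  hs_high <- if (protein_class == "fus_like") 1.1 else 1.3
  args <- switch(regime,
    low      = list(chi = 4, hydro_scale = 1.0, cation_pi_eps = cation_pi_eps),
    moderate = list(chi = 2, hydro_scale = 1.0, cation_pi_eps = 0),
    high     = list(chi = 1, hydro_scale = hs_high, cation_pi_eps = 0))
  do.call(interaction_scaling,
          c(args, list(temperature = temperature), list(...)))
}

# Ashbaugh-Hatch hydrophobic pair term, shifted to zero at the cutoff.
# lambda_ij may exceed 1 when hydro_scale > 1.
.ah_energy <- function(r, sigma_ij, lambda_ij, eps, cutoff) {
  if (r >= cutoff) return(0)
  lj <- function(x) 4 * eps * ((sigma_ij / x)^12 - (sigma_ij / x)^6)
  shift <- lambda_ij * lj(cutoff)
  rmin <- 2^(1 / 6) * sigma_ij
  if (r <= rmin) lj(r) + (1 - lambda_ij) * eps - shift
  else lambda_ij * lj(r) - shift
}

# Plain LJ well of depth eps at sigma_ij, shifted at cutoff (cation-pi).
.lj_energy <- function(r, sigma_ij, eps, cutoff) {
  if (r >= cutoff || eps == 0) return(0)
  lj <- function(x) 4 * eps * ((sigma_ij / x)^12 - (sigma_ij / x)^6)
  lj(r) - lj(cutoff)
}

# Screened Coulomb, shifted at cutoff.
.dh_energy <- function(r, qq, chi, eps_r, lam_d, cutoff) {
  if (r >= cutoff || qq == 0 || chi == 0) return(0)
  u <- function(x) chi * qq * .KE / (eps_r * x) * exp(-x / lam_d)
  u(r) - u(cutoff)
}

#' Pairwise interaction energy between two residues
#'
#' Evaluates the three nonbonded terms of the model at separation `r`:
#' the Ashbaugh-Hatch hydrophobic term (lambda_ij-weighted attraction,
#' lambda-independent repulsive core), the chi-scaled Debye-Hueckel
#' electrostatic term, and the cation-pi well (cation x aromatic pairs
#' only).  All terms are truncated and shifted to zero at the module
#' cutoffs.  Residues flagged buried (inside globular regions) have
#' their own lambda multiplied by 0.7 before pair averaging.
#'
#' @param r Separation, nm (> 0).
#' @param res_i,res_j One-letter residue codes.
#' @param params A `residue_params` table.
#' @param scaling An `interaction_scaling`.
#' @param buried_i,buried_j Whether each residue lies in a globular
#'   (buried) region.
#' @return A `pair_energy_breakdown` list with components `hydrophobic`,
#'   `electrostatic`, `cation_pi` and `total` (kJ/mol; `total` is the
#'   exact sum of the parts).
#' @export
pair_energy <- function(r, res_i, res_j, params, scaling,
                        buried_i = FALSE, buried_j = FALSE) {
  if (!(r > 0)) stop("r must be > 0")
  if (!(res_i %in% AA_CODES)) stop("unknown residue code: ", res_i)
  if (!(res_j %in% AA_CODES)) stop("unknown residue code: ", res_j)
  pi_ <- params[res_i, ]
  pj <- params[res_j, ]
  sigma_ij <- (pi_$sigma + pj$sigma) / 2
  li <- pi_$lambda * if (buried_i) 0.7 else 1
  lj_ <- pj$lambda * if (buried_j) 0.7 else 1
  lambda_ij <- scaling$hydro_scale * (li + lj_) / 2

  hyd <- .ah_energy(r, sigma_ij, lambda_ij, scaling$eps_ah,
                    scaling$cutoff_hydro)
  ele <- .dh_energy(r, pi_$charge * pj$charge, scaling$chi,
                    scaling$rel_permittivity, scaling$debye_length,
                    scaling$cutoff_elec)
  is_cp <- (pi_$is_cation && pj$is_aromatic) ||
    (pj$is_cation && pi_$is_aromatic)
  cp <- if (is_cp) .lj_energy(r, sigma_ij, scaling$cation_pi_eps,
                              scaling$cutoff_hydro) else 0
  structure(list(hydrophobic = hyd, electrostatic = ele, cation_pi = cp,
                 total = hyd + ele + cp),
            class = "pair_energy_breakdown")
}
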