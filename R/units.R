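## Internal unit system: nm, ps, amu, kJ/mol.  Everything converts on ingest.

#' Physical constants and unit conversions
#'
#' Constants used throughout the package. Energies are in kJ/mol, lengths in
#' nm, times in ps, masses in amu.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{R_GAS}{ideal gas constant, kJ mol^-1 K^-1 (0.0083145)}
#'   \item{AMU_PER_NM3_TO_KG_M3}{density conversion, 1 amu/nm^3 in kg/m^3}
#'   \item{UM2_S_TO_NM2_PS}{diffusion conversion, 1 um^2/s in nm^2/ps}
#'   \item{NM_PS_TO_CM_S}{velocity/permeability conversion, 1 nm/ps in cm/s}
#'   \item{CM2_S_TO_NM2_PS}{diffusion conversion, 1 cm^2/s in nm^2/ps}
#' }
#' @export
ox_constants <- list(
  R_GAS                = 8.314462618e-3,  # kJ mol^-1 K^-1
  AMU_PER_NM3_TO_KG_M3 = 1.66053906660,
  UM2_S_TO_NM2_PS      = 1e-6,
  NM_PS_TO_CM_S        = 1e5,
  CM2_S_TO_NM2_PS      = 1e-3
)

#' Thermal energy RT
#'
#' @param T_K temperature in kelvin.
#' @return RT in kJ/mol.
#' @examples
#' ox_kT(310)  # ~2.577 kJ/mol
#' @export
ox_kT <- function(T_K) {
  stopifnot(is.numeric(T_K), length(T_K) == 1L, T_K > 0)
  ox_constants$R_GAS * T_K
}

## Run code with a temporary, explicitly seeded RNG; restores global state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ox_stop <- function(...) stop(..., call. = FALSE)

## Angle (deg) between two 3-vectors, or between row-wise vectors of two
## matrices; numerically clamped acos.
vec_angle_deg <- function(v1, v2) {
  if (is.matrix(v1)) {
    dot <- rowSums(v1 * v2)
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  } else {
    dot <- sum(v1 * v2)
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  }
  ct <- pmin(1, pmax(-1, dot / (n1 * n2)))
  acos(ct) * 180 / pi
}
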