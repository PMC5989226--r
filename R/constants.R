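#' Spectroscopic constants used throughout hemebind
#'
#' A single registry of the literature constants wired into the package:
#' the extinction coefficient used to standardize alkaline hemin stock
#' solutions (58,440 M^-1 cm^-1 at 385 nm), the Reinheitszahl (purity
#' ratio A_Soret/A280) of fully heme-bound wild-type protein (1.43), the
#' Soret monitor wavelengths for the wild-type protein and the two
#' heme-pocket histidine mutants, and the aromatic residue extinction
#' coefficients at 280 nm (Pace / Gill-von Hippel convention).
#'
#' @return A named list of constants.
#' @export
#' @examples
#' heme_constants()$eps_hemin_385
heme_constants <- function() {
  list(
    # hemin stock standardization at 385 nm, M^-1 cm^-1
    eps_hemin_385 = 58440,
    # purity ratio A_Soret/A280 of the fully heme-bound wild-type protein
    reinheitszahl = 1.43,
    # Soret monitor wavelengths, nm: wild type and heme-pocket His mutants
    monitor_wavelengths = c(wild_type = 425, H245A = 418, H245AH249A = 416),
    # per-residue extinction coefficients at 280 nm, M^-1 cm^-1
    eps280_trp = 5500,
    eps280_tyr = 1490,
    eps280_cystine = 125
  )
}
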