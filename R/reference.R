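## Hooks for analysing the genome-scale Synechocystis reconstruction the
## package was built around. The SBML file itself is distributed as
## supplementary material of the reconstruction (it is not bundled here);
## point the package at a local copy to reproduce the genome-scale numbers.

#' Path to the reference genome-scale reconstruction
#'
#' Returns the path where the genome-scale Synechocystis sp. PCC 6803
#' reconstruction (SBML L3V1 + fbc, 920 reactions, 7 compartments) is
#' expected: the option `photofba.reference_model` if set, otherwise
#' `inst/extdata/syn6803.xml` inside the installed package. The file is a
#' user-supplied input; [file.exists()] on the returned path tells you
#' whether it is available.
#'
#' @return character path (possibly to a non-existing file).
#' @export
reference_model_path <- function() {
  opt <- getOption("photofba.reference_model", NULL)
  if (!is.null(opt)) return(opt)
  p <- system.file("extdata", "syn6803.xml", package = "photofba")
  if (nzchar(p)) p else file.path("inst", "extdata", "syn6803.xml")
}

#' Reaction roles of the reference reconstruction
#'
#' The role-to-identifier mapping for the genome-scale Synechocystis
#' reconstruction, using its published reaction abbreviations: RuBisCO
#' carboxylase/oxygenase `RBPC`/`RBCh`, maintenance `ATPM`, Mehler-like
#' `MEHLER_1`, terminal oxidases `CYOOum` and `PR0011`, Mehler reactions at
#' PSI/PSII `PR0032`/`PR0034`. Identifiers for the photon-consuming
#' photosystem reactions, ATPase, FNR, the O2/carbon exchanges and the
#' biomass reaction vary with the SBML id convention and can be overridden.
#'
#' @param ... overrides passed to [reaction_roles()].
#' @return a [reaction_roles()] object.
#' @export
reference_reaction_roles <- function(...) {
  defaults <- list(
    photon_consuming = c("PSII", "PSI"),
    psii = "PSII", psii_o2_coefficient = 1,
    rubisco_carboxylase = "RBPC", rubisco_oxygenase = "RBCh",
    mehler_like = "MEHLER_1", mehler_psi = "PR0032", mehler_psii = "PR0034",
    oxidase = c("CYOOum", "PR0011"), ngam = "ATPM",
    atpase = "ATPSum", fnr = "FNOR",
    o2_exchange = "EX_o2_e", carbon_exchanges = c("EX_co2_e", "EX_hco3_e"),
    biomass = "BIOMASS")
  over <- list(...)
  defaults[names(over)] <- over
  do.call(reaction_roles, defaults)
}
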