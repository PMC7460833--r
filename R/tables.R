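# Reference data for the PaDa-I heme-channel variant panel: the channel
# residue list, reported steady-state kinetic parameters, and reported
# H2O2 inactivation constants. These drive report layout, synthetic-data
# defaults and consistency checks of the derived quantities
# (kcat/Km, t_1/2).

#' Residues lining the PaDa-I heme access channel
#'
#' The 21 residues that delimit the channel from bulk solvent to the distal
#' heme face, in author/PDB numbering.
#'
#' @return named integer vector (names are residue types).
#' @export
heme_channel_residues <- function() {
  c(Phe = 69L, Asp = 70L, Gln = 72L, Ala = 73L, Phe = 76L, Ala = 77L,
    Thr = 78L, Ala = 80L, Ala = 81L, Phe = 121L, Phe = 188L, Arg = 189L,
    Phe = 191L, Thr = 192L, Glu = 196L, Phe = 199L, Leu = 203L, Ser = 240L,
    Phe = 274L, Ala = 316L, Ala = 317L)
}

#' Reported steady-state kinetic parameters of PaDa-I and channel variants
#'
#' Turnover numbers (kcat, 1/s), Michaelis constants (Km, uM) and the
#' printed catalytic efficiencies (kcat/Km, 1/(M s)) for NBD, naphthalene
#' and ABTS, together with the enzyme concentration and substrate range used
#' in each assay.
#'
#' @return data frame with one row per variant x substrate.
#' @export
reference_kinetics <- function() {
  variants <- c("PaDa-I", "F76A", "F191A", "F76L", "F76A/F191A",
                "F76L/F191A")
  build <- function(substrate, kcat, kcat_se, Km, Km_se, eff, enzyme_nM,
                    conc_lo, conc_hi) {
    data.frame(variant = variants, substrate = substrate,
               kcat = kcat, kcat_se = kcat_se, Km = Km, Km_se = Km_se,
               kcat_over_Km_printed = eff, enzyme_nM = enzyme_nM,
               conc_lo_uM = conc_lo, conc_hi_uM = conc_hi,
               stringsAsFactors = FALSE)
  }
  rbind(
    build("NBD",
          kcat = c(286, 356, 279, 454, 258, 332),
          kcat_se = c(18, 30, 18, 22, 15, 33),
          Km = c(736, 1386, 525, 890, 1389, 1552),
          Km_se = c(87, 176, 73, 81, 119, 155),
          eff = c(3.89e5, 2.57e5, 5.31e5, 5.10e5, 1.86e5, 2.14e5),
          enzyme_nM = 30, conc_lo = 100, conc_hi = 1000),
    build("naphthalene",
          kcat = c(308, 305, 512, 341, 327, 485),
          kcat_se = c(25, 13, 28, 10, 17, 39),
          Km = c(289, 544, 740, 466, 627, 486),
          Km_se = c(23, 58, 41, 36, 78, 39),
          eff = c(1.07e6, 5.61e5, 6.92e5, 7.33e5, 5.22e5, 9.98e5),
          enzyme_nM = 30, conc_lo = 100, conc_hi = 2000),
    build("ABTS",
          kcat = c(1620, 751, 1039, 1122, 702, 926),
          kcat_se = c(67, 77, 33, 49, 15, 65),
          Km = c(186, 298, 93, 80, 136, 55),
          Km_se = c(15, 51, 8, 9, 7, 12),
          eff = c(8.71e6, 2.52e6, 1.12e7, 1.40e7, 5.16e6, 1.68e7),
          enzyme_nM = 10, conc_lo = 20, conc_hi = 400))
}

#' Reported H2O2 inactivation constants of PaDa-I and channel variants
#'
#' First-order inactivation rate constants (1 mM H2O2, no reducing
#' substrate), printed half-lives, and catalase specific activities.
#'
#' @return data frame with one row per variant.
#' @export
reference_inactivation <- function() {
  data.frame(
    variant = c("PaDa-I", "F76A", "F191A", "F76L", "F76A/F191A",
                "F76L/F191A"),
    k_inact = c(0.181, 0.368, 0.204, 0.322, 0.250, 0.267),
    k_inact_se = c(0.014, 0.048, 0.012, 0.062, 0.014, 0.012),
    t_half_printed = c(3.8, 1.9, 3.4, 2.2, 2.8, 2.6),
    catalase_U_mg = c(704, 517, 686, 518, 595, 1349),
    catalase_U_mg_se = c(4, 29, 32, 10, 7, 234),
    stringsAsFactors = FALSE)
}

#' Channel-mouth sphere reference atom for a residue type
#'
#' The channel-mouth inclusion sphere is anchored between positions 76 and
#' 191; the anchoring side-chain atom depends on the residue present:
#' Ala uses CB, Leu CD1, Phe CZ.
#'
#' @param residue_name 3-letter residue code(s).
#' @return atom name(s).
#' @export
mouth_reference_atom <- function(residue_name) {
  map <- c(ALA = "CB", LEU = "CD1", PHE = "CZ")
  out <- map[toupper(residue_name)]
  if (anyNA(out))
    stop("no channel-mouth reference atom defined for residue type(s): ",
         paste(unique(residue_name[is.na(out)]), collapse = ", "),
         " (defined: Ala CB, Leu CD1, Phe CZ)")
  unname(out)
}
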