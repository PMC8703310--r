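# Built-in phantom measurement table: 3 T, 37 degC, pH 7.0 / 7.5 solutions,
# PCr internal reference at 0 ppm.  One row per 31P signal.  `basisp` holds the
# chemical shift used for the fitting basis (absent means the signal is not a
# basis member, i.e. the two ADP resonances).  `invivo` is a numeric reading of
# the in vivo column (midpoint where a range is printed, sign matched to the
# phantom shifts); `invivo_raw` keeps the printed text.  `dec_mult` overrides
# the multiplicity under proton decoupling where the collapse rule does not
# apply (NAD+ reshapes from an unresolved singlet to a resolved doublet).
#
# Coupling-partner nuclei are not tabulated; they are assigned from the
# observed decoupling behaviour: P-H coupled multiplets (PE, PC, G1P, G6P,
# GPC, 2,3-DPG, PtdC) collapse to singlets under 1H decoupling, while P-P
# coupled multiplets (ATP, ADP, NAD+, UDPG; J ~ 10-20 Hz) do not.
# PtdC has no printed J; 6.0 Hz (typical choline headgroup J_P-H) is assigned.

.phos_component_table <- function() {
  df <- data.frame(
    abbrev = c("PCr", "Pi",
               "ATP", "ATP", "ATP",
               "ADP", "ADP",
               "PE", "PC", "G1P", "G6P", "PEP", "PtdC", "GPC",
               "DPG23", "DPG23",
               "NADH", "NADplus",
               "UDPG", "UDPG",
               "MP", "GPE"),
    label = c("PCr", "Pi",
              "aATP", "bATP", "gATP",
              "aADP", "bADP",
              "PE", "PC", "G1P", "G6P", "PEP", "PtdC", "GPC",
              "DPG2", "DPG3",
              "NADH", "NAD+",
              "UDPG_a", "UDPG_b",
              "MP", "GPE"),
    multiplicity = c("s", "s",
                     "d", "t", "d",
                     "d", "d",
                     "t", "t", "d", "t", "s", "t", "t",
                     "d", "t",
                     "s", "s",
                     "d", "d",
                     "s", "s"),
    j_hz = c(NA, NA,
             19.5, 20.0, 19.0,
             19.0, 19.5,
             7.0, 6.0, 7.5, 6.1, NA, 6.0, 5.5,
             6.0, 9.5,
             NA, 6.0,
             10.0, 10.0,
             NA, NA),
    partner = c("none", "none",
                "phosphorus", "phosphorus", "phosphorus",
                "phosphorus", "phosphorus",
                "proton", "proton", "proton", "proton", "none", "proton",
                "proton",
                "proton", "proton",
                "none", "phosphorus",
                "phosphorus", "phosphorus",
                "none", "none"),
    dec_mult = c(NA, NA,
                 NA, NA, NA,
                 NA, NA,
                 NA, NA, NA, NA, NA, NA, NA,
                 NA, NA,
                 NA, "d",
                 NA, NA,
                 NA, NA),
    shift_ph70 = c(0, 4.78,
                   -7.98, -18.80, -4.18,
                   -7.28, -3.50,
                   6.74, 6.19, 4.99, 7.03, 2.00, 2.14, 2.97,
                   4.09, 5.338,
                   -8.16, -8.32,
                   -8.11, -9.78,
                   NA, NA),
    shift_ph75 = c(0, 5.27,
                   -7.94, -18.58, -3.37,
                   -7.32, -3.20,
                   6.85, 6.35, NA, 7.30, 2.27, 2.13, 2.96,
                   4.60, 5.84,
                   -8.16, -8.32,
                   -8.11, -9.78,
                   NA, NA),
    invivo = c(0, 5,
               -7.5, -16, -3.5,
               NA, NA,
               6.78, 5.9, NA, 7.15, 2.06, 2.06, 2.76,
               5.5, 6.3,
               -8.1, -8.3,
               -8.1, -9.8,
               NA, NA),
    invivo_raw = c("0", "~5",
                   "~7-8", "~16", "~3-4",
                   NA, NA,
                   "6.78", "5.9", "overlay with PME", "7.1-7.2", "2.06",
                   "2.06", "2.76",
                   "5.5", "6.3",
                   "~8.1", "~8.3",
                   "-8.1", "-9.8",
                   NA, NA),
    shift_deelchand = c(0, 4.84,
                        -7.56, -16.18, -2.53,
                        NA, NA,
                        6.77, 6.23, NA, NA, NA, NA, 2.94,
                        5.23, 5.71,
                        -8.13, -8.31,
                        NA, NA,
                        2.3, 3.49),
    shift_basisp = c(0, 4.78,
                     -7.53, -16.18, -2.7,
                     NA, NA,
                     6.77, 6.23, 4.99, 7.03, 2.00, 2.14, 2.97,
                     4.05, 5.32,
                     -8.13, -8.31,
                     -7.98, -9.78,
                     2.3, 3.49),
    stringsAsFactors = FALSE
  )
  df
}

.phos_entry_table <- function() {
  data.frame(
    abbrev = c("PCr", "Pi", "ATP", "ADP", "PE", "PC", "G1P", "G6P", "PEP",
               "PtdC", "GPC", "DPG23", "NADH", "NADplus", "UDPG", "MP", "GPE"),
    name = c("Phosphocreatine", "Inorganic phosphate",
             "Adenosine triphosphate", "Adenosine diphosphate",
             "Phosphoethanolamine", "Phosphocholine",
             "Glucose 1-phosphate", "Glucose 6-phosphate",
             "Phosphoenolpyruvate", "Phosphatidylcholine",
             "Glycerophosphocholine", "2,3-diphosphoglycerate",
             "Nicotinamide adenine dinucleotide (reduced)",
             "Nicotinamide adenine dinucleotide (oxidized)",
             "Uridine diphosphoglucose", "Membrane phospholipids",
             "Glycerophosphoethanolamine"),
    phantom_mm = c(5, 40, 10, 10, 10, 10, 10, 10, 10, 10, 10, 2, 10, 10, 2,
                   NA, NA),
    # phosphate buffer concentration in that metabolite's phantom (mM);
    # reduced from 40 to 10 for the low-concentration UDPG / 2,3-DPG phantoms
    buffer_mm = c(40, 40, 40, 40, 40, 40, 40, 40, 40, 40, 40, 10, 40, 40, 10,
                  NA, NA),
    notes = c("internal standard, 0 ppm at both pH values", "buffer",
              "three resonances fitted as separate basis members",
              "excluded from basis: both resonances overlapped by ATP",
              "", "", "", "",
              "", "solvent 40% ethanol + surfactant; acid shift read at pH 7.21",
              "", "reduced phosphate buffer", "", "",
              "reduced phosphate buffer",
              "literature-only, modeled as broad singlet",
              "literature-only"),
    stringsAsFactors = FALSE
  )
}
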