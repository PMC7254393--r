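# Curated primary-metabolite formulas used to seed the synthetic compound
# generator: amino acids, sugars and polyols, organic acids, fatty acids
# and a few algal osmolytes. Keeping real formulas keeps the TMS/MeOX
# derivatization arithmetic honest against known chemistry.

#' Curated primary-metabolite formulas
#'
#' @return Tibble with columns `name` and `formula` (~60 metabolites
#'   typical of derivatized-extract GC-MS profiles: amino acids, sugars,
#'   organic and fatty acids, polyols, osmolytes).
#' @export
metabolite_formulas <- function() {
  tibble::tribble(
    ~name, ~formula,
    "glycine", "C2H5NO2",
    "alanine", "C3H7NO2",
    "serine", "C3H7NO3",
    "proline", "C5H9NO2",
    "valine", "C5H11NO2",
    "threonine", "C4H9NO3",
    "leucine", "C6H13NO2",
    "isoleucine", "C6H13NO2",
    "asparagine", "C4H8N2O3",
    "aspartic acid", "C4H7NO4",
    "glutamine", "C5H10N2O3",
    "glutamic acid", "C5H9NO4",
    "lysine", "C6H14N2O2",
    "arginine", "C6H14N4O2",
    "histidine", "C6H9N3O2",
    "phenylalanine", "C9H11NO2",
    "tyrosine", "C9H11NO3",
    "tryptophan", "C11H12N2O2",
    "methionine", "C5H11NO2S",
    "cysteine", "C3H7NO2S",
    "ornithine", "C5H12N2O2",
    "pyroglutamic acid", "C5H7NO3",
    "pyrrole-2-carboxylic acid", "C5H5NO2",
    "4-aminobutyric acid", "C4H9NO2",
    "taurine", "C2H7NO3S",
    "urea", "CH4N2O",
    "putrescine", "C4H12N2",
    "spermidine", "C7H19N3",
    "glucose", "C6H12O6",
    "fructose", "C6H12O6",
    "galactose", "C6H12O6",
    "mannose", "C6H12O6",
    "ribose", "C5H10O5",
    "xylose", "C5H10O5",
    "arabinose", "C5H10O5",
    "rhamnose", "C6H12O5",
    "sucrose", "C12H22O11",
    "trehalose", "C12H22O11",
    "maltose", "C12H22O11",
    "myo-inositol", "C6H12O6",
    "mannitol", "C6H14O6",
    "sorbitol", "C6H14O6",
    "glycerol", "C3H8O3",
    "erythritol", "C4H10O4",
    "threono-1,4-lactone", "C4H6O4",
    "dehydroascorbic acid", "C6H6O6",
    "ascorbic acid", "C6H8O6",
    "lactic acid", "C3H6O3",
    "glycolic acid", "C2H4O3",
    "pyruvic acid", "C3H4O3",
    "oxalic acid", "C2H2O4",
    "malonic acid", "C3H4O4",
    "succinic acid", "C4H6O4",
    "fumaric acid", "C4H4O4",
    "malic acid", "C4H6O5",
    "2-oxoglutaric acid", "C5H6O5",
    "citric acid", "C6H8O7",
    "benzoic acid", "C7H6O2",
    "phosphoric acid", "H3PO4",
    "glycerol-3-phosphate", "C3H9O6P",
    "glucose-6-phosphate", "C6H13O9P",
    "lauric acid", "C12H24O2",
    "myristic acid", "C14H28O2",
    "palmitic acid", "C16H32O2",
    "stearic acid", "C18H36O2",
    "oleic acid", "C18H34O2",
    "linoleic acid", "C18H32O2",
    "eicosapentaenoic acid", "C20H30O2",
    "dimethylsulfoniopropionate", "C5H10O2S",
    "glycine betaine", "C5H11NO2"
  )
}
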