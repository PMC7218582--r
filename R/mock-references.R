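#' Built-in mock community reference compositions
#'
#' Theoretical 16S rRNA gene compositions of two widely used commercial mock
#' communities:
#' \describe{
#'   \item{zymobiomics}{ZymoBIOMICS Microbial Community Standard: an even
#'     8-member mixture (3 gram-negative Proteobacteria, 5 gram-positive
#'     Firmicutes).}
#'   \item{bei}{BEI Resources HM-783D: a staggered 17-member mixture spanning
#'     proportions from 21.9% down to 0.02%. The manufacturer's printed
#'     proportions total 99.88%; they are renormalized here so the composition
#'     sums to exactly 1.}
#' }
#'
#' @param name `"zymobiomics"` or `"bei"`.
#' @return A `mock_reference` tibble (columns taxon, genus, proportion).
#' @export
builtin_mock <- function(name) {
  known <- c("zymobiomics", "bei")
  if (!is.character(name) || length(name) != 1 || !(name %in% known)) {
    abort(sprintf("unknown mock reference '%s'; available: %s",
                  paste(name, collapse = ","), paste(known, collapse = ", ")))
  }
  if (name == "zymobiomics") {
    taxa <- c("Pseudomonas aeruginosa", "Escherichia coli",
              "Salmonella enterica", "Lactobacillus fermentum",
              "Enterococcus faecalis", "Staphylococcus aureus",
              "Listeria monocytogenes", "Bacillus subtilis")
    prop <- c(0.046, 0.100, 0.113, 0.188, 0.104, 0.133, 0.159, 0.157)
    return(new_mock_reference("zymobiomics", taxa, prop))
  }
  taxa <- c("Pseudomonas aeruginosa", "Escherichia coli",
            "Rhodobacter sphaeroides", "Clostridium beijerinckii",
            "Streptococcus spp.", "Staphylococcus spp.",
            "Bacillus cereus", "Acinetobacter baumannii",
            "Neisseria meningitidis", "Lactobacillus gasseri",
            "Listeria monocytogenes", "Helicobacter pylori",
            "Propionibacterium acnes", "Enterococcus faecalis",
            "Bacteroides vulgatus", "Actinomyces odontolyticus",
            "Deinococcus radiodurans")
  pct <- c(2.2, 21.9, 21.9, 2.2, 24.1, 24.1, 2.2, 0.2, 0.2, 0.2, 0.2, 0.2,
           0.2, 0.02, 0.02, 0.02, 0.02)
  new_mock_reference("bei", taxa, pct / sum(pct))
}

# gram staining class of the genera used by the built-in mocks and the
# synthetic generator; drives kit lysis bias
GRAM_CLASS <- c(
  Pseudomonas = "gram_negative", Escherichia = "gram_negative",
  Salmonella = "gram_negative", Lactobacillus = "gram_positive",
  Enterococcus = "gram_positive", Staphylococcus = "gram_positive",
  Listeria = "gram_positive", Bacillus = "gram_positive",
  Rhodobacter = "gram_negative", Clostridium = "gram_positive",
  Streptococcus = "gram_positive", Acinetobacter = "gram_negative",
  Neisseria = "gram_negative", Helicobacter = "gram_negative",
  Propionibacterium = "gram_positive", Bacteroides = "gram_negative",
  Actinomyces = "gram_positive", Deinococcus = "gram_positive",
  Moraxella = "gram_negative", Corynebacterium = "gram_positive",
  Haemophilus = "gram_negative", Dolosigranulum = "gram_positive",
  Prevotella = "gram_negative", Veillonella = "gram_negative",
  Gemella = "gram_positive", Rothia = "gram_positive",
  Fusobacterium = "gram_negative", Granulicatella = "gram_positive",
  Porphyromonas = "gram_negative", Klebsiella = "gram_negative",
  Aquabacterium = "gram_negative", Acidovorax = "gram_negative",
  Noviherbaspirillum = "gram_negative", Stenotrophomonas = "gram_negative",
  Ralstonia = "gram_negative", Sphingomonas = "gram_negative",
  Bradyrhizobium = "gram_negative", Methylobacterium = "gram_negative",
  Burkholderia = "gram_negative", Cupriavidus = "gram_negative",
  Pelomonas = "gram_negative", Herbaspirillum = "gram_negative",
  Delftia = "gram_negative", Comamonas = "gram_negative",
  Brevundimonas = "gram_negative", Caulobacter = "gram_negative",
  Phyllobacterium = "gram_negative", Mesorhizobium = "gram_negative",
  Micrococcus = "gram_positive", Paracoccus = "gram_negative"
)
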