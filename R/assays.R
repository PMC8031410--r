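#' Construct an Assay description
#'
#' @param speciesCode four-letter species code.
#' @param gene marker gene label.
#' @param primerF,primerR,probe IUPAC DNA strings (probe given without
#'   fluorophore/quencher chemistry).
#' @param annealTempC annealing/elongation temperature, Celsius.
#' @param positiveCallMaxCycle Cq cutoff for calling a tissue specimen the
#'   target species.
#' @param offtargetFloorCycle earliest cycle any off-target congener has been
#'   observed to amplify.
#' @return an [Assay-class] object.
#' @examples
#' a <- Assay("BRME", "12S rRNA", "CCGTCGCTTAGAGGATTACATT",
#'            "ATGAGCTACGCCTTGATCTG", "TTTAAATTCTTTTATTGGGAGTTCC",
#'            annealTempC = 59, positiveCallMaxCycle = 20,
#'            offtargetFloorCycle = 30)
#' @export
Assay <- function(speciesCode, gene, primerF, primerR, probe, annealTempC,
                  positiveCallMaxCycle, offtargetFloorCycle) {
  new("Assay", speciesCode = speciesCode, gene = gene,
      primerF = toupper(primerF), primerR = toupper(primerR),
      probe = toupper(probe), annealTempC = annealTempC,
      positiveCallMaxCycle = positiveCallMaxCycle,
      offtargetFloorCycle = offtargetFloorCycle)
}

#' The four vernal pool branchiopod assays
#'
#' Returns the species-specific TaqMan assays for the Conservancy Fairy
#' Shrimp (*Branchinecta conservatio*, BRCO), Vernal Pool Fairy Shrimp
#' (*B. lynchi*, BRLY), Midvalley Fairy Shrimp (*B. mesovallensis*, BRME)
#' and Vernal Pool Tadpole Shrimp (*Lepidurus packardi*, LEPA), with their
#' annealing temperatures and tissue-identification cycle cutoffs.  Targets
#' amplify within 20 cycles (30 for BRLY) on tissue-derived DNA while no
#' off-target congener amplifies before 30 cycles (42 for BRLY).
#'
#' @return named list of [Assay-class] objects.
#' @examples
#' vernalAssays()[["LEPA"]]
#' @export
vernalAssays <- function() {
  list(
    BRCO = Assay("BRCO", "COI",
                 "TGCAGAAAGGGGAGGATARACC", "TGCCTCCTGCCTTRACCTTRC",
                 "YCACCCAGTCCCAGCTCCACT",
                 annealTempC = 56.2, positiveCallMaxCycle = 20,
                 offtargetFloorCycle = 30),
    BRLY = Assay("BRLY", "12S rRNA",
                 "GGATTTGGCGGTTCTTAAACTT", "TTTTCCTAGAAAAATGCATCCGT",
                 "TYAACAGCTTATATACCGTCGTTTAGAGGA",
                 annealTempC = 58.2, positiveCallMaxCycle = 30,
                 offtargetFloorCycle = 42),
    BRME = Assay("BRME", "12S rRNA",
                 "CCGTCGCTTAGAGGATTACATT", "ATGAGCTACGCCTTGATCTG",
                 "TTTAAATTCTTTTATTGGGAGTTCC",
                 annealTempC = 59, positiveCallMaxCycle = 20,
                 offtargetFloorCycle = 30),
    LEPA = Assay("LEPA", "16S rRNA",
                 "CCGTGCGAAGGTAGCATAAT", "AGGGTCTTATCGTCCCTCAA",
                 "TGAAGGCTGGTATGAATGGCTGGA",
                 annealTempC = 57, positiveCallMaxCycle = 20,
                 offtargetFloorCycle = 30)
  )
}

setMethod("show", "Assay", function(object) {
  cat(sprintf("Assay %s (%s)\n", object@speciesCode, object@gene))
  cat(sprintf("  F: %s\n  R: %s\n  P: %s\n",
              object@primerF, object@primerR, object@probe))
  cat(sprintf("  anneal %.1f C; target call <= %g cycles; off-target floor %g\n",
              object@annealTempC, object@positiveCallMaxCycle,
              object@offtargetFloorCycle))
})
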