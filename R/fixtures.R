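## Small published catalogues used as worked-example inputs: the
## B. germanica novel-miRNA matures, the seven-species insect topology,
## and the presence patterns of the families whose gains and losses
## mark the hemimetabolan/holometabolan transition.

#' The published B. germanica novel miRNA catalogue
#'
#' The 13 bona-fide novel miRNA genes identified in *Blattella
#' germanica* (Bge-Mir-bg1 ... Bge-Mir-bg9, with the bg3/bg4/bg5
#' paralogues) and their mature sequences. Grouping these matures by
#' seed (positions 2-7) reproduces the published 9 seed families, of
#' which MIR-bg5 (later found in *L. migratoria* and *A. pisum*, hence
#' conserved in insects) holds two genes.
#'
#' @return data.frame with `name` and `mature`.
#' @examples
#' fams <- groupFamilies(data.frame(name = bgeNovelMatures()$name,
#'                                  mature = bgeNovelMatures()$mature))
#' length(unique(fams$family))  # 9
#' @export
bgeNovelMatures <- function() {
  data.frame(
    name = c("Bge-Mir-bg1", "Bge-Mir-bg2", "Bge-Mir-bg3a",
             "Bge-Mir-bg3b", "Bge-Mir-bg4a", "Bge-Mir-bg4b",
             "Bge-Mir-bg4c", "Bge-Mir-bg5a", "Bge-Mir-bg5b",
             "Bge-Mir-bg6", "Bge-Mir-bg7", "Bge-Mir-bg8",
             "Bge-Mir-bg9"),
    mature = c(
      "TGACTCCAGACCTTGTTGCTGA",
      "TCGGACGAAGTGCACTTATTTACGT",
      "ATGAAATGGACGATTGGCTGTG",
      "TTGAAATGGACGATTGTCTGTG",
      "TACATAACCGCAATCACCGATT",
      "TACATAACCGCAACCACCGACT",
      "TACATAACCGCAACCACCGACT",
      "TGTGATGTGCATGTGGGCTTTCC",
      "TGTGATGTGCATGTGGGCTTTCC",
      "TCACAACTTTCTGTCCAGAAC",
      "CTACGAACCAGAATGACATCGCG",
      "CATAGGCGCTATTTCCTCTGCC",
      "CATTCTTCCTAGAATGGTCCGT"
    ),
    stringsAsFactors = FALSE
  )
}

#' The seven-species insect phylogeny
#'
#' Rooted topology of the seven species whose miRNA complements are
#' compared (after Misof and colleagues' insect phylogeny):
#' ((Bge,Lmi),(Api,(Ame,(Tca,(Bmo,Dme))))). Bge = *Blattella
#' germanica*, Lmi = *Locusta migratoria*, Api = *Acyrthosiphon
#' pisum*, Ame = *Apis mellifera*, Tca = *Tribolium castaneum*,
#' Bmo = *Bombyx mori*, Dme = *Drosophila melanogaster*.
#'
#' @return an `ape` `phylo` tree.
#' @export
insectSpeciesTree <- function() {
  readSpeciesTree(text = "((Bge,Lmi),(Api,(Ame,(Tca,(Bmo,Dme)))));")
}

#' Presence patterns of the endopterygote-transition miRNA families
#'
#' Species sets carrying the miRNA families whose gains/losses mark
#' the hemimetabolan-to-holometabolan transition: MIR-989 (all four
#' endopterygotes), MIR-1006 (*A. mellifera*, *B. mori*,
#' *D. melanogaster*), MIR-1007 (*A. mellifera*, *D. melanogaster*),
#' MIR-bg5 (the three hemimetabolans: gained deep, lost on the
#' endopterygote stem), and MIR-970 (coleopteran + panorpid clade).
#'
#' @return named list: family -> character vector of species codes.
#' @export
endopterygotePresencePatterns <- function() {
  list(
    `MIR-989` = c("Ame", "Tca", "Bmo", "Dme"),
    `MIR-1006` = c("Ame", "Bmo", "Dme"),
    `MIR-1007` = c("Ame", "Dme"),
    `MIR-bg5` = c("Bge", "Lmi", "Api"),
    `MIR-970` = c("Tca", "Bmo", "Dme")
  )
}
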