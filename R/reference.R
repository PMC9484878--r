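#' Reference class-size profile of the curated human localization dataset
#'
#' The published curated Swiss-Prot human dataset behind this workflow
#' assigns 4986 proteins to 16 subcellular compartments with a strongly
#' imbalanced profile (from 3 proteins in the flagellum/cilium class up to
#' 1487 in the biological-membrane class).  This profile is the default
#' imbalance shape of [simulation_config()] and the reference for the
#' printed-arithmetic consistency checks.
#'
#' @return A tibble with columns `class_index`, `category`, `n_proteins`.
#' @examples
#' sum(reference_class_profile()$n_proteins)
#' @export
reference_class_profile <- function() {
  tibble(
    class_index = 1:16,
    category = c(
      "Biological membrane", "Cell periphery", "Cytoplasm",
      "Cytoplasmic vesicle", "Endoplasmic reticulum", "Endosome",
      "Extracellular space or cell surface", "Flagellum or cilium",
      "Golgi apparatus", "Microtubule cytoskeleton", "Mitochondrion",
      "Nuclear periphery", "Nucleolus", "Nucleus", "Peroxisome", "Vacuole"),
    n_proteins = c(1487L, 35L, 506L, 70L, 190L, 25L, 649L, 3L, 98L, 48L,
                   345L, 33L, 112L, 1285L, 46L, 54L)
  )
}

#' Reference feature-block sizes of the full-scale encoding
#'
#' At full scale the encoding represents each protein by one adjacency
#' feature per network node (20770, STRING v9 human network), one GO
#' enrichment score per GO term (20681) and one pathway enrichment score
#' per KEGG pathway (297), i.e. 41748 features in total.
#'
#' @return A tibble with columns `group`, `n_features`.
#' @examples
#' sum(reference_feature_blocks()$n_features)
#' @export
reference_feature_blocks <- function() {
  tibble(group = c("network", "GO", "pathway"),
         n_features = c(20770L, 20681L, 297L))
}

#' Reference per-group counts of Boruta-retained features
#'
#' In the reference full-scale analysis the Boruta all-relevant filter
#' retained 4773 of the 41748 features: 399 network features, 4223 GO
#' enrichment features and 151 pathway enrichment features.
#'
#' @return A tibble with columns `group`, `n_features`.
#' @examples
#' sum(reference_boruta_retained()$n_features)
#' @export
reference_boruta_retained <- function() {
  tibble(group = c("network", "GO", "pathway"),
         n_features = c(399L, 4223L, 151L))
}
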