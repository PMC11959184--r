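# A small bundled worked example: three genomics research proposals with
# their publication-derived labels, their ontology-derived labels at a 1%
# document-frequency threshold, and the top-10 machine keyphrases an
# unsupervised extractor produced for each. The lists are already in
# stemmed form, as such results are customarily reported; they re-stem to
# themselves, so they can be fed straight into the evaluator.

#' Worked-example documents, labels and machine keyphrases
#'
#' Three genomics proposals (halorespiring Firmicutes genomics, Sorghum
#' diversity resources, and the Amanita thiersii genome) with, per
#' document, the publication-derived label list, the top-10 machine
#' keyphrases generated against those labels, the ontology-derived label
#' list at a 1% document-frequency threshold, and the top-10 machine
#' keyphrases from the ontology-tuned run. Useful for demonstrating
#' stemmed exact matching end to end: for document 1, for example, exactly
#' "desulfitobacterium" and "genom" match.
#'
#' @return A list of four tibbles, each with `doc_id` and `phrase` (plus
#'   `rank` for the keyphrase tables): `publication_labels`,
#'   `ml_keyphrases`, `ontology_labels`, `ml_keyphrases_ontology`.
#' @export
worked_example <- function() {
  publication_labels <- tibble::tribble(
    ~doc_id, ~phrase,
    "1", "desulfitobacterium",
    "1", "genom",
    "2", "polymorph",
    "2", "rice",
    "2", "evolut",
    "2", "diverg",
    "2", "trait",
    "2", "gene",
    "2", "genom",
    "2", "sorghum",
    "3", "compar genom",
    "3", "evolut of symbiosi",
    "3", "sequenc",
    "3", "genom",
    "3", "evolutionari",
    "3", "amanita"
  )
  ml_keyphrases <- dplyr::bind_rows(
    tibble::tibble(doc_id = "1", rank = 1:10, phrase = c(
      "desulfitobacterium", "strain", "isol", "environment", "sequenc",
      "dehalobact", "genom", "halorespir", "bacteria", "degrad")),
    tibble::tibble(doc_id = "2", rank = 1:10, phrase = c(
      "function", "saccharum", "crop", "saccharina", "sequenc", "grass",
      "variat", "genom", "sorghum", "divers")),
    tibble::tibble(doc_id = "3", rank = 1:10, phrase = c(
      "symbiosi", "ectomycorrhiz", "evolut", "thiersii", "saprotroph",
      "speci", "sequenc", "genom", "genu", "amanita"))
  )
  ontology_labels <- tibble::tribble(
    ~doc_id, ~phrase,
    "1", "halogen compound",
    "1", "dehalogen",
    "1", "clostridium",
    "1", "dehalobact restrictu",
    "1", "dehalobact",
    "1", "dehalobact sp.",
    "1", "verrucomicrobium",
    "1", "gram-posit bacteria",
    "1", "sedimentibact",
    "1", "sedimentibact sp.",
    "1", "desulfitobacterium",
    "1", "desulfitobacterium hafniens tcp-a",
    "1", "desulfitobacterium hafniens dp7",
    "1", "desulfitobacterium hafniens",
    "1", "desulfitobacterium metallireducen",
    "1", "threat",
    "1", "reduct",
    "1", "adapt",
    "2", "high temperatur",
    "2", "fossil-fuel",
    "2", "population-genet",
    "2", "demograph",
    "2", "strength",
    "2", "mutat rate",
    "2", "bac",
    "2", "gene order",
    "2", "saccharum",
    "2", "water suppli",
    "2", "johnson grass",
    "2", "motiv",
    "2", "sorghum",
    "2", "saccharina",
    "2", "bank",
    "2", "attract",
    "3", "decompos",
    "3", "cellulos degrad",
    "3", "amanita: thiersii",
    "3", "laccaria",
    "3", "amanita thiersii",
    "3", "laccaria bicolor",
    "3", "isotop"
  )
  ml_keyphrases_ontology <- dplyr::bind_rows(
    tibble::tibble(doc_id = "1", rank = 1:10, phrase = c(
      "plastic", "elucid genom", "halorespir", "strain desulfitobacterium",
      "strain", "dehalobact", "genom sequenc", "genom",
      "desulfitobacterium", "sequenc")),
    tibble::tibble(doc_id = "2", rank = 1:10, phrase = c(
      "saccharina function", "sorghum genom", "sorghum genu",
      "johnson grass", "sorghum", "saccharina", "cell wall", "genom",
      "function genom", "sorghum sorghum")),
    tibble::tibble(doc_id = "3", rank = 1:10, phrase = c(
      "thiersii genom", "genu amanita", "compar genom", "amanita thiersii",
      "ectomycorrhiz genu", "heather hallen", "genom sequenc",
      "amanita speci", "genom", "ectomycorrhiz symbiosi"))
  )
  as_labels <- function(x, source) {
    tibble::tibble(doc_id = x$doc_id, phrase = x$phrase,
                   stem = stem_phrase(x$phrase), source = source,
                   score = NA_real_)
  }
  list(
    publication_labels = as_labels(publication_labels, "publication"),
    ml_keyphrases = ml_keyphrases,
    ontology_labels = as_labels(ontology_labels, "ontology"),
    ml_keyphrases_ontology = ml_keyphrases_ontology
  )
}
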