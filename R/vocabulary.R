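#' Default subcellular compartment vocabulary
#'
#' The eleven Gene Ontology cellular-component terms used to train the
#' predictor: nucleus, mitochondrion, vacuole, peroxisome, endoplasmic
#' reticulum, Golgi apparatus, cytosol, plasma membrane, cell plate, plastid
#' and extracellular. Annotations to any other GO term are dropped (and
#' counted) during training.
#'
#' By default evaluation reports cover ten compartments: cell plate
#' (GO:0009504) is retained for training but excluded from performance
#' summaries, reflecting how rarely it is annotated.
#'
#' @return A tibble with columns `go_id` and `compartment`, one row per term.
#' @examples
#' compartment_vocabulary()
#' @export
compartment_vocabulary <- function() {
  tibble::tribble(
    ~go_id,       ~compartment,
    "GO:0005634", "nucleus",
    "GO:0005739", "mitochondrion",
    "GO:0005773", "vacuole",
    "GO:0005777", "peroxisome",
    "GO:0005783", "endoplasmic reticulum",
    "GO:0005794", "Golgi apparatus",
    "GO:0005829", "cytosol",
    "GO:0005886", "plasma membrane",
    "GO:0009504", "cell plate",
    "GO:0009536", "plastid",
    "GO:0048046", "extracellular"
  )
}

#' Read a compartment vocabulary from a TSV file
#'
#' @param path Path to a two-column tab-separated file with columns
#'   `go_id` and `compartment` (a header row is expected).
#' @return A validated vocabulary tibble.
#' @export
read_vocabulary <- function(path) {
  vocab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_vocabulary(vocab)
}

validate_vocabulary <- function(vocab) {
  if (!all(c("go_id", "compartment") %in% names(vocab))) {
    abort("vocabulary must have columns 'go_id' and 'compartment'")
  }
  if (anyDuplicated(vocab$go_id)) abort("vocabulary go_ids must be unique")
  if (anyDuplicated(vocab$compartment)) abort("vocabulary compartment names must be unique")
  bad <- !grepl("^GO:\\d{7}$", vocab$go_id)
  if (any(bad)) {
    abort(paste0("malformed GO ids in vocabulary: ", paste(vocab$go_id[bad], collapse = ", ")))
  }
  tibble::as_tibble(vocab[c("go_id", "compartment")])
}

# Compartments reported by default in evaluation output (cell plate excluded).
reporting_compartments <- function(vocab = compartment_vocabulary()) {
  setdiff(vocab$compartment, "cell plate")
}
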