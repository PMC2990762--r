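#' Count Pfam-compartment co-occurrences
#'
#' For each protein, each *distinct* Pfam domain it carries is credited once
#' to each compartment the protein is experimentally annotated to. Counting
#' is protein-weighted: repeated copies of a domain within one protein, or
#' repeated experiments localizing a protein to the same compartment, do not
#' inflate the count. Proteins lacking any Pfam assignment contribute nothing.
#'
#' @param protein_compartments Tibble (`protein_id`, `compartment`) from
#'   [map_compartments()].
#' @param assignments Tibble (`protein_id`, `pfam_id`, ...) from
#'   [read_pfam_assignments()].
#' @return A tibble with columns `pfam_id`, `compartment`, `count`, `total`,
#'   where `total` is the domain's count summed over compartments. Only
#'   observed (pfam, compartment) pairs appear.
#' @export
build_count_matrix <- function(protein_compartments, assignments) {
  pairs <- dplyr::distinct(assignments, .data$protein_id, .data$pfam_id)
  hits <- dplyr::inner_join(pairs, protein_compartments, by = "protein_id",
                            relationship = "many-to-many")
  counts <- dplyr::count(hits, .data$pfam_id, .data$compartment, name = "count")
  counts %>%
    dplyr::group_by(.data$pfam_id) %>%
    dplyr::mutate(total = sum(.data$count)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$pfam_id, .data$compartment)
}

#' Compute per-Pfam localization ratios
#'
#' The localization ratio of a Pfam for a compartment is the fraction of the
#' domain's experimentally localized occurrences seen in that compartment:
#' `ratio = count / total`. The result is completed to the full compartment
#' vocabulary, so never-seen compartments carry ratio 0; domains with zero
#' total are absent entirely. Within each domain the ratios sum to one.
#'
#' @param counts Count tibble from [build_count_matrix()].
#' @param compartments Character vector of all compartment names the model
#'   should score (default: the standard vocabulary).
#' @return A `pfam_ratio_table`: a tibble with columns `pfam_id`,
#'   `compartment`, `count`, `total`, `ratio`, one row per (domain,
#'   compartment) pair over the full vocabulary.
#' @export
compute_ratio_table <- function(counts, compartments = compartment_vocabulary()$compartment) {
  counts <- dplyr::filter(counts, .data$total > 0)
  extra <- setdiff(unique(counts$compartment), compartments)
  if (length(extra) > 0) {
    abort(paste0("count matrix has compartments outside the vocabulary: ",
                 paste(extra, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    pfam_id = unique(counts$pfam_id),
    compartment = compartments
  )
  tab <- grid %>%
    dplyr::left_join(counts, by = c("pfam_id", "compartment")) %>%
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) %>%
    dplyr::group_by(.data$pfam_id) %>%
    dplyr::mutate(
      total = max(.data$total, na.rm = TRUE),
      ratio = .data$count / .data$total
    ) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$pfam_id, match(.data$compartment, compartments))
  bad <- tab %>%
    dplyr::group_by(.data$pfam_id) %>%
    dplyr::summarise(s = sum(.data$ratio), .groups = "drop") %>%
    dplyr::filter(abs(.data$s - 1) > 1e-9)
  if (nrow(bad) > 0) {
    abort(paste0("ratio rows do not sum to 1 for: ", paste(bad$pfam_id, collapse = ", ")))
  }
  new_ratio_table(tab)
}

new_ratio_table <- function(tab) {
  structure(tab, class = c("pfam_ratio_table", class(tibble())))
}

#' Train a localization predictor end to end
#'
#' Convenience wrapper: filter annotations by evidence, map GO terms to
#' compartments, count Pfam-compartment co-occurrences, and form the ratio
#' table that constitutes the trained model.
#'
#' @param annotations Annotation tibble from [read_annotations()].
#' @param assignments Pfam assignment tibble from [read_pfam_assignments()].
#' @param vocab Compartment vocabulary (default [compartment_vocabulary()]).
#' @param evidence Evidence codes to keep (default `"IDA"`).
#' @param expansion Optional GO-id expansion table, see [map_compartments()].
#' @return A `pfam_ratio_table` (see [compute_ratio_table()]).
#' @examples
#' ann <- tibble::tibble(
#'   protein_id = c("AT1G01010", "AT1G01020"),
#'   go_id = c("GO:0005634", "GO:0005886"),
#'   evidence_code = c("IDA", "IDA")
#' )
#' dom <- tibble::tibble(
#'   protein_id = c("AT1G01010", "AT1G01020"),
#'   pfam_id = c("PF00010", "PF00069"), start = NA_integer_, end = NA_integer_
#' )
#' train_localization(ann, dom)
#' @export
train_localization <- function(annotations, assignments,
                               vocab = compartment_vocabulary(),
                               evidence = "IDA", expansion = NULL) {
  vocab <- validate_vocabulary(vocab)
  kept <- filter_evidence(annotations, evidence)
  memb <- map_compartments(kept, vocab, expansion)
  counts <- build_count_matrix(memb, assignments)
  compute_ratio_table(counts, vocab$compartment)
}

#' Write / read a trained ratio table as TSV
#'
#' The on-disk layout has columns `pfam_id`, `compartment`, `count`, `total`,
#' `ratio`, and round-trips bit-exactly: ratios are written as full-precision
#' `count/total` quotients and recomputed on read.
#'
#' @param table A `pfam_ratio_table`.
#' @param path Output/input file path.
#' @return `write_ratio_table()` returns `table` invisibly; `read_ratio_table()`
#'   returns a `pfam_ratio_table`.
#' @export
write_ratio_table <- function(table, path) {
  out <- table
  out$ratio <- format(out$ratio, digits = 17, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path)
  invisible(table)
}

#' @rdname write_ratio_table
#' @export
read_ratio_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    pfam_id = readr::col_character(),
    compartment = readr::col_character(),
    count = readr::col_integer(),
    total = readr::col_integer(),
    ratio = readr::col_double()
  ))
  # recompute to guard against decimal truncation in hand-edited files
  tab$ratio <- tab$count / tab$total
  new_ratio_table(tibble::as_tibble(tab))
}

#' @exportS3Method
tidy.pfam_ratio_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method
glance.pfam_ratio_table <- function(x, ...) {
  tibble(
    n_pfams = dplyr::n_distinct(x$pfam_id),
    n_compartments = dplyr::n_distinct(x$compartment),
    n_annotations = sum(x$count),
    mean_total = mean(unique(dplyr::select(tibble::as_tibble(unclass(x)), "pfam_id", "total"))$total)
  )
}

#' @exportS3Method
print.pfam_ratio_table <- function(x, ...) {
  cat("# Pfam localization ratio table: ",
      dplyr::n_distinct(x$pfam_id), " domains x ",
      dplyr::n_distinct(x$compartment), " compartments\n", sep = "")
  NextMethod()
}
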