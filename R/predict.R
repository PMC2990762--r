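#' Score a protein's compartments by geometric mean of its domains' ratios
#'
#' With domains \eqn{d_1,\dots,d_k} present in the trained table, the score
#' for compartment \eqn{c} is
#' \deqn{s(c) = \left(\prod_{i=1}^{k} r(d_i, c)\right)^{1/k},}
#' the geometric mean of the domains' localization ratios. Duplicate domain
#' accessions collapse to one; domains absent from the table are excluded
#' from the mean and recorded in the `domains_skipped` attribute. A single
#' zero ratio annihilates that compartment's score (no smoothing by default).
#'
#' @param pfam_ids Character vector of Pfam accessions carried by the protein.
#' @param table A `pfam_ratio_table` from [compute_ratio_table()] /
#'   [train_localization()].
#' @param smoothing Additive pseudo-ratio applied to every (domain,
#'   compartment) cell before the mean, for exploratory use only; default 0
#'   (the bare geometric mean).
#' @return A tibble (`compartment`, `score`) covering every compartment in
#'   the table, with attributes `domains_used` and `domains_skipped`. When no
#'   domain has data all scores are 0 and `domains_used` is empty.
#' @examples
#' tab <- example_ratio_table()
#' score_protein("PF00010", tab)
#' @export
score_protein <- function(pfam_ids, table, smoothing = 0) {
  compartments <- unique(table$compartment)
  pfam_ids <- unique(pfam_ids[!is.na(pfam_ids)])
  known <- unique(table$pfam_id)
  used <- intersect(pfam_ids, known)
  skipped <- setdiff(pfam_ids, known)
  if (length(used) == 0) {
    scores <- tibble(compartment = compartments, score = 0)
  } else {
    sub <- table[table$pfam_id %in% used, c("pfam_id", "compartment", "ratio")]
    if (smoothing > 0) {
      sub$ratio <- (sub$ratio + smoothing) / (1 + smoothing * length(compartments))
    }
    scores <- sub %>%
      dplyr::group_by(.data$compartment) %>%
      dplyr::summarise(score = exp(mean(log(.data$ratio))), .groups = "drop")
    # exp(mean(log(0))) = 0 via -Inf; make that explicit
    scores$score[is.nan(scores$score) | scores$score < 0] <- 0
    scores <- scores[match(compartments, scores$compartment), ]
  }
  structure(scores, domains_used = used, domains_skipped = skipped)
}

#' Turn compartment scores into a localization call
#'
#' The called set is the (tied) argmax of the scores: every compartment
#' within `tie_tolerance` of the maximum. Status semantics:
#' \describe{
#'   \item{predicted}{a single compartment called}
#'   \item{tie}{two or more compartments share the top score (reported
#'     e.g. "vacuole/plastid" at 50/50)}
#'   \item{no_pfam}{the protein carried no Pfam domains at all}
#'   \item{no_data}{it carried domains, but none occur in the trained table}
#'   \item{below_threshold}{the top score fell below `threshold`}
#' }
#'
#' @param scores Output of [score_protein()].
#' @param threshold Minimum top score required to call (default 0: always
#'   call the argmax, as in standard reporting; thresholds matter for ROC).
#' @param tie_tolerance Scores within this distance of the maximum are
#'   co-called (default 1e-9: exact ties only).
#' @param had_pfams Whether the protein carried any domain assignment; only
#'   needed to distinguish `no_pfam` from `no_data` when all domains were
#'   skipped. Defaults to the evidence in the score attributes.
#' @return A one-row tibble: `called` (slash-joined compartment names, ""
#'   when none), `compartments` (list column of the called set), `score`
#'   (top score, NA when nothing called), `status`.
#' @export
call_localization <- function(scores, threshold = 0, tie_tolerance = 1e-9,
                              had_pfams = NULL) {
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  used <- attr(scores, "domains_used") %||% character()
  skipped <- attr(scores, "domains_skipped") %||% character()
  if (is.null(had_pfams)) had_pfams <- length(used) + length(skipped) > 0
  empty_call <- function(status) {
    tibble(called = "", compartments = list(character()),
           score = NA_real_, status = status)
  }
  if (length(used) == 0) {
    return(empty_call(if (had_pfams) "no_data" else "no_pfam"))
  }
  m <- max(scores$score)
  if (m < threshold) return(empty_call("below_threshold"))
  called_set <- scores$compartment[m - scores$score <= tie_tolerance]
  tibble(
    called = paste(called_set, collapse = "/"),
    compartments = list(called_set),
    score = m,
    status = if (length(called_set) > 1) "tie" else "predicted"
  )
}

#' Predict localization for a batch of proteins
#'
#' Data-frame-first batch interface: takes a long table of protein-to-domain
#' assignments, scores every protein independently against the trained ratio
#' table, and calls each one. Proteins listed with an `NA` domain (or present
#' in `protein_ids` but absent from `proteins`) are treated as having no
#' Pfam domains.
#'
#' @param proteins Tibble with columns `protein_id` and `pfam_id` (multiple
#'   rows per protein for multi-domain proteins; `pfam_id` may be NA).
#' @param table A `pfam_ratio_table`.
#' @param threshold,tie_tolerance,smoothing Passed to [call_localization()] /
#'   [score_protein()].
#' @param protein_ids Optional character vector fixing the output rows and
#'   their order; defaults to the proteins in `proteins`, first-appearance
#'   order.
#' @return A tibble with one row per protein: `protein_id`, `called`,
#'   `compartments` (list), `score`, `status`, `domains_used`,
#'   `domains_skipped` (comma-joined). Status counts are attached as the
#'   `status_counts` attribute.
#' @examples
#' tab <- example_ratio_table()
#' prot <- tibble::tibble(protein_id = "AT5G48560", pfam_id = "PF00010")
#' predict_localization(prot, tab)
#' @export
predict_localization <- function(proteins, table, threshold = 0,
                                 tie_tolerance = 1e-9, smoothing = 0,
                                 protein_ids = NULL) {
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  if (is.null(protein_ids)) protein_ids <- unique(proteins$protein_id)
  eng <- batch_score_engine(proteins, table, smoothing, protein_ids)
  scored <- if (nrow(eng$scores) == 0) {
    tibble(protein_id = character(), compartments = list(), score = numeric())
  } else {
    eng$scores %>%
      dplyr::group_by(.data$protein_id) %>%
      dplyr::summarise(
        compartments = list(.data$compartment[max(.data$score) - .data$score <= tie_tolerance]),
        score = max(.data$score),
        .groups = "drop"
      )
  }
  calls <- tibble(protein_id = protein_ids) %>%
    dplyr::left_join(eng$domains, by = "protein_id") %>%
    dplyr::left_join(scored, by = "protein_id") %>%
    dplyr::mutate(
      n_called = vapply(.data$compartments, length, integer(1)),
      status = dplyr::case_when(
        .data$n_pfams == 0 ~ "no_pfam",
        .data$n_used == 0 ~ "no_data",
        .data$score < threshold ~ "below_threshold",
        .data$n_called > 1 ~ "tie",
        TRUE ~ "predicted"
      ),
      callable = .data$status %in% c("predicted", "tie"),
      compartments = purrr::map2(.data$compartments, .data$callable,
                                 function(x, ok) if (ok) x else character()),
      called = vapply(.data$compartments, paste, character(1), collapse = "/"),
      score = ifelse(.data$callable, .data$score, NA_real_)
    ) %>%
    dplyr::select("protein_id", "called", "compartments", "score", "status",
                  "domains_used", "domains_skipped")
  structure(calls, status_counts = table_statuses(calls$status))
}

# Shared vectorized scoring for the batch interfaces. Returns per-protein
# domain bookkeeping and a long (protein_id, compartment, score) table for
# proteins with at least one domain present in the ratio table.
batch_score_engine <- function(proteins, table, smoothing, protein_ids) {
  compartments <- unique(table$compartment)
  pairs <- proteins %>%
    dplyr::filter(!is.na(.data$pfam_id), .data$protein_id %in% protein_ids) %>%
    dplyr::distinct(.data$protein_id, .data$pfam_id) %>%
    dplyr::mutate(in_table = .data$pfam_id %in% unique(table$pfam_id))
  domains <- tibble(protein_id = protein_ids) %>%
    dplyr::left_join(
      pairs %>%
        dplyr::group_by(.data$protein_id) %>%
        dplyr::summarise(
          n_pfams = dplyr::n(),
          n_used = sum(.data$in_table),
          domains_used = paste(.data$pfam_id[.data$in_table], collapse = ","),
          domains_skipped = paste(.data$pfam_id[!.data$in_table], collapse = ","),
          .groups = "drop"
        ),
      by = "protein_id"
    ) %>%
    dplyr::mutate(
      n_pfams = dplyr::coalesce(.data$n_pfams, 0L),
      n_used = dplyr::coalesce(.data$n_used, 0L),
      domains_used = dplyr::coalesce(.data$domains_used, ""),
      domains_skipped = dplyr::coalesce(.data$domains_skipped, "")
    )
  ratios <- tibble::as_tibble(unclass(table))[c("pfam_id", "compartment", "ratio")]
  if (smoothing > 0) {
    ratios$ratio <- (ratios$ratio + smoothing) / (1 + smoothing * length(compartments))
  }
  scores <- pairs %>%
    dplyr::filter(.data$in_table) %>%
    dplyr::inner_join(ratios, by = "pfam_id", relationship = "many-to-many") %>%
    dplyr::group_by(.data$protein_id, .data$compartment) %>%
    dplyr::summarise(score = exp(mean(log(.data$ratio))), .groups = "drop") %>%
    dplyr::mutate(score = ifelse(is.nan(.data$score), 0, .data$score)) %>%
    dplyr::arrange(.data$protein_id, match(.data$compartment, compartments))
  list(domains = domains, scores = scores)
}

table_statuses <- function(status) {
  lv <- c("predicted", "tie", "no_pfam", "no_data", "below_threshold")
  as.list(base::table(factor(status, levels = lv)))
}

#' Score a batch of proteins (long output)
#'
#' Companion to [predict_localization()] returning the full per-compartment
#' score surface, as needed for ROC sweeps.
#'
#' @inheritParams predict_localization
#' @return A tibble (`protein_id`, `compartment`, `score`), one row per
#'   protein-compartment pair, restricted to proteins with at least one
#'   domain present in the table.
#' @export
score_proteins <- function(proteins, table, smoothing = 0, protein_ids = NULL) {
  if (is.null(protein_ids)) protein_ids <- unique(proteins$protein_id)
  eng <- batch_score_engine(proteins, table, smoothing, protein_ids)
  compartments <- unique(table$compartment)
  eng$scores %>%
    dplyr::mutate(
      protein_id = factor(.data$protein_id, levels = protein_ids),
      compartment = factor(.data$compartment, levels = compartments)
    ) %>%
    dplyr::arrange(.data$protein_id, .data$compartment) %>%
    dplyr::mutate(
      protein_id = as.character(.data$protein_id),
      compartment = as.character(.data$compartment)
    )
}

#' A small worked-example ratio table
#'
#' Two-domain toy model used in documentation examples: PF00010 is mostly
#' nuclear, PF00069 mostly plasma membrane.
#'
#' @return A `pfam_ratio_table`.
#' @export
example_ratio_table <- function() {
  counts <- tibble(
    pfam_id = c("PF00010", "PF00010", "PF00069", "PF00069"),
    compartment = c("nucleus", "cytosol", "plasma membrane", "cytosol"),
    count = c(81L, 19L, 70L, 30L)
  ) %>%
    dplyr::group_by(.data$pfam_id) %>%
    dplyr::mutate(total = sum(.data$count)) %>%
    dplyr::ungroup()
  compute_ratio_table(counts)
}

#' Format scores as percentages for human-readable reports
#'
#' @param score Numeric fractional scores in \[0, 1\].
#' @param digits Decimal places (default 1, e.g. "80.9").
#' @return Character vector of percentages without the \% sign.
#' @export
format_percent <- function(score, digits = 1) {
  formatC(100 * score, format = "f", digits = digits)
}
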