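#' Read a ranked co-expression list for one bait gene
#'
#' Expects a TSV whose columns include `gene_id` and `mutual_rank` (a
#' leading `rank` column, as in published top-300 tables, is accepted and
#' ignored; headerless 2- or 3-column files are also accepted). Identifiers
#' are normalized via [normalize_locus()], entries re-sorted by Mutual Rank
#' (MR; lower = more tightly co-expressed), and duplicate genes rejected.
#'
#' @param path Path to the TSV file.
#' @param bait_id Identifier of the bait gene whose co-expression
#'   neighborhood the list describes.
#' @return A `ranked_coexpression` tibble (`bait_id`, `rank`, `gene_id`,
#'   `mutual_rank`), sorted by MR with ranks 1..n.
#' @export
read_ranked_list <- function(path, bait_id) {
  if (!file.exists(path)) abort(paste0("ranked list file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  nm <- tolower(names(raw))
  if (all(c("gene_id", "mutual_rank") %in% nm)) {
    genes <- raw[[which(nm == "gene_id")[1]]]
    mrs <- as.numeric(raw[[which(nm == "mutual_rank")[1]]])
  } else {
    # headerless: re-read without header; last column is MR, the one before it the gene
    raw <- readr::read_tsv(path, col_names = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (ncol(raw) < 2) abort("ranked list needs gene_id and mutual_rank columns")
    genes <- raw[[ncol(raw) - 1]]
    mrs <- as.numeric(raw[[ncol(raw)]])
  }
  ranked_list(genes, mrs, bait_id)
}

#' Construct a ranked co-expression list from vectors
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param mutual_ranks Numeric MR values, all >= 1.
#' @param bait_id Bait gene identifier.
#' @return A `ranked_coexpression` tibble; see [read_ranked_list()].
#' @export
ranked_list <- function(gene_ids, mutual_ranks, bait_id) {
  gene_ids <- normalize_locus(gene_ids)
  if (anyNA(mutual_ranks)) abort("mutual_rank values must be numeric")
  if (any(mutual_ranks < 1)) abort("mutual_rank values must be >= 1")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene(s) in ranked list for bait ", bait_id, ": ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  o <- order(mutual_ranks)
  out <- tibble(
    bait_id = bait_id,
    rank = seq_along(gene_ids),
    gene_id = gene_ids[o],
    mutual_rank = mutual_ranks[o]
  )
  structure(out, class = c("ranked_coexpression", class(tibble())))
}

#' Geometric-mean average Mutual Rank
#'
#' The average MR of a gene across several bait lists is the geometric mean
#' of its per-bait MR values, `(prod(mrs))^(1/n)`, computed in log space.
#'
#' @param mrs Numeric vector of positive MR values (one per bait).
#' @return The geometric mean, a positive scalar.
#' @examples
#' average_mutual_rank(c(2, 4, 8)) # 4
#' @export
average_mutual_rank <- function(mrs) {
  if (length(mrs) == 0) abort("need at least one MR value")
  if (anyNA(mrs) || any(mrs <= 0)) abort("MR values must be positive")
  exp(mean(log(mrs)))
}

#' Largest Mutual Rank in a list
#'
#' For a published top-n list this is the n-th gene's MR, a measure of how
#' tight the bait's co-expression neighborhood is (lower = tighter).
#'
#' @param list A `ranked_coexpression` tibble.
#' @return The maximum `mutual_rank`.
#' @export
max_mr <- function(list) {
  if (nrow(list) == 0) abort("ranked list is empty")
  max(list$mutual_rank)
}

#' Intersect ranked co-expression lists across baits
#'
#' Computes every pairwise shared-gene count and the k-way intersection
#' (Venn counts) over two or more bait lists, on normalized gene ids. Genes
#' present in every list are summarized with their per-bait MRs and the
#' geometric-mean average MR; bait genes found in all lists are included and
#' flagged in `is_bait` so either convention (with or without baits) is
#' recoverable.
#'
#' @param lists List of `ranked_coexpression` tibbles with distinct baits.
#' @return An `mr_intersection` object: a list with elements
#'   \describe{
#'     \item{bait_ids}{character vector of baits}
#'     \item{pairwise}{tibble (`bait_a`, `bait_b`, `n_shared`)}
#'     \item{kway_count}{number of genes shared by all lists}
#'     \item{shared_genes}{tibble (`gene_id`, one `mr_<bait>` column per
#'       bait, `average_mr`, `is_bait`), sorted by average MR}
#'   }
#' @export
intersect_ranked_lists <- function(lists) {
  if (length(lists) < 2) abort("need at least two ranked lists to intersect")
  bait_ids <- vapply(lists, function(l) l$bait_id[1], character(1))
  if (anyDuplicated(bait_ids)) abort("bait ids must be distinct")
  gene_sets <- lapply(lists, function(l) l$gene_id)
  pair_idx <- combn(length(lists), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pair_idx)), function(j) {
    a <- pair_idx[1, j]; b <- pair_idx[2, j]
    tibble(bait_a = bait_ids[a], bait_b = bait_ids[b],
           n_shared = length(intersect(gene_sets[[a]], gene_sets[[b]])))
  })
  core <- Reduce(intersect, gene_sets)
  shared <- tibble(gene_id = core)
  for (i in seq_along(lists)) {
    mr_col <- setNames(
      lists[[i]]$mutual_rank[match(core, lists[[i]]$gene_id)],
      NULL
    )
    shared[[paste0("mr_", bait_ids[i])]] <- mr_col
  }
  if (nrow(shared) > 0) {
    mr_mat <- as.matrix(shared[, -1, drop = FALSE])
    shared$average_mr <- exp(rowMeans(log(mr_mat)))
  } else {
    shared$average_mr <- numeric()
  }
  shared$is_bait <- shared$gene_id %in% normalize_locus(bait_ids)
  shared <- dplyr::arrange(shared, .data$average_mr)
  structure(
    list(bait_ids = bait_ids, pairwise = pairwise,
         kway_count = length(core), shared_genes = shared,
         list_lengths = vapply(gene_sets, length, integer(1)),
         union_size = length(unique(unlist(gene_sets)))),
    class = "mr_intersection"
  )
}

#' @exportS3Method
print.mr_intersection <- function(x, ...) {
  cat("Mutual-Rank intersection of", length(x$bait_ids), "bait lists:",
      paste(x$bait_ids, collapse = ", "), "\n")
  cat("Pairwise shared-gene counts:\n")
  print(x$pairwise)
  cat(length(x$bait_ids), "-way intersection: ", x$kway_count, " genes\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.mr_intersection <- function(x, ...) {
  x$shared_genes
}

#' @exportS3Method
glance.mr_intersection <- function(x, ...) {
  out <- tibble(
    n_baits = length(x$bait_ids),
    kway_count = x$kway_count,
    min_pairwise = min(x$pairwise$n_shared),
    max_pairwise = max(x$pairwise$n_shared)
  )
  out
}

#' Shared-gene fractions under both denominators
#'
#' The percentage of genes shared by all baits can be quoted against the
#' per-bait list length (e.g. 124/300) or against the union of all listed
#' genes; both are reported so either convention is available.
#'
#' @param x An `mr_intersection`.
#' @return A one-row tibble with `kway_count`, `pct_of_list` (denominator:
#'   the maximum input list length) and `pct_of_union`.
#' @export
intersection_fractions <- function(x) {
  tibble(
    kway_count = x$kway_count,
    pct_of_list = 100 * x$kway_count / max(x$list_lengths),
    pct_of_union = 100 * x$kway_count / x$union_size
  )
}

#' Summarize shared genes by their joint Pfam-domain sets
#'
#' Genes in a shared co-expression set are grouped by the full set of Pfam
#' domains they carry (multi-domain proteins group by the joint set, so
#' "PF00560, PF00069, PF08263" forms one group). Groups where at least one
#' member gene has an average MR below `cutoff` are retained (strict `<`);
#' genes with no Pfam assignment are collected in an "unassigned" bucket.
#' If a trained ratio table is supplied, each group's Pfam set is scored and
#' the called localization and score are carried into the summary.
#'
#' @param shared_genes Tibble from [intersect_ranked_lists()] (`gene_id`,
#'   `average_mr`, ...).
#' @param assignments Pfam assignment tibble (`protein_id`, `pfam_id`).
#' @param cutoff Retain groups whose minimum member average MR is strictly
#'   below this (default 70).
#' @param table Optional `pfam_ratio_table` used to predict each group's
#'   localization.
#' @return A tibble with one row per retained Pfam group: `pfam_set`
#'   (comma-joined sorted accessions, or "unassigned"), `n_genes`, `genes`
#'   (list column), `min_average_mr`, and when `table` is given, `called`
#'   and `score`.
#' @export
pfam_group_summary <- function(shared_genes, assignments, cutoff = 70, table = NULL) {
  if (cutoff <= 0) abort("cutoff must be positive")
  gene_pfams <- assignments %>%
    dplyr::distinct(.data$protein_id, .data$pfam_id) %>%
    dplyr::group_by(.data$protein_id) %>%
    dplyr::summarise(pfam_set = paste(sort(.data$pfam_id), collapse = ","), .groups = "drop")
  ann <- shared_genes %>%
    dplyr::left_join(gene_pfams, by = c(gene_id = "protein_id")) %>%
    dplyr::mutate(pfam_set = dplyr::coalesce(.data$pfam_set, "unassigned"))
  groups <- ann %>%
    dplyr::group_by(.data$pfam_set) %>%
    dplyr::summarise(
      n_genes = dplyr::n(),
      genes = list(.data$gene_id),
      min_average_mr = min(.data$average_mr),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$min_average_mr < cutoff) %>%
    dplyr::arrange(.data$min_average_mr)
  if (!is.null(table)) {
    calls <- purrr::map_dfr(groups$pfam_set, function(ps) {
      if (identical(ps, "unassigned")) {
        return(tibble(called = "", score = NA_real_))
      }
      sc <- score_protein(strsplit(ps, ",", fixed = TRUE)[[1]], table)
      call <- call_localization(sc)
      tibble(called = call$called, score = call$score)
    })
    groups <- dplyr::bind_cols(groups, calls)
  }
  groups
}
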