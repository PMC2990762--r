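#' Generate a synthetic annotation corpus with known localization structure
#'
#' Each synthetic protein draws a domain count, then that many distinct Pfam
#' domains (uniformly from the inventory), then one true compartment per
#' domain from the domain's conditional distribution p(compartment | pfam).
#' Multi-domain proteins may therefore be multiply localized, exercising
#' multi-label evaluation. One annotation record is emitted per (protein,
#' true compartment), with an evidence code drawn from `evidence_mix`;
#' records with non-experimental codes are later removed by evidence
#' filtering (evidence is drawn independently of the compartment, so
#' filtering thins the training set without biasing the ratios). The truth
#' table records drawn compartments regardless of evidence.
#'
#' All output is a deterministic function of the arguments and `seed`.
#'
#' @param cond_probs Row-stochastic numeric matrix, rows named by Pfam
#'   accession, columns by compartment: p(compartment | pfam).
#' @param n_proteins Number of proteins to generate.
#' @param domain_count_probs Probabilities of a protein carrying 0, 1, 2 or 3
#'   domains (default `c(0.1, 0.6, 0.2, 0.1)`, mimicking the predominance of
#'   single-domain annotations in genome-wide Pfam tables).
#' @param evidence_mix Named probabilities over evidence codes (default
#'   `c(IDA = 0.7, IMP = 0.2, ISS = 0.1)`: mostly direct-assay evidence with
#'   a computational minority that training discards).
#' @param vocab Compartment vocabulary; its compartments must cover the
#'   columns of `cond_probs`.
#' @param seed Integer seed.
#' @return A list with tibbles `annotations` (`protein_id`, `go_id`,
#'   `evidence_code`), `assignments` (`protein_id`, `pfam_id`, `start`,
#'   `end`) and `truth` (`protein_id`, `compartment`).
#' @examples
#' cp <- matrix(c(0.8, 0.2), 1, dimnames = list("PF00001", c("nucleus", "cytosol")))
#' corpus <- simulate_annotation_corpus(cp, n_proteins = 10, seed = 1)
#' corpus$truth
#' @export
simulate_annotation_corpus <- function(cond_probs, n_proteins,
                                       domain_count_probs = c(0.1, 0.6, 0.2, 0.1),
                                       evidence_mix = c(IDA = 0.7, IMP = 0.2, ISS = 0.1),
                                       vocab = compartment_vocabulary(),
                                       seed = 1L) {
  if (n_proteins < 0) abort("n_proteins must be non-negative")
  cond_probs <- as.matrix(cond_probs)
  row_sums <- rowSums(cond_probs)
  if (any(abs(row_sums - 1) > 1e-8) || any(cond_probs < 0)) {
    abort("each row of cond_probs must be a probability distribution")
  }
  if (!all(colnames(cond_probs) %in% vocab$compartment)) {
    abort("cond_probs columns must be compartments in the vocabulary")
  }
  if (abs(sum(domain_count_probs) - 1) > 1e-8) {
    abort("domain_count_probs must sum to 1")
  }
  if (abs(sum(evidence_mix) - 1) > 1e-8 || is.null(names(evidence_mix))) {
    abort("evidence_mix must be a named probability vector")
  }
  pfams <- rownames(cond_probs)
  go_of <- setNames(vocab$go_id, vocab$compartment)
  empty <- list(
    annotations = tibble(protein_id = character(), go_id = character(),
                         evidence_code = character()),
    assignments = tibble(protein_id = character(), pfam_id = character(),
                         start = integer(), end = integer()),
    truth = tibble(protein_id = character(), compartment = character())
  )
  if (n_proteins == 0) return(empty)
  with_seed(seed, {
    protein_ids <- sprintf("SYN%06d", seq_len(n_proteins))
    n_domains <- sample(0:3, n_proteins, replace = TRUE, prob = domain_count_probs)
    per_protein <- purrr::map(seq_len(n_proteins), function(i) {
      k <- min(n_domains[i], length(pfams))
      if (k == 0) return(NULL)
      my_pfams <- sample(pfams, k)
      comps <- vapply(my_pfams, function(p) {
        sample(colnames(cond_probs), 1, prob = cond_probs[p, ])
      }, character(1))
      list(pid = protein_ids[i], pfams = my_pfams, comps = unique(comps))
    })
    per_protein <- purrr::compact(per_protein)
    assignments <- purrr::map_dfr(per_protein, function(x) {
      tibble(protein_id = x$pid, pfam_id = x$pfams,
             start = NA_integer_, end = NA_integer_)
    })
    truth <- purrr::map_dfr(per_protein, function(x) {
      tibble(protein_id = x$pid, compartment = x$comps)
    })
    annotations <- truth %>%
      dplyr::mutate(
        go_id = unname(go_of[.data$compartment]),
        evidence_code = sample(names(evidence_mix), dplyr::n(),
                               replace = TRUE, prob = evidence_mix)
      ) %>%
      dplyr::select("protein_id", "go_id", "evidence_code")
    if (nrow(assignments) == 0) return(empty)
    list(annotations = annotations, assignments = assignments, truth = truth)
  })
}

#' Write a simulated corpus to plain-text files
#'
#' Emits the three tables of [simulate_annotation_corpus()] as a GAF-dialect
#' annotation file (17 columns, `!gaf-version` header), a Pfam-assignment
#' TSV, and a truth TSV, for exercising the file-reading path.
#'
#' @param corpus List from [simulate_annotation_corpus()].
#' @param dir Output directory (created if needed).
#' @param vocab Vocabulary used to fill GO ids (unused at present; GO ids are
#'   already resolved in the corpus).
#' @return Invisibly, the three file paths (`annotations`, `assignments`,
#'   `truth`).
#' @export
write_corpus <- function(corpus, dir, vocab = compartment_vocabulary()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann_path <- file.path(dir, "annotations.gaf")
  gaf <- corpus$annotations
  lines <- c(
    "!gaf-version: 2.1",
    sprintf("TAIR\t%s\t%s\t\t%s\tREF:0000001\t%s\t\tC\t\t\tprotein\ttaxon:3702\t20100101\tTAIR\t\t",
            gaf$protein_id, gaf$protein_id, gaf$go_id, gaf$evidence_code)
  )
  readr::write_lines(lines, ann_path)
  asn_path <- file.path(dir, "assignments.tsv")
  readr::write_tsv(corpus$assignments, asn_path, col_names = FALSE, na = "")
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(corpus$truth, truth_path)
  invisible(c(annotations = ann_path, assignments = asn_path, truth = truth_path))
}

#' Generate synthetic Mutual-Rank ranked lists with exact designed overlaps
#'
#' Builds one ranked list per bait such that every realized pairwise
#' intersection and the k-way intersection match the designed sizes exactly.
#' The construction populates three kinds of Venn regions: a common core
#' shared by all baits (`kway`), a pair-exclusive region for each bait pair
#' (`pairwise - kway`), and per-bait unique genes filling each list to
#' `list_length`. MR values are jittered ranks: position-proportional values
#' plus Gaussian noise, re-sorted, floored at 1, so each list is strictly
#' ordered.
#'
#' When `include_baits` is `TRUE` (default) the bait genes themselves are
#' placed in the common core — as in real co-expression neighborhoods where
#' tightly co-regulated baits retrieve each other — which requires
#' `kway >= n_baits`.
#'
#' @param n_baits Number of bait lists (>= 2).
#' @param list_length Genes per list (default 300, the conventional cut).
#' @param pairwise Designed pairwise intersection sizes: a single number or
#'   a vector of length `choose(n_baits, 2)` in [combn()] column order.
#' @param kway Designed size of the all-baits intersection.
#' @param mr_scale Mean MR spacing between consecutive ranks (default 1.2,
#'   so a 300-gene list tops out near MR 360, in the range published
#'   top-300 lists reach).
#' @param mr_jitter Standard deviation of the rank noise (default 5).
#' @param include_baits Place bait genes in the common core (default TRUE).
#' @param seed Integer seed; outputs are deterministic given it.
#' @return A list of `ranked_coexpression` tibbles, baits named
#'   `BAIT1..BAITk`, genes named `GENE000001...`.
#' @examples
#' lists <- simulate_mr_lists(pairwise = c(165, 121, 123), kway = 83, seed = 1)
#' intersect_ranked_lists(lists)$kway_count # 83
#' @export
simulate_mr_lists <- function(n_baits = 3, list_length = 300,
                              pairwise = 120, kway = 80,
                              mr_scale = 1.2, mr_jitter = 5,
                              include_baits = TRUE, seed = 1L) {
  if (n_baits < 2) abort("need at least two baits")
  n_pairs <- choose(n_baits, 2)
  if (length(pairwise) == 1) pairwise <- rep(pairwise, n_pairs)
  if (length(pairwise) != n_pairs) {
    abort(paste0("pairwise must have length 1 or ", n_pairs))
  }
  if (any(kway > pairwise)) {
    abort(paste0("infeasible design: kway (", kway,
                 ") exceeds a pairwise overlap (", min(pairwise), ")"))
  }
  if (any(pairwise > list_length)) {
    abort("infeasible design: a pairwise overlap exceeds list_length")
  }
  if (include_baits && kway < n_baits) {
    abort("kway must be >= n_baits to hold the bait genes (or set include_baits = FALSE)")
  }
  pair_idx <- combn(n_baits, 2)
  pair_only <- pairwise - kway
  # unique genes per bait after core and pair-exclusive regions
  unique_n <- vapply(seq_len(n_baits), function(i) {
    list_length - kway - sum(pair_only[apply(pair_idx == i, 2, any)])
  }, numeric(1))
  if (any(unique_n < 0)) {
    i <- which(unique_n < 0)[1]
    abort(paste0("infeasible design: bait ", i, "'s shared regions total ",
                 list_length - unique_n[i], " genes, exceeding list_length ",
                 list_length))
  }
  bait_ids <- paste0("BAIT", seq_len(n_baits))
  with_seed(seed, {
    counter <- 0L
    next_genes <- function(n) {
      ids <- sprintf("GENE%06d", counter + seq_len(n))
      counter <<- counter + n
      ids
    }
    n_core_fill <- kway - if (include_baits) n_baits else 0L
    core <- c(if (include_baits) bait_ids, next_genes(n_core_fill))
    pair_genes <- lapply(seq_len(n_pairs), function(j) next_genes(pair_only[j]))
    uniq_genes <- lapply(seq_len(n_baits), function(i) next_genes(unique_n[i]))
    lapply(seq_len(n_baits), function(i) {
      members <- c(core,
                   unlist(pair_genes[apply(pair_idx == i, 2, any)]),
                   uniq_genes[[i]])
      # random ordering, but baits near the top as in real neighborhoods
      others <- sample(setdiff(members, bait_ids))
      ordered <- c(intersect(members, bait_ids), others)
      mrs <- sort(pmax(seq_along(ordered) * mr_scale + rnorm(length(ordered), 0, mr_jitter), 1))
      ranked_list(ordered, mrs, bait_ids[i])
    })
  })
}

#' Write ranked lists to TSV files
#'
#' One file per bait, columns `rank`, `gene_id`, `mutual_rank` — the layout
#' [read_ranked_list()] reads back.
#'
#' @param lists List of `ranked_coexpression` tibbles.
#' @param dir Output directory.
#' @return Invisibly, the written file paths named by bait.
#' @export
write_ranked_lists <- function(lists, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(lists, function(l) {
    path <- file.path(dir, paste0(l$bait_id[1], ".tsv"))
    out <- l
    out$mutual_rank <- format(out$mutual_rank, digits = 17, scientific = FALSE, trim = TRUE)
    readr::write_tsv(out[c("rank", "gene_id", "mutual_rank")], path)
    path
  }, character(1))
  invisible(setNames(paths, vapply(lists, function(l) l$bait_id[1], character(1))))
}
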