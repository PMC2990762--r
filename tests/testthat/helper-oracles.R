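# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately avoid the package's own code paths.

# Triple-loop count of (pfam, compartment) co-occurrences: for each protein,
# each distinct pfam, each compartment membership, one increment.
oracle_count_matrix <- function(protein_compartments, assignments) {
  counts <- list()
  for (pid in unique(assignments$protein_id)) {
    pfams <- unique(assignments$pfam_id[assignments$protein_id == pid])
    comps <- protein_compartments$compartment[protein_compartments$protein_id == pid]
    for (pf in pfams) {
      for (cm in comps) {
        key <- paste(pf, cm, sep = "\r")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  if (length(counts) == 0) {
    return(tibble::tibble(pfam_id = character(), compartment = character(), count = integer()))
  }
  keys <- strsplit(names(counts), "\r", fixed = TRUE)
  tibble::tibble(
    pfam_id = vapply(keys, `[`, "", 1),
    compartment = vapply(keys, `[`, "", 2),
    count = unlist(counts, use.names = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-protein loop confusion tally for one compartment, one-vs-rest.
oracle_confusion <- function(calls, truth, compartment) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(calls))) {
    if (calls$status[i] %in% c("no_pfam", "no_data")) next
    called <- compartment %in% calls$compartments[[i]]
    istrue <- any(truth$compartment[truth$protein_id == calls$protein_id[i]] == compartment)
    if (called && istrue) tp <- tp + 1L
    else if (called && !istrue) fp <- fp + 1L
    else if (!called && istrue) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Nested-loop pairwise and k-way intersection counts over character vectors.
oracle_intersections <- function(gene_sets) {
  k <- length(gene_sets)
  pairwise <- c()
  for (a in seq_len(k - 1)) {
    for (b in seq((a + 1), k)) {
      n <- 0L
      for (g in gene_sets[[a]]) if (g %in% gene_sets[[b]]) n <- n + 1L
      pairwise <- c(pairwise, n)
    }
  }
  core <- 0L
  for (g in gene_sets[[1]]) {
    if (all(vapply(gene_sets[-1], function(s) g %in% s, logical(1)))) core <- core + 1L
  }
  list(pairwise = pairwise, kway = core)
}

# Draw a feasible 3-bait overlap design: core, then pairwise >= core, with
# each bait's shared regions fitting inside the list length.
random_feasible_design <- function(list_length = 60) {
  repeat {
    kway <- sample(3:20, 1)
    pairwise <- kway + sample(0:10, 3, replace = TRUE)
    pair_idx <- utils::combn(3, 2)
    pair_only <- pairwise - kway
    uniq <- vapply(1:3, function(i) {
      list_length - kway - sum(pair_only[apply(pair_idx == i, 2, any)])
    }, numeric(1))
    if (all(uniq >= 0)) return(list(pairwise = pairwise, kway = kway, list_length = list_length))
  }
}

# A compartment-pure ratio table: each pfam fully committed to one compartment.
pure_ratio_table <- function(pfams, compartments) {
  counts <- tibble::tibble(
    pfam_id = pfams,
    compartment = compartments,
    count = 10L,
    total = 10L
  )
  compute_ratio_table(counts)
}

# Small mixed-evidence annotation fixture: 3 IDA, 2 IMP, 1 ISS.
mixed_evidence_records <- function() {
  tibble::tibble(
    protein_id = paste0("AT1G0000", 1:6),
    go_id = rep(c("GO:0005634", "GO:0005886"), 3),
    evidence_code = c("IDA", "IDA", "IDA", "IMP", "IMP", "ISS")
  )
}
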