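make_calls <- function(protein_id, called_sets, status = NULL) {
  tibble::tibble(
    protein_id = protein_id,
    called = vapply(called_sets, paste, "", collapse = "/"),
    compartments = called_sets,
    score = 1,
    status = status %||% ifelse(lengths(called_sets) > 1, "tie",
                                ifelse(lengths(called_sets) == 0, "no_data", "predicted"))
  )
}

test_that("confusion counts follow one-vs-rest semantics", {
  calls <- make_calls(c("P1", "P2"), list("nucleus", "nucleus"))
  truth <- tibble::tibble(protein_id = c("P1", "P2"), compartment = "nucleus")
  cc <- confusion_counts(calls, truth, "nucleus")
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]), c(tp = 2L, fp = 0L, tn = 0L, fn = 0L))
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, cc$n_evaluated)

  # 6 proteins: 2 Golgi hits, 1 false call, 1 miss, 2 correctly negative
  calls6 <- make_calls(
    sprintf("Q%d", 1:6),
    list("Golgi apparatus", "Golgi apparatus", "Golgi apparatus",
         "nucleus", "nucleus", "cytosol")
  )
  truth6 <- tibble::tibble(
    protein_id = c("Q1", "Q2", "Q3", "Q4", "Q5", "Q6", "Q4"),
    compartment = c("Golgi apparatus", "Golgi apparatus", "nucleus",
                    "Golgi apparatus", "nucleus", "cytosol", "nucleus")
  )
  cc6 <- confusion_counts(calls6, truth6, "Golgi apparatus")
  expect_equal(unlist(cc6[c("tp", "fp", "tn", "fn")]),
               c(tp = 2L, fp = 1L, tn = 2L, fn = 1L))

  empty <- confusion_counts(calls6[0, ], truth6, "Golgi apparatus")
  expect_true(all(unlist(empty[c("tp", "fp", "tn", "fn")]) == 0))

  expect_error(
    confusion_counts(make_calls("ZZ", list("nucleus")), truth6, "nucleus"),
    "absent from truth"
  )
})

test_that("uncovered proteins are excluded by default and countable on request", {
  calls <- dplyr::bind_rows(
    make_calls(c("P1", "P2"), list("nucleus", "nucleus")),
    make_calls("P3", list(character()), status = "no_data")
  )
  truth <- tibble::tibble(protein_id = c("P1", "P2", "P3"), compartment = "nucleus")
  excl <- confusion_counts(calls, truth, "nucleus")
  expect_equal(excl$n_evaluated, 2L)
  expect_equal(excl$n_uncovered, 1L)
  incl <- confusion_counts(calls, truth, "nucleus", include_uncovered = TRUE)
  expect_equal(incl$n_evaluated, 3L)
  expect_equal(incl$fn, 1L)
})

test_that("sensitivity and specificity follow their definitions, NA when undefined", {
  m <- performance_metrics(tibble::tibble(tp = 2L, fp = 0L, tn = 0L, fn = 0L))
  expect_equal(m$sensitivity, 1)
  expect_true(is.na(m$specificity))

  m2 <- performance_metrics(tibble::tibble(tp = 13L, fp = 4L, tn = 76L, fn = 7L))
  expect_equal(m2$sensitivity, 0.65)
  expect_equal(m2$specificity, 0.95)
})

test_that("evaluator agrees with a brute-force recount on random small corpora", {
  set.seed(31)
  comps <- compartment_vocabulary()$compartment
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    pids <- sprintf("P%03d", seq_len(n))
    truth <- tibble::tibble(
      protein_id = rep(pids, times = sample(1:2, n, replace = TRUE))
    ) |>
      dplyr::mutate(compartment = sample(comps, dplyr::n(), replace = TRUE)) |>
      dplyr::distinct()
    status <- sample(c("predicted", "tie", "no_data"), n, replace = TRUE,
                     prob = c(0.7, 0.15, 0.15))
    called_sets <- lapply(status, function(s) {
      if (s == "no_data") character()
      else sample(comps, if (s == "tie") 2 else 1)
    })
    calls <- make_calls(pids, called_sets, status = status)
    for (cmp in sample(comps, 4)) {
      got <- confusion_counts(calls, truth, cmp)
      want <- oracle_confusion(calls, truth, cmp)
      expect_equal(unlist(got[c("tp", "fp", "tn", "fn")]), want)
      pm <- performance_metrics(got)
      if (!is.na(pm$sensitivity)) {
        expect_equal(pm$sensitivity, want["tp"] / (want["tp"] + want["fn"]),
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("performance_report covers the ten reporting compartments", {
  calls <- make_calls(c("P1", "P2"), list("nucleus", "vacuole"))
  truth <- tibble::tibble(protein_id = c("P1", "P2"), compartment = c("nucleus", "vacuole"))
  rep <- performance_report(calls, truth)
  expect_equal(nrow(rep), 10)
  expect_false("cell plate" %in% rep$compartment)
  expect_true(all(rep$predictor == "pfam"))
})

test_that("ROC sweep is monotone, maximal at threshold zero, and perfect on pure corpora", {
  comps <- compartment_vocabulary()$compartment[1:6]
  tab <- pure_ratio_table(sprintf("PF%05d", 1:6), comps)
  set.seed(41)
  n <- 300
  pf_of <- sample(sprintf("PF%05d", 1:6), n, replace = TRUE)
  proteins <- tibble::tibble(protein_id = sprintf("P%03d", 1:n), pfam_id = pf_of)
  truth <- tibble::tibble(protein_id = proteins$protein_id,
                          compartment = comps[match(pf_of, sprintf("PF%05d", 1:6))])
  sc <- score_proteins(proteins, tab)
  roc <- roc_sweep(sc, truth, "nucleus", step = 0.05)
  expect_true(all(diff(roc$threshold) > 0))
  expect_true(all(diff(roc$tpr) <= 1e-12))
  expect_true(all(diff(roc$fpr) <= 1e-12))
  expect_equal(roc$tpr[1], max(roc$tpr))
  expect_equal(attr(roc, "auc"), 1)
})

test_that("ROC AUC is near 0.5 when labels are shuffled against scores", {
  comps <- compartment_vocabulary()$compartment[1:6]
  set.seed(51)
  counts <- tibble::tibble(
    pfam_id = rep(sprintf("PF%05d", 1:6), each = 3),
    compartment = unlist(lapply(1:6, function(i) sample(comps, 3))),
    count = as.integer(sample(5:30, 18, replace = TRUE))
  ) |>
    dplyr::group_by(pfam_id) |>
    dplyr::mutate(total = sum(count)) |>
    dplyr::ungroup()
  tab <- compute_ratio_table(counts)
  n <- 1000
  pf_of <- sample(sprintf("PF%05d", 1:6), n, replace = TRUE)
  proteins <- tibble::tibble(protein_id = sprintf("P%04d", 1:n), pfam_id = pf_of)
  truth <- tibble::tibble(protein_id = proteins$protein_id,
                          compartment = sample(comps, n, replace = TRUE))
  sc <- score_proteins(proteins, tab)
  roc <- roc_sweep(sc, truth, comps[1])
  expect_lt(abs(attr(roc, "auc") - 0.5), 0.05)
})

test_that("trapezoid AUC agrees with pROC on graded scores", {
  skip_if_not_installed("pROC")
  comps <- compartment_vocabulary()$compartment[1:4]
  set.seed(61)
  counts <- tibble::tibble(
    pfam_id = rep(sprintf("PF%05d", 1:8), each = 2),
    compartment = unlist(lapply(1:8, function(i) sample(comps, 2))),
    count = as.integer(sample(1:40, 16, replace = TRUE))
  ) |>
    dplyr::group_by(pfam_id) |>
    dplyr::mutate(total = sum(count)) |>
    dplyr::ungroup()
  tab <- compute_ratio_table(counts)
  n <- 400
  pf_of <- sample(sprintf("PF%05d", 1:8), n, replace = TRUE)
  proteins <- tibble::tibble(protein_id = sprintf("P%04d", 1:n), pfam_id = pf_of)
  ratios <- tibble::as_tibble(unclass(tab))
  # truth drawn from each pfam's own ratio distribution
  truth <- tibble::tibble(
    protein_id = proteins$protein_id,
    compartment = vapply(pf_of, function(pf) {
      r <- ratios[ratios$pfam_id == pf, ]
      sample(r$compartment, 1, prob = r$ratio + 1e-9)
    }, "")
  )
  sc <- score_proteins(proteins, tab)
  cmp <- comps[2]
  roc <- roc_sweep(sc, truth, cmp, step = 0.001)
  # independent oracle: rank-based AUC on the same called-score variable
  per <- sc |>
    dplyr::group_by(protein_id) |>
    dplyr::summarise(
      s = ifelse(max(score) - score[compartment == cmp] <= 1e-9,
                 score[compartment == cmp], 0),
      .groups = "drop"
    )
  labels <- as.integer(per$protein_id %in% truth$protein_id[truth$compartment == cmp])
  proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, per$s, quiet = TRUE,
                                             direction = "<")))
  expect_equal(attr(roc, "auc"), proc_auc, tolerance = 0.02)
})

test_that("ROC and performance plots build without error", {
  calls <- make_calls(c("P1", "P2"), list("nucleus", "vacuole"))
  truth <- tibble::tibble(protein_id = c("P1", "P2"), compartment = c("nucleus", "vacuole"))
  rep <- performance_report(calls, truth)
  expect_s3_class(plot_performance(rep), "ggplot")
  tab <- example_ratio_table()
  proteins <- tibble::tibble(protein_id = c("A", "B"), pfam_id = c("PF00010", "PF00069"))
  sc <- score_proteins(proteins, tab)
  roc <- roc_sweep(sc, tibble::tibble(protein_id = c("A", "B"),
                                      compartment = c("nucleus", "plasma membrane")),
                   "nucleus", step = 0.25)
  expect_s3_class(autoplot(roc), "ggplot")
})
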