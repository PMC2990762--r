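#' Normalize locus identifiers
#'
#' Arabidopsis (AGI) loci are uppercased and splice-variant suffixes such as
#' ".1" stripped, so annotation and domain tables join on the gene locus.
#' Rice RAP identifiers ("OsNNgNNNNNNN") keep their mixed case.
#'
#' @param ids Character vector of locus identifiers.
#' @return Character vector of normalized identifiers.
#' @examples
#' normalize_locus(c("at5g48560.1", "Os01g0926400"))
#' @export
normalize_locus <- function(ids) {
  ids <- sub("\\.\\d+$", "", ids)
  agi <- grepl("^at[1-5cm]g\\d{5}$", ids, ignore.case = TRUE)
  ids[agi] <- toupper(ids[agi])
  ids
}

#' Read GO annotation records
#'
#' Reads either a GAF 2.x file (17 tab-separated columns, `!` comment lines)
#' or a simplified three-column TSV (`protein_id`, `go_id`, `evidence_code`,
#' no header). Lines that do not yield a well-formed record (missing fields or
#' a GO id not matching `GO:\\d{7}`) are dropped with a warning; the number
#' dropped is attached as the `n_malformed` attribute.
#'
#' When reading GAF, rows with a negating qualifier (any qualifier containing
#' "NOT") are excluded.
#'
#' @param path Path to the annotation file.
#' @param format `"gaf"`, `"tsv"`, or `"auto"` (default: sniff by column
#'   count of the first data line).
#' @return A tibble with columns `protein_id`, `go_id`, `evidence_code`, one
#'   row per surviving annotation line, in file order.
#' @export
read_annotations <- function(path, format = c("auto", "gaf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(structure(
      tibble(protein_id = character(), go_id = character(), evidence_code = character()),
      n_malformed = 0L
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (length(fields[[1]]) >= 15) "gaf" else "tsv"
  }
  if (format == "gaf") {
    keep_qualifier <- vapply(fields, function(f) {
      length(f) < 4 || !grepl("(^|\\|)NOT($|\\|)", f[4])
    }, logical(1))
    recs <- lapply(fields, function(f) {
      if (length(f) < 7) return(c(NA, NA, NA))
      c(f[2], f[5], f[7])
    })
  } else {
    keep_qualifier <- rep(TRUE, length(fields))
    recs <- lapply(fields, function(f) {
      if (length(f) < 3) return(c(NA, NA, NA))
      f[1:3]
    })
  }
  mat <- do.call(rbind, recs)
  out <- tibble(
    protein_id = normalize_locus(mat[, 1]),
    go_id = mat[, 2],
    evidence_code = mat[, 3]
  )
  ok <- keep_qualifier &
    !is.na(out$protein_id) & nzchar(out$protein_id) &
    !is.na(out$evidence_code) & nzchar(out$evidence_code) &
    !is.na(out$go_id) & grepl("^GO:\\d{7}$", out$go_id)
  n_malformed <- sum(!ok & keep_qualifier)
  if (n_malformed > 0) {
    warn(paste0(n_malformed, " malformed annotation line(s) dropped from ", path))
  }
  structure(out[ok, ], n_malformed = n_malformed)
}

#' Filter annotation records by GO evidence code
#'
#' The predictor trains only on experimentally evidenced localizations; the
#' default keeps IDA ("inferred from direct assay") records, discarding
#' computational evidence such as ISS or IEA.
#'
#' @param records Annotation tibble (`protein_id`, `go_id`, `evidence_code`).
#' @param allowed Character vector of evidence codes to keep (default `"IDA"`).
#' @return The subsequence of `records` whose evidence code is allowed,
#'   original order preserved.
#' @export
filter_evidence <- function(records, allowed = "IDA") {
  if (length(allowed) == 0) abort("'allowed' must name at least one evidence code")
  dplyr::filter(records, .data$evidence_code %in% allowed)
}

#' Map annotated GO terms to compartment memberships
#'
#' A protein belongs to a compartment if it carries at least one annotation
#' whose GO id maps to it; repeated annotations to the same compartment
#' collapse to a single membership. Records whose GO id is absent from the
#' vocabulary are dropped; their count is attached as attribute `n_unmapped`.
#'
#' @param records Evidence-filtered annotation tibble.
#' @param vocab Compartment vocabulary tibble (default [compartment_vocabulary()]).
#' @param expansion Optional two-column tibble (`go_id`, `maps_to`) rewriting
#'   annotation GO ids to vocabulary GO ids before matching, e.g. to fold
#'   descendant terms into their parents. No ontology reasoning is performed.
#' @return A tibble with columns `protein_id`, `compartment`; one row per
#'   distinct membership.
#' @export
map_compartments <- function(records, vocab = compartment_vocabulary(), expansion = NULL) {
  vocab <- validate_vocabulary(vocab)
  if (!is.null(expansion)) {
    idx <- match(records$go_id, expansion$go_id)
    hit <- !is.na(idx)
    records$go_id[hit] <- expansion$maps_to[idx[hit]]
  }
  joined <- dplyr::inner_join(records, vocab, by = "go_id")
  out <- dplyr::distinct(joined, .data$protein_id, .data$compartment)
  structure(out, n_unmapped = nrow(records) - nrow(joined))
}

#' Read Pfam domain assignments
#'
#' Expects a tab-separated file with at least two columns: `protein_id` and
#' `pfam_id`, optionally followed by 1-based `start` and `end` residue
#' coordinates. Rows whose accession does not match `PF\\d{5}` are rejected
#' with a warning. Duplicate rows are kept; de-duplication happens when
#' counting (a repeated domain in one protein counts once).
#'
#' @param path Path to the assignment TSV (no header expected; a header row
#'   starting with "protein_id" is skipped if present).
#' @return A tibble with columns `protein_id`, `pfam_id`, `start`, `end`.
#' @export
read_pfam_assignments <- function(path) {
  if (!file.exists(path)) abort(paste0("pfam assignment file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 && startsWith(tolower(lines[1]), "protein_id")) {
    lines <- lines[-1]
  }
  empty <- tibble(
    protein_id = character(), pfam_id = character(),
    start = integer(), end = integer()
  )
  if (length(lines) == 0) return(empty)
  # rows may have 2-4 fields (coordinates optional per row)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  field <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))
  if (any(lengths(fields) < 2)) {
    warn(paste0(sum(lengths(fields) < 2), " row(s) with fewer than 2 columns rejected"))
    keep <- lengths(fields) >= 2
    fields <- fields[keep]
    if (length(fields) == 0) return(empty)
  }
  out <- tibble(
    protein_id = normalize_locus(field(1)),
    pfam_id = field(2),
    start = suppressWarnings(as.integer(field(3))),
    end = suppressWarnings(as.integer(field(4)))
  )
  bad <- !grepl("^PF\\d{5}$", out$pfam_id)
  if (any(bad)) {
    warn(paste0(sum(bad), " row(s) with malformed Pfam accession rejected (e.g. '",
                out$pfam_id[which(bad)[1]], "')"))
    out <- out[!bad, ]
  }
  bad_coord <- !is.na(out$start) & !is.na(out$end) & (out$start < 1 | out$start > out$end)
  if (any(bad_coord)) {
    warn(paste0(sum(bad_coord), " row(s) with invalid coordinates rejected"))
    out <- out[!bad_coord, ]
  }
  out
}
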