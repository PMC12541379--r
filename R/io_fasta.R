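# Reading proteomes from per-protein amino-acid FASTA and annotation tables.
#
# The default grouping convention follows INPHARED-style protein ids, where
# the genome accession is the record id with its final underscore-delimited
# suffix removed (e.g. MZ747518_00043 -> MZ747518). An explicit protein ->
# accession map overrides the convention.

#' Read a per-protein FASTA file grouped into proteomes
#'
#' @param fasta_path Path to an amino-acid FASTA file.
#' @param grouping Either `"prefix"` (strip the suffix after the last
#'   underscore of the record id; the default) or a data frame / TSV path
#'   with columns `protein_id` and `genome_accession` mapping records
#'   explicitly.
#' @return Tibble with one row per accepted protein: `protein_id`,
#'   `genome_accession`, `sequence`, `description`. Records that match no
#'   accession under an explicit map are returned in the `rejects` attribute
#'   (and a warning is raised), never silently dropped. Record order is
#'   preserved.
#' @export
read_proteomes <- function(fasta_path, grouping = "prefix") {
  seqs <- tryCatch(
    Biostrings::readAAStringSet(fasta_path),
    error = function(e) abort(
      sprintf("unparseable FASTA '%s': %s", fasta_path, conditionMessage(e)),
      class = "phagempr_format_error"
    )
  )
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  recs <- tibble(
    protein_id = ids,
    sequence = as.character(seqs),
    description = desc
  )
  if (anyDuplicated(recs$protein_id)) {
    abort("duplicate protein ids in FASTA", class = "phagempr_format_error")
  }
  if (is.character(grouping) && length(grouping) == 1L && grouping == "prefix") {
    recs$genome_accession <- accession_from_id(recs$protein_id)
    rejects <- recs[0, ]
  } else {
    map <- grouping
    if (is.character(map) && length(map) == 1L) {
      map <- readr::read_tsv(map, show_col_types = FALSE)
    }
    stopifnot(is.data.frame(map),
              all(c("protein_id", "genome_accession") %in% names(map)))
    idx <- match(recs$protein_id, map$protein_id)
    recs$genome_accession <- map$genome_accession[idx]
    rejects <- recs[is.na(idx), ]
    if (nrow(rejects) > 0L) {
      warn(sprintf("%d FASTA record(s) matched no accession in the explicit map; see attr(,'rejects')",
                   nrow(rejects)))
    }
    recs <- recs[!is.na(idx), ]
  }
  if (any(!nzchar(recs$genome_accession))) {
    abort("empty genome accession derived for at least one record",
          class = "phagempr_format_error")
  }
  out <- dplyr::relocate(recs, "protein_id", "genome_accession", "sequence", "description")
  attr(out, "rejects") <- as_tibble(rejects)
  out
}

#' Derive the genome accession from an INPHARED-style protein id
#'
#' Strips the suffix after the last underscore; ids without an underscore are
#' returned unchanged (the record is its own proteome).
#' @param protein_id Character vector of protein ids.
#' @return Character vector of accessions.
#' @export
accession_from_id <- function(protein_id) {
  ifelse(grepl("_", protein_id), sub("_[^_]*$", "", protein_id), protein_id)
}

#' Split a proteome table into per-accession record tables
#'
#' @param records Tibble from [read_proteomes()].
#' @return Named list of tibbles, one per genome accession (first-appearance
#'   order), each non-empty.
#' @export
split_proteomes <- function(records) {
  stopifnot(is.data.frame(records), "genome_accession" %in% names(records))
  acc <- unique(records$genome_accession)
  setNames(lapply(acc, function(a) records[records$genome_accession == a, , drop = FALSE]), acc)
}

#' Read an annotation table keyed by genome accession
#'
#' Accepts TSV or CSV (by extension). The table must contain an `accession`
#' column; missing rank columns are added filled with the sentinel
#' `"unclassified"`.
#'
#' @param path Path to a TSV/CSV annotation table.
#' @return Tibble with `accession` plus the rank columns of
#'   [taxonomy_ranks()] and any extra columns present.
#' @export
read_annotations <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  tab <- reader(path, show_col_types = FALSE)
  if (!"accession" %in% names(tab)) {
    abort("annotation table must have an 'accession' column",
          class = "phagempr_format_error")
  }
  if (anyDuplicated(tab$accession)) {
    abort("annotation table has duplicate accessions", class = "phagempr_format_error")
  }
  for (r in taxonomy_ranks()) {
    if (!r %in% names(tab)) tab[[r]] <- UNCLASSIFIED
    tab[[r]] <- ifelse(is_sentinel(tab[[r]]), UNCLASSIFIED, as.character(tab[[r]]))
  }
  as_tibble(tab)
}

#' Flag accessions whose protein annotations contain keywords
#'
#' Case-insensitive substring matching of free-text protein descriptions
#' (e.g. flagging proteomes that encode an integrase), aggregated to one
#' boolean per accession and keyword.
#'
#' @param protein_annotations Data frame with columns `protein_id`,
#'   `genome_accession` and `description` (free text), or a named character
#'   vector of descriptions whose names are protein ids (accessions then
#'   derived via [accession_from_id()]).
#' @param keywords Character vector of keywords.
#' @return Tibble with `accession` and one logical `has_<keyword>` column per
#'   keyword; empty inputs give zero rows.
#' @export
extract_keyword_flags <- function(protein_annotations, keywords) {
  stopifnot(is.character(keywords))
  if (is.character(protein_annotations)) {
    protein_annotations <- tibble(
      protein_id = names(protein_annotations) %||% character(0),
      genome_accession = accession_from_id(names(protein_annotations) %||% character(0)),
      description = unname(protein_annotations)
    )
  }
  tab <- as_tibble(protein_annotations)
  if (nrow(tab) == 0L) {
    out <- tibble(accession = character(0))
    for (k in keywords) out[[flag_name(k)]] <- logical(0)
    return(out)
  }
  out <- tab |>
    group_by(accession = .data$genome_accession) |>
    summarise(
      !!!setNames(
        lapply(keywords, function(k) {
          rlang::quo(any(stringr::str_detect(
            stringr::str_to_lower(.data$description),
            stringr::fixed(tolower(!!k))
          )))
        }),
        flag_name(keywords)
      ),
      .groups = "drop"
    )
  out
}

flag_name <- function(keyword) {
  paste0("has_", gsub("[^a-z0-9]+", "_", tolower(keyword)))
}
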