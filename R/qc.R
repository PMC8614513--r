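# Ortholog-group quality control: CDS validation, translation, and
# single- vs multigene family classification.

translate_codon_vector <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  vapply(codons, function(cd) {
    if (grepl("N", cd, fixed = TRUE)) return("X")
    aa <- gc[[cd]]
    if (is.null(aa)) stop("untranslatable codon: ", cd)
    aa
  }, character(1), USE.NAMES = FALSE)
}

#' Validate a coding sequence
#'
#' A CDS is valid when its length is a multiple of three and it contains no
#' in-frame stop codon before the final codon. A single terminal stop codon
#' is trimmed rather than failing the gene (set `trim_terminal_stop = FALSE`
#' to count it as an internal stop instead). Characters other than
#' `A, C, G, T, N` are a format error.
#'
#' @param cds Nucleotide sequence (character scalar).
#' @param trim_terminal_stop Trim a trailing stop codon (default `TRUE`).
#' @return List: `valid` (logical), `reason` (`NA` if valid), `cds` (the
#'   possibly trimmed sequence).
#' @export
validate_cds <- function(cds, trim_terminal_stop = TRUE) {
  stopifnot(is.character(cds), length(cds) == 1L, nzchar(cds))
  cds <- toupper(cds)
  if (grepl("[^ACGTN]", cds)) stop("non-nucleotide characters in CDS")
  if (nchar(cds) %% 3L != 0L)
    return(list(valid = FALSE, reason = "length_not_multiple_of_three", cds = cds))
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- Biostrings::GENETIC_CODE
  is_stop <- vapply(codons, function(cd) {
    !grepl("N", cd, fixed = TRUE) && gc[[cd]] == "*"
  }, logical(1))
  n <- length(codons)
  if (trim_terminal_stop && n > 1L && is_stop[n]) {
    codons <- codons[-n]; is_stop <- is_stop[-n]
  }
  if (any(is_stop))
    return(list(valid = FALSE, reason = "internal_stop_codon", cds = cds))
  list(valid = TRUE, reason = NA_character_,
       cds = paste0(codons, collapse = ""))
}

#' Translate a valid CDS
#'
#' Standard-code translation; codons containing `N` translate to `X`. An
#' internal stop codon is an error (run [validate_cds()] first).
#'
#' @param cds Nucleotide sequence, length a multiple of three (a terminal
#'   stop codon is dropped).
#' @return Protein sequence (character scalar).
#' @export
translate_cds <- function(cds) {
  v <- validate_cds(cds)
  if (!v$valid) stop("invalid CDS (", v$reason, ")")
  codons <- substring(v$cds, seq(1, nchar(v$cds), 3), seq(3, nchar(v$cds), 3))
  paste0(translate_codon_vector(codons), collapse = "")
}

#' Filter ortholog groups on CDS validity
#'
#' An ortholog group is excluded when any member CDS fails [validate_cds()].
#'
#' @param groups Named list of ortholog groups; each group is a named
#'   character vector of CDS sequences (names = taxa).
#' @param trim_terminal_stop Passed to [validate_cds()].
#' @return List with `retained` (subset of `groups`, terminal stops trimmed)
#'   and `report` (data frame: group, taxon, reason for each exclusion).
#' @export
filter_ortholog_groups <- function(groups, trim_terminal_stop = TRUE) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  rows <- list()
  retained <- list()
  for (g in names(groups)) {
    verdicts <- lapply(groups[[g]], validate_cds,
                       trim_terminal_stop = trim_terminal_stop)
    bad <- !vapply(verdicts, `[[`, logical(1), "valid")
    if (any(bad)) {
      for (tx in names(verdicts)[bad]) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, taxon = tx, reason = verdicts[[tx]]$reason,
          stringsAsFactors = FALSE)
      }
    } else {
      retained[[g]] <- vapply(verdicts, `[[`, character(1), "cds")
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), taxon = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(retained = retained, report = report)
}

#' Classify a gene family as single- or multigene
#'
#' A family is `"multi"` when any species contributes two or more members,
#' `"single"` otherwise.
#'
#' @param members Data frame with columns `taxon` and `gene_id` (one row per
#'   family member), or a character vector of taxa (one entry per member).
#' @return `"single"` or `"multi"`.
#' @export
classify_family <- function(members) {
  taxa <- if (is.data.frame(members)) members$taxon else members
  if (length(taxa) < 1L) stop("family must have at least one member")
  if (max(table(taxa)) >= 2L) "multi" else "single"
}

#' Classify every family in a family map
#'
#' @param family_map Data frame with columns `gene_id`, `family_id`, `taxon`.
#' @return Data frame: `family_id`, `class` (`single`/`multi`).
#' @export
classify_families <- function(family_map) {
  stopifnot(all(c("gene_id", "family_id", "taxon") %in% names(family_map)))
  cls <- vapply(split(family_map$taxon, family_map$family_id),
                classify_family, character(1))
  data.frame(family_id = names(cls), class = unname(cls),
             stringsAsFactors = FALSE)
}
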