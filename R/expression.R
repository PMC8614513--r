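# Tissue-specificity (tau) and expression-level comparison of selected
# genes against their closest paralogous non-selected family members.
# All pattern measures run on log2(TPM + 1) values.

#' Log-transform a TPM matrix
#'
#' Elementwise `log2(x + 1)`. The transform state travels with the matrix;
#' applying it twice is an error.
#'
#' @param mat Nonnegative numeric matrix (genes x tissues).
#' @return Transformed matrix with attribute `transformed = TRUE`.
#' @export
log_transform <- function(mat) {
  if (isTRUE(attr(mat, "transformed"))) stop("matrix is already log-transformed")
  if (any(mat < 0)) stop("TPM values must be nonnegative")
  out <- log2(mat + 1)
  attr(out, "transformed") <- TRUE
  out
}

#' Tissue-specificity index tau
#'
#' `tau = sum_i (1 - x_i / max(x)) / (n - 1)` over tissues; 0 for uniform
#' expression, 1 for single-tissue expression. Undefined (NA) when the gene
#' is silent everywhere. Scale-invariant.
#'
#' @param x Nonnegative expression vector over >= 2 tissues (log scale in
#'   this pipeline).
#' @return tau in `[0, 1]`, or `NA` when `max(x) == 0`.
#' @export
tau <- function(x) {
  if (length(x) < 2L) stop("tau needs at least two tissues")
  if (any(x < 0)) stop("expression values must be nonnegative")
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1L)
}

#' Per-gene tau and mean expression
#'
#' @param mat Raw TPM matrix (genes x tissues); log-transformed internally.
#' @return Data frame: `gene_id`, `tau`, `mean_expr` (mean log2(TPM+1)).
#' @export
expression_summary <- function(mat) {
  lm <- if (isTRUE(attr(mat, "transformed"))) mat else log_transform(mat)
  data.frame(gene_id = rownames(lm),
             tau = apply(lm, 1, tau),
             mean_expr = rowMeans(lm),
             stringsAsFactors = FALSE)
}

#' Closest paralogous non-PSG of a selected gene
#'
#' Among family members that are not themselves PSGs, picks the one with the
#' highest global protein identity (matches / alignment length). Ties break
#' to the longer aligned length, then the lexicographically smaller gene id.
#' Returns `NULL` when the family offers no eligible paralog.
#'
#' @param psg Gene id of the selected gene.
#' @param family_members Gene ids in the same family.
#' @param proteins Named character vector of protein sequences.
#' @param psg_set Gene ids considered PSGs (excluded as paralogs).
#' @return List: `psg`, `paralog`, `identity`, `aligned_length`; or `NULL`.
#' @export
closest_paralog <- function(psg, family_members, proteins, psg_set) {
  cands <- setdiff(family_members, union(psg, psg_set))
  cands <- cands[cands %in% names(proteins)]
  if (length(cands) == 0L || !psg %in% names(proteins)) return(NULL)
  scores <- lapply(cands, function(g) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteins[[psg]]),
      Biostrings::AAString(proteins[[g]]),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    len <- Biostrings::nchar(al)
    list(gene = g, identity = Biostrings::nmatch(al) / len,
         aligned_length = len)
  })
  ids <- vapply(scores, `[[`, numeric(1), "identity")
  lens <- vapply(scores, `[[`, numeric(1), "aligned_length")
  genes <- vapply(scores, `[[`, character(1), "gene")
  ord <- order(-ids, -lens, genes)
  best <- scores[[ord[1]]]
  list(psg = psg, paralog = best$gene, identity = best$identity,
       aligned_length = best$aligned_length)
}

#' Pair every PSG with its closest non-PSG paralog
#'
#' @param psg_set PSG gene ids.
#' @param family_map Data frame `gene_id`, `family_id` (taxon column ignored).
#' @param proteins Named protein sequences.
#' @param expr_summary Result of [expression_summary()].
#' @return Data frame, one row per pairable PSG: ids, identity, tau and mean
#'   expression for both members.
#' @export
paralog_pairs <- function(psg_set, family_map, proteins, expr_summary) {
  fm <- unique(family_map[, c("gene_id", "family_id")])
  rows <- list()
  for (g in sort(psg_set)) {
    fam <- fm$family_id[fm$gene_id == g]
    if (length(fam) == 0L) next
    members <- fm$gene_id[fm$family_id == fam[1]]
    pair <- closest_paralog(g, members, proteins, psg_set)
    if (is.null(pair)) next
    e1 <- expr_summary[expr_summary$gene_id == g, ]
    e2 <- expr_summary[expr_summary$gene_id == pair$paralog, ]
    if (nrow(e1) == 0L || nrow(e2) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      psg = g, paralog = pair$paralog, identity = pair$identity,
      tau_psg = e1$tau, tau_paralog = e2$tau,
      mean_psg = e1$mean_expr, mean_paralog = e2$mean_expr,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(psg = character(), paralog = character(),
                      identity = numeric(), tau_psg = numeric(),
                      tau_paralog = numeric(), mean_psg = numeric(),
                      mean_paralog = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Compare expression patterns across PSG/paralog pairs
#'
#' Reports per-pair differences and how many pairs have the PSG strictly
#' higher, for tissue specificity and for mean expression. Pairs with an
#' undefined tau are excluded from the tau count.
#'
#' @param pairs Data frame from [paralog_pairs()].
#' @return List: `pairs` (with `d_tau`, `d_mean`), `n_pairs`,
#'   `n_psg_higher_tau`, `n_tau_pairs`, `n_psg_higher_mean`.
#' @export
compare_pairs <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(list(pairs = pairs, n_pairs = 0L, n_psg_higher_tau = 0L,
                n_tau_pairs = 0L, n_psg_higher_mean = 0L))
  pairs$d_tau <- pairs$tau_psg - pairs$tau_paralog
  pairs$d_mean <- pairs$mean_psg - pairs$mean_paralog
  tau_ok <- !is.na(pairs$d_tau)
  list(pairs = pairs,
       n_pairs = nrow(pairs),
       n_psg_higher_tau = sum(pairs$d_tau[tau_ok] > 0),
       n_tau_pairs = sum(tau_ok),
       n_psg_higher_mean = sum(pairs$d_mean > 0))
}
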