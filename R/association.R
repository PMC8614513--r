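# Enrichment association tests on 2x2 contingency tables: PSG status vs
# multigene-family membership, and PSG status vs disease-gene status, over
# the retained ortholog universe. The test is the one-sided upper-tail
# Fisher exact test (hypergeometric tail, exact summation).

#' One-sided upper-tail Fisher exact test
#'
#' Computes `P(X >= a)` for the top-left cell with all margins fixed
#' (hypergeometric), by exact summation — the enrichment direction for the
#' category counted in `a`. Degenerate margins give p = 1 with a warning.
#'
#' @param tab 2x2 matrix (or vector a, b, c, d by row).
#' @return List: `p` (in (0, 1]), `odds_ratio` (sample ad/bc), `alternative`.
#' @export
fisher_upper_tail <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0), all(tab == round(tab)))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (sum(tab) < 1L) stop("empty table")
  m <- a + b          # row-1 total
  k <- a + c          # column-1 total
  N <- sum(tab)
  if (m == 0L || k == 0L || m == N || k == N) {
    warning("degenerate margin: p set to 1")
    return(list(p = 1, odds_ratio = NA_real_, alternative = "greater"))
  }
  hi <- min(m, k)
  p <- sum(stats::dhyper(a:hi, m, N - m, k))
  p <- min(p, 1)
  or <- if (b > 0 && c > 0) (a * d) / (b * c) else Inf
  list(p = p, odds_ratio = or, alternative = "greater")
}

round_half_up <- function(x, digits = 3) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' PSG x multigene-family association for one branch
#'
#' Rows: genes in multigene vs single-gene families; columns: PSG on the
#' branch vs not. Upper-tail test on the multigene-PSG cell; per-row PSG
#' proportions are reported rounded half-up to 3 decimals (raw p retained).
#'
#' @param psg_genes Gene ids that are PSGs on the branch.
#' @param gene_classes Data frame: `gene_id`, `class` (`"single"`/`"multi"`)
#'   covering the whole ortholog universe.
#' @return List: `table` (2x2), `proportions`, `p`, `p_rounded`,
#'   `odds_ratio`.
#' @export
multigene_association <- function(psg_genes, gene_classes) {
  stopifnot(all(c("gene_id", "class") %in% names(gene_classes)))
  if (!all(gene_classes$class %in% c("single", "multi")))
    stop("every gene must be classified single or multi")
  if (any(!psg_genes %in% gene_classes$gene_id))
    stop("PSG gene absent from the classified universe")
  is_psg <- gene_classes$gene_id %in% psg_genes
  is_multi <- gene_classes$class == "multi"
  tab <- matrix(c(sum(is_multi & is_psg), sum(is_multi & !is_psg),
                  sum(!is_multi & is_psg), sum(!is_multi & !is_psg)),
                2, 2, byrow = TRUE,
                dimnames = list(c("multi", "single"), c("PSG", "non-PSG")))
  ft <- fisher_upper_tail(tab)
  props <- round_half_up(tab[, 1] / rowSums(tab))
  list(table = tab, proportions = props, p = ft$p,
       p_rounded = round_half_up(ft$p), odds_ratio = ft$odds_ratio)
}

#' PSG x disease-gene association
#'
#' Rows: PSG vs non-PSG over the ortholog universe; columns: disease vs
#' non-disease. Upper-tail test for disease enrichment among PSGs. Disease
#' genes absent from the universe are counted out (logged as an attribute).
#'
#' @param psg_genes PSG gene ids.
#' @param disease_genes Disease-associated gene ids (nonempty).
#' @param universe All retained ortholog gene ids.
#' @return List: `table`, `proportions` (disease fraction per row, 3 dp),
#'   `p`, `p_rounded`, `odds_ratio`, `n_disease_outside_universe`.
#' @export
disease_association <- function(psg_genes, disease_genes, universe) {
  stopifnot(length(disease_genes) >= 1L)
  outside <- sum(!disease_genes %in% universe)
  disease <- intersect(disease_genes, universe)
  is_psg <- universe %in% psg_genes
  is_dis <- universe %in% disease
  tab <- matrix(c(sum(is_psg & is_dis), sum(is_psg & !is_dis),
                  sum(!is_psg & is_dis), sum(!is_psg & !is_dis)),
                2, 2, byrow = TRUE,
                dimnames = list(c("PSG", "non-PSG"),
                                c("disease", "non-disease")))
  ft <- fisher_upper_tail(tab)
  props <- round_half_up(tab[, 1] / rowSums(tab))
  list(table = tab, proportions = props, p = ft$p,
       p_rounded = round_half_up(ft$p), odds_ratio = ft$odds_ratio,
       n_disease_outside_universe = outside)
}
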