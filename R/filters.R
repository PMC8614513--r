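# Four-stage determination cascade for positively selected genes:
# (1) LRT p < alpha with at least one selected site, (2) no alignment gap
# within 5 residues of any selected site, (3) all selected-site columns at
# the maximal confidence score, (4) no significant selection relaxation on
# the tested branch. Thresholds are strict inequalities and configurable.

#' Candidate call from a branch-site test
#'
#' A gene x branch is a PSG candidate when the LRT p-value is strictly below
#' `alpha` and at least one site has BEB posterior above the threshold.
#' An unconverged fit is never a candidate.
#'
#' @param p LRT p-value (or `NA` for an unconverged fit).
#' @param selected_sites Integer vector of selected alignment columns.
#' @param alpha Significance level (default 0.05, strict).
#' @return Logical.
#' @export
candidate_from_fit <- function(p, selected_sites, alpha = 0.05) {
  if (is.na(p)) return(FALSE)
  (p < alpha) && length(selected_sites) >= 1L
}

#' Gap-proximity filter
#'
#' A selected site fails when any taxon has a gap codon within `window`
#' amino-acid columns of it (inclusive on both sides; the site's own column
#' counts). In mode `"any"` (default) one failing site removes the gene; in
#' mode `"all"` the gene survives while at least one selected site is clean.
#'
#' @param selected_sites Alignment columns of selected sites.
#' @param aln The gene's [codon_alignment()].
#' @param window Residues scanned on each side (default 5).
#' @param mode `"any"` or `"all"` (which sites must be clean).
#' @return List: `pass`, `failing_sites`.
#' @export
gap_proximity_filter <- function(selected_sites, aln, window = 5,
                                 mode = c("any", "all")) {
  mode <- match.arg(mode)
  gaps <- gap_mask(aln)
  nc <- n_codons(aln)
  any_gap_col <- apply(gaps, 2, any)
  fails <- vapply(selected_sites, function(cc) {
    lo <- max(1L, cc - window); hi <- min(nc, cc + window)
    any(any_gap_col[lo:hi])
  }, logical(1))
  pass <- if (mode == "any") !any(fails) else !all(fails)
  if (length(selected_sites) == 0L) pass <- TRUE
  list(pass = pass, failing_sites = selected_sites[fails])
}

#' Column-score filter
#'
#' The gene fails when any selected site sits in an alignment column whose
#' confidence score is strictly below `threshold` (mode `"any"`, default) —
#' or when all do (mode `"all"`).
#'
#' @param selected_sites Alignment columns of selected sites.
#' @param scores Per-column score vector (from the attached score table).
#' @param threshold Minimum acceptable score (default 1.0).
#' @param mode `"any"` or `"all"`.
#' @return List: `pass`, `failing_sites`.
#' @export
column_score_filter <- function(selected_sites, scores, threshold = 1.0,
                                mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (is.null(scores)) stop("alignment has no column scores attached")
  if (length(selected_sites) && max(selected_sites) > length(scores))
    stop("selected site outside score table")
  fails <- scores[selected_sites] < threshold
  pass <- if (mode == "any") !any(fails) else !all(fails)
  if (length(selected_sites) == 0L) pass <- TRUE
  list(pass = pass, failing_sites = selected_sites[fails])
}

#' Relaxation filter
#'
#' The gene fails only when the relaxation test is both significant and in
#' the relaxed direction: `K < 1` and `p < alpha`. An unconverged relaxation
#' fit passes with a warning rather than silently dropping the gene.
#'
#' @param K Selection-intensity estimate.
#' @param p Relaxation LRT p-value.
#' @param alpha Significance level (default 0.05).
#' @param converged Convergence flag of the relaxation fit.
#' @return Logical (pass).
#' @export
relaxation_filter <- function(K, p, alpha = 0.05, converged = TRUE) {
  if (!isTRUE(converged) || is.na(K) || is.na(p)) {
    warning("unconverged relaxation fit: gene passes the relaxation stage")
    return(TRUE)
  }
  !(K < 1 && p < alpha)
}

#' Run the full PSG filter cascade
#'
#' Applies the four stages in order over a table of per-gene-per-branch
#' fits and returns the per-record flags plus Table-2-shaped survivor counts
#' per branch (counts are non-increasing across stages by construction).
#'
#' @param fits Data frame: `gene`, `branch`, `p` (LRT p-value; `NA` if
#'   unconverged).
#' @param beb Named list keyed `"gene|branch"` of selected-site column
#'   vectors.
#' @param alignments Named list keyed by gene of [codon_alignment()]s with
#'   scores attached.
#' @param relax Data frame: `gene`, `branch`, `K`, `p`, `converged`. Only
#'   consulted for records surviving the first three stages.
#' @param alpha,beb_threshold,gap_window,score_threshold,site_mode Cascade
#'   thresholds (defaults 0.05, 0.95, 5, 1.0, `"any"`).
#' @param enabled Logical vector of length 3 switching the gap, score and
#'   relaxation stages on/off (all on by default).
#' @return List: `records` (one row per gene x branch with all flags),
#'   `stage_counts` (per branch).
#' @export
run_cascade <- function(fits, beb, alignments, relax = NULL,
                        alpha = 0.05, beb_threshold = 0.95,
                        gap_window = 5, score_threshold = 1.0,
                        site_mode = "any",
                        enabled = c(gap = TRUE, score = TRUE, relax = TRUE)) {
  stopifnot(all(c("gene", "branch", "p") %in% names(fits)))
  recs <- fits
  n <- nrow(recs)
  recs$n_sel_sites <- 0L
  recs$sel_sites <- ""
  recs$candidate <- FALSE
  recs$passed_gap_filter <- NA
  recs$passed_column_filter <- NA
  recs$passed_relax_filter <- NA
  for (i in seq_len(n)) {
    key <- paste0(recs$gene[i], "|", recs$branch[i])
    sites <- beb[[key]]
    if (is.null(sites)) sites <- integer(0)
    recs$n_sel_sites[i] <- length(sites)
    recs$sel_sites[i] <- paste(sites, collapse = ";")
    recs$candidate[i] <- candidate_from_fit(recs$p[i], sites, alpha)
    if (!recs$candidate[i]) next
    aln <- alignments[[recs$gene[i]]]
    if (is.null(aln)) stop("no alignment for gene ", recs$gene[i])
    recs$passed_gap_filter[i] <- if (enabled[["gap"]])
      gap_proximity_filter(sites, aln, gap_window, site_mode)$pass else TRUE
    recs$passed_column_filter[i] <- if (enabled[["score"]])
      column_score_filter(sites, aln$scores, score_threshold, site_mode)$pass
    else TRUE
    if (enabled[["relax"]]) {
      if (is.null(relax)) stop("relaxation fits required but not supplied")
      r <- relax[relax$gene == recs$gene[i] & relax$branch == recs$branch[i], ]
      if (nrow(r) == 0L) stop("missing relaxation fit for ", key)
      recs$passed_relax_filter[i] <-
        relaxation_filter(r$K[1], r$p[1], alpha, r$converged[1])
    } else recs$passed_relax_filter[i] <- TRUE
  }
  recs$psg <- recs$candidate &
    recs$passed_gap_filter %in% TRUE &
    recs$passed_column_filter %in% TRUE &
    recs$passed_relax_filter %in% TRUE
  counts <- do.call(rbind, lapply(split(recs, recs$branch), function(d) {
    s1 <- d$candidate
    s2 <- s1 & d$passed_gap_filter %in% TRUE
    s3 <- s2 & d$passed_column_filter %in% TRUE
    s4 <- s3 & d$passed_relax_filter %in% TRUE
    data.frame(branch = d$branch[1],
               n_candidates = sum(s1),
               n_after_gap_filter = sum(s2),
               n_after_column_filter = sum(s3),
               n_after_relax_filter = sum(s4),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  list(records = recs, stage_counts = counts)
}
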