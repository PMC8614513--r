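# End-to-end orchestration: QC -> back-translation -> per-branch
# branch-site fits -> filter cascade -> fixation -> expression ->
# association, from a dataset directory laid out as written by
# simulate_ortholog_set() (or assembled by hand in the same shape).

#' Scan configuration
#'
#' One auditable place for every threshold the scan uses. Defaults follow
#' the standard cascade: LRT alpha 0.05, BEB posterior 0.95, gap window 5
#' residues, column score 1.0, relaxation K < 1 with p < 0.05, fixation
#' allele frequency 0.95 (all strict inequalities).
#'
#' @param foreground Branch names to test (default all seven great-ape
#'   branches).
#' @param alpha,beb_threshold,gap_window,score_threshold,fixation_af
#'   Cascade and fixation thresholds.
#' @param freq_method Codon frequency model (`"F3x4"` default).
#' @param site_mode Gap/score filter mode (`"any"` or `"all"`).
#' @param seed Seed for any stochastic stage.
#' @return A named list.
#' @export
scan_config <- function(foreground = foreground_branches(),
                        alpha = 0.05, beb_threshold = 0.95,
                        gap_window = 5, score_threshold = 1.0,
                        fixation_af = 0.95,
                        freq_method = "F3x4",
                        site_mode = "any",
                        seed = 1) {
  stopifnot(alpha > 0, alpha < 1, beb_threshold > 0, beb_threshold < 1,
            gap_window >= 0, score_threshold >= 0, score_threshold <= 1)
  list(foreground = foreground, alpha = alpha,
       beb_threshold = beb_threshold, gap_window = gap_window,
       score_threshold = score_threshold, fixation_af = fixation_af,
       freq_method = freq_method, site_mode = site_mode, seed = seed)
}

read_ortholog_groups <- function(cds_dir) {
  files <- sort(list.files(cds_dir, pattern = "\\.fasta$", full.names = TRUE))
  groups <- list()
  for (f in files) {
    seqs <- Biostrings::readDNAStringSet(f)
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    taxa <- vapply(parts, `[[`, character(1), 1)
    gene <- vapply(parts, `[[`, character(1), 2)[1]
    cds <- as.character(seqs)
    names(cds) <- taxa
    groups[[gene]] <- cds
  }
  groups
}

#' Run the full positive-selection scan
#'
#' @param data_dir Dataset directory containing `manifest.json` (the layout
#'   written by [simulate_ortholog_set()]).
#' @param config A [scan_config()].
#' @param out_dir Output directory for result tables (default
#'   `file.path(data_dir, "results")`).
#' @param resume Reuse the per-gene fit cache in `out_dir` if present, so an
#'   interrupted run continues where it stopped.
#' @return List: `records` and `stage_counts` (cascade), `fixation`
#'   (site and gene tables), `expression` (pair comparison), `association`
#'   (multigene per branch + disease), `qc` (exclusion report), `paths`.
#' @export
run_scan <- function(data_dir, config = scan_config(), out_dir = NULL,
                     resume = FALSE) {
  manifest <- jsonlite::read_json(file.path(data_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (is.null(out_dir)) out_dir <- file.path(data_dir, "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- manifest$paths

  # --- QC ---------------------------------------------------------------
  groups <- read_ortholog_groups(p$cds_dir)
  qc <- filter_ortholog_groups(groups)
  genes <- names(qc$retained)

  # --- alignments -------------------------------------------------------
  tree <- ape::read.tree(p$tree)
  tree$tip.label <- sub("#1$", "", tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- sub("#1$", "", tree$node.label)
  alignments <- list()
  for (g in genes) {
    prot <- Biostrings::readAAStringSet(file.path(p$alignment_dir,
                                                  paste0(g, ".faa")))
    aln <- backtranslate(prot, qc$retained[[g]])
    sc <- utils::read.delim(file.path(p$score_dir, paste0(g, ".tsv")))
    alignments[[g]] <- attach_column_scores(aln, sc)
  }

  # --- selection fits (cached for resumability) -------------------------
  cache <- file.path(out_dir, "fits_cache.rds")
  fitted <- if (resume && file.exists(cache)) readRDS(cache) else
    list(fits = NULL, beb = list(), relax = NULL, done = character(0))
  for (g in genes) {
    if (g %in% fitted$done) next
    aln <- alignments[[g]]
    m0 <- fit_m0(aln, tree, freq_method = config$freq_method)
    for (br in config$foreground) {
      lt <- labeled_tree(tree, br)
      ts <- if (isTRUE(m0$converged)) branch_site_test(aln, lt, m0) else NULL
      pval <- if (!is.null(ts) && !is.null(ts$lrt)) ts$lrt$p else NA_real_
      fitted$fits <- rbind(fitted$fits, data.frame(
        gene = g, branch = br, p = pval,
        omega2 = if (!is.null(ts$alt$omega2)) ts$alt$omega2 else NA_real_,
        converged = !is.null(ts) && !is.null(ts$lrt),
        stringsAsFactors = FALSE))
      if (!is.na(pval) && pval < config$alpha) {
        bb <- beb_site_posteriors(aln, lt, m0, ts$alt,
                                  threshold = config$beb_threshold)
        fitted$beb[[paste0(g, "|", br)]] <- bb$selected_sites
        rf <- fit_relax_style(aln, lt, m0)
        fitted$relax <- rbind(fitted$relax, data.frame(
          gene = g, branch = br,
          K = if (isTRUE(rf$converged)) rf$K else NA_real_,
          p = if (isTRUE(rf$converged)) rf$p else NA_real_,
          converged = isTRUE(rf$converged), stringsAsFactors = FALSE))
      }
    }
    fitted$done <- c(fitted$done, g)
    saveRDS(fitted, cache)
  }

  # --- cascade ----------------------------------------------------------
  casc <- run_cascade(fitted$fits, fitted$beb, alignments, fitted$relax,
                      alpha = config$alpha, gap_window = config$gap_window,
                      score_threshold = config$score_threshold,
                      site_mode = config$site_mode)

  # --- fixation ---------------------------------------------------------
  variants <- read_population_vcf(p$vcf)
  gff <- rtracklayer::import(p$gff)
  fix_rows <- list()
  psg_rows <- casc$records[casc$records$psg, , drop = FALSE]
  psg_rows$gene_fixed <- rep(NA, nrow(psg_rows))
  for (i in seq_len(nrow(psg_rows))) {
    g <- psg_rows$gene[i]; br <- psg_rows$branch[i]
    sites <- as.integer(strsplit(psg_rows$sel_sites[i], ";")[[1]])
    lt <- labeled_tree(tree, br)
    tip <- foreground_tip(lt)
    calls <- list()
    for (cc in sites) {
      ms <- map_site(alignments[[g]], cc, tip, gff = gff, gene_id = g)
      if (is.na(ms$ungapped_pos)) next
      call <- is_site_fixed(list(chrom = ms$chrom, positions = ms$genomic_pos),
                            variants, af_available = TRUE)
      calls[[length(calls) + 1L]] <- call
      fix_rows[[length(fix_rows) + 1L]] <- data.frame(
        gene = g, branch = br, aa_column = cc, site = ms$ungapped_pos,
        fixed = call$fixed, mode = call$mode, stringsAsFactors = FALSE)
    }
    if (length(calls)) {
      gf <- classify_gene_fixed(calls)
      psg_rows$gene_fixed[i] <- gf$fixed
    }
  }
  fixation <- list(
    sites = if (length(fix_rows)) do.call(rbind, fix_rows) else NULL,
    genes = psg_rows)

  # --- expression -------------------------------------------------------
  expr_df <- utils::read.delim(p$expression, check.names = FALSE)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$gene_id
  esum <- expression_summary(expr)
  fam <- utils::read.delim(p$family_map)
  psg_set <- unique(casc$records$gene[casc$records$psg])
  focal <- if ("hsap" %in% tree$tip.label) "hsap" else tree$tip.label[1]
  proteins <- vapply(genes, function(g) {
    row <- alignments[[g]]$codons[focal, ]
    paste0(translate_codon_vector(row[row != "---"]), collapse = "")
  }, character(1))
  pairs <- paralog_pairs(psg_set, fam, proteins, esum)
  expr_cmp <- compare_pairs(pairs)

  # --- association ------------------------------------------------------
  classes <- classify_families(fam)
  fam_u <- unique(fam[, c("gene_id", "family_id")])
  gene_classes <- data.frame(
    gene_id = fam_u$gene_id,
    class = classes$class[match(fam_u$family_id, classes$family_id)],
    stringsAsFactors = FALSE)
  gene_classes <- gene_classes[gene_classes$gene_id %in% genes, ]
  assoc <- list()
  for (br in config$foreground) {
    psg_br <- casc$records$gene[casc$records$psg & casc$records$branch == br]
    assoc[[br]] <- multigene_association(psg_br, gene_classes)
  }
  disease <- utils::read.delim(p$disease)$gene_id
  disease_res <- if (length(disease))
    disease_association(psg_set, disease, genes) else NULL

  # --- outputs ----------------------------------------------------------
  paths <- list(
    records = file.path(out_dir, "psg_records.tsv"),
    stage_counts = file.path(out_dir, "stage_counts.tsv"),
    fixation_sites = file.path(out_dir, "fixation_sites.tsv"),
    expression_pairs = file.path(out_dir, "expression_pairs.tsv"))
  utils::write.table(casc$records, paths$records, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(casc$stage_counts, paths$stage_counts, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(fixation$sites))
    utils::write.table(fixation$sites, paths$fixation_sites, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (nrow(expr_cmp$pairs))
    utils::write.table(expr_cmp$pairs, paths$expression_pairs, sep = "\t",
                       row.names = FALSE, quote = FALSE)

  list(records = casc$records, stage_counts = casc$stage_counts,
       fixation = fixation, expression = expr_cmp,
       association = list(multigene = assoc, disease = disease_res),
       qc = qc$report, paths = paths)
}
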