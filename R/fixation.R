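# Population fixation calling of positively selected sites. A selected
# amino-acid site is fixed when, at every population variant overlapping its
# codon, the allele carried by the analysis assembly keeps frequency > 0.95
# (when frequencies are available), or when no alternative allele segregates
# in the codon at all (when they are not). A gene is fixed when at least one
# of its selected sites is fixed.

#' Read a population VCF into a variant table
#'
#' @param path VCF file (v4.x; `AF` INFO parsed when present).
#' @return Data frame: `chrom`, `pos`, `ref`, `alt` (comma-joined), `af`
#'   (total alternative-allele frequency, `NA` when absent).
#' @export
read_population_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), af = numeric(),
                      stringsAsFactors = FALSE))
  af_raw <- vcfR::extract.info(v, "AF")
  af <- vapply(af_raw, function(x) {
    if (is.na(x)) return(NA_real_)
    sum(as.numeric(strsplit(x, ",")[[1]]))
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT, af = af, stringsAsFactors = FALSE)
}

#' Fixation call for one selected site
#'
#' @param codon_span List or data frame row with `chrom` and `positions`
#'   (the codon's three 1-based genomic positions).
#' @param variants Variant table ([read_population_vcf()] shape); only rows
#'   overlapping the codon positions are considered.
#' @param af_available Use the allele-frequency rule (`TRUE`) or the
#'   no-alternative-allele rule (`FALSE`).
#' @param assembly_bases Optional named character vector (position ->
#'   assembly base) used to check that the VCF REF matches the assembly; a
#'   variant matching neither allele yields a warning and a not-fixed call.
#' @return List: `fixed` (logical), `mode` (`"AF_rule"`, `"no_alt_rule"` or
#'   `"no_overlap"`), `n_variants`.
#' @export
is_site_fixed <- function(codon_span, variants, af_available = TRUE,
                          assembly_bases = NULL) {
  pos <- codon_span$positions
  stopifnot(length(pos) == 3L)
  ov <- variants[variants$chrom == codon_span$chrom & variants$pos %in% pos, ,
                 drop = FALSE]
  if (nrow(ov) == 0L)
    return(list(fixed = TRUE, mode = "no_overlap", n_variants = 0L))
  if (!af_available) {
    has_alt <- nzchar(ov$alt) & ov$alt != "."
    return(list(fixed = !any(has_alt), mode = "no_alt_rule",
                n_variants = nrow(ov)))
  }
  ok <- vapply(seq_len(nrow(ov)), function(i) {
    r <- ov[i, ]
    if (is.na(r$af)) return(FALSE)            # conservative: no AF, not fixed
    alts <- strsplit(r$alt, ",")[[1]]
    assembly <- if (!is.null(assembly_bases)) assembly_bases[[as.character(r$pos)]]
    else r$ref
    if (identical(assembly, r$ref)) {
      (1 - r$af) > 0.95
    } else if (!is.null(assembly) && assembly %in% alts) {
      # af is the summed ALT frequency; attributable to the assembly allele
      # only when it is the sole ALT, otherwise call not fixed conservatively
      length(alts) == 1L && r$af > 0.95
    } else {
      warning("variant at ", r$pos, " matches neither assembly allele")
      FALSE
    }
  }, logical(1))
  list(fixed = all(ok), mode = "AF_rule", n_variants = nrow(ov))
}

#' Gene-level fixation from site calls
#'
#' A gene x branch is fixed when at least one of its selected sites is fixed.
#'
#' @param calls List of [is_site_fixed()] results (>= 1).
#' @return List: `fixed`, `n_sites`, `n_fixed_sites`.
#' @export
classify_gene_fixed <- function(calls) {
  stopifnot(length(calls) >= 1L)
  fixed <- vapply(calls, `[[`, logical(1), "fixed")
  list(fixed = any(fixed), n_sites = length(fixed),
       n_fixed_sites = sum(fixed))
}
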