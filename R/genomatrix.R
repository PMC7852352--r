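#' Construct a single-cell genotype matrix
#'
#' The central container of the package: a cells-by-sites matrix of ternary
#' genotype calls (0 = reference, 1 = mutant, `NA` = missing) with per-site
#' and per-cell metadata attached by id.
#'
#' @param calls Integer matrix with cell ids as rownames and site ids as
#'   colnames; entries in `{0, 1, NA}`.
#' @param site_meta `data.frame` with one row per site, columns `site_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `gene`, `variant_class`
#'   (`"SNV"` or `"INDEL"`) and optionally `vaf` (bulk variant allele
#'   frequency in `[0, 0.5]`, `NA` when unannotated).
#' @param cell_meta `data.frame` with one row per cell, columns `cell_id`
#'   and `tissue` (one of `"paratumor"`, `"tumor"`, `"metastasis"`,
#'   `"other"`).
#' @return Object of class `GenotypeMatrix`: list with elements `calls`,
#'   `site_meta`, `cell_meta`.
#' @export
genotype_matrix <- function(calls, site_meta, cell_meta) {
  stopifnot(is.matrix(calls), is.data.frame(site_meta), is.data.frame(cell_meta))
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop2("calls must have cell ids as rownames and site ids as colnames")
  }
  bad <- calls[!is.na(calls) & !(calls %in% c(0L, 1L))]
  if (length(bad) > 0L) stop2("genotype calls must be 0, 1 or NA")
  if (anyDuplicated(rownames(calls))) stop2("duplicate cell ids")
  if (anyDuplicated(colnames(calls))) stop2("duplicate site ids")
  req_site <- c("site_id", "chrom", "pos", "ref", "alt", "gene", "variant_class")
  if (!all(req_site %in% names(site_meta))) {
    stop2("site_meta must contain columns: ", paste(req_site, collapse = ", "))
  }
  if (!all(c("cell_id", "tissue") %in% names(cell_meta))) {
    stop2("cell_meta must contain columns: cell_id, tissue")
  }
  if (!setequal(site_meta$site_id, colnames(calls)) ||
      nrow(site_meta) != ncol(calls)) {
    stop2("site_meta does not match the matrix columns (dimension or id mismatch)")
  }
  if (!setequal(cell_meta$cell_id, rownames(calls)) ||
      nrow(cell_meta) != nrow(calls)) {
    stop2("cell_meta does not match the matrix rows (dimension or id mismatch)")
  }
  bad_tissue <- setdiff(unique(cell_meta$tissue), c("paratumor", "tumor", "metastasis", "other"))
  if (length(bad_tissue) > 0L) stop2("unknown tissue label(s): ", paste(bad_tissue, collapse = ", "))
  site_meta <- site_meta[match(colnames(calls), site_meta$site_id), , drop = FALSE]
  cell_meta <- cell_meta[match(rownames(calls), cell_meta$cell_id), , drop = FALSE]
  rownames(site_meta) <- NULL
  rownames(cell_meta) <- NULL
  snv <- site_meta$variant_class == "SNV"
  bad_snv <- snv & (nchar(site_meta$ref) != 1L | nchar(site_meta$alt) != 1L |
                      site_meta$ref == site_meta$alt)
  if (any(bad_snv)) {
    stop2("SNV sites must have distinct single-base ref/alt: ",
          paste(site_meta$site_id[bad_snv], collapse = ", "))
  }
  structure(list(calls = calls, site_meta = site_meta, cell_meta = cell_meta),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$calls), "cells x", ncol(x$calls), "sites\n")
  cat("  tissues:", paste(sprintf("%s (%d)", names(table(x$cell_meta$tissue)),
                                  table(x$cell_meta$tissue)), collapse = ", "), "\n")
  cat("  missing calls:", sprintf("%.1f%%", 100 * mean(is.na(x$calls))), "\n")
  invisible(x)
}

#' Subset a genotype matrix by cells and/or sites
#'
#' @param gm A `GenotypeMatrix`.
#' @param cells,sites Character vectors of ids to keep (default: all).
#' @return A `GenotypeMatrix` restricted to the selection.
#' @export
subset_genotype_matrix <- function(gm, cells = NULL, sites = NULL) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  cells <- cells %||% rownames(gm$calls)
  sites <- sites %||% colnames(gm$calls)
  genotype_matrix(gm$calls[cells, sites, drop = FALSE],
                  gm$site_meta[gm$site_meta$site_id %in% sites, , drop = FALSE],
                  gm$cell_meta[gm$cell_meta$cell_id %in% cells, , drop = FALSE])
}

tumor_cell_ids <- function(gm, tissues = c("tumor", "metastasis")) {
  gm$cell_meta$cell_id[gm$cell_meta$tissue %in% tissues]
}

## ---- TSV / VCF I/O ---------------------------------------------------------

#' Read a genotype matrix from three TSV files
#'
#' Matrix TSV dialect: first column `cell_id`, remaining columns named by
#' site id; genotype tokens `"0"`, `"1"`, missing as `"NA"`. Site TSV
#' columns: `site_id, chrom, pos, ref, alt, gene, variant_class[, vaf]`.
#' Cell TSV columns: `cell_id, tissue`. Round-trips bit-exactly with
#' [write_genotype_matrix()].
#'
#' @param matrix_path,site_path,cell_path Paths to the three TSV files.
#' @return A `GenotypeMatrix`.
#' @export
read_genotype_matrix <- function(matrix_path, site_path, cell_path) {
  raw <- utils::read.delim(matrix_path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (names(raw)[1] != "cell_id") stop2("matrix TSV must start with a cell_id column")
  cell_ids <- raw[[1]]
  tokens <- as.matrix(raw[, -1, drop = FALSE])
  rownames(tokens) <- cell_ids
  ok <- matrix(tokens %in% c("0", "1", "NA"), nrow(tokens), ncol(tokens))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop2(sprintf("invalid genotype token '%s' at cell '%s', site '%s'",
                  tokens[bad[1, 1], bad[1, 2]],
                  rownames(tokens)[bad[1, 1]], colnames(tokens)[bad[1, 2]]))
  }
  calls <- matrix(NA_integer_, nrow(tokens), ncol(tokens),
                  dimnames = dimnames(tokens))
  calls[tokens == "0"] <- 0L
  calls[tokens == "1"] <- 1L
  site_meta <- utils::read.delim(site_path, check.names = FALSE,
                                 colClasses = c(site_id = "character", chrom = "character",
                                                ref = "character", alt = "character",
                                                gene = "character", variant_class = "character"))
  cell_meta <- utils::read.delim(cell_path, colClasses = "character", check.names = FALSE)
  genotype_matrix(calls, site_meta, cell_meta)
}

#' Write a genotype matrix to three TSV files
#'
#' @param gm A `GenotypeMatrix`.
#' @param matrix_path,site_path,cell_path Output paths (see
#'   [read_genotype_matrix()] for the dialects).
#' @export
write_genotype_matrix <- function(gm, matrix_path, site_path, cell_path) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  tokens <- matrix(as.character(gm$calls), nrow(gm$calls), ncol(gm$calls))
  tokens[is.na(gm$calls)] <- "NA"
  df <- data.frame(cell_id = rownames(gm$calls), tokens, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("cell_id", colnames(gm$calls))
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$site_meta, site_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$cell_meta, cell_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gm)
}

#' Read a site table from a minimal VCF
#'
#' Accepts VCF 4.x with INFO keys `GENE` and optionally `VAF`; site ids are
#' taken from the ID column when present, otherwise `chrom:pos`. Single-base
#' ref and alt give variant class SNV, anything longer INDEL.
#'
#' @param path Path to a VCF file.
#' @return Site metadata `data.frame` in the layout of
#'   [genotype_matrix()]'s `site_meta`.
#' @export
read_sites_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gene <- vcfR::extract.info(vcf, "GENE")
  vaf <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "VAF")))
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(id) | id == "."]
  data.frame(site_id = id, chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             gene = ifelse(is.na(gene), ".", gene),
             variant_class = ifelse(nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L,
                                    "SNV", "INDEL"),
             vaf = vaf, stringsAsFactors = FALSE)
}

#' Write a site table as a minimal VCF
#'
#' Emits a VCF 4.2 header and one line per site with INFO `GENE=` and, for
#' annotated sites, `VAF=`.
#'
#' @param site_meta Site metadata table (see [genotype_matrix()]).
#' @param path Output path.
#' @export
write_sites_vcf <- function(site_meta, path) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
              "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Bulk variant allele frequency\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  vaf <- if ("vaf" %in% names(site_meta)) site_meta$vaf else rep(NA_real_, nrow(site_meta))
  info <- paste0("GENE=", site_meta$gene,
                 ifelse(is.na(vaf), "", sprintf(";VAF=%.6g", vaf)))
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                   site_meta$chrom, site_meta$pos, site_meta$site_id,
                   site_meta$ref, site_meta$alt, info)
  writeLines(c(header, lines), path)
  invisible(path)
}

## ---- QC --------------------------------------------------------------------

#' Per-site mutated cell fractions
#'
#' Fraction of mutant calls among non-missing calls at each site, over the
#' cells passing a tissue filter. Sites with no non-missing call in the
#' selection are undefined and reported `NA`.
#'
#' @param gm A `GenotypeMatrix`.
#' @param tissues Tissue labels to include (default: tumor and metastasis
#'   cells, i.e. the tumor compartment). `NULL` means all cells.
#' @return Named numeric vector over sites.
#' @export
mutated_cell_fraction <- function(gm, tissues = c("tumor", "metastasis")) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  cells <- if (is.null(tissues)) rownames(gm$calls) else tumor_cell_ids(gm, tissues)
  if (length(cells) == 0L) stop2("tissue filter selects no cells")
  sub <- gm$calls[cells, , drop = FALSE]
  n_obs <- colSums(!is.na(sub))
  frac <- colSums(sub == 1L, na.rm = TRUE) / n_obs
  frac[n_obs == 0L] <- NA_real_
  frac
}

#' Estimate the allele-dropout rate from heterozygous germline control sites
#'
#' At a site known to be heterozygous germline in every cell, each of the two
#' alleles independently fails to amplify with probability `d`. Both dropping
#' gives a missing call, exactly one dropping gives a homozygous-looking
#' call, so among non-missing observations the homozygous fraction is
#' `h = 2d(1-d) / (1-d^2) = 2d/(1+d)`; inverting gives the estimator
#' `d_hat = h / (2 - h)`.
#'
#' @param control Character matrix of allele-presence summaries at control
#'   sites, entries in `{"both", "ref-only", "alt-only", NA}` (cells in rows).
#' @return Estimated dropout probability in `[0, 1)`.
#' @export
estimate_ado <- function(control) {
  stopifnot(is.character(control) || is.matrix(control))
  vals <- control[!is.na(control)]
  bad <- setdiff(unique(vals), c("both", "ref-only", "alt-only"))
  if (length(bad) > 0L) stop2("invalid control call token(s): ", paste(bad, collapse = ", "))
  if (length(vals) == 0L) stop2("no non-missing control observations")
  h <- mean(vals != "both")
  h / (2 - h)
}

#' Concordance between mutated cell fractions and bulk VAF
#'
#' Correlates the per-site mutated cell fraction (tumor-compartment cells
#' only) with the bulk variant allele frequency annotation, over sites where
#' both are defined. With heterozygous diploid mutations and pure tumor, the
#' expected relationship is fraction = 2 x VAF, so good data give r near 1.
#'
#' @param gm A `GenotypeMatrix` whose `site_meta` carries a `vaf` column.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient; `NA` with a warning when one of the
#'   vectors has zero variance (correlation undefined).
#' @export
vaf_concordance <- function(gm, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(gm, "GenotypeMatrix"))
  if (!"vaf" %in% names(gm$site_meta)) stop2("site_meta has no vaf column")
  frac <- mutated_cell_fraction(gm)
  vaf <- gm$site_meta$vaf[match(names(frac), gm$site_meta$site_id)]
  keep <- !is.na(frac) & !is.na(vaf)
  if (sum(keep) < 3L) stop2("need at least 3 sites with both a defined fraction and a bulk VAF")
  if (stats::sd(frac[keep]) == 0 || stats::sd(vaf[keep]) == 0) {
    warning("zero-variance vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(frac[keep], vaf[keep], method = method)
}

#' Filter germline variants and recurrent artifacts using paratumor cells
#'
#' Paratumor (adjacent normal) cells carry no somatic tumor mutations, so a
#' site frequently mutant among them is germline or a technical artifact.
#' Sites whose mutated cell fraction among paratumor cells exceeds the
#' threshold are removed, provided at least `min_mutant_calls` paratumor
#' cells actually carry the mutant call (a single false-positive call in a
#' small paratumor panel should not discard a somatic site). With no
#' paratumor cells the operation is a no-op with a warning.
#'
#' @param gm A `GenotypeMatrix`.
#' @param max_paratumor_fraction Removal threshold (default 0.1).
#' @param min_mutant_calls Minimum mutant paratumor calls backing a removal
#'   (default 2).
#' @return List with `matrix` (the filtered `GenotypeMatrix`) and `removed`
#'   (`data.frame` of removed sites with columns `site_id`, `reason`,
#'   `paratumor_fraction`).
#' @export
filter_germline_artifacts <- function(gm, max_paratumor_fraction = 0.1,
                                      min_mutant_calls = 2L) {
  stopifnot(inherits(gm, "GenotypeMatrix"), is_prob(max_paratumor_fraction))
  empty <- data.frame(site_id = character(), reason = character(),
                      paratumor_fraction = numeric(), stringsAsFactors = FALSE)
  if (!any(gm$cell_meta$tissue == "paratumor")) {
    warning("no paratumor cells; germline/artifact filter skipped")
    return(list(matrix = gm, removed = empty))
  }
  para <- gm$cell_meta$cell_id[gm$cell_meta$tissue == "paratumor"]
  n_mut <- colSums(gm$calls[para, , drop = FALSE] == 1L, na.rm = TRUE)
  frac <- mutated_cell_fraction(gm, tissues = "paratumor")
  drop <- !is.na(frac) & frac > max_paratumor_fraction & n_mut >= min_mutant_calls
  if (!any(drop)) return(list(matrix = gm, removed = empty))
  removed <- data.frame(site_id = names(frac)[drop], reason = "paratumor-positive",
                        paratumor_fraction = unname(frac[drop]), stringsAsFactors = FALSE)
  keep_sites <- setdiff(colnames(gm$calls), removed$site_id)
  list(matrix = subset_genotype_matrix(gm, sites = keep_sites), removed = removed)
}

#' Assemble a QC report for a genotype matrix
#'
#' Bundles the allele-dropout estimate (when a control matrix is supplied),
#' the mutated-cell-fraction vs bulk-VAF concordance (when at least three
#' sites carry a VAF annotation), per-site mutated cell fractions, and the
#' germline/artifact filtering result.
#'
#' @param gm A `GenotypeMatrix`.
#' @param control Optional heterozygous-germline control matrix for
#'   [estimate_ado()].
#' @param max_paratumor_fraction Threshold for
#'   [filter_germline_artifacts()].
#' @param vaf_method Correlation method for [vaf_concordance()].
#' @return Object of class `QCReport`.
#' @export
qc_report <- function(gm, control = NULL, max_paratumor_fraction = 0.1,
                      vaf_method = "pearson") {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  ado <- if (!is.null(control)) estimate_ado(control) else NA_real_
  n_vaf <- if ("vaf" %in% names(gm$site_meta)) sum(!is.na(gm$site_meta$vaf)) else 0L
  r <- if (n_vaf >= 3L) vaf_concordance(gm, method = vaf_method) else NA_real_
  filt <- suppressWarnings(filter_germline_artifacts(gm, max_paratumor_fraction))
  structure(list(ado_estimate = ado,
                 vaf_concordance_r = r,
                 mutated_cell_fraction = mutated_cell_fraction(gm),
                 filtered_sites = filt$removed,
                 filtered_matrix = filt$matrix),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QC report\n")
  cat("  ADO estimate:        ", ifelse(is.na(x$ado_estimate), "not estimated",
                                        sprintf("%.4f", x$ado_estimate)), "\n")
  cat("  VAF concordance r:   ", ifelse(is.na(x$vaf_concordance_r), "not computed",
                                        sprintf("%.4f", x$vaf_concordance_r)), "\n")
  cat("  sites filtered:      ", nrow(x$filtered_sites), "\n")
  invisible(x)
}
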