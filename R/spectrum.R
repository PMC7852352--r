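#' The six pyrimidine-reference substitution classes
#'
#' Single-base substitutions are conventionally collapsed to the six classes
#' with a pyrimidine (C or T) reference base; a purine-reference substitution
#' is reported on the opposite strand (e.g. A>T is counted as T>A). This is
#' the ordering used throughout the package, including by
#' [simulation_config()]'s `signature_bias`.
#'
#' @return Character vector of the six class labels.
#' @export
substitution_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' Classify a single-base substitution into a pyrimidine-reference class
#'
#' Purine-reference pairs are reverse-complemented onto the pyrimidine
#' strand, so for example both `T>A` and `A>T` report as `"T>A"`. Anything
#' that is not a proper single-base substitution (multi-base alleles, i.e.
#' INDELs; identical ref and alt; non-ACGT characters) is excluded and
#' returns `NA` with the reason in the `"reason"` attribute.
#'
#' @param ref Reference allele (character scalar, uppercase).
#' @param alt Alternate allele (character scalar, uppercase).
#' @return One of the labels from [substitution_classes()], or `NA_character_`
#'   with attribute `reason` when the pair is excluded.
#' @examples
#' classify_substitution("T", "A")  # "T>A"
#' classify_substitution("A", "T")  # also "T>A" (opposite strand)
#' @export
classify_substitution <- function(ref, alt) {
  stopifnot(is.character(ref), is.character(alt), length(ref) == 1L, length(alt) == 1L)
  if (is.na(ref) || is.na(alt)) return(structure(NA_character_, reason = "missing allele"))
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    return(structure(NA_character_, reason = "INDEL"))
  }
  if (!(ref %in% DNA_BASES) || !(alt %in% DNA_BASES)) {
    return(structure(NA_character_, reason = "non-ACGT"))
  }
  if (ref == alt) return(structure(NA_character_, reason = "identical ref/alt"))
  if (ref %in% c("A", "G")) {
    ref <- DNA_COMPLEMENT[[ref]]
    alt <- DNA_COMPLEMENT[[alt]]
  }
  paste0(ref, ">", alt)
}

#' Tabulate a substitution spectrum for a set of sites
#'
#' Counts the six pyrimidine-reference substitution classes over a set of
#' site ids, looking up ref/alt alleles in a site metadata table. INDELs and
#' otherwise unclassifiable sites are counted in `n_excluded`.
#'
#' @param site_ids Character vector of site ids.
#' @param site_meta Site metadata `data.frame` with columns `site_id`, `ref`,
#'   `alt` (as in a [genotype_matrix()]).
#' @return An object of class `SubstitutionSpectrum`: list with `counts`
#'   (named integer vector over [substitution_classes()]), `n_snv`, and
#'   `n_excluded`.
#' @export
substitution_spectrum <- function(site_ids, site_meta) {
  stopifnot(is.data.frame(site_meta), all(c("site_id", "ref", "alt") %in% names(site_meta)))
  missing_ids <- setdiff(site_ids, site_meta$site_id)
  if (length(missing_ids) > 0L) {
    stop2("site id(s) not found in site metadata: ", paste(missing_ids, collapse = ", "))
  }
  counts <- stats::setNames(integer(6L), substitution_classes())
  n_excluded <- 0L
  idx <- match(site_ids, site_meta$site_id)
  for (i in idx) {
    cls <- classify_substitution(site_meta$ref[i], site_meta$alt[i])
    if (is.na(cls)) n_excluded <- n_excluded + 1L else counts[[cls]] <- counts[[cls]] + 1L
  }
  structure(list(counts = counts, n_snv = sum(counts), n_excluded = n_excluded),
            class = "SubstitutionSpectrum")
}

#' @export
print.SubstitutionSpectrum <- function(x, ...) {
  cat("Substitution spectrum:", x$n_snv, "SNVs,", x$n_excluded, "excluded\n")
  print(x$counts)
  invisible(x)
}

#' Per-branch substitution spectra of newly acquired mutations
#'
#' For every edge of a clone tree, tabulates the substitution spectrum of the
#' mutations acquired on that edge (i.e. mutations new relative to the most
#' recent ancestor). INDELs on an edge are counted in that edge's
#' `n_excluded`.
#'
#' @param tree A `CloneTree` from [build_clone_tree()] or
#'   [simulate_clone_tree()].
#' @param site_meta Site metadata table resolving every acquired site id;
#'   defaults to the tree's own `site_meta` when present.
#' @return Named list (by child node id) of `SubstitutionSpectrum` objects.
#' @export
branch_spectra <- function(tree, site_meta = NULL) {
  stopifnot(inherits(tree, "CloneTree"))
  site_meta <- site_meta %||% tree$site_meta
  if (is.null(site_meta)) stop2("site_meta is required (tree carries none)")
  out <- lapply(tree$edges$child, function(child) {
    substitution_spectrum(tree$acquired[[child]], site_meta)
  })
  names(out) <- tree$edges$child
  out
}

#' Write per-branch spectra as a long-format TSV
#'
#' Columns `edge` (child node id), `class`, `count`; one extra row per edge
#' with class `"excluded"` carrying the INDEL/unclassifiable count.
#'
#' @param spectra Result of [branch_spectra()].
#' @param path Output file path.
#' @export
write_spectra_tsv <- function(spectra, path) {
  rows <- do.call(rbind, lapply(names(spectra), function(edge) {
    sp <- spectra[[edge]]
    data.frame(edge = edge,
               class = c(names(sp$counts), "excluded"),
               count = c(unname(sp$counts), sp$n_excluded),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
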