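#' Configure a synthetic single-cell genotyping simulation
#'
#' Describes a full generative scenario: a clone tree of a chosen shape with
#' mutations planted on its edges, cells sampled per clone with tissue
#' labels, and the noise model applied to the true genotypes. Defaults
#' emulate a targeted single-cell panel of ~60 mutation sites over a
#' primary-tumor/metastasis pair: a 10-mutation trunk, 3-5 mutations per
#' subsequent edge, 50 cells per observed clone, and a substitution signature
#' dominated by T>A transversions (the aristolochic-acid exposure pattern
#' seen in liver cancer).
#'
#' @param n_clones Number of tumor clones.
#' @param tree_shape `"bifurcating"`, `"linear"`, `"star"`, or `"custom"`
#'   (with `custom_parent`). Bifurcating places clone 1 under the root and
#'   clones `2i`, `2i+1` under clone `i`; linear chains the clones; star puts
#'   every clone directly under the root.
#' @param custom_parent For `"custom"`: integer vector, `custom_parent[i]` is
#'   the parent clone index of clone `i` (0 = root).
#' @param trunk_size Mutations on the root edge (the trunk). Must be 0 for
#'   star trees, where every edge is a private branch.
#' @param private_size_range Integer interval; each non-trunk edge acquires a
#'   uniformly drawn number of mutations in this range.
#' @param cells_per_clone Integer scalar or per-clone vector; clones with 0
#'   cells become unobserved ancestors.
#' @param n_paratumor_cells Paratumor (normal) cells, all-reference in truth.
#' @param tissue_assignment Character vector over clones with values
#'   `"tumor"`, `"metastasis"` or `"other"`; default all `"tumor"`.
#' @param panel_size Total target sites; sites without a planted mutation
#'   remain invariant reference columns.
#' @param ado_rate Per-allele dropout probability `d` in `[0, 1)`.
#' @param fp_rate False-positive probability `f` in `[0, 1)` (reference
#'   genotype observed mutant).
#' @param missing_rate Site-level missingness `m` in `[0, 1)`, applied after
#'   dropout.
#' @param signature_bias Probability vector over [substitution_classes()]
#'   used to draw ref/alt alleles for SNV sites.
#' @param indel_fraction Probability that a planted mutation is an INDEL.
#' @param purity Tumor purity used for pseudo-bulk VAFs, in `(0, 1]`.
#' @param seed Master seed; per-stage streams are derived from it so each
#'   stage is independently reproducible.
#' @return Object of class `SimulationConfig`.
#' @export
simulation_config <- function(n_clones = 4,
                              tree_shape = c("bifurcating", "linear", "star", "custom"),
                              custom_parent = NULL,
                              trunk_size = 10,
                              private_size_range = c(3, 5),
                              cells_per_clone = 50,
                              n_paratumor_cells = 10,
                              tissue_assignment = NULL,
                              panel_size = 60,
                              ado_rate = 0.1,
                              fp_rate = 0.005,
                              missing_rate = 0.05,
                              signature_bias = c("C>A" = 0.10, "C>G" = 0.05,
                                                 "C>T" = 0.15, "T>A" = 0.50,
                                                 "T>C" = 0.10, "T>G" = 0.10),
                              indel_fraction = 0.1,
                              purity = 1,
                              seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_clones >= 1, trunk_size >= 0, panel_size >= 1,
            n_paratumor_cells >= 0, length(private_size_range) == 2L)
  if (private_size_range[1] < 0 || private_size_range[1] > private_size_range[2]) {
    stop2("private_size_range must be a non-negative interval (lo <= hi)")
  }
  for (p in list(ado_rate = ado_rate, fp_rate = fp_rate, missing_rate = missing_rate)) {
    if (!is_prob(p) || p >= 1) stop2("ado_rate, fp_rate and missing_rate must be in [0, 1)")
  }
  if (!is_prob(indel_fraction)) stop2("indel_fraction must be in [0, 1]")
  if (!is.numeric(purity) || purity <= 0 || purity > 1) stop2("purity must be in (0, 1]")
  if (length(signature_bias) != 6L || any(signature_bias < 0) ||
      abs(sum(signature_bias) - 1) > 1e-8) {
    stop2("signature_bias must be 6 non-negative probabilities summing to 1")
  }
  names(signature_bias) <- substitution_classes()
  if (tree_shape == "star" && trunk_size > 0) {
    stop2("star trees have no trunk edge; set trunk_size = 0")
  }
  if (tree_shape == "custom") {
    if (is.null(custom_parent) || length(custom_parent) != n_clones) {
      stop2("custom tree shape requires custom_parent of length n_clones")
    }
    if (any(custom_parent < 0) || any(custom_parent > n_clones) ||
        any(custom_parent >= seq_len(n_clones))) {
      stop2("custom_parent[i] must reference the root (0) or an earlier clone (< i)")
    }
  }
  cells_per_clone <- as.integer(rep_len(cells_per_clone, n_clones))
  if (any(cells_per_clone < 0)) stop2("cells_per_clone must be non-negative")
  tissue_assignment <- tissue_assignment %||% rep("tumor", n_clones)
  if (length(tissue_assignment) != n_clones) {
    stop2("tissue_assignment must name a tissue for every clone")
  }
  bad <- setdiff(unique(tissue_assignment), c("tumor", "metastasis", "other"))
  if (length(bad) > 0L) stop2("unknown tissue label(s) in tissue_assignment: ",
                              paste(bad, collapse = ", "))
  structure(list(n_clones = as.integer(n_clones), tree_shape = tree_shape,
                 custom_parent = custom_parent, trunk_size = as.integer(trunk_size),
                 private_size_range = as.integer(private_size_range),
                 cells_per_clone = cells_per_clone,
                 n_paratumor_cells = as.integer(n_paratumor_cells),
                 tissue_assignment = tissue_assignment,
                 panel_size = as.integer(panel_size),
                 ado_rate = ado_rate, fp_rate = fp_rate, missing_rate = missing_rate,
                 signature_bias = signature_bias, indel_fraction = indel_fraction,
                 purity = purity, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Preset scenario: shared trunk, two tissues, unobserved metastasis ancestor
#'
#' A five-clone bifurcating truth with four observed clones: an observed
#' founder clone carrying only the 10-mutation trunk, one primary-tumor
#' subclone, and two metastasis clones descending from an *unobserved*
#' metastasis ancestor (0 sampled cells) whose private edge mutations are
#' therefore metastasis-private clonal. This reproduces the qualitative
#' "common origin, independent evolution" structure of a primary
#' tumor / portal-vein-tumor-thrombus pair and exercises virtual-ancestor
#' insertion during reconstruction.
#'
#' @param seed Master seed.
#' @param cells_per_observed_clone Cells sampled per observed clone.
#' @param ... Further arguments passed to [simulation_config()].
#' @return A `SimulationConfig`.
#' @export
two_tissue_preset <- function(seed = 1L, cells_per_observed_clone = 50, ...) {
  simulation_config(
    n_clones = 5, tree_shape = "bifurcating", trunk_size = 10,
    private_size_range = c(3, 5),
    cells_per_clone = c(cells_per_observed_clone, 0, cells_per_observed_clone,
                        cells_per_observed_clone, cells_per_observed_clone),
    tissue_assignment = c("tumor", "metastasis", "tumor", "metastasis", "metastasis"),
    seed = seed, ...)
}

clone_parent_vector <- function(config) {
  n <- config$n_clones
  switch(config$tree_shape,
         linear = c(0L, seq_len(n - 1L)),
         star = rep(0L, n),
         bifurcating = c(0L, floor(seq(2L, length.out = max(0L, n - 1L)) / 2L)),
         custom = as.integer(config$custom_parent))
}

#' Simulate a clone tree with mutations planted on its edges
#'
#' Builds the true clonal phylogeny for a scenario: a rooted tree whose root
#' carries no mutations, with a disjoint set of newly planted mutations on
#' every edge. Each planted SNV gets ref/alt alleles drawn from the
#' configured substitution-signature bias (reported on either strand with
#' equal probability); a configurable fraction of mutations are INDELs.
#' Panel sites without a planted mutation are generated as invariant
#' reference columns. The panel's site metadata table is attached to the
#' returned tree as `$site_meta`.
#'
#' @param config A `SimulationConfig`.
#' @return A `CloneTree` with node ids `"root"`, `"clone1"`, ...,
#'   observed = TRUE for all clones, and `$site_meta` describing all
#'   `panel_size` sites.
#' @export
simulate_clone_tree <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  ss <- stage_seeds(config$seed)
  parent <- clone_parent_vector(config)
  n <- config$n_clones
  with_seed(ss[["tree"]], {
    lo <- config$private_size_range[1]; hi <- config$private_size_range[2]
    edge_sizes <- vapply(seq_len(n), function(i) {
      if (i == 1L && parent[1] == 0L && config$tree_shape != "star") {
        config$trunk_size
      } else {
        sample(seq.int(lo, hi), 1L)
      }
    }, integer(1))
    total <- sum(edge_sizes)
    if (total > config$panel_size) {
      stop2("configuration error: ", total, " mutations requested but panel_size is ",
            config$panel_size)
    }
    w <- max(2L, nchar(as.character(config$panel_size)))
    site_ids <- sprintf("M%0*d", w, seq_len(config$panel_size))
    genes <- sprintf("GENE%0*d", w, seq_len(config$panel_size))
    chrom <- paste0("chr", sample(1:22, config$panel_size, replace = TRUE))
    pos <- sort(sample.int(2e8L, config$panel_size))
    is_planted <- seq_len(config$panel_size) %in%
      sample.int(config$panel_size, total)
    is_indel <- is_planted & (stats::runif(config$panel_size) < config$indel_fraction)
    ref <- alt <- character(config$panel_size)
    classes <- substitution_classes()
    for (i in seq_len(config$panel_size)) {
      if (is_indel[i]) {
        b <- sample(DNA_BASES, 1L)
        if (stats::runif(1) < 0.5) {                      # insertion
          ref[i] <- b; alt[i] <- paste0(b, sample(DNA_BASES, 1L))
        } else {                                          # deletion
          ref[i] <- paste0(b, sample(DNA_BASES, 1L)); alt[i] <- b
        }
      } else {
        cls <- sample(classes, 1L, prob = config$signature_bias)
        r <- substr(cls, 1L, 1L); a <- substr(cls, 3L, 3L)
        if (stats::runif(1) < 0.5) {                      # opposite strand
          r <- DNA_COMPLEMENT[[r]]; a <- DNA_COMPLEMENT[[a]]
        }
        ref[i] <- r; alt[i] <- a
      }
    }
    site_meta <- data.frame(site_id = site_ids, chrom = chrom, pos = pos,
                            ref = ref, alt = alt, gene = genes,
                            variant_class = ifelse(is_indel, "INDEL", "SNV"),
                            vaf = NA_real_, stringsAsFactors = FALSE)
    planted <- sample(site_ids[is_planted])                # shuffled assignment order
    clone_ids <- paste0("clone", seq_len(n))
    acquired <- vector("list", n)
    names(acquired) <- clone_ids
    offset <- 0L
    for (i in seq_len(n)) {
      acquired[[i]] <- sort(planted[seq_len(edge_sizes[i]) + offset])
      offset <- offset + edge_sizes[i]
    }
    cumulative <- vector("list", n + 1L)
    names(cumulative) <- c("root", clone_ids)
    cumulative[["root"]] <- character()
    for (i in seq_len(n)) {
      p <- if (parent[i] == 0L) "root" else clone_ids[parent[i]]
      cumulative[[clone_ids[i]]] <- sort(union(cumulative[[p]], acquired[[i]]))
    }
    nodes <- data.frame(id = c("root", clone_ids),
                        observed = c(FALSE, rep(TRUE, n)), stringsAsFactors = FALSE)
    edges <- data.frame(parent = ifelse(parent == 0L, "root", clone_ids[pmax(parent, 1L)]),
                        child = clone_ids, stringsAsFactors = FALSE)
    clone_tree(nodes, edges, cumulative, acquired, root = "root",
               site_meta = site_meta)
  })
}

#' Sample single cells from a simulated clone tree
#'
#' Assigns the configured number of cells to each clone (clones with 0 cells
#' remain unobserved ancestors), gives every tumor cell its clone's
#' cumulative mutation set as true genotype, adds all-reference paratumor
#' cells, and attaches tissue labels.
#'
#' @param tree A `CloneTree` from [simulate_clone_tree()].
#' @param config The `SimulationConfig` used to build `tree`.
#' @return Object of class `GroundTruth`: list with `true_tree` (tissue
#'   counts filled in), `cell_labels` (named map cell -> clone over tumor
#'   cells), `true_matrix` (noise-free `GenotypeMatrix`), and
#'   `clone_fractions` (per-clone proportions among tumor cells).
#' @export
sample_cells <- function(tree, config) {
  stopifnot(inherits(tree, "CloneTree"), inherits(config, "SimulationConfig"))
  clone_ids <- paste0("clone", seq_len(config$n_clones))
  if (!all(clone_ids %in% tree$nodes$id)) stop2("tree does not match config")
  if (length(config$tissue_assignment) != config$n_clones) {
    stop2("configuration error: tissue_assignment missing a clone")
  }
  counts <- config$cells_per_clone
  site_ids <- tree$site_meta$site_id
  cell_ids <- character(0); tissues <- character(0); labels <- character(0)
  rows <- list()
  for (i in seq_len(config$n_clones)) {
    if (counts[i] == 0L) next
    ids <- sprintf("%s_c%03d", clone_ids[i], seq_len(counts[i]))
    cell_ids <- c(cell_ids, ids)
    tissues <- c(tissues, rep(config$tissue_assignment[i], counts[i]))
    labels <- c(labels, rep(clone_ids[i], counts[i]))
    row <- as.integer(site_ids %in% tree$cumulative[[clone_ids[i]]])
    rows <- c(rows, rep(list(row), counts[i]))
  }
  if (config$n_paratumor_cells > 0L) {
    ids <- sprintf("para_c%03d", seq_len(config$n_paratumor_cells))
    cell_ids <- c(cell_ids, ids)
    tissues <- c(tissues, rep("paratumor", config$n_paratumor_cells))
    rows <- c(rows, rep(list(integer(length(site_ids))), config$n_paratumor_cells))
  }
  calls <- do.call(rbind, rows)
  dimnames(calls) <- list(cell_ids, site_ids)
  cell_meta <- data.frame(cell_id = cell_ids, tissue = tissues, stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, tree$site_meta, cell_meta)
  tumor_cells <- cell_ids[tissues != "paratumor"]
  cell_labels <- stats::setNames(labels, tumor_cells)
  tissue_counts <- lapply(seq_len(config$n_clones), function(i) {
    stats::setNames(as.integer(counts[i]), config$tissue_assignment[i])
  })
  names(tissue_counts) <- clone_ids
  tree$tissue_counts <- tissue_counts
  fractions <- if (sum(counts) > 0L) counts / sum(counts) else rep(0, config$n_clones)
  structure(list(true_tree = tree,
                 cell_labels = cell_labels,
                 true_matrix = gm,
                 clone_fractions = stats::setNames(fractions, clone_ids)),
            class = "GroundTruth")
}

#' Apply the allele-dropout / false-positive / missingness noise model
#'
#' Entry-wise, independently, with dropout `d`, false-positive rate `f` and
#' missingness `m` from the configuration: a true heterozygous-mutant call
#' becomes missing when both alleles drop (probability `d^2`), reference when
#' only the mutant allele drops (probability `d(1-d)`), and stays mutant
#' otherwise; a true reference call flips to mutant with probability `f`.
#' Afterwards every non-missing entry is masked missing with probability `m`.
#' Deterministic given the configuration seed; matrix dimensions are never
#' changed.
#'
#' @param truth A `GroundTruth` from [sample_cells()].
#' @param config The `SimulationConfig`.
#' @return A noisy `GenotypeMatrix` with the same cells, sites and metadata.
#' @export
apply_noise <- function(truth, config) {
  stopifnot(inherits(truth, "GroundTruth"), inherits(config, "SimulationConfig"))
  ss <- stage_seeds(config$seed)
  gm <- truth$true_matrix
  calls <- gm$calls
  d <- config$ado_rate; f <- config$fp_rate; m <- config$missing_rate
  with_seed(ss[["noise"]], {
    u <- matrix(stats::runif(length(calls)), nrow(calls), ncol(calls))
    out <- calls
    mut <- !is.na(calls) & calls == 1L
    out[mut & u < d^2] <- NA_integer_
    out[mut & u >= d^2 & u < d^2 + d * (1 - d)] <- 0L
    ref <- !is.na(calls) & calls == 0L
    out[ref & u < f] <- 1L
    u2 <- matrix(stats::runif(length(calls)), nrow(calls), ncol(calls))
    out[!is.na(out) & u2 < m] <- NA_integer_
    genotype_matrix(out, gm$site_meta, gm$cell_meta)
  })
}

#' Pseudo-bulk variant allele frequencies implied by the clone fractions
#'
#' Under the heterozygous-diploid assumption, a site's bulk VAF is half the
#' fraction of tumor cells carrying it, scaled by purity:
#' `VAF = purity * sum(fractions of carrying clones) / 2`. Invariant
#' reference sites get VAF 0.
#'
#' @param truth A `GroundTruth`.
#' @param purity Tumor purity in `(0, 1]`.
#' @return Named numeric vector of VAFs over all panel sites.
#' @export
simulate_bulk_vaf <- function(truth, purity = 1) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (!is.numeric(purity) || length(purity) != 1L || purity <= 0 || purity > 1) {
    stop2("purity must be in (0, 1]")
  }
  tree <- truth$true_tree
  site_ids <- tree$site_meta$site_id
  fr <- truth$clone_fractions
  vaf <- vapply(site_ids, function(s) {
    carrying <- names(fr)[vapply(names(fr), function(cl) s %in% tree$cumulative[[cl]], TRUE)]
    purity * sum(fr[carrying]) / 2
  }, numeric(1))
  stats::setNames(vaf, site_ids)
}

#' Simulate a heterozygous-germline control matrix for ADO estimation
#'
#' Generates allele-presence summaries at sites heterozygous germline in
#' every cell: each allele independently drops with probability `ado_rate`
#' (both dropping gives a missing observation, one dropping a homozygous-
#' looking `"ref-only"`/`"alt-only"` call), then site-level missingness is
#' applied.
#'
#' @param n_cells,n_sites Matrix dimensions.
#' @param ado_rate Per-allele dropout probability.
#' @param missing_rate Additional missingness on non-missing entries.
#' @param seed RNG seed.
#' @return Character matrix with entries in
#'   `{"both", "ref-only", "alt-only", NA}`.
#' @export
simulate_control_matrix <- function(n_cells, n_sites, ado_rate,
                                    missing_rate = 0, seed = 1L) {
  stopifnot(is_prob(ado_rate), ado_rate < 1, is_prob(missing_rate), missing_rate < 1)
  with_seed(seed, {
    n <- n_cells * n_sites
    drop_ref <- stats::runif(n) < ado_rate
    drop_alt <- stats::runif(n) < ado_rate
    x <- rep("both", n)
    x[drop_ref & !drop_alt] <- "alt-only"
    x[!drop_ref & drop_alt] <- "ref-only"
    x[drop_ref & drop_alt] <- NA
    x[!is.na(x) & stats::runif(n) < missing_rate] <- NA
    matrix(x, n_cells, n_sites,
           dimnames = list(sprintf("cell%03d", seq_len(n_cells)),
                           sprintf("ctrl%03d", seq_len(n_sites))))
  })
}

#' Run a full simulation scenario
#'
#' Convenience wrapper: builds the clone tree, samples cells, applies noise,
#' computes pseudo-bulk VAFs (attached to the site metadata of both the true
#' and the noisy matrix), and simulates a germline control matrix at the same
#' dropout rate.
#'
#' @param config A `SimulationConfig`.
#' @param n_control_obs Number of control observations for the ADO control
#'   matrix (default 10000).
#' @return List with `config`, `truth` (`GroundTruth`), `matrix` (noisy
#'   `GenotypeMatrix`), `control` and `vaf`.
#' @export
simulate_dataset <- function(config, n_control_obs = 10000L) {
  stopifnot(inherits(config, "SimulationConfig"))
  ss <- stage_seeds(config$seed)
  tree <- simulate_clone_tree(config)
  truth <- sample_cells(tree, config)
  noisy <- apply_noise(truth, config)
  vaf <- simulate_bulk_vaf(truth, purity = config$purity)
  truth$true_matrix$site_meta$vaf <- unname(vaf[truth$true_matrix$site_meta$site_id])
  noisy$site_meta$vaf <- unname(vaf[noisy$site_meta$site_id])
  n_ctrl_cells <- max(1L, as.integer(ceiling(sqrt(n_control_obs))))
  n_ctrl_sites <- as.integer(ceiling(n_control_obs / n_ctrl_cells))
  control <- simulate_control_matrix(n_ctrl_cells, n_ctrl_sites,
                                     ado_rate = config$ado_rate,
                                     missing_rate = config$missing_rate,
                                     seed = ss[["control"]])
  list(config = config, truth = truth, matrix = noisy, control = control, vaf = vaf)
}

#' Write a simulated dataset to disk
#'
#' Emits the noisy genotype matrix, site and cell TSV tables, a minimal VCF
#' of the site table, the ground-truth clone tree as JSON, and the true
#' cell-to-clone labels as TSV.
#'
#' @param sim Result of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_genotype_matrix(sim$matrix, p("matrix.tsv"), p("sites.tsv"), p("cells.tsv"))
  write_sites_vcf(sim$matrix$site_meta, p("sites.vcf"))
  write_clone_tree_json(sim$truth$true_tree, p("true_tree.json"))
  utils::write.table(data.frame(cell_id = names(sim$truth$cell_labels),
                                clone_id = unname(sim$truth$cell_labels)),
                     p("true_cell_labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(control = c(sim$control)), p("control.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p("matrix.tsv"), p("sites.tsv"), p("cells.tsv"), p("sites.vcf"),
              p("true_tree.json"), p("true_cell_labels.tsv"), p("control.tsv")))
}
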