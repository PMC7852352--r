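#' Configure an end-to-end run
#'
#' Exactly one of `simulate` (a [simulation_config()] or a list of its
#' arguments) and `inputs` (paths to `matrix`, `sites`, `cells` TSVs and
#' optionally `controls`) must be given.
#'
#' @param simulate A `SimulationConfig`, or a list of arguments for
#'   [simulation_config()].
#' @param inputs Named list of input paths (`matrix`, `sites`, `cells`,
#'   optional `controls`).
#' @param outdir Output directory for all artifacts.
#' @param tau,min_cells,min_overlap,min_site_coverage Clone-calling
#'   parameters, see [call_clones()].
#' @param max_paratumor_fraction Germline/artifact filter threshold.
#' @param phylo_mode Search mode for [search_mp_tree()].
#' @param include_tissues Tissues entering the cell-level parsimony tree.
#' @param seed Seed for the run (drives the phylo traversal order; the
#'   simulation carries its own seed).
#' @return Object of class `RunConfig`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL, outdir = tempfile("ctrun"),
                       tau = 0.07, min_cells = 10L, min_overlap = 10L,
                       min_site_coverage = 0.5, max_paratumor_fraction = 0.1,
                       phylo_mode = "auto",
                       include_tissues = c("tumor", "metastasis"), seed = 1L) {
  if (is.null(simulate) == is.null(inputs)) {
    stop2("exactly one of 'simulate' and 'inputs' must be given")
  }
  if (!is.null(simulate) && !inherits(simulate, "SimulationConfig")) {
    simulate <- do.call(simulation_config, simulate)
  }
  if (!is.null(inputs)) {
    if (!all(c("matrix", "sites", "cells") %in% names(inputs))) {
      stop2("inputs must name 'matrix', 'sites' and 'cells' paths")
    }
  }
  stopifnot(tau >= 0, min_cells >= 1, min_overlap >= 1,
            is_prob(min_site_coverage), is_prob(max_paratumor_fraction))
  phylo_mode <- match.arg(phylo_mode, c("auto", "exhaustive", "nni"))
  structure(list(simulate = simulate, inputs = inputs, outdir = outdir,
                 tau = tau, min_cells = as.integer(min_cells),
                 min_overlap = as.integer(min_overlap),
                 min_site_coverage = min_site_coverage,
                 max_paratumor_fraction = max_paratumor_fraction,
                 phylo_mode = phylo_mode, include_tissues = include_tissues,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]'s arguments; a `simulate:` block holds
#' [simulation_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$signature_bias)) {
      y$simulate$signature_bias <- unlist(y$simulate$signature_bias)
    }
    if (!is.null(y$simulate$cells_per_clone)) {
      y$simulate$cells_per_clone <- unlist(y$simulate$cells_per_clone)
    }
  }
  do.call(run_config, y)
}

run_stage <- function(stage, expr, warnings_env) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop2("stage '", stage, "' failed: ", conditionMessage(e))
    }),
    warning = function(w) {
      warnings_env$log <- rbind(warnings_env$log,
                                data.frame(stage = stage,
                                           message = conditionMessage(w),
                                           stringsAsFactors = FALSE))
      invokeRestart("muffleWarning")
    })
}

#' Run the full clonal-evolution analysis
#'
#' Executes, in order: data acquisition (simulation or file input), QC
#' (allele-dropout estimate, VAF concordance, mutated cell fractions),
#' germline/artifact filtering against paratumor cells, clone calling,
#' conflict resolution, clone-tree reconstruction with virtual ancestors,
#' mutation classification, per-branch substitution spectra, and the
#' maximum-parsimony cell tree. Every intermediate artifact is written to
#' the output directory together with a machine-readable manifest (all
#' parameters and their defaults, seed, package version, per-stage warnings)
#' and a Markdown report. Identical configurations produce byte-identical
#' outputs.
#'
#' @param config A `RunConfig`.
#' @return Invisibly, the report bundle: list with `qc`, `clones`,
#'   `conflicts`, `tree`, `classification`, `spectra`, `alignment`,
#'   `cell_tree`, `manifest` and `paths`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)
  wenv <- new.env()
  wenv$log <- data.frame(stage = character(), message = character(),
                         stringsAsFactors = FALSE)

  acq <- run_stage("input", {
    if (!is.null(config$simulate)) {
      sim <- simulate_dataset(config$simulate)
      write_simulation(sim, config$outdir)
      list(gm = sim$matrix, control = sim$control, truth = sim$truth)
    } else {
      gm <- read_genotype_matrix(config$inputs$matrix, config$inputs$sites,
                                 config$inputs$cells)
      control <- NULL
      if (!is.null(config$inputs$controls)) {
        ctrl_df <- utils::read.delim(config$inputs$controls,
                                     colClasses = "character")
        control <- as.matrix(ctrl_df)
        control[control == "NA"] <- NA
      }
      list(gm = gm, control = control, truth = NULL)
    }
  }, wenv)

  qc <- run_stage("qc", qc_report(acq$gm, control = acq$control,
                                  max_paratumor_fraction = config$max_paratumor_fraction),
                  wenv)
  gmf <- qc$filtered_matrix

  clones <- run_stage("clones", call_clones(gmf, tau = config$tau,
                                            min_cells = config$min_cells,
                                            min_overlap = config$min_overlap,
                                            min_site_coverage = config$min_site_coverage),
                      wenv)
  if (length(clones$clones) == 0L) {
    stop2("stage 'clones' failed: no cluster reached min_cells = ", config$min_cells)
  }
  fractions <- mutated_cell_fraction(gmf)
  resolved <- run_stage("conflicts", resolve_conflicts(clones, fractions), wenv)
  tree <- run_stage("tree", build_clone_tree(resolved$clones), wenv)
  classification <- run_stage("classify",
                              classify_mutations(tree, sites = gmf$site_meta$site_id),
                              wenv)
  spectra <- run_stage("spectra", branch_spectra(tree, gmf$site_meta), wenv)
  phylo_cells <- gmf$cell_meta$cell_id[gmf$cell_meta$tissue %in% config$include_tissues]
  alignment <- run_stage("phylo", build_alignment(gmf, cells = phylo_cells), wenv)
  cell_tree <- run_stage("phylo", search_mp_tree(alignment, mode = config$phylo_mode,
                                                 seed = config$seed), wenv)

  run_stage("write", {
    jsonlite::write_json(list(
      ado_estimate = qc$ado_estimate,
      vaf_concordance_r = qc$vaf_concordance_r,
      mutated_cell_fraction = as.list(qc$mutated_cell_fraction),
      filtered_sites = qc$filtered_sites), p("qc.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
    write_clone_assignments(clones, p("assignments.tsv"))
    utils::write.table(resolved$removed, p("removed_sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_clone_tree_json(tree, p("clone_tree.json"))
    write_classification(classification, p("classification.tsv"))
    write_spectra_tsv(spectra, p("spectra.tsv"))
    write_alignment_fasta(alignment, p("alignment.fasta"))
    write_cell_tree(cell_tree, p("cell_tree.nwk"))
  }, wenv)

  manifest <- list(
    package = "clonetracer",
    version = as.character(utils::packageVersion("clonetracer")),
    seed = config$seed,
    parameters = list(tau = config$tau, min_cells = config$min_cells,
                      min_overlap = config$min_overlap,
                      min_site_coverage = config$min_site_coverage,
                      max_paratumor_fraction = config$max_paratumor_fraction,
                      phylo_mode = config$phylo_mode,
                      include_tissues = config$include_tissues),
    simulate = if (!is.null(config$simulate)) unclass(config$simulate) else NULL,
    inputs = config$inputs,
    stages = c("input", "qc", "clones", "conflicts", "tree", "classify",
               "spectra", "phylo", "write"),
    n_cells = nrow(acq$gm$calls), n_sites = ncol(acq$gm$calls),
    n_clones = length(clones$clones),
    n_unassigned = length(clones$unassigned),
    n_sites_filtered = nrow(qc$filtered_sites),
    n_sites_conflict_removed = nrow(resolved$removed),
    parsimony_score = cell_tree$score,
    warnings = wenv$log)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null", null = "null")

  report <- render_report(qc, clones, resolved, tree, classification, spectra,
                          cell_tree)
  writeLines(report, p("report.md"))

  invisible(list(qc = qc, clones = clones, conflicts = resolved, tree = tree,
                 classification = classification, spectra = spectra,
                 alignment = alignment, cell_tree = cell_tree,
                 manifest = manifest, truth = acq$truth,
                 paths = list(outdir = config$outdir)))
}

render_report <- function(qc, clones, resolved, tree, classification, spectra,
                          cell_tree) {
  lines <- c("# Clonal evolution report", "")
  lines <- c(lines, "## QC", "",
             sprintf("- ADO estimate: %s",
                     ifelse(is.na(qc$ado_estimate), "not estimated",
                            sprintf("%.4f", qc$ado_estimate))),
             sprintf("- VAF concordance r: %s",
                     ifelse(is.na(qc$vaf_concordance_r), "not computed",
                            sprintf("%.4f", qc$vaf_concordance_r))),
             sprintf("- Sites removed as germline/artifact: %d", nrow(qc$filtered_sites)),
             sprintf("- Sites removed as conflicting: %d", nrow(resolved$removed)), "")
  lines <- c(lines, "## Clones", "", "| clone | cells | mutations | tissues |",
             "|---|---|---|---|")
  for (cl in clones$clones) {
    tc <- cl$tissue_counts
    lines <- c(lines, sprintf("| %s | %d | %d | %s |", cl$clone_id,
                              length(cl$cells), sum(cl$consensus),
                              paste(sprintf("%s:%d", names(tc), tc), collapse = " ")))
  }
  lines <- c(lines, sprintf("| unassigned | %d | - | - |", length(clones$unassigned)), "")
  lines <- c(lines, "## Clone tree", "")
  for (i in seq_len(nrow(tree$edges))) {
    ch <- tree$edges$child[i]
    virt <- !tree$nodes$observed[tree$nodes$id == ch]
    lines <- c(lines, sprintf("- %s -> %s%s : acquires {%s}", tree$edges$parent[i],
                              ch, ifelse(virt, " (virtual ancestor)", ""),
                              paste(tree$acquired[[ch]], collapse = ", ")))
  }
  lines <- c(lines, "", "## Mutation classification", "")
  tab <- table(classification$category)
  for (nm in names(tab)) lines <- c(lines, sprintf("- %s: %d", nm, tab[[nm]]))
  lines <- c(lines, "", "## Substitution spectra (acquired SNVs per branch)", "",
             paste0("| edge | ", paste(substitution_classes(), collapse = " | "),
                    " | excluded |"),
             paste0(paste(rep("|---", 8), collapse = ""), "|"))
  for (edge in names(spectra)) {
    sp <- spectra[[edge]]
    lines <- c(lines, paste0("| ", edge, " | ",
                             paste(sp$counts, collapse = " | "), " | ",
                             sp$n_excluded, " |"))
  }
  lines <- c(lines, "", "## Cell-level maximum parsimony tree", "",
             sprintf("- %d unique sequences (%s search), parsimony score %d",
                     cell_tree$n_unique, cell_tree$mode, cell_tree$score))
  lines
}

## ---- ground-truth comparison helpers --------------------------------------

#' Compare inferred clone assignments with the simulated truth
#'
#' Adjusted Rand index between the inferred cell-to-clone partition and the
#' ground-truth labels. Cells the caller left unassigned make no clone-
#' membership claim, so they are excluded from the partition comparison and
#' their fraction is reported in the `unassigned_fraction` attribute (and as
#' its own column by [recovery_benchmark()]); an assignment is only as
#' trustworthy as both numbers together.
#'
#' @param clones A `CloneSet`.
#' @param truth A `GroundTruth`.
#' @param unassigned `"exclude"` (default) drops unassigned cells from the
#'   comparison; `"singletons"` keeps them as one-cell groups, so wholesale
#'   abstention drives the index toward 0 instead of being invisible.
#' @return ARI in `[-1, 1]` (1 = identical partitions), with attribute
#'   `unassigned_fraction`.
#' @export
clone_ari <- function(clones, truth, unassigned = c("exclude", "singletons")) {
  unassigned <- match.arg(unassigned)
  stopifnot(inherits(clones, "CloneSet"), inherits(truth, "GroundTruth"))
  cells <- intersect(names(clones$assignments), names(truth$cell_labels))
  inferred <- clones$assignments[cells]
  ok <- !is.na(inferred)
  ari <- if (unassigned == "exclude") {
    mclust::adjustedRandIndex(inferred[ok], truth$cell_labels[cells][ok])
  } else {
    inferred[!ok] <- paste0(".u", seq_len(sum(!ok)))
    mclust::adjustedRandIndex(inferred, truth$cell_labels[cells])
  }
  structure(ari, unassigned_fraction = mean(!ok))
}

# the perfect phylogeny the observed part of the truth should reconstruct to
expected_observed_tree <- function(truth) {
  tree <- truth$true_tree
  obs <- names(truth$clone_fractions)[truth$clone_fractions > 0]
  sites <- tree$site_meta$site_id
  cmat <- do.call(rbind, lapply(obs, function(cl) {
    as.integer(sites %in% tree$cumulative[[cl]])
  }))
  dimnames(cmat) <- list(obs, sites)
  build_clone_tree(cmat)
}

tree_signature <- function(tree) {
  sort(vapply(seq_len(nrow(tree$edges)), function(i) {
    p <- tree$edges$parent[i]; ch <- tree$edges$child[i]
    paste(paste(sort(tree$cumulative[[p]]), collapse = "+"),
          paste(sort(tree$cumulative[[ch]]), collapse = "+"), sep = " -> ")
  }, character(1)))
}

#' Ground-truth recovery checks for an inferred clone tree
#'
#' `trunk_recovered()`: the mutations carried by every inferred observed
#' clone exactly equal the true trunk (mutations shared by all observed true
#' clones). `virtual_ancestor_recovered()`: every unobserved true ancestor
#' that the observed clones imply (a virtual node of the perfect phylogeny
#' restricted to observed clones) is present in the inferred tree as a
#' virtual node with the identical cumulative mutation set.
#' `topology_recovered()`: the inferred tree and the expected
#' observed-restricted truth have identical edge structure over cumulative
#' mutation sets.
#'
#' @param tree An inferred `CloneTree`.
#' @param truth A `GroundTruth`.
#' @return Logical scalar.
#' @export
trunk_recovered <- function(tree, truth) {
  obs <- tree$nodes$id[tree$nodes$observed]
  inferred_trunk <- Reduce(intersect, tree$cumulative[obs])
  true_obs <- names(truth$clone_fractions)[truth$clone_fractions > 0]
  true_trunk <- Reduce(intersect, truth$true_tree$cumulative[true_obs])
  setequal(inferred_trunk, true_trunk)
}

#' @rdname trunk_recovered
#' @export
virtual_ancestor_recovered <- function(tree, truth) {
  expected <- expected_observed_tree(truth)
  exp_virtual <- expected$nodes$id[!expected$nodes$observed &
                                     expected$nodes$id != expected$root]
  inf_virtual <- tree$nodes$id[!tree$nodes$observed & tree$nodes$id != tree$root]
  all(vapply(exp_virtual, function(v) {
    any(vapply(inf_virtual, function(w) {
      setequal(tree$cumulative[[w]], expected$cumulative[[v]])
    }, TRUE))
  }, TRUE))
}

#' @rdname trunk_recovered
#' @export
topology_recovered <- function(tree, truth) {
  identical(tree_signature(tree), tree_signature(expected_observed_tree(truth)))
}

#' Benchmark parameter recovery over a grid of noise settings
#'
#' For every grid point, simulates `n_seeds` replicates of the two-tissue
#' shared-trunk scenario ([two_tissue_preset()]), runs clone calling and
#' tree reconstruction, and scores recovery against the ground truth:
#' clone-assignment adjusted Rand index, exact trunk-set recovery, virtual-
#' ancestor and topology recovery, and the bias of the allele-dropout
#' estimator at 10^4 control observations.
#'
#' @param grid `data.frame` with columns `d`, `f`, `m`, `cells_per_clone`.
#' @param n_seeds Replicates per grid point.
#' @param base_seed Offset from which per-replicate seeds are derived.
#' @param tau,min_cells Clone-calling parameters (see [call_clones()]); for
#'   near-noiseless grids `tau` should sit below the minimum clone
#'   divergence (3 mutations on a 60-site panel is 0.05) rather than at the
#'   dropout-calibrated default.
#' @param path Optional TSV output path.
#' @return `data.frame` with one row per grid point: mean ARI, unassigned
#'   rate, recovery rates, and ADO-estimator bias (`mean(d_hat) - d`).
#' @export
recovery_benchmark <- function(grid, n_seeds = 50L, base_seed = 1L,
                               tau = 0.07, min_cells = 10L, path = NULL) {
  stopifnot(is.data.frame(grid),
            all(c("d", "f", "m", "cells_per_clone") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    d <- grid$d[g]; f <- grid$f[g]; m <- grid$m[g]
    cpc <- grid$cells_per_clone[g]
    res <- vapply(seq_len(n_seeds), function(s) {
      cfg <- two_tissue_preset(seed = base_seed + 7919L * g + s,
                               cells_per_observed_clone = cpc,
                               ado_rate = d, fp_rate = f, missing_rate = m)
      sim <- simulate_dataset(cfg)
      clones <- call_clones(sim$matrix, tau = tau, min_cells = min_cells)
      ari <- clone_ari(clones, sim$truth)
      resolved <- resolve_conflicts(clones, mutated_cell_fraction(sim$matrix))
      tree <- build_clone_tree(resolved$clones)
      d_hat <- estimate_ado(sim$control)
      c(ari = as.numeric(ari),
        unassigned = attr(ari, "unassigned_fraction"),
        trunk = as.numeric(trunk_recovered(tree, sim$truth)),
        virtual = as.numeric(virtual_ancestor_recovered(tree, sim$truth)),
        topology = as.numeric(topology_recovered(tree, sim$truth)),
        d_hat = d_hat)
    }, numeric(6))
    data.frame(d = d, f = f, m = m, cells_per_clone = cpc, n_seeds = n_seeds,
               mean_ari = mean(res["ari", ]),
               unassigned_rate = mean(res["unassigned", ]),
               trunk_recovery = mean(res["trunk", ]),
               virtual_recovery = mean(res["virtual", ]),
               topology_recovery = mean(res["topology", ]),
               ado_bias = mean(res["d_hat", ]) - d)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
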