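## --- configuration ----------------------------------------------------

default_config <- function() {
  list(grid_K = 300, grid_L = 300,
       combos = names(map_combos()),
       f_range_ml = 1:50, f_range_k = 1:100,
       learners = learner_configs(),
       folds = 10, seed = 1, tolerance = 0,
       axes = 2, n_perm = 999, wt_label = "WT",
       out_dir = NULL)
}

#' Read a run configuration
#'
#' Merges a YAML file (or list) over the package defaults and validates
#' the fields against the module preconditions.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated configuration list.
#' @export
read_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (cfg$grid_K < 2 || cfg$grid_L < 2) stopf("grid dims must be >= 2")
  if (!all(cfg$combos %in% names(map_combos())))
    stopf("unknown combo in config")
  if (!all(cfg$learners %in% learner_configs()))
    stopf("unknown learner in config")
  if (cfg$folds < 2) stopf("folds must be >= 2")
  if (cfg$n_perm < 1) stopf("n_perm must be >= 1")
  cfg
}

## FNV-1a hash of the canonical JSON of the config, for the run manifest.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Load all annotated specimens from a directory
#'
#' Reads every mesh file (`.ply`, `.obj`, `.stl`) with a `<file>.json`
#' annotation sidecar carrying `outline_indices`, `buccal_anchor`,
#' `specimen_id` and `group`.
#'
#' @param dir directory path.
#' @return list of specimens (`mesh`, `outline`, `buccal_anchor`,
#'   `specimen_id`, `group`).
#' @export
load_specimen_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(ply|obj|stl)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stopf("no mesh files in %s", dir)
  lapply(files, function(fp) {
    ann_path <- paste0(fp, ".json")
    ann <- read_annotation(ann_path)
    lm <- load_mesh(fp, ann_path)
    list(mesh = lm$mesh, outline = lm$outline,
         buccal_anchor = lm$buccal_anchor,
         specimen_id = ann$specimen_id %||% basename(fp),
         group = ann$group %||% NA_character_)
  })
}

## Orient, sample and normalize one specimen into a map_set.
specimen_to_mapset <- function(sp, grid_K, grid_L) {
  crown <- orient_and_crop(sp$mesh, sp$outline, sp$buccal_anchor)
  grid <- radial_sample(crown, grid_K, grid_L)
  maps <- compute_parameter_maps(grid, crown,
                                 specimen_id = sp$specimen_id,
                                 group = sp$group)
  centroid_size_normalize(maps)
}

#' Build normalized map sets for a list of specimens
#'
#' @param specimens list as returned by [load_specimen_dir()] (or built in
#'   memory; each element needs `mesh`, `outline`, `buccal_anchor`, and
#'   optionally `specimen_id`, `group`).
#' @param grid_K,grid_L sampling grid.
#' @return list of normalized `map_set` objects.
#' @export
specimens_to_mapsets <- function(specimens, grid_K = 300, grid_L = 300) {
  lapply(seq_along(specimens), function(i) {
    sp <- specimens[[i]]
    sp$specimen_id <- sp$specimen_id %||% sprintf("specimen_%03d", i)
    tryCatch(specimen_to_mapset(sp, grid_K, grid_L),
             error = function(e) stopf("specimen %s: %s", sp$specimen_id,
                                       conditionMessage(e)))
  })
}

write_artifact <- function(obj, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, name)
  if (is.data.frame(obj) || is.matrix(obj)) {
    utils::write.csv(as.data.frame(obj), path, row.names = TRUE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

#' Mutant-classification workflow
#'
#' End-to-end analysis of a labelled specimen set: morphometric maps,
#' cross-validated accuracy grid over (combination, filter size, learner),
#' parsimonious model selection, between-group PCA on the winning
#' features, phenetic and pseudo-genetic distances, Mantel test and the
#' wild-type disparity correlation. A JSON manifest with the seeds and a
#' configuration hash is written when `out_dir` is set.
#'
#' @param config configuration (list or YAML path; see [read_config()]).
#'   Must provide specimens via `specimen_dir` or a `specimens` list, and
#'   a genotype table via `genotype_table` (CSV path with columns
#'   `strain`, `gene`, `dosage`, or a data frame).
#' @return list with `grid`, `selected`, `features`, `morphospace`,
#'   `distances` (phenetic + pseudo-genetic + Mantel + disparity),
#'   `manifest`.
#' @export
run_classification_workflow <- function(config) {
  cfg <- read_config(config)
  specimens <- cfg$specimens %||% load_specimen_dir(cfg$specimen_dir)
  gt <- cfg$genotype_table
  if (is.character(gt)) gt <- utils::read.csv(gt, stringsAsFactors = FALSE)

  mapsets <- specimens_to_mapsets(specimens, cfg$grid_K, cfg$grid_L)
  groups <- vapply(mapsets, `[[`, "", "group")
  strains <- sort(unique(groups))
  missing <- setdiff(strains, unique(as.character(gt$strain)))
  if (length(missing))
    stopf("genotype table lacks strain(s): %s", paste(missing, collapse = ", "))

  grid <- cv_accuracy_grid(mapsets, combos = cfg$combos,
                           f_range = cfg$f_range_ml,
                           learners = cfg$learners,
                           folds = cfg$folds, seed = cfg$seed)
  selected <- select_parsimonious_model(grid, tolerance = cfg$tolerance)

  feats <- assemble_features(mapsets, selected$combo, selected$f)
  space <- between_group_pca(feats, groups, project = unclass(feats))

  pgd <- pseudo_genetic_distance(gt)
  pgd_strains <- intersect(rownames(pgd$pairwise), strains)
  phen <- phenetic_distance_matrix(space, axes = min(cfg$axes, ncol(space$scores)))
  common <- intersect(rownames(phen), pgd_strains)
  mt <- mantel_test(phen[common, common], pgd$pairwise[common, common],
                    n_perm = cfg$n_perm, seed = cfg$seed)
  wt <- cfg$wt_label
  disp <- if (wt %in% common && length(common) >= 4) {
    disparity_correlation(pgd$from_wt[setdiff(common, wt)],
                          phen[wt, setdiff(common, wt)])
  } else NULL

  manifest <- list(workflow = "classification", seed = cfg$seed,
                   folds = cfg$folds, grid = c(cfg$grid_K, cfg$grid_L),
                   combos = cfg$combos, f_range = range(cfg$f_range_ml),
                   selected = as.list(selected),
                   n_specimens = length(mapsets), strains = strains,
                   config_hash = config_hash(cfg[setdiff(names(cfg), "specimens")]),
                   package_version = as.character(utils::packageVersion("crownmap")))
  out <- list(grid = grid, selected = selected, features = feats,
              morphospace = space,
              distances = list(phenetic = phen, pseudo_genetic = pgd,
                               mantel = mt, disparity = disp),
              manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    write_artifact(grid, cfg$out_dir, "accuracy_grid.csv")
    write_artifact(space$scores, cfg$out_dir, "pca_scores.csv")
    write_artifact(phen, cfg$out_dir, "phenetic_distances.csv")
    write_artifact(pgd$pairwise, cfg$out_dir, "pseudo_genetic_distances.csv")
    write_artifact(manifest, cfg$out_dir, "manifest.json")
  }
  out
}

#' Wild-species phylogenetic workflow
#'
#' Species map sets are screened over the (combination, filter size) grid
#' by multivariate phylogenetic signal; the winning features are extracted
#' for species (and mutants, if provided), combined in a between-group
#' PCA, ancestral states are reconstructed by squared-change parsimony and
#' projected, diet effects are tested by permutation PGLS, and mutant vs
#' wild-species convex-hull coverage is reported.
#'
#' @param config configuration list or YAML path. Must provide species
#'   specimens (`specimen_dir`/`specimens`, groups = tip labels), a tree
#'   (`tree` as `ape::phylo` or `tree_file` Newick), and a diet table
#'   (`diet_table`: CSV or data frame with columns `taxon`, `diet`).
#'   Optional mutant specimens via `mutant_specimens` or `mutant_dir`.
#' @return list with `k_grid`, `best`, `morphospace`, `ancestors`, `pgls`,
#'   `hulls`, `manifest`.
#' @export
run_phylo_workflow <- function(config) {
  cfg <- read_config(config)
  specimens <- cfg$specimens %||% load_specimen_dir(cfg$specimen_dir)
  tree <- cfg$tree %||% ape::read.tree(cfg$tree_file)
  diet <- cfg$diet_table
  if (is.character(diet)) diet <- utils::read.csv(diet, stringsAsFactors = FALSE)

  mapsets <- specimens_to_mapsets(specimens, cfg$grid_K, cfg$grid_L)
  sp_groups <- vapply(mapsets, `[[`, "", "group")
  missing_diet <- setdiff(tree$tip.label, as.character(diet$taxon))
  if (length(missing_diet))
    stopf("diet table lacks taxon(s): %s", paste(missing_diet, collapse = ", "))

  kg <- phylo_signal_grid(mapsets, tree, combos = cfg$combos,
                          f_range = cfg$f_range_k)
  best <- attr(kg, "best")

  mut_specimens <- cfg$mutant_specimens %||%
    (if (!is.null(cfg$mutant_dir)) load_specimen_dir(cfg$mutant_dir) else NULL)
  mut_mapsets <- if (!is.null(mut_specimens))
    specimens_to_mapsets(mut_specimens, cfg$grid_K, cfg$grid_L) else NULL

  all_sets <- c(mapsets, mut_mapsets)
  feats <- assemble_features(all_sets, best$combo, best$f)
  groups <- vapply(all_sets, `[[`, "", "group")
  space <- between_group_pca(feats, groups)

  tip_scores <- space$scores[tree$tip.label, , drop = FALSE]
  anc <- ancestral_states(tree, tip_scores)

  sp_feats <- unclass(feats)[seq_along(mapsets), , drop = FALSE]
  tip_feats <- rowsum(sp_feats, sp_groups) /
    as.vector(table(sp_groups)[sort(unique(sp_groups))])
  diet_f <- stats::setNames(as.factor(diet$diet), as.character(diet$taxon))
  pg <- pgls_categorical(tip_feats[tree$tip.label, , drop = FALSE], tree,
                         diet_f[tree$tip.label],
                         n_perm = cfg$n_perm, seed = cfg$seed)

  hulls <- NULL
  if (!is.null(mut_mapsets)) {
    mut_groups <- unique(vapply(mut_mapsets, `[[`, "", "group"))
    if (length(mut_groups) >= 3 && length(tree$tip.label) >= 3)
      hulls <- hull_coverage(space$scores, mut_groups, tree$tip.label)
  }

  manifest <- list(workflow = "phylo", seed = cfg$seed,
                   grid = c(cfg$grid_K, cfg$grid_L),
                   combos = cfg$combos, f_range = range(cfg$f_range_k),
                   best = as.list(best), n_species = length(tree$tip.label),
                   n_mutant_strains = if (is.null(mut_mapsets)) 0 else
                     length(unique(vapply(mut_mapsets, `[[`, "", "group"))),
                   config_hash = config_hash(cfg[setdiff(names(cfg),
                     c("specimens", "mutant_specimens", "tree"))]),
                   package_version = as.character(utils::packageVersion("crownmap")))
  out <- list(k_grid = kg, best = best, morphospace = space,
              ancestors = anc, pgls = pg, hulls = hulls, manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    write_artifact(kg, cfg$out_dir, "k_grid.csv")
    write_artifact(space$scores, cfg$out_dir, "pca_scores.csv")
    write_artifact(anc, cfg$out_dir, "ancestral_scores.csv")
    write_artifact(list(pgls = pg), cfg$out_dir, "pgls.json")
    write_artifact(manifest, cfg$out_dir, "manifest.json")
  }
  out
}
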