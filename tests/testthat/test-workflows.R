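## In-memory specimen lists for the two workflows.

classification_specimens <- function(n_per = 4) {
  cached(paste0("cls_spec_", n_per), function() {
    specs <- strain_specs()
    out <- list()
    for (s in seq_along(specs)) {
      samp <- make_strain_sample(specs[[s]], n_per, noise = 0.02,
                                 seed = 300 + s)
      for (i in seq_along(samp)) {
        sp <- samp[[i]]
        sp$specimen_id <- sprintf("%s_%02d", names(specs)[s], i)
        sp$group <- names(specs)[s]
        out[[length(out) + 1L]] <- sp
      }
    }
    out
  })
}

strain_genotypes <- function() {
  data.frame(
    strain = c("strain6", "strain4", "strain4", "strain2", "strain2"),
    gene = c("Eda", "Eda", "Shh", "Eda", "Shh"),
    dosage = c("normal", "hetero", "loss", "loss", "loss"))
}

classification_config <- function(out_dir = NULL) {
  list(specimens = classification_specimens(),
       genotype_table = strain_genotypes(),
       grid_K = 24, grid_L = 24,
       combos = "Nxyz", f_range_ml = c(4, 6),
       learners = "knn1", folds = 4, seed = 7,
       wt_label = "strain6", n_perm = 99, out_dir = out_dir)
}

test_that("the classification workflow runs end to end and is reproducible", {
  out_dir <- file.path(tempdir(), "cls_run")
  res <- run_classification_workflow(classification_config(out_dir))

  expect_s3_class(res$grid, "ml_grid")
  expect_gte(max(res$grid$accuracy, na.rm = TRUE), 0.9)
  expect_equal(res$selected$combo, "Nxyz")
  expect_s3_class(res$morphospace, "morphospace")
  expect_equal(nrow(res$morphospace$scores), 3)
  expect_equal(dim(res$distances$phenetic), c(3, 3))
  expect_true(res$distances$mantel$r >= -1 && res$distances$mantel$r <= 1)

  ## manifest records seeds and configuration
  expect_equal(res$manifest$seed, 7)
  expect_match(res$manifest$config_hash, "^[0-9a-f]{8}$")
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  expect_true(file.exists(file.path(out_dir, "accuracy_grid.csv")))

  ## rerun with the same config: identical numbers
  res2 <- run_classification_workflow(classification_config())
  expect_identical(res$grid$accuracy, res2$grid$accuracy)
  expect_identical(res$selected, res2$selected)
  expect_equal(res$morphospace$scores, res2$morphospace$scores)
})

test_that("a missing genotype row aborts with the strain name", {
  cfg <- classification_config()
  cfg$genotype_table <- cfg$genotype_table[cfg$genotype_table$strain != "strain2", ]
  expect_error(run_classification_workflow(cfg), "strain2")
})

phylo_setup <- function() {
  cached("phylo_setup", function() {
    samp <- make_strain_sample(tooth_spec(mesh_resolution = 2000), 5,
                               noise = 0.12, seed = 77)
    tree <- ape::rcoal(5)
    tree$tip.label <- paste0("sp", 1:5)
    for (i in 1:5) {
      samp[[i]]$specimen_id <- paste0("sp", i, "_1")
      samp[[i]]$group <- paste0("sp", i)
    }
    list(specimens = samp, tree = tree,
         diet = data.frame(taxon = paste0("sp", 1:5),
                           diet = c("generalist", "herbivore", "generalist",
                                    "insectivore", "herbivore")))
  })
}

test_that("the phylogenetic workflow runs end to end", {
  ps <- phylo_setup()
  mut <- classification_specimens()[c(1, 5, 9)] # one per strain
  cfg <- list(specimens = ps$specimens, tree = ps$tree,
              diet_table = ps$diet, mutant_specimens = mut,
              grid_K = 24, grid_L = 24,
              combos = "Nxyzr", f_range_k = c(2, 3),
              seed = 5, n_perm = 99)
  res <- run_phylo_workflow(cfg)

  expect_s3_class(res$k_grid, "k_grid")
  expect_true(all(res$k_grid$k_value > 0, na.rm = TRUE))
  expect_equal(nrow(res$morphospace$scores), 8) # 5 species + 3 strains
  expect_equal(nrow(res$ancestors), ps$tree$Nnode)

  ## reconstructed ancestors lie inside the tips' bounding box per axis
  tips <- res$morphospace$scores[ps$tree$tip.label, , drop = FALSE]
  for (j in seq_len(ncol(tips))) {
    expect_gte(min(res$ancestors[, j]), min(tips[, j]) - 1e-9)
    expect_lte(max(res$ancestors[, j]), max(tips[, j]) + 1e-9)
  }

  expect_true(res$pgls$p_value > 0 && res$pgls$p_value <= 1)
  expect_true(!is.null(res$hulls))
  expect_equal(res$manifest$n_species, 5)
})

test_that("a missing diet taxon aborts with the taxon name", {
  ps <- phylo_setup()
  cfg <- list(specimens = ps$specimens, tree = ps$tree,
              diet_table = ps$diet[ps$diet$taxon != "sp3", ],
              grid_K = 24, grid_L = 24, combos = "hr", f_range_k = 2)
  expect_error(run_phylo_workflow(cfg), "sp3")
})

test_that("configs are validated before compute", {
  expect_error(read_config(list(grid_K = 1)), "grid dims")
  expect_error(read_config(list(combos = "zzz")), "unknown combo")
  expect_error(read_config(list(learners = "mlp")), "unknown learner")
  cfg <- read_config(list(seed = 3))
  expect_equal(cfg$folds, 10)
  expect_match(crownmap:::config_hash(cfg), "^[0-9a-f]{8}$")
})
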