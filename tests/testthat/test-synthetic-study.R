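test_that("config validation names the offending field", {
  expect_error(sim_config(n_frb = 300, n_fsb = 200, n_species = 400), "n_frb")
  expect_error(sim_config(frb_effect = 0), "effect")
  expect_error(sim_config(baseline_load = -1), "load")
  expect_error(sim_config(n_driven_metabolites = 50, n_metabolites = 10),
               "n_driven_metabolites")
  expect_error(sim_config(phylum_weights = c(a = 0.5, b = 0.2)), "phylum_weights")
  expect_error(sim_config(fasting_consistency = 2), "fasting_consistency")
})

test_that("catalog generation is deterministic with realistic genome properties", {
  cfg <- small_config()
  c1 <- generate_catalog(cfg)
  c2 <- generate_catalog(cfg)
  expect_identical(c1$species, c2$species)
  expect_identical(c1$ko_counts, c2$ko_counts)
  expect_identical(c1$genes, c2$genes)
  expect_true(all(c1$species$genome_length >= 1e6 & c1$species$genome_length <= 8e6))
  expect_true(all(lengths(c1$ko_counts) >= 1))
  # changing the seed changes the catalog
  c3 <- generate_catalog(small_config(seed = 2))
  expect_false(identical(c1$species, c3$species))
  # degenerate single-species catalog still carries a repertoire
  c4 <- generate_catalog(small_config(n_species = 1, n_frb = 0, n_fsb = 0))
  expect_equal(nrow(c4$species), 1)
  expect_gte(length(c4$ko_counts[[1]]), 1)
})

test_that("a 433-species catalog represents all eight configured phyla", {
  cfg <- sim_config(n_species = 433, n_frb = 130, n_fsb = 140, seed = 1)
  cat433 <- generate_catalog(cfg)
  expect_equal(nrow(cat433$species), 433)
  expect_setequal(unique(cat433$species$phylum),
                  c("Bacteroidetes", "Firmicutes", "Proteobacteria",
                    "Actinobacteria", "Fusobacteria", "Verrucomicrobia",
                    "Synergistetes", "Euryarchaeota"))
  # phylum counts follow the configured weights
  tab <- table(cat433$species$phylum)
  expect_gt(tab[["Firmicutes"]], tab[["Bacteroidetes"]])
  expect_equal(unname(tab[["Synergistetes"]]), 1)
})

test_that("abundances are column-stochastic with planted labels and loads", {
  cfg <- small_config()
  cat <- generate_catalog(cfg)
  truth <- simulate_abundances(cat, cfg)
  expect_equal(unname(colSums(truth$abundance)), rep(1, ncol(truth$abundance)),
               tolerance = 1e-12)
  expect_equal(sum(truth$labels == "FRB"), cfg$n_frb)
  expect_equal(sum(truth$labels == "FSB"), cfg$n_fsb)
  expect_equal(nrow(truth$design), cfg$n_subjects * length(cfg$timepoints))
  fasting <- truth$design$timepoint %in% c("T1", "T2")
  expect_true(all(truth$loads[fasting] < min(truth$loads[!fasting])))
  # determinism
  truth2 <- simulate_abundances(cat, cfg)
  expect_identical(truth$abundance, truth2$abundance)
})

test_that("planted FRB effect raises fasting gross abundance in every seeded run", {
  for (s in 1:20) {
    cfg <- small_config(n_subjects = 4, n_species = 40, n_frb = 12, n_fsb = 12,
                        seed = s)
    truth <- simulate_abundances(generate_catalog(cfg), cfg)
    frb <- names(truth$labels)[truth$labels == "FRB"]
    fasting <- truth$design$timepoint %in% c("T1", "T2")
    base <- truth$design$timepoint == "T0"
    expect_gt(mean(colSums(truth$abundance[frb, fasting])),
              mean(colSums(truth$abundance[frb, base])),
              label = paste("seed", s, "fasting FRB share"))
  }
})

test_that("fasting loads center on the configured collapse value", {
  cfg <- sim_config(n_subjects = 46, n_species = 50, n_frb = 10, n_fsb = 10, seed = 3)
  truth <- simulate_abundances(generate_catalog(cfg), cfg)
  t1 <- truth$design$timepoint == "T1"
  gm <- exp(mean(log(truth$loads[t1])))
  # geometric mean of 46 lognormal(log 1.1e8, 0.5) draws: +/- 3 se band
  se <- cfg$load_noise_sd / sqrt(sum(t1))
  expect_lt(abs(log(gm) - log(1.1e8)), 3 * se)
})

test_that("read counts invert the length normalization by construction", {
  # two species, equal abundance, lengths 1:3 -> expected counts 1:3
  cfg <- small_config(n_species = 2, n_frb = 0, n_fsb = 0, reads_per_sample = 4e5)
  cat <- generate_catalog(cfg)
  cat$species$genome_length <- c(2e6, 6e6)
  ab <- matrix(0.5, 2, 3, dimnames = list(cat$species$species_id, paste0("s", 1:3)))
  counts <- simulate_read_counts(ab, cat, cfg)
  expect_equal(unname(colSums(counts)), rep(4e5, 3))
  ratio <- counts[2, ] / counts[1, ]
  expect_equal(unname(ratio), rep(3, 3), tolerance = 0.05)
  expect_error(simulate_read_counts(ab, cat, small_config(reads_per_sample = 0)),
               "reads_per_sample")
})

test_that("qPCR simulation obeys the log2 law and inverts exactly at zero noise", {
  cfg <- small_config(ct_noise_sd = 0)
  loads <- c(a_T0 = 6e9, b_T0 = 1.2e10, c_T1 = 1.1e8)
  q <- simulate_qpcr(loads, cfg)
  ct <- tapply(q$measurements$ct, q$measurements$sample_id, mean)
  # doubling the load lowers Ct by exactly one cycle
  expect_equal(ct[["a_T0"]] - ct[["b_T0"]], 1, tolerance = 1e-12)
  # reference consistency: when cells in reaction equal reference cells, Ct matches
  ref <- q$references
  load_eq <- ref$cells[1] / cfg$feces_mass_g
  q2 <- simulate_qpcr(c(x = load_eq), cfg)
  expect_equal(mean(q2$measurements$ct), ref$ct[1], tolerance = 1e-12)
  # estimator round-trip at zero noise
  est <- qpcr_total_load(q$measurements, q$references)
  expect_equal(stats::setNames(est$cells_per_g, est$sample_id), loads,
               tolerance = 1e-9)
  expect_error(simulate_qpcr(c(a = -1), cfg), "positive")
})

test_that("metabolome generator plants linear structure and pure-noise features", {
  cfg <- small_config(noise_sd = 0)
  cat <- generate_catalog(cfg)
  truth <- simulate_abundances(cat, cfg)
  met <- simulate_metabolome(truth, cfg)
  expect_equal(dim(met$intensities), c(cfg$n_metabolites, ncol(truth$abundance)))
  driven <- which(rowSums(met$loading != 0) > 0)
  expect_length(driven, cfg$n_driven_metabolites)
  # with zero residual noise a driven metabolite reproduces its linear model
  # up to the planted timepoint offsets (bounded by 1)
  i <- driven[1]
  fit <- as.numeric(met$loading[i, ] %*% truth$abundance)
  expect_true(all(abs(met$intensities[i, ] - fit) <= 1 + 1e-9))
  # determinism
  met2 <- simulate_metabolome(truth, cfg)
  expect_identical(met$intensities, met2$intensities)
  expect_error(simulate_metabolome(truth, small_config(n_driven_metabolites = 99,
                                                       n_metabolites = 98)),
               "n_driven")
})

test_that("study writer emits the reader-compatible table set with a manifest", {
  cfg <- small_config(n_subjects = 3, n_species = 12, n_frb = 3, n_fsb = 3,
                      reads_per_sample = 1e4, n_metabolites = 8,
                      n_driven_metabolites = 2)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(all(file.exists(file.path(dir,
    c("counts.tsv", "true_abundance.tsv", "design.tsv", "labels.tsv",
      "loads.tsv", "qpcr_ct.tsv", "qpcr_references.tsv", "metabolome.tsv",
      "catalog.tsv", "gene_annotation.tsv", "manifest.json")))))
  counts <- read_count_matrix(file.path(dir, "counts.tsv"))
  expect_equal(counts, study$counts, ignore_attr = TRUE)
  design <- read_design(file.path(dir, "design.tsv"))
  expect_equal(design$sample_id, study$truth$design$sample_id)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, cfg$seed)
  expect_equal(man$config$n_species, cfg$n_species)
})

test_that("YAML configs round-trip into validated configurations", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 5", "n_species: 30", "n_frb: 5", "n_fsb: 5",
               "seed: 9", "frb_effect: 2.5"), path)
  cfg <- sim_config_from_yaml(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_subjects, 5)
  expect_equal(cfg$frb_effect, 2.5)
  writeLines("not_a_field: 1", path)
  expect_error(sim_config_from_yaml(path), "unknown config field")
})
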