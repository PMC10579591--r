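#' Configuration for a synthetic fasting study
#'
#' Bundles and validates all generator parameters.  Defaults emulate
#' the study design the package targets: 46 subjects sampled at five
#' timepoints (T0 baseline; T1/T2 during a 7-day water-only fast;
#' T3/T4 after refeeding), a catalog of 400 species with a realistic
#' phylum composition, 130 planted fasting-resistant (FRB, 4x) and 140
#' fasting-sensitive (FSB, 0.25x) species, and a collapse of total
#' bacterial load from 6.0e9 to 1.1e8 cells per gram of feces during
#' fasting.
#'
#' @param n_subjects Number of subjects.
#' @param timepoints Ordered timepoint labels; the fasting phase is
#'   `T1`/`T2`.
#' @param n_species Catalog size.
#' @param phylum_weights Named probabilities summing to 1; species are
#'   apportioned to phyla by largest remainder so every phylum with
#'   positive weight is represented when `n_species` allows.
#' @param n_frb,n_fsb Numbers of planted fasting-resistant/-sensitive
#'   species.
#' @param frb_effect,fsb_effect Multiplicative fold-changes applied to
#'   responder species' relative abundances at fasting timepoints,
#'   before renormalization.
#' @param baseline_load,fasting_load Total bacterial load (cells per
#'   gram of feces) at non-fasting (T0/T3/T4) and fasting (T1/T2)
#'   timepoints.
#' @param reads_per_sample Mapped reads simulated per sample.
#' @param dispersion Lognormal sample-level noise SD (log scale) on
#'   abundances.
#' @param sigma_log Between-species lognormal SD of baseline abundance.
#' @param subject_sd Lognormal SD of the per-(species, subject) random
#'   intercept creating repeated-measures structure.
#' @param fasting_consistency Attenuation factor in \[0, 1\] applied to
#'   responder species' subject intercepts at fasting timepoints: the
#'   bloom/collapse is a shared physiological response, so individual
#'   signatures of responders weaken while fasting.  Ignored for
#'   species with effect 1, so an all-null configuration is fully
#'   exchangeable across phases.
#' @param baseline_frb_share,baseline_fsb_share Expected share of total
#'   baseline community mass held by the FRB and FSB groups.  Defaults
#'   (0.164, 0.59) reproduce a baseline FRB gross relative abundance of
#'   16.4% rising to ~63% under a 4x effect.
#' @param load_noise_sd Lognormal SD of per-sample load noise.
#' @param n_metabolites,n_driven_metabolites Metabolome size and number
#'   of metabolites linearly driven by species abundances.
#' @param noise_sd Gaussian residual SD of driven metabolite
#'   intensities.
#' @param ct_noise_sd Gaussian SD (cycles) of qPCR replicate noise.
#' @param qpcr_replicates Replicates per qPCR reaction.
#' @param feces_mass_g Feces mass extracted per test reaction (grams).
#' @param module_file Module-definition flat file used to assemble KO
#'   repertoires (defaults to the packaged synthetic module set).
#' @param seed Integer master seed; expanded into independent child
#'   seeds for the catalog, abundance, count, qPCR and metabolome
#'   streams.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 46,
                       timepoints = c("T0", "T1", "T2", "T3", "T4"),
                       n_species = 400,
                       phylum_weights = NULL,
                       n_frb = 130, n_fsb = 140,
                       frb_effect = 4, fsb_effect = 0.25,
                       baseline_load = 6.0e9, fasting_load = 1.1e8,
                       reads_per_sample = 1e6,
                       dispersion = 0.5,
                       sigma_log = 1.5,
                       subject_sd = 0.5,
                       fasting_consistency = 0.5,
                       baseline_frb_share = 0.164,
                       baseline_fsb_share = 0.59,
                       load_noise_sd = 0.5,
                       n_metabolites = 300,
                       n_driven_metabolites = 30,
                       noise_sd = 0.5,
                       ct_noise_sd = 0.15,
                       qpcr_replicates = 3,
                       feces_mass_g = 0.170,
                       module_file = NULL,
                       seed = 1) {
  if (is.null(phylum_weights)) {
    counts <- c(Bacteroidetes = 76, Firmicutes = 204, Proteobacteria = 30,
                Actinobacteria = 18, Fusobacteria = 5, Verrucomicrobia = 2,
                Synergistetes = 1, Euryarchaeota = 1)
    phylum_weights <- counts / sum(counts)
  }
  if (is.null(module_file))
    module_file <- system.file("extdata", "synthetic_kegg_modules.tsv",
                               package = "gutfast")
  chk <- function(ok, field, msg) if (!ok) stop("invalid config field '", field, "': ", msg)
  chk(n_subjects >= 1, "n_subjects", "must be >= 1")
  chk(length(timepoints) >= 1 && !anyDuplicated(timepoints), "timepoints",
      "must be distinct labels")
  chk(n_species >= 1, "n_species", "must be >= 1")
  chk(abs(sum(phylum_weights) - 1) < 1e-8 && all(phylum_weights >= 0),
      "phylum_weights", "must be nonnegative and sum to 1")
  chk(n_frb >= 0 && n_fsb >= 0 && n_frb + n_fsb <= n_species, "n_frb/n_fsb",
      "must satisfy n_frb + n_fsb <= n_species")
  chk(frb_effect > 0 && fsb_effect > 0, "frb_effect/fsb_effect", "must be > 0")
  chk(baseline_load > 0 && fasting_load > 0, "baseline_load/fasting_load", "must be > 0")
  chk(reads_per_sample > 0, "reads_per_sample", "must be > 0")
  chk(dispersion >= 0 && sigma_log >= 0 && subject_sd >= 0, "dispersion/sigma_log/subject_sd",
      "must be >= 0")
  chk(fasting_consistency >= 0 && fasting_consistency <= 1, "fasting_consistency",
      "must lie in [0, 1]")
  chk(baseline_frb_share > 0 && baseline_fsb_share > 0 &&
        baseline_frb_share + baseline_fsb_share < 1, "baseline_*_share",
      "group shares must be positive and sum below 1")
  chk(n_metabolites >= 0 && n_driven_metabolites >= 0, "n_metabolites", "must be >= 0")
  chk(n_driven_metabolites <= n_metabolites, "n_driven_metabolites",
      "cannot exceed n_metabolites")
  chk(noise_sd >= 0 && ct_noise_sd >= 0 && load_noise_sd >= 0,
      "noise_sd/ct_noise_sd/load_noise_sd", "must be >= 0")
  chk(qpcr_replicates >= 1, "qpcr_replicates", "must be >= 1")
  chk(feces_mass_g > 0, "feces_mass_g", "must be > 0")
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be a single integer")
  structure(as.list(environment())[setdiff(names(formals(sim_config)), "")],
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic fasting-study configuration:\n")
  cat(sprintf("  %d subjects x %d timepoints; %d species (%d FRB @%gx, %d FSB @%gx)\n",
              x$n_subjects, length(x$timepoints), x$n_species,
              x$n_frb, x$frb_effect, x$n_fsb, x$fsb_effect))
  cat(sprintf("  loads %.3g (non-fasting) vs %.3g (fasting) cells/g; %g reads/sample; seed %d\n",
              x$baseline_load, x$fasting_load, x$reads_per_sample, as.integer(x$seed)))
  invisible(x)
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$phylum_weights)) vals$phylum_weights <- unlist(vals$phylum_weights)
  do.call(sim_config, vals)
}

child_seeds <- function(config) {
  set.seed(as.integer(config$seed))
  s <- sample.int(2^31 - 2, 5)
  names(s) <- c("catalog", "abundance", "counts", "qpcr", "metabolome")
  s
}

# apportion n species over phyla by largest remainder, guaranteeing one
# species per positive-weight phylum when n allows
apportion_phyla <- function(n, weights) {
  w <- weights[weights > 0]
  raw <- n * w / sum(w)
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  if (n >= length(w)) {
    while (any(cnt == 0)) {
      cnt[which.max(cnt)] <- max(cnt) - 1
      cnt[which(cnt == 0)[1]] <- 1
    }
  }
  cnt
}

#' Generate a synthetic species catalog
#'
#' Species with phylum-structured taxonomy, genome lengths in 1-8 Mbp,
#' phylum-typical GC content, and KO repertoires assembled by sampling
#' whole modules from the packaged module-definition file (so module
#' completion ratios are nontrivial), plus background KOs.  A gene
#' table (one row per gene copy, with gene lengths) is included for
#' gene-level profiling.
#'
#' @param config `sim_config`.
#' @return Object of class `species_catalog`: list with `species` data
#'   frame (`species_id`, `domain`, `phylum`, `genus`, `genome_length`,
#'   `gc`), `taxonomy` (same frame, for roll-ups), `ko_counts` (named
#'   list of per-species named gene-copy vectors), `genes` data frame
#'   (`gene_id`, `species_id`, `ko`, `length`), and `modules` (parsed
#'   module definitions used).
#' @export
generate_catalog <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must come from sim_config()")
  seeds <- child_seeds(config)
  set.seed(seeds[["catalog"]])
  n <- config$n_species
  cnt <- apportion_phyla(n, config$phylum_weights)
  phyla <- rep(names(cnt), cnt)[sample.int(n)]
  gc_mean <- c(Bacteroidetes = 43, Firmicutes = 40, Proteobacteria = 52,
               Actinobacteria = 62, Fusobacteria = 28, Verrucomicrobia = 58,
               Synergistetes = 52, Euryarchaeota = 50)
  gcm <- ifelse(phyla %in% names(gc_mean), gc_mean[phyla], 45)
  species <- data.frame(
    species_id = sprintf("sp%04d", seq_len(n)),
    domain = ifelse(phyla == "Euryarchaeota", "Archaea", "Bacteria"),
    phylum = phyla,
    genus = paste0(substr(phyla, 1, 4), "_g", 1 + (seq_len(n) %% pmax(1, cnt[phyla] %/% 4))),
    genome_length = pmin(8e6, pmax(1e6, round(stats::rlnorm(n, log(3e6), 0.35)))),
    gc = pmin(75, pmax(20, gcm + stats::rnorm(n, 0, 3))),
    stringsAsFactors = FALSE)
  modules <- read_module_definitions(config$module_file)
  mod_req <- lapply(modules, module_kos, include_optional = FALSE)
  mod_opt <- lapply(modules, function(m)
    setdiff(module_kos(m, include_optional = TRUE), module_kos(m)))
  universe <- sort(unique(unlist(c(mod_req, mod_opt))))
  prevalence <- stats::runif(length(modules), 0.2, 0.8)
  ko_counts <- vector("list", n)
  names(ko_counts) <- species$species_id
  for (i in seq_len(n)) {
    has <- stats::runif(length(modules)) < prevalence
    kos <- unlist(mod_req[has])
    opt <- unlist(mod_opt[has])
    if (length(opt)) kos <- c(kos, opt[stats::runif(length(opt)) < 0.5])
    kos <- c(kos, sample(universe, stats::rpois(1, 10), replace = TRUE))
    kos <- unique(kos)
    if (length(kos) == 0) kos <- unique(c(mod_req[[sample.int(length(modules), 1)]],
                                          sample(universe, 1)))
    cnts <- 1L + stats::rpois(length(kos), 0.3)
    names(cnts) <- kos
    ko_counts[[i]] <- cnts
  }
  n_genes <- vapply(ko_counts, sum, numeric(1))
  genes <- data.frame(
    gene_id = sprintf("gene%06d", seq_len(sum(n_genes))),
    species_id = rep(species$species_id, n_genes),
    ko = unlist(lapply(ko_counts, function(k) rep(names(k), k)), use.names = FALSE),
    stringsAsFactors = FALSE)
  genes$length <- pmax(150, round(stats::rnorm(nrow(genes), 900, 200)))
  structure(list(species = species, taxonomy = species, ko_counts = ko_counts,
                 genes = genes, modules = modules, config = config),
            class = "species_catalog")
}

#' @export
print.species_catalog <- function(x, ...) {
  cat("Synthetic species catalog:", nrow(x$species), "species,",
      length(unique(x$species$phylum)), "phyla,",
      nrow(x$genes), "genes,", length(x$modules), "modules\n")
  invisible(x)
}

#' Simulate true abundances, loads and responder labels
#'
#' Baseline abundances are lognormal per species around group-specific
#' means calibrated so the FRB/FSB/neutral groups hold the configured
#' shares of community mass, with a per-(species, subject) lognormal
#' intercept and per-sample lognormal noise.  At fasting timepoints
#' (T1/T2) planted FRB species are multiplied by `frb_effect` and FSB
#' by `fsb_effect` before column renormalization, and responder
#' subject intercepts are attenuated by `fasting_consistency`.  Total
#' loads are `baseline_load` at non-fasting and `fasting_load` at
#' fasting timepoints with lognormal per-sample noise.
#'
#' @param catalog `species_catalog`.
#' @param config `sim_config` (the one used for the catalog).
#' @return Object of class `synthetic_truth`: list with `abundance`
#'   (species x sample, columns sum to 1), `design` data frame
#'   (`sample_id`, `subject_id`, `timepoint`), `loads` (named cells/g
#'   per sample), `labels` (named FRB/FSB/neutral per species).
#' @export
simulate_abundances <- function(catalog, config) {
  if (!inherits(catalog, "species_catalog")) stop("catalog must come from generate_catalog()")
  seeds <- child_seeds(config)
  set.seed(seeds[["abundance"]])
  n <- config$n_species
  ids <- catalog$species$species_id
  labels <- rep("neutral", n)
  pick <- sample.int(n, config$n_frb + config$n_fsb)
  labels[pick[seq_len(config$n_frb)]] <- "FRB"
  if (config$n_fsb > 0) labels[pick[config$n_frb + seq_len(config$n_fsb)]] <- "FSB"
  names(labels) <- ids

  shares <- c(FRB = config$baseline_frb_share, FSB = config$baseline_fsb_share)
  shares["neutral"] <- 1 - sum(shares)
  m <- stats::rnorm(n, 0, config$sigma_log)
  # calibrate the realized (not merely expected) baseline mass of each
  # group to its configured share: under a heavy-tailed baseline the
  # realized group totals would otherwise wander far from the targets
  for (g in names(shares)) {
    idx <- labels == g
    if (!any(idx)) next
    m[idx] <- m[idx] + log(shares[[g]] / sum(exp(m[idx])))
  }

  subjects <- sprintf("subj%02d", seq_len(config$n_subjects))
  design <- expand.grid(subject_id = subjects, timepoint = config$timepoints,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample_id <- paste0(design$subject_id, "_", design$timepoint)
  design <- design[, c("sample_id", "subject_id", "timepoint")]

  u <- matrix(stats::rnorm(n * config$n_subjects, 0, config$subject_sd), n,
              dimnames = list(ids, subjects))
  effect <- ifelse(labels == "FRB", config$frb_effect,
                   ifelse(labels == "FSB", config$fsb_effect, 1))
  responder <- effect != 1

  A <- matrix(0, n, nrow(design), dimnames = list(ids, design$sample_id))
  fasting <- design$timepoint %in% c("T1", "T2")
  for (s in seq_len(nrow(design))) {
    e <- stats::rnorm(n, 0, config$dispersion)
    us <- u[, design$subject_id[s]]
    if (fasting[s]) {
      us[responder] <- config$fasting_consistency * us[responder]
      raw <- exp(m + us + e) * effect
    } else {
      raw <- exp(m + us + e)
    }
    A[, s] <- raw / sum(raw)
  }
  loads <- ifelse(fasting, config$fasting_load, config$baseline_load) *
    exp(stats::rnorm(nrow(design), 0, config$load_noise_sd))
  names(loads) <- design$sample_id
  structure(list(abundance = A, design = design, loads = loads, labels = labels),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", nrow(x$abundance), "species x", ncol(x$abundance), "samples;",
      sum(x$labels == "FRB"), "FRB,", sum(x$labels == "FSB"), "FSB\n")
  invisible(x)
}

#' Simulate mapped-read counts
#'
#' Per sample, counts are multinomial with probabilities proportional
#' to relative abundance times genome length, so that length-normalized
#' profiling ([species_relative_abundance()]) recovers the truth.
#'
#' @param abundance Species x sample matrix of true relative abundances
#'   (columns sum to 1), or a `synthetic_truth` object.
#' @param catalog `species_catalog` providing genome lengths.
#' @param config `sim_config`.
#' @return Species x sample integer count matrix.
#' @export
simulate_read_counts <- function(abundance, catalog, config) {
  if (inherits(abundance, "synthetic_truth")) abundance <- abundance$abundance
  if (config$reads_per_sample <= 0) stop("reads_per_sample must be positive")
  if (any(abs(colSums(abundance) - 1) > 1e-6))
    stop("abundance columns must sum to 1")
  seeds <- child_seeds(config)
  set.seed(seeds[["counts"]])
  L <- catalog$species$genome_length[match(rownames(abundance),
                                           catalog$species$species_id)]
  counts <- matrix(0L, nrow(abundance), ncol(abundance), dimnames = dimnames(abundance))
  for (s in seq_len(ncol(abundance))) {
    p <- abundance[, s] * L
    counts[, s] <- stats::rmultinom(1, size = config$reads_per_sample, prob = p / sum(p))
  }
  counts
}

# universal-primer standard-curve intercept: Ct of a single cell
QPCR_INTERCEPT <- 38

#' Simulate a qPCR experiment
#'
#' Two internal reference strains (a Gram-positive and a Gram-negative,
#' with CFU-counted cell numbers) define the standard curve
#' `Ct = C0 - log2(cells)`.  Test reactions on `feces_mass_g` grams of
#' feces yield replicate Ct values
#' `Ct_test = Ct_ref - log2(cells_in_reaction / cells_ref) + noise`,
#' i.e. one cycle per doubling of template.
#'
#' @param loads Named vector of true loads (cells per gram of feces)
#'   per sample, or a `synthetic_truth` object.
#' @param config `sim_config` (uses `ct_noise_sd`, `qpcr_replicates`,
#'   `feces_mass_g`).
#' @return List with `measurements` (data frame `sample_id`,
#'   `replicate`, `ct`, `mass_g`) and `references` (data frame `strain`,
#'   `gram`, `ct`, `cells`).
#' @export
simulate_qpcr <- function(loads, config) {
  if (inherits(loads, "synthetic_truth")) loads <- loads$loads
  if (any(loads <= 0)) stop("loads must be positive")
  seeds <- child_seeds(config)
  set.seed(seeds[["qpcr"]])
  references <- data.frame(
    strain = c("Lactococcus-like reference", "Escherichia-like reference"),
    gram = c("positive", "negative"),
    cells = c(1.2e7, 8.0e6),
    stringsAsFactors = FALSE)
  references$ct <- QPCR_INTERCEPT - log2(references$cells)
  cells_rxn <- loads * config$feces_mass_g
  if (any(cells_rxn <= 0)) stop("nonpositive cells in reaction")
  reps <- config$qpcr_replicates
  measurements <- data.frame(
    sample_id = rep(names(loads), each = reps),
    replicate = rep(seq_len(reps), length(loads)),
    ct = rep(QPCR_INTERCEPT - log2(cells_rxn), each = reps) +
      stats::rnorm(length(loads) * reps, 0, config$ct_noise_sd),
    mass_g = config$feces_mass_g,
    stringsAsFactors = FALSE)
  list(measurements = measurements, references = references)
}

#' Simulate a metabolome partially driven by species abundances
#'
#' The first `n_driven_metabolites` metabolites are linear combinations
#' of 1-3 driver species' relative abundances (drivers drawn from the
#' 50 most abundant species so the signal is detectable) plus a
#' timepoint offset and Gaussian noise; the remaining metabolites are
#' pure lognormal noise.  The species-loading matrix is returned as
#' ground truth.
#'
#' @param truth `synthetic_truth` (abundance + design), or a species x
#'   sample abundance matrix together with `design`.
#' @param config `sim_config`.
#' @param design Required when `truth` is a bare matrix.
#' @return List with `intensities` (metabolite x sample matrix) and
#'   `loading` (metabolite x species coefficient matrix).
#' @export
simulate_metabolome <- function(truth, config, design = NULL) {
  if (inherits(truth, "synthetic_truth")) {
    A <- truth$abundance; design <- truth$design
  } else {
    A <- truth
    if (is.null(design)) stop("design is required when truth is a matrix")
  }
  if (config$n_driven_metabolites > config$n_metabolites)
    stop("n_driven_metabolites cannot exceed n_metabolites")
  seeds <- child_seeds(config)
  set.seed(seeds[["metabolome"]])
  n_met <- config$n_metabolites
  n_drv <- config$n_driven_metabolites
  met_ids <- sprintf("met%04d", seq_len(n_met))
  M <- matrix(0, n_met, ncol(A), dimnames = list(met_ids, colnames(A)))
  loading <- matrix(0, n_met, nrow(A), dimnames = list(met_ids, rownames(A)))
  top <- order(rowMeans(A), decreasing = TRUE)[seq_len(min(50, nrow(A)))]
  offsets <- matrix(stats::runif(n_drv * length(config$timepoints), 0, 1),
                    nrow = max(1, n_drv))
  tp_idx <- match(design$timepoint, config$timepoints)
  if (n_drv > 0) {
    for (i in seq_len(n_drv)) {
      drivers <- sample(top, sample(1:3, 1))
      coefs <- stats::runif(length(drivers), 50, 200)
      loading[i, drivers] <- coefs
      M[i, ] <- as.numeric(coefs %*% A[drivers, , drop = FALSE]) +
        offsets[i, tp_idx] +
        stats::rnorm(ncol(A), 0, config$noise_sd)
    }
    M[seq_len(n_drv), ] <- pmax(M[seq_len(n_drv), , drop = FALSE], 0)
  }
  if (n_met > n_drv) {
    idx <- (n_drv + 1):n_met
    M[idx, ] <- stats::rlnorm(length(idx) * ncol(A), 0.5, 1)
  }
  list(intensities = M, loading = loading)
}

#' Simulate species replication rates
#'
#' Synthetic stand-in for coverage-derived replication-rate tables
#' (peak-to-trough style indices): baseline rates near 1.4 with
#' Gaussian noise, FRB species boosted and FSB species reduced at
#' fasting timepoints.
#'
#' @param truth `synthetic_truth` (for labels and design).
#' @param config `sim_config`.
#' @param frb_fold,fsb_fold Multiplicative change of responder rates at
#'   fasting timepoints (defaults 1.5 and 0.67).
#' @return Species x sample matrix of replication rates (all >= 1).
#' @export
simulate_replication_rates <- function(truth, config, frb_fold = 1.5, fsb_fold = 0.67) {
  seeds <- child_seeds(config)
  set.seed(seeds[["abundance"]] %% (2^31 - 2) + 1)
  labels <- truth$labels
  design <- truth$design
  n <- length(labels)
  R <- matrix(stats::rnorm(n * nrow(design), 1.4, 0.15), n,
              dimnames = list(names(labels), design$sample_id))
  fasting <- design$timepoint %in% c("T1", "T2")
  fold <- ifelse(labels == "FRB", frb_fold, ifelse(labels == "FSB", fsb_fold, 1))
  R[, fasting] <- R[, fasting] * fold
  pmax(R, 1)
}

#' Generate a complete synthetic study
#'
#' Runs every generator stage from one configuration: catalog,
#' abundances/loads/labels, read counts, qPCR tables and metabolome.
#'
#' @param config `sim_config`.
#' @return Object of class `synthetic_study`: list with `config`,
#'   `catalog`, `truth`, `counts`, `qpcr`, `metabolome`.
#' @export
simulate_study <- function(config) {
  catalog <- generate_catalog(config)
  truth <- simulate_abundances(catalog, config)
  counts <- simulate_read_counts(truth, catalog, config)
  qpcr <- simulate_qpcr(truth, config)
  metabolome <- simulate_metabolome(truth, config)
  structure(list(config = config, catalog = catalog, truth = truth,
                 counts = counts, qpcr = qpcr, metabolome = metabolome),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  print(x$config)
  print(x$catalog)
  print(x$truth)
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits every table as TSV in the reader formats of the analysis
#' functions, plus a JSON run manifest (configuration, seed, package
#' version).
#'
#' @param study `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv_matrix(study$counts, p("counts.tsv"), "species_id")
  write_tsv_matrix(study$truth$abundance, p("true_abundance.tsv"), "species_id")
  utils::write.table(study$truth$design, p("design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(species_id = names(study$truth$labels),
                                label = study$truth$labels),
                     p("labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(study$truth$loads),
                                cells_per_g = signif(study$truth$loads, 10)),
                     p("loads.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$qpcr$measurements, p("qpcr_ct.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$qpcr$references, p("qpcr_references.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tsv_matrix(study$metabolome$intensities, p("metabolome.tsv"), "metabolite_id")
  utils::write.table(study$catalog$species, p("catalog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$catalog$genes, p("gene_annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "gutfast",
    version = as.character(utils::packageVersion("gutfast")),
    seed = as.integer(study$config$seed),
    config = study$config[!vapply(study$config, is.null, logical(1))])
  manifest$config$timepoints <- as.list(manifest$config$timepoints)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
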