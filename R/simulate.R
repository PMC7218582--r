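#' Expected true-signal mixing weight at a given biomass
#'
#' In the contamination model a library's expected profile is
#' `w * true + (1 - w) * contaminant` with `w = B / (B + kappa)`: as specimen
#' biomass `B` falls towards the reagent pseudo-biomass `kappa`, contaminant
#' reads displace true reads.
#'
#' @param B Specimen biomass (16S copies/ul), non-negative.
#' @param kappa Reagent contaminant pseudo-biomass (copies/ul equivalents).
#' @return `w` in \[0, 1\]; the expected contaminant read share is `1 - w`.
#' @export
contamination_weight <- function(B, kappa) {
  if (any(B < 0) || any(kappa < 0)) abort("B and kappa must be non-negative")
  if (any(B == 0 & kappa == 0)) {
    abort("mixing weight is undefined when B and kappa are both zero")
  }
  B / (B + kappa)
}

#' Apply extraction-kit lysis bias to a composition
#'
#' Hard-to-lyse taxa yield less DNA; each part is multiplied by a lysis
#' efficiency in (0, 1] and the composition is re-closed:
#' `p'_j = b_j p_j / sum_k b_k p_k`.
#'
#' @param composition Proportion vector summing to 1.
#' @param bias Multipliers in (0, 1], recycled against `composition`.
#' @return The re-closed biased composition.
#' @export
apply_kit_bias <- function(composition, bias) {
  if (abs(sum(composition) - 1) > 1e-6) abort("composition must sum to 1")
  if (any(bias <= 0) || any(bias > 1)) abort("bias multipliers must lie in (0, 1]")
  x <- composition * bias
  s <- sum(x)
  if (s == 0) abort("composition is all-zero after biasing")
  x / s
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[sample.int(length(x), 1)] <- 1
  x / sum(x)
}

# genus pools for the synthetic taxonomy ----------------------------------

TRUE_GENUS_POOL <- c(
  "Moraxella", "Corynebacterium", "Haemophilus", "Streptococcus",
  "Staphylococcus", "Neisseria", "Dolosigranulum", "Prevotella",
  "Veillonella", "Gemella", "Rothia", "Fusobacterium", "Granulicatella",
  "Porphyromonas", "Klebsiella", "Lactobacillus")

CONTAM_GENUS_POOL <- c(
  "Aquabacterium", "Acidovorax", "Noviherbaspirillum", "Stenotrophomonas",
  "Ralstonia", "Sphingomonas", "Bradyrhizobium", "Methylobacterium",
  "Burkholderia", "Cupriavidus", "Pelomonas", "Herbaspirillum", "Delftia",
  "Comamonas", "Brevundimonas", "Caulobacter", "Phyllobacterium",
  "Mesorhizobium", "Micrococcus", "Paracoccus")

# the first ten true OTUs anchor the cluster-dominant genera so synthetic
# communities mirror the Moraxella/Corynebacterium/Haemophilus/Streptococcus/
# Staphylococcus-dominated profiles seen in infant nasopharyngeal data
TRUE_ANCHOR <- data.frame(
  genus = c("Moraxella", "Moraxella", "Corynebacterium", "Corynebacterium",
            "Haemophilus", "Haemophilus", "Streptococcus", "Neisseria",
            "Staphylococcus", "Dolosigranulum"),
  species = c("catarrhalis", "nonliquefaciens", "propinquum",
              "pseudodiphtheriticum", "influenzae", "parainfluenzae",
              "pneumoniae", "lactamica", "aureus", "pigrum"),
  stringsAsFactors = FALSE)

build_taxa_tables <- function(cfg) {
  n_true <- cfg$n_true_taxa
  extra <- n_true - nrow(TRUE_ANCHOR)
  pool <- rep(TRUE_GENUS_POOL, length.out = max(extra, 0))
  true_tab <- tibble(
    otu_id = sprintf("OTU_T%03d", seq_len(n_true)),
    genus = c(TRUE_ANCHOR$genus, pool)[seq_len(n_true)],
    species = c(TRUE_ANCHOR$species,
                sprintf("sp%02d", seq_len(max(extra, 0))))[seq_len(n_true)],
    origin = "true_taxon")
  contam_genus <- rep(CONTAM_GENUS_POOL, length.out = cfg$n_contam_taxa)
  contam_tab <- tibble(
    otu_id = sprintf("OTU_C%03d", seq_len(cfg$n_contam_taxa)),
    genus = contam_genus,
    species = sprintf("sp%02d", seq_len(cfg$n_contam_taxa)),
    origin = "reagent_contaminant")
  ref <- builtin_mock(cfg$mock_reference)
  mock_tab <- tibble(
    otu_id = sprintf("OTU_M%03d", seq_len(nrow(ref))),
    genus = ref$genus,
    species = vapply(strsplit(ref$taxon, " "), function(x) {
      paste(x[-1], collapse = " ")
    }, character(1)),
    origin = "true_taxon")
  list(true = true_tab, contam = contam_tab, mock = mock_tab, mock_ref = ref)
}

gram_of <- function(genus) {
  g <- unname(GRAM_CLASS[genus])
  g[is.na(g)] <- "gram_negative"
  g
}

cluster_bases <- function(cfg) {
  n_true <- cfg$n_true_taxa
  bases <- matrix(0.3 / n_true, nrow = cfg$n_clusters, ncol = n_true)
  for (k in seq_len(cfg$n_clusters)) {
    dom <- ((k - 1) * 2 + 1):((k - 1) * 2 + 2)
    bases[k, dom[1]] <- bases[k, dom[1]] + 0.5
    bases[k, dom[2]] <- bases[k, dom[2]] + 0.2
  }
  sweep(bases, 1, rowSums(bases), "/")
}

kappa_for <- function(cfg, buffer) {
  switch(buffer,
         primestore = cfg$kappa_primestore,
         stgg = cfg$kappa_stgg,
         none = 0)
}

#' Generate a truth-labelled synthetic low-biomass amplicon cohort
#'
#' Simulates an OTU count table, sample metadata, taxonomy and per-OTU /
#' per-library truth labels under the generative model described in the
#' package vignette: specimen biomass follows a lognormal age model; each
#' library's expected profile mixes a kit-biased true composition with a
#' buffer-specific reagent contaminant profile at weight
#' `w = B/(B + kappa)`, receives plate-local spill-over from its
#' biomass-weighted plate mates, lognormal amplification jitter, negative-
#' binomial read depth and multinomial read sampling; low-biomass libraries
#' additionally accrue rare spurious OTUs.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `lbqc_cohort` with elements `counts` (integer
#'   matrix, OTUs x libraries), `metadata` (tibble), `taxonomy` (tibble),
#'   `truth` (list with per-OTU `otus` and per-library `samples` tibbles) and
#'   `config`.
#' @export
generate_cohort <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  taxa <- build_taxa_tables(cfg)
  n_true <- nrow(taxa$true); n_con <- nrow(taxa$contam); n_mock <- nrow(taxa$mock)
  core_ids <- c(taxa$true$otu_id, taxa$contam$otu_id, taxa$mock$otu_id)
  idx_true <- seq_len(n_true)
  idx_con <- n_true + seq_len(n_con)
  idx_mock <- n_true + n_con + seq_len(n_mock)
  D <- length(core_ids)
  gram <- gram_of(c(taxa$true$genus, taxa$contam$genus, taxa$mock$genus))

  contam_base <- list(
    primestore = rdirichlet1(rep(cfg$contam_dirichlet_alpha, n_con)),
    stgg = rdirichlet1(rep(cfg$contam_dirichlet_alpha, n_con)))
  bases <- cluster_bases(cfg)
  mock_comp <- taxa$mock_ref$proportion

  # --- specimen-level state -------------------------------------------------
  spec <- NULL
  if (cfg$n_specimens > 0) {
    age <- exp(runif(cfg$n_specimens, 0, log(cfg$age_max_days + 1))) - 1
    B <- exp(cfg$age_beta0 + cfg$age_beta1 * log(age + 1) +
               rnorm(cfg$n_specimens, 0, cfg$age_sigma))
    cl <- sample.int(cfg$n_clusters, cfg$n_specimens, replace = TRUE)
    comp <- t(vapply(cl, function(k) {
      rdirichlet1(cfg$cluster_concentration * bases[k, ])
    }, numeric(n_true)))
    classes <- c(names(cfg$repeat_design), "single")
    probs <- c(cfg$repeat_design, single = 1 - sum(cfg$repeat_design))
    rclass <- sample(classes, cfg$n_specimens, replace = TRUE, prob = probs)
    copies_meas <- (B + kappa_for(cfg, "primestore")) *
      rlnorm(cfg$n_specimens, 0, cfg$copies_noise_sigma)
    spec <- tibble(specimen_id = sprintf("SP%03d", seq_len(cfg$n_specimens)),
                   age_days = round(age, 1), B = B, cluster = cl,
                   rclass = rclass, copies_meas = copies_meas)
    spec_comp <- comp
  }

  # --- enumerate libraries --------------------------------------------------
  n_libs_spec <- if (is.null(spec)) 0 else {
    sum(c(dup_within = 2, dup_between = 2, trip_between = 3,
          quad_between = 4, single = 1)[spec$rclass])
  }
  n_libs <- n_libs_spec + cfg$n_ntc + cfg$n_mock_high + cfg$n_mock_low
  n_runs <- max(2, ceiling(n_libs / 176))
  n_plates <- 2 * n_runs
  capacity <- rep(96L, n_plates)
  plate_run <- rep(seq_len(n_runs), each = 2)

  take_plate <- function(runs_allowed) {
    ok <- which(plate_run %in% runs_allowed & capacity > 0)
    if (length(ok) == 0) ok <- which(capacity > 0)
    p <- if (length(ok) == 1) ok else sample(ok, 1, prob = capacity[ok])
    capacity[p] <<- capacity[p] - 1L
    p
  }

  lib <- list()
  add_lib <- function(sample_id, specimen_id, role, buffer, kit, plate,
                      group_key) {
    lib[[length(lib) + 1]] <<- list(
      sample_id = sample_id, specimen_id = specimen_id, role = role,
      buffer = buffer, kit = kit, plate = plate,
      run = plate_run[plate], group_key = group_key)
  }

  if (!is.null(spec)) {
    for (i in seq_len(nrow(spec))) {
      sid <- spec$specimen_id[i]
      nlib <- c(dup_within = 2, dup_between = 2, trip_between = 3,
                quad_between = 4, single = 1)[[spec$rclass[i]]]
      p1 <- take_plate(seq_len(n_runs))
      used_runs <- plate_run[p1]
      for (r in seq_len(nlib)) {
        name <- if (r == 1) sid else sprintf("%s_R%d", sid, r)
        if (r == 1) {
          plate <- p1
        } else if (spec$rclass[i] == "dup_within") {
          # same run (ideally the same plate): re-amplification of one extract
          ok <- which(plate_run == plate_run[p1] & capacity > 0)
          plate <- if (length(ok) > 0) {
            pp <- if (p1 %in% ok) p1 else ok[1]
            capacity[pp] <- capacity[pp] - 1L; pp
          } else take_plate(plate_run[p1])
        } else {
          plate <- take_plate(setdiff(seq_len(n_runs), used_runs))
          used_runs <- c(used_runs, plate_run[plate])
        }
        # libraries of one specimen in one run share extraction-level state
        add_lib(name, sid, "specimen", "primestore", "kit_qs", plate,
                paste(sid, plate_run[plate], sep = "@"))
      }
    }
  }
  for (i in seq_len(cfg$n_ntc)) {
    p <- take_plate(seq_len(n_runs))
    add_lib(sprintf("NTC%02d", i), NA_character_, "ntc", "primestore",
            "kit_qs", p, sprintf("NTC%02d@%d", i, plate_run[p]))
  }
  mock_slots <- function(n, level) {
    if (n == 0) return()
    combos <- expand.grid(buffer = c("primestore", "stgg"),
                          kit = c("kit_qs", "kit_zb"),
                          stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      cb <- combos[((i - 1) %% nrow(combos)) + 1, ]
      p <- take_plate(seq_len(n_runs))
      id <- sprintf("MOCK_%s_%s_%s_%02d", toupper(substr(cb$buffer, 1, 2)),
                    toupper(substr(cb$kit, 5, 6)), level, i)
      add_lib(id, NA_character_, "mock", cb$buffer, cb$kit, p,
              paste(id, plate_run[p], sep = "@"))
    }
  }
  mock_slots(cfg$n_mock_high, "HI")
  mock_slots(cfg$n_mock_low, "LO")

  lib <- dplyr::bind_rows(lapply(lib, as_tibble))
  stopifnot(!anyDuplicated(lib$sample_id))

  # --- per-library biomass and true composition -----------------------------
  B_low <- cfg$mock_high_copies / cfg$dilution_factor
  lib$B <- 0
  lib$cluster <- NA_integer_
  true_profile <- matrix(0, nrow = nrow(lib), ncol = D)
  for (i in seq_len(nrow(lib))) {
    if (lib$role[i] == "specimen") {
      j <- match(lib$specimen_id[i], spec$specimen_id)
      lib$B[i] <- spec$B[j]
      lib$cluster[i] <- spec$cluster[j]
      true_profile[i, idx_true] <- spec_comp[j, ]
    } else if (lib$role[i] == "mock") {
      lib$B[i] <- if (grepl("_HI_", lib$sample_id[i])) cfg$mock_high_copies else B_low
      true_profile[i, idx_mock] <- mock_comp
    }
  }
  # kit lysis bias on the true part
  for (i in seq_len(nrow(lib))) {
    if (sum(true_profile[i, ]) > 0) {
      b <- cfg$kit_bias[[lib$kit[i]]][gram]
      true_profile[i, ] <- apply_kit_bias(true_profile[i, ], b)
    }
  }

  # --- extraction-level state shared by within-run repeats ------------------
  keys <- unique(lib$group_key)
  state <- list()
  for (k in keys) {
    i <- which(lib$group_key == k)[1]
    kap <- kappa_for(cfg, lib$buffer[i])
    # the longitudinal specimen runs carry a heavier reagent background than
    # the dedicated mock-community experiment (many reagent batches vs one
    # pooled batch); mocks keep the buffer-calibrated load
    if (lib$role[i] %in% c("specimen", "ntc")) {
      kap <- kap * cfg$reagent_load_specimen_runs
    }
    contam <- rdirichlet1(cfg$contam_library_concentration *
                            contam_base[[lib$buffer[i]]])
    eps <- cfg$spillover_rate * rgamma(1, shape = 2, rate = 2)
    mu <- cfg$depth_mean * (cfg$depth_floor + (1 - cfg$depth_floor) *
                              lib$B[i] / (lib$B[i] + cfg$depth_halfsat))
    depth <- max(200L, rnbinom(1, mu = mu, size = cfg$depth_dispersion))
    # run/extraction-level amplification effect: shared by re-amplifications
    # of one extract within a run, re-drawn across runs
    runfx <- exp(rnorm(D, 0, cfg$amplification_sigma))
    state[[k]] <- list(contam = contam, eps = eps, depth = depth, kappa = kap,
                       runfx = runfx)
  }

  w <- numeric(nrow(lib))
  eps <- numeric(nrow(lib))
  depth <- integer(nrow(lib))
  mixed <- matrix(0, nrow = nrow(lib), ncol = D)
  for (i in seq_len(nrow(lib))) {
    st <- state[[lib$group_key[i]]]
    w[i] <- if (lib$B[i] == 0 && st$kappa == 0) 0 else
      contamination_weight(lib$B[i], st$kappa)
    eps[i] <- st$eps
    depth[i] <- st$depth
    cv <- numeric(D); cv[idx_con] <- st$contam
    mixed[i, ] <- w[i] * true_profile[i, ] + (1 - w[i]) * cv
  }

  # --- plate-local spill-over, biomass-weighted donors ----------------------
  final <- mixed
  for (p in unique(lib$plate)) {
    on_p <- which(lib$plate == p)
    if (length(on_p) < 2) next
    Bp <- lib$B[on_p]
    for (ii in seq_along(on_p)) {
      i <- on_p[ii]
      donors <- on_p[-ii]
      wts <- lib$B[donors]
      if (sum(wts) == 0) next
      s <- colSums(mixed[donors, , drop = FALSE] * (wts / sum(wts)))
      final[i, ] <- (mixed[i, ] + eps[i] * s) / (1 + eps[i])
    }
  }

  # --- amplification jitter, read sampling ----------------------------------
  counts <- matrix(0L, nrow = D, ncol = nrow(lib),
                   dimnames = list(core_ids, lib$sample_id))
  for (i in seq_len(nrow(lib))) {
    a <- final[i, ] * state[[lib$group_key[i]]]$runfx *
      exp(rnorm(D, 0, cfg$library_sigma))
    a <- a / sum(a)
    counts[, i] <- rmultinom(1, depth[i], a)[, 1]
  }

  # --- spurious OTUs: disjoint id space, <= 2 libraries each ----------------
  sp_rows <- list(); sp_counter <- 0L
  for (i in seq_len(nrow(lib))) {
    lambda <- cfg$spurious_rate * (lib$B[i] + 1)^(-cfg$spurious_exponent)
    n_sp <- rpois(1, lambda)
    if (n_sp == 0) next
    for (s in seq_len(n_sp)) {
      sp_counter <- sp_counter + 1L
      cnt <- min(4L, 1L + rpois(1, 1))
      row <- integer(nrow(lib)); row[i] <- cnt
      if (cnt < 4L && runif(1) < 0.2 && nrow(lib) > 1) {
        row[sample(setdiff(seq_len(nrow(lib)), i), 1)] <- 1L
      }
      sp_rows[[sp_counter]] <- row
    }
  }
  if (sp_counter > 0) {
    sp_mat <- do.call(rbind, sp_rows)
    rownames(sp_mat) <- sprintf("OTU_S%04d", seq_len(sp_counter))
    colnames(sp_mat) <- lib$sample_id
    counts <- rbind(counts, sp_mat)
  }

  # --- metadata, taxonomy, truth --------------------------------------------
  copies <- numeric(nrow(lib))
  for (i in seq_len(nrow(lib))) {
    if (lib$role[i] == "specimen") {
      copies[i] <- spec$copies_meas[match(lib$specimen_id[i], spec$specimen_id)]
    } else {
      kap <- kappa_for(cfg, lib$buffer[i])
      copies[i] <- (lib$B[i] + kap) * rlnorm(1, 0, cfg$copies_noise_sigma)
    }
  }
  n_repeats <- table(lib$specimen_id[lib$role == "specimen"])
  metadata <- tibble(
    sample_id = lib$sample_id,
    role = lib$role,
    copies_per_ul = round(copies, 2),
    age_days = ifelse(lib$role == "specimen",
                      spec$age_days[match(lib$specimen_id, spec$specimen_id)],
                      NA_real_),
    run_id = sprintf("run%02d", lib$run),
    well = sprintf("P%02d_%s%02d", lib$plate,
                   LETTERS[((seq_len(nrow(lib)) - 1) %% 8) + 1],
                   ((seq_len(nrow(lib)) - 1) %/% 8 %% 12) + 1),
    repeat_group = ifelse(lib$role == "specimen", lib$specimen_id,
                          NA_character_),
    buffer = lib$buffer,
    kit = lib$kit)

  spur_tax <- if (sp_counter > 0) {
    tibble(otu_id = sprintf("OTU_S%04d", seq_len(sp_counter)),
           genus = "unclassified", species = "unclassified",
           origin = "spurious")
  } else {
    tibble(otu_id = character(), genus = character(), species = character(),
           origin = character())
  }
  tax_all <- dplyr::bind_rows(taxa$true, taxa$contam, taxa$mock, spur_tax)
  taxonomy <- tax_all[, c("otu_id", "genus", "species")]
  truth <- list(
    otus = tax_all[, c("otu_id", "origin")],
    samples = tibble(sample_id = lib$sample_id,
                     specimen_id = lib$specimen_id,
                     role = lib$role,
                     biomass_true = lib$B,
                     cluster = lib$cluster,
                     w = w,
                     spill_fraction = eps / (1 + eps),
                     depth = depth,
                     run_id = sprintf("run%02d", lib$run)))

  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy,
                 truth = truth, config = cfg),
            class = "lbqc_cohort")
}

#' @export
print.lbqc_cohort <- function(x, ...) {
  cat(sprintf("<lbqc_cohort> %d OTUs x %d libraries (%d specimens, %d NTCs, %d mocks)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$metadata$role == "specimen"),
              sum(x$metadata$role == "ntc"),
              sum(x$metadata$role == "mock")))
  invisible(x)
}
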