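#' Configuration for the synthetic three-domain cohort generator
#'
#' Defaults emulate the statistical structure of a 96-sample stool survey
#' covering bacteria, archaea and fungi: sparse genus count tables with
#' Dirichlet-multinomial noise, a near-mutually-exclusive pair of focal
#' archaeal genera (Methanobrevibacter / Nitrososphaera; the "both present"
#' probability `eps_both` defaults to 6/96), a reciprocal
#' Prevotella/Bacteroides abundance axis, a reciprocal
#' Ascomycota/Basidiomycota fungal phylum axis, and two nutrient inventories
#' (usual and recent) with block-exchangeable correlation plus planted
#' taxon-nutrient and taxon-status effects.
#'
#' @param n_samples cohort size (default 96).
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth parameters
#'   per sample and domain (default ~1000 reads).
#' @param dirichlet_theta Dirichlet concentration controlling overdispersion
#'   of within-sample proportions (larger = less noisy).
#' @param p_mbb_only,p_nit_only probabilities of a sample carrying only the
#'   methanogen or only the ammonia oxidizer (defaults 24/96 and 10/96).
#' @param eps_both probability that both focal archaea co-occur (default
#'   6/96; the predominant lineage still differs, shares `both_share` /
#'   `1 - both_share`).
#' @param both_share dominant-lineage share in co-occupied samples (0.8).
#' @param minor_archaea_occupancy occupancy probability of each non-focal
#'   archaeal genus.
#' @param pb_strength log-scale strength of the reciprocal
#'   Prevotella/Bacteroides latent axis.
#' @param fungal_phylum_strength log-scale strength of the reciprocal
#'   Ascomycota/Basidiomycota latent axis.
#' @param n_nutrients,n_blocks nutrient panel size and number of correlated
#'   blocks (defaults 200 and 20, i.e. clusters ~10% of nutrients).
#' @param rho_within,rho_between within-block and between-block nutrient
#'   correlation (defaults 0.7 and 0).
#' @param diet_effects data.frame of planted taxon-diet effects with columns
#'   `domain`, `genus`, `block` (nutrient block index), `rho` (target rank
#'   correlation of the latent tilt with the block factor).
#' @param status_effects data.frame of planted taxon-status effects with
#'   columns `domain`, `genus`, `status`, `delta` (log-scale shift in
#'   samples of that archaeal status).
#' @param diet_status_block nutrient block whose factor is shifted upward in
#'   methanogen-positive samples (0 = none), with shift `diet_status_delta`.
#' @param diet_status_delta see above.
#' @param effect_scale log-abundance and occupancy-logit gain applied to the
#'   planted tilt; the default sits in the saturation regime where the
#'   observable association is governed by the planted copula correlation
#'   `rho` rather than by the gain itself.
#' @param seed integer seed; all randomness flows from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 96,
                          depth_meanlog = log(1000), depth_sdlog = 0.5,
                          dirichlet_theta = 200,
                          p_mbb_only = 24 / 96, p_nit_only = 10 / 96,
                          eps_both = 6 / 96, both_share = 0.8,
                          minor_archaea_occupancy = 0.02,
                          pb_strength = 2, fungal_phylum_strength = 1.5,
                          n_nutrients = 200, n_blocks = 20,
                          rho_within = 0.7, rho_between = 0,
                          diet_effects = default_diet_effects(),
                          status_effects = default_status_effects(),
                          diet_status_block = 1, diet_status_delta = 0.6,
                          effect_scale = 3,
                          seed = 1) {
  stopifnot(p_mbb_only >= 0, p_nit_only >= 0, eps_both >= 0,
            p_mbb_only + p_nit_only + eps_both <= 1,
            rho_within >= 0, rho_within <= 1, rho_between >= 0, rho_between <= 1)
  if (n_nutrients %% n_blocks != 0)
    stop("block sizes must partition the nutrient count")
  structure(as.list(environment()), class = "cohort_config")
}

default_diet_effects <- function() {
  data.frame(domain = c("fungi", "bacteria", "bacteria"),
             genus = c("Candida", "Prevotella", "Bacteroides"),
             block = c(1, 1, 2),
             rho = c(0.5, 0.5, 0.5),
             stringsAsFactors = FALSE)
}

default_status_effects <- function() {
  data.frame(domain = c("fungi", "fungi", "bacteria", "bacteria"),
             genus = c("Candida", "Saccharomyces", "Ruminococcus", "Bacteroides"),
             status = rep("Methanobrevibacter", 4),
             delta = c(0.9, 0.7, 0.9, -0.7),
             stringsAsFactors = FALSE)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# genus roster per domain: names, occupancy probability, base log abundance,
# phylum assignment used for taxonomy and latent axes
domain_rosters <- function() {
  bact_named <- c("Bacteroides", "Prevotella", "Parabacteroides", "Faecalibacterium",
                  "Ruminococcus", "Blautia", "Roseburia", "Alistipes", "Oscillibacter",
                  "Dialister", "Oxalobacter", "Papillibacter")
  bact_fill <- sprintf("BactGenus%02d", seq_len(28))
  bact <- data.frame(
    genus = c(bact_named, bact_fill),
    occupancy = c(0.97, 0.35, 0.92, 0.95, 0.85, 0.9, 0.8, 0.75, 0.6, 0.45, 0.2, 0.15,
                  seq(0.8, 0.05, length.out = 28)),
    base = c(3.0, 2.6, 2.2, 2.4, 2.0, 2.0, 1.8, 1.6, 1.2, 1.0, 0.2, 0.2,
             seq(1.5, -1.5, length.out = 28)),
    phylum = c("Bacteroidetes", "Bacteroidetes", "Bacteroidetes", "Firmicutes",
               "Firmicutes", "Firmicutes", "Firmicutes", "Bacteroidetes",
               "Firmicutes", "Firmicutes", "Proteobacteria", "Firmicutes",
               rep(c("Firmicutes", "Bacteroidetes", "Actinobacteria", "Proteobacteria"),
                   length.out = 28)),
    stringsAsFactors = FALSE)
  arch <- data.frame(
    genus = c("Methanobrevibacter", "Nitrososphaera", "Methanosphaera",
              "Methanomassiliicoccus", "Thermogymnomonas"),
    occupancy = c(NA, NA, 0.02, 0.02, 0.02), # focal occupancy set by state machine
    base = c(3.0, 2.0, 0.5, 0.3, 0.2),
    phylum = c("Euryarchaeota", "Thaumarchaeota", "Euryarchaeota",
               "Euryarchaeota", "Euryarchaeota"),
    stringsAsFactors = FALSE)
  fung_named <- c("Saccharomyces", "Candida", "Cladosporium", "Aspergillus",
                  "Penicillium", "Debaryomyces", "Pichia", "Fusarium",
                  "Alternaria", "Galactomyces", "Malassezia", "Cryptococcus")
  fung_fill <- sprintf("FungGenus%02d", seq_len(12))
  fung_fill[1] <- "Agaricus"
  fung <- data.frame(
    genus = c(fung_named, fung_fill),
    occupancy = c(0.89, 0.57, 0.42, 0.30, 0.28, 0.25, 0.22, 0.18, 0.15, 0.12,
                  0.30, 0.20,
                  seq(0.06, 0.01, length.out = 12)),
    base = c(3.2, 2.6, 1.6, 1.4, 1.3, 1.2, 1.1, 1.0, 0.9, 0.8, 1.4, 1.0,
             seq(0.5, -0.5, length.out = 12)),
    phylum = c(rep("Ascomycota", 10), "Basidiomycota", "Basidiomycota",
               "Basidiomycota", rep(c("Ascomycota", "Basidiomycota"), length.out = 11)),
    stringsAsFactors = FALSE)
  list(bacteria = bact, archaea = arch, fungi = fung)
}

roster_taxonomy <- function(roster) {
  n <- nrow(roster)
  lin <- cbind(roster$phylum,
               paste0(roster$phylum, "_classA"),
               paste0(roster$phylum, "_order", 1 + seq_len(n) %% 3),
               paste0(roster$genus, "_fam"),
               roster$genus)
  rownames(lin) <- roster$genus
  taxonomy_table(lin)
}

#' Generate a synthetic three-domain cohort
#'
#' Draws archaeal occupancy states, latent reciprocal axes, block-correlated
#' nutrient inventories and Dirichlet-multinomial count tables, injecting
#' the configured taxon-diet and taxon-status effects on the latent
#' (Dirichlet-mean) scale so proportion-based statistics see the intended
#' signal. All randomness flows from `cfg$seed`.
#'
#' @param cfg a [cohort_config()].
#' @return list with `counts` (named list of three [count_table()]s),
#'   `taxonomy` (named list of three [taxonomy_table()]s), `nutrients`
#'   (list with `usual` and `recent` [nutrient_table()]s) and `truth`
#'   (ground truth: archaeal state per sample, nutrient block membership,
#'   planted effect lists, latent axes).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  rosters <- domain_rosters()

  # archaeal occupancy state machine
  st_p <- c(mbb = cfg$p_mbb_only, nit = cfg$p_nit_only, both = cfg$eps_both)
  state <- sample(c(names(st_p), "none"), n, replace = TRUE,
                  prob = c(st_p, 1 - sum(st_p)))
  names(state) <- samples

  # nutrient inventories: block factor model, usual factors reused for taxa effects
  blk_size <- cfg$n_nutrients / cfg$n_blocks
  block_of <- rep(seq_len(cfg$n_blocks), each = blk_size)
  make_inventory <- function(inv) {
    Fb <- matrix(stats::rnorm(n * cfg$n_blocks), n, cfg$n_blocks)
    if (cfg$diet_status_block > 0)
      Fb[, cfg$diet_status_block] <- Fb[, cfg$diet_status_block] +
        cfg$diet_status_delta * (state %in% c("mbb", "both"))
    shared <- if (cfg$rho_between > 0) sqrt(cfg$rho_between) * stats::rnorm(n) else 0
    vals <- vapply(seq_len(cfg$n_nutrients), function(j) {
      f <- Fb[, block_of[j]]
      sqrt(cfg$rho_within) * f + shared +
        sqrt(max(1 - cfg$rho_within - cfg$rho_between, 0)) * stats::rnorm(n)
    }, numeric(n))
    dimnames(vals) <- list(samples, sprintf("%s_nut_%03d", inv, seq_len(cfg$n_nutrients)))
    list(table = nutrient_table(vals, inv), factors = Fb)
  }
  usual <- make_inventory("usual")
  recent <- make_inventory("recent")

  # latent reciprocal axes
  u_pb <- stats::rnorm(n)        # Prevotella/Bacteroides axis
  v_phy <- stats::rnorm(n)       # Ascomycota/Basidiomycota axis

  status_of <- function(s) switch(s, mbb = "Methanobrevibacter", both = "Methanobrevibacter",
                                  nit = "Nitrososphaera", "none")
  # planted diet tilts: Gaussian copula with the usual-inventory block factor
  tilt <- list()
  for (k in seq_len(nrow(cfg$diet_effects))) {
    e <- cfg$diet_effects[k, ]
    f <- scale(usual$factors[, e$block])[, 1]
    tilt[[paste(e$domain, e$genus, sep = ":")]] <-
      e$rho * f + sqrt(1 - e$rho^2) * stats::rnorm(n)
  }

  make_domain <- function(dom) {
    ro <- rosters[[dom]]
    G <- nrow(ro)
    # planted effects act on the latent scale: they shift both the
    # Dirichlet mean (abundance) and the occupancy logit (detection)
    eff <- matrix(0, G, n)
    for (k in seq_len(nrow(cfg$diet_effects))) {
      e <- cfg$diet_effects[k, ]
      if (e$domain == dom && e$genus %in% ro$genus)
        eff[ro$genus == e$genus, ] <- eff[ro$genus == e$genus, ] +
          cfg$effect_scale * tilt[[paste(e$domain, e$genus, sep = ":")]]
    }
    for (k in seq_len(nrow(cfg$status_effects))) {
      e <- cfg$status_effects[k, ]
      if (e$domain == dom && e$genus %in% ro$genus) {
        hit <- vapply(state, function(s) status_of(s) == e$status, logical(1))
        eff[ro$genus == e$genus, hit] <- eff[ro$genus == e$genus, hit] + e$delta
      }
    }
    pocc <- stats::plogis(stats::qlogis(pmin(pmax(ro$occupancy, 1e-6), 1 - 1e-6)) + eff)
    occ <- matrix(stats::runif(G * n), G, n) < pocc
    if (dom == "archaea") {
      occ[1, ] <- state %in% c("mbb", "both")
      occ[2, ] <- state %in% c("nit", "both")
      occ[3:G, ] <- matrix(stats::runif((G - 2) * n) < cfg$minor_archaea_occupancy,
                           G - 2, n)
    } else {
      # fungal and bacterial sequences were detected in every sample:
      # guarantee at least the most prevalent genus
      none <- colSums(occ) == 0
      occ[which.max(ro$occupancy), none] <- TRUE
    }
    lm <- matrix(ro$base, G, n) + eff
    if (dom == "bacteria") {
      lm[ro$genus == "Prevotella", ] <- lm[ro$genus == "Prevotella", ] + cfg$pb_strength * u_pb
      lm[ro$genus == "Bacteroides", ] <- lm[ro$genus == "Bacteroides", ] - cfg$pb_strength * u_pb
    }
    if (dom == "fungi") {
      asc <- ro$phylum == "Ascomycota"
      lm[asc, ] <- sweep(lm[asc, , drop = FALSE], 2, cfg$fungal_phylum_strength * v_phy, "+")
      lm[!asc, ] <- sweep(lm[!asc, , drop = FALSE], 2, cfg$fungal_phylum_strength * v_phy, "-")
    }
    if (dom == "archaea" && any(state == "both")) {
      # predominant lineage always decidable: fix shares in co-occupied samples
      co <- state == "both"
      lm[1, co] <- log(cfg$both_share) + 3
      lm[2, co] <- log(1 - cfg$both_share) + 3
    }
    depth <- round(stats::rlnorm(n, cfg$depth_meanlog, cfg$depth_sdlog))
    counts <- matrix(0L, G, n, dimnames = list(ro$genus, samples))
    for (s in seq_len(n)) {
      a <- exp(lm[, s]) * occ[, s]
      if (sum(a) == 0) next
      p <- rdirichlet1(cfg$dirichlet_theta * a / sum(a))
      counts[, s] <- stats::rmultinom(1, depth[s], p)[, 1]
    }
    count_table(counts, dom)
  }

  counts <- list(bacteria = make_domain("bacteria"),
                 archaea = make_domain("archaea"),
                 fungi = make_domain("fungi"))
  taxonomy <- lapply(rosters, roster_taxonomy)

  truth <- list(
    archaeal_state = vapply(state, status_of, character(1)),
    raw_state = state,
    nutrient_block = stats::setNames(block_of, colnames(usual$table)),
    diet_effects = cfg$diet_effects,
    status_effects = cfg$status_effects,
    diet_status_block = cfg$diet_status_block,
    pb_axis = stats::setNames(u_pb, samples),
    phylum_axis = stats::setNames(v_phy, samples))

  list(counts = counts, taxonomy = taxonomy,
       nutrients = list(usual = usual$table, recent = recent$table),
       truth = truth, config = cfg)
}

#' Unequal-variance robustness simulation for PERMANOVA
#'
#' Generates two groups of points with equal centroids but within-group
#' dispersions differing by a given ratio, and reports the empirical
#' PERMANOVA rejection rate at `alpha` on Euclidean distances. With ratio 1
#' this is a type-I error calibration; larger ratios probe whether unequal
#' dispersion alone inflates rejections.
#'
#' @param dispersion_ratios dispersion (sd) ratios between the two groups.
#' @param n_per_group samples per group (default 20 + 20).
#' @param n_dims dimensionality of the simulated point cloud.
#' @param n_reps replicates per ratio.
#' @param n_perm permutations per test.
#' @param alpha nominal level (default 0.05).
#' @param seed integer seed.
#' @return data.frame with `ratio`, `rejection_rate`, `n_reps`.
#' @export
unequal_variance_simulation <- function(dispersion_ratios = c(1, 2, 4),
                                        n_per_group = 20, n_dims = 5,
                                        n_reps = 200, n_perm = 199,
                                        alpha = 0.05, seed = 1) {
  groups <- rep(c("g1", "g2"), each = n_per_group)
  out <- lapply(dispersion_ratios, function(r) {
    rej <- 0
    for (i in seq_len(n_reps)) {
      set.seed(seed + 7919L * i + round(1000 * r))
      x <- rbind(matrix(stats::rnorm(n_per_group * n_dims), n_per_group),
                 matrix(stats::rnorm(n_per_group * n_dims, sd = r), n_per_group))
      d <- as.matrix(stats::dist(x))
      dimnames(d) <- list(paste0("s", seq_len(2 * n_per_group)),
                          paste0("s", seq_len(2 * n_per_group)))
      pr <- permanova(d, groups, n_perm = n_perm, seed = seed + i)
      if (pr$p_value <= alpha) rej <- rej + 1
    }
    data.frame(ratio = r, rejection_rate = rej / n_reps, n_reps = n_reps)
  })
  do.call(rbind, out)
}
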