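#' Configuration for the synthetic AMD community generator
#'
#' Defines the planted structure of a simulated acid-mine-drainage amplicon
#' survey: lineage/sequence layout, occupancy classes, conditionally rare
#' taxa (CRT), the pH-anchored environmental gradient with collinear metal
#' concentrations, per-taxon Gaussian pH niches, and the community assembly
#' regime. Defaults emulate the scale of a multi-season AMD survey at reduced
#' size: 60 samples (10 sites x water/sediment x 3 events) and 50,000 reads
#' per sample.
#'
#' @param n_samples Number of samples (taken from the site x habitat x event
#'   grid in order).
#' @param n_sites Number of sites, laid out along the pH gradient.
#' @param habitats Habitat labels; each site is sampled in every habitat.
#' @param n_events Number of sampling events.
#' @param n_lineages Number of parent lineages (species-like clusters).
#' @param lineage_sizes Integer vector of ASVs per lineage. Default cycles
#'   through `c(1, 1, 2, 2, 4, 8, 12, 16)`.
#' @param seq_length Amplicon length in nt (V4-V5-like default 412).
#' @param max_subs Maximum substitutions between a member ASV and its lineage
#'   parent. `2 * max_subs` must stay within 1.3\% of `seq_length` so planted
#'   lineages re-cluster at the 98.7\% identity threshold.
#' @param broad_frac,intermediate_frac,narrow_frac Planted fractions of
#'   broad / intermediate / narrow occupancy taxa (must sum to <= 1; the
#'   remainder is assigned to `intermediate`).
#' @param n_crt Number of planted conditionally rare taxa.
#' @param crt_bloom Bloom multiplier for CRT (default 100).
#' @param crt_n_blooms Range (min, max) of bloom samples per CRT.
#' @param depth Sequencing depth per sample (>= 5000 so microdiversity
#'   analysis is possible).
#' @param pH_range Range of site pH values.
#' @param niche_optimum_range Range over which taxon pH optima are spread
#'   (default: `pH_range`). Setting it wider than `pH_range` simulates a
#'   species pool mostly maladapted to the sampled conditions, the situation
#'   in which environmental filtering is detectable.
#' @param metal_noise Lognormal noise (sdlog) on the metal-pH coupling.
#' @param niche_coupling Strength of the Gaussian pH niche response
#'   (0 disables environmental filtering).
#' @param niche_divergence_coupling Step size of per-substitution random
#'   walks in a member ASV's affinity to several spatio-temporal sample
#'   axes (habitat, sampling event, site parity), so the expected squared
#'   niche distance between two members is proportional to their
#'   nucleotide divergence. Plants a rho-vs-divergence signal.
#' @param microdiv_link If `TRUE`, lineages with >= 2 members are planted as
#'   broad/persistent and singleton lineages as intermediate, planting a
#'   persistence advantage for microdiverse OTUs.
#' @param regime Assembly regime: `"mixed"` (default; occupancy-class masks
#'   plus moderate filtering), `"selection"` (strong phylogenetically
#'   conserved pH filtering, one shared pool), `"dispersal_limitation"`
#'   (disjoint taxon pools across site blocks, no filtering), or `"drift"`
#'   (one pool, heavy demographic noise, no filtering).
#' @param n_site_blocks Number of site blocks for the dispersal-limitation
#'   regime.
#' @param baseline_sdlog Lognormal spread of per-taxon baseline intensities.
#' @param presence_lottery Per-(taxon, sample) dropout probability under the
#'   selection regime (recruitment stochasticity; 0 disables).
#' @param demographic_sdlog Per-sample lognormal demographic noise in the
#'   mixed regime (the drift regime uses a heavy fixed value of 2).
#' @param equal_members If `TRUE`, all members of a lineage share baseline,
#'   niche optimum, habitat preference and occupancy class (equal member
#'   intensities within each planted OTU; the condition under which
#'   effective microdiversity should recover the lineage size).
#' @param equal_intensities If `TRUE`, all baselines are 1 and masks,
#'   habitat effects, niches and noise are disabled (uniform expected
#'   relative abundances; used for calibration checks).
#' @param seed Integer seed; every simulation is fully reproducible.
#' @return A list of class `amd_sim_config`.
#' @export
sim_config <- function(n_samples = 60,
                       n_sites = 10,
                       habitats = c("water", "sediment"),
                       n_events = 3,
                       n_lineages = 40,
                       lineage_sizes = NULL,
                       seq_length = 412,
                       max_subs = 2,
                       broad_frac = 0.05,
                       intermediate_frac = 0.20,
                       narrow_frac = 0.70,
                       n_crt = 15,
                       crt_bloom = 100,
                       crt_n_blooms = c(1, 3),
                       depth = 50000,
                       pH_range = c(2, 7),
                       niche_optimum_range = NULL,
                       metal_noise = 0.3,
                       niche_coupling = 1,
                       niche_divergence_coupling = 0,
                       microdiv_link = FALSE,
                       regime = c("mixed", "selection",
                                  "dispersal_limitation", "drift"),
                       n_site_blocks = 4,
                       baseline_sdlog = 1,
                       demographic_sdlog = 0.3,
                       presence_lottery = 0.3,
                       equal_members = FALSE,
                       equal_intensities = FALSE,
                       seed = 20231201) {
  regime <- match.arg(regime)
  if (is.null(lineage_sizes))
    lineage_sizes <- rep(c(1L, 1L, 2L, 2L, 4L, 8L, 12L, 16L),
                         length.out = n_lineages)
  if (length(lineage_sizes) != n_lineages)
    stop("lineage_sizes must have length n_lineages")
  if (sum(lineage_sizes) < 2) stop("need at least 2 ASVs in total")
  if (2 * max_subs > floor(0.013 * seq_length))
    stop("infeasible config: within-cluster divergence exceeds the 98.7% ",
         "identity threshold")
  if (broad_frac + intermediate_frac + narrow_frac > 1 + 1e-9)
    stop("occupancy fractions must sum to <= 1")
  if (depth < 5000) stop("depth must be >= 5000 for microdiversity analysis")
  grid_n <- n_sites * length(habitats) * n_events
  if (n_samples > grid_n)
    stop("n_samples exceeds the site x habitat x event grid (", grid_n, ")")
  cfg <- as.list(environment())
  class(cfg) <- "amd_sim_config"
  cfg
}

jc_dist <- function(p) {
  # Jukes-Cantor distance from a raw proportion of differing sites.
  ifelse(p <= 0, 0, -0.75 * log(pmax(1 - 4 * p / 3, 1e-12)))
}

mutate_seq <- function(x, n_sub, alphabet = c("A", "C", "G", "T")) {
  if (n_sub == 0) return(x)
  v <- strsplit(x, "")[[1L]]
  pos <- sample(length(v), n_sub)
  for (i in pos) v[i] <- sample(setdiff(alphabet, v[i]), 1L)
  paste(v, collapse = "")
}

#' Simulate ASV sequences, a rooted phylogeny and the lineage map
#'
#' Parent lineages evolve along a pure-birth backbone tree (branch lengths in
#' substitutions/site; backbone rescaled so parents are mutually > 5\%
#' divergent), and each lineage's member ASVs are grafted as shallow tips at
#' Jukes-Cantor distances matching their planted substitution counts. The
#' first member of every lineage carries the parent sequence itself.
#'
#' @param cfg An [sim_config()] object.
#' @return A list with `sequences` (named character), `tree` ([ape::phylo],
#'   tips = ASV ids), `lineages` (data.frame: asv_id, lineage, genus,
#'   subs_from_parent) and `backbone` (the parent-level tree).
#' @export
simulate_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "amd_sim_config"))
  with_seed(cfg$seed, {
    L <- cfg$seq_length
    nl <- cfg$n_lineages
    sizes <- cfg$lineage_sizes
    alphabet <- c("A", "C", "G", "T")

    if (nl >= 2) {
      backbone <- ape::rphylo(nl, birth = 1, death = 0)
      backbone$tip.label <- paste0("P", seq_len(nl))
      # 16S-like overall depth; parent sequences are additionally forced
      # > 5% divergent below, which dominates for very recent splits
      coph <- ape::cophenetic.phylo(backbone)
      height <- max(coph) / 2
      backbone$edge.length <- backbone$edge.length * 0.6 / height
    } else {
      backbone <- NULL
    }

    # evolve parent sequences along the backbone (deterministic substitution
    # counts per edge keep raw divergence close to the branch lengths)
    root_seq <- paste(sample(alphabet, L, replace = TRUE), collapse = "")
    parents <- character(nl)
    if (nl >= 2) {
      nn <- ape::Nnode(backbone) + nl
      seq_at <- character(nn)
      root_node <- nl + 1L
      seq_at[root_node] <- root_seq
      eo <- ape::reorder.phylo(backbone, "cladewise")
      for (k in seq_len(nrow(eo$edge))) {
        par <- eo$edge[k, 1L]; chd <- eo$edge[k, 2L]
        nsub <- min(L, round(eo$edge.length[k] * L))
        seq_at[chd] <- mutate_seq(seq_at[par], nsub, alphabet)
      }
      parents <- seq_at[seq_len(nl)]
      # enforce mutual parent divergence > 5%
      min_div <- ceiling(0.05 * L) + 1L
      for (i in seq_len(nl)) for (j in seq_len(i - 1L)) {
        d <- sum(strsplit(parents[i], "")[[1L]] !=
                   strsplit(parents[j], "")[[1L]])
        if (d < min_div)
          parents[i] <- mutate_seq(parents[i], min_div - d, alphabet)
      }
    } else {
      parents[1L] <- root_seq
    }

    n_asv <- sum(sizes)
    ids <- sprintf("ASV_%04d", seq_len(n_asv))
    lineage <- rep(seq_len(nl), sizes)
    genus <- sprintf("Genus_%02d", lineage)
    subs <- integer(n_asv)
    seqs <- character(n_asv)
    idx <- 1L
    for (l in seq_len(nl)) {
      for (m in seq_len(sizes[l])) {
        if (m == 1L) {
          subs[idx] <- 0L
          seqs[idx] <- parents[l]
        } else {
          subs[idx] <- sample(seq_len(cfg$max_subs), 1L)
          seqs[idx] <- mutate_seq(parents[l], subs[idx], alphabet)
        }
        idx <- idx + 1L
      }
    }
    names(seqs) <- ids

    # graft member tips onto the backbone by Newick text substitution
    clade_txt <- function(l) {
      mem <- which(lineage == l)
      if (length(mem) == 1L) return(ids[mem])
      d <- pmax(jc_dist(subs[mem] / L), 1e-9)
      paste0("(", paste0(ids[mem], ":", format(d, scientific = FALSE),
                         collapse = ","), ")")
    }
    if (nl >= 2) {
      txt <- ape::write.tree(backbone)
      for (l in seq_len(nl))
        txt <- sub(paste0("P", l, ":"), paste0(clade_txt(l), ":"), txt,
                   fixed = TRUE)
      tree <- ape::read.tree(text = txt)
    } else {
      tree <- ape::read.tree(text = paste0(clade_txt(1L), ";"))
    }

    list(sequences = seqs, tree = tree,
         lineages = data.frame(asv_id = ids, lineage = lineage,
                               genus = genus, subs_from_parent = subs,
                               stringsAsFactors = FALSE),
         backbone = backbone)
  })
}

#' Simulate a count table, sample metadata and ground truth
#'
#' Counts are drawn per sample as a multinomial over taxon intensities:
#' lognormal baseline x Gaussian pH-niche response x habitat effect x
#' demographic noise. Narrow-occupancy taxa are masked to their home site
#' (the site nearest their pH optimum), intermediate taxa to the 3-6 nearest
#' sites, and CRT taxa sit below 0.1\% relative abundance except for 1-3
#' bloom samples. Metal concentrations are log-linear in pH with lognormal
#' noise, reproducing the strong geochemical collinearity of AMD systems.
#'
#' @param cfg An [sim_config()] object.
#' @param seqsim Result of [simulate_sequences()] for the same config.
#' @return A list with `counts` (features x samples integer matrix), `meta`
#'   (data.frame, sample ids as rownames) and `truth` (list: per-ASV
#'   data.frame `taxa`, regime, and the expected dominant process).
#' @export
simulate_counts <- function(cfg, seqsim) {
  stopifnot(inherits(cfg, "amd_sim_config"))
  with_seed(cfg$seed + 1L, {
    lin <- seqsim$lineages
    n_asv <- nrow(lin)
    ids <- lin$asv_id

    grid <- expand.grid(event = paste0("E", seq_len(cfg$n_events)),
                        habitat = cfg$habitats,
                        site = paste0("S", sprintf("%02d", seq_len(cfg$n_sites))),
                        stringsAsFactors = FALSE)[, 3:1]
    grid <- grid[seq_len(cfg$n_samples), , drop = FALSE]
    sample_ids <- sprintf("%s_%s_%s", grid$site, grid$habitat, grid$event)
    site_idx <- as.integer(sub("S", "", grid$site))

    # --- environment -----------------------------------------------------
    site_pH <- seq(cfg$pH_range[1], cfg$pH_range[2],
                   length.out = cfg$n_sites)
    pH <- pmin(13, pmax(1, site_pH[site_idx] + rnorm(cfg$n_samples, 0, 0.15)))
    lnoise <- function() rnorm(cfg$n_samples, 0, cfg$metal_noise)
    meta <- data.frame(
      habitat = grid$habitat, event = grid$event, site = grid$site,
      pH = round(pH, 2),
      Fe = exp(10 - 1.1 * pH + lnoise()),
      Mn = exp(7 - 0.9 * pH + lnoise()),
      Zn = exp(5.5 - 0.9 * pH + lnoise()),
      Cu = exp(4 - 0.9 * pH + lnoise()),
      Cd = exp(1 - 0.8 * pH + lnoise()),
      sulfate = exp(9 - 0.6 * pH + lnoise()),
      EC = exp(9.5 - 0.5 * pH + lnoise()),
      DO = pmax(0.2, rnorm(cfg$n_samples, 6.5, 1.5) -
                  3 * (grid$event == "E1")),
      ORP = 650 - 60 * pH + rnorm(cfg$n_samples, 0, 30),
      temperature = rnorm(cfg$n_samples, 18, 3),
      row.names = sample_ids, stringsAsFactors = FALSE)

    # --- planted taxon attributes ---------------------------------------
    crt <- rep(FALSE, n_asv)
    if (cfg$n_crt > 0) crt[sample(n_asv, min(cfg$n_crt, n_asv))] <- TRUE
    occ_class <- rep(NA_character_, n_asv)
    free <- which(!crt)
    if (cfg$microdiv_link) {
      k <- table(lin$lineage)[as.character(lin$lineage)]
      occ_class[free] <- ifelse(k[free] >= 2, "broad", "intermediate")
    } else {
      nf <- length(free)
      n_b <- round(cfg$broad_frac * nf)
      n_n <- round(cfg$narrow_frac * nf)
      n_i <- nf - n_b - n_n
      occ_class[free] <- sample(rep(c("broad", "intermediate", "narrow"),
                                    c(n_b, n_i, n_n)))
    }
    occ_class[crt] <- "broad"  # CRT are unmasked; blooms ride on a low base

    # phylogenetically conserved pH optima: Brownian trait on the backbone
    if (!is.null(seqsim$backbone)) {
      tr <- ape::rTraitCont(seqsim$backbone, model = "BM", sigma = 1)
      tr <- tr[paste0("P", seq_len(cfg$n_lineages))]
      orng <- if (is.null(cfg$niche_optimum_range)) cfg$pH_range else
        cfg$niche_optimum_range
      # rank-uniformize the Brownian trait: keeps its phylogenetic
      # ordering while spreading lineage optima evenly over the range,
      # so the favoured fraction does not swing with the tree draw
      opt_lin <- if (cfg$n_lineages > 1)
        orng[1] + diff(orng) * (rank(tr) - 1) / (cfg$n_lineages - 1)
      else rep(mean(orng), cfg$n_lineages)
    } else {
      orng <- if (is.null(cfg$niche_optimum_range)) cfg$pH_range else
        cfg$niche_optimum_range
      opt_lin <- runif(1, orng[1], orng[2])
    }
    if (cfg$regime == "selection") {
      # niche conservatism at the lineage scale only: optima are
      # independent across lineages, so every phylogenetic bin contains
      # favoured and unfavoured lineages and within-bin tip shuffles can
      # detect the consistent placement of selected taxa
      orng <- if (is.null(cfg$niche_optimum_range)) cfg$pH_range else
        cfg$niche_optimum_range
      opt_lin <- runif(cfg$n_lineages, orng[1], orng[2])
    }
    optimum <- opt_lin[lin$lineage]
    breadth <- c(broad = 3, intermediate = 1.5, narrow = 1)[occ_class]

    hpref <- sample(c("water", "sediment", "none"), n_asv, replace = TRUE,
                    prob = c(0.3, 0.3, 0.4))
    if (cfg$niche_divergence_coupling > 0) {
      # coarse habitat preference is conserved within a lineage; fine-scale
      # divergence in habitat affinity (below) rides on top of it
      hpref <- hpref[match(lin$lineage, lin$lineage)]
    }
    # narrow/intermediate baselines are kept low and tight so masked taxa
    # stay below the 1% bloom threshold: planted occupancy classes and CRT
    # flags must not overlap (a narrow taxon peaking above 1% would satisfy
    # the operational CRT definition)
    base_meanlog <- c(broad = 2, intermediate = 0.5, narrow = -2)[occ_class]
    if (cfg$microdiv_link) {
      # the persistence contrast is planted via occupancy masks, so the
      # intermediate (singleton-lineage) taxa keep a broad-level abundance
      # inside their home sites and stay above the OTU retention cutoff
      base_meanlog[occ_class == "intermediate"] <- 2
    }
    base_sdlog <- c(broad = 1, intermediate = 0.7,
                    narrow = 0.5)[occ_class] * cfg$baseline_sdlog
    baseline <- rlnorm(n_asv, base_meanlog, base_sdlog)
    if (cfg$equal_members) {
      # members of one lineage share all ecological attributes, so planted
      # within-OTU member intensities are equal in expectation
      first <- match(lin$lineage, lin$lineage)
      baseline <- baseline[first]
      optimum <- optimum[first]
      hpref <- hpref[first]
      occ_class <- occ_class[first]
      breadth <- breadth[first]
      crt <- crt[first]
    }
    # dispersal-limitation pools are disjoint at the ASV level and
    # phylogenetically random (cycling over ASV index spreads every lineage
    # across blocks), so restricted dispersal shows up as taxonomic
    # turnover (Raup-Crick) without a phylogenetic-selection signature
    block <- sample(rep_len(seq_len(cfg$n_site_blocks), n_asv))
    site_block <- ((site_idx - 1L) %% cfg$n_site_blocks) + 1L

    regime <- cfg$regime
    coupling <- switch(regime, selection = 3 * max(cfg$niche_coupling, 1),
                       dispersal_limitation = 0, drift = 0,
                       cfg$niche_coupling)
    if (regime == "selection") {
      # strong environmental filtering acts on every taxon: narrow niche
      # breadths, plus enough demographic noise that sample presence sets
      # overlap only partially (the regime null models detect selection
      # through the phylogenetic placement of non-shared taxa)
      breadth[] <- 0.8
    }
    demog <- switch(regime, drift = 0.8, selection = 0.3,
                    mixed = cfg$demographic_sdlog, 0)

    if (cfg$equal_intensities) {
      baseline <- rep(1, n_asv); coupling <- 0; demog <- 0
      hpref <- rep("none", n_asv); crt[] <- FALSE
      occ_class[] <- "broad"
    }

    # --- intensity matrix (taxa x samples) -------------------------------
    I <- matrix(baseline, n_asv, cfg$n_samples)
    if (coupling > 0) {
      resp <- exp(-outer((optimum), pH, "-")^2 /
                    (2 * breadth^2))^coupling
      I <- I * resp
    }
    hmul <- matrix(1, n_asv, cfg$n_samples)
    hmul[hpref == "water", meta$habitat != "water"] <- 0.25
    hmul[hpref == "water", meta$habitat == "water"] <- 2
    hmul[hpref == "sediment", meta$habitat != "sediment"] <- 0.25
    hmul[hpref == "sediment", meta$habitat == "sediment"] <- 2
    I <- I * hmul
    hwalk <- rep(0, n_asv)
    if (cfg$niche_divergence_coupling > 0) {
      # fine-scale niche divergence among close relatives: every mutated
      # member drifts along its own niche axis (a random mean-zero,
      # mutually orthogonal in-sample log-intensity contrast) by
      # `coupling * sqrt(substitutions)`, so the squared niche distance
      # between any two members is exactly coupling^2 * divergence
      has <- which(lin$subs_from_parent > 0)
      if (length(has)) {
        k <- min(length(has), cfg$n_samples - 2L)
        M <- matrix(rnorm(cfg$n_samples * k), cfg$n_samples, k)
        M <- sweep(M, 2L, colMeans(M))
        Q <- qr.Q(qr(M))
        sdQ <- apply(Q, 2L, sd)
        for (idx in seq_along(has)) {
          i <- has[idx]
          ax <- Q[, ((idx - 1L) %% k) + 1L]
          disp <- cfg$niche_divergence_coupling *
            sqrt(lin$subs_from_parent[i])
          hwalk[i] <- disp
          I[i, ] <- I[i, ] * exp(disp * ax / sdQ[((idx - 1L) %% k) + 1L])
        }
      }
    }

    home_sites <- vector("list", n_asv)
    if (regime == "mixed" && !cfg$equal_intensities) {
      hi <- max(2L, min(6L, floor(0.7 * cfg$n_sites)))
      n_int_sites <- sample(seq(min(3L, hi), hi), n_asv, replace = TRUE)
      if (cfg$equal_members)
        n_int_sites <- n_int_sites[match(lin$lineage, lin$lineage)]
      for (i in seq_len(n_asv)) {
        if (crt[i]) next
        rankd <- order(abs(site_pH - optimum[i]))
        if (occ_class[i] == "narrow") {
          home <- rankd[1L]
        } else if (occ_class[i] == "intermediate") {
          home <- rankd[seq_len(n_int_sites[i])]
        } else next
        home_sites[[i]] <- home
        I[i, !(site_idx %in% home)] <- 0
      }
    }
    if (regime == "dispersal_limitation")
      for (i in seq_len(n_asv)) I[i, site_block != block[i]] <- 0
    if (demog > 0)
      I <- I * matrix(rlnorm(n_asv * cfg$n_samples, 0, demog),
                      n_asv, cfg$n_samples)
    if (regime == "selection") {
      if (cfg$presence_lottery > 0) {
        # recruitment lottery: random per-sample dropouts give the
        # member-level presence turnover through which the null models can
        # see the phylogenetic placement of non-shared close relatives
        I <- I * matrix(rbinom(n_asv * cfg$n_samples, 1L,
                               1 - cfg$presence_lottery),
                        n_asv, cfg$n_samples)
      }
      # competitive exclusion: taxa whose filtered intensity share falls
      # below a detectability floor are truly absent, not trace "flicker"
      # presences re-drawn every sample
      share <- sweep(I, 2L, pmax(colSums(I), 1e-300), "/")
      I[share < 5e-5] <- 0
    }

    # CRT: baseline below 0.1% of the sample, x crt_bloom in 1-3 samples
    bloom_at <- vector("list", n_asv)
    if (any(crt)) {
      other_tot <- colSums(I[!crt, , drop = FALSE])
      for (i in which(crt)) {
        eps <- runif(1, 0.0001, 0.0008)
        I[i, ] <- eps * other_tot
        nb <- sample(seq(cfg$crt_n_blooms[1], cfg$crt_n_blooms[2]), 1L)
        at <- sample(cfg$n_samples, nb)
        I[i, at] <- I[i, at] * cfg$crt_bloom
        bloom_at[[i]] <- sample_ids[at]
      }
    }

    counts <- matrix(0L, n_asv, cfg$n_samples,
                     dimnames = list(ids, sample_ids))
    for (s in seq_len(cfg$n_samples)) {
      p <- I[, s]
      if (sum(p) == 0) p <- rep(1, n_asv)
      counts[, s] <- rmultinom(1L, cfg$depth, p / sum(p))
    }

    truth <- list(
      taxa = data.frame(asv_id = ids, lineage = lin$lineage,
                        genus = lin$genus, occupancy_class = occ_class,
                        crt = crt, niche_optimum = optimum,
                        habitat_affinity = hwalk,
                        habitat_pref = hpref, block = block,
                        stringsAsFactors = FALSE),
      regime = regime,
      expected_process = switch(regime, selection = "HoS",
                                dispersal_limitation = "DL",
                                drift = "DR", "mixed"))
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Simulate a complete synthetic community
#'
#' Convenience wrapper running [simulate_sequences()] then
#' [simulate_counts()].
#'
#' @param cfg An [sim_config()] object.
#' @return A list of class `amd_sim` with `counts`, `meta`, `sequences`,
#'   `tree`, `taxonomy` (asv_id + genus) and `truth`.
#' @export
simulate_community <- function(cfg) {
  ss <- simulate_sequences(cfg)
  cc <- simulate_counts(cfg, ss)
  out <- list(counts = cc$counts, meta = cc$meta, sequences = ss$sequences,
              tree = ss$tree,
              taxonomy = ss$lineages[, c("asv_id", "genus")],
              lineages = ss$lineages, truth = cc$truth, config = cfg)
  class(out) <- "amd_sim"
  out
}

#' @export
print.amd_sim <- function(x, ...) {
  cat("Synthetic AMD community:", nrow(x$counts), "ASVs x",
      ncol(x$counts), "samples;", x$config$n_lineages, "lineages; regime =",
      x$truth$regime, "\n")
  invisible(x)
}

#' Write / read ground truth as JSON (lossless round-trip)
#' @param truth Truth list from [simulate_counts()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$taxa <- as.data.frame(tr$taxa, stringsAsFactors = FALSE)
  tr
}
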