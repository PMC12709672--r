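#' End-to-end pipeline run
#'
#' Orchestrates simulate -> occupancy classification -> microdiversity ->
#' niche proportionality -> assembly partitioning -> environment
#' association -> supporting stats, writing every stage's table plus a JSON
#' run manifest (parameters, seed, input checksums, per-stage row counts)
#' into `out_dir`. Inputs are either file paths or a simulation config;
#' stage defaults are the field-standard values (1\% abundance, 75\%/10\%
#' occupancy, bimodality 0.9, 98.7\% identity, 5000-read rarefaction,
#' 100-permutation rho FDR, 5 nt / 10 ASV genus rule, 90/10 CV, 999
#' permutations, FDR 0.05, R2CV 0.01).
#'
#' @param out_dir Output directory (created if needed).
#' @param counts,meta,seqs,tree Input file paths (TSV/TSV/FASTA/Newick), or
#'   `NULL` to simulate.
#' @param taxonomy Taxonomy TSV path (required with file inputs).
#' @param sim A [sim_config()] used when file inputs are absent.
#' @param stages Character vector of stages to run, a subset of
#'   `c("occupancy", "microdiversity", "proportionality", "assembly",
#'   "env_association", "stats")`. `env_association` requires `assembly`.
#' @param params Named list overriding stage parameters: `depth`,
#'   `identity`, `min_asvs`, `max_div`, `n_perm_rho`, `ds`, `min_bin`,
#'   `n_null_z`, `n_null_rc`, `n_rep_cv`, `n_perm_assoc`, `n_rep_inner`.
#' @param seed Master seed; every stage derives its own substream.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(out_dir, counts = NULL, meta = NULL, seqs = NULL,
                         tree = NULL, taxonomy = NULL, sim = sim_config(),
                         stages = c("occupancy", "microdiversity",
                                    "proportionality", "assembly",
                                    "env_association", "stats"),
                         params = list(), seed = 20231201) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pdef <- list(depth = 5000, identity = 0.987, min_asvs = 10, max_div = 5,
               n_perm_rho = 100, ds = 0.2, min_bin = 12, n_null_z = 199,
               n_null_rc = 999, n_rep_cv = 1000, n_perm_assoc = 999,
               n_rep_inner = 100)
  pdef[names(params)] <- params
  p <- pdef
  manifest <- list(seed = seed, parameters = p, stages = stages,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  if (is.null(counts)) {
    simres <- simulate_community(sim)
    cm <- simres$counts; md <- simres$meta
    sq <- simres$sequences; tr <- simres$tree
    tx <- simres$taxonomy
    write_count_table(cm, file.path(out_dir, "counts.tsv"))
    write_sample_metadata(md, file.path(out_dir, "meta.tsv"))
    write_sequences(sq, file.path(out_dir, "seqs.fasta"))
    ape::write.tree(tr, file.path(out_dir, "tree.nwk"))
    write_truth(simres$truth, file.path(out_dir, "truth.json"))
    manifest$inputs <- list(simulated = TRUE, sim_seed = sim$seed)
  } else {
    cm <- read_count_table(counts)
    md <- if (!is.null(meta)) read_sample_metadata(meta) else NULL
    sq <- if (!is.null(seqs)) read_sequences(seqs) else NULL
    tr <- if (!is.null(tree)) read_phylo(tree) else NULL
    tx <- if (!is.null(taxonomy)) read_taxonomy(taxonomy) else NULL
    paths <- c(counts = counts, meta = meta, seqs = seqs, tree = tree,
               taxonomy = taxonomy)
    manifest$inputs <- as.list(tools::md5sum(paths[!vapply(paths, is.null,
                                                           TRUE)]))
  }
  results <- list()
  rowcount <- list()

  if ("occupancy" %in% stages) {
    occ <- occupancy_classes(cm, meta = md)
    write.table(occ, file.path(out_dir, "occupancy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$occupancy <- occ
    rowcount$occupancy <- nrow(occ)
  }
  if ("microdiversity" %in% stages) {
    if (is.null(sq)) stop("microdiversity stage needs sequences")
    mdp <- microdiversity_profile(cm, sq, depth = p$depth,
                                  identity = p$identity,
                                  seed = derive_seed(seed, "microdiv"))
    write.table(mdp, file.path(out_dir, "microdiversity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    otus <- attr(mdp, "otus")
    write.table(otus, file.path(out_dir, "otus.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$microdiversity <- mdp
    rowcount$microdiversity <- nrow(mdp)
  }
  if ("proportionality" %in% stages) {
    if (is.null(sq) || is.null(tx))
      stop("proportionality stage needs sequences and taxonomy")
    np <- niche_proportionality(cm, sq, tx, meta = md,
                                min_asvs = p$min_asvs, max_div = p$max_div,
                                n_perm = p$n_perm_rho,
                                seed = derive_seed(seed, "propr"))
    if (!is.null(np$genus_models))
      write.table(np$genus_models, file.path(out_dir, "genus_models.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    results$proportionality <- np
    rowcount$proportionality <-
      if (is.null(np$genus_models)) 0L else nrow(np$genus_models)
  }
  if ("assembly" %in% stages) {
    if (is.null(tr)) stop("assembly stage needs a tree")
    asm <- assembly_processes(cm, tr, ds = p$ds, min_size = p$min_bin,
                              n_null_z = p$n_null_z,
                              n_null_rc = p$n_null_rc,
                              seed = derive_seed(seed, "assembly"))
    write.table(asm$pair_bin, file.path(out_dir, "pair_bin.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    si <- data.frame(sample_id = rownames(asm$sample_importance),
                     asm$sample_importance, stringsAsFactors = FALSE)
    write.table(si, file.path(out_dir, "sample_importance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(asm$importance),
                         file.path(out_dir, "community_importance.json"),
                         auto_unbox = TRUE, digits = NA)
    results$assembly <- asm
    rowcount$assembly <- nrow(asm$pair_bin)
  }
  if ("env_association" %in% stages) {
    if (!"assembly" %in% stages) {
      message("env_association skipped: requires the assembly stage")
    } else if (is.null(md)) {
      message("env_association skipped: no metadata")
    } else {
      envv <- intersect(c("pH", "Fe", "Mn", "Zn", "Cu", "Cd", "sulfate",
                          "EC", "DO", "ORP", "temperature"), colnames(md))
      pc <- transform_processes(results$assembly$sample_importance)
      E <- transform_env(as.matrix(
        md[rownames(pc), envv, drop = FALSE]))
      assoc <- associate_all(pc, E, n_rep = p$n_rep_cv,
                             n_perm = p$n_perm_assoc,
                             n_rep_inner = p$n_rep_inner,
                             seed = derive_seed(seed, "envassoc"))
      write.table(assoc, file.path(out_dir, "associations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(E) >= ncol(E) + 2) {
        vf <- vif(E)
        write.table(vf, file.path(out_dir, "vif.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      } else {
        message("vif skipped: fewer samples than variables + 2")
        vf <- NULL
      }
      results$env_association <- assoc
      results$vif <- vf
      rowcount$env_association <- nrow(assoc)
    }
  }
  if ("stats" %in% stages) {
    alpha <- alpha_diversity(cm)
    write.table(alpha, file.path(out_dir, "alpha.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$alpha <- alpha
    rowcount$alpha <- nrow(alpha)
    if (!is.null(md) && "habitat" %in% colnames(md)) {
      ra <- to_relative(cm)
      d <- vegan::vegdist(t(ra), method = "bray")
      results$anosim <- anosim_test(d, md[colnames(cm), "habitat"],
                                    seed = derive_seed(seed, "anosim"))
      jsonlite::write_json(results$anosim,
                           file.path(out_dir, "anosim.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  manifest$row_counts <- rowcount
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
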