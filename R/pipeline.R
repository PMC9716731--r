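#' Pipeline configuration
#'
#' Collects every tunable threshold of the funnel (all defaulting to the
#' analysis' standard values), the Monte-Carlo settings, the synthetic-study
#' dimensions and the output directory. A seed is mandatory because the
#' enrichment null is stochastic.
#'
#' @param out_dir Output directory for [run_pipeline()].
#' @param seed Integer master seed.
#' @param alpha Significance cutoff used throughout.
#' @param min_fold Linear fold-change threshold (strict).
#' @param min_basemean Expression floor for the model-organism arm.
#' @param tumor_min_avg RPMMM floor for the tumor arm.
#' @param tumor_min_counts Normalized-count floor for tumor gene DE.
#' @param min_hits Recurrence requirement across genotype comparisons.
#' @param mc_iterations Monte-Carlo iterations for the enrichment null.
#' @param n_genes,n_mirnas,replicates,n_pairs,dispersion Synthetic-study
#'   dimensions.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "mirfunnel_out", seed = NULL,
                            alpha = 0.05, min_fold = 1.5, min_basemean = 500,
                            tumor_min_avg = 1000, tumor_min_counts = 1000,
                            min_hits = 3, mc_iterations = 1000,
                            n_genes = 300, n_mirnas = 24, replicates = 4,
                            n_pairs = 8, dispersion = 0.05) {
  cfg <- list(
    out_dir = out_dir, seed = seed, alpha = alpha, min_fold = min_fold,
    min_basemean = min_basemean, tumor_min_avg = tumor_min_avg,
    tumor_min_counts = tumor_min_counts, min_hits = min_hits,
    mc_iterations = mc_iterations, n_genes = n_genes, n_mirnas = n_mirnas,
    replicates = replicates, n_pairs = n_pairs, dispersion = dispersion
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed)) {
    abort("A `seed` is required: the enrichment null is stochastic.")
  }
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$min_fold >= 1,
            cfg$mc_iterations >= 100, cfg$min_hits >= 1)
  cfg
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose keys override the defaults.
#' @export
load_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Simulate a complete two-arm candidate-discovery study
#'
#' Builds every input the funnel consumes, with one planted signal: a guide
#' miRNA upregulated (+2 log2) in every mutant genotype and in the tumor
#' condition, whose planted targets are repressed wherever the miRNA is up.
#' The dataset also contains the nuisance structure the funnel must remove: a
#' passenger strand and a degradation-product annotation that track the
#' signal, a decoy miRNA upregulated in only two genotypes, and a second
#' regulated miRNA whose activity (not expression) changes, so the DE gene
#' lists are not purely signal targets.
#'
#' @param seed Integer seed.
#' @param n_genes,n_mirnas,replicates,n_pairs,dispersion Dimensions (defaults
#'   match [pipeline_config()]).
#' @param n_targets Planted targets of the signal miRNA.
#' @param mirna_effect_log2,target_effect_log2 Planted effect sizes.
#' @return A list bundling both arms' counts, metadata, sequences, site
#'   table, annotations and truth records.
#' @export
simulate_study <- function(seed, n_genes = 300, n_mirnas = 24,
                           replicates = 4, n_pairs = 8, dispersion = 0.05,
                           n_targets = 35, mirna_effect_log2 = 2,
                           target_effect_log2 = -1.5) {
  genotypes <- c("WT", "A", "B", "KRP", "KRS", "KRPS")
  mutants <- setdiff(genotypes, "WT")
  guide_ids <- paste0("miR-sim-", seq_len(n_mirnas), "-3p")
  signal <- guide_ids[1]
  activity_decoy <- guide_ids[2]
  passenger <- "miR-sim-1-5p"
  degradation <- "mir-5099"
  partial_decoy <- guide_ids[3]

  # --- sequence layer: UTRs, sites, conservation -------------------------
  seqs <- simulate_utrs_and_sites(
    n_genes = n_genes, n_mirnas = n_mirnas,
    utr_length_range = c(200, 1200),
    site_rates = c("8mer" = 0.3, "7mer-m8" = 0.3, "7mer-1A" = 0.3),
    conservation_rate = 0.8,
    planted = tibble::tibble(
      gene_id = paste0("gene-", seq_len(n_targets)),
      mirna_id = signal, site_class = "8mer", n_sites = 2L
    ),
    mirna_ids = guide_ids,
    seed = seed
  )

  target_map <- tibble::tibble(
    gene_id = paste0("gene-", seq_len(n_targets)),
    mirna_id = signal, effect_log2 = target_effect_log2
  )
  # activity-only decoy: its targets shift although the miRNA's counts do not
  decoy_targets <- tibble::tibble(
    gene_id = paste0("gene-", n_targets + seq_len(20)),
    mirna_id = activity_decoy, effect_log2 = target_effect_log2
  )

  # --- mouse (enteroid) arm ---------------------------------------------
  pat <- function(x) list(setNames(x, genotypes))
  modules <- tibble::tibble(
    module = c("signal", "passenger", "degradation", "partial"),
    pattern = c(
      pat(c(0, rep(mirna_effect_log2, 5))),
      pat(c(0, rep(mirna_effect_log2, 5))),
      pat(c(0, rep(mirna_effect_log2, 5))),
      pat(c(0, mirna_effect_log2, mirna_effect_log2, 0, 0, 0))
    ),
    n_members = c(1L, 1L, 1L, 1L)
  )
  mdesign <- sim_design(genotypes, wild_type = "WT", replicates = replicates,
                        n_features = n_mirnas + 2L, dispersion = dispersion,
                        base_mean_range = c(800, 5000), seed = seed + 11L)
  mouse_mirna <- simulate_mirna_counts(mdesign, modules)
  # planted features occupy the first rows; rename to the id scheme
  ids <- c(signal, passenger, degradation, partial_decoy,
           setdiff(guide_ids, c(signal, partial_decoy)))
  mouse_mirna$counts$feature_id <- ids
  mouse_mirna$truth$module_assignment$feature_id <- ids

  gdesign <- sim_design(genotypes, wild_type = "WT", replicates = replicates,
                        n_features = n_genes, dispersion = dispersion,
                        base_mean_range = c(600, 4000), seed = seed + 23L)
  mouse_mrna <- simulate_mrna_counts(
    gdesign, dplyr::bind_rows(target_map, decoy_targets),
    mirna_activity = tibble::tibble(
      mirna_id = c(signal, activity_decoy), activity_log2 = c(1, -1)
    )
  )

  # --- human (tumor/normal) arm -----------------------------------------
  tdesign <- sim_design(c("normal", "tumor"), wild_type = "normal",
                        replicates = n_pairs, n_features = n_mirnas + 2L,
                        dispersion = dispersion,
                        base_mean_range = c(800, 5000), seed = seed + 37L)
  tumor_modules <- tibble::tibble(
    module = c("signal", "passenger", "degradation"),
    pattern = c(
      list(c(normal = 0, tumor = mirna_effect_log2)),
      list(c(normal = 0, tumor = mirna_effect_log2)),
      list(c(normal = 0, tumor = mirna_effect_log2))
    ),
    n_members = c(1L, 1L, 1L)
  )
  tumor_mirna <- simulate_mirna_counts(tdesign, tumor_modules)
  tumor_mirna$counts$feature_id <- c(signal, passenger, degradation,
                                     setdiff(guide_ids, signal))
  tumor_mirna$meta$pair_id <- rep(paste0("pair-", seq_len(n_pairs)), 2)
  tumor_mirna$meta$tumor_type <- "COAD"

  hdesign <- sim_design(c("normal", "tumor"), wild_type = "normal",
                        replicates = n_pairs, n_features = n_genes,
                        dispersion = dispersion,
                        base_mean_range = c(600, 4000), seed = seed + 41L)
  tumor_mrna <- simulate_mrna_counts(
    hdesign, target_map,
    mirna_activity = tibble::tibble(mirna_id = signal, activity_log2 = 1)
  )

  # --- annotations -------------------------------------------------------
  guide_annotation <- tibble::tibble(
    mirna_id = c(guide_ids, passenger, degradation),
    strand = c(rep("guide", n_mirnas), "passenger", "guide")
  )
  family_map <- tibble::tibble(
    mirna_id = c(guide_ids, passenger, degradation),
    family = c(sub("^miR-sim-", "fam-", guide_ids), "fam-1-5p", "fam-deg")
  )

  mutations <- simulate_mutation_table(
    n_tumors = 60,
    per_gene_rates = tibble::tibble(
      gene = c("APC", "TP53", "SMAD4", "CTNNB1", "KRAS"),
      p_mutation = c(0.7, 0.55, 0.3, 0.05, 0.4),
      p_gain = c(0.05, 0.05, 0.05, 0.1, 0.15),
      p_loss = c(0.3, 0.25, 0.2, 0.05, 0.05)
    ),
    seed = seed + 53L
  )

  list(
    genotypes = genotypes, mutants = mutants,
    signal = signal, signal_family = sub("^miR-sim-", "fam-", signal),
    guide_ids = guide_ids,
    seqs = seqs, target_map = target_map,
    mouse_mirna = mouse_mirna, mouse_mrna = mouse_mrna,
    tumor_mirna = tumor_mirna, tumor_mrna = tumor_mrna,
    guide_annotation = guide_annotation, family_map = family_map,
    mutations = mutations, seed = seed
  )
}

#' Run the two-arm candidate funnel on a simulated (or assembled) study
#'
#' Executes, in order: degradation-id and guide filtering, per-genotype
#' pairwise DE on miRNAs, DE selection and the cross-comparison direction
#' consistency filter, per-comparison Monte-Carlo target enrichment on the
#' oppositely-regulated gene lists (cons1), recurrence calling; then the
#' tumor arm (RPMMM filter, tumor/normal DE, enrichment under cons2, matched
#' confirmation), paralog collapse on both arms and the final intersection.
#'
#' @param study A [simulate_study()] result (or a like-shaped list of real
#'   tables).
#' @param config A [pipeline_config()]; its seed drives the enrichment nulls.
#' @return A list of stage outputs ending in `final` (a family-level
#'   `candidate_set`).
#' @export
discover_candidates <- function(study, config = pipeline_config(seed = study$seed)) {
  cfg <- validate_config(config)
  log_stage <- function(...) message(sprintf(...))

  # ---- mouse arm -------------------------------------------------------
  mm <- study$mouse_mirna
  ids <- drop_degradation_ids(mm$counts$feature_id)
  ids <- filter_guides(ids, study$guide_annotation)
  log_stage("mouse miRNA universe: %d ids after guide/degradation filters",
            length(ids))
  counts_f <- mm$counts[mm$counts$feature_id %in% ids, , drop = FALSE]
  mirna_de <- lapply(study$mutants, function(g) {
    pairwise_de(counts_f, mm$meta, group_a = "WT", group_b = g)
  })
  names(mirna_de) <- study$mutants
  per_geno <- lapply(mirna_de, select_de, min_basemean = cfg$min_basemean,
                     min_fold = cfg$min_fold, alpha = cfg$alpha)
  union_ids <- unique(unlist(lapply(per_geno, function(x) x$mirna_id)))
  log_stage("DE in at least one genotype: %d miRNAs", length(union_ids))
  consistent <- consistent_direction(
    lapply(mirna_de, function(d) d[d$feature_id %in% union_ids, , drop = FALSE]),
    min_fold = cfg$min_fold
  )
  log_stage("direction-consistent across all comparisons: %d",
            nrow(consistent))

  gene_de <- lapply(study$mutants, function(g) {
    pairwise_de(study$mouse_mrna$counts, study$mouse_mrna$meta,
                group_a = "WT", group_b = g)
  })
  names(gene_de) <- study$mutants
  index_cons1 <- build_target_index(
    conservation_filter(study$seqs$sites, "cons1"),
    study$seqs$utr_lengths
  )
  enrich_mouse <- NULL
  mouse_set <- consistent[0, ]
  if (nrow(consistent) > 0) {
    enrich_mouse <- purrr::map_dfr(seq_len(nrow(consistent)), function(i) {
      cand <- consistent$mirna_id[i]
      opposite <- if (consistent$direction[i] == "up") "down" else "up"
      purrr::map_dfr(study$mutants, function(g) {
        de <- gene_de[[g]]
        sel <- !is.na(de$padj) & de$padj < cfg$alpha &
          abs(de$log2fc) > log2(cfg$min_fold) &
          de$baseMean > cfg$min_basemean &
          (if (opposite == "down") de$log2fc < 0 else de$log2fc > 0)
        genes <- de$feature_id[sel]
        if (length(genes) == 0) {
          return(tibble::tibble(mirna_id = cand, comparison = g,
                                empirical_p = 1))
        }
        res <- monte_carlo_enrichment(
          genes, index_cons1, mirnas = cand,
          n_iterations = cfg$mc_iterations,
          seed = cfg$seed + 1000L * i + match(g, study$mutants)
        )
        tibble::tibble(mirna_id = cand, comparison = g,
                       empirical_p = res$empirical_p)
      })
    })
    recur <- recurrent_candidates(enrich_mouse, alpha = cfg$alpha,
                                  min_hits = cfg$min_hits)
    mouse_set <- consistent[consistent$mirna_id %in% recur, , drop = FALSE]
  }
  log_stage("recurrently enriched (>= %d of %d comparisons): %d",
            cfg$min_hits, length(study$mutants), nrow(mouse_set))
  mouse_fam <- collapse_paralogs(mouse_set, study$family_map)

  # ---- tumor arm -------------------------------------------------------
  tm <- study$tumor_mirna
  t_ids <- filter_guides(drop_degradation_ids(tm$counts$feature_id),
                         study$guide_annotation)
  t_counts <- tm$counts[tm$counts$feature_id %in% t_ids, , drop = FALSE]
  rp <- rpmmm(t_counts)
  expressed <- tcga_expression_filter(rp, tm$meta, min_avg = cfg$tumor_min_avg)
  t_de <- pairwise_de(t_counts, tm$meta, group_a = "normal",
                      group_b = "tumor")
  tumor_cand <- select_de(t_de, min_basemean = 0, min_fold = cfg$min_fold,
                          alpha = cfg$alpha)
  tumor_cand <- tumor_cand[tumor_cand$mirna_id %in% expressed, , drop = FALSE]
  log_stage("tumor-arm DE miRNAs above %g RPMMM: %d", cfg$tumor_min_avg,
            nrow(tumor_cand))

  tumor_gene_de <- pairwise_de(study$tumor_mrna$counts,
                               study$tumor_mrna$meta,
                               group_a = "normal", group_b = "tumor")
  index_cons2 <- build_target_index(
    conservation_filter(study$seqs$sites, "cons2"),
    study$seqs$utr_lengths
  )
  enrich_tumor <- NULL
  if (nrow(tumor_cand) > 0) {
    enrich_tumor <- purrr::map_dfr(seq_len(nrow(tumor_cand)), function(i) {
      cand <- tumor_cand$mirna_id[i]
      opposite_down <- tumor_cand$direction[i] == "up"
      de <- tumor_gene_de
      sel <- !is.na(de$padj) & de$padj < cfg$alpha &
        abs(de$log2fc) > log2(cfg$min_fold) &
        de$baseMean > cfg$tumor_min_counts &
        (if (opposite_down) de$log2fc < 0 else de$log2fc > 0)
      genes <- de$feature_id[sel]
      if (length(genes) == 0) {
        return(tibble::tibble(mirna_id = cand, empirical_p = 1))
      }
      res <- monte_carlo_enrichment(
        genes, index_cons2, mirnas = cand,
        n_iterations = cfg$mc_iterations,
        seed = cfg$seed + 60000L + i
      )
      tibble::tibble(mirna_id = cand, empirical_p = res$empirical_p)
    })
    keep <- enrich_tumor$mirna_id[enrich_tumor$empirical_p < cfg$alpha]
    tumor_cand <- tumor_cand[tumor_cand$mirna_id %in% keep, , drop = FALSE]
  }
  log_stage("tumor-arm target-enriched miRNAs: %d", nrow(tumor_cand))
  confirmed <- matched_confirmation(rp, tm$meta, tumor_cand,
                                    alpha = cfg$alpha)
  log_stage("confirmed in matched pairs: %d", nrow(confirmed))
  human_fam <- collapse_paralogs(confirmed, study$family_map)

  final <- intersect_candidates(mouse_fam, human_fam)
  log_stage("cross-dataset intersection: %d family(ies)", nrow(final))

  list(
    mirna_de = mirna_de, per_genotype = per_geno, consistent = consistent,
    gene_de = gene_de, enrich_mouse = enrich_mouse, mouse_set = mouse_set,
    mouse_families = mouse_fam,
    tumor_de = t_de, tumor_gene_de = tumor_gene_de,
    enrich_tumor = enrich_tumor, tumor_confirmed = confirmed,
    human_families = human_fam,
    final = final
  )
}

#' Run the full synthetic end-to-end pipeline and write a manifest
#'
#' Simulates a study from the config's seed, runs every stage (module
#' clustering of the LRT screen, both funnel arms, genotype binning of the
#' simulated mutation table, the pan-cancer summary for the final candidate,
#' and the steady/nascent triage), writes each output as a plain-text table
#' under `config$out_dir`, and returns a manifest of files with MD5 hashes.
#' Rerunning with the same config and seed reproduces the manifest
#' bit-identically.
#'
#' @param config A [pipeline_config()] with a seed.
#' @return Tibble manifest (`file`, `md5`) with the config hash and seed as
#'   attributes; also written to `manifest.tsv` in the output directory.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(cfg$out_dir, name)

  cfg_path <- outfile("config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)

  study <- simulate_study(
    seed = cfg$seed, n_genes = cfg$n_genes, n_mirnas = cfg$n_mirnas,
    replicates = cfg$replicates, n_pairs = cfg$n_pairs,
    dispersion = cfg$dispersion
  )
  write_count_matrix(study$mouse_mirna$counts, outfile("mouse_mirna_counts.tsv"),
                     study$mouse_mirna$meta, outfile("mouse_mirna_meta.tsv"))
  write_count_matrix(study$mouse_mrna$counts, outfile("mouse_mrna_counts.tsv"),
                     study$mouse_mrna$meta, outfile("mouse_mrna_meta.tsv"))
  write_count_matrix(study$tumor_mirna$counts, outfile("tumor_mirna_counts.tsv"),
                     study$tumor_mirna$meta, outfile("tumor_mirna_meta.tsv"))
  write_utr_fasta(study$seqs$utrs, outfile("utrs.fasta"))
  write_site_table(study$seqs$sites, outfile("site_table.tsv"))
  readr::write_tsv(study$mutations, outfile("mutation_table.tsv"))
  yaml::write_yaml(
    list(signal = study$signal, signal_family = study$signal_family,
         targets = study$target_map$gene_id),
    outfile("truth.yaml")
  )

  # expression modules from the multi-genotype screen
  lrt <- lrt_screen(study$mouse_mirna$counts, study$mouse_mirna$meta,
                    full_factors = "condition")
  write_de_table(lrt, outfile("lrt_screen.tsv"))
  hits <- lrt_hit_filter(lrt, min_basemean = cfg$min_basemean,
                         alpha = cfg$alpha)
  transformed <- rlog_like(study$mouse_mirna$counts)
  mods <- cluster_modules(
    transformed[transformed$feature_id %in% hits, , drop = FALSE],
    study$mouse_mirna$meta
  )
  readr::write_tsv(mods$assignment, outfile("modules.tsv"))
  delta <- delta_vs_wt(transformed, study$mouse_mirna$meta, wt_label = "WT")
  readr::write_tsv(delta$display, outfile("delta_vs_wt.tsv"))

  # both funnel arms
  res <- discover_candidates(study, cfg)
  for (g in names(res$mirna_de)) {
    write_de_table(res$mirna_de[[g]],
                   outfile(paste0("mirna_de_", g, ".tsv")))
    write_de_table(res$gene_de[[g]],
                   outfile(paste0("gene_de_", g, ".tsv")))
  }
  write_candidates(res$consistent, outfile("consistent_candidates.tsv"))
  if (!is.null(res$enrich_mouse)) {
    readr::write_tsv(res$enrich_mouse, outfile("enrichment_mouse.tsv"))
  }
  write_candidates(res$mouse_families, outfile("mouse_families.tsv"))
  write_de_table(res$tumor_de, outfile("tumor_mirna_de.tsv"))
  write_de_table(res$tumor_gene_de, outfile("tumor_gene_de.tsv"))
  write_candidates(res$human_families, outfile("tumor_families.tsv"))
  write_candidates(res$final, outfile("final_intersection.tsv"))

  # genotype binning of the simulated mutation table
  bins <- assign_genotypes(study$mutations)
  readr::write_tsv(bins, outfile("tumor_genotypes.tsv"))

  # pan-cancer style summary for the signal miRNA
  rp <- rpmmm(study$tumor_mirna$counts)
  pc <- pan_cancer_summary(rp, study$tumor_mirna$meta, study$signal)
  readr::write_tsv(pc, outfile("pan_cancer.tsv"))

  # steady/nascent classification and triage
  pair_design <- sim_design(c("control", "treated"), wild_type = "control",
                            replicates = 4, n_features = 200,
                            dispersion = cfg$dispersion,
                            base_mean_range = c(600, 4000),
                            seed = cfg$seed + 71L)
  labels <- tibble::tibble(
    gene_id = paste0("gene-", seq_len(200)),
    label = c(rep("post_transcriptional", 30), rep("transcriptional", 30),
              rep("unregulated", 140)),
    sign = rep(c(1, -1), 100)
  )
  pair <- simulate_rna_chro_pair(pair_design, labels, effect_log2 = 1)
  steady_de <- pairwise_de(pair$steady, pair$meta, "control", "treated")
  nascent_de <- pairwise_de(pair$nascent, pair$meta, "control", "treated")
  calls <- classify_regulation(steady_de, nascent_de)
  write_regulation_calls(calls, outfile("regulation_calls.tsv"))
  tiers <- triage_targets(steady_de, study$target_map$gene_id,
                          res$tumor_gene_de,
                          min_counts = cfg$min_basemean,
                          tumor_min_counts = cfg$tumor_min_counts,
                          tumor_min_fold = cfg$min_fold, alpha = cfg$alpha)
  readr::write_tsv(
    tibble::tibble(
      tier = rep(c("tier1", "tier2", "tier3"), lengths(tiers)),
      gene_id = unlist(tiers, use.names = FALSE)
    ),
    outfile("triage_tiers.tsv")
  )

  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.tsv"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files)))
  )
  attr(manifest, "config_md5") <- unname(tools::md5sum(cfg_path))
  attr(manifest, "seed") <- cfg$seed
  readr::write_tsv(manifest, outfile("manifest.tsv"))
  manifest
}
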