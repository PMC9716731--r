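#' Specify a synthetic multi-genotype count design
#'
#' Captures the experimental skeleton the simulators share: a set of genotype
#' (or condition) labels with one designated wild-type/reference, a replicate
#' count, the number of features, a negative-binomial dispersion shared across
#' features, the range baseline means are drawn from (log-uniform), optional
#' per-sample batch labels, and a seed.
#'
#' @param genotypes Character vector of condition labels.
#' @param wild_type The reference label; must appear exactly once in
#'   `genotypes`.
#' @param replicates Replicates per genotype (>= 1).
#' @param n_features Number of features to simulate.
#' @param dispersion NB dispersion alpha (> 0); variance = mu + alpha * mu^2.
#' @param base_mean_range Length-2 positive range for baseline means.
#' @param batch Optional character vector of batch labels, one per sample
#'   (samples ordered genotype-major, replicate-minor).
#' @param seed Integer seed.
#' @return A `sim_design` list.
#' @export
sim_design <- function(genotypes, wild_type = genotypes[1], replicates = 3,
                       n_features = 100, dispersion = 0.05,
                       base_mean_range = c(100, 5000), batch = NULL, seed = 1) {
  if (sum(genotypes == wild_type) != 1) {
    abort("`wild_type` must appear exactly once in `genotypes`.")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  if (length(base_mean_range) != 2 || any(base_mean_range <= 0) ||
      base_mean_range[1] > base_mean_range[2]) {
    abort("`base_mean_range` must be a positive, ordered length-2 range.")
  }
  n_samples <- length(genotypes) * replicates
  if (!is.null(batch) && length(batch) != n_samples) {
    abort("`batch` must have one label per sample.")
  }
  structure(
    list(
      genotypes = genotypes, wild_type = wild_type, replicates = replicates,
      n_features = n_features, dispersion = dispersion,
      base_mean_range = base_mean_range, batch = batch, seed = seed
    ),
    class = "sim_design"
  )
}

design_meta <- function(design, prefix = "s") {
  g <- rep(design$genotypes, each = design$replicates)
  meta <- tibble::tibble(
    sample = paste0(prefix, "_", g, "_", rep(seq_len(design$replicates),
                                             times = length(design$genotypes))),
    condition = g
  )
  if (!is.null(design$batch)) meta$batch <- design$batch
  meta
}

draw_base_means <- function(design) {
  exp(runif(design$n_features, log(design$base_mean_range[1]),
            log(design$base_mean_range[2])))
}

# NB draw for a matrix of means under the design's shared dispersion
nb_draw <- function(mu, dispersion) {
  m <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
    nrow = nrow(mu), dimnames = dimnames(mu)
  )
  storage.mode(m) <- "double"
  m
}

#' Simulate a miRNA count matrix with planted expression modules
#'
#' Features belonging to a module have their genotype means multiplied by
#' `2^pattern[genotype]`; all other features follow the all-zero pattern.
#' Optional additive log2 batch offsets are applied to the mean and recorded
#' in the metadata, so the batch-removal step can be validated against truth.
#'
#' @param design A [sim_design()].
#' @param modules Tibble with columns `module` (id), `pattern` (list-column of
#'   numeric vectors in log2 units, one entry per genotype in design order)
#'   and `n_members`. `NULL` means no planted structure.
#' @param batch_effects Optional named numeric of additive log2 offsets per
#'   batch label.
#' @param feature_prefix Prefix for generated feature ids.
#' @return A list with `counts` (wide tibble), `meta` (tibble, including any
#'   `batch` and `batch_offset_log2` columns) and `truth` (a list with
#'   `module_assignment` and `de_direction` tibbles and the `pattern` matrix).
#' @export
simulate_mirna_counts <- function(design, modules = NULL, batch_effects = NULL,
                                  feature_prefix = "miR-sim") {
  set.seed(design$seed)
  ng <- length(design$genotypes)
  if (!is.null(modules)) {
    if (sum(modules$n_members) > design$n_features) {
      abort("Module member counts exceed `n_features`.")
    }
    bad <- vapply(modules$pattern, length, 1L) != ng
    if (any(bad)) {
      abort("Each module pattern must have one entry per genotype.")
    }
  }
  feature_id <- paste0(feature_prefix, "-", seq_len(design$n_features))
  base <- draw_base_means(design)
  pattern <- matrix(0, design$n_features, ng,
                    dimnames = list(feature_id, design$genotypes))
  assignment <- rep(NA_character_, design$n_features)
  if (!is.null(modules)) {
    at <- 1L
    for (i in seq_len(nrow(modules))) {
      idx <- seq(at, at + modules$n_members[i] - 1L)
      pattern[idx, ] <- matrix(rep(modules$pattern[[i]], each = length(idx)),
                               nrow = length(idx))
      assignment[idx] <- as.character(modules$module[i])
      at <- at + modules$n_members[i]
    }
  }
  meta <- design_meta(design, prefix = feature_prefix)
  mu <- base * 2^pattern[, meta$condition, drop = FALSE]
  colnames(mu) <- meta$sample
  if (!is.null(batch_effects)) {
    if (is.null(design$batch)) abort("`batch_effects` given but design has no batch labels.")
    off <- unname(batch_effects[design$batch])
    off[is.na(off)] <- 0
    mu <- mu * rep(2^off, each = nrow(mu))
    meta$batch_offset_log2 <- off
  }
  counts <- values_to_counts(nb_draw(mu, design$dispersion))
  wt_pat <- pattern[, design$wild_type]
  de <- tidyr::expand_grid(feature_id = feature_id,
                           genotype = setdiff(design$genotypes, design$wild_type)) |>
    dplyr::mutate(
      delta = pattern[cbind(.data$feature_id, .data$genotype)] -
        wt_pat[.data$feature_id],
      direction = dplyr::case_when(
        .data$delta > 0 ~ "up",
        .data$delta < 0 ~ "down",
        TRUE ~ "null"
      )
    ) |>
    dplyr::select(-"delta")
  list(
    counts = counts, meta = meta,
    truth = list(
      module_assignment = tibble::tibble(feature_id = feature_id,
                                         module = assignment),
      de_direction = de,
      pattern = pattern,
      base_mean = setNames(base, feature_id)
    )
  )
}

#' Simulate 3'UTR sequences with planted miRNA seed sites
#'
#' UTRs are uniform-random RNA; seed-match substrings (8mer, 7mer-m8,
#' 7mer-1A) for randomly chosen miRNAs are written in at random
#' non-overlapping positions at the per-class Poisson rates given, and
#' specific (gene, miRNA) sites can be planted explicitly. The returned site
#' table is the result of rescanning the finished sequences with
#' [find_seed_sites()], so chance matches are included and the table is exact
#' by construction. Every site carries independent per-species Bernoulli
#' conservation flags.
#'
#' @param n_genes,n_mirnas Numbers of UTRs and miRNAs.
#' @param utr_length_range Length-2 range (>= 30 nt) for uniform UTR lengths.
#' @param site_rates Named numeric: expected planted sites per UTR for classes
#'   `8mer`, `7mer-m8`, `7mer-1A` (missing classes default to 0).
#' @param conservation_rate Per-species probability a site is flagged
#'   conserved.
#' @param species Species universe for conservation flags.
#' @param planted Optional tibble (`gene_id`, `mirna_id`, `site_class`,
#'   `n_sites`) of guaranteed sites (default one per row).
#' @param mirna_ids Optional explicit miRNA ids (length `n_mirnas`).
#' @param seed Integer seed.
#' @return A list with `utrs` (named character, RNA), `mirnas` (tibble
#'   `mirna_id`, `sequence`), `sites` (the rescanned site table with a
#'   `conserved_in` comma-joined species column), `utr_lengths` (tibble) and
#'   `truth` (tibble of intended plants).
#' @export
simulate_utrs_and_sites <- function(n_genes, n_mirnas,
                                    utr_length_range = c(200, 1200),
                                    site_rates = c("8mer" = 0.2,
                                                   "7mer-m8" = 0.2,
                                                   "7mer-1A" = 0.2),
                                    conservation_rate = 0.5,
                                    species = c("mouse", "human", "rat",
                                                "dog", "chicken"),
                                    planted = NULL, mirna_ids = NULL,
                                    seed = 1) {
  set.seed(seed)
  if (any(site_rates < 0)) abort("`site_rates` must be >= 0.")
  if (utr_length_range[1] < 30) abort("UTR lengths must be >= 30 nt.")
  classes <- c("8mer", "7mer-m8", "7mer-1A")
  rates <- setNames(rep(0, 3), classes)
  rates[intersect(names(site_rates), classes)] <-
    site_rates[intersect(names(site_rates), classes)]

  gene_id <- paste0("gene-", seq_len(n_genes))
  mirna_id <- mirna_ids %||% paste0("miR-sim-", seq_len(n_mirnas))
  if (length(mirna_id) != n_mirnas) abort("`mirna_ids` must have length `n_mirnas`.")
  if (!is.null(planted)) {
    bad <- setdiff(unique(planted$mirna_id), mirna_id)
    if (length(bad) > 0) {
      abort(paste0("Planted sites for unknown miRNA ids: ",
                   paste(bad, collapse = ", ")))
    }
    bad_g <- setdiff(unique(planted$gene_id), gene_id)
    if (length(bad_g) > 0) {
      abort(paste0("Planted sites for unknown genes: ",
                   paste(bad_g, collapse = ", ")))
    }
  }
  mirna_seq <- vapply(seq_len(n_mirnas), function(i) {
    paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = "")
  }, "")
  utr_len <- floor(runif(n_genes, utr_length_range[1], utr_length_range[2] + 1))
  utrs <- setNames(vapply(utr_len, function(L) {
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
  }, ""), gene_id)

  # per-gene bookkeeping of occupied intervals so plants never overlap
  occupied <- lapply(utr_len, function(L) logical(L))
  names(occupied) <- gene_id
  plant_one <- function(g, m, cls) {
    s <- site_sequences(mirna_seq[m])[[cls]]
    L <- nchar(utrs[[g]])
    if (nchar(s) > L) abort("Planted site longer than UTR.")
    for (try in 1:50) {
      p <- sample.int(L - nchar(s) + 1L, 1L)
      span <- p:(p + nchar(s) - 1L)
      if (!any(occupied[[g]][span])) {
        occupied[[g]][span] <<- TRUE
        substr(utrs[[g]], p, p + nchar(s) - 1L) <<- s
        return(p)
      }
    }
    NA_integer_  # no free slot found; skip silently
  }

  truth <- list()
  # explicit plants first
  if (!is.null(planted)) {
    if (!"n_sites" %in% names(planted)) planted$n_sites <- 1L
    for (i in seq_len(nrow(planted))) {
      for (k in seq_len(planted$n_sites[i])) {
        p <- plant_one(planted$gene_id[i],
                       match(planted$mirna_id[i], mirna_id),
                       planted$site_class[i])
        truth[[length(truth) + 1L]] <- tibble::tibble(
          gene_id = planted$gene_id[i], mirna_id = planted$mirna_id[i],
          site_class = planted$site_class[i], start = p
        )
      }
    }
  }
  # background plants at the class rates
  for (g in gene_id) {
    for (cls in classes) {
      for (k in seq_len(rpois(1, rates[cls]))) {
        m <- sample.int(n_mirnas, 1L)
        p <- plant_one(g, m, cls)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          gene_id = g, mirna_id = mirna_id[m], site_class = cls, start = p
        )
      }
    }
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(gene_id = character(), mirna_id = character(),
                   site_class = character(), start = integer())

  mirnas <- tibble::tibble(mirna_id = mirna_id, sequence = mirna_seq)
  sites <- scan_seed_sites(utrs, mirnas)
  # independent Bernoulli conservation flags per (site, species)
  if (nrow(sites) > 0) {
    flags <- matrix(rbinom(nrow(sites) * length(species), 1,
                           conservation_rate) == 1,
                    nrow = nrow(sites))
    sites$conserved_in <- apply(flags, 1, function(f) {
      paste(species[f], collapse = ",")
    })
  } else {
    sites$conserved_in <- character()
  }
  list(
    utrs = utrs, mirnas = mirnas, sites = sites,
    utr_lengths = tibble::tibble(gene_id = gene_id, utr_length = utr_len),
    truth = truth
  )
}

#' Simulate mRNA counts with planted miRNA-driven repression
#'
#' Each target gene's mean in every non-wild-type condition is shifted by the
#' sum over its targeting miRNAs of `effect_log2 * activity_log2` (log2
#' units), emulating the inverse miRNA-target expression relationship; noise
#' is negative binomial as in [simulate_mirna_counts()].
#'
#' @param design A [sim_design()]; `design$n_features` genes named `gene-i`
#'   unless `gene_ids` is given.
#' @param target_map Tibble (`gene_id`, `mirna_id`, `effect_log2` <= 0).
#' @param mirna_activity Tibble (`mirna_id`, `activity_log2`); applied in all
#'   non-wild-type genotypes, or per genotype when a `genotype` column is
#'   present.
#' @param gene_ids Optional explicit gene universe.
#' @return List of `counts`, `meta`, `truth` (per-gene, per-genotype planted
#'   log2 shifts).
#' @export
simulate_mrna_counts <- function(design, target_map, mirna_activity,
                                 gene_ids = NULL) {
  set.seed(design$seed + 1L)
  gene_ids <- gene_ids %||% paste0("gene-", seq_len(design$n_features))
  if (nrow(target_map) > 0 && !all(target_map$gene_id %in% gene_ids)) {
    missing <- setdiff(target_map$gene_id, gene_ids)
    abort(paste0("target_map genes absent from universe: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (nrow(mirna_activity) > 0 && !all(is.finite(mirna_activity$activity_log2))) {
    abort("miRNA activities must be finite.")
  }
  ng <- length(design$genotypes)
  shift <- matrix(0, length(gene_ids), ng,
                  dimnames = list(gene_ids, design$genotypes))
  mutants <- setdiff(design$genotypes, design$wild_type)
  if (nrow(target_map) > 0 && nrow(mirna_activity) > 0) {
    per_geno <- "genotype" %in% names(mirna_activity)
    acts <- if (per_geno) mirna_activity else
      tidyr::expand_grid(mirna_activity, genotype = mutants)
    joined <- dplyr::inner_join(target_map, acts, by = "mirna_id",
                                relationship = "many-to-many") |>
      dplyr::mutate(delta = .data$effect_log2 * .data$activity_log2) |>
      dplyr::summarise(delta = sum(.data$delta),
                       .by = c("gene_id", "genotype"))
    shift[cbind(joined$gene_id, joined$genotype)] <- joined$delta
  }
  base <- exp(runif(length(gene_ids), log(design$base_mean_range[1]),
                    log(design$base_mean_range[2])))
  meta <- design_meta(design, prefix = "rna")
  mu <- base * 2^shift[, meta$condition, drop = FALSE]
  colnames(mu) <- meta$sample
  counts <- values_to_counts(nb_draw(mu, design$dispersion))
  list(
    counts = counts, meta = meta,
    truth = list(shift = shift, base_mean = setNames(base, gene_ids))
  )
}

#' Simulate a paired steady-state / nascent-transcription count pair
#'
#' Two-condition design. Genes labelled `post_transcriptional` shift (by
#' `effect_log2`) in the steady-state matrix only; `transcriptional` genes
#' shift in both; `unregulated` genes shift in neither. This is the ground
#' truth the joint steady/nascent classifier is asked to recover.
#'
#' @param design A two-genotype [sim_design()] (wild-type = control).
#' @param posttx_labels Tibble (`gene_id`, `label`), labels in
#'   `post_transcriptional`, `transcriptional`, `unregulated`; an optional
#'   `sign` column (+1/-1, default +1) sets each gene's shift direction, so
#'   regulated genes can move in both directions as they do after a real
#'   perturbation (keeping library-size normalization unbiased).
#' @param effect_log2 Planted log2 shift magnitude in the treated condition.
#' @return List of `steady`, `nascent` (each `counts` + shared `meta`) and
#'   `truth`.
#' @export
simulate_rna_chro_pair <- function(design, posttx_labels, effect_log2 = 1) {
  if (length(design$genotypes) != 2) {
    abort("`design` must have exactly two conditions (control, treated).")
  }
  ok <- c("post_transcriptional", "transcriptional", "unregulated")
  if (!all(posttx_labels$label %in% ok)) {
    abort(paste0("Unknown regulation label: ",
                 paste(setdiff(unique(posttx_labels$label), ok), collapse = ", ")))
  }
  set.seed(design$seed)
  gene_ids <- posttx_labels$gene_id
  treated <- setdiff(design$genotypes, design$wild_type)
  base <- exp(runif(length(gene_ids), log(design$base_mean_range[1]),
                    log(design$base_mean_range[2])))
  meta <- design_meta(design, prefix = "pair")
  sgn <- if ("sign" %in% names(posttx_labels)) posttx_labels$sign else
    rep(1, nrow(posttx_labels))
  one_matrix <- function(shifted_labels) {
    shift <- ifelse(posttx_labels$label %in% shifted_labels,
                    effect_log2 * sgn, 0)
    mu <- outer(base, rep(1, nrow(meta)))
    mu[, meta$condition == treated] <- mu[, meta$condition == treated] *
      2^shift
    dimnames(mu) <- list(gene_ids, meta$sample)
    values_to_counts(nb_draw(mu, design$dispersion))
  }
  steady <- one_matrix(c("post_transcriptional", "transcriptional"))
  nascent <- one_matrix("transcriptional")
  list(steady = steady, nascent = nascent, meta = meta,
       truth = posttx_labels)
}

#' Simulate a tumor mutation / copy-number event table
#'
#' Independent Bernoulli draws per tumor, gene and event class; copy-number
#' gain and loss are mutually exclusive per tumor-gene (conflicting draws are
#' redrawn).
#'
#' @param n_tumors Number of tumors (> 0).
#' @param per_gene_rates Tibble (`gene`, `p_mutation`, `p_gain`, `p_loss`),
#'   probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @return Tibble (`tumor_id`, `gene`, `event`) with event in
#'   `nonsynonymous`, `cnv_gain`, `cnv_loss`.
#' @export
simulate_mutation_table <- function(n_tumors, per_gene_rates, seed = 1) {
  if (n_tumors <= 0) abort("`n_tumors` must be > 0.")
  pr <- as.matrix(per_gene_rates[c("p_mutation", "p_gain", "p_loss")])
  if (any(pr < 0 | pr > 1)) abort("Rates must lie in [0, 1].")
  set.seed(seed)
  grid <- tidyr::expand_grid(tumor_id = paste0("tumor-", seq_len(n_tumors)),
                             gene = per_gene_rates$gene) |>
    dplyr::left_join(per_gene_rates, by = "gene")
  mut <- rbinom(nrow(grid), 1, grid$p_mutation) == 1
  gain <- rbinom(nrow(grid), 1, grid$p_gain) == 1
  loss <- rbinom(nrow(grid), 1, grid$p_loss) == 1
  conflict <- which(gain & loss)
  while (length(conflict) > 0) {
    gain[conflict] <- rbinom(length(conflict), 1, grid$p_gain[conflict]) == 1
    loss[conflict] <- rbinom(length(conflict), 1, grid$p_loss[conflict]) == 1
    conflict <- which(gain & loss)
  }
  dplyr::bind_rows(
    grid[mut, c("tumor_id", "gene")] |> dplyr::mutate(event = "nonsynonymous"),
    grid[gain, c("tumor_id", "gene")] |> dplyr::mutate(event = "cnv_gain"),
    grid[loss, c("tumor_id", "gene")] |> dplyr::mutate(event = "cnv_loss")
  ) |>
    dplyr::arrange(.data$tumor_id, .data$gene, .data$event)
}

#' Write simulated UTRs to FASTA
#'
#' @param utrs Named character vector of RNA sequences.
#' @param path Output path.
#' @export
write_utr_fasta <- function(utrs, path) {
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(utrs), path)
  invisible(path)
}
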