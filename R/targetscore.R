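SEED_SPECIES <- c("mouse", "human", "rat", "dog", "chicken")
SITE_CLASSES <- c("8mer", "7mer-m8", "7mer-1A")
SITE_WEIGHTS <- c("8mer" = 3, "7mer-m8" = 2, "7mer-1A" = 1)

rna_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

# the three canonical site strings (5'->3' on the UTR) for one miRNA
site_sequences <- function(mirna_sequence) {
  rc7 <- rna_revcomp(substr(mirna_sequence, 2, 8))   # pairs miRNA 2-8
  list(
    "8mer" = paste0(rc7, "A"),                        # 2-8 match + A opposite 1
    "7mer-m8" = rc7,
    "7mer-1A" = paste0(substr(rc7, 2, 7), "A")        # 2-7 match + A
  )
}

check_rna <- function(x, what) {
  bad <- regexpr("[^ACGU]", x)
  if (bad > 0) {
    abort(sprintf("Non-ACGU symbol in %s at position %d.", what, bad))
  }
  x
}

# all (possibly overlapping) start positions of `pat` in the char vector
match_positions <- function(chars, pat) {
  k <- nchar(pat)
  n <- length(chars)
  if (n < k) return(integer())
  pc <- strsplit(pat, "")[[1]]
  idx <- seq_len(n - k + 1L)
  hit <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) hit <- hit & chars[idx + j - 1L] == pc[j]
  which(hit)
}

#' Scan a 3'UTR for canonical miRNA seed-match sites
#'
#' Finds 8mer (Watson-Crick match to miRNA positions 2-8 followed by an A
#' opposite position 1), 7mer-m8 (match to 2-8 without the A) and 7mer-1A
#' (match to 2-7 plus the A) sites. Overlapping candidates at one locus
#' collapse to the single best class (8mer > 7mer-m8 > 7mer-1A). Positions
#' are 1-based on the UTR sense strand.
#'
#' @param utr_sequence RNA string (ACGU).
#' @param mirna_sequence Mature miRNA RNA string, at least 8 nt.
#' @return Tibble with `start`, `site_class`, ordered by position.
#' @export
find_seed_sites <- function(utr_sequence, mirna_sequence) {
  utr_sequence <- toupper(utr_sequence)
  mirna_sequence <- toupper(mirna_sequence)
  check_rna(utr_sequence, "UTR")
  check_rna(mirna_sequence, "miRNA")
  if (nchar(mirna_sequence) < 8) abort("miRNA must be at least 8 nt.")
  chars <- strsplit(utr_sequence, "")[[1]]
  s <- site_sequences(mirna_sequence)
  p8 <- match_positions(chars, s[["8mer"]])
  p7 <- match_positions(chars, s[["7mer-m8"]])
  p1a <- match_positions(chars, s[["7mer-1A"]])
  out <- dplyr::bind_rows(
    tibble::tibble(start = p8, site_class = "8mer"),
    tibble::tibble(start = setdiff(p7, p8), site_class = "7mer-m8"),
    tibble::tibble(start = setdiff(p1a, union(p8 + 1L, p7)),
                   site_class = "7mer-1A")
  )
  dplyr::arrange(out, .data$start)
}

#' Scan many UTRs against many miRNAs
#'
#' Batch version of [find_seed_sites()]: each UTR is tokenised once and
#' scanned against every miRNA's three site strings.
#'
#' @param utrs Named character vector of UTR RNA sequences.
#' @param mirnas Tibble with `mirna_id` and `sequence`.
#' @return Site table tibble: `gene_id`, `mirna_id`, `site_class`, `start`.
#' @export
scan_seed_sites <- function(utrs, mirnas) {
  site_strs <- lapply(toupper(mirnas$sequence), function(s) {
    check_rna(s, "miRNA")
    site_sequences(s)
  })
  acc_g <- acc_m <- acc_c <- list()
  acc_p <- list()
  k <- 1L
  for (g in names(utrs)) {
    u <- toupper(utrs[[g]])
    check_rna(u, "UTR")
    chars <- strsplit(u, "")[[1]]
    for (i in seq_along(site_strs)) {
      s <- site_strs[[i]]
      p8 <- match_positions(chars, s[["8mer"]])
      p7 <- match_positions(chars, s[["7mer-m8"]])
      p1a <- match_positions(chars, s[["7mer-1A"]])
      p7 <- setdiff(p7, p8)
      p1a <- setdiff(p1a, union(p8 + 1L, union(p8, p7)))
      n <- length(p8) + length(p7) + length(p1a)
      if (n == 0) next
      acc_g[[k]] <- rep(g, n)
      acc_m[[k]] <- rep(mirnas$mirna_id[i], n)
      acc_c[[k]] <- rep(c("8mer", "7mer-m8", "7mer-1A"),
                        c(length(p8), length(p7), length(p1a)))
      acc_p[[k]] <- c(p8, p7, p1a)
      k <- k + 1L
    }
  }
  out <- tibble::tibble(
    gene_id = unlist(acc_g) %||% character(),
    mirna_id = unlist(acc_m) %||% character(),
    site_class = unlist(acc_c) %||% character(),
    start = as.integer(unlist(acc_p) %||% integer())
  )
  dplyr::arrange(out, .data$gene_id, .data$mirna_id, .data$start)
}

#' Filter sites by species conservation
#'
#' `cons1` (model-organism arm) keeps sites conserved in mouse and at least
#' one of human, rat, dog, chicken. `cons2` (human tumor arm) keeps sites
#' conserved in human and at least two of mouse, rat, dog, chicken.
#'
#' @param sites Site table with a `conserved_in` column (comma-joined species
#'   names, or a list-column of character vectors).
#' @param mode `"cons1"` or `"cons2"`.
#' @return The filtered site table.
#' @export
conservation_filter <- function(sites, mode = c("cons1", "cons2")) {
  if (!mode[1] %in% c("cons1", "cons2")) {
    abort(paste0("Unknown conservation mode: ", mode[1]))
  }
  mode <- mode[1]
  sets <- if (is.list(sites$conserved_in)) sites$conserved_in else
    strsplit(sites$conserved_in, ",", fixed = TRUE)
  keep <- vapply(sets, function(sp) {
    sp <- trimws(sp)
    if (mode == "cons1") {
      "mouse" %in% sp &&
        length(intersect(sp, c("human", "rat", "dog", "chicken"))) >= 1
    } else {
      "human" %in% sp &&
        length(intersect(sp, c("mouse", "rat", "dog", "chicken"))) >= 2
    }
  }, TRUE)
  sites[keep, , drop = FALSE]
}

#' Build a target index from a site table
#'
#' Bundles (conservation-filtered) sites, per-gene UTR lengths and the gene
#' universe, and fixes the reference length (median UTR length over the
#' universe) used by the length-controlled gene score.
#'
#' @param sites Site table (`gene_id`, `mirna_id`, `site_class`, ...).
#' @param utr_lengths Tibble (`gene_id`, `utr_length`).
#' @param universe Optional gene universe; defaults to all genes in
#'   `utr_lengths`.
#' @return A `target_index` object.
#' @export
build_target_index <- function(sites, utr_lengths, universe = NULL) {
  universe <- universe %||% utr_lengths$gene_id
  if (!all(universe %in% utr_lengths$gene_id)) {
    abort("Every universe gene needs a UTR length.")
  }
  if (any(utr_lengths$utr_length <= 0)) abort("UTR lengths must be > 0.")
  lens <- setNames(utr_lengths$utr_length, utr_lengths$gene_id)
  structure(
    list(
      sites = sites[sites$gene_id %in% universe, , drop = FALSE],
      utr_lengths = lens[universe],
      universe = universe,
      reference_length = median(lens[universe]),
      mirna_ids = sort(unique(sites$mirna_id))
    ),
    class = "target_index"
  )
}

#' @export
print.target_index <- function(x, ...) {
  cat(sprintf("<target_index> %d genes, %d miRNAs, %d sites (reference UTR %.0f nt)\n",
              length(x$universe), length(x$mirna_ids), nrow(x$sites),
              x$reference_length))
  invisible(x)
}

#' Length-controlled gene targeting score
#'
#' Weighted site count (8mer = 3, 7mer-m8 = 2, 7mer-1A = 1) scaled by
#' `reference_length / utr_length`, so long UTRs are not rewarded for chance
#' site accumulation.
#'
#' @param site_classes Character vector of site classes for one (gene, miRNA)
#'   pair (already conservation-filtered).
#' @param utr_length The gene's 3'UTR length (> 0).
#' @param reference_length Reference (median) UTR length.
#' @return Nonnegative score.
#' @export
gene_score <- function(site_classes, utr_length, reference_length) {
  if (utr_length <= 0) abort("`utr_length` must be > 0.")
  sum(SITE_WEIGHTS[site_classes]) * (reference_length / utr_length)
}

# genes x miRNAs matrix of gene scores over the whole universe
score_matrix <- function(index, mirnas = NULL) {
  mirnas <- mirnas %||% index$mirna_ids
  S <- matrix(0, length(index$universe), length(mirnas),
              dimnames = list(index$universe, mirnas))
  st <- index$sites[index$sites$mirna_id %in% mirnas, , drop = FALSE]
  if (nrow(st) > 0) {
    agg <- st |>
      dplyr::mutate(w = SITE_WEIGHTS[.data$site_class]) |>
      dplyr::summarise(w = sum(.data$w), .by = c("gene_id", "mirna_id"))
    S[cbind(agg$gene_id, agg$mirna_id)] <- agg$w
  }
  S * (index$reference_length / index$utr_lengths[index$universe])
}

#' Cumulative targeting score of a gene list
#'
#' Sum of [gene_score()] over the listed genes for one miRNA; genes with no
#' sites contribute zero. The list is a set: duplicates and genes outside the
#' universe are errors.
#'
#' @param gene_list Character vector of gene ids (subset of the universe).
#' @param mirna miRNA id.
#' @param index A [build_target_index()] object.
#' @return A single nonnegative number.
#' @export
cumulative_score <- function(gene_list, mirna, index) {
  if (anyDuplicated(gene_list)) {
    abort("Gene lists are sets; duplicated ids found.")
  }
  outside <- setdiff(gene_list, index$universe)
  if (length(outside) > 0) {
    abort(paste0("Genes outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  S <- score_matrix(index, mirna)
  sum(S[gene_list, 1])
}

#' Monte-Carlo target-site enrichment
#'
#' For each miRNA, compares the observed cumulative targeting score of the
#' input gene list against a null distribution built by repeatedly drawing
#' random gene lists of the same size from the universe, matched to the input
#' list's UTR-length composition by quintile. The empirical p-value uses the
#' +1-corrected estimator `(1 + #{null >= observed}) / (n_iterations + 1)`,
#' so it is never zero.
#'
#' @param gene_list Input gene list (subset of the universe).
#' @param index A [build_target_index()] object.
#' @param mirnas miRNA ids to score (default: all in the index).
#' @param n_iterations Number of null draws (>= 100; default 1000).
#' @param seed Integer seed (mandatory: the null is stochastic).
#' @return A `mirhub_result` tibble: `mirna_id`, `observed`, `null_mean`,
#'   `null_sd`, `empirical_p`, `n_iter`, `seed`; the null score matrix is
#'   attached as attribute `"null_scores"`.
#' @export
monte_carlo_enrichment <- function(gene_list, index, mirnas = NULL,
                                   n_iterations = 1000, seed) {
  if (n_iterations < 100) abort("`n_iterations` must be >= 100.")
  if (missing(seed)) abort("A `seed` is required for the Monte-Carlo null.")
  mirnas <- mirnas %||% index$mirna_ids
  if (anyDuplicated(gene_list)) abort("Gene lists are sets; duplicates found.")
  outside <- setdiff(gene_list, index$universe)
  if (length(outside) > 0) {
    abort(paste0("Genes outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  lens <- index$utr_lengths[index$universe]
  br <- unique(quantile(lens, probs = seq(0, 1, 0.2)))
  bin <- cut(lens, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bin) <- index$universe
  need <- table(bin[gene_list])
  have <- table(bin)
  short <- names(need)[need > have[names(need)]]
  if (length(short) > 0) {
    abort("A UTR-length quintile of the input list exceeds the universe's supply; consider unmatched sampling.")
  }
  by_bin <- split(index$universe, bin)
  S <- score_matrix(index, mirnas)
  observed <- colSums(S[gene_list, , drop = FALSE])
  set.seed(seed)
  null_scores <- matrix(0, n_iterations, length(mirnas),
                        dimnames = list(NULL, mirnas))
  for (it in seq_len(n_iterations)) {
    idx <- unlist(lapply(names(need), function(b) {
      pool <- by_bin[[b]]
      pool[sample.int(length(pool), need[[b]])]
    }), use.names = FALSE)
    null_scores[it, ] <- colSums(S[idx, , drop = FALSE])
  }
  emp_p <- (1 + colSums(null_scores >= rep(observed, each = n_iterations))) /
    (n_iterations + 1)
  out <- tibble::tibble(
    mirna_id = mirnas,
    observed = unname(observed),
    null_mean = unname(colMeans(null_scores)),
    null_sd = unname(apply(null_scores, 2, sd)),
    empirical_p = unname(emp_p),
    n_iter = n_iterations,
    seed = seed
  )
  attr(out, "null_scores") <- null_scores
  class(out) <- c("mirhub_result", class(out))
  out
}

#' @export
glance.mirhub_result <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_mirnas = nrow(x),
    n_significant = sum(x$empirical_p < alpha),
    n_iter = x$n_iter[1],
    alpha = alpha
  )
}

#' @export
autoplot.mirhub_result <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      neglog = -log10(.data$empirical_p),
                      significant = .data$empirical_p < alpha)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$mirna_id, .data$neglog),
    y = .data$neglog, fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p))),
                  title = "Target-site enrichment") +
    ggplot2::theme_minimal()
}

#' Recurrently enriched miRNAs across comparisons
#'
#' Keeps miRNAs whose empirical enrichment p-value falls below `alpha` in at
#' least `min_hits` of the comparisons.
#'
#' @param p_long Long tibble (`mirna_id`, `comparison`, `empirical_p`), e.g.
#'   bound rows of [monte_carlo_enrichment()] results.
#' @param alpha Significance cutoff per comparison.
#' @param min_hits Minimum number of significant comparisons.
#' @return Character vector of recurrent miRNA ids.
#' @export
recurrent_candidates <- function(p_long, alpha = 0.05, min_hits = 3) {
  n_comp <- length(unique(p_long$comparison))
  if (min_hits > n_comp) {
    abort("`min_hits` exceeds the number of comparisons.")
  }
  if (any(p_long$empirical_p <= 0 | p_long$empirical_p > 1)) {
    abort("Empirical p-values must lie in (0, 1].")
  }
  hits <- p_long |>
    dplyr::summarise(n_sig = sum(.data$empirical_p < alpha),
                     .by = "mirna_id") |>
    dplyr::filter(.data$n_sig >= min_hits)
  hits$mirna_id
}

#' Write site / enrichment tables
#'
#' @param sites Site table with `conserved_in`.
#' @param path Output path.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}

#' @rdname write_site_table
#' @param result A `mirhub_result`.
#' @export
write_enrichment <- function(result, path) {
  readr::write_tsv(tibble::as_tibble(result), path)
  invisible(path)
}
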