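#' Retain likelihood-ratio screen hits
#'
#' Keeps features with `padj < alpha` and `baseMean > min_basemean`, in the
#' input order. These are the features passed on to module clustering.
#'
#' @param lrt A `de_table` from [lrt_screen()].
#' @param min_basemean Minimum mean of normalized counts (default 500).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Character vector of feature ids.
#' @export
lrt_hit_filter <- function(lrt, min_basemean = 500, alpha = 0.05) {
  keep <- !is.na(lrt$padj) & lrt$padj < alpha & lrt$baseMean > min_basemean
  lrt$feature_id[keep]
}

#' Cluster features into expression modules across genotypes
#'
#' Each feature is z-scored across samples, summarised as a genotype-mean
#' profile, and clustered by average-linkage hierarchical clustering on
#' `1 - Pearson correlation` of profiles. The tree is cut at distance
#' `1 - cohesion`; clusters with at most `min_members` members are discarded
#' (so with the default 5, only modules of six or more features are
#' reported). Features are processed in id order, which fixes tie-breaking.
#'
#' @param corrected Wide tibble of batch-corrected, transformed values.
#' @param meta Sample metadata with the genotype column.
#' @param group_col Metadata column holding genotype labels.
#' @param min_members Modules must have strictly more members than this.
#' @param cohesion Correlation threshold at which the tree is cut.
#' @return A `module_assignment` object: list with `assignment` (tibble
#'   `feature_id`, `module`; unassigned features have `NA`), `profiles`
#'   (tibble `module`, `genotype`, `mean_z`) and the parameters used.
#' @export
cluster_modules <- function(corrected, meta, group_col = "condition",
                            min_members = 5, cohesion = 0.7) {
  meta <- meta[match(sample_names(corrected), meta$sample), , drop = FALSE]
  g <- meta[[group_col]]
  if (length(unique(g)) < 2) abort("Need at least two genotypes to cluster.")
  m <- as.matrix(corrected[setdiff(names(corrected), "feature_id")])
  rownames(m) <- corrected$feature_id
  m <- m[order(rownames(m)), , drop = FALSE]
  empty <- new_module_assignment(
    tibble::tibble(feature_id = rownames(m), module = NA_character_),
    tibble::tibble(module = character(), genotype = character(),
                   mean_z = double()),
    min_members, cohesion
  )
  if (nrow(m) < min_members + 1) {
    warn("Fewer features than the minimum module size; no modules reported.")
    return(empty)
  }
  z <- t(scale(t(m)))
  keep <- rowSums(!is.finite(z)) == 0
  if (!all(keep)) {
    warn(sprintf("%d constant feature(s) dropped before clustering.",
                 sum(!keep)))
  }
  z <- z[keep, , drop = FALSE]
  prof <- t(apply(z, 1, function(r) tapply(r, g, mean)))
  prof <- prof[, unique(g), drop = FALSE]
  pvar <- apply(prof, 1, var)
  usable <- pvar > 0
  prof <- prof[usable, , drop = FALSE]
  if (nrow(prof) < min_members + 1) {
    warn("Too few variable profiles; no modules reported.")
    return(empty)
  }
  d <- as.dist(1 - cor(t(prof)))
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, h = 1 - cohesion)
  sizes <- table(cl)
  keep_cl <- names(sizes)[sizes > min_members]
  module <- ifelse(as.character(cl) %in% keep_cl,
                   paste0("M", match(as.character(cl), keep_cl)),
                   NA_character_)
  names(module) <- rownames(prof)
  assignment <- tibble::tibble(
    feature_id = rownames(m),
    module = module[rownames(m)]
  )
  profiles <- tibble::as_tibble(prof, rownames = "feature_id") |>
    dplyr::inner_join(assignment, by = "feature_id") |>
    dplyr::filter(!is.na(.data$module)) |>
    tidyr::pivot_longer(-c("feature_id", "module"),
                        names_to = "genotype", values_to = "z") |>
    dplyr::summarise(mean_z = mean(.data$z), .by = c("module", "genotype"))
  new_module_assignment(assignment, profiles, min_members, cohesion)
}

new_module_assignment <- function(assignment, profiles, min_members,
                                  cohesion) {
  structure(
    list(assignment = assignment, profiles = profiles,
         min_members = min_members, cohesion = cohesion),
    class = "module_assignment"
  )
}

#' @export
print.module_assignment <- function(x, ...) {
  n_mod <- length(unique(stats::na.omit(x$assignment$module)))
  cat(sprintf("<module_assignment> %d features, %d modules (> %d members, cohesion %.2f)\n",
              nrow(x$assignment), n_mod, x$min_members, x$cohesion))
  invisible(x)
}

#' @export
tidy.module_assignment <- function(x, ...) x$assignment

#' @export
glance.module_assignment <- function(x, ...) {
  assigned <- !is.na(x$assignment$module)
  tibble::tibble(
    n_features = nrow(x$assignment),
    n_modules = length(unique(x$assignment$module[assigned])),
    n_assigned = sum(assigned),
    min_members = x$min_members,
    cohesion = x$cohesion
  )
}

#' @export
autoplot.module_assignment <- function(object, ...) {
  df <- object$profiles |>
    dplyr::mutate(genotype = factor(.data$genotype,
                                    levels = unique(.data$genotype)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$mean_z,
                                   group = .data$module)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~module) +
    ggplot2::labs(x = NULL, y = "mean z-score",
                  title = "Expression modules across genotypes") +
    ggplot2::theme_minimal()
}

#' Expression relative to wild-type, with display clipping
#'
#' Subtracts the per-feature mean of the wild-type samples from every sample,
#' and returns both the raw delta matrix and a copy clipped to
#' `[-clip, clip]` for heatmap display.
#'
#' @param corrected Wide tibble of transformed (batch-corrected) values.
#' @param meta Sample metadata.
#' @param wt_label Wild-type condition label.
#' @param clip Saturation bound for the display copy (default 3).
#' @param group_col Metadata column with condition labels.
#' @return List with `delta` (unclipped wide tibble) and `display` (clipped).
#' @export
delta_vs_wt <- function(corrected, meta, wt_label, clip = 3,
                        group_col = "condition") {
  meta <- meta[match(sample_names(corrected), meta$sample), , drop = FALSE]
  wt <- meta[[group_col]] == wt_label
  if (!any(wt)) abort(paste0("No samples labelled `", wt_label, "`."))
  m <- as.matrix(corrected[setdiff(names(corrected), "feature_id")])
  rownames(m) <- corrected$feature_id
  delta <- m - rowMeans(m[, wt, drop = FALSE])
  display <- pmin(pmax(delta, -clip), clip)
  list(delta = values_to_counts(delta), display = values_to_counts(display))
}

#' Heatmap-style tile plot of a relative-expression matrix
#'
#' @param display Clipped wide tibble from [delta_vs_wt()].
#' @param clip Saturation bound used (sets the fill limits).
#' @return A ggplot object.
#' @export
plot_delta_heatmap <- function(display, clip = 3) {
  df <- tidyr::pivot_longer(display, -"feature_id",
                            names_to = "sample", values_to = "delta")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$feature_id,
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-clip, clip),
                                  low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Δ vs WT") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
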