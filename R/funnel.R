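new_candidate_set <- function(df) {
  structure(df, class = c("candidate_set", class(tibble::tibble())))
}

#' Keep guide-strand miRNAs
#'
#' Restricts a miRNA id list to strands annotated as preferentially loaded
#' into the silencing complex (guide strands); unannotated ids are dropped
#' with a warning.
#'
#' @param mirna_ids Character vector of miRNA ids.
#' @param guide_annotation Tibble (`mirna_id`, `strand`) with strand in
#'   `guide` / `passenger`.
#' @return Filtered id vector.
#' @export
filter_guides <- function(mirna_ids, guide_annotation) {
  ann <- setNames(guide_annotation$strand, guide_annotation$mirna_id)
  unknown <- setdiff(mirna_ids, names(ann))
  if (length(unknown) > 0) {
    warn(paste0("Dropping unannotated miRNA ids: ",
                paste(head(unknown, 5), collapse = ", ")))
  }
  mirna_ids[!is.na(ann[mirna_ids]) & ann[mirna_ids] == "guide"]
}

#' Drop degradation-product annotations
#'
#' miRNA ids whose annotation number falls in the degradation-product block
#' (the 5000s by default) are removed; ids without a parseable number are
#' kept.
#'
#' @param mirna_ids Character vector.
#' @param id_number_threshold Start of the removed block (default 5000; the
#'   block spans `[threshold, threshold + 1000)`).
#' @return Filtered id vector.
#' @export
drop_degradation_ids <- function(mirna_ids, id_number_threshold = 5000) {
  num <- suppressWarnings(as.integer(
    stringr::str_match(mirna_ids, stringr::regex("mir-?([0-9]+)",
                                                 ignore_case = TRUE))[, 2]
  ))
  drop <- !is.na(num) & num >= id_number_threshold &
    num < id_number_threshold + 1000
  mirna_ids[!drop]
}

#' Select differentially expressed candidates
#'
#' Thresholds a DE table on adjusted p, linear fold change (strict) and mean
#' expression; direction is the sign of the fold change.
#'
#' @param de A `de_table`.
#' @param min_basemean Minimum `baseMean`.
#' @param min_fold Minimum linear fold change (> 1; strict inequality).
#' @param alpha Adjusted-p cutoff.
#' @return A `candidate_set` tibble (`mirna_id`, `direction`, `provenance`).
#' @export
select_de <- function(de, min_basemean = 500, min_fold = 1.5, alpha = 0.05) {
  if (min_fold < 1) abort("`min_fold` must be >= 1.")
  keep <- !is.na(de$padj) & de$padj < alpha &
    abs(de$log2fc) > log2(min_fold) & de$baseMean > min_basemean
  new_candidate_set(tibble::tibble(
    mirna_id = de$feature_id[keep],
    direction = ifelse(de$log2fc[keep] > 0, "up", "down"),
    provenance = sprintf("de(padj<%g, fold>%g, baseMean>%g)",
                         alpha, min_fold, min_basemean)
  ))
}

#' Features changing consistently across all comparisons
#'
#' Keeps features whose fold change exceeds `min_fold` with the same sign in
#' every supplied DE table.
#'
#' @param de_tables Named list of `de_table`s over the same feature universe.
#' @param min_fold Minimum linear fold change (strict).
#' @return A `candidate_set`.
#' @export
consistent_direction <- function(de_tables, min_fold = 1.5) {
  universes <- purrr::map(de_tables, ~ sort(.x$feature_id))
  if (!all(purrr::map_lgl(universes, identical, universes[[1]]))) {
    abort("DE tables must share one feature universe.")
  }
  lfc <- purrr::map(de_tables, ~ setNames(.x$log2fc, .x$feature_id))
  ids <- universes[[1]]
  L <- do.call(cbind, purrr::map(lfc, ~ .x[ids]))
  pass <- rowSums(abs(L) > log2(min_fold), na.rm = FALSE) == ncol(L) &
    (rowSums(L > 0) == ncol(L) | rowSums(L < 0) == ncol(L))
  pass[is.na(pass)] <- FALSE
  new_candidate_set(tibble::tibble(
    mirna_id = ids[pass],
    direction = unname(ifelse(rowMeans(L)[pass] > 0, "up", "down")),
    provenance = sprintf("consistent(%d comparisons, fold>%g)",
                         ncol(L), min_fold)
  ))
}

#' Reads per million miRNA-mapped reads
#'
#' Scales each sample of a miRNA count matrix to a library size of one
#' million, the expression unit used for the tumor arm.
#'
#' @param counts Wide miRNA count tibble.
#' @return Wide tibble of RPMMM values; each sample column sums to 1e6.
#' @export
rpmmm <- function(counts) {
  m <- count_values(validate_counts(counts))
  tot <- colSums(m)
  if (any(tot == 0)) abort("A sample has zero miRNA-mapped reads.")
  values_to_counts(sweep(m, 2, tot, "/") * 1e6)
}

#' Expression filter for the tumor arm
#'
#' Keeps miRNAs whose mean RPMMM reaches `min_avg` in the tumor condition or
#' in the normal condition (either suffices).
#'
#' @param rpmmm_tbl Wide RPMMM tibble.
#' @param meta Sample metadata with the condition column (labels must include
#'   `tumor_label` and `normal_label`).
#' @param min_avg Minimum mean RPMMM (default 1000).
#' @param tumor_label,normal_label Condition labels.
#' @param group_col Metadata column name.
#' @return Character vector of retained miRNA ids.
#' @export
tcga_expression_filter <- function(rpmmm_tbl, meta, min_avg = 1000,
                                   tumor_label = "tumor",
                                   normal_label = "normal",
                                   group_col = "condition") {
  meta <- meta[match(sample_names(rpmmm_tbl), meta$sample), , drop = FALSE]
  g <- meta[[group_col]]
  for (lab in c(tumor_label, normal_label)) {
    if (!lab %in% g) abort(paste0("Condition `", lab, "` missing."))
  }
  m <- as.matrix(rpmmm_tbl[setdiff(names(rpmmm_tbl), "feature_id")])
  mt <- rowMeans(m[, g == tumor_label, drop = FALSE])
  mn <- rowMeans(m[, g == normal_label, drop = FALSE])
  rpmmm_tbl$feature_id[mt >= min_avg | mn >= min_avg]
}

#' Confirm candidates in matched tumor/normal pairs
#'
#' Runs a two-sided paired test on `log2(RPMMM + 1)` differences across
#' matched pairs and retains candidates that are significant with a direction
#' matching the candidate's.
#'
#' @param rpmmm_tbl Wide RPMMM tibble covering the matched samples.
#' @param meta Metadata with `pair_id` and the condition column.
#' @param candidates A `candidate_set`.
#' @param alpha Significance cutoff.
#' @param tumor_label,normal_label,group_col As in
#'   [tcga_expression_filter()].
#' @return The confirmed `candidate_set`.
#' @export
matched_confirmation <- function(rpmmm_tbl, meta, candidates, alpha = 0.05,
                                 tumor_label = "tumor",
                                 normal_label = "normal",
                                 group_col = "condition") {
  meta <- meta[match(sample_names(rpmmm_tbl), meta$sample), , drop = FALSE]
  pairs <- split(seq_len(nrow(meta)), meta$pair_id)
  ok <- vapply(pairs, function(ix) {
    length(ix) == 2 && setequal(meta[[group_col]][ix],
                                c(tumor_label, normal_label))
  }, TRUE)
  if (!all(ok)) abort("Every pair needs exactly one tumor and one normal sample.")
  if (length(pairs) < 2) abort("At least two matched pairs are required.")
  m <- as.matrix(rpmmm_tbl[setdiff(names(rpmmm_tbl), "feature_id")])
  rownames(m) <- rpmmm_tbl$feature_id
  lg <- log2(m + 1)
  t_ix <- vapply(pairs, function(ix) ix[meta[[group_col]][ix] == tumor_label], 1L)
  n_ix <- vapply(pairs, function(ix) ix[meta[[group_col]][ix] == normal_label], 1L)
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    id <- candidates$mirna_id[i]
    if (!id %in% rownames(m)) return(FALSE)
    d <- lg[id, t_ix] - lg[id, n_ix]
    tt <- tryCatch(t.test(d), error = function(e) NULL)
    if (is.null(tt) || is.na(tt$p.value)) return(FALSE)
    dir_ok <- (mean(d) > 0) == (candidates$direction[i] == "up")
    tt$p.value < alpha && dir_ok
  }, TRUE)
  out <- candidates[keep, , drop = FALSE]
  out$provenance <- paste0(out$provenance, " + matched")
  new_candidate_set(out)
}

#' Collapse paralogs into miRNA families
#'
#' Groups candidate miRNAs that share a family; members with discordant
#' directions are excluded and flagged.
#'
#' @param candidates A `candidate_set`.
#' @param family_map Tibble (`mirna_id`, `family`).
#' @return A `candidate_set` over families (column `family`), with excluded
#'   discordant families in attribute `"discordant"`.
#' @export
collapse_paralogs <- function(candidates, family_map) {
  fam <- setNames(family_map$family, family_map$mirna_id)
  unmapped <- setdiff(candidates$mirna_id, names(fam))
  if (length(unmapped) > 0) {
    warn(paste0("No family for: ", paste(head(unmapped, 5), collapse = ", "),
                "; treating each as its own family."))
  }
  df <- dplyr::mutate(tibble::as_tibble(candidates),
                      family = unname(dplyr::coalesce(fam[.data$mirna_id],
                                                      .data$mirna_id)))
  agg <- df |>
    dplyr::summarise(
      n_dirs = length(unique(.data$direction)),
      direction = .data$direction[1],
      provenance = paste(unique(.data$provenance), collapse = "; "),
      .by = "family"
    )
  discordant <- agg$family[agg$n_dirs > 1]
  out <- new_candidate_set(
    agg[agg$n_dirs == 1, c("family", "direction", "provenance")]
  )
  attr(out, "discordant") <- discordant
  out
}

#' Intersect family-collapsed candidate sets
#'
#' Families present in both arms with the same direction.
#'
#' @param mouse,human Family-collapsed `candidate_set`s.
#' @return A `candidate_set` of shared families.
#' @export
intersect_candidates <- function(mouse, human) {
  j <- dplyr::inner_join(
    tibble::as_tibble(mouse), tibble::as_tibble(human),
    by = c("family", "direction"), suffix = c("_mouse", "_human")
  )
  new_candidate_set(tibble::tibble(
    family = j$family, direction = j$direction,
    provenance = paste(j$provenance_mouse, j$provenance_human, sep = " & ")
  ))
}

#' Pan-cancer tumor/normal summary for one miRNA
#'
#' Per tumor type: log2 ratio of geometric means (RPMMM + 1) of tumor vs
#' normal, a two-sided Welch test on `log2(RPMMM + 1)`, BH adjustment across
#' types, and the geometric mean tumor RPMMM as a size statistic. Types
#' missing a condition are skipped with a warning.
#'
#' @param rpmmm_tbl Wide RPMMM tibble (one miRNA row suffices).
#' @param meta Metadata with `tumor_type` and the condition column.
#' @param mirna miRNA id to summarise.
#' @param alpha Significance cutoff for the flag.
#' @param tumor_label,normal_label,group_col Condition labels.
#' @return Tibble: `tumor_type`, `log2fc`, `pvalue`, `padj`, `significant`,
#'   `geomean_tumor`, `n_tumor`, `n_normal`.
#' @export
pan_cancer_summary <- function(rpmmm_tbl, meta, mirna, alpha = 0.05,
                               tumor_label = "tumor", normal_label = "normal",
                               group_col = "condition") {
  meta <- meta[match(sample_names(rpmmm_tbl), meta$sample), , drop = FALSE]
  m <- as.matrix(rpmmm_tbl[setdiff(names(rpmmm_tbl), "feature_id")])
  rownames(m) <- rpmmm_tbl$feature_id
  if (!mirna %in% rownames(m)) abort(paste0("Unknown miRNA: ", mirna))
  x <- m[mirna, ]
  geo <- function(v) exp(mean(log(v + 1)))
  rows <- purrr::map_dfr(unique(meta$tumor_type), function(tt) {
    sel <- meta$tumor_type == tt
    g <- meta[[group_col]][sel]
    if (!all(c(tumor_label, normal_label) %in% g)) {
      warn(paste0("Tumor type `", tt, "` lacks a condition; skipped."))
      return(NULL)
    }
    xt <- x[sel][g == tumor_label]
    xn <- x[sel][g == normal_label]
    p <- tryCatch(t.test(log2(xt + 1), log2(xn + 1))$p.value,
                  error = function(e) NA_real_)
    tibble::tibble(
      tumor_type = tt,
      log2fc = log2(geo(xt) / geo(xn)),
      pvalue = p,
      geomean_tumor = geo(xt) - 1,
      n_tumor = length(xt), n_normal = length(xn)
    )
  })
  rows$padj <- bh_adjust(rows$pvalue)
  rows$significant <- !is.na(rows$padj) & rows$padj < alpha
  rows[c("tumor_type", "log2fc", "pvalue", "padj", "significant",
         "geomean_tumor", "n_tumor", "n_normal")]
}

GENOTYPE_GENES <- tibble::tibble(
  gene = c("APC", "TP53", "SMAD4", "CTNNB1", "KRAS"),
  label = c("A", "P", "S", "B", "K"),
  class = c("loss", "loss", "loss", "gain", "gain")
)

#' Bin tumors into driver genotypes from mutation/CNV events
#'
#' Loss-class genes (APC, TP53, SMAD4) are assigned when a tumor carries a
#' non-synonymous mutation and/or a copy-number loss, unless it carries both
#' a copy-number gain and a non-synonymous mutation. Gain-class genes
#' (CTNNB1, KRAS) mirror this: non-synonymous and/or gain assigns, except
#' loss plus non-synonymous excludes. Unknown gene symbols are ignored with a
#' warning.
#'
#' @param mutations Tibble (`tumor_id`, `gene`, `event`) with event in
#'   `nonsynonymous`, `cnv_gain`, `cnv_loss`.
#' @param min_bin_n Bins smaller than this are flagged low-n in the summary
#'   attribute.
#' @return Tibble (`tumor_id`, `labels`) where `labels` concatenates assigned
#'   letters (e.g. `"AKP"`); per-label counts with low-n flags in attribute
#'   `"bin_sizes"`.
#' @export
assign_genotypes <- function(mutations, min_bin_n = 4) {
  unknown <- setdiff(unique(mutations$gene), GENOTYPE_GENES$gene)
  if (length(unknown) > 0) {
    warn(paste0("Ignoring unrecognised genes: ",
                paste(unknown, collapse = ", ")))
  }
  ev <- mutations |>
    dplyr::filter(.data$gene %in% GENOTYPE_GENES$gene) |>
    dplyr::distinct(.data$tumor_id, .data$gene, .data$event) |>
    dplyr::mutate(flag = TRUE) |>
    tidyr::pivot_wider(names_from = "event", values_from = "flag",
                       values_fill = FALSE)
  for (col in c("nonsynonymous", "cnv_gain", "cnv_loss")) {
    if (!col %in% names(ev)) ev[[col]] <- FALSE
  }
  ev <- dplyr::left_join(ev, GENOTYPE_GENES, by = "gene") |>
    dplyr::mutate(assigned = dplyr::if_else(
      .data$class == "loss",
      (.data$nonsynonymous | .data$cnv_loss) &
        !(.data$cnv_gain & .data$nonsynonymous),
      (.data$nonsynonymous | .data$cnv_gain) &
        !(.data$cnv_loss & .data$nonsynonymous)
    ))
  out <- ev |>
    dplyr::filter(.data$assigned) |>
    dplyr::summarise(
      labels = paste(sort(.data$label), collapse = ""),
      .by = "tumor_id"
    )
  all_tumors <- unique(mutations$tumor_id)
  out <- dplyr::left_join(tibble::tibble(tumor_id = all_tumors), out,
                          by = "tumor_id") |>
    dplyr::mutate(labels = dplyr::coalesce(.data$labels, ""))
  sizes <- ev |>
    dplyr::filter(.data$assigned) |>
    dplyr::count(.data$label, name = "n") |>
    dplyr::mutate(low_n = .data$n < min_bin_n)
  attr(out, "bin_sizes") <- sizes
  out
}

#' Write a candidate set
#'
#' @param candidates A `candidate_set`.
#' @param path Output path (tab-delimited).
#' @export
write_candidates <- function(candidates, path) {
  readr::write_tsv(tibble::as_tibble(candidates), path)
  invisible(path)
}
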