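#' Gene-body windows excluding the promoter-proximal pause region
#'
#' Builds per-gene counting windows from gene models: genes shorter than
#' `min_gene_length` are dropped (the length filter applies to the annotated
#' gene, before shrinking), and the first `tss_offset` bases downstream of
#' the transcription start site are excluded on the correct strand (start
#' shifted on `+`, end shifted on `-`). Coordinates are 0-based, half-open,
#' as in BED.
#'
#' @param genes Tibble of BED-like gene models: `chrom`, `start`, `end`,
#'   `gene_id`, `strand` (a `score` column is ignored).
#' @param tss_offset Bases to exclude downstream of the TSS (default 500).
#' @param min_gene_length Minimum annotated gene length (default 1000).
#' @return A `gene_body_windows` tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
gene_body_windows <- function(genes, tss_offset = 500, min_gene_length = 1000) {
  if (inherits(genes, "gene_body_windows")) {
    abort("Input is already a window table; refusing to offset twice.")
  }
  if (!"strand" %in% names(genes) || any(!genes$strand %in% c("+", "-"))) {
    abort("Every gene model needs a strand of '+' or '-'.")
  }
  if (any(genes$end <= genes$start)) abort("Gene intervals must have end > start.")
  g <- genes[genes$end - genes$start >= min_gene_length, , drop = FALSE]
  win <- tibble::tibble(
    gene_id = g$gene_id,
    chrom = g$chrom,
    start = ifelse(g$strand == "+", g$start + tss_offset, g$start),
    end = ifelse(g$strand == "+", g$end, g$end - tss_offset),
    strand = g$strand
  )
  bad <- win$end <= win$start
  if (any(bad)) {
    warn(sprintf("%d window(s) collapsed to nonpositive length; dropped.",
                 sum(bad)))
    win <- win[!bad, , drop = FALSE]
  }
  structure(win, class = c("gene_body_windows", class(tibble::tibble())))
}

#' Read a 6-column BED file of gene models
#'
#' @param path BED path (0-based, half-open; strand in column 6).
#' @return Tibble `chrom`, `start`, `end`, `gene_id`, `score`, `strand`.
#' @export
read_gene_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "gene_id", "score",
                                "strand"),
                  col_types = "ciicic", comment = "#")
}

#' Count read 5' ends in gene-body windows
#'
#' A read counts toward a window when its (0-based) position lies in
#' `[start, end)` on the matching strand; reads in no window are ignored.
#'
#' @param reads Tibble of read 5'-end positions: `chrom`, `position`,
#'   `strand`.
#' @param windows A [gene_body_windows()] table.
#' @return Tibble (`gene_id`, `count`), one row per window.
#' @export
count_in_windows <- function(reads, windows) {
  counts <- vapply(seq_len(nrow(windows)), function(i) {
    sum(reads$chrom == windows$chrom[i] &
          reads$strand == windows$strand[i] &
          reads$position >= windows$start[i] &
          reads$position < windows$end[i])
  }, 1L)
  tibble::tibble(gene_id = windows$gene_id, count = counts)
}

#' Classify post-transcriptional versus transcriptional regulation
#'
#' Joint decision rule over a steady-state (RNA-seq) and a nascent
#' (run-on) DE table: a gene significant in steady state but not in nascent
#' transcription is called `post_transcriptional`; significant in both with
#' the same sign, `transcriptional`; in both with opposite signs,
#' `both_discordant`; otherwise `unchanged`. Genes present in only one table
#' are reported `unclassifiable`.
#'
#' @param steady,nascent `de_table`s over a shared gene universe.
#' @param alpha_steady,alpha_nascent Adjusted-p cutoffs (defaults 0.05).
#' @return A `regulation_calls` tibble: `gene_id`, `label`, `steady_log2fc`,
#'   `steady_padj`, `nascent_log2fc`, `nascent_padj`.
#' @export
classify_regulation <- function(steady, nascent, alpha_steady = 0.05,
                                alpha_nascent = 0.05) {
  j <- dplyr::full_join(
    dplyr::select(tibble::as_tibble(steady), "feature_id",
                  steady_log2fc = "log2fc", steady_padj = "padj"),
    dplyr::select(tibble::as_tibble(nascent), "feature_id",
                  nascent_log2fc = "log2fc", nascent_padj = "padj"),
    by = "feature_id"
  )
  sig_s <- !is.na(j$steady_padj) & j$steady_padj < alpha_steady
  sig_n <- !is.na(j$nascent_padj) & j$nascent_padj < alpha_nascent
  in_both <- j$feature_id %in% steady$feature_id &
    j$feature_id %in% nascent$feature_id
  label <- dplyr::case_when(
    !in_both ~ "unclassifiable",
    sig_s & !sig_n ~ "post_transcriptional",
    sig_s & sig_n & sign(j$steady_log2fc) == sign(j$nascent_log2fc) ~
      "transcriptional",
    sig_s & sig_n ~ "both_discordant",
    TRUE ~ "unchanged"
  )
  out <- tibble::tibble(
    gene_id = j$feature_id, label = label,
    steady_log2fc = j$steady_log2fc, steady_padj = j$steady_padj,
    nascent_log2fc = j$nascent_log2fc, nascent_padj = j$nascent_padj
  )
  structure(out, class = c("regulation_calls", class(tibble::tibble())),
            alpha_steady = alpha_steady, alpha_nascent = alpha_nascent)
}

#' @export
glance.regulation_calls <- function(x, ...) {
  tibble::as_tibble(table(label = x$label)) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n")
}

#' @export
autoplot.regulation_calls <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nascent_log2fc,
                                   y = .data$steady_log2fc,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(x = "nascent log2 fold change",
                  y = "steady-state log2 fold change",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tiered triage of candidate miRNA targets
#'
#' Three nested tiers: tier 1 keeps genes significantly elevated after miRNA
#' inhibition (padj < `alpha`, positive fold change, expression above
#' `min_counts` normalized counts in either condition); tier 2 intersects
#' tier 1 with predicted targets; tier 3 further requires significant
#' downregulation in the tumor DE table at the tumor thresholds. Tier 3 is
#' ranked by inhibition fold change, descending.
#'
#' @param up_after_inhibition `de_table` for inhibitor vs control, with
#'   `mean_a`/`mean_b` per-condition means (as produced by [pairwise_de()]).
#' @param predicted_targets Character vector of predicted target gene ids.
#' @param tumor_de `de_table` for tumor vs normal.
#' @param min_counts Expression floor for tier 1 (default 500).
#' @param tumor_min_counts,tumor_min_fold Tumor-arm thresholds (defaults
#'   1000, 1.5).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return List of character vectors `tier1`, `tier2`, `tier3`.
#' @export
triage_targets <- function(up_after_inhibition, predicted_targets, tumor_de,
                           min_counts = 500, tumor_min_counts = 1000,
                           tumor_min_fold = 1.5, alpha = 0.05) {
  de <- up_after_inhibition
  if (nrow(de) == 0) abort("Empty gene universe.")
  expr_ok <- if (all(c("mean_a", "mean_b") %in% names(de))) {
    pmax(de$mean_a, de$mean_b) > min_counts
  } else {
    de$baseMean > min_counts
  }
  t1 <- !is.na(de$padj) & de$padj < alpha & de$log2fc > 0 & expr_ok
  tier1 <- de$feature_id[t1]
  tier2 <- intersect(tier1, predicted_targets)
  tumor_down <- tumor_de$feature_id[
    !is.na(tumor_de$padj) & tumor_de$padj < alpha &
      tumor_de$log2fc < -log2(tumor_min_fold) &
      tumor_de$baseMean > tumor_min_counts
  ]
  tier3 <- intersect(tier2, tumor_down)
  lfc <- setNames(de$log2fc, de$feature_id)
  tier3 <- tier3[order(lfc[tier3], decreasing = TRUE)]
  list(tier1 = tier1, tier2 = tier2, tier3 = tier3)
}

#' Write regulation calls
#'
#' @param calls A `regulation_calls` tibble.
#' @param path Output path (tab-delimited).
#' @export
write_regulation_calls <- function(calls, path) {
  readr::write_tsv(tibble::as_tibble(calls), path)
  invisible(path)
}
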