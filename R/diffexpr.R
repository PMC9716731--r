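#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted to
#' features with strictly positive counts in every sample) of the ratio of
#' the sample's count to the feature's geometric mean across samples.
#'
#' @param counts Wide count tibble.
#' @return Named positive numeric, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  m <- count_values(validate_counts(counts))
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort("No feature has all-positive counts; size factors are undefined.")
  }
  lg <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, median)
  setNames(sf, colnames(m))
}

# prior degrees of freedom for empirical-Bayes dispersion moderation: the
# per-feature method-of-moments estimate is shrunk toward the panel median
# with this weight, and the Wald reference gains the same df
DISPERSION_PRIOR_DF <- 10

# per-feature method-of-moments NB dispersion, pooled over design groups
mom_dispersion_raw <- function(y_norm, groups) {
  ms <- tapply(y_norm, groups, mean)
  vs <- tapply(y_norm, groups, var)
  a <- (vs - ms) / ms^2
  a <- a[is.finite(a)]
  if (length(a)) mean(a) else NA_real_
}

# shrink per-feature estimates toward the panel median (floored at 1e-4)
moderate_dispersions <- function(mom, resid_df, floor = 1e-4) {
  mom_f <- pmax(mom, floor)
  common <- stats::median(mom_f, na.rm = TRUE)
  if (!is.finite(common)) common <- floor
  out <- (DISPERSION_PRIOR_DF * common + resid_df * mom_f) /
    (DISPERSION_PRIOR_DF + resid_df)
  out[!is.finite(out)] <- common
  pmax(out, floor)
}

de_table <- function(df) {
  structure(df, class = c("de_table", class(tibble::tibble())))
}

# shared per-feature NB fit machinery. Returns a de_table.
fit_nb_tests <- function(m, sf, X_full, X_reduced, coef_idx, log2fc_fun = NULL) {
  off <- log(sf)
  n <- ncol(m)
  grp <- groups_of(X_full)
  resid_df <- n - ncol(X_full)
  norm <- sweep(m, 2, sf, "/")
  mom <- apply(norm, 1, mom_dispersion_raw, groups = grp)
  alpha <- moderate_dispersions(mom, resid_df)
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    base_mean <- mean(y / sf)
    if (all(y == 0)) {
      return(list(baseMean = 0, log2fc = NA_real_, pvalue = NA_real_))
    }
    fam <- MASS::negative.binomial(theta = 1 / alpha[i])
    f1 <- suppressWarnings(glm.fit(X_full, y, family = fam, offset = off))
    if (is.null(X_reduced)) {
      # Wald test on one coefficient; t reference whose df include the
      # moderation prior, matching the information the shrunk dispersion adds
      se <- glm_coef_se(f1, X_full)
      est <- f1$coefficients[coef_idx]
      stat <- est / se[coef_idx]
      p <- 2 * pt(-abs(stat), df = DISPERSION_PRIOR_DF + resid_df)
      list(baseMean = base_mean, log2fc = est / log(2), pvalue = p)
    } else {
      # deviance difference, dispersion-scaled F reference
      f0 <- suppressWarnings(glm.fit(X_reduced, y, family = fam, offset = off))
      df1 <- ncol(X_full) - ncol(X_reduced)
      phi <- sum(nb_pearson_resid(y, f1$fitted.values, alpha[i])^2) / resid_df
      stat <- (f0$deviance - f1$deviance) / (df1 * max(phi, 1e-8))
      p <- pf(stat, df1, resid_df, lower.tail = FALSE)
      l2fc <- if (is.null(log2fc_fun)) NA_real_ else log2fc_fun(f1)
      list(baseMean = base_mean, log2fc = l2fc, pvalue = p)
    }
  })
  out <- tibble::tibble(
    feature_id = rownames(m),
    baseMean = purrr::map_dbl(res, "baseMean"),
    log2fc = purrr::map_dbl(res, "log2fc"),
    pvalue = purrr::map_dbl(res, "pvalue")
  )
  out$padj <- bh_adjust(out$pvalue)
  de_table(out)
}

# grouping vector from the full design matrix (unique rows)
groups_of <- function(X) {
  match(apply(X, 1, paste, collapse = "\r"),
        unique(apply(X, 1, paste, collapse = "\r")))
}

nb_pearson_resid <- function(y, mu, alpha) {
  (y - mu) / sqrt(mu + alpha * mu^2)
}

# expected-information standard errors at the fitted IRLS weights
glm_coef_se <- function(fit, X) {
  XtWX <- crossprod(X * sqrt(fit$weights))
  cov <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  sqrt(diag(cov))
}

#' Pairwise negative-binomial differential expression
#'
#' Per-feature NB regression (log link) of counts on a two-level condition
#' indicator plus optional covariates, with median-of-ratios size factors as
#' offsets. The reported `log2fc` is the condition coefficient (group
#' `group_b` relative to `group_a`) in log2 units; p-values are two-sided
#' Wald-style tests against a t reference with residual degrees of freedom,
#' and `padj` is Benjamini-Hochberg across tested features. Features with
#' all-zero counts get missing statistics and are excluded from the
#' adjustment.
#'
#' @param counts Wide count tibble.
#' @param meta Sample metadata with a `sample` column and the grouping column.
#' @param group_a,group_b Reference and comparison condition labels.
#' @param covariates Optional character vector of additional metadata columns
#'   to adjust for.
#' @param group_col Metadata column holding the condition labels.
#' @return A `de_table` tibble: `feature_id`, `baseMean`, `mean_a`, `mean_b`,
#'   `log2fc`, `pvalue`, `padj`.
#' @export
pairwise_de <- function(counts, meta, group_a, group_b, covariates = NULL,
                        group_col = "condition") {
  meta <- aligned_meta(counts, meta)
  g <- meta[[group_col]]
  if (is.null(g)) abort(paste0("Metadata lacks column `", group_col, "`."))
  for (lab in c(group_a, group_b)) {
    if (!lab %in% g) abort(paste0("Unknown group label: ", lab))
    if (sum(g == lab) < 2) abort(paste0("Group `", lab, "` has < 2 samples."))
  }
  keep <- g %in% c(group_a, group_b)
  sub <- counts[c("feature_id", sample_names(counts)[keep])]
  meta_sub <- meta[keep, , drop = FALSE]
  cond <- factor(meta_sub[[group_col]], levels = c(group_a, group_b))
  dat <- data.frame(cond = cond)
  for (cv in covariates) dat[[cv]] <- meta_sub[[cv]]
  X <- model.matrix(~ ., dat)
  m <- count_values(sub)
  sf <- estimate_size_factors(sub)
  out <- fit_nb_tests(m, sf, X, NULL, coef_idx = 2L)
  norm <- sweep(m, 2, sf, "/")
  out$mean_a <- rowMeans(norm[, cond == group_a, drop = FALSE])
  out$mean_b <- rowMeans(norm[, cond == group_b, drop = FALSE])
  de_table(out[c("feature_id", "baseMean", "mean_a", "mean_b",
                 "log2fc", "pvalue", "padj")])
}

#' Likelihood-ratio screen across a multi-level design
#'
#' Tests, per feature, whether the factors in `full_factors` improve on the
#' nested `reduced_factors` model (e.g. genotype on top of batch). The
#' deviance difference is referred to an F distribution after scaling by a
#' moment-estimated dispersion, which keeps null p-values uniform at the
#' small replicate numbers typical of organoid panels. `log2fc` reports the
#' largest-magnitude factor coefficient in log2 units (a summary of effect
#' size, not a specific contrast).
#'
#' @param counts Wide count tibble.
#' @param meta Sample metadata.
#' @param full_factors Character vector of metadata columns for the full
#'   model.
#' @param reduced_factors Character vector for the reduced model; must be a
#'   strict subset of `full_factors` (an intercept-only reduced model is
#'   `character(0)`).
#' @return A `de_table` tibble.
#' @export
lrt_screen <- function(counts, meta, full_factors,
                       reduced_factors = character(0)) {
  meta <- aligned_meta(counts, meta)
  if (!all(reduced_factors %in% full_factors)) {
    abort("`reduced_factors` must be nested in `full_factors`.")
  }
  if (setequal(reduced_factors, full_factors)) {
    abort("Full and reduced designs are identical; nothing to test.")
  }
  for (v in full_factors) {
    if (is.null(meta[[v]])) abort(paste0("Metadata lacks column `", v, "`."))
  }
  form <- function(vars) {
    if (length(vars) == 0) ~1 else
      stats::reformulate(vars)
  }
  X1 <- model.matrix(form(full_factors), data = meta)
  X0 <- model.matrix(form(reduced_factors), data = meta)
  if (qr(X1)$rank < ncol(X1)) abort("Full design matrix is rank deficient.")
  m <- count_values(counts)
  sf <- estimate_size_factors(counts)
  extra <- setdiff(colnames(X1), colnames(X0))
  fit_nb_tests(m, sf, X1, X0, coef_idx = NA_integer_,
               log2fc_fun = function(f1) {
                 b <- f1$coefficients[extra]
                 b <- b[is.finite(b)]
                 if (!length(b)) return(NA_real_)
                 b[which.max(abs(b))] / log(2)
               })
}

#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' Step-up false-discovery-rate control; `NA` entries are passed through
#' untouched and excluded from the adjustment. Values outside \[0, 1\] are an
#' error.
#'
#' @param pvalues Numeric vector of p-values (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  out <- pvalues
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Normalized log2 transform
#'
#' A simple variance-stabilizing stand-in for regularized log transforms:
#' `log2(count / size_factor + pseudocount)`. Monotone in counts per sample;
#' doubling every count of a sample leaves its transformed values unchanged
#' (the size factor absorbs the scaling).
#'
#' @param counts Wide count tibble.
#' @param pseudocount Positive pseudocount (default 1).
#' @return Wide tibble of transformed values (same shape as `counts`).
#' @export
rlog_like <- function(counts, pseudocount = 1) {
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  m <- count_values(counts)
  sf <- estimate_size_factors(counts)
  values_to_counts(log2(sweep(m, 2, sf, "/") + pseudocount))
}

#' Remove batch effects from a transformed matrix
#'
#' Least-squares removal of additive batch terms while protecting the
#' biological design: per feature, values are regressed on the protected
#' design plus batch indicators and only the fitted batch terms are
#' subtracted. Errors when batch is confounded with the protected design.
#'
#' @param transformed Wide tibble of (log-scale) values, as from
#'   [rlog_like()].
#' @param meta Sample metadata.
#' @param batch_col Metadata column with batch labels.
#' @param design_cols Metadata columns defining the protected design.
#' @return Wide tibble of corrected values.
#' @export
remove_batch <- function(transformed, meta, batch_col = "batch",
                         design_cols = "condition") {
  meta <- meta[match(sample_names(transformed), meta$sample), , drop = FALSE]
  if (is.null(meta[[batch_col]])) abort("Metadata lacks the batch column.")
  batch <- factor(meta[[batch_col]])
  if (nlevels(batch) < 2) return(transformed)
  design <- model.matrix(stats::reformulate(design_cols), data = meta)
  full <- cbind(design, model.matrix(~batch)[, -1, drop = FALSE])
  if (qr(full)$rank < ncol(full)) {
    abort("Batch is confounded with the protected design.")
  }
  m <- as.matrix(transformed[setdiff(names(transformed), "feature_id")])
  rownames(m) <- transformed$feature_id
  corrected <- limma::removeBatchEffect(m, batch = batch, design = design)
  values_to_counts(corrected)
}

#' @export
glance.de_table <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_tested = sum(!is.na(x$pvalue)),
    n_significant = sum(x$padj < alpha, na.rm = TRUE),
    alpha = alpha
  )
}

#' Write a DE table to disk
#'
#' @param de A `de_table`.
#' @param path Output path (tab-delimited).
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(de, path)
  invisible(path)
}
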