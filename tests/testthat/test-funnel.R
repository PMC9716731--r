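test_that("guide and degradation filters prune the id universe", {
  ann <- tibble::tibble(mirna_id = c("miR-X-5p", "miR-X-3p"),
                        strand = c("guide", "passenger"))
  expect_equal(filter_guides(c("miR-X-5p", "miR-X-3p"), ann), "miR-X-5p")
  all_guide <- tibble::tibble(mirna_id = c("a", "b"), strand = "guide")
  expect_equal(filter_guides(c("a", "b"), all_guide), c("a", "b"))
  expect_equal(filter_guides(character(0), ann), character(0))
  expect_warning(filter_guides(c("miR-X-5p", "novel"), ann), "unannotated")

  expect_equal(drop_degradation_ids(c("mir-5099", "miR-24-3p", "let-7a")),
               c("miR-24-3p", "let-7a"))
  # the removed block is [threshold, threshold + 1000)
  expect_equal(drop_degradation_ids(c("mir-4999", "mir-5000", "mir-5999",
                                      "mir-6000")),
               c("mir-4999", "mir-6000"))
  expect_equal(drop_degradation_ids(character(0)), character(0))
})

test_that("select_de applies strict fold, padj and expression thresholds", {
  de <- tibble::tibble(
    feature_id = c("up", "weak", "lowexpr"),
    baseMean = c(600, 600, 300),
    log2fc = c(0.7, 0.5, 2),
    pvalue = 0.001, padj = c(0.01, 0.01, 0.001)
  )
  got <- select_de(de, min_basemean = 500)
  expect_equal(got$mirna_id, "up")     # 2^0.7 = 1.62 > 1.5; others fail
  expect_equal(got$direction, "up")
  expect_error(select_de(de, min_fold = 0.5), ">= 1")
})

test_that("consistent_direction requires fold and sign in every comparison", {
  mk <- function(l2fc) tibble::tibble(feature_id = c("m1", "m2", "m3"),
                                      baseMean = 1000, log2fc = l2fc,
                                      pvalue = 0.01, padj = 0.01)
  tabs <- list(mk(c(0.8, 0.8, 0.8)), mk(c(0.9, 0.9, 0.9)),
               mk(c(1.1, 1.1, 1.1)), mk(c(0.7, 0.7, 0.7)),
               mk(c(2.0, -2.0, 0.3)))
  got <- consistent_direction(tabs)
  expect_equal(got$mirna_id, "m1")     # m2 flips sign, m3 under fold once
  expect_equal(got$direction, "up")
  bad <- c(tabs[1:4], list(mk(c(1, 1, 1))[c(1, 2), ]))
  expect_error(consistent_direction(bad), "universe")
})

test_that("rpmmm rescales each sample to a million mapped reads", {
  counts <- tibble::tibble(feature_id = c("a", "b"),
                           s1 = c(5, 15), s2 = c(1, 3))
  rp <- rpmmm(counts)
  expect_equal(rp$s1, c(250000, 750000))
  expect_equal(unname(colSums(as.matrix(rp[-1]))), c(1e6, 1e6))
  withzero <- tibble::tibble(feature_id = c("a", "b"),
                             s1 = c(10, 0), s2 = c(5, 0))
  expect_equal(rpmmm(withzero)$s1, c(1e6, 0))
  expect_error(rpmmm(tibble::tibble(feature_id = "a", s1 = 0)),
               "zero miRNA-mapped")
})

test_that("tumor expression filter keeps features passing in either condition", {
  meta <- tibble::tibble(sample = paste0("s", 1:4),
                         condition = c("tumor", "tumor", "normal", "normal"))
  rp <- tibble::tibble(
    feature_id = c("hi_tumor", "hi_both", "low"),
    s1 = c(1500, 2000, 900), s2 = c(1500, 2000, 900),
    s3 = c(200, 2000, 900), s4 = c(200, 2000, 900)
  )
  expect_equal(tcga_expression_filter(rp, meta),
               c("hi_tumor", "hi_both"))
  expect_equal(tcga_expression_filter(rp, meta, min_avg = 0),
               rp$feature_id)
  meta_bad <- dplyr::mutate(meta, condition = "tumor")
  expect_error(tcga_expression_filter(rp, meta_bad), "missing")
})

test_that("matched confirmation demands paired significance in the right direction", {
  set.seed(42)
  n_pairs <- 8
  meta <- tibble::tibble(
    sample = paste0("s", 1:(2 * n_pairs)),
    condition = rep(c("tumor", "normal"), n_pairs),
    pair_id = rep(paste0("p", 1:n_pairs), each = 2)
  )
  normal_vals <- 2^rnorm(n_pairs, mean = 10, sd = 0.1)
  tumor_up <- normal_vals * 2^rnorm(n_pairs, 1, 0.1)
  tumor_dn <- normal_vals * 2^rnorm(n_pairs, -1, 0.1)
  rp <- tibble::tibble(feature_id = c("mUp", "mDown"))
  for (i in seq_len(n_pairs)) {
    rp[[paste0("s", 2 * i - 1)]] <- c(tumor_up[i], tumor_dn[i])
    rp[[paste0("s", 2 * i)]] <- c(normal_vals[i], normal_vals[i])
  }
  cand <- structure(tibble::tibble(
    mirna_id = c("mUp", "mDown"), direction = c("up", "up"),
    provenance = "de"
  ), class = c("candidate_set", class(tibble::tibble())))
  got <- matched_confirmation(rp, meta, cand)
  # mUp is confirmed; mDown is significant but in the wrong direction
  expect_equal(got$mirna_id, "mUp")
  meta1 <- meta[1:2, ]
  rp1 <- rp[c("feature_id", "s1", "s2")]
  expect_error(matched_confirmation(rp1, meta1, cand), "two matched pairs")
  meta_bad <- dplyr::mutate(meta, condition = "tumor")
  expect_error(matched_confirmation(rp, meta_bad, cand),
               "one tumor and one normal")
})

test_that("paralog collapse merges concordant members and flags discordant ones", {
  fam <- tibble::tibble(
    mirna_id = c("miR-24-1-3p", "miR-24-2-3p", "miR-9-1", "miR-9-2", "solo"),
    family = c("miR-24-3p", "miR-24-3p", "miR-9", "miR-9", "solo-fam")
  )
  cand <- structure(tibble::tibble(
    mirna_id = c("miR-24-1-3p", "miR-24-2-3p", "miR-9-1", "miR-9-2", "solo"),
    direction = c("up", "up", "up", "down", "down"),
    provenance = "de"
  ), class = c("candidate_set", class(tibble::tibble())))
  got <- collapse_paralogs(cand, fam)
  expect_setequal(got$family, c("miR-24-3p", "solo-fam"))
  expect_equal(got$direction[got$family == "miR-24-3p"], "up")
  expect_equal(attr(got, "discordant"), "miR-9")
})

test_that("candidate intersection matches family and direction", {
  cs <- function(fam, dir) structure(
    tibble::tibble(family = fam, direction = dir, provenance = "x"),
    class = c("candidate_set", class(tibble::tibble()))
  )
  got <- intersect_candidates(cs(c("A", "B"), c("up", "down")),
                              cs(c("A", "C"), c("up", "up")))
  expect_equal(got$family, "A")
  expect_equal(nrow(intersect_candidates(cs("A", "up"), cs("A", "down"))), 0)
  expect_equal(nrow(intersect_candidates(cs("A", "up"), cs("B", "up"))), 0)
})

test_that("pan-cancer summary reports per-type geometric-mean fold changes", {
  set.seed(11)
  n <- 6
  meta <- tibble::tibble(
    sample = paste0("s", 1:(4 * n)),
    condition = rep(rep(c("tumor", "normal"), each = n), 2),
    tumor_type = rep(c("COAD", "LUAD"), each = 2 * n)
  )
  vals <- c(2^rnorm(n, 11, 0.05), 2^rnorm(n, 10, 0.05),  # COAD: 2x up
            2^rnorm(n, 10, 0.05), 2^rnorm(n, 10, 0.05))  # LUAD: null
  rp <- tibble::as_tibble(as.list(setNames(vals, meta$sample))) |>
    dplyr::mutate(feature_id = "miR-t", .before = 1)
  got <- pan_cancer_summary(rp, meta, "miR-t")
  expect_equal(got$log2fc[got$tumor_type == "COAD"], 1, tolerance = 0.1)
  expect_equal(got$log2fc[got$tumor_type == "LUAD"], 0, tolerance = 0.1)
  expect_true(got$significant[got$tumor_type == "COAD"])
  expect_false(got$significant[got$tumor_type == "LUAD"])
  # a type missing one condition is skipped with a warning
  meta2 <- meta
  meta2$condition[meta2$tumor_type == "LUAD"] <- "tumor"
  expect_warning(got2 <- pan_cancer_summary(rp, meta2, "miR-t"), "skipped")
  expect_equal(got2$tumor_type, "COAD")
})

test_that("genotype binning reproduces the full event truth table", {
  events <- c("nonsynonymous", "cnv_gain", "cnv_loss")
  combos <- expand.grid(mut = c(FALSE, TRUE), gain = c(FALSE, TRUE),
                        loss = c(FALSE, TRUE))
  # expected rules: loss-class assigns on mut|loss unless gain&mut;
  # gain-class assigns on mut|gain unless loss&mut
  expected_loss <- with(combos, (mut | loss) & !(gain & mut))
  expected_gain <- with(combos, (mut | gain) & !(loss & mut))
  mk_events <- function(gene) {
    purrr::map_dfr(seq_len(nrow(combos)), function(i) {
      ev <- events[c(combos$mut[i], combos$gain[i], combos$loss[i])]
      if (length(ev) == 0) return(
        tibble::tibble(tumor_id = character(), gene = character(),
                       event = character()))
      tibble::tibble(tumor_id = paste0("t", i), gene = gene, event = ev)
    })
  }
  got_loss <- assign_genotypes(mk_events("APC"))
  got_loss <- got_loss[match(paste0("t", 2:8), got_loss$tumor_id), ]
  expect_equal(got_loss$labels == "A", expected_loss[2:8])
  got_gain <- assign_genotypes(mk_events("KRAS"))
  got_gain <- got_gain[match(paste0("t", 2:8), got_gain$tumor_id), ]
  expect_equal(got_gain$labels == "K", expected_gain[2:8])
  # multi-gene tumors concatenate sorted labels
  multi <- tibble::tibble(
    tumor_id = "t1", gene = c("APC", "KRAS", "TP53"),
    event = c("nonsynonymous", "cnv_gain", "cnv_loss")
  )
  expect_equal(assign_genotypes(multi)$labels, "AKP")
  expect_warning(assign_genotypes(
    tibble::tibble(tumor_id = "t1", gene = "MYC", event = "cnv_gain")),
    "unrecognised")
})
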