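test_that("sim_design validates its invariants", {
  expect_error(sim_design(c("WT", "WT", "A"), wild_type = "WT"), "exactly once")
  expect_error(sim_design(c("WT", "A"), replicates = 0), ">= 1")
  expect_error(sim_design(c("WT", "A"), dispersion = 0), "> 0")
  d <- sim_design(c("WT", "A", "B"), replicates = 2, n_features = 10)
  expect_s3_class(d, "sim_design")
})

test_that("null-pattern counts have equal group means and fixed seeds reproduce", {
  d <- sim_design(c("WT", "A", "B"), replicates = 30, n_features = 40,
                  dispersion = 0.05, base_mean_range = c(500, 500), seed = 3)
  sim1 <- simulate_mirna_counts(d)
  sim2 <- simulate_mirna_counts(d)
  expect_identical(sim1$counts, sim2$counts)   # bit-reproducible
  m <- as.matrix(sim1$counts[-1])
  g <- sim1$meta$condition
  ratios <- t(apply(m, 1, function(r) tapply(r, g, mean)))
  # all-zero pattern: group means agree within a few NB standard errors
  se <- nb_mean_se(500, 0.05, 30)
  expect_true(all(abs(ratios - 500) < 4 * se))
})

test_that("a planted module shifts member group means by the planted ratio", {
  d <- sim_design(c("WT", "MUT1", "MUT2"), replicates = 50, n_features = 40,
                  dispersion = 0.05, base_mean_range = c(1000, 1000), seed = 11)
  mods <- tibble::tibble(module = "M1",
                         pattern = list(c(0, 2, 2)),
                         n_members = 10L)
  sim <- simulate_mirna_counts(d, mods)
  m <- as.matrix(sim$counts[-1])
  g <- sim$meta$condition
  gm <- t(apply(m, 1, function(r) tapply(r, g, mean)))[, c("WT", "MUT1", "MUT2")]
  members <- !is.na(sim$truth$module_assignment$module)
  log2_ratio <- log2(gm[, "MUT1"] / gm[, "WT"])
  # group-mean ratios converge on the planted pattern: ensemble means within
  # 0.1 at n = 50, every feature within 4 NB standard errors
  expect_equal(mean(log2_ratio[members]), 2, tolerance = 0.05)
  expect_equal(mean(log2_ratio[!members]), 0, tolerance = 0.1)
  se_log2 <- sqrt(2) * nb_mean_se(1000, 0.05, 50) / (1000 * log(2))
  expect_true(all(abs(log2_ratio[members] - 2) < 5 * se_log2))
  expect_true(all(abs(log2_ratio[!members]) < 5 * se_log2))
  expect_error(
    simulate_mirna_counts(d, tibble::tibble(module = "B",
                                            pattern = list(c(0, 1)),
                                            n_members = 2L)),
    "one entry per genotype"
  )
  expect_error(
    simulate_mirna_counts(d, tibble::tibble(module = "B",
                                            pattern = list(c(0, 1, 1)),
                                            n_members = 100L)),
    "exceed"
  )
})

test_that("simulated UTR site tables agree exactly with a rescan", {
  sim <- simulate_utrs_and_sites(
    n_genes = 25, n_mirnas = 6,
    utr_length_range = c(100, 400),
    site_rates = c("8mer" = 0.5, "7mer-m8" = 0.5, "7mer-1A" = 0.5),
    conservation_rate = 0.5, seed = 5
  )
  rescan <- scan_seed_sites(sim$utrs, sim$mirnas)
  expect_identical(
    sim$sites[c("gene_id", "mirna_id", "site_class", "start")],
    rescan
  )
  # planted sites are present in the table (allowing class upgrades in place)
  planted <- sim$truth[!is.na(sim$truth$start), ]
  found <- mapply(function(g, m, p) {
    any(sim$sites$gene_id == g & sim$sites$mirna_id == m &
          abs(sim$sites$start - p) <= 1)
  }, planted$gene_id, planted$mirna_id, planted$start)
  expect_true(all(found))
})

test_that("zero site rates leave only chance matches, all recorded", {
  sim <- simulate_utrs_and_sites(n_genes = 15, n_mirnas = 4,
                                 utr_length_range = c(100, 300),
                                 site_rates = c("8mer" = 0),
                                 conservation_rate = 1, seed = 9)
  expect_equal(nrow(sim$truth), 0)
  rescan <- scan_seed_sites(sim$utrs, sim$mirnas)
  expect_identical(sim$sites[c("gene_id", "mirna_id", "site_class", "start")],
                   rescan)
  # conservation_rate = 1 flags every site in every species
  if (nrow(sim$sites) > 0) {
    expect_true(all(sim$sites$conserved_in ==
                      "mouse,human,rat,dog,chicken"))
  }
})

test_that("an explicitly planted 8mer is recovered for a single gene", {
  sim <- simulate_utrs_and_sites(
    n_genes = 1, n_mirnas = 1, utr_length_range = c(60, 60),
    site_rates = c("8mer" = 0),
    planted = tibble::tibble(gene_id = "gene-1", mirna_id = "miR-sim-1",
                             site_class = "8mer"),
    seed = 2
  )
  hit <- sim$sites[sim$sites$start == sim$truth$start[1], ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$site_class, "8mer")
  expect_error(
    simulate_utrs_and_sites(
      n_genes = 1, n_mirnas = 1,
      planted = tibble::tibble(gene_id = "gene-1", mirna_id = "nope",
                               site_class = "8mer"), seed = 1),
    "unknown miRNA"
  )
})

test_that("planted repression shifts target means by effect times activity", {
  d <- sim_design(c("WT", "MUT"), replicates = 50, n_features = 30,
                  dispersion = 0.05, base_mean_range = c(1000, 1000),
                  seed = 21)
  tm <- tibble::tibble(gene_id = paste0("gene-", 1:10),
                       mirna_id = "miR-x", effect_log2 = -1)
  act <- tibble::tibble(mirna_id = "miR-x", activity_log2 = 1)
  sim <- simulate_mrna_counts(d, tm, act)
  m <- as.matrix(sim$counts[-1])
  g <- sim$meta$condition
  gm <- t(apply(m, 1, function(r) tapply(r, g, mean)))
  ratio <- gm[, "MUT"] / gm[, "WT"]
  expect_equal(mean(log2(ratio[1:10])), -1, tolerance = 0.08)  # targets halve
  expect_equal(mean(log2(ratio[11:30])), 0, tolerance = 0.08)  # rest unshifted
  # zero activity plants nothing
  sim0 <- simulate_mrna_counts(
    d, tm, tibble::tibble(mirna_id = "miR-x", activity_log2 = 0))
  expect_true(all(sim0$truth$shift == 0))
  expect_error(
    simulate_mrna_counts(d, tibble::tibble(gene_id = "gene-999",
                                           mirna_id = "miR-x",
                                           effect_log2 = -1), act),
    "absent from universe"
  )
})

test_that("steady/nascent pair shifts genes according to their label", {
  d <- sim_design(c("control", "treated"), wild_type = "control",
                  replicates = 50, n_features = 3, dispersion = 0.05,
                  base_mean_range = c(1000, 1000), seed = 33)
  labels <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    label = c("post_transcriptional", "transcriptional", "unregulated")
  )
  pair <- simulate_rna_chro_pair(d, labels, effect_log2 = 1)
  ratio <- function(counts, gene) {
    m <- as.matrix(counts[-1])
    rownames(m) <- counts$feature_id
    g <- pair$meta$condition
    mean(m[gene, g == "treated"]) / mean(m[gene, g == "control"])
  }
  expect_equal(ratio(pair$steady, "g1"), 2, tolerance = 0.15)
  expect_equal(ratio(pair$nascent, "g1"), 1, tolerance = 0.15)
  expect_equal(ratio(pair$steady, "g2"), 2, tolerance = 0.15)
  expect_equal(ratio(pair$nascent, "g2"), 2, tolerance = 0.15)
  expect_equal(ratio(pair$steady, "g3"), 1, tolerance = 0.15)
  expect_error(
    simulate_rna_chro_pair(d, tibble::tibble(gene_id = "g1", label = "odd")),
    "Unknown regulation label"
  )
  expect_error(
    simulate_rna_chro_pair(sim_design(c("a", "b", "c")), labels),
    "exactly two conditions"
  )
})

test_that("mutation tables respect rates, exclusivity and the seed", {
  rates <- tibble::tibble(gene = c("APC", "KRAS"),
                          p_mutation = c(1, 0), p_gain = c(0, 0.5),
                          p_loss = c(0, 0.5))
  tab <- simulate_mutation_table(20, rates, seed = 4)
  expect_identical(tab, simulate_mutation_table(20, rates, seed = 4))
  apc <- tab[tab$gene == "APC" & tab$event == "nonsynonymous", ]
  expect_equal(sort(unique(apc$tumor_id)), sort(paste0("tumor-", 1:20)))
  # gain and loss never co-occur for a tumor-gene pair
  both <- tab |>
    dplyr::filter(.data$event != "nonsynonymous") |>
    dplyr::count(.data$tumor_id, .data$gene)
  expect_true(all(both$n <= 1))
  empty <- simulate_mutation_table(
    5, tibble::tibble(gene = "APC", p_mutation = 0, p_gain = 0, p_loss = 0),
    seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(simulate_mutation_table(0, rates), "> 0")
})
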