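LET7 <- "UGAGGUAGUAGGUUGUAUAGUU"

test_that("find_seed_sites reproduces hand-derived canonical matches", {
  # reverse complement of seed 2-8 (GAGGUAG) is CUACCUC; with the A -> 8mer
  hit8 <- find_seed_sites("AAACUACCUCAAA", LET7)
  expect_equal(hit8$start, 4)
  expect_equal(hit8$site_class, "8mer")
  hit7 <- find_seed_sites("GGCUACCUCGGG", LET7)
  expect_equal(hit7$start, 3)
  expect_equal(hit7$site_class, "7mer-m8")
  # seed 2-7 match plus A, without the m8 base -> 7mer-1A
  hit1a <- find_seed_sites("GGGUACCUCAGG", LET7)
  expect_equal(hit1a$site_class, "7mer-1A")
  expect_equal(nrow(find_seed_sites("AAAAAAA", LET7)), 0)
  expect_error(find_seed_sites("ACGTACG", LET7), "position 4")
  expect_error(find_seed_sites("ACGU", "ACGUACG"), "at least 8")
})

test_that("scanner agrees exactly with the base-pairing oracle", {
  set.seed(101)
  for (i in 1:25) {
    utr <- random_rna(200)
    mir <- random_rna(22)
    got <- as.data.frame(find_seed_sites(utr, mir))
    want <- oracle_seed_sites(utr, mir)
    want <- want[order(want$start), ]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
  # adversarial composition: AU-rich sequences maximise A-rule edge cases
  for (i in 1:25) {
    utr <- random_rna(150, alphabet = c("A", "A", "U", "C", "G"))
    mir <- random_rna(22, alphabet = c("A", "U", "U", "C", "G"))
    got <- as.data.frame(find_seed_sites(utr, mir))
    want <- oracle_seed_sites(utr, mir)
    want <- want[order(want$start), ]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("conservation filters implement the two anchored rules", {
  sites <- tibble::tibble(
    gene_id = "g", mirna_id = "m", site_class = "8mer", start = 1:5,
    conserved_in = c("mouse,rat", "mouse", "human,rat,dog", "human,rat",
                     "mouse,human,rat,dog,chicken")
  )
  expect_equal(conservation_filter(sites, "cons1")$start, c(1, 5))
  expect_equal(conservation_filter(sites, "cons2")$start, c(3, 5))
  expect_error(conservation_filter(sites, "cons9"), "Unknown conservation")
})

test_that("gene and cumulative scores follow the weighted, length-controlled form", {
  expect_equal(gene_score("8mer", 100, 100), 3)
  expect_equal(gene_score(c("7mer-1A", "7mer-1A"), 200, 100), 1)
  expect_equal(gene_score(character(0), 100, 100), 0)
  expect_error(gene_score("8mer", 0, 100), "> 0")

  sites <- tibble::tibble(
    gene_id = c("g1", "g2"), mirna_id = "m1",
    site_class = c("8mer", "7mer-m8"), start = 1
  )
  lens <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         utr_length = c(100, 100, 100))
  idx <- build_target_index(sites, lens)
  expect_equal(cumulative_score(c("g1", "g2"), "m1", idx), 5)
  expect_equal(cumulative_score(character(0), "m1", idx), 0)
  expect_equal(cumulative_score("g3", "m1", idx), 0)
  expect_error(cumulative_score(c("g1", "g1"), "m1", idx), "sets")
  expect_error(cumulative_score("nope", "m1", idx), "outside the universe")
})

test_that("monte_carlo_enrichment honours the +1 empirical-p floor and the seed", {
  set.seed(7)
  n_genes <- 60
  sites <- tibble::tibble(
    gene_id = paste0("g", 1:10), mirna_id = "mX",
    site_class = "8mer", start = 1
  )
  lens <- tibble::tibble(gene_id = paste0("g", 1:n_genes),
                         utr_length = round(runif(n_genes, 100, 1000)))
  idx <- build_target_index(sites, lens)
  res <- monte_carlo_enrichment(paste0("g", 1:10), idx, "mX",
                                n_iterations = 1000, seed = 1)
  # the input list holds every target: no null draw can beat it often
  expect_equal(res$empirical_p, 1 / 1001, tolerance = 1e-3)
  expect_true(res$empirical_p > 0)
  res2 <- monte_carlo_enrichment(paste0("g", 1:10), idx, "mX",
                                 n_iterations = 1000, seed = 1)
  expect_identical(res$empirical_p, res2$empirical_p)
  expect_identical(attr(res, "null_scores"), attr(res2, "null_scores"))
  expect_error(monte_carlo_enrichment(paste0("g", 1:10), idx, "mX",
                                      n_iterations = 50, seed = 1),
               ">= 100")
  expect_error(monte_carlo_enrichment(paste0("g", 1:10), idx, "mX",
                                      n_iterations = 1000),
               "seed")
})

test_that("empirical p is monotone nonincreasing in the observed score", {
  # with a fixed null, a larger observed score can only lower the p-value
  null_scores <- c(1, 2, 3, 4, 5)
  emp <- function(obs) (1 + sum(null_scores >= obs)) / (length(null_scores) + 1)
  ps <- vapply(seq(0, 6, by = 0.5), emp, 1)
  expect_true(all(diff(ps) <= 0))
})

test_that("recurrent_candidates counts significant comparisons", {
  p_long <- tibble::tibble(
    mirna_id = rep(c("kept", "dropped"), each = 5),
    comparison = rep(paste0("c", 1:5), 2),
    empirical_p = c(0.01, 0.04, 0.2, 0.6, 0.03,
                    0.01, 0.04, 0.2, 0.6, 0.2)
  )
  expect_equal(recurrent_candidates(p_long), "kept")
  expect_equal(recurrent_candidates(p_long, alpha = 0), character(0))
  expect_error(recurrent_candidates(p_long, min_hits = 6), "exceeds")
})

test_that("cumulative score is invariant to gene-list order", {
  set.seed(3)
  sim <- simulate_utrs_and_sites(n_genes = 20, n_mirnas = 3,
                                 utr_length_range = c(100, 300),
                                 conservation_rate = 1, seed = 14)
  idx <- build_target_index(sim$sites, sim$utr_lengths)
  genes <- paste0("gene-", 1:15)
  m <- idx$mirna_ids[1]
  expect_equal(cumulative_score(genes, m, idx),
               cumulative_score(rev(genes), m, idx))
})
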