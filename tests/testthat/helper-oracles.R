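# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the seed-site oracle tests Watson-Crick pairing
# base by base instead of building match strings, and the BH oracle applies
# the step-up definition with explicit loops.

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# classify every UTR position by direct base-pairing against the miRNA seed
oracle_seed_sites <- function(utr, mirna) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  u <- strsplit(utr, "")[[1]]
  m <- strsplit(mirna, "")[[1]]
  L <- length(u)
  pairs_seed <- function(p, lo, hi) {
    k <- 0:(hi - lo)
    if (p + (hi - lo) > L || p < 1) return(FALSE)
    all(u[p + k] == comp[m[hi - k]])
  }
  starts <- integer()
  classes <- character()
  for (p in seq_len(L)) {
    if (pairs_seed(p, 2, 8)) {
      if (p + 7 <= L && u[p + 7] == "A") {
        starts <- c(starts, p); classes <- c(classes, "8mer")
      } else {
        starts <- c(starts, p); classes <- c(classes, "7mer-m8")
      }
    } else if (pairs_seed(p, 2, 7) && p + 6 <= L && u[p + 6] == "A") {
      # a 7mer-1A lying inside an 8mer one position upstream is the same locus
      inside_8mer <- p >= 2 && pairs_seed(p - 1, 2, 8)
      if (!inside_8mer) {
        starts <- c(starts, p); classes <- c(classes, "7mer-1A")
      }
    }
  }
  data.frame(start = starts, site_class = classes)
}

# Benjamini-Hochberg step-up by definition: padj for the i-th order statistic
# is min over j >= i of n * p_(j) / j, capped at 1
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, n * p[o[j]] / j)
    adj_sorted[i] <- min(1, best)
  }
  out <- numeric(n)
  out[o] <- adj_sorted
  out
}

# adjusted Rand index from the contingency-table formula
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# standard error of an NB group mean under dispersion alpha
nb_mean_se <- function(mu, alpha, n) sqrt((mu + alpha * mu^2) / n)
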