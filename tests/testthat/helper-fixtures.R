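# Shared fixtures, all built in code.

# 3 aphids x 2 parasitoids, total 16 individuals
tiny_web <- function() {
  interaction_table(matrix(c(5, 0, 2, 0, 7, 2), nrow = 3,
                           dimnames = list(c("A1", "A2", "A3"),
                                           c("P1", "P2"))))
}

# 4-rank taxonomy: A and B congeneric, C in a different family
abc_taxonomy <- function() {
  taxonomy_table(data.frame(
    aphid_id = c("A1", "A2", "A3"),
    family = c("F1", "F1", "F2"),
    subfamily = c("S1", "S1", "S2"),
    tribe = c("T1", "T1", "T2"),
    genus = c("G1", "G1", "G2"),
    stringsAsFactors = FALSE))
}

# complete trait table for arbitrary species ids, deterministic given seed
random_traits <- function(ids, seed = 1, missing_rate = 0) {
  set.seed(seed)
  vocab <- aphid_trait_levels()
  df <- data.frame(aphid_id = ids, stringsAsFactors = FALSE)
  for (tr in names(vocab)) {
    val <- sample(vocab[[tr]], length(ids), replace = TRUE)
    # guarantee >= 2 observed levels
    val[1:2] <- vocab[[tr]][1:2]
    if (missing_rate > 0) {
      mask <- runif(length(ids)) < missing_rate
      mask[1:2] <- FALSE
      val[mask] <- NA
    }
    df[[tr]] <- val
  }
  trait_table(df)
}

# random small web + nested taxonomy for property tests
random_small_web <- function(seed, n_aphids = 8, n_parasitoids = 4,
                             max_count = 30) {
  set.seed(seed)
  gen <- sample(1:3, n_aphids, replace = TRUE)
  fam <- ifelse(gen <= 2, 1L, 2L)
  tax <- taxonomy_table(data.frame(
    aphid_id = sprintf("a%02d", 1:n_aphids),
    family = paste0("f", fam),
    subfamily = paste0("s", fam),
    tribe = paste0("t", ifelse(gen <= 2, gen, 3)),
    genus = paste0("g", gen),
    stringsAsFactors = FALSE))
  repeat {
    m <- matrix(rpois(n_aphids * n_parasitoids, 1.2) *
                  sample(0:max_count, n_aphids * n_parasitoids, TRUE),
                n_aphids, n_parasitoids,
                dimnames = list(tax$aphid_id,
                                sprintf("p%02d", 1:n_parasitoids)))
    if (sum(m) > 0 && all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  list(web = interaction_table(m), tax = tax)
}

# independent brute-force PSV: 1 - mean pairwise correlation by double loop
oracle_psv <- function(hosts, C) {
  n <- length(hosts)
  if (n == 1) return(0)
  tot <- 0
  k <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + C[hosts[i], hosts[j]]
      k <- k + 1
    }
  }
  1 - tot / k
}

# independent two-sided hypergeometric p by explicit enumeration over all
# achievable overlaps, using only choose()
oracle_hyper_p <- function(n, n_k, n_l, n_kl) {
  ks <- max(0, n_l - (n - n_k)):min(n_k, n_l)
  pmf <- choose(n_k, ks) * choose(n - n_k, n_l - ks) / choose(n, n_l)
  lower <- sum(pmf[ks <= n_kl])
  upper <- sum(pmf[ks >= n_kl])
  min(1, 2 * min(lower, upper))
}

# independent triple-loop scorer: pairs x hosts, no shared code with the
# package internals
oracle_pair_scores <- function(m, idx_vals) {
  ids <- colnames(m)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      shared <- which(m[, i] > 0 & m[, j] > 0)
      if (!length(shared) || idx_vals[i] == idx_vals[j]) next
      sp <- if (idx_vals[i] < idx_vals[j]) i else j
      ge <- i + j - sp
      ph <- numeric(0)
      for (h in shared) ph <- c(ph, m[h, sp] / (m[h, sp] + m[h, ge]))
      out[[length(out) + 1L]] <- list(specialist = ids[sp],
                                      generalist = ids[ge],
                                      score = mean(ph))
    }
  }
  out
}
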