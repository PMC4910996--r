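make_test_study <- function(seed = 3, n_aphids = 40, n_parasitoids = 25,
                            advantage = NULL) {
  st <- simulate_study(simulation_spec(n_aphids = n_aphids,
                                       n_parasitoids = n_parasitoids,
                                       base_count = 20, missing_rate = 0,
                                       advantage = advantage, seed = seed))
  wf <- filter_rare_interactions(st$web)
  C <- taxonomic_correlation(st$taxonomy)
  list(st = st, web = wf, idx = host_range_indices(wf, C))
}

test_that("identical seeds give bit-identical bootstrap results", {
  x <- make_test_study()
  cfg <- bootstrap_config(B = 199, seed = 11)
  a <- bootstrap_trait_test(x$web, x$st$traits, "mobility", "high", "low",
                            "assemblage", x$idx, "psv", cfg)
  b <- bootstrap_trait_test(x$web, x$st$traits, "mobility", "high", "low",
                            "assemblage", x$idx, "psv", cfg)
  expect_identical(a$replicate_diffs, b$replicate_diffs)
  expect_identical(a$p_value, b$p_value)
  c <- bootstrap_trait_test(x$web, x$st$traits, "mobility", "high", "low",
                            "assemblage", x$idx, "psv",
                            bootstrap_config(B = 199, seed = 12))
  expect_false(identical(a$replicate_diffs, c$replicate_diffs))
})

test_that("two levels with identical count structure give p near one half", {
  # duplicate a block of aphids so both levels carry exactly the same rows
  rw <- random_small_web(5, n_aphids = 6, n_parasitoids = 6)
  m <- unclass(rw$web)
  m2 <- rbind(m, m)
  rownames(m2) <- c(paste0(rownames(m), "_x"), paste0(rownames(m), "_y"))
  w <- interaction_table(m2)
  tax1 <- as.data.frame(rw$tax)
  tax2 <- rbind(transform(tax1, aphid_id = paste0(aphid_id, "_x")),
                transform(tax1, aphid_id = paste0(aphid_id, "_y")))
  C <- taxonomic_correlation(taxonomy_table(tax2))
  idx <- host_range_indices(w, C)
  df <- as.data.frame(random_traits(rownames(m2), seed = 9))
  df$life_cycle <- rep(c("monoecious", "heteroecious"), each = nrow(m))
  res <- bootstrap_trait_test(w, trait_table(df), "life_cycle",
                              "monoecious", "heteroecious", "assemblage",
                              idx, "psv",
                              bootstrap_config(B = 4999, seed = 2, tail = "greater"))
  expect_equal(res$observed_diff, 0)
  expect_equal(res$p_value, 0.5, tolerance = 0.05)
})

test_that("p-values respect the counting rule and the chosen tail", {
  x <- make_test_study()
  cfg <- bootstrap_config(B = 499, seed = 21, tail = "two_sided")
  r <- bootstrap_trait_test(x$web, x$st$traits, "wax", "absent", "present",
                            "assemblage", x$idx, "sr", cfg)
  pg <- sum(r$replicate_diffs >= r$observed_diff) / r$B_effective
  pl <- sum(r$replicate_diffs <= r$observed_diff) / r$B_effective
  expect_equal(r$p_value, min(1, 2 * min(pg, pl)))
  expect_gte(r$p_value, 0)
  expect_lte(r$p_value, 1)
  # auto tail follows the sign of the observed difference
  r2 <- bootstrap_trait_test(x$web, x$st$traits, "wax", "absent", "present",
                             "assemblage", x$idx, "sr",
                             bootstrap_config(B = 499, seed = 21))
  expect_equal(r2$tail, if (r2$observed_diff >= 0) "greater" else "less")
  expect_equal(r2$p_value, if (r2$observed_diff >= 0) pg else pl)
})

test_that("an injected specialist advantage is detected", {
  x <- make_test_study(seed = 6, n_aphids = 60, n_parasitoids = 75,
                       advantage = list(trait = "colony_aggregation",
                                        level = "sparse", delta = 3))
  res <- bootstrap_trait_test(x$web, x$st$traits, "colony_aggregation",
                              "sparse", "dense", "mean_score", x$idx, "psv",
                              bootstrap_config(B = 999, seed = 1, tail = "greater"))
  expect_gt(res$observed_diff, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("widely undefined statistics abort with the failure rate", {
  # one applicable pair hinging on a single aphid: resampling one row from a
  # pool of 12 leaves the statistic undefined most of the time
  m <- matrix(0L, 12, 2, dimnames = list(sprintf("h%02d", 1:12), c("S", "G")))
  m[1, ] <- c(10L, 10L)
  m[2, ] <- c(10L, 10L)
  m[3:12, 2] <- 8L
  w <- interaction_table(m)
  idx <- data.frame(parasitoid_id = c("S", "G"), sr = c(2, 12), psv = NA)
  df <- as.data.frame(random_traits(rownames(m), seed = 4))
  df$wax <- c("absent", rep("present", 11))
  expect_error(
    bootstrap_trait_test(w, trait_table(df), "wax", "absent", "present",
                         "mean_score", idx, "sr",
                         bootstrap_config(B = 199, seed = 5)),
    "undefined on \\d+% of replicates")
})

test_that("the full battery yields 40 primary rows with the pooled contrasts", {
  x <- make_test_study(seed = 12, n_aphids = 50)
  out <- run_all_trait_tests(x$web, x$st$traits, x$idx,
                             bootstrap_config(B = 59, seed = 3))
  prim <- out[out$contrast == "primary", ]
  expect_equal(nrow(prim), 10 * 2 * 2)
  ant <- prim[prim$trait == "ant_attendance", ]
  expect_true(all(ant$level_a == "absent" & ant$level_b == "facultative+obligatory"))
  bs <- prim[prim$trait == "body_size", ]
  expect_true(all(bs$level_a == "large" & bs$level_b == "medium+small"))
  db <- prim[prim$trait == "diet_breadth", ]
  expect_true(all(db$level_a == "monophagous" & db$level_b == "polyphagous"))
  # supplementary pairwise contrasts for every 3-level trait
  supp <- out[out$contrast == "supplementary", ]
  expect_equal(nrow(supp), 3 * 3 * 2 * 2)
  # batch determinism
  out2 <- run_all_trait_tests(x$web, x$st$traits, x$idx,
                              bootstrap_config(B = 59, seed = 3))
  expect_identical(out, out2)
})

test_that("a failing contrast is flagged without aborting the batch", {
  x <- make_test_study(seed = 13, n_aphids = 30)
  df <- as.data.frame(x$st$traits)
  df$wax[] <- "absent"   # empty 'present' level
  out <- run_all_trait_tests(x$web, trait_table(df), x$idx,
                             bootstrap_config(B = 39, seed = 1))
  waxrow <- out[out$trait == "wax" & out$statistic == "assemblage" &
                out$index == "sr", ]
  expect_match(waxrow$flag, "at least one qualifying species")
  expect_true(any(out$flag == ""))
})

test_that("per-trait substreams are independent of the battery composition", {
  x <- make_test_study(seed = 14, n_aphids = 40)
  full <- run_all_trait_tests(x$web, x$st$traits, x$idx,
                              bootstrap_config(B = 99, seed = 8),
                              statistics = "assemblage")
  solo <- run_all_trait_tests(x$web, x$st$traits, x$idx,
                              bootstrap_config(B = 99, seed = 8),
                              which_set = "psv", statistics = "assemblage")
  shared <- full[full$index == "psv" & full$statistic == "assemblage", ]
  rownames(shared) <- rownames(solo) <- NULL
  expect_equal(shared, solo)
})
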