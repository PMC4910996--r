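# hand-built indicator objects let the CA engine be probed outside the
# ten-trait vocabulary
make_indicator <- function(Z, trait, Q) {
  structure(Z, trait = trait, n_traits = Q,
            class = c("indicator_matrix", "matrix", "array"))
}

test_that("total inertia of a complete indicator matrix is J/Q - 1", {
  # two binary traits, J = 4, Q = 2 -> total inertia 1
  set.seed(1)
  a <- sample(0:1, 20, TRUE)
  b <- sample(0:1, 20, TRUE)
  Z <- cbind(a, 1 - a, b, 1 - b)
  rownames(Z) <- paste0("s", 1:20)
  m <- fit_mca(make_indicator(Z, c("t1", "t1", "t2", "t2"), 2L))
  expect_equal(m$total_inertia, 1, tolerance = 1e-10)
  # and on random complete ten-trait tables
  for (seed in 1:10) {
    tr <- random_traits(sprintf("s%02d", 1:30), seed = seed)
    mm <- fit_mca(tr)
    expect_equal(mm$total_inertia, mm$n_categories / mm$n_traits - 1,
                 tolerance = 1e-10)
  }
})

test_that("two perfectly associated binary traits load one axis entirely", {
  a <- rep(c(1, 0), times = c(8, 12))
  Z <- cbind(a, 1 - a, a, 1 - a)
  rownames(Z) <- paste0("s", 1:20)
  m <- fit_mca(make_indicator(Z, c("t1", "t1", "t2", "t2"), 2L))
  expect_equal(m$pct_variance[1], 100, tolerance = 1e-8)
  expect_equal(m$eigenvalues[1], 1, tolerance = 1e-10)
  # cross-check against the explicit 2x2 correspondence analysis: the
  # contingency table is diagonal, so the single nontrivial CA axis
  # separates the two blocks completely
  tab <- table(a, a)
  expect_equal(sum(diag(tab)), 20)
})

test_that("row permutation leaves eigenvalues unchanged and permutes scores", {
  tr <- random_traits(sprintf("s%02d", 1:25), seed = 7)
  m1 <- fit_mca(tr)
  perm <- sample(nrow(tr))
  tr2 <- trait_table(as.data.frame(tr)[perm, ])
  m2 <- fit_mca(tr2)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-10)
  # coordinates agree up to axis sign
  for (k in 1:2) {
    x1 <- m1$row_coords[perm, k]
    x2 <- m2$row_coords[, k]
    expect_equal(min(max(abs(x1 - x2)), max(abs(x1 + x2))), 0, tolerance = 1e-8)
  }
})

test_that("a constant table is degenerate", {
  a <- rep(1, 10)
  Z <- cbind(a, 0 * a, a, 0 * a)
  rownames(Z) <- paste0("s", 1:10)
  expect_error(fit_mca(make_indicator(Z, c("t1", "t1", "t2", "t2"), 2L)),
               "zero row or column mass|degenerate")
})

test_that("imputation is the identity on complete tables", {
  tr <- random_traits(sprintf("s%02d", 1:20), seed = 3)
  out <- impute_mca(tr)
  expect_identical(out$traits, tr)
  expect_equal(out$n_iter, 0L)
  expect_equal(out$n_missing, 0L)
})

test_that("a missing cell is imputed from its look-alike species", {
  # nine species in three groups whose profiles span more dimensions than
  # ncp, so the reconstruction is genuinely low-rank; s3 lacks
  # colony_aggregation but matches the s1/s2 group on the group-structured
  # traits, and that group's level must win even though the overall
  # marginal favours the other level (observed: 2 dense vs 6 sparse)
  vocab <- aphid_trait_levels()
  grp <- rep(1:3, each = 3)
  df <- data.frame(aphid_id = paste0("s", 1:9), stringsAsFactors = FALSE)
  i <- 0
  for (tr in setdiff(names(vocab), c("colony_aggregation", "wax"))) {
    lv <- vocab[[tr]]; i <- i + 1
    pat <- switch(1 + i %% 3,
                  c(lv[1], lv[2], lv[2]),
                  c(lv[1], lv[1], lv[2]),
                  c(lv[1], lv[2], lv[1]))
    df[[tr]] <- pat[grp]
  }
  df$wax <- rep(c("absent", "present"), length.out = 9)  # within-group noise
  df$colony_aggregation <- c("dense", "dense", NA, rep("sparse", 6))
  out <- impute_mca(trait_table(df), ncp = 2)
  expect_true(out$converged)
  expect_equal(as.character(out$traits$colony_aggregation[3]), "dense")
  # fuzzy weight concentrated on the imputed level
  jj <- which(attr(out$indicator, "trait") == "colony_aggregation")
  expect_gt(out$indicator[3, jj[1]], 0.9)
})

test_that("imputation never alters observed cells", {
  tr <- random_traits(sprintf("s%02d", 1:40), seed = 5, missing_rate = 0.1)
  out <- impute_mca(tr)
  obs <- !is.na(as.data.frame(tr)[-1])
  before <- as.data.frame(tr)[-1]
  after <- as.data.frame(out$traits)[-1]
  expect_identical(unlist(lapply(before, as.character))[as.vector(as.matrix(obs))],
                   unlist(lapply(after, as.character))[as.vector(as.matrix(obs))])
  expect_false(anyNA(as.data.frame(out$traits)[-1]))
})

test_that("excessive missingness is rejected", {
  tr <- as.data.frame(random_traits(paste0("s", 1:10), seed = 6))
  tr$wax[1:6] <- NA
  expect_error(impute_mca(trait_table(tr)), "60% missing")
  tr$wax[1:10] <- NA
  expect_error(impute_mca(trait_table(tr)), "at least 2 observed levels|entirely missing")
})

test_that("v.test matches exact hypergeometric enumeration", {
  # complete containment is strongly significant
  df <- data.frame(aphid_id = paste0("s", 1:10), stringsAsFactors = FALSE)
  vocab <- aphid_trait_levels()
  for (tr in names(vocab)) df[[tr]] <- rep(vocab[[tr]][1:2], length.out = 10)
  df$mobility <- c(rep("high", 4), "low", "high", rep("low", 4))   # n_k = 5
  df$wax <- c(rep("present", 4), rep("absent", 6))                 # n_l = 4
  r <- category_vtest(trait_table(df), c("mobility", "high"), c("wax", "present"))
  expect_equal(r$n_kl, 4L)
  # frozen from the enumeration oracle: doubled upper tail 2 * 5/210
  expect_equal(r$p, oracle_hyper_p(10, 5, 4, 4), tolerance = 1e-12)
  expect_equal(r$p, 2 * 5 / 210, tolerance = 1e-12)
  expect_equal(r$v, 1.9807518, tolerance = 1e-6)
  # enrichment exactly at the base rate gives v = 0
  df$mobility <- rep(c("high", "low"), 5)
  df$wax <- rep(c("present", "present", "absent", "absent"), length.out = 10)
  r0 <- category_vtest(trait_table(df), c("mobility", "high"), c("wax", "present"))
  expect_equal(r0$prop_in_condition, r0$prop_overall)
  expect_equal(r0$v, 0)
  # random tables, exhaustively enumerated oracle
  set.seed(8)
  for (k in 1:80) {
    n <- sample(5:30, 1)
    vk <- sample(c("high", "low"), n, TRUE); vk[1:2] <- c("high", "low")
    vl <- sample(c("present", "absent"), n, TRUE); vl[1:2] <- c("present", "absent")
    ids <- paste0("s", 1:n)
    d2 <- data.frame(aphid_id = ids, stringsAsFactors = FALSE)
    for (tr in names(vocab)) d2[[tr]] <- rep(vocab[[tr]][1:2], length.out = n)
    d2$mobility <- vk; d2$wax <- vl
    r <- category_vtest(trait_table(d2), c("mobility", "high"), c("wax", "present"))
    expect_equal(r$p, oracle_hyper_p(n, sum(vk == "high"), sum(vl == "present"),
                                     sum(vk == "high" & vl == "present")),
                 tolerance = 1e-12)
    expect_equal(r$v, sign(r$prop_in_condition - r$prop_overall) *
                        qnorm(1 - r$p / 2))
  }
})

test_that("v is antisymmetric in the tested level and order matters", {
  tr <- random_traits(sprintf("s%02d", 1:30), seed = 9)
  a <- category_vtest(tr, c("mobility", "high"), c("wax", "present"))
  b <- category_vtest(tr, c("mobility", "low"), c("wax", "present"))
  expect_equal(abs(a$v), abs(b$v), tolerance = 1e-12)   # success/failure swap
  expect_equal(a$v, -b$v, tolerance = 1e-12)
  ab <- category_vtest(tr, c("wax", "present"), c("mobility", "high"))
  # the two orders test different proportions (asymmetry by construction)
  expect_false(isTRUE(all.equal(a$prop_in_condition, ab$prop_in_condition)))
})

test_that("the all-pairs table excludes within-trait comparisons", {
  tr <- random_traits(sprintf("s%02d", 1:20), seed = 10)
  vt <- all_pairwise_vtests(tr)
  J <- sum(lengths(lapply(names(aphid_trait_levels()), function(t)
    levels(droplevels(tr[[t]])))))
  within <- sum(vapply(names(aphid_trait_levels()), function(t)
    length(levels(droplevels(tr[[t]])))^2, numeric(1)))
  expect_equal(nrow(vt), J^2 - within)
  expect_false(any(sub(":.*", "", vt$tested) == sub(":.*", "", vt$conditioning)))
})
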