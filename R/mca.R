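#' Indicator (complete disjunctive) matrix of a trait table
#'
#' One column per observed trait level; for each species and trait the block
#' of columns holds a single 1 (observed value), fractional completion
#' weights in `[0, 1]` summing to one (imputed value), or `NA` (missing
#' value, before imputation). Levels never observed in the data are dropped
#' so that every column has positive mass.
#'
#' @param traits A [trait_table()].
#' @return Matrix of class `indicator_matrix`, species in rows, categories
#'   (`trait:level`) in columns, with attributes `trait` (the trait each
#'   column belongs to) and `n_traits`.
#' @export
indicator_matrix <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  vocab <- aphid_trait_levels()
  cols <- list()
  col_trait <- character()
  for (tr in names(vocab)) {
    val <- traits[[tr]]
    used <- levels(droplevels(val))
    if (length(used) < 2L)
      stop(sprintf("trait '%s' needs at least 2 observed levels", tr))
    for (lv in used) {
      cols[[paste(tr, lv, sep = ":")]] <- ifelse(is.na(val), NA_real_,
                                                 as.numeric(val == lv))
      col_trait <- c(col_trait, tr)
    }
  }
  Z <- do.call(cbind, cols)
  rownames(Z) <- traits$aphid_id
  structure(Z, trait = col_trait, n_traits = length(vocab),
            class = c("indicator_matrix", "matrix", "array"))
}

# Correspondence analysis engine shared by fit_mca and the imputation:
# returns masses, centered standardized residuals and their SVD.
.ca_core <- function(Z) {
  N <- sum(Z)
  P <- Z / N
  r <- rowSums(P)
  c <- colSums(P)
  if (any(r <= 0) || any(c <= 0)) stop("zero row or column mass in indicator matrix")
  S <- (P - tcrossprod(r, c)) / tcrossprod(sqrt(r), sqrt(c))
  sv <- svd(S)
  list(N = N, P = P, r = r, c = c, svd = sv)
}

#' Multiple correspondence analysis of a trait table
#'
#' Correspondence analysis of the indicator matrix: relative frequencies are
#' centred on the product of row and column masses, standardized, and
#' decomposed by SVD; eigenvalues are squared singular values and principal
#' coordinates are mass-rescaled singular vectors. Categories sit at the
#' (rescaled) barycentre of the species that carry them. The total inertia
#' of a complete indicator matrix with `J` categories over `Q` traits is
#' `J/Q - 1`.
#'
#' @param Z An [indicator_matrix()] without missing entries (run
#'   [impute_mca()] first if the trait table has missing values), or a
#'   [trait_table()] without missing values.
#' @return Object of class `mca`: list with `eigenvalues`, `pct_variance`,
#'   `row_coords`, `category_coords`, `category_labels`, `n_categories`,
#'   `n_traits`, `total_inertia`.
#' @export
fit_mca <- function(Z) {
  if (inherits(Z, "trait_table")) Z <- indicator_matrix(Z)
  stopifnot(inherits(Z, "indicator_matrix"))
  if (anyNA(Z)) stop("indicator matrix has missing entries; impute first")
  Q <- attr(Z, "n_traits")
  J <- ncol(Z)
  core <- .ca_core(unclass(Z))
  lambda <- core$svd$d^2
  keep <- lambda > 1e-12
  if (sum(keep) < 1L) stop("degenerate trait table: no variation after centering")
  lambda <- lambda[keep]
  U <- core$svd$u[, keep, drop = FALSE]
  V <- core$svd$v[, keep, drop = FALSE]
  d <- core$svd$d[keep]
  F_row <- sweep(U, 2L, d, `*`) / sqrt(core$r)
  G_col <- sweep(V, 2L, d, `*`) / sqrt(core$c)
  dimnames(F_row) <- list(rownames(Z), paste0("Dim", seq_along(d)))
  dimnames(G_col) <- list(colnames(Z), paste0("Dim", seq_along(d)))
  structure(list(
    eigenvalues = lambda,
    pct_variance = 100 * lambda / sum(lambda),
    row_coords = F_row,
    category_coords = G_col,
    category_labels = colnames(Z),
    n_categories = J, n_traits = Q,
    total_inertia = sum(lambda)
  ), class = "mca")
}

#' @export
print.mca <- function(x, ...) {
  cat(sprintf("MCA: %d species, %d categories over %d traits; total inertia %.4f\n",
              nrow(x$row_coords), x$n_categories, x$n_traits, x$total_inertia))
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("  Dim%d: eigenvalue %.4f (%.1f%%)\n", seq_len(k),
              x$eigenvalues[seq_len(k)], x$pct_variance[seq_len(k)]), sep = "")
  invisible(x)
}

#' Impute missing trait values by regularized iterative MCA
#'
#' Missing indicator cells are initialized at the observed level
#' proportions of their trait; the algorithm then alternates a
#' correspondence analysis of the completed matrix with a reconstruction
#' from the first `ncp` dimensions whose singular values are shrunk by the
#' mean of the discarded eigenvalues (regularization against overfitting
#' the imputed cells), overwriting only the missing cells — clipped to
#' `[0, 1]` and renormalized within each trait block — until the largest
#' change falls below `tol`. Observed cells are never modified. For
#' downstream categorical analyses each missing value is finally
#' hard-assigned to the level with the largest completion weight.
#'
#' @param traits A [trait_table()] (missing values allowed; every trait
#'   must have at least two observed levels and under 50% missingness).
#' @param ncp Number of MCA dimensions used in the reconstruction
#'   (default 2).
#' @param tol Convergence threshold on the largest absolute change of an
#'   imputed cell (default 1e-6).
#' @param max_iter Iteration cap; non-convergence raises a warning and is
#'   flagged on the result.
#' @return List with `traits` (completed [trait_table()]), `indicator`
#'   (fuzzy [indicator_matrix()]), `n_iter`, `converged`, and
#'   `n_missing` (count of imputed cells).
#' @export
impute_mca <- function(traits, ncp = 2L, tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(traits, "trait_table"))
  vocab <- aphid_trait_levels()
  for (tr in names(vocab)) {
    miss <- mean(is.na(traits[[tr]]))
    if (miss >= 1) stop(sprintf("trait '%s' is entirely missing", tr))
    if (miss >= 0.5)
      stop(sprintf("trait '%s' has %.0f%% missing values (>= 50%%)", tr, 100 * miss))
  }
  Z <- indicator_matrix(traits)
  col_trait <- attr(Z, "trait")
  miss_mask <- is.na(unclass(Z))
  if (!any(miss_mask)) {
    return(list(traits = traits, indicator = Z, n_iter = 0L,
                converged = TRUE, n_missing = 0L))
  }
  Zc <- unclass(Z)
  # initialize each missing block at the observed level proportions
  for (tr in unique(col_trait)) {
    jj <- which(col_trait == tr)
    prop <- colMeans(Zc[, jj, drop = FALSE], na.rm = TRUE)
    prop <- prop / sum(prop)
    for (j in seq_along(jj)) {
      col <- Zc[, jj[j]]
      col[is.na(col)] <- prop[j]
      Zc[, jj[j]] <- col
    }
  }
  renorm <- function(M) {
    for (tr in unique(col_trait)) {
      jj <- which(col_trait == tr)
      s <- rowSums(M[, jj, drop = FALSE])
      bad <- s <= 0
      if (any(bad)) {
        M[bad, jj] <- 1 / length(jj)
        s[bad] <- 1
      }
      M[, jj] <- M[, jj, drop = FALSE] / s
    }
    M
  }
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    core <- .ca_core(Zc)
    lambda <- core$svd$d^2
    k <- min(ncp, length(lambda))
    sigma2 <- if (length(lambda) > k) mean(lambda[(k + 1L):length(lambda)]) else 0
    d_reg <- pmax((lambda[seq_len(k)] - sigma2) / core$svd$d[seq_len(k)], 0)
    Uk <- core$svd$u[, seq_len(k), drop = FALSE]
    Vk <- core$svd$v[, seq_len(k), drop = FALSE]
    Phat <- tcrossprod(core$r, core$c) +
      tcrossprod(sqrt(core$r), sqrt(core$c)) *
      (sweep(Uk, 2L, d_reg, `*`) %*% t(Vk))
    Zhat <- pmin(pmax(Phat * core$N, 0), 1)
    Znew <- Zc
    Znew[miss_mask] <- Zhat[miss_mask]
    Znew <- renorm(Znew)
    delta <- max(abs(Znew[miss_mask] - Zc[miss_mask]))
    Zc <- Znew
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("impute_mca did not converge in ", max_iter, " iterations")
  # hard assignment for downstream categorical analyses
  completed <- traits
  cats <- sub("^[^:]+:", "", colnames(Z))
  for (tr in unique(col_trait)) {
    jj <- which(col_trait == tr)
    val <- completed[[tr]]
    for (i in which(is.na(val))) {
      val[i] <- cats[jj[which.max(Zc[i, jj])]]
    }
    completed[[tr]] <- val
  }
  fuzzy <- structure(Zc, trait = col_trait, n_traits = attr(Z, "n_traits"),
                     class = c("indicator_matrix", "matrix", "array"))
  list(traits = completed, indicator = fuzzy, n_iter = it,
       converged = converged, n_missing = sum(miss_mask))
}

#' Hypergeometric v.test for trait-level co-occurrence
#'
#' Tests whether species carrying the conditioning category are enriched
#' (or depleted) in the tested category, relative to its overall frequency.
#' With `n` species, `n_k` carrying the tested category, `n_l` the
#' conditioning category and `n_kl` both, the two-sided p-value is the
#' doubled smaller hypergeometric tail (each tail including the observed
#' overlap), and the v statistic is the signed standard-normal quantile
#' `sign(n_kl/n_l - n_k/n) * qnorm(1 - p/2)`; `|v| > 2` roughly corresponds
#' to p < 0.05. The test is asymmetric: testing k among l is not the same
#' as testing l among k.
#'
#' @param traits A completed [trait_table()] (no missing values in the two
#'   traits involved; rows with missing values are dropped with a warning).
#' @param tested,conditioning Length-2 character vectors
#'   `c(trait, level)`.
#' @return List with `tested`, `conditioning`, `n`, `n_k`, `n_l`, `n_kl`,
#'   `prop_in_condition`, `prop_overall`, `v`, `p`.
#' @export
category_vtest <- function(traits, tested, conditioning) {
  stopifnot(length(tested) == 2L, length(conditioning) == 2L)
  tr_k <- tested[1L]; lv_k <- tested[2L]
  tr_l <- conditioning[1L]; lv_l <- conditioning[2L]
  for (tr in c(tr_k, tr_l)) if (!tr %in% names(traits)) stop("unknown trait: ", tr)
  vk <- traits[[tr_k]]
  vl <- traits[[tr_l]]
  ok <- !is.na(vk) & !is.na(vl)
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " species with missing values")
    vk <- vk[ok]; vl <- vl[ok]
  }
  n <- length(vk)
  n_k <- sum(vk == lv_k)
  n_l <- sum(vl == lv_l)
  n_kl <- sum(vk == lv_k & vl == lv_l)
  if (n_l == 0L) stop(sprintf("conditioning category %s:%s is empty", tr_l, lv_l))
  if (n_k == 0L) stop(sprintf("tested category %s:%s is empty", tr_k, lv_k))
  lower <- stats::phyper(n_kl, n_k, n - n_k, n_l)
  upper <- stats::phyper(n_kl - 1L, n_k, n - n_k, n_l, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  s <- sign(n_kl / n_l - n_k / n)
  v <- s * stats::qnorm(1 - p / 2)
  list(tested = paste(tr_k, lv_k, sep = ":"),
       conditioning = paste(tr_l, lv_l, sep = ":"),
       n = n, n_k = n_k, n_l = n_l, n_kl = n_kl,
       prop_in_condition = n_kl / n_l, prop_overall = n_k / n,
       v = v, p = p)
}

#' All ordered cross-trait v.tests
#'
#' [category_vtest()] for every ordered pair of observed categories from
#' different traits (within-trait pairs are excluded; the two orders of a
#' pair generally give different results).
#'
#' @param traits A completed [trait_table()].
#' @return Data frame, one row per ordered category pair, sorted by
#'   decreasing `|v|`.
#' @export
all_pairwise_vtests <- function(traits) {
  cat_list <- list()
  for (tr in names(aphid_trait_levels())) {
    for (lv in levels(droplevels(traits[[tr]]))) {
      cat_list[[length(cat_list) + 1L]] <- c(tr, lv)
    }
  }
  rows <- list()
  for (a in cat_list) {
    for (b in cat_list) {
      if (a[1L] == b[1L]) next
      r <- category_vtest(traits, tested = a, conditioning = b)
      rows[[length(rows) + 1L]] <- data.frame(
        tested = r$tested, conditioning = r$conditioning,
        n = r$n, n_k = r$n_k, n_l = r$n_l, n_kl = r$n_kl,
        prop_in_condition = r$prop_in_condition,
        prop_overall = r$prop_overall, v = r$v, p = r$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(-abs(out$v)), , drop = FALSE]
}
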