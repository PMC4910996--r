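#' Cross-validate the three input tables
#'
#' Checks species-label consistency between interactions, taxonomy and
#' traits, and summarizes species counts, interaction totals, per-trait
#' level frequencies and missingness. Problems are reported, not raised.
#'
#' @param web An [interaction_table()].
#' @param tax A [taxonomy_table()].
#' @param traits A [trait_table()].
#' @return Object of class `web_validation`: list with `n_aphids`,
#'   `n_parasitoids`, `total_individuals`, `problems` (character vector),
#'   `trait_levels` (per-trait level counts) and `trait_missing`.
#' @export
validate_inputs <- function(web, tax, traits) {
  problems <- character()
  miss_tax <- setdiff(rownames(web), tax$aphid_id)
  if (length(miss_tax))
    problems <- c(problems, paste0("aphid in interactions missing from taxonomy: ",
                                   paste(miss_tax, collapse = ", ")))
  miss_tr <- setdiff(rownames(web), traits$aphid_id)
  if (length(miss_tr))
    problems <- c(problems, paste0("aphid in interactions missing from traits: ",
                                   paste(miss_tr, collapse = ", ")))
  lv <- lapply(traits[names(aphid_trait_levels())], function(x) table(x, useNA = "no"))
  structure(list(
    n_aphids = nrow(web), n_parasitoids = ncol(web),
    total_individuals = sum(web),
    problems = problems,
    trait_levels = lv,
    trait_missing = vapply(traits[names(aphid_trait_levels())],
                           function(x) sum(is.na(x)), integer(1L))
  ), class = "web_validation")
}

#' @export
print.web_validation <- function(x, ...) {
  cat(sprintf("web: %d aphid x %d parasitoid species, %d individuals\n",
              x$n_aphids, x$n_parasitoids, x$total_individuals))
  cat(sprintf("trait missingness: %d cells\n", sum(x$trait_missing)))
  if (length(x$problems)) {
    cat(length(x$problems), "problems:\n")
    cat(paste0("  - ", x$problems, collapse = "\n"), "\n")
  } else cat("0 problems\n")
  invisible(x)
}

.round_df <- function(df, digits = 6L) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Run the full trait analysis end-to-end
#'
#' Filters rare interactions, computes host-range indices and assemblage
#' specialization, scores specialist advantage per trait level, runs the
#' bootstrap test battery for both statistics and both indices, imputes
#' missing trait values, and computes the MCA and the cross-trait v.tests.
#' If `output_dir` is given, the report tables are written as CSV files
#' with fixed column order and 6-decimal rounding (for reproducible
#' diffs), and the full-precision results are returned invisibly.
#'
#' @param web An [interaction_table()] or path to its CSV.
#' @param tax A [taxonomy_table()] or path.
#' @param traits A [trait_table()] or path.
#' @param min_count Rare-interaction threshold (default 5); set to 1 to
#'   skip filtering (for inputs deposited post-filtering).
#' @param cfg A [bootstrap_config()].
#' @param rank_weights Optional per-segment weights for
#'   [taxonomic_correlation()].
#' @param ncp MCA dimensions used by [impute_mca()].
#' @param output_dir Optional directory for the CSV report bundle.
#' @return List (invisibly if writing) with `web` (filtered), `validation`,
#'   `indices`, `assemblage`, `assemblage_by_level` (summary-table layout),
#'   `pair_scores`, `tests`, `mca`, `vtests`, `imputation`.
#' @export
run_full_analysis <- function(web, tax, traits, min_count = 5L,
                              cfg = bootstrap_config(), rank_weights = NULL,
                              ncp = 2L, output_dir = NULL) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  if (is.character(web)) web <- stage("read interactions", read_interaction_table(web))
  if (is.character(tax)) tax <- stage("read taxonomy", read_taxonomy_table(tax, web))
  if (is.character(traits)) traits <- stage("read traits", read_trait_table(traits))

  web_f <- stage("filter", filter_rare_interactions(web, min_count))
  if (nrow(web_f) == 0L) stop("[filter] no interactions survive filtering")
  validation <- stage("validate", validate_inputs(web_f, tax, traits))
  if (length(validation$problems))
    stop("[validate] ", paste(validation$problems, collapse = "; "))

  C <- stage("indices", taxonomic_correlation(tax, weights = rank_weights))
  indices <- stage("indices", host_range_indices(web_f, C))
  assem <- stage("assemblage", assemblage_table(web_f, indices))

  # Per-trait-level summary in the layout of the study's Table: one row per
  # level present, mean w_PSV and w_SR, with the primary-contrast p-values
  # attached to the first level of each trait.
  tests <- stage("bootstrap", run_all_trait_tests(web_f, traits, indices, cfg))
  vocab <- aphid_trait_levels()
  lvl_rows <- list()
  for (tr in names(vocab)) {
    for (lv in vocab[[tr]]) {
      row <- data.frame(trait = tr, level = lv, n_species = NA_integer_,
                        w_psv_mean = NA_real_, w_sr_mean = NA_real_,
                        p_psv = NA_real_, p_sr = NA_real_,
                        flag = "", stringsAsFactors = FALSE)
      res <- tryCatch({
        a <- trait_level_mean_assemblage(web_f, traits, indices, tr, lv, "psv")
        b <- trait_level_mean_assemblage(web_f, traits, indices, tr, lv, "sr")
        row$n_species <- a$n_species
        row$w_psv_mean <- a$mean
        row$w_sr_mean <- b$mean
        row
      }, error = function(e) { row$flag <- conditionMessage(e); row })
      lvl_rows[[length(lvl_rows) + 1L]] <- res
    }
  }
  by_level <- do.call(rbind, lvl_rows)
  prim <- tests[tests$contrast == "primary" & tests$statistic == "assemblage", ]
  for (tr in names(vocab)) {
    first <- which(by_level$trait == tr)[1L]
    by_level$p_psv[first] <- prim$p_value[prim$trait == tr & prim$index == "psv"][1L]
    by_level$p_sr[first] <- prim$p_value[prim$trait == tr & prim$index == "sr"][1L]
  }

  pair_rows <- list()
  for (wh in c("sr", "psv")) {
    prs <- enumerate_pairs(web_f, indices, wh)
    for (tr in names(vocab)) {
      for (lv in vocab[[tr]]) {
        sc <- tryCatch(
          trait_level_mean_score(web_f, traits, tr, lv, indices, wh, pairs = prs),
          error = function(e) NULL)
        if (is.null(sc)) next
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          trait = tr, level = lv, index = wh,
          mean_score = sc$mean_score, n_pairs = sc$n_pairs,
          n_species = sc$n_species, stringsAsFactors = FALSE)
      }
    }
  }
  pair_scores <- do.call(rbind, pair_rows)

  imp <- stage("impute", impute_mca(traits, ncp = ncp))
  mca <- stage("mca", fit_mca(imp$indicator))
  vt <- stage("vtest", all_pairwise_vtests(imp$traits))

  result <- list(web = web_f, validation = validation, indices = indices,
                 assemblage = assem, assemblage_by_level = by_level,
                 pair_scores = pair_scores, tests = tests, mca = mca,
                 vtests = vt, imputation = imp)

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    w <- function(df, f) utils::write.csv(.round_df(as.data.frame(df)),
                                          file.path(output_dir, f),
                                          row.names = FALSE)
    write_interaction_table(web_f, file.path(output_dir, "filtered_web.csv"))
    w(indices, "indices.csv")
    w(assem, "assemblage_table.csv")
    w(by_level, "assemblage_by_level.csv")
    w(pair_scores, "pair_scores.csv")
    w(tests, "advantage_tests.csv")
    w(vt, "vtests.csv")
    eig <- data.frame(dim = seq_along(mca$eigenvalues),
                      eigenvalue = mca$eigenvalues,
                      pct_variance = mca$pct_variance)
    w(eig, "mca_eigenvalues.csv")
    w(data.frame(category = rownames(mca$category_coords),
                 mca$category_coords[, 1:2, drop = FALSE]), "mca_coords.csv")
    writeLines(c(sprintf("seed: %d", cfg$seed),
                 sprintf("B: %d", cfg$B),
                 sprintf("min_count: %d", as.integer(min_count)),
                 sprintf("R: %s", R.version.string)),
               file.path(output_dir, "run_info.txt"))
    return(invisible(result))
  }
  result
}
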