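#' Enumerate relative specialist / generalist parasitoid pairs
#'
#' All unordered pairs of parasitoids that share at least one host species
#' and have strictly different host-range index values. Within each pair the
#' member with the smaller index is the relative specialist. Pairs with
#' exactly equal index values are excluded (for PSV, equality is judged
#' after rounding to 12 decimals to ignore representation noise).
#'
#' @param tbl An [interaction_table()] (the full, filtered web).
#' @param indices Output of [host_range_indices()] computed on `tbl`.
#' @param which Index defining the host range: `"sr"` or `"psv"`.
#' @return Data frame with columns `specialist_id`, `generalist_id`,
#'   `index_used`, `spec_index`, `gen_index`, `n_shared`, and a list column
#'   `shared_hosts` of the full-web shared host species.
#' @export
enumerate_pairs <- function(tbl, indices, which = c("sr", "psv")) {
  which <- match.arg(which)
  stopifnot(inherits(tbl, "interaction_table"))
  pos <- unclass(tbl) > 0L
  share <- crossprod(pos)                       # parasitoid x parasitoid host overlap
  S <- .index_vector(indices, which)[colnames(tbl)]
  key <- if (which == "psv") round(S, 12L) else S
  ids <- colnames(tbl)
  out <- list()
  n <- length(ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (share[i, j] == 0L || key[i] == key[j]) next
      sp <- if (key[i] < key[j]) i else j
      ge <- if (sp == i) j else i
      out[[length(out) + 1L]] <- list(
        specialist_id = ids[sp], generalist_id = ids[ge],
        spec_index = unname(S[sp]), gen_index = unname(S[ge]),
        shared = rownames(tbl)[pos[, i] & pos[, j]])
    }
  }
  if (!length(out)) {
    return(data.frame(specialist_id = character(), generalist_id = character(),
                      index_used = character(), spec_index = numeric(),
                      gen_index = numeric(), n_shared = integer(),
                      shared_hosts = I(list()), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    specialist_id = vapply(out, `[[`, "", "specialist_id"),
    generalist_id = vapply(out, `[[`, "", "generalist_id"),
    index_used = which,
    spec_index = vapply(out, `[[`, 0, "spec_index"),
    gen_index = vapply(out, `[[`, 0, "gen_index"),
    n_shared = vapply(out, function(x) length(x$shared), 0L),
    stringsAsFactors = FALSE)
  df$shared_hosts <- I(lapply(out, `[[`, "shared"))
  df
}

#' Mean relative parasitism of a specialist on the hosts shared with its
#' generalist
#'
#' For every host shared by the pair within `tbl_subset`, the specialist's
#' share of the pair's combined counts `n_S / (n_S + n_G)` is computed, and
#' the unweighted mean over shared hosts returned. If the pair shares no
#' host within the subset the pair is not applicable and the score is `NA`
#' (a sentinel, not an error).
#'
#' @param tbl_subset An [interaction_table()] or a row subset of one (e.g.
#'   the rows of a trait level).
#' @param specialist_id,generalist_id Parasitoid column labels.
#' @return List with `score` (mean relative parasitism, `NA` if not
#'   applicable), `n_shared`, and `shared_hosts`.
#' @export
pair_mean_relative_parasitism <- function(tbl_subset, specialist_id,
                                          generalist_id) {
  m <- unclass(tbl_subset)
  s <- m[, specialist_id]
  g <- m[, generalist_id]
  shared <- s > 0L & g > 0L
  if (!any(shared)) {
    return(list(score = NA_real_, n_shared = 0L, shared_hosts = character()))
  }
  p <- s[shared] / (s[shared] + g[shared])
  list(score = mean(p), n_shared = sum(shared),
       shared_hosts = rownames(m)[shared])
}

# npairs x naphids matrix of the specialist's relative parasitism per host;
# NA where the host is not shared by the pair. Drives both the observed
# trait-level scores and the bootstrap replicates.
.pair_share_fractions <- function(tbl, pairs) {
  m <- unclass(tbl)
  P <- matrix(NA_real_, nrow(pairs), nrow(m),
              dimnames = list(NULL, rownames(m)))
  for (k in seq_len(nrow(pairs))) {
    s <- m[, pairs$specialist_id[k]]
    g <- m[, pairs$generalist_id[k]]
    shared <- s > 0L & g > 0L
    P[k, shared] <- s[shared] / (s[shared] + g[shared])
  }
  P
}

# Mean score over applicable pairs given aphid columns idx (possibly with
# multiplicity, as under row resampling). Returns NA when no pair applies.
.mean_score_from_fractions <- function(P, idx) {
  if (!length(idx)) return(NA_real_)
  sub <- P[, idx, drop = FALSE]
  k <- rowSums(!is.na(sub))
  ok <- k > 0L
  if (!any(ok)) return(NA_real_)
  mean(rowSums(sub, na.rm = TRUE)[ok] / k[ok])
}

#' Mean specialist score for one trait level
#'
#' Restricts the web to the aphids carrying the trait level (species with a
#' missing value for the trait are excluded), evaluates
#' [pair_mean_relative_parasitism()] for every enumerated pair on that
#' subset, and averages the applicable pairs without weighting.
#'
#' @param tbl An [interaction_table()] (full filtered web).
#' @param traits A [trait_table()].
#' @param trait Trait name; `level` one level or several pooled levels.
#' @param level Trait level(s) defining the subset.
#' @param indices Output of [host_range_indices()].
#' @param which Index defining host range: `"sr"` or `"psv"`.
#' @param designation `"full"` (default): specialist/generalist labels come
#'   from indices on the full web; `"subset"`: indices are recomputed on the
#'   trait-level subset before pairing (sensitivity analysis).
#' @param C Host correlation matrix; only needed for
#'   `designation = "subset"` with `which = "psv"`.
#' @param pairs Optional precomputed [enumerate_pairs()] result (full-web
#'   designation only).
#' @return List with `trait`, `level`, `index_used`, `mean_score`,
#'   `n_pairs` (applicable pairs; 0 with `mean_score = NA` when none apply)
#'   and `n_species`.
#' @export
trait_level_mean_score <- function(tbl, traits, trait, level, indices,
                                   which = c("sr", "psv"),
                                   designation = c("full", "subset"),
                                   C = NULL, pairs = NULL) {
  which <- match.arg(which)
  designation <- match.arg(designation)
  ids <- .level_members(traits, trait, level, rownames(tbl))
  label <- paste(level, collapse = "+")
  if (!length(ids))
    stop(sprintf("no qualifying species for trait '%s' level '%s'", trait, label))
  if (designation == "subset") {
    sub <- tbl[ids, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0L, drop = FALSE]
    sub <- structure(sub, class = c("interaction_table", "matrix", "array"))
    if (which == "psv" && is.null(C))
      stop("subset designation with PSV requires the host correlation matrix C")
    idx_sub <- if (which == "psv") host_range_indices(sub, C) else {
      data.frame(parasitoid_id = colnames(sub),
                 sr = colSums(sub > 0L), psv = NA_real_,
                 stringsAsFactors = FALSE)
    }
    pairs <- enumerate_pairs(sub, idx_sub, which)
    P <- .pair_share_fractions(sub, pairs)
    idx <- seq_len(nrow(sub))
  } else {
    if (is.null(pairs)) pairs <- enumerate_pairs(tbl, indices, which)
    P <- .pair_share_fractions(tbl, pairs)
    idx <- match(ids, rownames(tbl))
  }
  if (!nrow(pairs)) {
    return(list(trait = trait, level = label, index_used = which,
                mean_score = NA_real_, n_pairs = 0L, n_species = length(ids)))
  }
  sub <- P[, idx, drop = FALSE]
  k <- rowSums(!is.na(sub))
  ok <- k > 0L
  score <- if (any(ok)) mean(rowSums(sub, na.rm = TRUE)[ok] / k[ok]) else NA_real_
  list(trait = trait, level = label, index_used = which,
       mean_score = score, n_pairs = sum(ok), n_species = length(ids))
}
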