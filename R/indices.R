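#' Taxonomic correlation matrix among hosts
#'
#' Relatedness between two species is the proportion of shared leading
#' lineage segments out of `L + 1` equal segments, where `L` is the number
#' of taxonomic ranks and the extra terminal segment represents the species
#' level (shared only by a species with itself). Two species in the same
#' genus under `L = 4` ranks therefore have correlation 4/5; species in
#' different families have correlation 0; the diagonal is 1. Per-segment
#' weights can be overridden.
#'
#' @param tax A [taxonomy_table()].
#' @param weights Optional positive weights for the `L + 1` lineage
#'   segments, coarse to fine, terminal species segment last. Default: equal
#'   weights.
#' @return Object of class `host_correlation`: a symmetric matrix with unit
#'   diagonal and entries in `[0, 1]`, row/column names the aphid species.
#' @export
#' @examples
#' tax <- taxonomy_table(data.frame(
#'   aphid_id = c("A", "B", "C"),
#'   family = c("F1", "F1", "F2"), subfamily = c("S1", "S1", "S2"),
#'   tribe = c("T1", "T1", "T2"), genus = c("G1", "G1", "G2")))
#' taxonomic_correlation(tax)
taxonomic_correlation <- function(tax, weights = NULL) {
  stopifnot(inherits(tax, "taxonomy_table"))
  n <- nrow(tax)
  L <- ncol(tax) - 1L
  if (is.null(weights)) weights <- rep(1, L + 1L)
  if (length(weights) != L + 1L || any(weights <= 0))
    stop("weights must be ", L + 1L, " positive values (one per rank plus the terminal species segment)")
  w <- weights / sum(weights)
  C <- matrix(0, n, n, dimnames = list(tax$aphid_id, tax$aphid_id))
  agree <- matrix(TRUE, n, n)
  for (k in seq_len(L)) {
    rk <- tax[[k + 1L]]
    agree <- agree & outer(rk, rk, "==")
    C <- C + w[k] * agree
  }
  diag(C) <- 1
  structure(C, class = c("host_correlation", "matrix", "array"))
}

#' Host species richness of a parasitoid
#'
#' The number of host species from which the parasitoid was reared: the
#' count of positive cells in its column of the interaction table.
#'
#' @param tbl An [interaction_table()].
#' @param parasitoid_id Column label.
#' @return Integer host count.
#' @export
host_range_sr <- function(tbl, parasitoid_id) {
  stopifnot(inherits(tbl, "interaction_table"))
  if (!parasitoid_id %in% colnames(tbl))
    stop("unknown parasitoid: ", parasitoid_id)
  sum(tbl[, parasitoid_id] > 0L)
}

#' Phylogenetic species variability of a parasitoid's hosts
#'
#' PSV over the `n` host species of the parasitoid (presence-only; counts do
#' not enter): `1 -` the mean pairwise taxonomic correlation among hosts,
#' equivalently `(n * trace(C) - sum(C)) / (n * (n - 1))` on the host
#' submatrix of `C`. A parasitoid with a single host gets PSV 0 by
#' convention (maximally specialized); `single_host = "exclude"` returns
#' `NA` instead for sensitivity analyses.
#'
#' @param tbl An [interaction_table()].
#' @param C A [taxonomic_correlation()] matrix covering all hosts.
#' @param parasitoid_id Column label.
#' @param single_host `"zero"` (default) or `"exclude"`.
#' @return PSV in `[0, 1]` (or `NA` for single-host parasitoids under
#'   `"exclude"`).
#' @export
host_psv <- function(tbl, C, parasitoid_id, single_host = c("zero", "exclude")) {
  single_host <- match.arg(single_host)
  stopifnot(inherits(tbl, "interaction_table"))
  if (!parasitoid_id %in% colnames(tbl))
    stop("unknown parasitoid: ", parasitoid_id)
  hosts <- rownames(tbl)[tbl[, parasitoid_id] > 0L]
  missing <- setdiff(hosts, rownames(C))
  if (length(missing))
    stop("host missing from correlation matrix: ", paste(missing, collapse = ", "))
  n <- length(hosts)
  if (n == 1L) return(if (single_host == "zero") 0 else NA_real_)
  Cs <- C[hosts, hosts]
  (n * sum(diag(Cs)) - sum(Cs)) / (n * (n - 1))
}

#' Host-range index table for all parasitoids
#'
#' @inheritParams host_psv
#' @return Data frame with columns `parasitoid_id`, `sr`, `psv`.
#' @export
host_range_indices <- function(tbl, C, single_host = c("zero", "exclude")) {
  single_host <- match.arg(single_host)
  ids <- colnames(tbl)
  data.frame(
    parasitoid_id = ids,
    sr = vapply(ids, function(p) host_range_sr(tbl, p), integer(1L)),
    psv = vapply(ids, function(p) host_psv(tbl, C, p, single_host), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.index_vector <- function(indices, which = c("sr", "psv")) {
  which <- match.arg(which)
  stats::setNames(as.numeric(indices[[which]]), indices$parasitoid_id)
}

#' Abundance-weighted specialization of an aphid's parasitoid assemblage
#'
#' For one aphid species, the sum over its parasitoids of the parasitoid's
#' specialization index times its relative abundance on that aphid:
#' `sum_j S_j * A_j`, with `A_j = count[aphid, j] / sum_j count[aphid, j]`.
#'
#' @param tbl An [interaction_table()].
#' @param indices Output of [host_range_indices()].
#' @param aphid_id Row label.
#' @param which Which index to weight: `"sr"` or `"psv"`.
#' @return The weighted mean index (a scalar).
#' @export
assemblage_weighted_specialization <- function(tbl, indices, aphid_id,
                                               which = c("sr", "psv")) {
  which <- match.arg(which)
  if (!aphid_id %in% rownames(tbl)) stop("unknown aphid: ", aphid_id)
  row <- tbl[aphid_id, ]
  if (sum(row) == 0L) stop("no parasitoids attack aphid '", aphid_id, "'")
  S <- .index_vector(indices, which)[colnames(tbl)]
  sum(S * row / sum(row), na.rm = FALSE)
}

#' Assemblage specialization for every aphid
#'
#' @inheritParams assemblage_weighted_specialization
#' @return Data frame with columns `aphid_id`, `w_sr`, `w_psv`.
#' @export
assemblage_table <- function(tbl, indices) {
  A <- unclass(tbl) / rowSums(tbl)
  data.frame(
    aphid_id = rownames(tbl),
    w_sr = as.numeric(A %*% .index_vector(indices, "sr")[colnames(tbl)]),
    w_psv = as.numeric(A %*% .index_vector(indices, "psv")[colnames(tbl)]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Mean assemblage specialization for one trait level
#'
#' Unweighted mean of [assemblage_weighted_specialization()] over the aphids
#' carrying a given trait level; species with a missing value for the trait
#' are excluded from that trait's analysis.
#'
#' @inheritParams assemblage_weighted_specialization
#' @param traits A [trait_table()].
#' @param trait Trait name.
#' @param level One level, or several levels pooled into one group.
#' @return List with `mean`, `n_species`, and the species used.
#' @export
trait_level_mean_assemblage <- function(tbl, traits, indices, trait, level,
                                        which = c("sr", "psv")) {
  which <- match.arg(which)
  ids <- .level_members(traits, trait, level, rownames(tbl))
  if (!length(ids))
    stop(sprintf("no qualifying species for trait '%s' level '%s'",
                 trait, paste(level, collapse = "+")))
  W <- vapply(ids, function(a)
    assemblage_weighted_specialization(tbl, indices, a, which), numeric(1L))
  list(mean = mean(W), n_species = length(ids), aphid_ids = ids)
}

# Species at a trait level (or pooled levels), restricted to the web and
# excluding missing trait values.
.level_members <- function(traits, trait, level, web_ids) {
  if (!trait %in% names(traits)) stop("unknown trait: ", trait)
  vocab <- aphid_trait_levels()[[trait]]
  bad <- setdiff(level, vocab)
  if (length(bad)) stop(sprintf("unknown level '%s' for trait '%s'", bad[1L], trait))
  val <- traits[[trait]][match(web_ids, traits$aphid_id)]
  web_ids[!is.na(val) & val %in% level]
}
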