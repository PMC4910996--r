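#' Construct an interaction table
#'
#' An interaction table is a non-negative integer matrix of reared
#' individuals with aphid (host) species as rows and parasitoid species as
#' columns. All-zero rows and columns are dropped so that every retained
#' species takes part in at least one interaction.
#'
#' @param counts Numeric matrix with row names (aphid species) and column
#'   names (parasitoid species); cells are counts of reared individuals.
#' @return Object of class `interaction_table` (an integer matrix).
#' @export
#' @examples
#' m <- matrix(c(5, 0, 2, 0, 7, 2), nrow = 3,
#'             dimnames = list(paste0("A", 1:3), c("P1", "P2")))
#' interaction_table(m)
interaction_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("interaction matrix must have aphid row names and parasitoid column names")
  dup_r <- rownames(counts)[duplicated(rownames(counts))]
  dup_c <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_r)) stop("duplicate aphid label: ", dup_r[1L])
  if (length(dup_c)) stop("duplicate parasitoid label: ", dup_c[1L])
  if (anyNA(counts)) counts[is.na(counts)] <- 0
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative or non-integer count at row '%s', column '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  }
  storage.mode(counts) <- "integer"
  counts <- counts[rowSums(counts) > 0L, colSums(counts) > 0L, drop = FALSE]
  structure(counts, class = c("interaction_table", "matrix", "array"))
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("interaction_table: %d aphid x %d parasitoid species, %d individuals\n",
              nrow(x), ncol(x), sum(x)))
  note <- attr(x, "note")
  if (!is.null(note)) cat("note:", note, "\n")
  invisible(x)
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # comma-separated with a semicolon fallback (supplementary CSVs vary)
  l1 <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(l1, gregexpr(";", l1))) >
             lengths(regmatches(l1, gregexpr(",", l1)))) ";" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL, fileEncoding = "UTF-8",
                    comment.char = "")
}

#' Read an aphid x parasitoid count matrix from CSV
#'
#' Expects a header row of parasitoid labels and a first column of aphid
#' labels; blank cells are read as zero. Comma- and semicolon-delimited
#' files are both accepted.
#'
#' @param path Path to the CSV file.
#' @return An [interaction_table()].
#' @export
read_interaction_table <- function(path) {
  df <- .read_delim_auto(path)
  if (ncol(df) < 2L) stop("no interactions: need at least one parasitoid column")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  colnames(m) <- names(df)[-1L]   # data-frame subsetting deduplicates names
  m[m == "" | is.na(m)] <- "0"
  suppressWarnings(storage.mode(m) <- "numeric")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("non-numeric count at row '%s', column '%s'",
                 ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  rownames(m) <- ids
  if (sum(m) == 0) stop("no interactions: count matrix is empty")
  interaction_table(m)
}

#' Write an interaction table to CSV
#'
#' @param tbl An [interaction_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(tbl, path) {
  df <- data.frame(aphid_id = rownames(tbl), as.data.frame(unclass(tbl)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a taxonomy table
#'
#' Per-aphid ranked lineage, ordered from the coarsest rank (e.g. family) to
#' the finest (e.g. genus). All species must have complete lineages of the
#' same length.
#'
#' @param df Data frame whose first column is `aphid_id` and remaining
#'   columns are ranks ordered coarse to fine.
#' @return Object of class `taxonomy_table` (a data frame).
#' @export
taxonomy_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxonomy needs an aphid_id column plus at least one rank")
  names(df)[1L] <- "aphid_id"
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$aphid_id))
    stop("duplicate aphid label in taxonomy: ",
         df$aphid_id[duplicated(df$aphid_id)][1L])
  ranks <- df[, -1L, drop = FALSE]
  miss <- which(is.na(ranks) | ranks == "", arr.ind = TRUE)
  if (nrow(miss)) {
    stop(sprintf("missing rank value '%s' for species '%s'",
                 names(ranks)[miss[1L, 2L]], df$aphid_id[miss[1L, 1L]]))
  }
  rownames(df) <- NULL
  structure(df, class = c("taxonomy_table", "data.frame"))
}

#' Read an aphid taxonomy table from CSV
#'
#' @param path Path to the CSV file (aphid_id column plus one column per
#'   rank, coarse to fine).
#' @param interactions Optional [interaction_table()]; if given, every aphid
#'   in it must be present in the taxonomy.
#' @return A [taxonomy_table()].
#' @export
read_taxonomy_table <- function(path, interactions = NULL) {
  tax <- taxonomy_table(.read_delim_auto(path))
  if (!is.null(interactions)) {
    missing <- setdiff(rownames(interactions), tax$aphid_id)
    if (length(missing))
      stop("aphids present in interactions but absent from taxonomy: ",
           paste(missing, collapse = ", "))
  }
  tax
}

#' @export
#' @rdname taxonomy_table
#' @param tbl A `taxonomy_table`.
write_taxonomy_table <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a trait table
#'
#' Per-aphid categorical values for the ten traits of
#' [aphid_trait_levels()]; missing values are allowed and retained. Level
#' strings are normalised case-insensitively to the canonical vocabulary
#' (synonyms such as "weak" mobility or "obligate" ant attendance are
#' mapped); an undeclared level is a hard error.
#'
#' @param df Data frame with an `aphid_id` column plus one column per trait.
#' @return Object of class `trait_table`: a data frame whose trait columns
#'   are factors on the declared levels.
#' @export
trait_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  names(df)[1L] <- "aphid_id"
  df$aphid_id <- as.character(df$aphid_id)
  if (anyDuplicated(df$aphid_id))
    stop("duplicate aphid label in traits: ",
         df$aphid_id[duplicated(df$aphid_id)][1L])
  vocab <- aphid_trait_levels()
  missing_tr <- setdiff(names(vocab), names(df))
  if (length(missing_tr))
    stop("trait table lacks columns: ", paste(missing_tr, collapse = ", "))
  for (tr in names(vocab)) {
    val <- as.character(df[[tr]])
    bad <- tryCatch(.normalize_trait_value(tr, val), error = function(e) e)
    if (inherits(bad, "error")) {
      x <- tolower(trimws(val))
      syn <- .trait_level_synonyms[[tr]]
      if (!is.null(syn)) x[x %in% names(syn)] <- syn[x[x %in% names(syn)]]
      i <- which(!is.na(x) & x != "" & !(x %in% vocab[[tr]]))[1L]
      stop(sprintf("unknown level '%s' for trait '%s' in species '%s'",
                   val[i], tr, df$aphid_id[i]))
    }
    df[[tr]] <- bad
  }
  df <- df[, c("aphid_id", names(vocab))]
  rownames(df) <- NULL
  structure(df, class = c("trait_table", "data.frame"))
}

#' Read an aphid trait table from CSV
#'
#' @param path Path to the CSV file; empty cells are read as missing.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path) {
  trait_table(.read_delim_auto(path))
}

#' @export
#' @rdname trait_table
#' @param tbl A `trait_table`.
#' @param path Output path.
write_trait_table <- function(tbl, path) {
  df <- as.data.frame(tbl)
  df[] <- lapply(df, as.character)
  df[is.na(df)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove poorly sampled interactions
#'
#' Cells with a positive count below `min_count` are set to zero (the
#' boundary is kept: "fewer than" is strict), and aphid rows or parasitoid
#' columns left without any interaction are dropped. The input is not
#' modified.
#'
#' @param tbl An [interaction_table()].
#' @param min_count Minimum number of reared individuals for an interaction
#'   to be retained (default 5).
#' @return A new, filtered [interaction_table()]. If nothing survives, an
#'   empty table is returned with attribute `note =
#'   "no interactions survive filtering"`.
#' @export
#' @examples
#' m <- matrix(c(4, 5, 0, 12), 2, dimnames = list(c("A1","A2"), c("P1","P2")))
#' filter_rare_interactions(interaction_table(m), min_count = 5)
filter_rare_interactions <- function(tbl, min_count = 5L) {
  stopifnot(inherits(tbl, "interaction_table"), min_count >= 1)
  m <- unclass(tbl)
  m[m > 0L & m < min_count] <- 0L
  keep_r <- rowSums(m) > 0L
  keep_c <- colSums(m) > 0L
  m <- m[keep_r, keep_c, drop = FALSE]
  out <- structure(m, class = c("interaction_table", "matrix", "array"))
  if (length(m) == 0L || sum(m) == 0L)
    attr(out, "note") <- "no interactions survive filtering"
  out
}

#' Export a taxonomy as a Newick tree
#'
#' Builds the rank-nested tree implied by the lineages (internal nodes are
#' rank values, tips are species) with unit branch lengths, and returns it
#' as an [ape::phylo] object or writes it to file.
#'
#' @param tax A [taxonomy_table()].
#' @param path Optional output path; if given the tree is written with
#'   [ape::write.tree()].
#' @return An `ape` phylo object (invisibly, if `path` is given).
#' @export
taxonomy_newick <- function(tax, path = NULL) {
  stopifnot(inherits(tax, "taxonomy_table"))
  build <- function(ids, depth) {
    ranks <- ncol(tax) - 1L
    if (depth > ranks) {
      return(paste0(gsub("[ ,():;]", "_", tax$aphid_id[ids]), ":1",
                    collapse = ","))
    }
    vals <- tax[[depth + 1L]][ids]
    parts <- vapply(split(ids, vals), function(sub) {
      lab <- gsub("[ ,():;]", "_", tax[[depth + 1L]][sub[1L]])
      sprintf("(%s)%s:1", build(sub, depth + 1L), lab)
    }, character(1L))
    paste0(parts, collapse = ",")
  }
  nwk <- sprintf("(%s);", build(seq_len(nrow(tax)), 1L))
  tree <- ape::read.tree(text = nwk)
  if (!is.null(path)) {
    ape::write.tree(tree, file = path)
    return(invisible(tree))
  }
  tree
}
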