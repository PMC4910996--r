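#' Specification for a synthetic aphid-parasitoid study
#'
#' Defaults emulate the structure of a large multi-country rearing survey:
#' 142 aphid species in a rank-structured taxonomy, 75 parasitoid species,
#' a mean of 20 reared individuals per realized link (so the default
#' rare-interaction filter removes only a small tail), ten categorical
#' traits with a few percent missing values, and an even mix of
#' taxonomically clustered specialists and broad generalists.
#'
#' @param n_aphids,n_parasitoids Species numbers on the two web levels.
#' @param n_families,genera_per_family Shape of the 4-rank host taxonomy
#'   (family / subfamily / tribe / genus).
#' @param breadth_mix List with `p_specialist` (proportion of taxonomically
#'   clustered, narrow-range parasitoids), `specialist_max_sr` (their host
#'   ranges are uniform on 1..this) and `generalist_mean_sr` (Poisson mean
#'   host range of the broad parasitoids, minimum 2).
#' @param advantage `NULL`, or `list(trait =, level =, delta =)`: counts of
#'   below-median-PSV parasitoids on hosts at that trait level are
#'   multiplied by `delta >= 1` (their host sets, hence SR and PSV, are
#'   untouched, keeping identity and performance orthogonal).
#' @param trait_association List of
#'   `list(trait_a =, level_a =, trait_b =, level_b =, odds =)` entries;
#'   for species with `level_a`, the probability of `level_b` is tilted by
#'   the odds multiplier (traits are generated in vocabulary order, so
#'   `trait_a` must precede `trait_b`).
#' @param missing_rate Probability that any trait cell is masked, missing
#'   completely at random; must be below 0.5.
#' @param base_count Poisson mean of reared individuals per realized link
#'   (zero-truncated, so every link has at least one individual).
#' @param seed Integer seed; all generators are fully deterministic given
#'   the spec.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_aphids = 142L, n_parasitoids = 75L,
                            n_families = 4L, genera_per_family = 5L,
                            breadth_mix = list(p_specialist = 0.5,
                                               specialist_max_sr = 2L,
                                               generalist_mean_sr = 8),
                            advantage = NULL,
                            trait_association = list(),
                            missing_rate = 0.02,
                            base_count = 20,
                            seed = 1L) {
  stopifnot(n_aphids >= 1L, n_parasitoids >= 1L, n_families >= 1L,
            genera_per_family >= 1L, base_count > 0,
            missing_rate >= 0, missing_rate < 0.5)
  if (!is.null(advantage)) {
    stopifnot(is.list(advantage), advantage$delta >= 1,
              advantage$trait %in% names(aphid_trait_levels()),
              advantage$level %in% aphid_trait_levels()[[advantage$trait]])
  }
  structure(list(n_aphids = as.integer(n_aphids),
                 n_parasitoids = as.integer(n_parasitoids),
                 n_families = as.integer(n_families),
                 genera_per_family = as.integer(genera_per_family),
                 breadth_mix = breadth_mix, advantage = advantage,
                 trait_association = trait_association,
                 missing_rate = missing_rate, base_count = base_count,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a rank-structured aphid taxonomy
#'
#' Species are nested in genera, tribes (two genera per tribe), one
#' subfamily per family, and families. Each family receives at least one
#' species; the rest are assigned to uniformly random genera.
#'
#' @param spec A [simulation_spec()].
#' @return A [taxonomy_table()] with ranks family, subfamily, tribe, genus.
#' @export
simulate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_aphids
  Fam <- spec$n_families
  gpf <- spec$genera_per_family
  if (n < Fam)
    stop(sprintf("impossible nesting: %d species cannot cover %d families", n, Fam))
  G <- Fam * gpf
  genus_family <- rep(seq_len(Fam), each = gpf)
  genus_within <- rep(seq_len(gpf), times = Fam)
  genus_tribe <- paste0("Tribe_", genus_family, "_", ceiling(genus_within / 2))
  .with_seed(spec$seed, {
    g <- c((seq_len(Fam) - 1L) * gpf + 1L,       # one species per family first
           sample.int(G, n - Fam, replace = TRUE))
    taxonomy_table(data.frame(
      aphid_id = sprintf("Aphid_%03d", seq_len(n)),
      family = paste0("Fam_", genus_family[g]),
      subfamily = paste0("Subfam_", genus_family[g]),
      tribe = genus_tribe[g],
      genus = paste0("Genus_", genus_family[g], "_", genus_within[g]),
      stringsAsFactors = FALSE))
  })
}

#' Simulate a categorical aphid trait table
#'
#' Trait levels are drawn with roughly uniform marginals; pairwise
#' associations listed in the spec tilt the conditional odds of the target
#' level; cells are then masked completely at random at the spec's missing
#' rate.
#'
#' @param tax A [taxonomy_table()] (supplies the species list).
#' @param spec A [simulation_spec()].
#' @return A [trait_table()].
#' @export
simulate_traits <- function(tax, spec) {
  stopifnot(inherits(tax, "taxonomy_table"), inherits(spec, "simulation_spec"))
  vocab <- aphid_trait_levels()
  n <- nrow(tax)
  .with_seed(spec$seed + 1L, {
    df <- data.frame(aphid_id = tax$aphid_id, stringsAsFactors = FALSE)
    for (tr in names(vocab)) {
      lv <- vocab[[tr]]
      probs <- matrix(1 / length(lv), n, length(lv),
                      dimnames = list(NULL, lv))
      for (as_ in spec$trait_association) {
        if (!identical(as_$trait_b, tr)) next
        if (!as_$trait_a %in% names(df))
          stop(sprintf("association %s -> %s: '%s' must be generated first",
                       as_$trait_a, tr, as_$trait_a))
        hit <- !is.na(df[[as_$trait_a]]) & df[[as_$trait_a]] == as_$level_a
        probs[hit, as_$level_b] <- probs[hit, as_$level_b] * as_$odds
      }
      probs <- probs / rowSums(probs)
      u <- stats::runif(n)
      cum <- t(apply(probs, 1L, cumsum))
      pick <- 1L + rowSums(u > cum)
      df[[tr]] <- lv[pick]
    }
    if (spec$missing_rate > 0) {
      for (tr in names(vocab)) {
        mask <- stats::runif(n) < spec$missing_rate
        # keep at least 2 observed levels per trait
        if (mean(mask) < 0.5) df[[tr]][mask] <- NA
      }
    }
    trait_table(df)
  })
}

# zero-truncated Poisson via inverse CDF
.rtpois <- function(m, lambda) {
  u <- stats::runif(m, stats::ppois(0L, lambda), 1)
  stats::qpois(u, lambda)
}

#' Simulate an aphid-parasitoid interaction web
#'
#' Each parasitoid draws a host-range size from the breadth mix; specialist
#' parasitoids choose taxonomically clustered hosts (a genus, widened to
#' tribe and family only if needed), generalists choose hosts uniformly.
#' Reared counts per realized link are zero-truncated Poisson with mean
#' `base_count`. If the spec injects a specialist advantage, counts of
#' below-median-PSV parasitoids on hosts at the focal trait level are
#' multiplied by `delta` (and rounded), leaving every host set — and
#' therefore SR and PSV — unchanged.
#'
#' @param tax A [taxonomy_table()].
#' @param traits A [trait_table()] (only needed when an advantage is
#'   injected).
#' @param spec A [simulation_spec()].
#' @return An [interaction_table()].
#' @export
simulate_web <- function(tax, traits, spec) {
  stopifnot(inherits(tax, "taxonomy_table"), inherits(spec, "simulation_spec"))
  n <- nrow(tax)
  np <- spec$n_parasitoids
  bm <- spec$breadth_mix
  genus <- tax$genus
  tribe <- tax$tribe
  family <- tax$family
  .with_seed(spec$seed + 2L, {
    m <- matrix(0L, n, np,
                dimnames = list(tax$aphid_id,
                                sprintf("Para_%03d", seq_len(np))))
    is_spec <- stats::runif(np) < bm$p_specialist
    for (j in seq_len(np)) {
      if (is_spec[j]) {
        sr <- sample.int(bm$specialist_max_sr, 1L)
        focal <- sample.int(n, 1L)
        pool <- which(genus == genus[focal])
        if (length(pool) < sr) pool <- which(tribe == tribe[focal])
        if (length(pool) < sr) pool <- which(family == family[focal])
        sr <- min(sr, length(pool))
        hosts <- if (length(pool) == 1L) pool else sample(pool, sr)
      } else {
        sr <- min(n, 2L + stats::rpois(1L, max(bm$generalist_mean_sr - 2, 0)))
        hosts <- sample.int(n, sr)
      }
      m[hosts, j] <- .rtpois(length(hosts), spec$base_count)
    }
    breadth_class <- ifelse(is_spec, "specialist", "generalist")
    names(breadth_class) <- colnames(m)
    if (!is.null(spec$advantage)) {
      adv <- spec$advantage
      tbl0 <- interaction_table(m)
      C <- taxonomic_correlation(tax)
      idx <- host_range_indices(tbl0, C)
      psv_all <- stats::setNames(idx$psv, idx$parasitoid_id)[colnames(m)]
      boosted <- !is.na(psv_all) & psv_all < stats::median(psv_all, na.rm = TRUE)
      val <- traits[[adv$trait]][match(rownames(m), traits$aphid_id)]
      focal_rows <- !is.na(val) & val == adv$level
      block <- m[focal_rows, boosted, drop = FALSE]
      m[focal_rows, boosted] <- as.integer(pmax(round(block * adv$delta),
                                                (block > 0L) * 1L))
    }
    out <- interaction_table(m)
    attr(out, "breadth_class") <- breadth_class[colnames(out)]
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Taxonomy, traits and web from one spec, plus the ground truth needed to
#' score recovery (injected advantage, injected associations, which
#' parasitoids were generated as clustered specialists).
#'
#' @param spec A [simulation_spec()].
#' @return List with `taxonomy`, `traits`, `web`, `spec`, `ground_truth`.
#' @export
simulate_study <- function(spec = simulation_spec()) {
  tax <- simulate_taxonomy(spec)
  traits <- simulate_traits(tax, spec)
  web <- simulate_web(tax, traits, spec)
  list(taxonomy = tax, traits = traits, web = web, spec = spec,
       ground_truth = list(advantage = spec$advantage,
                           trait_association = spec$trait_association,
                           breadth_class = attr(web, "breadth_class"),
                           seed = spec$seed))
}
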