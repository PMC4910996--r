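#' Canonical aphid trait vocabulary
#'
#' The ten categorical aphid traits used throughout the package, with their
#' declared levels. Traits describe colony structure (concealment,
#' aggregation, ant attendance, wax), individual defence and size (mobility,
#' body size), and host-plant/habitat use (life cycle, diet breadth, habitat
#' specialization, habitat disturbance).
#'
#' @return Named list; each element is the character vector of admissible
#'   levels for that trait, in canonical order.
#' @export
#' @examples
#' names(aphid_trait_levels())
#' aphid_trait_levels()$ant_attendance
aphid_trait_levels <- function() {
  list(
    concealment            = c("exposed", "semi-concealed"),
    colony_aggregation     = c("dense", "sparse"),
    ant_attendance         = c("absent", "facultative", "obligatory"),
    mobility               = c("low", "high"),
    wax                    = c("absent", "present"),
    body_size              = c("large", "medium", "small"),
    life_cycle             = c("heteroecious", "monoecious"),
    diet_breadth           = c("monophagous", "oligophagous", "polyphagous"),
    habitat_specialization = c("specialist", "generalist"),
    habitat_disturbance    = c("semi-natural", "agricultural")
  )
}

# Synonyms accepted on input and mapped to canonical levels (normalisation is
# case-insensitive; these cover common printed variants such as "weak"
# mobility or "obligate" ant attendance).
.trait_level_synonyms <- list(
  mobility       = c(weak = "low"),
  ant_attendance = c(obligate = "obligatory"),
  concealment    = c("semiconcealed" = "semi-concealed",
                     "semi_concealed" = "semi-concealed"),
  habitat_disturbance = c("seminatural" = "semi-natural",
                          "semi_natural" = "semi-natural")
)

.normalize_trait_value <- function(trait, value) {
  lv <- aphid_trait_levels()[[trait]]
  x <- tolower(trimws(value))
  x[x == ""] <- NA_character_
  syn <- .trait_level_synonyms[[trait]]
  if (!is.null(syn)) {
    hit <- x %in% names(syn)
    x[hit] <- syn[x[hit]]
  }
  bad <- !is.na(x) & !(x %in% lv)
  if (any(bad)) {
    stop(sprintf("unknown level '%s' for trait '%s'",
                 value[bad][1L], trait), call. = FALSE)
  }
  factor(x, levels = lv)
}
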