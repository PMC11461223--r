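#' NEO-PI-R scale catalog
#'
#' The Five-Factor Model battery analysed by this package: 5 domains, each
#' with 6 facets (30 facets, 35 scales in total). Facets are scored from 8
#' five-point Likert items (0--4), so a facet score lies in \[0, 32\] and a
#' domain score (48 items) in \[0, 192\]. The catalog fixes the canonical
#' analysis order: each domain followed by its six facets.
#'
#' @return A `data.frame` with one row per scale and columns
#'   `scale` (display name), `domain`, `type` (`"domain"` or `"facet"`),
#'   `column` (the cohort CSV column name, `neo_*`), `min`, `max`.
#' @examples
#' cat35 <- neoScales()
#' nrow(cat35)          # 35
#' table(cat35$type)    # 5 domains, 30 facets
#' @export
neoScales <- function() {
  domains <- c("Neuroticism", "Extraversion", "Openness",
               "Agreeableness", "Conscientiousness")
  facets <- list(
    Neuroticism = c("Anxiety", "Hostility", "Depression",
                    "Self-consciousness", "Impulsiveness", "Vulnerability"),
    Extraversion = c("Warmth", "Gregariousness", "Assertiveness",
                     "Activity", "Excitement seeking", "Positive emotions"),
    Openness = c("Fantasy", "Aesthetics", "Feelings",
                 "Actions", "Ideas", "Values"),
    Agreeableness = c("Trust", "Straightforwardness", "Altruism",
                      "Compliance", "Modesty", "Tender mindedness"),
    Conscientiousness = c("Competence", "Order", "Dutifulness",
                          "Achievement striving", "Self-discipline",
                          "Deliberation"))
  rows <- lapply(domains, function(d) {
    data.frame(
      scale  = c(d, facets[[d]]),
      domain = d,
      type   = c("domain", rep("facet", 6L)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$column <- paste0("neo_", .canonScaleName(out$scale))
  out$min <- 0L
  out$max <- ifelse(out$type == "domain", 192L, 32L)
  out
}

# canonical snake_case key for a scale display name
.canonScaleName <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(x)))
}

#' Resolve scale names against the catalog
#'
#' Case-insensitive canonicalisation of scale names (display names or
#' `neo_*` column names) to catalog column names. Unknown scales are an
#' error rather than being dropped, so a battery can never silently shrink.
#'
#' @param scales character vector of scale names.
#' @return character vector of `neo_*` column names, same length.
#' @export
resolveScales <- function(scales) {
  cat35 <- neoScales()
  key <- .canonScaleName(sub("^neo_", "", scales))
  idx <- match(key, .canonScaleName(cat35$scale))
  if (anyNA(idx)) {
    stop("unknown NEO-PI-R scale(s): ",
         paste(scales[is.na(idx)], collapse = ", "))
  }
  cat35$column[idx]
}
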