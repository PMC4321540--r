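#' Load the habitat classification lexicon
#'
#' Reads the controlled vocabulary (wet-habitat keywords, well-drained soil
#' keywords, and the water-score mapping) from a YAML file. The packaged
#' default maps Hydrophyte = 5, Helophyte = 4, Mesophyte = 3, Xerophyte = 1
#' and lists the wetland/soil trigger terms used by [classify_habitat()].
#'
#' @param path Optional path to a custom YAML lexicon.
#' @return A list with elements `wet`, `arid` (character vectors) and
#'   `water_score` (named numeric).
#' @export
habitat_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "habitat_lexicon.yaml", package = "leafwater")
  }
  lex <- yaml::read_yaml(path)
  if (!all(c("wet", "arid", "water_score") %in% names(lex))) {
    abort("lexicon must define `wet`, `arid` and `water_score`.")
  }
  lex$water_score <- unlist(lex$water_score)
  lex
}

#' Water score and range from flora moisture descriptors
#'
#' Maps each flora descriptor to its numeric water-availability value
#' (Hydrophyte = 5, Helophyte = 4, Mesophyte = 3, Xerophyte = 1, giving equal
#' weight to the extremes) and summarises a species' descriptor list as its
#' mean (`water_score`) and spread (`water_range = max - min`).
#'
#' @param descriptors Character vector of descriptors for one species.
#' @param lexicon A lexicon from [habitat_lexicon()].
#' @return A one-row tibble with `water_score` and `water_range`.
#' @examples
#' water_score(c("Mesophyte", "Xerophyte")) # score 2, range 2
#' @export
water_score <- function(descriptors, lexicon = habitat_lexicon()) {
  if (length(descriptors) == 0) abort("empty descriptor list.")
  map <- lexicon$water_score
  unknown <- setdiff(descriptors, names(map))
  if (length(unknown)) {
    abort(sprintf(
      "unknown descriptor(s) %s; valid terms: %s",
      paste(unknown, collapse = ", "), paste(names(map), collapse = ", ")
    ))
  }
  vals <- map[descriptors]
  tibble::tibble(
    water_score = mean(vals),
    water_range = max(vals) - min(vals)
  )
}

#' Classify a species' habitat water availability
#'
#' Applies the three-way rule used for floras: `wet` if any habitat keyword
#' names a wetland, bog, swamp, river or other water body; otherwise `arid`
#' if the species occurs on well-drained soils described as sandy, stony,
#' gravelly or rocky; otherwise `intermediate` (open grasslands or
#' woodlands). Precedence is wet > arid > intermediate, and matching is on
#' word stems anywhere in the free-text keywords.
#'
#' @param keywords Character vector of habitat phrases for one species.
#' @param lexicon A lexicon from [habitat_lexicon()].
#' @return `"wet"`, `"arid"` or `"intermediate"`.
#' @examples
#' classify_habitat("swamps") # "wet"
#' classify_habitat("open grassland") # "intermediate"
#' @export
classify_habitat <- function(keywords, lexicon = habitat_lexicon()) {
  if (length(keywords) == 0) return("intermediate")
  text <- tolower(paste(keywords, collapse = " "))
  hit <- function(terms) {
    any(vapply(
      terms,
      function(tm) grepl(tm, text, fixed = TRUE),
      logical(1)
    ))
  }
  if (hit(tolower(lexicon$wet))) return("wet")
  if (hit(tolower(lexicon$arid))) return("arid")
  "intermediate"
}

#' Species climate niche from occurrence records
#'
#' Averages the mean annual temperature and precipitation over all
#' occurrence records of each species (unweighted arithmetic means), giving
#' one realized-niche value per species.
#'
#' @param records Data frame with columns `species`, `mat` (degrees C) and
#'   `map` (mm), one row per occurrence.
#' @return A tibble with one row per species: `species`, `mat`, `map`,
#'   `n_records`.
#' @examples
#' climate_niche(tibble::tibble(
#'   species = "a", mat = c(17, 19), map = c(700, 900)
#' ))
#' @export
climate_niche <- function(records) {
  need <- c("species", "mat", "map")
  if (!all(need %in% names(records))) {
    abort(paste("`records` needs columns:", paste(need, collapse = ", ")))
  }
  records |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      mat = mean(.data$mat), map = mean(.data$map),
      n_records = dplyr::n(), .groups = "drop"
    )
}
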