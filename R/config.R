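#' Read item codings from a YAML block configuration
#'
#' The configuration maps each thematic block to its items and each item to
#' its admissible integer analysis codes (polarity-aligned: within every
#' block a higher code means a worse situation). Items may additionally
#' declare a `recode` map (raw code -> analysis code) and `missing_codes`.
#'
#' @param path Path to a YAML file shaped like the shipped
#'   `share_covid_items.yaml` (see `system.file("extdata",
#'   "share_covid_items.yaml", package = "surveyprofiles")`).
#' @return A tibble with one row per item: `name`, `block`, `codes`
#'   (list-column of admissible integer codes), `recode` (list-column of
#'   named maps or `NULL`), `missing_codes` (list-column).
#' @export
#' @examples
#' codings <- covid_item_codings()
#' dplyr::count(codings, block)
read_item_codings <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$blocks)) abort("Config must have a top-level `blocks` entry.")
  rows <- purrr::imap(cfg$blocks, function(items, block) {
    purrr::imap(items, function(def, item) {
      codes <- as.integer(def$codes)
      if (length(codes) < 2L) {
        abort(paste0("Item `", item, "` must have at least two admissible codes."))
      }
      recode <- def$recode
      if (!is.null(recode)) {
        recode <- setNames(as.integer(unlist(recode)), names(recode))
        if (anyDuplicated(recode)) {
          abort(paste0("Recode map for `", item, "` must be a bijection."))
        }
      }
      tibble::tibble(
        name = item, block = block,
        codes = list(codes),
        recode = list(recode),
        missing_codes = list(as.integer(def$missing_codes %||% integer()))
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Item codings for the shipped COVID-era survey instrument
#'
#' Thirty-five polarity-aligned items grouped into nine thematic blocks
#' (general health, physical health, mental health, staying at home,
#' practice of safety measures, social contact, electronic social contact,
#' direct COVID experience, healthcare access).
#'
#' @return A tibble of item codings; see [read_item_codings()].
#' @export
covid_item_codings <- function() {
  read_item_codings(system.file("extdata", "share_covid_items.yaml",
    package = "surveyprofiles", mustWork = TRUE
  ))
}

#' Composite-indicator specifications from item codings
#'
#' One specification per thematic block: the ordered item list and the
#' theoretical minimum/maximum block sum implied by the admissible codes.
#' Indicators are block sums rescaled to 0-10 over this theoretical range
#' (not the observed range), so the scale is dataset-independent.
#'
#' @param codings An item-codings tibble, by default the shipped instrument.
#' @return A tibble with one row per indicator: `name`, `variables`
#'   (list-column of item names, in block order), `raw_min`, `raw_max`.
#' @export
#' @examples
#' indicator_specs()
indicator_specs <- function(codings = covid_item_codings()) {
  specs <- codings |>
    dplyr::group_by(block) |>
    dplyr::summarise(
      variables = list(name),
      raw_min = sum(vapply(codes, min, integer(1))),
      raw_max = sum(vapply(codes, max, integer(1))),
      .groups = "drop"
    ) |>
    dplyr::rename(name = block)
  # preserve instrument block order, not alphabetical
  specs[match(unique(codings$block), specs$name), , drop = FALSE]
}

#' Default descriptive-variable labels for the synthetic generator
#'
#' 27 country labels (the EU Member States except Austria, plus Israel),
#' two genders and the three age groups used to describe respondents aged
#' 50 or over.
#'
#' @name descriptive-labels
#' @return Character vectors of category labels.
#' @export
eu_country_labels <- function() {
  c(
    "Belgium", "Bulgaria", "Croatia", "Cyprus", "Czech Republic", "Denmark",
    "Estonia", "Finland", "France", "Germany", "Greece", "Hungary", "Ireland",
    "Israel", "Italy", "Latvia", "Lithuania", "Luxembourg", "Malta",
    "Netherlands", "Poland", "Portugal", "Romania", "Slovakia", "Slovenia",
    "Spain", "Sweden"
  )
}

#' @rdname descriptive-labels
#' @export
default_age_groups <- function() c("50-65", "66-80", "80+")

#' @rdname descriptive-labels
#' @export
default_genders <- function() c("female", "male")
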