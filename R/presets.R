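#' Shipped innovation presets
#'
#' Eight innovation parameter sets ship with the package, covering five
#' health conditions across the prevention/diagnosis/treatment continuum:
#'
#' | preset | condition | mechanism |
#' |---|---|---|
#' | `oxytocin_new_formulation` | postpartum hemorrhage | coverage expansion |
#' | `ubt` | postpartum hemorrhage | second-line treatment |
#' | `odon` | obstructed labor | coverage expansion |
#' | `chlorhexidine` | neonatal sepsis | mortality reduction |
#' | `diarrhea_treatment` | diarrhea | adherence boost (ORS +15pp) |
#' | `water_chlorinator` | diarrhea | incidence reduction |
#' | `pulse_oximeter` | pneumonia | diagnostic improvement |
#' | `rr_monitor` | pneumonia | diagnostic improvement |
#'
#' Presets are stored as JSON under `inst/extdata/presets/` and parsed with
#' [read_innovation_spec()]; nothing about a mechanism is hard-coded to an
#' innovation name.
#'
#' @param name Preset identifier; see `preset_names()`.
#' @return `builtin_preset()` returns an [innovation_spec()];
#'   `preset_names()` the available identifiers.
#' @export
#' @examples
#' preset_names()
#' builtin_preset("chlorhexidine")
builtin_preset <- function(name) {
  available <- preset_names()
  if (length(name) != 1L || !name %in% available) {
    abort(sprintf(
      "Unknown preset '%s'. Available presets: %s.",
      paste(name, collapse = ", "), paste(available, collapse = ", ")
    ))
  }
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "mnchimpact", mustWork = TRUE)
  read_innovation_spec(path)
}

#' @rdname builtin_preset
#' @export
preset_names <- function() {
  dir <- system.file("extdata", "presets", package = "mnchimpact", mustWork = TRUE)
  sort(sub("\\.json$", "", list.files(dir, pattern = "\\.json$")))
}

#' Roster adjustment for chlorhexidine
#'
#' Chlorhexidine cord care targets home births in countries with a neonatal
#' mortality rate of at least 30 per 1000 live births, so its modeled country
#' roster differs slightly from the common roster: Angola, Botswana,
#' Equatorial Guinea, Gabon, Afghanistan, and Djibouti are added, while
#' Bhutan, Indonesia, North Korea, and Sri Lanka are dropped.
#'
#' @param roster Character vector of ISO-3166 alpha-3 country codes.
#' @return Adjusted roster (sorted, unique).
#' @export
#' @examples
#' adjust_roster_chlorhexidine(c("IDN", "NGA", "LKA"))
adjust_roster_chlorhexidine <- function(roster) {
  add <- c("AGO", "BWA", "GNQ", "GAB", "AFG", "DJI")
  drop <- c("BTN", "IDN", "PRK", "LKA")
  sort(unique(setdiff(union(roster, add), drop)))
}
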