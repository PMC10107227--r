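#' @keywords internal
"_PACKAGE"

## Two-letter codes of the 12 focal species, in ascending order of mean body
## mass. This ordering is total (no mass ties), so "immediately adjacent in
## size" is well defined for the relative size schemas.
CO_SPECIES_CODES <- c("DH", "WB", "WE", "OC", "BH", "RB",
                      "CF", "YC", "ME", "SC", "BY", "RG")

## The 11 standard zone codes of the observation site.
CO_ZONES <- c("1A", "1B", "1C", "2A", "2B", "2C",
              "3A", "3B", "3B1", "3B2", "3C")

#' Attribute table for the 12 focal parrot species
#'
#' Returns the species-attribute table used throughout the package: two-letter
#' code, common name, mean body mass (g), clade/shape class, large-macaw flag,
#' plumage colour classes (majority back colour, rear head colour, distinctive
#' face colour) and a three-level size class. The categorical columns define
#' the absolute categorization schemas; `mass_g` defines the relative ones
#' (larger/smaller and similar-size) as well as the mass-difference edge test.
#'
#' Mean masses for the smallest (DH, 108 g) and largest (RG, 1250 g) species
#' are fixed; the remaining ten defaults are handbook-style means chosen to be
#' strictly increasing in the order DH < WB < WE < OC < BH < RB < CF < YC <
#' ME < SC < BY < RG, and can be overridden per species.
#'
#' @param mass_overrides optional named numeric vector of masses in grams,
#'   names being species codes, replacing the package defaults.
#' @return a `data.frame` with one row per species (row names are the codes)
#'   and columns `code`, `common_name`, `mass_g`, `clade`, `large_macaw`,
#'   `back_colour`, `head_colour`, `face_colour`, `size_class`.
#' @examples
#' attrs <- species_attributes()
#' attrs["BH", "clade"]
#' @export
species_attributes <- function(mass_overrides = NULL) {
  attrs <- data.frame(
    code = CO_SPECIES_CODES,
    common_name = c("dusky-headed parakeet", "white-bellied parrot",
                    "white-eyed parakeet", "orange-cheeked parrot",
                    "blue-headed parrot", "red-bellied macaw",
                    "chestnut-fronted macaw", "yellow-crowned parrot",
                    "mealy parrot", "scarlet macaw",
                    "blue-and-yellow macaw", "red-and-green macaw"),
    mass_g = c(108, 155, 157, 165, 234, 314, 360, 440, 626, 1015, 1125, 1250),
    clade = c("parakeet", "small parrot", "parakeet", "small parrot",
              "small parrot", "small macaw", "small macaw", "large parrot",
              "large parrot", "large macaw", "large macaw", "large macaw"),
    large_macaw = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    back_colour = c("green", "green", "green", "green", "green", "green",
                    "green", "green", "green", "red", "blue", "red"),
    head_colour = c("green", "orange", "green", "black", "blue", "green",
                    "green", "green", "green", "red", "blue", "red"),
    face_colour = c("green-grey", "orange", "green-grey", "yellow", "blue",
                    "white", "white", "yellow", "green-grey", "white",
                    "white", "white"),
    size_class = c("small", "small", "small", "small", "small", "medium",
                   "medium", "medium", "medium", "large", "large", "large"),
    stringsAsFactors = FALSE
  )
  rownames(attrs) <- attrs$code
  if (!is.null(mass_overrides)) {
    if (is.null(names(mass_overrides)) ||
        !all(names(mass_overrides) %in% attrs$code)) {
      stop("mass_overrides must be named with valid species codes")
    }
    attrs[names(mass_overrides), "mass_g"] <- as.numeric(mass_overrides)
  }
  validate_species_attributes(attrs)
  attrs
}

#' Validate a species-attribute table
#'
#' Checks the invariants the pipeline relies on: exactly the 12 focal codes,
#' positive masses, DH the lightest and RG the heaviest species, and a total
#' (tie-free) mass ordering so size adjacency is well defined.
#'
#' @param attrs a species-attribute table as from [species_attributes()].
#' @return `attrs`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_species_attributes <- function(attrs) {
  needed <- c("code", "common_name", "mass_g", "clade", "large_macaw",
              "back_colour", "head_colour", "face_colour", "size_class")
  missing <- setdiff(needed, names(attrs))
  if (length(missing) > 0) {
    stop("species attribute table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (nrow(attrs) != 12L || !setequal(attrs$code, CO_SPECIES_CODES) ||
      anyDuplicated(attrs$code) > 0) {
    stop("species attribute table must contain exactly the 12 focal codes: ",
         paste(CO_SPECIES_CODES, collapse = ", "))
  }
  if (any(!is.finite(attrs$mass_g)) || any(attrs$mass_g <= 0)) {
    stop("all mass_g values must be positive and finite")
  }
  if (anyDuplicated(attrs$mass_g) > 0) {
    stop("mass_g values must be distinct (size ordering must be total)")
  }
  if (attrs$code[which.min(attrs$mass_g)] != "DH") {
    stop("DH must be the lightest species")
  }
  if (attrs$code[which.max(attrs$mass_g)] != "RG") {
    stop("RG must be the heaviest species")
  }
  invisible(attrs)
}

#' Read a species-attribute table from CSV
#'
#' The file must contain the columns of [species_attributes()]; `large_macaw`
#' may be written as TRUE/FALSE or yes/no.
#'
#' @param path path to a CSV file.
#' @return a validated species-attribute table.
#' @export
read_species_attributes <- function(path) {
  attrs <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("large_macaw" %in% names(attrs) && is.character(attrs$large_macaw)) {
    attrs$large_macaw <- tolower(attrs$large_macaw) %in% c("true", "yes", "y")
  }
  rownames(attrs) <- attrs$code
  validate_species_attributes(attrs)
  attrs[CO_SPECIES_CODES[CO_SPECIES_CODES %in% attrs$code], , drop = FALSE]
}

#' Standard zone codes
#'
#' @return character vector of the 11 standard zone codes.
#' @export
standard_zones <- function() CO_ZONES

#' Focal species codes
#'
#' @return character vector of the 12 focal species codes, in ascending order
#'   of default mean body mass.
#' @export
focal_species <- function() CO_SPECIES_CODES
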