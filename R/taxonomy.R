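#' Build a species -> genus -> family taxonomy map
#'
#' The genus of a binomial defaults to its first whitespace-delimited token;
#' a lookup table can override the genus of individual species and must
#' supply the family of each genus (families cannot be derived from
#' binomials).
#'
#' @param species character vector of species binomials (tree tips).
#' @param genus_of optional data frame with columns `species`, `genus`
#'   overriding the first-token rule for the listed species.
#' @param family_of data frame with columns `genus`, `family` assigning each
#'   genus to a family. Genera absent from the table get `NA` family;
#'   [divergence_table()] refuses such gaps.
#' @return a data frame of class `taxonomy_map` with columns `species`,
#'   `genus`, `family`.
#' @export
taxonomy_map <- function(species, family_of = NULL, genus_of = NULL) {
  species <- normalize_names(species)
  if (anyDuplicated(species)) {
    stop("duplicated species names: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  genus <- vapply(strsplit(species, " ", fixed = TRUE), `[[`, character(1), 1L)
  if (!is.null(genus_of)) {
    .check_cols(genus_of, c("species", "genus"), "genus_of")
    i <- match(normalize_names(genus_of$species), species)
    if (anyNA(i)) {
      stop("genus_of lists species not in 'species': ",
           paste(genus_of$species[is.na(i)], collapse = ", "))
    }
    genus[i] <- normalize_names(genus_of$genus)
  }
  family <- rep(NA_character_, length(species))
  if (!is.null(family_of)) {
    .check_cols(family_of, c("genus", "family"), "family_of")
    fg <- normalize_names(family_of$genus)
    if (anyDuplicated(fg)) stop("family_of maps some genus twice")
    family <- normalize_names(family_of$family)[match(genus, fg)]
  }
  structure(data.frame(species = species, genus = genus, family = family,
                       stringsAsFactors = FALSE),
            class = c("taxonomy_map", "data.frame"))
}

#' Tips belonging to a taxon
#'
#' @param taxonomy a [taxonomy_map()].
#' @param rank `"genus"` or `"family"`.
#' @param name taxon name.
#' @return character vector of species (tip) names.
#' @export
taxon_tips <- function(taxonomy, rank = c("genus", "family"), name) {
  rank <- match.arg(rank)
  taxonomy$species[!is.na(taxonomy[[rank]]) & taxonomy[[rank]] == name]
}

.check_cols <- function(df, cols, what) {
  if (!is.data.frame(df) || !all(cols %in% names(df))) {
    stop("'", what, "' must be a data frame with columns ",
         paste(cols, collapse = ", "))
  }
}
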