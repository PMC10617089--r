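#' Read a county-level occurrence table
#'
#' A CSV with columns `species`, `county`; duplicate records are collapsed.
#'
#' @param path path to the CSV.
#' @return data frame with columns `species`, `county`, one row per
#'   distinct (species, county) pair.
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_occurrences(occ)
}

#' Coerce/validate an occurrence table
#'
#' @param occ data frame with columns `species`, `county`.
#' @return deduplicated occurrence data frame.
#' @export
as_occurrences <- function(occ) {
  .check_cols(occ, c("species", "county"), "occ")
  occ$species <- normalize_names(occ$species)
  occ$county <- trimws(as.character(occ$county))
  drop <- is.na(occ$county) | occ$county == ""
  if (any(drop)) {
    warning(sum(drop), " occurrence records without a county dropped")
    occ <- occ[!drop, ]
  }
  unique(occ[, c("species", "county")])
}

#' Define a focal region
#'
#' @param name region name.
#' @param counties character vector of member county identifiers.
#' @param subregions optional named list of character vectors of counties,
#'   each a subset of `counties` (floristic subregions).
#' @return a list of class `region` with `name`, `counties`, `subregions`.
#' @export
region_definition <- function(name, counties, subregions = NULL) {
  counties <- unique(trimws(as.character(counties)))
  if (length(counties) == 0) stop("region has no counties")
  if (!is.null(subregions)) {
    if (is.null(names(subregions)) || any(!nzchar(names(subregions)))) {
      stop("subregions must be a named list")
    }
    subregions <- lapply(subregions, function(s) unique(trimws(as.character(s))))
    bad <- names(subregions)[!vapply(subregions, function(s)
      all(s %in% counties), logical(1))]
    if (length(bad)) {
      stop("subregion counties not contained in the region: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(name = name, counties = counties,
                 subregions = subregions), class = "region")
}

#' Read a region definition from YAML
#'
#' Expected keys: `name`, `counties` (list), optional `subregions` (mapping
#' of subregion name to a county list).
#'
#' @param path path to the YAML file.
#' @return a [region_definition()].
#' @export
read_region <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$name) || is.null(y$counties)) {
    stop("region YAML must define 'name' and 'counties'")
  }
  region_definition(y$name, unlist(y$counties),
                    subregions = y$subregions)
}

#' Identify endemic species by the range-fraction rule
#'
#' A species is endemic to the region when at least a fraction `threshold`
#' (default 90%) of its distribution range lies inside the region. The
#' range is operationalized as the set of distinct occupied counties, so
#' the fraction is `|counties in region| / |counties|`; the boundary case
#' is inclusive (9 of 10 counties qualifies at the default threshold).
#'
#' @param occ an occurrence table (see [as_occurrences()]).
#' @param region a [region_definition()], or a character vector of counties.
#' @param threshold endemism threshold in `(0, 1]`.
#' @return data frame with one row per species: `species`, `n_counties`,
#'   `n_in_region`, `fraction`, `endemic`.
#' @export
endemic_species <- function(occ, region, threshold = 0.9) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  occ <- as_occurrences(occ)
  counties <- if (inherits(region, "region")) region$counties else region
  n_tot <- tapply(occ$county, occ$species, function(x) length(unique(x)))
  n_in <- tapply(occ$county, occ$species,
                 function(x) length(unique(x[x %in% counties])))
  sp <- names(n_tot)
  frac <- as.numeric(n_in) / as.numeric(n_tot)
  out <- data.frame(species = sp, n_counties = as.integer(n_tot),
                    n_in_region = as.integer(n_in), fraction = frac,
                    endemic = frac >= threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$species), , drop = FALSE]
}

#' Genus confinement derived from pooled member-species occurrences
#'
#' Pools the counties of all member species of each genus and applies the
#' same range-fraction rule as [endemic_species()]. Used as the default
#' confinement source for [endemic_genera()] when no curated flag table is
#' supplied.
#'
#' @param occ occurrence table.
#' @param taxonomy a [taxonomy_map()] (species to genus).
#' @param region a [region_definition()] or character vector of counties.
#' @param threshold confinement threshold in `(0, 1]`.
#' @return named logical vector: genus -> confined to the region?
#' @export
genus_confinement <- function(occ, taxonomy, region, threshold = 0.9) {
  occ <- as_occurrences(occ)
  counties <- if (inherits(region, "region")) region$counties else region
  g <- taxonomy$genus[match(occ$species, taxonomy$species)]
  keep <- !is.na(g)
  occ <- occ[keep, ]; g <- g[keep]
  n_tot <- tapply(occ$county, g, function(x) length(unique(x)))
  n_in <- tapply(occ$county, g,
                 function(x) length(unique(x[x %in% counties])))
  out <- as.numeric(n_in) / as.numeric(n_tot) >= threshold
  names(out) <- names(n_tot)
  out
}

#' Identify endemic genera
#'
#' A genus is endemic when its Wu distribution type is 14 (East Asia) or 15
#' (Endemic to China) AND it is confined to the focal region. Confinement
#' comes from a curated flag table when available, otherwise derive it with
#' [genus_confinement()].
#'
#' @param assignments a [classify_genera()] result.
#' @param confinement named logical vector (genus -> confined). Every
#'   type-14/15 genus must be covered.
#' @return character vector of endemic genus names.
#' @export
endemic_genera <- function(assignments, confinement) {
  cand <- assignments$genus[assignments$type %in% c(14L, 15L)]
  missing <- setdiff(cand, names(confinement))
  if (length(missing)) {
    stop("no confinement flag for type-14/15 genera: ",
         paste(missing, collapse = ", "))
  }
  cand[confinement[cand]]
}

#' Per-bin divergence statistics of endemic taxa
#'
#' Restricts a divergence table to a set of endemic taxon names of the
#' given rank and bins their ages like [bin_counts()]; percentages are
#' relative to the number of endemics with an age in the tree. Endemic
#' names absent from the divergence table are reported via a message and
#' excluded.
#'
#' @param div a [divergence_table()].
#' @param endemic character vector of endemic taxon names.
#' @param scale a [make_timescale()] object.
#' @param rank `"genus"` or `"species"`.
#' @param include_root include `at_root` rows.
#' @return as [bin_counts()]; zero endemics give an empty (0-row) table
#'   with a warning.
#' @export
endemic_divergence_stats <- function(div, endemic, scale,
                                     rank = c("genus", "species"),
                                     include_root = TRUE) {
  rank <- match.arg(rank)
  endemic <- unique(normalize_names(endemic))
  rows <- div[div$rank == rank, ]
  absent <- setdiff(endemic, rows$name)
  if (length(absent)) {
    message(length(absent), " endemic ", rank,
            " name(s) absent from the divergence table: ",
            paste(absent, collapse = ", "))
  }
  sub <- div[div$rank == rank & div$name %in% endemic, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no endemic ", rank, " with divergence ages; empty table")
    out <- data.frame(bin = character(0), old_bound = numeric(0),
                      young_bound = numeric(0), count = integer(0),
                      percentage = numeric(0), rate = numeric(0))
    return(out)
  }
  bin_counts(sub, scale, rank = rank, include_root = include_root)
}
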