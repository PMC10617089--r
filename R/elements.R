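#' Wu's 15 areal distribution types
#'
#' The standard areal types used to classify the geographic distribution of
#' genera of the Chinese flora, together with the grouping used throughout
#' this package: type 1 is widespread; types 2-7 are tropical; types 8-15
#' are temperate, subdivided into northern temperate (8-11), Tethys (12-13)
#' and East Asian (14-15) elements.
#'
#' @return a data frame with columns `type` (1-15), `label`, `group`
#'   (widespread/tropical/temperate), `element` (widespread/tropical/
#'   northern_temperate/tethys/east_asian).
#' @export
wu_types <- function() {
  labels <- c(
    "Cosmopolitan",
    "Pantropic",
    "Tropical Asia and Tropical America disjunct",
    "Old World Tropics",
    "Tropical Asia to Tropical Australasia",
    "Tropical Asia to Tropical Africa",
    "Tropical Asia (Indo-Malaysian)",
    "North Temperate",
    "East Asia and North America disjunct",
    "Old World Temperate",
    "Temperate Asia",
    "Mediterranean, West Asia to Central Asia",
    "Central Asia",
    "East Asia",
    "Endemic to China"
  )
  data.frame(type = 1:15, label = labels,
             group = .type_group(1:15), element = .type_element(1:15),
             stringsAsFactors = FALSE)
}

.type_group <- function(type) {
  ifelse(type == 1, "widespread",
         ifelse(type <= 7, "tropical", "temperate"))
}

.type_element <- function(type) {
  ifelse(type == 1, "widespread",
  ifelse(type <= 7, "tropical",
  ifelse(type <= 11, "northern_temperate",
  ifelse(type <= 13, "tethys", "east_asian"))))
}

#' Classify genera into floristic elements
#'
#' Maps each genus, via its Wu distribution type, to a group (widespread /
#' tropical / temperate) and an element (widespread / tropical /
#' northern_temperate / tethys / east_asian). Overrides take precedence
#' over the default type mapping and are logged via a message.
#'
#' @param type_table data frame with columns `genus`, `type` (integers
#'   1-15); typically read from a TSV.
#' @param genera optional character vector restricting/ordering the output;
#'   defaults to all genera in `type_table`. Genera absent from the table
#'   are an error unless `skip_unclassified = TRUE`, in which case they are
#'   dropped with a message.
#' @param overrides optional data frame from [load_overrides()] with columns
#'   `genus`, `group` and optionally `element`.
#' @param skip_unclassified drop (and report) genera missing from the type
#'   table instead of erroring.
#' @return a data frame of class `element_assignment` with columns `genus`,
#'   `type`, `group`, `element`, `overridden`.
#' @export
classify_genera <- function(type_table, genera = NULL, overrides = NULL,
                            skip_unclassified = FALSE) {
  .check_cols(type_table, c("genus", "type"), "type_table")
  tg <- normalize_names(type_table$genus)
  if (anyDuplicated(tg)) {
    stop("type table lists some genus twice: ",
         paste(unique(tg[duplicated(tg)]), collapse = ", "))
  }
  ty <- as.integer(type_table$type)
  if (anyNA(ty) || any(ty < 1 | ty > 15)) {
    stop("distribution types must be integers in 1..15")
  }
  if (is.null(genera)) genera <- tg
  genera <- normalize_names(genera)
  i <- match(genera, tg)
  if (anyNA(i)) {
    missing <- genera[is.na(i)]
    if (!skip_unclassified) {
      stop("genera without a distribution type: ",
           paste(missing, collapse = ", "),
           " (use skip_unclassified = TRUE to drop them)")
    }
    message(length(missing), " genera without a distribution type skipped")
    genera <- genera[!is.na(i)]
    i <- i[!is.na(i)]
  }
  out <- data.frame(genus = genera, type = ty[i],
                    group = .type_group(ty[i]), element = .type_element(ty[i]),
                    overridden = FALSE, stringsAsFactors = FALSE)
  if (!is.null(overrides) && nrow(overrides) > 0) {
    og <- normalize_names(overrides$genus)
    j <- match(og, tg)
    if (anyNA(j)) {
      stop("override references genera absent from the type table: ",
           paste(og[is.na(j)], collapse = ", "))
    }
    k <- match(og, out$genus)
    keep <- !is.na(k)
    if (any(keep)) {
      out$group[k[keep]] <- overrides$group[keep]
      el <- if ("element" %in% names(overrides)) overrides$element[keep] else NA
      # element defaults to the group's natural element when not given
      out$element[k[keep]] <- ifelse(!is.na(el) & nzchar(el), el,
                                     ifelse(overrides$group[keep] == "temperate",
                                            out$element[k[keep]],
                                            overrides$group[keep]))
      out$overridden[k[keep]] <- TRUE
      message(sum(keep), " genera reassigned by overrides: ",
              paste(og[keep], collapse = ", "))
    }
  }
  class(out) <- c("element_assignment", "data.frame")
  out
}

#' Load an element-classification override file
#'
#' A TSV with header and columns `genus`, `group` (one of widespread,
#' tropical, temperate) and optionally `element`. Two example files
#' resolving the classification of *Calcareoboea*, *Craspedolobium*,
#' *Malania*, *Musella* and *Whytockia* — whose placement between the
#' tropical and temperate elements is ambiguous — ship with the package;
#' see [element_overrides_file()].
#'
#' @param path path to the TSV.
#' @return data frame with columns `genus`, `group` (and `element` if
#'   present), ready for [classify_genera()].
#' @export
load_overrides <- function(path) {
  if (!file.exists(path)) stop("override file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    return(data.frame(genus = character(0), group = character(0),
                      element = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(parts[[1L]])
  if (!all(c("genus", "group") %in% header)) {
    stop("override file must have tab-separated columns 'genus' and 'group'")
  }
  rows <- parts[-1L]
  if (length(rows) == 0) {
    out <- as.data.frame(matrix(character(0), ncol = length(header),
                                dimnames = list(NULL, header)),
                         stringsAsFactors = FALSE)
    return(out)
  }
  bad <- which(lengths(rows) != length(header))
  if (length(bad)) {
    stop("malformed override row at line ", bad[1L] + 1L, " of ", path,
         ": expected ", length(header), " fields, got ", lengths(rows)[bad[1L]])
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  valid <- c("widespread", "tropical", "temperate")
  badg <- which(!df$group %in% valid)
  if (length(badg)) {
    stop("invalid group '", df$group[badg[1L]], "' at line ", badg[1L] + 1L,
         " of ", path, " (expected one of ", paste(valid, collapse = ", "), ")")
  }
  df$genus <- normalize_names(df$genus)
  df
}

#' Path to a bundled element override file
#'
#' @param which `"tropical"` or `"temperate"`: the direction in which the
#'   five ambiguous Chinese-endemic genera are reassigned. There is no
#'   default applied anywhere in the package; the analysis configuration
#'   must pick a direction explicitly (or apply no override).
#' @return file path inside the installed package.
#' @export
element_overrides_file <- function(which = c("tropical", "temperate")) {
  which <- match.arg(which)
  system.file("extdata", paste0("revise_to_", which, ".tsv"),
              package = "floristics", mustWork = TRUE)
}
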