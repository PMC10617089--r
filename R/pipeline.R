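#' Run the full flora-assembly pipeline from a configuration
#'
#' Orchestrates every stage — input (or synthetic generation), pruning,
#' divergence extraction, element classification, binning, trajectory, and
#' endemism — and writes the standard output tables plus a manifest. All
#' outputs are staged in a temporary directory and moved into `out_dir`
#' only on success, so a failing run leaves no partial outputs. Outputs are
#' deterministic: identical configuration and inputs give byte-identical
#' CSVs.
#'
#' The configuration (YAML file or list) either names input files —
#' `tree` (Newick/Nexus), `taxonomy` (TSV: species, genus, family),
#' `type_table` (TSV: genus, type), optional `species_list`, `overrides`,
#' `occurrences` (CSV: species, county), `region` (YAML) — or contains a
#' `synthetic:` block with a mandatory `seed` and any [simulate_flora()]
#' parameter, in which case the inputs are generated and their ground truth
#' is written alongside the results. Analysis settings (`bin_width`,
#' `trajectory_width`, `endemic_threshold`, `temperate_includes_type15`,
#' `skip_unclassified`, `include_root`, `allow_nonultrametric`,
#' `tree_format`) may be given at the top level; function arguments
#' override config values.
#'
#' @param config path to a YAML file, or a named list.
#' @param out_dir output directory; created if needed.
#' @param ... settings overriding the config (e.g. `endemic_threshold`).
#' @return the [flora_assembly()] object, invisibly, with attribute
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, ...) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  } else {
    cfg_dir <- getwd()
  }
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  dots <- list(...)
  config[names(dots)] <- dots

  setting <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(cfg_dir, p)
  }

  synthetic <- config$synthetic
  flora <- NULL
  if (!is.null(synthetic)) {
    if (is.null(synthetic$seed)) stop("synthetic mode requires a seed")
    flora <- do.call(simulate_flora, synthetic)
    tree <- flora$tree
    taxonomy <- flora$taxonomy
    type_table <- flora$type_table
    occurrences <- flora$occurrences
    region <- flora$region
  } else {
    # validate all inputs before producing any output
    for (key in c("tree", "taxonomy", "type_table")) {
      if (is.null(config[[key]])) stop("config lacks required input: ", key)
      if (!file.exists(resolve(config[[key]]))) {
        stop("input file for '", key, "' not found: ", config[[key]])
      }
    }
    for (key in c("species_list", "overrides", "occurrences", "region")) {
      if (!is.null(config[[key]]) && !file.exists(resolve(config[[key]]))) {
        stop("input file for '", key, "' not found: ", config[[key]])
      }
    }
    tree <- read_dated_tree(resolve(config$tree),
                            format = setting("tree_format", "newick"),
                            allow_nonultrametric =
                              setting("allow_nonultrametric", FALSE))
    tax_df <- utils::read.delim(resolve(config$taxonomy),
                                stringsAsFactors = FALSE)
    .check_cols(tax_df, c("species", "genus", "family"), "taxonomy")
    if (!is.null(config$species_list)) {
      keep <- readLines(resolve(config$species_list))
      keep <- keep[nzchar(trimws(keep))]
      tree <- prune_to_taxa(tree, keep)
    }
    taxonomy <- taxonomy_map(
      tax_df$species,
      family_of = unique(tax_df[, c("genus", "family")]),
      genus_of = tax_df[, c("species", "genus")])
    taxonomy <- taxonomy[taxonomy$species %in% tree$phylo$tip.label, ]
    type_table <- utils::read.delim(resolve(config$type_table),
                                    stringsAsFactors = FALSE)
    occurrences <- if (!is.null(config$occurrences)) {
      read_occurrences(resolve(config$occurrences))
    }
    region <- if (!is.null(config$region)) read_region(resolve(config$region))
  }
  overrides <- if (!is.null(config$overrides)) {
    load_overrides(resolve(config$overrides))
  }

  fa <- flora_assembly(
    tree, taxonomy, type_table, overrides = overrides,
    occurrences = occurrences, region = region,
    bin_width = setting("bin_width", 5),
    trajectory_width = setting("trajectory_width", 10),
    endemic_threshold = setting("endemic_threshold", 0.9),
    temperate_includes_type15 = setting("temperate_includes_type15", TRUE),
    skip_unclassified = setting("skip_unclassified", FALSE),
    include_root = setting("include_root", TRUE))

  # stage outputs, then move atomically on success
  stage <- tempfile("floristics_out_")
  dir.create(stage)
  wcsv <- function(df, name) {
    utils::write.csv(as.data.frame(df), file.path(stage, name),
                     row.names = FALSE)
  }
  wcsv(fa$divergence, "divergence.csv")
  for (rk in c("family", "genus", "species")) {
    wcsv(fa$bins[[rk]]$fixed, paste0("bins_", rk, "_fixed.csv"))
    wcsv(fa$bins[[rk]]$geological, paste0("bins_", rk, "_geological.csv"))
  }
  wcsv(fa$assignments, "element_assignments.csv")
  wcsv(fa$trajectory$fixed, "element_trajectory_fixed.csv")
  wcsv(fa$trajectory$geological, "element_trajectory_geological.csv")
  if (!is.null(fa$endemism)) {
    wcsv(fa$endemism$species, "endemic_species.csv")
    wcsv(data.frame(genus = fa$endemism$genera), "endemic_genera.csv")
    wcsv(fa$endemism$species_stats$fixed, "endemic_species_bins_fixed.csv")
    wcsv(fa$endemism$species_stats$geological,
         "endemic_species_bins_geological.csv")
    if (!is.null(fa$endemism$genus_stats)) {
      wcsv(fa$endemism$genus_stats$fixed, "endemic_genus_bins_fixed.csv")
      wcsv(fa$endemism$genus_stats$geological,
           "endemic_genus_bins_geological.csv")
    }
  }
  if (!is.null(flora)) write_flora_dataset(flora, file.path(stage, "inputs"))
  manifest <- list(
    package = "floristics",
    package_version = as.character(utils::packageVersion("floristics")),
    r_version = R.version.string,
    config = config,
    crossover_mya = fa$crossover_mya,
    n = list(families = sum(fa$divergence$rank == "family"),
             genera = sum(fa$divergence$rank == "genus"),
             species = sum(fa$divergence$rank == "species"),
             classified_genera = nrow(fa$assignments),
             endemic_species = if (is.null(fa$endemism)) NULL else
               sum(fa$endemism$species$endemic),
             endemic_genera = if (is.null(fa$endemism)) NULL else
               length(fa$endemism$genera)))
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage, recursive = TRUE)) {
    dir.create(dirname(file.path(out_dir, f)), recursive = TRUE,
               showWarnings = FALSE)
    file.copy(file.path(stage, f), file.path(out_dir, f), overwrite = TRUE)
  }
  unlink(stage, recursive = TRUE)
  attr(fa, "out_dir") <- out_dir
  invisible(fa)
}

#' Path to the bundled synthetic demo configuration
#'
#' A ready-to-run [run_pipeline()] configuration in synthetic mode.
#'
#' @return file path inside the installed package.
#' @export
demo_config_file <- function() {
  system.file("extdata", "demo_config.yaml", package = "floristics",
              mustWork = TRUE)
}
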