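#' Build a timescale of contiguous age bins
#'
#' Bins are half-open intervals `(old, young]` on the Mya axis, ordered old
#' to young, jointly covering `[0, oldest]`; an age equal to the oldest
#' bound falls in the oldest bin and age 0 falls in the youngest bin, so
#' the bins partition all admissible ages.
#'
#' `kind = "fixed"` gives equal-width bins from `start` down to 0 (default
#' five-million-year windows from 145 Mya, the base of the Cretaceous). If
#' `start` is not a multiple of `width` it is raised to the next multiple
#' with a warning. `kind = "geological"` gives the period-level
#' International Chronostratigraphic timescale since the Cretaceous:
#' Early Cretaceous 145-100.5, Late Cretaceous 100.5-66, Paleocene 66-56,
#' Eocene 56-33.9, Oligocene 33.9-23.03, Miocene 23.03-5.333, Pliocene
#' 5.333-2.58, Quaternary 2.58-0. With `quaternary_split = TRUE` the
#' Quaternary is split into Pleistocene 2.58-0.0117 and Holocene 0.0117-0.
#'
#' @param kind `"fixed"` or `"geological"`, or `"custom"` with `bins`.
#' @param width bin width in My for `kind = "fixed"`.
#' @param start oldest bound in Mya for `kind = "fixed"`.
#' @param bins for `kind = "custom"`: a data frame with columns `name`,
#'   `old_bound`, `young_bound`; must be contiguous, old to young, ending
#'   at 0.
#' @param quaternary_split split the Quaternary into Pleistocene/Holocene.
#' @return a data frame of class `timescale` with columns `name`,
#'   `old_bound`, `young_bound`.
#' @export
make_timescale <- function(kind = c("fixed", "geological", "custom"),
                           width = 5, start = 145, bins = NULL,
                           quaternary_split = FALSE) {
  kind <- match.arg(kind)
  if (kind == "fixed") {
    if (!is.numeric(width) || width <= 0) stop("bin width must be > 0")
    if (start <= 0) stop("'start' must be > 0")
    if (start %% width != 0) {
      start2 <- ceiling(start / width) * width
      warning("start ", start, " is not a multiple of width ", width,
              "; raised to ", start2)
      start <- start2
    }
    old <- seq(start, width, by = -width)
    out <- data.frame(name = sprintf("%g-%g", old, old - width),
                      old_bound = old, young_bound = old - width,
                      stringsAsFactors = FALSE)
  } else if (kind == "geological") {
    out <- data.frame(
      name = c("Early Cretaceous", "Late Cretaceous", "Paleocene", "Eocene",
               "Oligocene", "Miocene", "Pliocene", "Quaternary"),
      old_bound = c(145, 100.5, 66, 56, 33.9, 23.03, 5.333, 2.58),
      young_bound = c(100.5, 66, 56, 33.9, 23.03, 5.333, 2.58, 0),
      stringsAsFactors = FALSE)
    if (quaternary_split) {
      out <- rbind(out[out$name != "Quaternary", ],
                   data.frame(name = c("Pleistocene", "Holocene"),
                              old_bound = c(2.58, 0.0117),
                              young_bound = c(0.0117, 0)))
    }
  } else {
    if (is.null(bins)) stop("kind = 'custom' requires 'bins'")
    .check_cols(bins, c("name", "old_bound", "young_bound"), "bins")
    out <- as.data.frame(bins)[, c("name", "old_bound", "young_bound")]
  }
  .validate_timescale(out)
  class(out) <- c("timescale", "data.frame")
  rownames(out) <- NULL
  out
}

.validate_timescale <- function(b) {
  if (nrow(b) < 1) stop("timescale has no bins")
  if (any(b$old_bound <= b$young_bound)) {
    stop("each bin must have old_bound > young_bound")
  }
  if (b$young_bound[nrow(b)] != 0) stop("the youngest bin must end at 0 Mya")
  if (nrow(b) > 1 &&
      any(abs(b$young_bound[-nrow(b)] - b$old_bound[-1L]) > 1e-9)) {
    stop("bins must be contiguous and ordered old to young")
  }
  invisible(b)
}

#' Extend a timescale to cover ages older than its oldest bound
#'
#' Prepends a single catch-all bin from `oldest` down to the scale's
#' current oldest bound. Used by the pipeline when a tree is older than
#' the default 145-Mya horizon.
#'
#' @param scale a [make_timescale()] object.
#' @param oldest new oldest bound (Mya), greater than the current one.
#' @param name name for the prepended bin.
#' @return a `timescale`.
#' @export
extend_timescale <- function(scale, oldest, name = "older") {
  if (oldest <= scale$old_bound[1L]) return(scale)
  out <- rbind(data.frame(name = name, old_bound = oldest,
                          young_bound = scale$old_bound[1L],
                          stringsAsFactors = FALSE),
               as.data.frame(scale))
  class(out) <- c("timescale", "data.frame")
  rownames(out) <- NULL
  out
}

#' Assign ages to timescale bins
#'
#' An age `a` falls in the bin `(old, young]` with `old >= a > young`; age
#' 0 falls in the youngest bin. Each admissible age belongs to exactly one
#' bin.
#'
#' @param age numeric vector of ages in Mya, `0 <= age <= oldest bound`.
#' @param scale a [make_timescale()] object.
#' @param names optional labels (e.g. taxon names) used in error messages
#'   for out-of-scale ages.
#' @return a factor of bin names with levels in old-to-young scale order.
#' @export
assign_bin <- function(age, scale, names = NULL) {
  old <- scale$old_bound; young <- scale$young_bound
  k <- nrow(scale)
  if (any(age < 0, na.rm = TRUE)) stop("ages must be >= 0")
  over <- !is.na(age) & age > old[1L]
  if (any(over)) {
    lab <- if (!is.null(names)) paste0(names[over], " (", age[over], " Mya)")
           else paste(age[over], "Mya")
    stop("age(s) older than the timescale (oldest bound ", old[1L], " Mya): ",
         paste(lab, collapse = ", "))
  }
  idx <- rep(NA_integer_, length(age))
  ok <- !is.na(age)
  for (i in seq_len(k)) {
    sel <- ok & is.na(idx) & age <= old[i] & age > young[i]
    idx[sel] <- i
  }
  idx[ok & age == 0] <- k
  factor(scale$name[idx], levels = scale$name)
}

#' Per-bin divergence counts and percentages for one rank
#'
#' Counts how many taxa of the given rank diverged in each bin, the
#' percentage of the rank total (so percentages sum to 100 across bins),
#' and the divergence rate (count per My of bin width). A `total` row is
#' appended.
#'
#' @param div a [divergence_table()].
#' @param scale a [make_timescale()] object.
#' @param rank `"family"`, `"genus"` or `"species"`.
#' @param include_root include taxa whose age was taken at the tree root
#'   (`at_root`); default TRUE.
#' @return data frame with columns `bin`, `old_bound`, `young_bound`,
#'   `count`, `percentage`, `rate`.
#' @export
bin_counts <- function(div, scale, rank = c("genus", "family", "species"),
                       include_root = TRUE) {
  rank <- match.arg(rank)
  rows <- div[div$rank == rank, ]
  if (!include_root) rows <- rows[!rows$at_root, ]
  if (nrow(rows) == 0) stop("no rows of rank '", rank, "' in the table")
  b <- assign_bin(rows$age_mya, scale, names = rows$name)
  cnt <- as.integer(table(b))
  width <- scale$old_bound - scale$young_bound
  out <- data.frame(bin = scale$name,
                    old_bound = scale$old_bound,
                    young_bound = scale$young_bound,
                    count = cnt,
                    percentage = 100 * cnt / nrow(rows),
                    rate = cnt / width,
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(bin = "total", old_bound = scale$old_bound[1L],
                        young_bound = 0, count = nrow(rows),
                        percentage = 100, rate = NA_real_))
}

#' Tropical-temperate balance ratio
#'
#' `ht_ratio(H, T) = (H - T) / (H + T)` where `H` and `T` are the tropical
#' and temperate shares (counts or percentages — the ratio is scale
#' invariant) of genera diverging in a time bin. Positive values mean
#' tropical dominance, negative temperate dominance. When `H + T = 0` the
#' ratio is undefined and returned as `NA`, never as 0.
#'
#' @param H,T non-negative numerics, recycled to a common length.
#' @return numeric vector in `[-1, 1]` with `NA` where `H + T = 0`.
#' @export
ht_ratio <- function(H, T) {
  if (any(H < 0, na.rm = TRUE) || any(T < 0, na.rm = TRUE)) {
    stop("H and T must be non-negative")
  }
  s <- H + T
  ifelse(s == 0, NA_real_, (H - T) / s)
}

#' Element trajectory: per-bin floristic-element composition and HT ratio
#'
#' Joins genus divergence ages with element assignments and, for each time
#' bin, counts the genera of each element diverging in it, the within-bin
#' composition percentages, the tropical (`H`) and temperate (`T`) group
#' counts (widespread genera are excluded from both), and the
#' [ht_ratio()].
#'
#' @param div a [divergence_table()]; only `rank == "genus"` rows are used.
#' @param assignments an [classify_genera()] result covering the genera.
#' @param scale a [make_timescale()] object; typical analyses use
#'   ten-million-year windows and the geological scale.
#' @param temperate_includes_type15 if `FALSE`, genera of Wu type 15
#'   (Endemic to China) are excluded from the temperate count `T` (the
#'   narrow reading in which temperate elements are types 8-14).
#' @param skip_unclassified drop genera without an assignment (with a
#'   message) instead of erroring.
#' @param include_root include `at_root` genera; default TRUE.
#' @param cumulative if `TRUE`, counts accumulate from the oldest bin
#'   forward (standing diversity rather than per-period divergence).
#'   Default `FALSE`: per-period counts.
#' @return a data frame of class `element_trajectory`: one row per bin with
#'   columns `bin`, `old_bound`, `young_bound`, `n_classified`, one count
#'   and one `pct_` column per element, `H`, `T`, `ht_ratio`.
#' @export
element_trajectory <- function(div, assignments, scale,
                               temperate_includes_type15 = TRUE,
                               skip_unclassified = FALSE,
                               include_root = TRUE,
                               cumulative = FALSE) {
  g <- div[div$rank == "genus", ]
  if (!include_root) g <- g[!g$at_root, ]
  if (nrow(g) == 0) stop("no genus rows in the divergence table")
  i <- match(g$name, assignments$genus)
  if (anyNA(i)) {
    if (!skip_unclassified) {
      stop("unclassified genera: ", paste(g$name[is.na(i)], collapse = ", "),
           " (use skip_unclassified = TRUE to drop them)")
    }
    message(sum(is.na(i)), " unclassified genera skipped")
    g <- g[!is.na(i), ]
    i <- i[!is.na(i)]
  }
  g$group <- assignments$group[i]
  g$element <- assignments$element[i]
  g$type <- assignments$type[i]
  g$bin <- assign_bin(g$age_mya, scale, names = g$name)

  elements <- c("widespread", "tropical", "northern_temperate", "tethys",
                "east_asian")
  cnt <- sapply(elements, function(e) {
    as.integer(table(g$bin[g$element == e]))
  })
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1, dimnames = list(NULL, elements))
  in_T <- g$group == "temperate" &
    (temperate_includes_type15 | g$type != 15L)
  H <- as.integer(table(g$bin[g$group == "tropical"]))
  T_ <- as.integer(table(g$bin[in_T]))
  if (cumulative) {
    cnt <- apply(cnt, 2, cumsum)
    if (is.null(dim(cnt))) {
      cnt <- matrix(cnt, nrow = 1, dimnames = list(NULL, elements))
    }
    H <- cumsum(H); T_ <- cumsum(T_)
  }
  n_classified <- rowSums(cnt)
  pct <- 100 * cnt / ifelse(n_classified == 0, NA_real_, n_classified)
  out <- data.frame(bin = scale$name, old_bound = scale$old_bound,
                    young_bound = scale$young_bound,
                    n_classified = as.integer(n_classified),
                    stringsAsFactors = FALSE)
  out[elements] <- as.data.frame(cnt)
  out[paste0("pct_", elements)] <- as.data.frame(pct)
  out$H <- H
  out$T <- T_
  out$ht_ratio <- ht_ratio(H, T_)
  class(out) <- c("element_trajectory", "data.frame")
  rownames(out) <- NULL
  out
}

#' Tropical-to-temperate crossover time
#'
#' Scans the HT-ratio series from the oldest to the youngest bin and
#' returns the old bound of the youngest bin at which the ratio changes
#' sign from positive (tropical dominance, older) to negative (temperate
#' dominance, younger). Bins with undefined ratio are skipped; exact zeros
#' indicate no dominance and are skipped in the sign determination.
#'
#' @param traj an [element_trajectory()].
#' @return the crossover time in Mya, or `NA_real_` if the ratio never
#'   crosses from positive to negative.
#' @export
crossover_time <- function(traj) {
  r <- traj$ht_ratio
  ok <- !is.na(r) & r != 0
  if (sum(ok) < 2) return(NA_real_)
  idx <- which(ok)
  s <- sign(r[idx])
  flip <- which(s[-1L] < 0 & s[-length(s)] > 0)
  if (length(flip) == 0) return(NA_real_)
  traj$old_bound[idx[max(flip) + 1L]]
}
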