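# Quadrat cover tables to diversity and composition variables.

#' Drop sampling locations near plot edges
#'
#' Removes every cover-table row whose sampling location lies strictly within
#' `buffer_m` of its plot boundary (edge effects from mowing and vehicle
#' traffic concentrate there). Locations must fall inside their plot; any
#' that do not raise an error listing the offenders.
#'
#' @param table a [sample_cover_tables()]-shaped cover table.
#' @param layout the matching [make_layout()] result.
#' @param buffer_m edge buffer in meters (default 5).
#' @return The filtered cover table; the number of locations dropped is
#'   attached as attribute `n_dropped`.
#' @export
edge_filter <- function(table, layout, buffer_m = 5) {
  locs <- unique(table[, c("plot_id", "location_id", "x", "y")])
  p <- layout$plots[match(locs$plot_id, layout$plots$plot_id), ]
  d <- pmin(locs$x - p$xmin, p$xmax - locs$x,
            locs$y - p$ymin, p$ymax - locs$y)
  if (any(d < 0)) {
    bad <- locs[d < 0, ]
    stop(sprintf("locations outside their plot: %s",
                 paste(sprintf("plot %d loc %d", bad$plot_id, bad$location_id),
                       collapse = ", ")), call. = FALSE)
  }
  drop <- d < buffer_m
  drop_key <- paste(locs$plot_id, locs$location_id)[drop]
  out <- table[!(paste(table$plot_id, table$location_id) %in% drop_key), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  class(out) <- class(table)
  out
}

#' Per-location diversity metrics from a cover table
#'
#' For each sampling location: species richness (species with cover > 0),
#' Shannon's index on species relative covers and on covers aggregated to
#' functional groups (C3, C4, forb), both in nats with ground rows (litter,
#' bare soil) excluded from the denominators, plus absolute cover fractions
#' of vegetation, litter, bare soil and each functional group. Locations
#' without vegetation get richness 0 and Shannon indices 0.
#'
#' @param table a cover table with `group` mapping each species to a
#'   functional group (`"ground"` marks litter/bare rows).
#' @return Data frame with one row per location: `plot_id`, `location_id`,
#'   `seeding`, `management`, `x`, `y`, `richness`, `shannon_species`,
#'   `shannon_functional`, `veg_fraction`, `litter_fraction`,
#'   `bare_fraction`, `cover_c3`, `cover_c4`, `cover_forb` (absolute percent
#'   cover).
#' @export
diversity_metrics <- function(table) {
  veg <- table$group != "ground"
  if (any(is.na(table$group[veg])) ||
      any(!table$group[veg] %in% c("C3", "C4", "forb"))) {
    stop("every species needs a functional group in {C3, C4, forb}",
         call. = FALSE)
  }
  key <- factor(paste(table$plot_id, table$location_id, sep = "\r"))
  is_veg <- veg & table$percent_cover > 0
  # location x species and location x group cover matrices, one vegan
  # diversity call each
  vd <- data.frame(key = key[is_veg], item = table$item[is_veg],
                   group = table$group[is_veg],
                   cover = table$percent_cover[is_veg])
  sp_m <- as.matrix(stats::xtabs(cover ~ key + item, data = vd))
  grp_m <- as.matrix(stats::xtabs(cover ~ key + group, data = vd))
  full <- matrix(0, nlevels(key), ncol(grp_m),
                 dimnames = list(levels(key), colnames(grp_m)))
  grp_full <- full
  grp_full[rownames(grp_m), ] <- grp_m
  for (gp in c("C3", "C4", "forb")) {
    if (!gp %in% colnames(grp_full)) {
      grp_full <- cbind(grp_full, 0)
      colnames(grp_full)[ncol(grp_full)] <- gp
    }
  }
  h_sp <- h_fun <- rich <- veg_tot <- stats::setNames(numeric(nlevels(key)),
                                                      levels(key))
  if (nrow(sp_m)) {
    h_sp[rownames(sp_m)] <- as.numeric(vegan::diversity(sp_m, "shannon"))
    rich[rownames(sp_m)] <- rowSums(sp_m > 0)
    veg_tot[rownames(sp_m)] <- rowSums(sp_m)
  }
  h_fun[rownames(grp_m)] <- as.numeric(vegan::diversity(grp_m, "shannon"))
  ground_sum <- function(what) {
    s <- stats::setNames(numeric(nlevels(key)), levels(key))
    sel <- table$item == what
    if (any(sel)) {
      agg <- tapply(table$percent_cover[sel], droplevels(key[sel]), sum)
      s[names(agg)] <- agg
    }
    s
  }
  first <- match(levels(key), as.character(key))
  out <- cbind(
    table[first, c("plot_id", "location_id", "seeding", "management",
                   "x", "y")],
    data.frame(richness = unname(rich),
               shannon_species = unname(h_sp),
               shannon_functional = unname(h_fun),
               veg_fraction = unname(veg_tot) / 100,
               litter_fraction = unname(ground_sum("litter")) / 100,
               bare_fraction = unname(ground_sum("bare_soil")) / 100,
               cover_c3 = unname(grp_full[, "C3"]),
               cover_c4 = unname(grp_full[, "C4"]),
               cover_forb = unname(grp_full[, "forb"])))
  rownames(out) <- NULL
  out[order(out$plot_id, out$location_id), ]
}

#' Plot-level relative-cover community matrix
#'
#' Aggregates the cover table to plot level (mean cover per species over the
#' plot's retained locations, zeros included) and normalizes each plot's row
#' by its total vegetation cover, excluding litter and bare soil. Plots with
#' no vegetation are excluded with a warning.
#'
#' @param table a cover table (typically after [edge_filter()]).
#' @return A plots x species matrix of relative covers (rows sum to 1), with
#'   attribute `units = "fraction"`.
#' @export
relative_cover_matrix <- function(table) {
  veg <- table[table$group != "ground", ]
  plots <- sort(unique(table$plot_id))
  species <- sort(unique(veg$item))
  n_loc <- tapply(table$location_id, table$plot_id,
                  function(l) length(unique(l)))
  m <- matrix(0, length(plots), length(species),
              dimnames = list(plots, species))
  agg <- stats::aggregate(percent_cover ~ plot_id + item, data = veg, FUN = sum)
  for (i in seq_len(nrow(agg))) {
    p <- as.character(agg$plot_id[i])
    m[p, agg$item[i]] <- agg$percent_cover[i] / n_loc[[p]]
  }
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning(sprintf("%d plot(s) without vegetation excluded", sum(tot == 0)))
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  m <- sweep(m, 1, tot, "/")
  attr(m, "units") <- "fraction"
  m
}

#' Remove rare species from a community matrix
#'
#' Drops species whose cover never reaches `threshold_percent` in any plot
#' (`stat = "max"`, default) or whose mean cover across plots stays below it
#' (`stat = "mean"`). The matrix may be in fractions (attribute
#' `units = "fraction"`) or percent; the threshold is interpreted in percent
#' either way. Idempotent.
#'
#' @param matrix plots x species relative-cover matrix.
#' @param threshold_percent rarity threshold in percent cover (default 5).
#' @param stat summary across plots compared against the threshold.
#' @return The reduced matrix with attributes `n_retained` and `n_removed`.
#' @export
rare_species_filter <- function(matrix, threshold_percent = 5,
                                stat = c("max", "mean")) {
  stat <- match.arg(stat)
  thr <- threshold_percent
  if (identical(attr(matrix, "units"), "fraction")) thr <- thr / 100
  s <- apply(matrix, 2, stat)
  keep <- s >= thr | threshold_percent <= 0
  out <- matrix[, keep, drop = FALSE]
  attr(out, "units") <- attr(matrix, "units")
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Bray-Curtis distance matrix between plots
#'
#' Pairwise Bray-Curtis dissimilarity
#' `d(j, k) = sum |x_j - x_k| / sum (x_j + x_k)` over species, computed with
#' the community-ecology standard implementation. Pairs of all-zero rows are
#' undefined and flagged missing.
#'
#' @param matrix nonnegative plots x species abundance matrix.
#' @return Symmetric distance matrix with zero diagonal, values in `[0, 1]`.
#' @export
bray_curtis <- function(matrix) {
  if (any(matrix < 0)) stop("abundances must be nonnegative", call. = FALSE)
  d <- as.matrix(suppressWarnings(vegan::vegdist(matrix, method = "bray")))
  zero <- rowSums(matrix) == 0
  d[zero, zero] <- NA_real_
  d
}

#' Grouped box-plot summaries
#'
#' Five-number box summaries per seeding x management group: quartiles by
#' linear interpolation, whiskers at the most extreme data points within 1.5
#' interquartile ranges of the quartiles, and points beyond the whiskers
#' listed as outliers.
#'
#' @param values numeric vector.
#' @param seeding,management grouping vectors matching `values`.
#' @return Data frame with one row per nonempty group: `seeding`,
#'   `management`, `n`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `n_outliers`, and list column `outliers`.
#' @export
box_summary <- function(values, seeding, management) {
  stopifnot(length(values) == length(seeding),
            length(values) == length(management))
  groups <- split(values, list(seeding = seeding, management = management),
                  drop = FALSE)
  empty <- vapply(groups, function(v) length(v) == 0, logical(1))
  if (any(empty)) {
    warning(sprintf("empty group(s) omitted: %s",
                    paste(names(groups)[empty], collapse = ", ")))
    groups <- groups[!empty]
  }
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(seeding = parts[1], management = parts[2],
               n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(inside), whisker_hi = max(inside),
               n_outliers = sum(v < lo_fence | v > hi_fence),
               stringsAsFactors = FALSE)
  }))
  out$outliers <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    v[v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr]
  })
  rownames(out) <- NULL
  out
}
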