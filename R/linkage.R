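# Grouped regressions and ANCOVA linking diversity/composition to airborne
# indices.

#' Simple linear regression with slope test
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()]; reports slope,
#' intercept, coefficient of determination and the slope t-test p-value.
#'
#' @param x predictor values (must not be constant; n >= 3).
#' @param y response values.
#' @return A list with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
ols_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations",
                          call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate fit: predictor is constant",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = length(x))
}

#' Grouped regressions mirroring the treatment-table layout
#'
#' Fits the response-predictor line on all data combined, within each
#' management group (burn, hay) and within each seeding group (control, mid,
#' high) - six fits per response, matching the overall / management /
#' seeding column layout of the treatment tables. Groups with fewer than
#' `min_n` complete observations are skipped with a warning.
#'
#' @param data a [build_linkage_dataset()]-shaped data frame.
#' @param response,predictor column names.
#' @param min_n minimum group size (default 3).
#' @return Data frame with `grouping` (`"overall"`, `"management"`,
#'   `"seeding"`), `group`, `slope`, `intercept`, `r2`, `p`, `n` and the
#'   significance `code`.
#' @export
grouped_regressions <- function(data, response, predictor, min_n = 3L) {
  specs <- list(list(grouping = "overall", group = "all",
                     rows = rep(TRUE, nrow(data))))
  for (m in c("burn", "hay")) {
    specs <- c(specs, list(list(grouping = "management", group = m,
                                rows = data$management == m)))
  }
  for (s in c("control", "mid", "high")) {
    specs <- c(specs, list(list(grouping = "seeding", group = s,
                                rows = data$seeding == s)))
  }
  out <- do.call(rbind, lapply(specs, function(sp) {
    x <- data[[predictor]][sp$rows]
    y <- data[[response]][sp$rows]
    if (sum(stats::complete.cases(x, y)) < min_n) {
      warning(sprintf("group '%s' below minimum n = %d: fit skipped",
                      sp$group, min_n))
      return(NULL)
    }
    f <- ols_fit(x, y)
    data.frame(grouping = sp$grouping, group = sp$group,
               slope = f$slope, intercept = f$intercept, r2 = f$r2,
               p = f$p, n = f$n, code = significance_code(f$p),
               stringsAsFactors = FALSE)
  }))
  out$response <- response
  out$predictor <- predictor
  rownames(out) <- NULL
  out
}

#' ANCOVA: slope heterogeneity and intercept differences across groups
#'
#' Two-stage analysis of covariance with indicator coding. The interaction
#' model `response ~ predictor * group` yields the F-test of all
#' predictor-group interaction terms (slope heterogeneity). The additive
#' refit `response ~ predictor + group` yields the F-test of the group terms
#' (intercept differences under a common slope) - the classic ANCOVA group
#' test, reported regardless of the slope-test outcome.
#'
#' @param data data frame.
#' @param response,predictor column names.
#' @param group grouping column name (>= 2 levels, each with >= 3 points).
#' @param alpha significance level used only to label the slopes as
#'   homogeneous (default 0.05).
#' @return A list with `interaction_f`, `interaction_p` (slope
#'   heterogeneity), `group_f`, `group_p` (intercepts, additive model),
#'   `slopes_homogeneous`, `n` and `n_groups`.
#' @export
ancova <- function(data, response, predictor, group, alpha = 0.05) {
  d <- data.frame(y = data[[response]], x = data[[predictor]],
                  g = factor(data[[group]]))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$g)) < 2) {
    stop("ANCOVA needs at least two groups", call. = FALSE)
  }
  d$g <- droplevels(d$g)
  if (any(table(d$g) < 3)) {
    stop("every group needs at least 3 observations", call. = FALSE)
  }
  if (stats::sd(d$x) == 0) stop("degenerate fit: predictor is constant",
                                call. = FALSE)
  fit_full <- stats::lm(y ~ x * g, data = d)
  if (any(is.na(stats::coef(fit_full)))) {
    stop("rank-deficient ANCOVA design", call. = FALSE)
  }
  fit_add <- stats::lm(y ~ x + g, data = d)
  fit_x <- stats::lm(y ~ x, data = d)
  a_int <- stats::anova(fit_add, fit_full)
  a_grp <- stats::anova(fit_x, fit_add)
  interaction_p <- a_int$`Pr(>F)`[2]
  list(interaction_f = a_int$F[2], interaction_p = interaction_p,
       group_f = a_grp$F[2], group_p = a_grp$`Pr(>F)`[2],
       slopes_homogeneous = interaction_p >= alpha,
       n = nrow(d), n_groups = nlevels(d$g))
}

#' Significance codes for p-values
#'
#' `"***"` for p < 0.001, `"**"` for 0.001 <= p < 0.01, `"*"` for
#' 0.01 <= p < 0.05 and `"ns"` otherwise.
#'
#' @param p p-value vector in `[0, 1]`.
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Join diversity records with extracted index values
#'
#' Builds the regression dataset: one row per retained sampling location
#' holding the quadrat diversity metrics and the airborne index values
#' sampled at the location's coordinates (NDVI, WBI and albedo from the 1-m
#' reflectance products; temperature from the 1.4-m retrieval). Locations
#' falling outside a raster are listed and dropped with a warning.
#'
#' @param diversity a [diversity_metrics()] result (after edge filtering).
#' @param index_maps named list of [raster_layer()]s, typically
#'   `list(ndvi = ..., wbi = ..., albedo = ...)`.
#' @param temperature a temperature [raster_layer()] (or the `temperature`
#'   element of a [retrieve_lst()] result).
#' @param footprint extraction window in pixels (odd; default 1 = nearest
#'   pixel).
#' @return Data frame of class `linkage_dataset` with the diversity columns
#'   plus one column per index map and `temperature` (kelvin).
#' @export
build_linkage_dataset <- function(diversity, index_maps, temperature,
                                  footprint = 1L) {
  if (inherits(temperature, "temperature_map")) {
    temperature <- temperature$temperature
  }
  out <- diversity
  ok <- rep(TRUE, nrow(out))
  for (lyr in c(index_maps, list(temperature))) {
    ext <- raster_extent(lyr)
    ok <- ok & out$x >= ext["xmin"] & out$x <= ext["xmax"] &
      out$y >= ext["ymin"] & out$y <= ext["ymax"]
  }
  if (any(!ok)) {
    bad <- out[!ok, ]
    warning(sprintf("%d location(s) outside raster extents dropped: %s",
                    sum(!ok),
                    paste(sprintf("plot %s loc %s", bad$plot_id,
                                  bad$location_id), collapse = ", ")))
    out <- out[ok, ]
  }
  for (nm in names(index_maps)) {
    out[[nm]] <- extract_at(index_maps[[nm]], out$x, out$y, footprint)
  }
  out$temperature <- extract_at(temperature, out$x, out$y, footprint)
  class(out) <- c("linkage_dataset", "data.frame")
  out
}
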