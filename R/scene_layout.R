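# Experiment layout and field sampling designs.

#' Generate the experiment layout
#'
#' Lays out `n_blocks` blocks of three plots each on a local metric grid.
#' Blocks alternate management (odd blocks burned, even blocks hayed), plots
#' within a block are stacked north-south, and each block holds exactly one
#' plot of each seeding level (control, mid, high) in a seed-determined
#' order, so treatments stay balanced across blocks.
#'
#' @param config a [scene_config()].
#' @param seed integer seed controlling the within-block seeding permutation.
#' @return An object of class `experiment_layout`: `blocks` (data frame with
#'   `block_id`, `management`), `plots` (data frame with `plot_id`,
#'   `block_id`, `seeding`, `management` and rectangle `xmin`/`xmax`/
#'   `ymin`/`ymax` in scene meters) and `extent` (`c(width, height)`).
#' @export
make_layout <- function(config = scene_config(), seed = 1L) {
  lc <- config$layout
  n_blocks <- as.integer(lc$n_blocks)
  stopifnot(n_blocks >= 1)
  bcols <- min(as.integer(lc$block_cols), n_blocks)
  brows <- ceiling(n_blocks / bcols)
  block_w <- lc$plot_w
  block_h <- 3 * lc$plot_h + 2 * lc$plot_gap
  width <- 2 * lc$margin_x + bcols * block_w + (bcols - 1) * lc$block_gap
  height <- 2 * lc$margin_y + brows * block_h + (brows - 1) * lc$block_gap
  if (lc$plot_w <= 0 || lc$plot_h <= 0 || width <= 0 || height <= 0) {
    stop("scene extent too small for the requested plots", call. = FALSE)
  }
  seedings <- c("control", "mid", "high")
  perms <- with_seed(stage_seed(seed, "layout"), {
    replicate(n_blocks, sample(seedings), simplify = FALSE)
  })
  blocks <- data.frame(
    block_id = seq_len(n_blocks),
    management = ifelse(seq_len(n_blocks) %% 2L == 1L, "burn", "hay"),
    stringsAsFactors = FALSE
  )
  plots <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    bc <- (b - 1L) %% bcols           # block column (0-based)
    br <- (b - 1L) %/% bcols          # block row
    x0 <- lc$margin_x + bc * (block_w + lc$block_gap)
    y0 <- lc$margin_y + br * (block_h + lc$block_gap)
    data.frame(
      plot_id = (b - 1L) * 3L + 1:3,
      block_id = b,
      seeding = perms[[b]],
      management = blocks$management[b],
      xmin = x0,
      xmax = x0 + lc$plot_w,
      ymin = y0 + (0:2) * (lc$plot_h + lc$plot_gap),
      ymax = y0 + (0:2) * (lc$plot_h + lc$plot_gap) + lc$plot_h,
      stringsAsFactors = FALSE
    )
  }))
  if (any(plots$xmax > width) || any(plots$ymax > height)) {
    stop("scene extent too small for the requested plots", call. = FALSE)
  }
  structure(list(blocks = blocks, plots = plots,
                 extent = c(width = width, height = height), config = lc),
            class = "experiment_layout")
}

#' @export
print.experiment_layout <- function(x, ...) {
  cat(sprintf("<experiment_layout> %d blocks, %d plots, scene %g x %g m\n",
              nrow(x$blocks), nrow(x$plots), x$extent["width"],
              x$extent["height"]))
  cat("  management: ", paste(sprintf("%s=%d", names(table(x$plots$management)),
                                      table(x$plots$management)), collapse = ", "), "\n")
  invisible(x)
}

plot_rect <- function(layout, plot_id) {
  p <- layout$plots[layout$plots$plot_id == plot_id, ]
  if (nrow(p) != 1) stop(sprintf("unknown plot_id %s", plot_id), call. = FALSE)
  list(xmin = p$xmin, xmax = p$xmax, ymin = p$ymin, ymax = p$ymax)
}

#' Vegetation survey sampling design
#'
#' Generates the quadrat sampling locations for each plot: the plot center,
#' points at meter 7 and meter 14 along four 15-m transects running in the
#' cardinal directions from the center (nine transect-derived locations), and
#' six subplots in a 2 x 3 east-west array on an exact 30-m grid, giving 15
#' locations per plot.
#'
#' @param layout an [make_layout()] result.
#' @param subplots logical; include the six-subplot array (default `TRUE`).
#' @param subplot_dx,subplot_dy subplot grid spacing in meters (east-west
#'   and north-south).
#' @return Data frame with `plot_id`, `location_id`, `type` (`"center"`,
#'   `"transect"` or `"subplot"`), and `x`, `y` scene coordinates.
#' @export
make_survey_design <- function(layout, subplots = TRUE,
                               subplot_dx = 30, subplot_dy = 30) {
  plots <- layout$plots
  w <- plots$xmax - plots$xmin
  h <- plots$ymax - plots$ymin
  if (any(w < 30) || any(h < 30)) {
    stop("plots must be at least 30 m across for the 15-m transects",
         call. = FALSE)
  }
  if (subplots && (any(w < 2 * subplot_dx + 10) || any(h < subplot_dy + 10))) {
    stop("plots too small for the 2 x 3 subplot array", call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    cx <- (plots$xmin[i] + plots$xmax[i]) / 2
    cy <- (plots$ymin[i] + plots$ymax[i]) / 2
    pts <- data.frame(type = "center", dx = 0, dy = 0,
                      stringsAsFactors = FALSE)
    for (m in c(7, 14)) {
      pts <- rbind(pts, data.frame(
        type = "transect",
        dx = c(0, 0, m, -m),
        dy = c(m, -m, 0, 0)))
    }
    if (subplots) {
      sub <- expand.grid(dx = c(-subplot_dx, 0, subplot_dx),
                         dy = c(-subplot_dy / 2, subplot_dy / 2))
      pts <- rbind(pts, data.frame(type = "subplot", dx = sub$dx, dy = sub$dy))
    }
    data.frame(plot_id = plots$plot_id[i],
               location_id = seq_len(nrow(pts)),
               type = pts$type,
               x = cx + pts$dx, y = cy + pts$dy,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Ground-spectroscopy sampling design
#'
#' One position at every meter along each of four 15-m transects running in
#' the cardinal directions from the plot center (the north-south and
#' east-west transect pairs), yielding 60 positions per plot.
#'
#' @param layout an [make_layout()] result.
#' @param arms which transect arms to include (default all four cardinal
#'   directions).
#' @return Data frame with `plot_id`, `position_id`, `arm`, `meter`, `x`, `y`.
#' @export
make_spectral_design <- function(layout, arms = c("N", "S", "E", "W")) {
  arms <- match.arg(arms, c("N", "S", "E", "W"), several.ok = TRUE)
  plots <- layout$plots
  w <- plots$xmax - plots$xmin
  h <- plots$ymax - plots$ymin
  if (any(w < 30) || any(h < 30)) {
    stop("plots must be at least 30 m across for the 15-m transects",
         call. = FALSE)
  }
  dirs <- list(N = c(0, 1), S = c(0, -1), E = c(1, 0), W = c(-1, 0))
  out <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    cx <- (plots$xmin[i] + plots$xmax[i]) / 2
    cy <- (plots$ymin[i] + plots$ymax[i]) / 2
    do.call(rbind, lapply(arms, function(a) {
      d <- dirs[[a]]
      m <- 1:15
      data.frame(plot_id = plots$plot_id[i], arm = a, meter = m,
                 x = cx + d[1] * m, y = cy + d[2] * m,
                 stringsAsFactors = FALSE)
    }))
  }))
  out$position_id <- stats::ave(seq_len(nrow(out)), out$plot_id,
                                FUN = seq_along)
  rownames(out) <- NULL
  out[, c("plot_id", "position_id", "arm", "meter", "x", "y")]
}
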