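#' Run a grid of synthetic measurement experiments
#'
#' The desk-scale analogue of a distance/angle/shape sweep: each row of
#' `grid` overrides [scene_spec] arguments (e.g. `shape`, `tilt_deg`,
#' `camera_distance_mm`, `noise_sd`), every cell is rendered `repeats` times
#' with seeds `base_seed + 0 .. repeats - 1`, measured with the full
#' pipeline, and the signed relative errors of area, perimeter, length and
#' width against the rendered ground truth are collected.  Failures in
#' individual scenes are recorded as failed rows without aborting the grid.
#'
#' @param grid Data frame whose columns name [scene_spec] arguments; one row
#'   per experimental cell.  An empty grid yields an empty result.
#' @param repeats Renders per cell (distinct sub-seeds).
#' @param base_seed First seed of each cell.
#' @param spec_defaults Named list of [scene_spec] arguments shared by all
#'   cells.
#' @return A `leaf_experiment`: list with `results` (long data frame: cell
#'   index, grid columns, seed, parameter, true value, measured value,
#'   `rel_err_pct`, status) and `summary` (per cell and parameter: mean,
#'   min, max of the relative error and the mean absolute relative error).
#' @export
run_experiment <- function(grid, repeats = 1, base_seed = 0,
                           spec_defaults = list()) {
  stopifnot(is.data.frame(grid))
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cell_args <- utils::modifyList(spec_defaults, as.list(grid[i, , drop = FALSE]))
    for (j in seq_len(repeats)) {
      seed <- base_seed + j - 1
      row <- tryCatch({
        spec <- do.call(scene_spec, c(cell_args, list(seed = seed)))
        sc <- render_scene(spec)
        m <- measure(sc$image, config_for_scene(spec))
        tr <- sc$truth
        data.frame(cell = i, grid[i, , drop = FALSE], seed = seed,
                   parameter = c("area_cm2", "perimeter_cm", "length_mm", "width_mm"),
                   true = c(tr$true_area_cm2, tr$true_perimeter_cm,
                            tr$true_length_mm, tr$true_width_mm),
                   measured = c(m$area_cm2, m$perimeter_cm,
                                m$length_mm, m$width_mm),
                   status = "ok", message = "", row.names = NULL)
      }, leafrect_error = function(e) {
        data.frame(cell = i, grid[i, , drop = FALSE], seed = seed,
                   parameter = "area_cm2", true = NA_real_,
                   measured = NA_real_, status = "failed",
                   message = conditionMessage(e), row.names = NULL)
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0L) {
    res <- data.frame(cell = integer(), seed = integer(), parameter = character(),
                      true = numeric(), measured = numeric(),
                      status = character(), message = character())
    return(structure(list(results = res, summary = res), class = "leaf_experiment"))
  }
  res <- do.call(rbind, rows)
  res$rel_err_pct <- 100 * (res$measured - res$true) / res$true
  ok <- res[res$status == "ok", , drop = FALSE]
  if (nrow(ok)) {
    summ <- do.call(rbind, lapply(split(ok, list(ok$cell, ok$parameter), drop = TRUE),
      function(d) {
        data.frame(cell = d$cell[1],
                   d[1, names(grid), drop = FALSE],
                   parameter = d$parameter[1],
                   n = nrow(d),
                   mean_rel_err_pct = mean(d$rel_err_pct),
                   min_rel_err_pct = min(d$rel_err_pct),
                   max_rel_err_pct = max(d$rel_err_pct),
                   mean_abs_rel_err_pct = mean(abs(d$rel_err_pct)),
                   row.names = NULL)
      }))
    summ <- summ[order(summ$cell, summ$parameter), , drop = FALSE]
    rownames(summ) <- NULL
  } else {
    summ <- data.frame()
  }
  structure(list(results = res, summary = summ), class = "leaf_experiment")
}

#' @export
print.leaf_experiment <- function(x, ...) {
  n_ok <- sum(x$results$status == "ok")
  n_fail <- sum(x$results$status == "failed")
  cat(sprintf("<leaf_experiment> %d measurements (%d failed)\n", n_ok, n_fail))
  if (nrow(x$summary)) {
    a <- x$summary[x$summary$parameter == "area_cm2", , drop = FALSE]
    if (nrow(a))
      cat(sprintf("  area relative error: mean %.3f%%, range [%.3f%%, %.3f%%]\n",
                  mean(a$mean_rel_err_pct), min(a$min_rel_err_pct),
                  max(a$max_rel_err_pct)))
  }
  invisible(x)
}
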