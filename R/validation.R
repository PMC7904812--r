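#' Modeled investible carbon inside a project footprint
#'
#' Sums the central-track total flux over cells whose centers fall inside
#' the project polygon (cell-center rule). One constant model value per
#' project is later paired with each of its VCU vintages. Set
#' `unbuffered = TRUE` to compare gross (pre-buffer) certifiable flux
#' instead of the buffered investible flux.
#'
#' @param investible A [certify()] result.
#' @param project A [project_record()].
#' @param unbuffered Undo the buffer withholding before summing.
#' @return Modeled flux, tCO2/yr.
#' @export
project_model_estimate <- function(investible, project, unbuffered = FALSE) {
  layer <- investible$flux_total$central
  g <- layer$grid
  lon <- cell_center_lons(g); lat <- cell_center_lats(g)
  px <- rep(lon, each = g$n_rows); py <- rep(lat, times = g$n_cols)
  bb <- ring_bbox(project$rings)
  cand <- which(px >= bb["xmin"] & px <= bb["xmax"] &
                  py >= bb["ymin"] & py <= bb["ymax"])
  inside <- if (length(cand))
    cand[points_in_rings(px[cand], py[cand], project$rings)] else integer(0)
  if (length(inside) == 0L)
    stop("empty footprint: project '", project$project_id,
         "' contains no cell centers", call. = FALSE)
  est <- sum(as.vector(layer$values)[inside], na.rm = TRUE)
  if (unbuffered) est <- est / (1 - investible$params$buffer_fraction)
  est
}

#' Compare modeled credits with issued verified carbon units
#'
#' The three comparison statistics between paired modeled and issued
#' series: Pearson's product-moment correlation, root-mean-square error,
#' and a two-sided paired t-test (differences `model - vcu`, sample sd,
#' `n - 1` df). Perfect agreement (all differences zero) returns `t = 0`,
#' `p = 1` by convention; zero-variance differences with a non-zero mean,
#' or a constant series (undefined correlation), raise errors.
#'
#' @param model,vcu Paired numeric vectors, tCO2/yr (n >= 3, finite).
#' @return Object of class `comparison_stats`: `n`, `pearson_r`, `rmse`,
#'   `t_stat`, `p_value`, `df`.
#' @export
compare_credits <- function(model, vcu) {
  stopifnot(length(model) == length(vcu))
  n <- length(model)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(model)) || !all(is.finite(vcu)))
    stop("non-finite values", call. = FALSE)
  if (stats::sd(model) == 0 || stats::sd(vcu) == 0)
    stop("undefined correlation: constant series", call. = FALSE)
  d <- model - vcu
  if (all(d == 0)) {
    t_stat <- 0; p <- 1
  } else if (stats::sd(d) == 0) {
    stop("degenerate paired t: zero-variance non-zero differences", call. = FALSE)
  } else {
    tt <- stats::t.test(model, vcu, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(n = n,
                 pearson_r = stats::cor(model, vcu),
                 rmse = sqrt(mean(d^2)),
                 t_stat = t_stat, p_value = p, df = n - 1L),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("<comparison_stats> n = %d: R = %.3f, RMSE = %.4g tCO2/yr, t(%d) = %.3f, p = %.3g\n",
              x$n, x$pearson_r, x$rmse, x$df, x$t_stat, x$p_value))
  invisible(x)
}

#' Validate the investible-carbon map against project VCU series
#'
#' Extracts one modeled estimate per project and pairs it with every issued
#' vintage (so a project with k vintages contributes k data points), then
#' runs [compare_credits()].
#'
#' @param investible A [certify()] result.
#' @param projects List of [project_record()]s.
#' @param unbuffered Compare gross (pre-buffer) flux.
#' @return List: `pairs` (`data.frame(project_id, vintage_year, model,
#'   vcu)`) and `stats` (a `comparison_stats`).
#' @export
validate_against_vcus <- function(investible, projects, unbuffered = FALSE) {
  pairs <- do.call(rbind, lapply(projects, function(p) {
    est <- project_model_estimate(investible, p, unbuffered)
    data.frame(project_id = p$project_id,
               vintage_year = p$vcu_series$vintage_year,
               model = est, vcu = p$vcu_series$vcu_tco2e)
  }))
  list(pairs = pairs, stats = compare_credits(pairs$model, pairs$vcu))
}
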