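#' Predicted-glucose-change grid over starting glucose and rate of change
#'
#' Evaluates the fitted primary model over a grid of starting glucose and
#' onset rate of change for both conditions (PA undertaken or not), holding
#' the remaining covariates at reference values: bout duration at the cohort
#' median (23 min) and everything else at the sample means used to centre the
#' model. This is the decision-tool surface: each cell is the expected glucose
#' change from event onset to 20 min post-event.
#'
#' Cells outside the central 95% of the observed covariate support are flagged
#' `extrapolated`; the fitted PA surface is guaranteed to sit at or below the
#' control surface only inside the supported region.
#'
#' @param model a converged [fit_primary_model()] result.
#' @param glucose_range starting-glucose axis, mmol/L.
#' @param roc_range rate-of-change axis, mmol/L per min.
#' @param duration reference bout duration, minutes.
#' @return object of class `glyco_heatmap`: `grid` (long data frame with
#'   condition, glucose, roc, predicted_change, extrapolated), the axes, the
#'   reference covariates and `units` (`"mmol"`).
#' @export
predict_grid <- function(model,
                         glucose_range = seq(10, 16, by = 0.5),
                         roc_range = seq(-0.15, 0.15, by = 0.025),
                         duration = 23) {
  stopifnot(inherits(model, "glyco_effect_model"), isTRUE(model$converged))
  centres <- model$centres
  newdata <- expand.grid(glucose = glucose_range, roc = roc_range,
                         pa = c(0L, 1L))
  nd <- data.frame(pa = newdata$pa)
  for (v in names(centres)) {
    raw <- switch(v,
                  start_glucose = newdata$glucose,
                  roc = newdata$roc,
                  duration = duration,
                  centres[[v]])
    nd[[paste0("c_", v)]] <- raw - centres[[v]]
  }
  form <- lme4::nobars(stats::formula(model$fit))
  X <- stats::model.matrix(form[-2], nd)
  beta <- lme4::fixef(model$fit)
  pred <- drop(X %*% beta[colnames(X)])
  sup <- model$support
  extrap <- newdata$glucose < sup$start_glucose[1] |
    newdata$glucose > sup$start_glucose[2] |
    newdata$roc < sup$roc[1] | newdata$roc > sup$roc[2]
  grid <- data.frame(
    condition = ifelse(newdata$pa == 1L, "PA", "control"),
    glucose = newdata$glucose, roc = newdata$roc,
    predicted_change = pred, extrapolated = extrap
  )
  structure(list(grid = grid, glucose_axis = glucose_range,
                 roc_axis = roc_range,
                 reference = c(duration = duration,
                               centres[setdiff(names(centres),
                                               c("start_glucose", "roc",
                                                 "duration"))]),
                 units = "mmol"),
            class = "glyco_heatmap")
}

#' Convert a heatmap grid between mmol/L and mg/dL
#'
#' All glucose quantities (axes, predicted changes) are scaled by 18.016; the
#' conversion is exactly linear and invertible.
#'
#' @param grid a `glyco_heatmap`.
#' @return the converted `glyco_heatmap`.
#' @export
to_mgdl <- function(grid) {
  stopifnot(inherits(grid, "glyco_heatmap"))
  if (grid$units == "mgdl") return(grid)
  grid$grid$glucose <- mmol_to_mgdl(grid$grid$glucose)
  grid$grid$roc <- mmol_to_mgdl(grid$grid$roc)
  grid$grid$predicted_change <- mmol_to_mgdl(grid$grid$predicted_change)
  grid$glucose_axis <- mmol_to_mgdl(grid$glucose_axis)
  grid$roc_axis <- mmol_to_mgdl(grid$roc_axis)
  grid$units <- "mgdl"
  grid
}

#' @rdname to_mgdl
#' @export
to_mmol <- function(grid) {
  stopifnot(inherits(grid, "glyco_heatmap"))
  if (grid$units == "mmol") return(grid)
  grid$grid$glucose <- mgdl_to_mmol(grid$grid$glucose)
  grid$grid$roc <- mgdl_to_mmol(grid$grid$roc)
  grid$grid$predicted_change <- mgdl_to_mmol(grid$grid$predicted_change)
  grid$glucose_axis <- mgdl_to_mmol(grid$glucose_axis)
  grid$roc_axis <- mgdl_to_mmol(grid$roc_axis)
  grid$units <- "mmol"
  grid
}

#' Plot the decision-tool heatmap
#'
#' Tile plot of predicted glucose change by starting glucose and rate of
#' change, faceted by condition. The colour scale is anchored at zero change;
#' warmer colours indicate larger predicted reductions. Extrapolated cells
#' are dimmed.
#'
#' @param grid a `glyco_heatmap`.
#' @return a ggplot object.
#' @export
plot_heatmap <- function(grid) {
  stopifnot(inherits(grid, "glyco_heatmap"))
  d <- grid$grid
  unit_lab <- if (grid$units == "mmol") "mmol/L" else "mg/dL"
  ggplot2::ggplot(d, ggplot2::aes(x = glucose, y = roc,
                                  fill = predicted_change,
                                  alpha = !extrapolated)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                  high = "#2166ac", midpoint = 0,
                                  name = sprintf("Predicted change (%s)",
                                                 unit_lab)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = sprintf("Starting glucose (%s)", unit_lab),
                  y = sprintf("Rate of change (%s/min)", unit_lab)) +
    ggplot2::theme_minimal()
}

#' Cohort descriptive table
#'
#' Median \[IQR\] for continuous participant characteristics and per-trace
#' glycaemic metrics, n (%) for categorical fields — the standard cohort
#' characteristics table layout.
#'
#' @param profiles participant table.
#' @param cgm long CGM data frame (`participant_id`, `time`, `glucose`).
#' @return list of class `glyco_cohort_table` with `continuous` (metric,
#'   median, q1, q3, display) and `categorical` (metric, level, n, pct).
#' @export
cohort_table <- function(profiles, cgm) {
  per_part <- do.call(rbind, lapply(split(cgm$glucose, cgm$participant_id),
                                    function(g) {
                                      glycaemic_metrics(
                                        data.frame(glucose = g))
                                    }))
  cont <- list(
    "Age (years)" = profiles$age,
    "BMI (kg/m2)" = profiles$bmi,
    "Weight (kg)" = profiles$weight,
    "HbA1c (mmol/mol)" = profiles$hba1c,
    "Average glucose (mmol/L)" = per_part$mean,
    "SD (mmol/L)" = per_part$sd,
    "CV (%)" = per_part$cv,
    "Time in range 3.9-10.0 mmol/L (%)" = per_part$tir,
    "Time below range <3.9 mmol/L (%)" = per_part$tbr,
    "Time above range >10 mmol/L (%)" = per_part$tar
  )
  continuous <- do.call(rbind, lapply(names(cont), function(nm) {
    q <- stats::quantile(cont[[nm]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                         names = FALSE)
    data.frame(metric = nm, median = q[2], q1 = q[1], q3 = q[3],
               display = sprintf("%.1f [%.1f, %.1f]", q[2], q[1], q[3]))
  }))
  cats <- list(Sex = profiles$sex, Modality = profiles$modality)
  categorical <- do.call(rbind, lapply(names(cats), function(nm) {
    tb <- table(cats[[nm]])
    data.frame(metric = nm, level = names(tb), n = as.integer(tb),
               pct = 100 * as.integer(tb) / sum(tb))
  }))
  rownames(continuous) <- rownames(categorical) <- NULL
  structure(list(continuous = continuous, categorical = categorical),
            class = "glyco_cohort_table")
}

#' @export
print.glyco_cohort_table <- function(x, ...) {
  cat("<glyco_cohort_table>\n")
  for (i in seq_len(nrow(x$continuous))) {
    cat(sprintf("  %-36s %s\n", x$continuous$metric[i],
                x$continuous$display[i]))
  }
  for (i in seq_len(nrow(x$categorical))) {
    cat(sprintf("  %-12s %-12s %d (%.0f%%)\n", x$categorical$metric[i],
                x$categorical$level[i], x$categorical$n[i],
                x$categorical$pct[i]))
  }
  invisible(x)
}
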