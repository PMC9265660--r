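# Three-stage orchestration and the derived summary statistics.
#
# Stage 1 scores the observed panel (super-efficiency EBM on the global
# frontier, CRS and VRS).  Stage 2 regresses each input's stage-one slack
# on the environmental covariates, separates management inefficiency from
# noise (JLMS), and harmonizes the inputs so every unit faces the least
# favorable environment and worst luck in the sample.  Stage 3 re-scores
# the adjusted panel.  The GML index is computed on both panels from
# non-super-efficiency scores (super-efficiency is a ranking device for
# the static tables only).

#' Run the full three-stage EBM-SFA-EBM pipeline
#'
#' @param panel a `panel_dataset` with environmental covariates `Z`.
#' @param config list of settings (all optional):
#'   \describe{
#'     \item{epsilon_x, input_weights}{EBM parameters; `NULL` =
#'       affinity-derived from the data (the default).}
#'     \item{super_efficiency}{use super-efficiency for the static stage
#'       tables (default `TRUE`).}
#'     \item{bad_output_mode}{`"as_input"` (default) or
#'       `"weak_disposability"`.}
#'     \item{slack_type}{dependent variable of stage 2:
#'       `"radial_plus_slack"` (default) — the total input contraction
#'       gap `(1 - theta) x + s` from the non-super global CRS run — or
#'       `"pure_slack"` for `s` alone.}
#'     \item{weight_pooling}{`"per_year"` (default): weighted unit means
#'       are computed per year then averaged over years; `"pooled"` uses
#'       all unit-period weights at once.}
#'     \item{grouping}{named character vector unit -> region for regional
#'       aggregates (optional).}
#'     \item{period_blocks}{named list of year vectors (e.g. five-year
#'       plan windows) for period aggregates (optional).}
#'   }
#' @return an object of class `stage_report` with components `stage1`,
#'   `sfa`, `decomposition`, `adjusted_panel`, `stage3`, `gml_before`,
#'   `gml_after`, `summaries` and `config`.
#' @export
run_three_stage <- function(panel, config = list()) {
  validate_panel(panel)
  if (is.null(panel$Z)) stop("environmental covariates Z are required")
  cfg <- utils::modifyList(list(
    epsilon_x = NULL, input_weights = NULL,
    super_efficiency = TRUE,
    bad_output_mode = "as_input",
    slack_type = "radial_plus_slack",
    weight_pooling = "per_year",
    grouping = NULL, period_blocks = NULL), config)
  if (!cfg$slack_type %in% c("radial_plus_slack", "pure_slack")) {
    stop("slack_type must be 'radial_plus_slack' or 'pure_slack'")
  }

  stage1 <- stage_scores(panel, cfg)

  # ---- stage 2: one SFA per input, pooled over all J x T observations ----
  J <- length(panel$dmu_ids); Tn <- length(panel$periods)
  m <- dim(panel$X)[3]
  Zp <- matrix(panel$Z, J * Tn, dim(panel$Z)[3],
               dimnames = list(NULL, dimnames(panel$Z)[[3]]))
  sfa_fits <- vector("list", m)
  decomps <- vector("list", m)
  Xadj <- panel$X
  slack_tab <- stage1$slack_for_sfa
  for (i in seq_len(m)) {
    Si <- as.vector(slack_tab[, , i])
    fit <- fit_slack_frontier(Si, Zp)
    dec <- jlms_decompose(Si, Zp, fit)
    Xi <- as.vector(panel$X[, , i])
    Xadj[, , i] <- matrix(adjust_inputs(Xi, dec$f_hat, dec$v_hat), J, Tn)
    sfa_fits[[i]] <- fit
    decomps[[i]] <- dec
  }
  names(sfa_fits) <- names(decomps) <- dimnames(panel$X)[[3]]
  adjusted <- panel
  adjusted$X <- Xadj
  validate_panel(adjusted)

  stage3 <- stage_scores(adjusted, cfg)

  gml_before <- compute_gml(stage1$ns_crs_g, stage1$ns_crs_c,
                            stage1$ns_vrs_g, stage1$ns_vrs_c)
  gml_after <- compute_gml(stage3$ns_crs_g, stage3$ns_crs_c,
                           stage3$ns_vrs_g, stage3$ns_vrs_c)

  report <- structure(list(
    stage1 = stage1, sfa = sfa_fits, decomposition = decomps,
    adjusted_panel = adjusted, stage3 = stage3,
    gml_before = gml_before, gml_after = gml_after,
    config = cfg, panel = panel), class = "stage_report")
  report$summaries <- summarize_stages(report)
  report
}

# score one panel under every technology the pipeline needs
stage_scores <- function(panel, cfg) {
  base <- function(rts, frontier, sup) {
    technology_spec(rts = rts, frontier = frontier,
                    epsilon_x = cfg$epsilon_x,
                    input_weights = cfg$input_weights,
                    super_efficiency = sup,
                    bad_output_mode = cfg$bad_output_mode)
  }
  sup <- isTRUE(cfg$super_efficiency)
  ep_crs <- score_panel(panel, base("crs", "global", sup))
  ep_vrs <- score_panel(panel, base("vrs", "global", sup))
  ns_crs_g <- if (sup) score_panel(panel, base("crs", "global", FALSE)) else
    ep_crs
  ns_vrs_g <- if (sup) score_panel(panel, base("vrs", "global", FALSE)) else
    ep_vrs
  ns_crs_c <- score_panel(panel, base("crs", "contemporaneous", FALSE))
  ns_vrs_c <- score_panel(panel, base("vrs", "contemporaneous", FALSE))

  m <- dim(panel$X)[3]
  s_only <- ns_crs_g$slacks[, , seq_len(m), drop = FALSE]
  slack_for_sfa <- if (cfg$slack_type == "pure_slack") s_only else {
    gap <- s_only
    for (i in seq_len(m)) {
      gap[, , i] <- (1 - ns_crs_g$theta) * panel$X[, , i] + s_only[, , i]
    }
    gap
  }
  list(cte = ep_crs$scores, pte = ep_vrs$scores,
       se = decompose_efficiency(ep_crs$scores, ep_vrs$scores),
       status_crs = ep_crs$status, status_vrs = ep_vrs$status,
       fallback_count = sum(ep_crs$status != "optimal") +
         sum(ep_vrs$status != "optimal"),
       epsilon_x = ep_crs$epsilon_x, input_weights = ep_crs$input_weights,
       ns_crs_g = ns_crs_g$scores, ns_vrs_g = ns_vrs_g$scores,
       ns_crs_c = ns_crs_c$scores, ns_vrs_c = ns_vrs_c$scores,
       slack_for_sfa = slack_for_sfa)
}

#' Weighted mean
#'
#' @param values numeric vector.
#' @param weights nonnegative weights, not all zero.
#' @return `sum(w * v) / sum(w)`.
#' @export
weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) stop("length mismatch")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) == 0) stop("weights must not be all zero")
  sum(weights * values) / sum(weights)
}

#' Range (max minus min) of a vector
#'
#' @param values nonempty numeric vector.
#' @return `max(values) - min(values)`.
#' @export
value_range <- function(values) {
  if (length(values) == 0L || all(is.na(values))) {
    stop("values must be nonempty")
  }
  max(values, na.rm = TRUE) - min(values, na.rm = TRUE)
}

#' Compound annual growth rate
#'
#' @param v_start positive starting value.
#' @param v_end ending value.
#' @param n_intervals number of periods between the endpoints (>= 1).
#' @return growth rate in percent: `((v_end/v_start)^(1/n) - 1) * 100`.
#' @export
annual_growth_rate <- function(v_start, v_end, n_intervals) {
  if (any(v_start <= 0)) stop("starting value must be positive")
  if (any(n_intervals < 1)) stop("n_intervals must be >= 1")
  ((v_end / v_start)^(1 / n_intervals) - 1) * 100
}

#' Stage-1 minus stage-3 efficiency gap
#'
#' The "promotional effect" of the external environment: how much a
#' favorable environment and good luck inflated a unit's apparent
#' efficiency.  Positive values mean the environment flattered the unit.
#'
#' @param stage1_mean named vector of stage-1 unit means.
#' @param stage3_mean named vector of stage-3 unit means (same units).
#' @return named vector of signed gaps.
#' @export
stage_gap <- function(stage1_mean, stage3_mean) {
  if (is.null(names(stage1_mean)) || is.null(names(stage3_mean))) {
    if (length(stage1_mean) != length(stage3_mean)) {
      stop("mismatched unit lists")
    }
    return(stage1_mean - stage3_mean)
  }
  if (!setequal(names(stage1_mean), names(stage3_mean))) {
    stop("mismatched unit lists")
  }
  stage1_mean - stage3_mean[names(stage1_mean)]
}

#' Rank units in two stages and label the change
#'
#' Descending-value ranking (rank 1 = highest efficiency).  Ties are
#' broken by unit-label order and flagged.
#'
#' @param stage1_values,stage3_values named numeric vectors over the same
#'   units.
#' @return data frame with columns `unit`, `stage1`, `rank1`, `stage3`,
#'   `rank3`, `change` ("rise", "fall" or "same") and `tie` flag.
#' @export
rank_with_changes <- function(stage1_values, stage3_values) {
  units <- names(stage1_values)
  if (is.null(units)) units <- paste0("DMU", seq_along(stage1_values))
  if (!is.null(names(stage3_values))) {
    if (!setequal(units, names(stage3_values))) stop("mismatched units")
    stage3_values <- stage3_values[units]
  } else if (length(stage3_values) != length(stage1_values)) {
    stop("mismatched units")
  }
  rk <- function(v) {
    ord <- order(-v, units)   # ties broken by unit label
    r <- integer(length(v)); r[ord] <- seq_along(v)
    r
  }
  r1 <- rk(stage1_values); r3 <- rk(stage3_values)
  tie <- duplicated(stage1_values) | duplicated(stage1_values,
                                                fromLast = TRUE) |
    duplicated(stage3_values) | duplicated(stage3_values, fromLast = TRUE)
  data.frame(unit = units,
             stage1 = as.numeric(stage1_values), rank1 = r1,
             stage3 = as.numeric(stage3_values), rank3 = r3,
             change = ifelse(r3 < r1, "rise",
                             ifelse(r3 > r1, "fall", "same")),
             tie = tie, stringsAsFactors = FALSE)
}

#' Weighted aggregates by region and period block
#'
#' @param score_table J x T matrix of scores (units in rows, years in
#'   columns).
#' @param grouping named character vector mapping every unit to a group.
#' @param weights J x T matrix of nonnegative weights (e.g. output).
#' @param periods optional named list of year vectors (as they appear in
#'   `colnames(score_table)`); default one block of all years.
#' @param pooling `"per_year"` (weighted mean per year, then arithmetic
#'   mean over the block's years) or `"pooled"` (one weighted mean over
#'   all unit-years of the block).
#' @return data frame `group` x `period` with the aggregated value.
#' @export
group_aggregate <- function(score_table, grouping, weights,
                            periods = NULL,
                            pooling = c("per_year", "pooled")) {
  pooling <- match.arg(pooling)
  units <- rownames(score_table)
  if (is.null(units)) units <- paste0("DMU", seq_len(nrow(score_table)))
  miss <- setdiff(units, names(grouping))
  if (length(miss)) stop("unmapped unit(s): ", paste(miss, collapse = ", "))
  years <- colnames(score_table) %||% as.character(seq_len(ncol(score_table)))
  if (is.null(periods)) periods <- list(all = years)
  out <- expand.grid(group = unique(grouping[units]),
                     period = names(periods),
                     stringsAsFactors = FALSE)
  out$value <- NA_real_
  for (r in seq_len(nrow(out))) {
    gu <- units[grouping[units] == out$group[r]]
    yrs <- as.character(periods[[out$period[r]]])
    if (!all(yrs %in% years)) stop("period block outside panel years")
    sv <- score_table[gu, yrs, drop = FALSE]
    wv <- weights[match(gu, units), match(yrs, years), drop = FALSE]
    out$value[r] <- if (pooling == "pooled") {
      weighted_mean(as.vector(sv), as.vector(wv))
    } else {
      mean(vapply(seq_along(yrs), function(tt)
        weighted_mean(sv[, tt], wv[, tt]), numeric(1)))
    }
  }
  out
}

# all derived summary tables of a stage report
summarize_stages <- function(report) {
  panel <- report$panel
  s1 <- report$stage1; s3 <- report$stage3
  units <- panel$dmu_ids
  years <- as.character(panel$periods)
  W <- panel$W

  unit_mean <- function(M) stats::setNames(rowMeans(M), units)
  yr_weighted <- function(M) {
    vapply(seq_along(years), function(tt) weighted_mean(M[, tt], W[, tt]),
           numeric(1))
  }

  u1 <- lapply(s1[c("cte", "pte", "se")], unit_mean)
  u3 <- lapply(s3[c("cte", "pte", "se")], unit_mean)
  annual <- data.frame(
    year = panel$periods,
    cte_stage1 = yr_weighted(s1$cte), cte_stage3 = yr_weighted(s3$cte),
    pte_stage1 = yr_weighted(s1$pte), pte_stage3 = yr_weighted(s3$pte),
    se_stage1 = yr_weighted(s1$se), se_stage3 = yr_weighted(s3$se))

  n_int <- length(years) - 1L
  growth <- if (n_int >= 1L) {
    data.frame(
      series = c("cte_stage1", "cte_stage3", "pte_stage1", "pte_stage3",
                 "se_stage1", "se_stage3"),
      cagr_pct = vapply(
        c("cte_stage1", "cte_stage3", "pte_stage1", "pte_stage3",
          "se_stage1", "se_stage3"),
        function(cl) annual_growth_rate(annual[[cl]][1],
                                        annual[[cl]][nrow(annual)], n_int),
        numeric(1)))
  } else NULL

  gml_b <- average_index(report$gml_before, by = "unit",
                         type = "arithmetic")
  gml_a <- average_index(report$gml_after, by = "unit",
                         type = "arithmetic")

  sums <- list(
    stage1_unit_means = do.call(cbind, u1),
    stage3_unit_means = do.call(cbind, u3),
    weighted_average = c(
      cte_stage1 = mean(yr_weighted(s1$cte)),
      pte_stage1 = mean(yr_weighted(s1$pte)),
      se_stage1 = mean(yr_weighted(s1$se)),
      cte_stage3 = mean(yr_weighted(s3$cte)),
      pte_stage3 = mean(yr_weighted(s3$pte)),
      se_stage3 = mean(yr_weighted(s3$se))),
    cte_range = c(stage1 = value_range(u1$cte), stage3 = value_range(u3$cte)),
    rank_table = rank_with_changes(u1$cte, u3$cte),
    stage_gap = stage_gap(u1$cte, u3$cte),
    annual = annual,
    growth = growth,
    gml_unit_means = list(before = gml_b, after = gml_a),
    gml_overall = c(
      before = average_index(report$gml_before, by = "overall",
                             type = "arithmetic")$gml,
      after = average_index(report$gml_after, by = "overall",
                            type = "arithmetic")$gml))

  if (!is.null(report$config$grouping)) {
    sums$regional_stage1 <- group_aggregate(
      s1$cte, report$config$grouping, W, report$config$period_blocks,
      pooling = if (report$config$weight_pooling == "pooled") "pooled" else
        "per_year")
    sums$regional_stage3 <- group_aggregate(
      s3$cte, report$config$grouping, W, report$config$period_blocks,
      pooling = if (report$config$weight_pooling == "pooled") "pooled" else
        "per_year")
  }
  sums
}

#' @export
print.stage_report <- function(x, ...) {
  cat("Three-stage EBM-SFA-EBM report\n")
  cat(sprintf("  panel: %d units x %d periods\n",
              length(x$panel$dmu_ids), length(x$panel$periods)))
  cat(sprintf("  EBM epsilon = %.4f; super-efficiency: %s; bad outputs: %s\n",
              x$stage1$epsilon_x, x$config$super_efficiency,
              x$config$bad_output_mode))
  cat(sprintf("  stage-2 dependent slack: %s\n", x$config$slack_type))
  wa <- x$summaries$weighted_average
  cat(sprintf("  weighted mean CTE: %.3f (stage 1) -> %.3f (stage 3)\n",
              wa["cte_stage1"], wa["cte_stage3"]))
  cat(sprintf("  mean GML: %.3f (before) / %.3f (after adjustment)\n",
              x$summaries$gml_overall["before"],
              x$summaries$gml_overall["after"]))
  if (x$stage1$fallback_count + x$stage3$fallback_count > 0) {
    cat(sprintf("  super-efficiency fallbacks: %d (stage 1), %d (stage 3)\n",
                x$stage1$fallback_count, x$stage3$fallback_count))
  }
  invisible(x)
}

#' Write all report tables to a directory
#'
#' Emits the stage score tables, SFA regression table, adjusted panel,
#' GML records and summary tables as CSV files plus a JSON run manifest
#' recording every configuration setting.
#'
#' @param report a [run_three_stage()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_stage_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(
    as.data.frame(x), file.path(dir, f), row.names = TRUE)
  wcsv(report$stage1$cte, "stage1_cte.csv")
  wcsv(report$stage1$pte, "stage1_pte.csv")
  wcsv(report$stage1$se, "stage1_se.csv")
  wcsv(report$stage3$cte, "stage3_cte.csv")
  wcsv(report$stage3$pte, "stage3_pte.csv")
  wcsv(report$stage3$se, "stage3_se.csv")
  utils::write.csv(report$gml_before, file.path(dir, "gml_before.csv"),
                   row.names = FALSE)
  utils::write.csv(report$gml_after, file.path(dir, "gml_after.csv"),
                   row.names = FALSE)
  sfa_tab <- do.call(rbind, lapply(names(report$sfa), function(nm) {
    m <- report$sfa[[nm]]
    data.frame(input = nm, term = names(m$beta), estimate = m$beta,
               t_value = m$beta_t, sigma_sq = m$sigma_sq, gamma = m$gamma,
               loglik = m$loglik, lr = m$lr_stat,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(sfa_tab, file.path(dir, "sfa_regression.csv"),
                   row.names = FALSE)
  write_panel(report$adjusted_panel, file.path(dir, "adjusted_panel.csv"))
  wcsv(report$summaries$stage1_unit_means, "stage1_unit_means.csv")
  wcsv(report$summaries$stage3_unit_means, "stage3_unit_means.csv")
  utils::write.csv(report$summaries$rank_table,
                   file.path(dir, "rank_changes.csv"), row.names = FALSE)
  utils::write.csv(report$summaries$annual,
                   file.path(dir, "annual_weighted.csv"), row.names = FALSE)
  manifest <- report$config
  manifest$epsilon_x_used <- report$stage1$epsilon_x
  manifest$input_weights_used <- report$stage1$input_weights
  manifest$fallbacks <- c(stage1 = report$stage1$fallback_count,
                          stage3 = report$stage3$fallback_count)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}
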