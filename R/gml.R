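# Global Malmquist(-Luenberger) productivity index.
#
# With ratio-form efficiencies measured against a single global frontier
# (E_G) and against each period's own frontier (E_t), the TFP change of
# unit j between t and t+1 and its decomposition are
#
#   GML  = E_G(t+1) / E_G(t)                      (global CRS)
#   GEFC = E_{t+1}(t+1) / E_t(t)                  (contemporaneous CRS)
#   GETC = GML / GEFC
#   GPEC = E^V_{t+1}(t+1) / E^V_t(t)              (contemporaneous VRS)
#   GSEC = GEFC / GPEC
#   GPTC = [E^V_G(t+1)/E^V_{t+1}(t+1)] / [E^V_G(t)/E^V_t(t)]  (global VRS)
#   GSTC = GETC / GPTC
#
# Because every period is scored against the same global technology, the
# index is transitive: GML(t -> t+2) = GML(t -> t+1) * GML(t+1 -> t+2).

gml_score_matrix <- function(x, what) {
  if (inherits(x, "efficiency_panel")) x <- x$scores
  x <- as.matrix(x)
  bad <- which(!is.finite(x) | x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("%s score missing or nonpositive at unit '%s', period %s",
                 what,
                 rownames(x)[bad[1, 1]] %||% bad[1, 1],
                 colnames(x)[bad[1, 2]] %||% bad[1, 2]))
  }
  x
}

#' Global Malmquist-Luenberger index and its decomposition
#'
#' Computes the per-unit, per-adjacent-period productivity records from
#' the four score tables (global/contemporaneous x CRS/VRS).  Scores must
#' come from non-super-efficiency runs (capped by the frontier) so that
#' all ratio factors are well defined.
#'
#' @param global_crs,contemp_crs,global_vrs,contemp_vrs J x T score
#'   matrices (or `efficiency_panel` objects) under the four
#'   technologies.
#' @return a data frame of class `gml_records` with one row per unit and
#'   adjacent period pair and columns `unit`, `from`, `to`, `gml`,
#'   `gefc`, `getc`, `gpec`, `gsec`, `gptc`, `gstc`.
#' @export
compute_gml <- function(global_crs, contemp_crs, global_vrs, contemp_vrs) {
  EG <- gml_score_matrix(global_crs, "global CRS")
  EC <- gml_score_matrix(contemp_crs, "contemporaneous CRS")
  EGV <- gml_score_matrix(global_vrs, "global VRS")
  ECV <- gml_score_matrix(contemp_vrs, "contemporaneous VRS")
  stopifnot(all(dim(EG) == dim(EC)), all(dim(EG) == dim(EGV)),
            all(dim(EG) == dim(ECV)))
  J <- nrow(EG); Tn <- ncol(EG)
  if (Tn < 2L) stop("at least two periods are required")
  units <- rownames(EG) %||% paste0("DMU", seq_len(J))
  periods <- colnames(EG) %||% as.character(seq_len(Tn))

  idx1 <- seq_len(Tn - 1L); idx2 <- idx1 + 1L
  gml <- EG[, idx2, drop = FALSE] / EG[, idx1, drop = FALSE]
  gefc <- EC[, idx2, drop = FALSE] / EC[, idx1, drop = FALSE]
  getc <- gml / gefc
  gpec <- ECV[, idx2, drop = FALSE] / ECV[, idx1, drop = FALSE]
  gsec <- gefc / gpec
  gptc <- (EGV[, idx2, drop = FALSE] / ECV[, idx2, drop = FALSE]) /
    (EGV[, idx1, drop = FALSE] / ECV[, idx1, drop = FALSE])
  gstc <- getc / gptc

  out <- data.frame(
    unit = rep(units, Tn - 1L),
    from = rep(periods[idx1], each = J),
    to = rep(periods[idx2], each = J),
    gml = as.vector(gml), gefc = as.vector(gefc), getc = as.vector(getc),
    gpec = as.vector(gpec), gsec = as.vector(gsec),
    gptc = as.vector(gptc), gstc = as.vector(gstc),
    stringsAsFactors = FALSE)
  class(out) <- c("gml_records", "data.frame")
  out
}

#' Average productivity records
#'
#' Averages the seven index factors over units (per period pair), over
#' period pairs (per unit), or overall.  Multiplicative indices are
#' averaged geometrically by default; an arithmetic option mirrors how
#' summary tables are usually presented.
#'
#' @param records a [compute_gml()] result.
#' @param by `"unit"` (one row per unit, averaged over period pairs),
#'   `"period"` (one row per period pair), or `"overall"`.
#' @param weights optional nonnegative weights named by unit, recycled
#'   across period pairs (e.g. output shares); default equal.
#' @param type `"geometric"` or `"arithmetic"`.
#' @return data frame of averaged indices.
#' @export
average_index <- function(records, by = c("unit", "period", "overall"),
                          weights = NULL,
                          type = c("geometric", "arithmetic")) {
  by <- match.arg(by); type <- match.arg(type)
  if (nrow(records) == 0L) stop("no records to average")
  cols <- c("gml", "gefc", "getc", "gpec", "gsec", "gptc", "gstc")
  if (any(as.matrix(records[cols]) <= 0)) {
    stop("indices must be positive")
  }
  w <- if (is.null(weights)) rep(1, nrow(records)) else {
    uw <- weights[records$unit]
    if (anyNA(uw)) stop("weights must be named by unit")
    as.numeric(uw)
  }
  key <- switch(by,
                unit = records$unit,
                period = paste(records$from, records$to, sep = "-"),
                overall = rep("overall", nrow(records)))
  agg <- function(x, w) {
    if (type == "geometric") exp(sum(w * log(x)) / sum(w)) else
      sum(w * x) / sum(w)
  }
  keys <- unique(key)
  out <- do.call(rbind, lapply(keys, function(kk) {
    sel <- key == kk
    vals <- vapply(cols, function(cl) agg(records[[cl]][sel], w[sel]),
                   numeric(1))
    as.data.frame(as.list(vals))
  }))
  out <- cbind(data.frame(group = keys, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
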