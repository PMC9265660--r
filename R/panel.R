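# Panel data model: a balanced DMU x period panel of inputs, desirable and
# undesirable outputs, environmental covariates and an output-based
# weighting basis.  DEA requires strictly positive inputs and a balanced
# panel; validation fails loudly rather than imputing.

#' Construct a balanced DMU-by-period panel
#'
#' The container used throughout the three-stage pipeline.  All arrays are
#' indexed `[unit, period, variable]`; the weighting basis `W` (typically
#' the desirable-output quantity, e.g. grain output) is used for weighted
#' regional and period averages.
#'
#' @param X numeric array of inputs, `J x T x m`, strictly positive.
#' @param Y numeric array of desirable outputs, `J x T x s_g`, nonnegative.
#'   A `J x T` matrix is promoted to a single-output array.
#' @param B numeric array of undesirable outputs, `J x T x s_b`,
#'   nonnegative, or `NULL` for none.
#' @param Z numeric array of environmental covariates, `J x T x p`, or
#'   `NULL`.
#' @param W `J x T` matrix of nonnegative weights, default the first
#'   desirable output.
#' @param dmu_ids character labels for the units.
#' @param periods strictly increasing integer years with no gaps.
#' @param units optional named character vector of measurement-unit
#'   metadata, carried verbatim (no conversion is attempted).
#' @return an object of class `panel_dataset`.
#' @export
panel_dataset <- function(X, Y, B = NULL, Z = NULL, W = NULL,
                          dmu_ids = NULL, periods = NULL, units = NULL) {
  as3d <- function(A, what) {
    if (is.null(A)) return(NULL)
    if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1L))
    if (length(dim(A)) != 3L) {
      stop(sprintf("%s must be a J x T x k array or a J x T matrix", what))
    }
    storage.mode(A) <- "double"
    A
  }
  X <- as3d(X, "X"); Y <- as3d(Y, "Y"); B <- as3d(B, "B"); Z <- as3d(Z, "Z")
  J <- dim(X)[1]; Tn <- dim(X)[2]
  if (is.null(dmu_ids)) dmu_ids <- dimnames(X)[[1]]
  if (is.null(dmu_ids)) dmu_ids <- paste0("DMU", seq_len(J))
  if (is.null(periods)) periods <- dimnames(X)[[2]]
  if (is.null(periods)) periods <- seq_len(Tn)
  periods <- as.integer(periods)
  if (is.null(W)) W <- Y[, , 1L, drop = TRUE]
  W <- matrix(as.numeric(W), J, Tn)

  name_dims <- function(A, vn_prefix) {
    if (is.null(A)) return(NULL)
    dn <- dimnames(A)
    v <- if (!is.null(dn) && !is.null(dn[[3]])) dn[[3]] else
      paste0(vn_prefix, seq_len(dim(A)[3]))
    dimnames(A) <- list(dmu_ids, periods, v)
    A
  }
  obj <- structure(list(
    dmu_ids = as.character(dmu_ids),
    periods = periods,
    X = name_dims(X, "x"),
    Y = name_dims(Y, "y"),
    B = name_dims(B, "b"),
    Z = name_dims(Z, "z"),
    W = W,
    units = units
  ), class = "panel_dataset")
  validate_panel(obj)
  obj
}

#' Validate a panel dataset
#'
#' Checks the structural invariants the three-stage method relies on:
#' consistent dimensions, a gap-free period sequence, no missing cells,
#' strictly positive inputs and nonnegative outputs/weights.  The first
#' violation found is reported with its (unit, year, variable) address.
#'
#' @param panel a `panel_dataset`.
#' @return the panel, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_dataset"))
  J <- length(panel$dmu_ids); Tn <- length(panel$periods)
  if (J < 1L || Tn < 1L) stop("panel must contain at least one unit-period")
  if (Tn > 1L && !all(diff(panel$periods) == diff(panel$periods)[1] &
                      diff(panel$periods) > 0)) {
    stop("periods must be strictly increasing with no gaps")
  }
  chk_dim <- function(A, what) {
    if (is.null(A)) return(invisible())
    if (dim(A)[1] != J || dim(A)[2] != Tn) {
      stop(sprintf("%s dimensions (%d x %d) do not match panel (%d x %d)",
                   what, dim(A)[1], dim(A)[2], J, Tn))
    }
    if (anyNA(A)) {
      idx <- which(is.na(A), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "missing value in %s at unit '%s', year %d, variable '%s'; %s",
        what, panel$dmu_ids[idx[1]], panel$periods[idx[2]],
        dimnames(A)[[3]][idx[3]],
        "the method requires a balanced panel (no imputation is performed)"))
    }
  }
  chk_dim(panel$X, "X"); chk_dim(panel$Y, "Y")
  chk_dim(panel$B, "B"); chk_dim(panel$Z, "Z")
  if (nrow(panel$W) != J || ncol(panel$W) != Tn) stop("W dimension mismatch")
  if (anyNA(panel$W)) stop("missing value in W")
  bad <- which(panel$X <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "nonpositive input at unit '%s', year %d, variable '%s' (DEA requires strictly positive inputs)",
      panel$dmu_ids[bad[1, 1]], panel$periods[bad[1, 2]],
      dimnames(panel$X)[[3]][bad[1, 3]]))
  }
  if (any(panel$Y < 0)) stop("desirable outputs must be nonnegative")
  if (!is.null(panel$B) && any(panel$B < 0)) {
    stop("undesirable outputs must be nonnegative")
  }
  if (any(panel$W < 0)) stop("weights must be nonnegative")
  invisible(panel)
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf(
    "panel_dataset: %d units x %d periods (%d-%d)\n",
    length(x$dmu_ids), length(x$periods), min(x$periods), max(x$periods)))
  cat(sprintf("  inputs: %s\n", paste(dimnames(x$X)[[3]], collapse = ", ")))
  cat(sprintf("  desirable outputs: %s\n",
              paste(dimnames(x$Y)[[3]], collapse = ", ")))
  if (!is.null(x$B)) {
    cat(sprintf("  undesirable outputs: %s\n",
                paste(dimnames(x$B)[[3]], collapse = ", ")))
  }
  if (!is.null(x$Z)) {
    cat(sprintf("  environmental covariates: %s\n",
                paste(dimnames(x$Z)[[3]], collapse = ", ")))
  }
  invisible(x)
}

#' Convert a panel to a long data frame
#'
#' @param x a `panel_dataset`.
#' @param ... unused.
#' @return data frame with columns unit, year, role, variable, value.
#' @export
as.data.frame.panel_dataset <- function(x, ...) {
  one <- function(A, role) {
    if (is.null(A)) return(NULL)
    d <- as.data.frame.table(A, stringsAsFactors = FALSE)
    names(d) <- c("unit", "year", "variable", "value")
    d$role <- role
    d
  }
  w <- as.data.frame.table(x$W, stringsAsFactors = FALSE)
  names(w) <- c("unit", "year", "value")
  w$unit <- rep(x$dmu_ids, length(x$periods))
  w$year <- rep(x$periods, each = length(x$dmu_ids))
  w$variable <- "weight"; w$role <- "weight"
  out <- rbind(one(x$X, "input"), one(x$Y, "output"),
               one(x$B, "bad_output"), one(x$Z, "env"),
               w[, c("unit", "year", "variable", "value", "role")])
  out$year <- as.integer(out$year)
  rownames(out) <- NULL
  out[, c("unit", "year", "role", "variable", "value")]
}

# resolve a schema argument: a list, or a path to a YAML/JSON file
resolve_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1L) {
    if (!file.exists(schema)) stop("schema file not found: ", schema)
    schema <- if (grepl("\\.json$", schema, ignore.case = TRUE)) {
      jsonlite::read_json(schema, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(schema)
    }
  }
  if (!is.list(schema)) stop("schema must be a list or a YAML/JSON file path")
  # YAML 1.1 parses bare y/n/yes/no as logicals; variable names must be
  # character (quote them in the schema file), so coerce defensively
  for (f in c("unit", "year", "variable", "value", "inputs", "outputs",
              "bads", "env", "weight")) {
    if (!is.null(schema[[f]]) && is.logical(schema[[f]])) {
      schema[[f]] <- ifelse(schema[[f]], "y", "n")
    }
  }
  schema$format <- match.arg(schema$format %||% "wide", c("wide", "long"))
  schema$unit <- schema$unit %||% "unit"
  schema$year <- schema$year %||% "year"
  if (is.null(schema$inputs) || is.null(schema$outputs)) {
    stop("schema error: 'inputs' and 'outputs' must name the panel variables")
  }
  schema
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a panel from a CSV file
#'
#' Accepts two dialects: a wide table (one row per unit-year, one column
#' per variable) and a long table (columns unit, year, variable, value).
#' The schema maps column/variable names to their roles; it can be given
#' as an R list or as a path to a YAML/JSON file with the same fields:
#' `format` ("wide" or "long"), `unit`, `year`, `variable`, `value`
#' (long format only), `inputs`, `outputs`, `bads`, `env`, `weight`.
#'
#' @param path CSV file path.
#' @param schema schema list or YAML/JSON file path (see Details).
#' @return a validated `panel_dataset`.
#' @export
load_panel <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- resolve_schema(schema)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)

  if (schema$format == "long") {
    need <- c(schema$unit, schema$year,
              schema$variable %||% "variable", schema$value %||% "value")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("schema error: missing column(s): ",
                           paste(miss, collapse = ", "))
    vcol <- schema$variable %||% "variable"
    valc <- schema$value %||% "value"
    df <- stats::reshape(
      df[, need], direction = "wide",
      idvar = c(schema$unit, schema$year), timevar = vcol, v.names = valc)
    names(df) <- sub(paste0("^", valc, "\\."), "", names(df))
  }

  roles <- list(inputs = schema$inputs, outputs = schema$outputs,
                bads = schema$bads, env = schema$env)
  all_vars <- unlist(roles, use.names = FALSE)
  miss <- setdiff(c(schema$unit, schema$year, all_vars), names(df))
  if (length(miss)) stop("schema error: missing column(s): ",
                         paste(miss, collapse = ", "))

  units <- sort(unique(as.character(df[[schema$unit]])))
  years <- sort(unique(as.integer(df[[schema$year]])))
  J <- length(units); Tn <- length(years)
  if (nrow(df) != J * Tn ||
      anyDuplicated(df[, c(schema$unit, schema$year)])) {
    stop(sprintf(
      "unbalanced panel: expected %d rows (%d units x %d years), found %d",
      J * Tn, J, Tn, nrow(df)))
  }
  ui <- match(as.character(df[[schema$unit]]), units)
  yi <- match(as.integer(df[[schema$year]]), years)

  build <- function(vars) {
    if (is.null(vars) || length(vars) == 0L) return(NULL)
    A <- array(NA_real_, c(J, Tn, length(vars)),
               dimnames = list(units, years, vars))
    for (k in seq_along(vars)) {
      A[cbind(ui, yi, k)] <- as.numeric(df[[vars[k]]])
    }
    A
  }
  X <- build(roles$inputs); Y <- build(roles$outputs)
  B <- build(roles$bads); Z <- build(roles$env)
  W <- if (!is.null(schema$weight)) {
    build(schema$weight)[, , 1L, drop = TRUE]
  } else NULL
  panel_dataset(X, Y, B, Z, W, dmu_ids = units, periods = years,
                units = schema$units)
}

#' Write a panel to a wide CSV file
#'
#' One row per unit-year; inputs, outputs, undesirable outputs, covariates
#' and the weight column, named as in the panel.  `load_panel()` on the
#' written file with the matching schema reproduces the panel.
#'
#' @param panel a `panel_dataset`.
#' @param path output CSV path.
#' @return the schema (as a list) that reads the file back, invisibly.
#' @export
write_panel <- function(panel, path) {
  J <- length(panel$dmu_ids); Tn <- length(panel$periods)
  df <- data.frame(
    unit = rep(panel$dmu_ids, Tn),
    year = rep(panel$periods, each = J),
    stringsAsFactors = FALSE)
  add <- function(A) {
    if (is.null(A)) return(invisible())
    for (k in seq_len(dim(A)[3])) {
      df[[dimnames(A)[[3]][k]]] <<- as.vector(A[, , k])
    }
  }
  add(panel$X); add(panel$Y); add(panel$B); add(panel$Z)
  df$weight <- as.vector(panel$W)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "year"
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(list(
    format = "wide", unit = "unit", year = "year",
    inputs = dimnames(panel$X)[[3]], outputs = dimnames(panel$Y)[[3]],
    bads = if (!is.null(panel$B)) dimnames(panel$B)[[3]],
    env = if (!is.null(panel$Z)) dimnames(panel$Z)[[3]],
    weight = "weight"))
}

#' Apportion a total quantity by the grain share of sown area
#'
#' Yearbook totals for fertilizer and machinery power cover all of
#' agriculture; the grain-attributable part is taken proportionally to the
#' grain share of the total sown area.
#'
#' @param total_quantity nonnegative total.
#' @param grain_share fraction in \[0, 1\].
#' @return `total_quantity * grain_share`.
#' @export
apportion_by_sown_share <- function(total_quantity, grain_share) {
  if (any(grain_share < 0 | grain_share > 1)) {
    stop("grain_share must lie in [0, 1]")
  }
  if (any(total_quantity < 0)) stop("total_quantity must be nonnegative")
  total_quantity * grain_share
}

#' Carbon emission coefficient set
#'
#' Emission factors per unit activity for the carbon-source categories
#' (e.g. fertilizer, pesticide, film, diesel, ploughing, irrigation).
#' Values are user-supplied: published coefficient sets differ, so none is
#' hard-coded.
#'
#' @param coefficients nonnegative numeric vector, optionally named.
#' @param source_names category labels (defaults to names of
#'   `coefficients`).
#' @return an object of class `carbon_coefficients`.
#' @export
carbon_coefficients <- function(coefficients, source_names = NULL) {
  if (any(coefficients < 0)) stop("coefficients must be nonnegative")
  if (is.null(source_names)) source_names <- names(coefficients)
  if (is.null(source_names)) {
    source_names <- paste0("source", seq_along(coefficients))
  }
  if (length(source_names) != length(coefficients)) {
    stop("one coefficient per source is required")
  }
  structure(list(source_names = source_names,
                 coefficients = as.numeric(coefficients)),
            class = "carbon_coefficients")
}

#' Aggregate carbon emissions from activity levels
#'
#' Total emissions as the inner product of activity quantities with their
#' emission coefficients.
#'
#' @param activity nonnegative activity quantities, one per source.
#' @param coeffs a [carbon_coefficients] object (or bare numeric vector).
#' @return total emissions (nonnegative scalar).
#' @export
aggregate_carbon <- function(activity, coeffs) {
  cf <- if (inherits(coeffs, "carbon_coefficients")) {
    coeffs$coefficients
  } else as.numeric(coeffs)
  if (length(activity) != length(cf)) {
    stop(sprintf("dimension error: %d activities vs %d coefficients",
                 length(activity), length(cf)))
  }
  if (any(activity < 0)) stop("activity quantities must be nonnegative")
  sum(activity * cf)
}
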