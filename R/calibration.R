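# Weighted-least-squares calibration: observation datasets keyed to
# protocols, the cost function and its EGP-restricted sub-cost, Latin
# hypercube multi-start optimization, and two-stage ensemble selection.

#' Construct a calibration dataset
#'
#' Observations are rows of a data.frame with columns `protocol_id`,
#' `observable` (`glucose`, `insulin`, `NEFA`, `TG`, `EGP_avg`, `GU_avg`),
#' `time` (NA for window averages), `value`, `se` and `source`. The
#' protocols the observations refer to travel with the dataset as an
#' attribute. `TG` rows are carried for transparency (TG is a model input)
#' and are excluded from the cost.
#'
#' @param observations data.frame as described.
#' @param protocols named list of `glunefa_protocol` objects, keyed by
#'   `protocol_id`.
#' @return an object of class `glunefa_dataset`.
#' @export
dataset <- function(observations, protocols) {
  need <- c("protocol_id", "observable", "time", "value", "se", "source")
  missing_cols <- setdiff(need, names(observations))
  if (length(missing_cols))
    stop("dataset missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(observations$se <= 0)) stop("all standard errors must be positive")
  unknown <- setdiff(unique(observations$protocol_id), names(protocols))
  if (length(unknown))
    stop("observations refer to unknown protocol(s): ",
         paste(unknown, collapse = ", "))
  structure(observations, protocols = protocols,
            class = c("glunefa_dataset", "data.frame"))
}

#' @export
print.glunefa_dataset <- function(x, ...) {
  cat("<glunefa_dataset> ", nrow(x), " observations, ",
      length(attr(x, "protocols")), " protocols\n", sep = "")
  print(table(x$source, x$observable))
  invisible(x)
}

#' Combine datasets
#' @param ... `glunefa_dataset` objects.
#' @return a single `glunefa_dataset` with merged protocols.
#' @export
combine_datasets <- function(...) {
  ds <- list(...)
  obs <- do.call(rbind, lapply(ds, function(d) as.data.frame(d)))
  protos <- do.call(c, lapply(ds, attr, "protocols"))
  dataset(obs, protos[!duplicated(names(protos))])
}

#' Model predictions for every observation of a dataset
#'
#' Simulates each referenced protocol once and reads off the predicted
#' value per observation row: plasma concentrations at the observation time
#' for meal observables, window averages for clamp `EGP_avg` / `GU_avg`.
#'
#' @param params a `glunefa_params` object.
#' @param data a `glunefa_dataset`.
#' @return numeric vector of predictions, NA for `TG` rows.
#' @export
predict_observations <- function(params, data) {
  protos <- attr(data, "protocols")
  pred <- rep(NA_real_, nrow(data))
  for (pid in unique(data$protocol_id)) {
    rows <- which(data$protocol_id == pid)
    proto <- protos[[pid]]
    if (proto$kind == "oral_challenge") {
      # integrating only to the observation times keeps calibration cheap
      tt <- sort(unique(c(0, data$time[rows])))
      sim <- simulate_oral_challenge(proto, params, t_grid = tt)
      conc <- plasma_concentrations(sim)
      for (i in rows) {
        ob <- data$observable[i]
        if (ob == "TG") next
        pred[i] <- conc[[ob]][match(data$time[i], conc$time)]
      }
    } else {
      res <- simulate_clamp(proto, params, dt = 2)
      for (i in rows) {
        pred[i] <- switch(data$observable[i],
                          EGP_avg = res$EGP_avg, GU_avg = res$GU_avg,
                          NA_real_)
      }
    }
  }
  pred
}

#' Weighted sum of squared residuals
#'
#' @param pred,obs,se aligned numeric vectors; NA predictions are skipped.
#' @return scalar cost.
#' @export
weighted_ss <- function(pred, obs, se) {
  keep <- !is.na(pred)
  sum(((pred[keep] - obs[keep]) / se[keep])^2)
}

#' Calibration cost function
#'
#' The weighted sum of squared residuals over all fitted observations
#' (Eq-of-record: sum over i of (y_i - y_obs_i)^2 / se_i^2). Simulation
#' failures yield `Inf` (recorded, not raised) so optimizers can continue.
#'
#' @param params a `glunefa_params` object.
#' @param data a `glunefa_dataset`.
#' @param detail if `TRUE`, also return the per-observation residual table.
#' @return scalar cost `V`, or a list `(V, V_EGP, residuals)` when
#'   `detail = TRUE`.
#' @export
cost <- function(params, data, detail = FALSE) {
  pred <- tryCatch(predict_observations(params, data),
                   error = function(e) NULL)
  if (is.null(pred)) {
    if (detail) return(list(V = Inf, V_EGP = Inf, residuals = NULL))
    return(Inf)
  }
  fit_rows <- data$observable != "TG"
  V <- weighted_ss(pred[fit_rows], data$value[fit_rows], data$se[fit_rows])
  if (!detail) return(V)
  egp_rows <- fit_rows & data$observable == "EGP_avg"
  V_EGP <- weighted_ss(pred[egp_rows], data$value[egp_rows],
                       data$se[egp_rows])
  res <- data.frame(protocol_id = data$protocol_id,
                    observable = data$observable, time = data$time,
                    observed = data$value, predicted = pred, se = data$se)
  list(V = V, V_EGP = V_EGP, residuals = res)
}

#' EGP-restricted sub-cost
#'
#' The cost function evaluated on the clamp EGP observations only; used to
#' shade ensemble members by the quality of their EGP fit.
#'
#' @inheritParams cost
#' @return scalar `V_EGP`.
#' @export
v_egp <- function(params, data) {
  keep <- data$observable == "EGP_avg"
  if (!any(keep)) return(0)
  sub <- dataset(as.data.frame(data)[keep, , drop = FALSE],
                 attr(data, "protocols"))
  cost(params, sub)
}

# ---- multi-start optimization ----------------------------------------------

# stratified-permutation Latin hypercube on [0,1]^d
.lhs_unit <- function(n, d) {
  u <- matrix(stats::runif(n * d), n, d)
  for (j in seq_len(d)) u[, j] <- (sample.int(n) - u[, j]) / n
  u
}

# free parameters are optimized on a log10 scale; pC on log10(-pC)
.to_internal <- function(x, nm) if (nm == "pC") log10(-x) else log10(x)
.from_internal <- function(z, nm) if (nm == "pC") -10^z else 10^z

#' Default optimization bounds
#'
#' Bounds spanning two orders of magnitude around the shipped default value
#' of each free parameter (on the magnitude for `pC`).
#'
#' @param params a `glunefa_params` object.
#' @param free character vector of free-parameter names.
#' @param span half-width in decades (default 1, i.e. a 100-fold range).
#' @return 2-row matrix (`lower`, `upper`) with one column per parameter.
#' @export
default_bounds <- function(params, free = names(params$free), span = 1) {
  ctr <- params$free[free]
  lo <- ifelse(free == "pC", -abs(ctr) * 10^span, ctr / 10^span)
  hi <- ifelse(free == "pC", -abs(ctr) / 10^span, ctr * 10^span)
  rbind(lower = stats::setNames(lo, free), upper = stats::setNames(hi, free))
}

#' Multi-start local optimization over free parameters
#'
#' Samples `n_starts` starting points by Latin hypercube over the bounds
#' (log-scaled), runs a bounded quasi-Newton (L-BFGS-B) local optimization
#' from each, and archives every parameter set evaluated along the way with
#' its total cost and EGP sub-cost. Deterministic given `seed`.
#'
#' @param data a `glunefa_dataset`.
#' @param config list with elements:
#'   `base_params` (a `glunefa_params`; defaults to [default_parameters()]),
#'   `free` (names of free parameters to vary; default all 21),
#'   `bounds` (as [default_bounds()]), `n_starts` (default 200),
#'   `seed`, `maxit` (default 50).
#' @param objective optional function `f(free_values_named) -> cost`
#'   replacing the dataset cost (used for self-contained optimizer checks).
#' @return a list of class `glunefa_archive`: `archive` data.frame (one row
#'   per evaluation: start, the free-parameter values, `V`, `V_EGP`),
#'   `best` (row index of minimum), `config`.
#' @export
multistart_optimize <- function(data = NULL, config = list(),
                                objective = NULL) {
  base <- config$base_params %||% default_parameters()
  free <- config$free %||% names(base$free)
  bounds <- config$bounds %||% default_bounds(base, free)
  n_starts <- config$n_starts %||% 200L
  maxit <- config$maxit %||% 50L
  seed <- config$seed %||% 1L
  if (is.null(objective) && is.null(data))
    stop("either a dataset or an objective is required")

  zlo <- mapply(.to_internal, bounds["lower", free], free)
  zhi <- mapply(.to_internal, bounds["upper", free], free)
  swap <- zlo > zhi   # pC: magnitude ordering flips
  tmp <- zlo[swap]; zlo[swap] <- zhi[swap]; zhi[swap] <- tmp

  arch_env <- new.env(parent = emptyenv())
  arch_env$rows <- vector("list", 0)
  eval_cost <- function(z, start_id) {
    vals <- mapply(.from_internal, z, free)
    names(vals) <- free
    if (!is.null(objective)) {
      V <- objective(vals); V_EGP <- NA_real_
    } else {
      p <- tryCatch(update_parameters(base, free = as.list(vals)),
                    error = function(e) NULL)
      if (is.null(p)) {
        V <- Inf; V_EGP <- Inf
      } else {
        cd <- cost(p, data, detail = TRUE)
        V <- cd$V; V_EGP <- cd$V_EGP
      }
    }
    arch_env$rows[[length(arch_env$rows) + 1L]] <-
      c(start = start_id, vals, V = unname(V), V_EGP = unname(V_EGP))
    if (!is.finite(V)) 1e12 else V
  }

  set.seed(seed)
  u <- .lhs_unit(n_starts, length(free))
  starts <- sweep(sweep(u, 2, zhi - zlo, `*`), 2, zlo, `+`)
  ok <- 0L
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[s, ], eval_cost, start_id = s,
                   method = "L-BFGS-B", lower = zlo, upper = zhi,
                   control = list(maxit = maxit, factr = 1e10)),
      error = function(e) NULL)
    if (!is.null(fit)) ok <- ok + 1L
  }
  if (ok == 0L) stop("calibration error: no successful optimization start")
  archive <- as.data.frame(do.call(rbind, arch_env$rows))
  out <- list(archive = archive,
              best = which.min(archive$V),
              config = list(free = free, bounds = bounds,
                            n_starts = n_starts, seed = seed, maxit = maxit,
                            base_params = base))
  class(out) <- "glunefa_archive"
  out
}

#' Two-stage ensemble selection from a sampling archive
#'
#' Stage 1 (`S_ext`): among all sampled parameter sets whose cost lies
#' within 120% of the lowest cost, pick, for every considered parameter,
#' the sets attaining its minimum and its maximum (ingestion parameters are
#' excluded from extremeness), plus the minimum-cost set itself. Stage 2
#' (`S_sel`): the same procedure after additionally requiring the minimal
#' stomach-emptying rate `kra3 >= 0.009` per minute.
#'
#' @param archive a `glunefa_archive`, or a data.frame with free-parameter
#'   columns and a `V` column (and optionally `V_EGP`).
#' @param kra3_min threshold for stage 2, 1/min.
#' @param band multiplicative cost band (1.2 = within 120% of the minimum).
#' @param exclude_extremeness parameters not considered when picking
#'   extremes (default the OFTT ingestion dose).
#' @return a list of class `glunefa_ensemble`: `members` (deduplicated
#'   data.frame with logical `in_Sext`, `in_Ssel`), `V_min`, `band_limit`.
#' @export
select_ensemble <- function(archive, kra3_min = 0.009, band = 1.2,
                            exclude_extremeness = "D_oftt") {
  arch <- if (inherits(archive, "glunefa_archive")) archive$archive
    else as.data.frame(archive)
  base <- if (inherits(archive, "glunefa_archive"))
    archive$config$base_params else NULL
  pcols <- setdiff(names(arch), c("start", "V", "V_EGP"))
  arch <- arch[is.finite(arch$V), , drop = FALSE]
  if (!nrow(arch)) stop("selection error: archive has no finite-cost member")
  V_min <- min(arch$V)
  limit <- band * V_min
  in_band <- arch[arch$V <= limit, , drop = FALSE]
  if (!nrow(in_band)) stop("selection error: empty cost band")

  extreme_rows <- function(df) {
    cols <- setdiff(pcols, exclude_extremeness)
    idx <- unlist(lapply(cols, function(cn)
      c(which.min(df[[cn]]), which.max(df[[cn]]))))
    # the minimum-cost member is always carried along with the extremes
    sort(unique(c(idx, which.min(df$V))))
  }
  kra3_of <- function(df) {
    if ("kra3" %in% pcols) df$kra3
    else rep(if (!is.null(base)) base$free[["kra3"]] else NA_real_, nrow(df))
  }

  ext_idx <- extreme_rows(in_band)
  sel_pool <- in_band[kra3_of(in_band) >= kra3_min, , drop = FALSE]
  sel_idx <- if (nrow(sel_pool)) extreme_rows(sel_pool) else integer(0)

  members <- rbind(in_band[ext_idx, , drop = FALSE],
                   sel_pool[sel_idx, , drop = FALSE])
  flags <- rbind(
    data.frame(in_Sext = TRUE, in_Ssel = FALSE)[rep(1, length(ext_idx)), ],
    data.frame(in_Sext = FALSE, in_Ssel = TRUE)[rep(1, length(sel_idx)), ])
  members <- cbind(members, flags)

  # deduplicate by relative parameter-vector equality (10 significant digits)
  key <- apply(members[pcols], 1, function(r)
    paste(signif(as.numeric(r), 10), collapse = "|"))
  out <- members[!duplicated(key), , drop = FALSE]
  out$in_Sext <- vapply(key[!duplicated(key)], function(k)
    any(members$in_Sext[key == k]), logical(1))
  out$in_Ssel <- vapply(key[!duplicated(key)], function(k)
    any(members$in_Ssel[key == k]), logical(1))
  rownames(out) <- NULL
  structure(list(members = out, V_min = V_min, band_limit = limit,
                 parameters = pcols),
            class = "glunefa_ensemble")
}

#' @export
print.glunefa_ensemble <- function(x, ...) {
  cat("<glunefa_ensemble> ", nrow(x$members), " members (",
      sum(x$members$in_Sext), " in S_ext, ", sum(x$members$in_Ssel),
      " in S_sel); V_min = ", signif(x$V_min, 5), "\n", sep = "")
  invisible(x)
}

#' Materialize an ensemble member as a parameter set
#'
#' @param ens a `glunefa_ensemble`.
#' @param i member row index.
#' @param base_params baseline `glunefa_params` whose free entries are
#'   overridden by the member's values.
#' @return a `glunefa_params`.
#' @export
ensemble_member_params <- function(ens, i, base_params) {
  vals <- as.list(ens$members[i, ens$parameters])
  update_parameters(base_params, free = vals)
}

#' Write an archive or ensemble as JSON lines
#' @param x a `glunefa_archive` or `glunefa_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(x, path) {
  df <- if (inherits(x, "glunefa_ensemble")) x$members else x$archive
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df)))
    writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}
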