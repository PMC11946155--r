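#' Stepwise multiple regression (forward entry, backward removal)
#'
#' At each step the candidate predictor with the smallest entry p-value is
#' added if that p-value is at or below `p_enter`; then any included
#' predictor whose p-value exceeds `p_remove` is removed (worst first). The
#' loop runs to a fixed point. Coefficients are reported standardised (both
#' predictors and response z-scored); t and p come from the unstandardised
#' fit and are identical by scale invariance.
#'
#' @param X data frame or matrix of candidate predictors (named columns).
#' @param y numeric response.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @param max_steps safety bound on entry/removal iterations.
#' @return list of class `oscdyn_stepwise`: `selected` (names), `beta`
#'   (standardised), `t`, `p` (final model), `r_squared`, `trace` (data frame
#'   of step/action/predictor/p), `n`.
#' @export
stepwise_regress <- function(X, y, p_enter = 0.05, p_remove = 0.10,
                             max_steps = 50) {
  X <- as.data.frame(X)
  if (anyDuplicated(names(X))) stop("duplicate predictor names", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values", call. = FALSE)
  n <- length(y)
  if (n != nrow(X)) stop("predictor/response length mismatch", call. = FALSE)
  if (n <= ncol(X) + 2) stop("too few cases for the predictor pool", call. = FALSE)
  if (ncol(X) && kappa(cbind(1, as.matrix(X)), exact = FALSE) > 1e8) {
    warning("near-collinear predictor pool")
  }
  vars <- names(X)
  included <- character(0)
  trace <- list()
  step_i <- 0L
  pval_of <- function(fit) {
    co <- summary(fit)$coefficients
    stats::setNames(co[-1, 4], rownames(co)[-1])  # drop intercept, keep names
  }
  fit_with <- function(sel) {
    stats::lm(y ~ ., data = cbind(X[, sel, drop = FALSE], y = y))
  }
  repeat {
    step_i <- step_i + 1L
    if (step_i > max_steps) break
    changed <- FALSE
    cands <- setdiff(vars, included)
    if (length(cands)) {
      entry_p <- vapply(cands, function(v) {
        fit <- fit_with(c(included, v))
        p <- unname(pval_of(fit)[v])
        if (length(p) != 1 || is.na(p)) Inf else p  # collinear candidate: never enters
      }, numeric(1))
      best <- which.min(entry_p)
      if (entry_p[best] <= p_enter) {
        included <- c(included, cands[best])
        trace[[length(trace) + 1L]] <- data.frame(
          step = step_i, action = "enter", predictor = cands[best],
          p = entry_p[best])
        changed <- TRUE
      }
    }
    if (length(included)) {
      pv <- pval_of(fit_with(included))[included]
      pv[is.na(pv)] <- Inf  # collinear within the model: drop it
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        out <- included[worst]
        included <- setdiff(included, out)
        trace[[length(trace) + 1L]] <- data.frame(
          step = step_i, action = "remove", predictor = out, p = pv[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(included)) {
    fit <- fit_with(included)
    sm <- summary(fit)
    co <- sm$coefficients[-1, , drop = FALSE]
    sx <- vapply(X[included], stats::sd, numeric(1))
    beta <- co[, 1] * sx / stats::sd(y)
    res <- list(selected = included, beta = beta, t = co[, 3], p = co[, 4],
                r_squared = sm$r.squared)
  } else {
    res <- list(selected = character(0), beta = numeric(0), t = numeric(0),
                p = numeric(0), r_squared = 0)
  }
  res$trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), action = character(0),
               predictor = character(0), p = numeric(0))
  res$n <- n
  class(res) <- "oscdyn_stepwise"
  res
}

#' Run the full linkage-regression suite
#'
#' One stepwise regression of every behavioural measure and every ERP
#' component amplitude on the prestimulus predictors (oscillation component
#' amplitudes plus pink- and white-noise amplitudes at 1 Hz), followed by the
#' secondary suite regressing behaviour on the EEG-affected ERP components.
#'
#' @param predictors data frame, one row per participant (e.g. columns `DT`,
#'   `TA`, `A1`, `AB`, `B1`, `PN`, `WN`).
#' @param erp data frame of per-participant ERP component amplitudes
#'   (column names e.g. `go_P3b`).
#' @param behaviour data frame of per-participant behavioural measures.
#' @param p_enter,p_remove stepwise thresholds.
#' @return list with `primary` (named list of `oscdyn_stepwise`, one per
#'   dependent variable) and `secondary` (behaviour on EEG-affected ERPs;
#'   empty when no ERP was affected).
#' @export
run_linkage_suite <- function(predictors, erp, behaviour,
                              p_enter = 0.05, p_remove = 0.10) {
  nr <- nrow(predictors)
  if (nrow(erp) != nr || nrow(behaviour) != nr) {
    stop("participant tables are misaligned", call. = FALSE)
  }
  dvs <- c(as.list(behaviour), as.list(erp))
  primary <- lapply(dvs, function(y)
    stepwise_regress(predictors, y, p_enter, p_remove))
  affected <- names(erp)[vapply(names(erp), function(nm)
    length(primary[[nm]]$selected) > 0, logical(1))]
  secondary <- if (length(affected)) {
    lapply(as.list(behaviour), function(y)
      stepwise_regress(erp[, affected, drop = FALSE], y, p_enter, p_remove))
  } else list()
  list(primary = primary, secondary = secondary)
}

#' Tidy a set of stepwise results into one data frame
#'
#' @param results named list of `oscdyn_stepwise`.
#' @return data frame with one row per selected predictor per dependent.
#' @export
tidy_stepwise <- function(results) {
  rows <- lapply(names(results), function(dv) {
    r <- results[[dv]]
    if (!length(r$selected)) {
      return(data.frame(dependent = dv, predictor = NA_character_,
                        beta = NA_real_, t = NA_real_, p = NA_real_,
                        r_squared = r$r_squared))
    }
    data.frame(dependent = dv, predictor = r$selected, beta = unname(r$beta),
               t = unname(r$t), p = unname(r$p), r_squared = r$r_squared)
  })
  do.call(rbind, rows)
}
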