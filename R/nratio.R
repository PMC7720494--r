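#' Distance of a hazard ratio from the null value
#'
#' The elementary weight of the modified staging: the absolute distance
#' between a fitted hazard ratio and the statistical null point HR = 1.
#'
#' @param hr Positive hazard ratio(s).
#' @return `|hr - 1|`, vectorised.
#' @export
#' @examples
#' nratio_delta_hr(1.064) # 0.064
#' nratio_delta_hr(0.962) # 0.038
nratio_delta_hr <- function(hr) {
  assert_that(is.numeric(hr) && all(is.finite(hr)) && all(hr > 0),
              "domain error: hazard ratio must be a positive finite number")
  abs(hr - 1)
}

#' Weighting coefficient from the two delta-HR distances
#'
#' The ratio of the positive-node distance to the negative-node distance;
#' used as the coefficient that re-adjusts the raw positive/negative node
#' count ratio.
#'
#' @param delta_pos Distance of the positive-node HR from 1 (>= 0).
#' @param delta_neg Distance of the negative-node HR from 1 (> 0).
#' @return `delta_pos / delta_neg`.
#' @export
nratio_weight <- function(delta_pos, delta_neg) {
  assert_that(is.numeric(delta_pos) && all(delta_pos >= 0),
              "domain error: delta_pos must be >= 0")
  assert_that(is.numeric(delta_neg) && all(is.finite(delta_neg)) && all(delta_neg > 0),
              paste("degenerate weight: delta_neg is 0 - the negative-node effect is",
                    "indistinguishable from the null, no ratio coefficient exists"))
  delta_pos / delta_neg
}

#' Delta-HR weights from the two per-node hazard ratios
#'
#' @param hr_pln,hr_nln Fitted hazard ratios per positive / negative node.
#' @return An `nratio_weights` object: `hr_pln`, `hr_nln`, `delta_pos`,
#'   `delta_neg`, and their quotient `coef`.
#' @export
#' @examples
#' w <- nratio_weights(1.064, 0.962)
#' w$coef # 0.064 / 0.038
nratio_weights <- function(hr_pln, hr_nln) {
  delta_pos <- nratio_delta_hr(hr_pln)
  delta_neg <- nratio_delta_hr(hr_nln)
  coef <- nratio_weight(delta_pos, delta_neg)
  structure(
    list(hr_pln = hr_pln, hr_nln = hr_nln,
         delta_pos = delta_pos, delta_neg = delta_neg, coef = coef),
    class = "nratio_weights"
  )
}

#' @export
print.nratio_weights <- function(x, ...) {
  cat(sprintf(
    "<nratio_weights> HR(PLN) = %.4f, HR(NLN) = %.4f; delta+ = %.4f, delta- = %.4f; coef = %.5f\n",
    x$hr_pln, x$hr_nln, x$delta_pos, x$delta_neg, x$coef
  ))
  invisible(x)
}

#' Configuration of the zero-count rules for the re-adjusted N ratio
#'
#' Two conventions govern zero node counts: when both counts are zero the
#' ratio is defined as 0 (the patient is fixed at stage N0); when exactly
#' one count is zero it is replaced by a small positive substitute
#' (default 0.0001) before division. `pln_zero_policy` controls how a
#' node-negative patient (zero positive nodes but examined negative nodes)
#' is treated: `"literal"` applies the substitution rule, giving a tiny
#' positive ratio (the patient is staged by the scan, in practice N1);
#' `"clinical"` maps any zero positive-node count to ratio 0 (N0), matching
#' the conventional meaning of node-negative disease.
#'
#' @param zero_substitute Positive constant replacing a single zero count.
#' @param pln_zero_policy `"literal"` (default) or `"clinical"`.
#' @return An `nratio_config` object.
#' @export
nratio_config <- function(zero_substitute = 1e-4,
                          pln_zero_policy = c("literal", "clinical")) {
  assert_that(is.numeric(zero_substitute) && zero_substitute > 0,
              "zero_substitute must be > 0")
  structure(
    list(zero_substitute = zero_substitute,
         both_zero_value = 0,
         pln_zero_policy = match.arg(pln_zero_policy)),
    class = "nratio_config"
  )
}

#' Re-adjusted N ratio per patient
#'
#' The per-patient staging score: the weighting coefficient (delta-HR ratio)
#' times the positive/negative node-count quotient, with the zero-count
#' rules of [nratio_config()] applied first.
#'
#' @param n_pln,n_nln Non-negative integer node counts (vectorised).
#' @param weights An [nratio_weights()] object, or a single numeric
#'   coefficient.
#' @param config An [nratio_config()].
#' @return Numeric ratio(s) >= 0.
#' @export
#' @examples
#' w <- nratio_weights(1.064, 0.962)
#' readjusted_n_ratio(0, 0, w)  # both zero -> 0
#' readjusted_n_ratio(0, 20, w) # single zero -> coef * 1e-4 / 20
readjusted_n_ratio <- function(n_pln, n_nln, weights, config = nratio_config()) {
  coef <- if (inherits(weights, "nratio_weights")) weights$coef else weights
  assert_that(is.numeric(coef) && length(coef) == 1 && is.finite(coef) && coef >= 0,
              "weights must be an nratio_weights object or a single non-negative number")
  assert_that(inherits(config, "nratio_config"), "config must come from nratio_config()")
  assert_that(length(n_pln) == length(n_nln), "node-count vectors must have equal length")
  ok <- !is.na(n_pln) & !is.na(n_nln)
  assert_that(all(is_whole(n_pln[ok]) & n_pln[ok] >= 0) &&
                all(is_whole(n_nln[ok]) & n_nln[ok] >= 0),
              "domain error: node counts must be non-negative integers")

  p <- as.numeric(n_pln)
  q <- as.numeric(n_nln)
  out <- rep(NA_real_, length(p))
  both_zero <- ok & p == 0 & q == 0
  out[both_zero] <- config$both_zero_value

  rest <- ok & !both_zero
  if (config$pln_zero_policy == "clinical") {
    clin0 <- rest & p == 0
    out[clin0] <- 0
    rest <- rest & p > 0
  }
  p_adj <- ifelse(p == 0, config$zero_substitute, p)
  q_adj <- ifelse(q == 0, config$zero_substitute, q)
  out[rest] <- coef * p_adj[rest] / q_adj[rest]
  out
}

#' Add the re-adjusted N ratio to a cohort
#'
#' @param data Cohort data frame with node-count columns.
#' @param weights An [nratio_weights()] object or coefficient.
#' @param config An [nratio_config()].
#' @param pln,nln Node-count column names.
#' @return `data` with an `n_ratio` column appended.
#' @export
add_n_ratio <- function(data, weights, config = nratio_config(),
                        pln = "n_pln", nln = "n_nln") {
  assert_cols(data, c(pln, nln), "cohort")
  dplyr::mutate(
    tibble::as_tibble(data),
    n_ratio = readjusted_n_ratio(data[[pln]], data[[nln]], weights, config)
  )
}

#' Stage cutoffs on the re-adjusted ratio scale
#'
#' Two cutpoints defining the modified stages with left-open right-closed
#' intervals: N0 at ratio 0, N1 on (0, c1], N2 on (c1, c2], N3 above c2.
#'
#' @param c1,c2 Cutpoints with `0 < c1 < c2`.
#' @return A `stage_cutoffs` object.
#' @export
stage_cutoffs <- function(c1, c2) {
  assert_that(is.numeric(c1) && is.numeric(c2) && length(c1) == 1 && length(c2) == 1 &&
                is.finite(c1) && is.finite(c2) && 0 < c1 && c1 < c2,
              "cutoffs must satisfy 0 < c1 < c2")
  structure(list(c1 = c1, c2 = c2, convention = "left-open right-closed; ratio 0 -> N0"),
            class = "stage_cutoffs")
}

#' @export
print.stage_cutoffs <- function(x, ...) {
  cat(sprintf("<stage_cutoffs> N0: ratio = 0 | N1: (0, %.4g] | N2: (%.4g, %.4g] | N3: (%.4g, Inf)\n",
              x$c1, x$c1, x$c2, x$c2))
  invisible(x)
}

#' Assign modified N stages from re-adjusted ratios
#'
#' @param ratio Numeric ratio(s) >= 0 (as from [readjusted_n_ratio()]).
#' @param cutoffs A [stage_cutoffs()] object (or numeric length-2 vector).
#' @return Ordered factor with levels N0 < N1 < N2 < N3.
#' @export
#' @examples
#' assign_stage(c(0, 0.08, 0.5, 0.64), stage_cutoffs(0.08, 0.63))
assign_stage <- function(ratio, cutoffs) {
  if (is.numeric(cutoffs) && length(cutoffs) == 2) {
    cutoffs <- stage_cutoffs(cutoffs[1], cutoffs[2])
  }
  assert_that(inherits(cutoffs, "stage_cutoffs"), "cutoffs must come from stage_cutoffs()")
  assert_that(is.numeric(ratio) && all(is.na(ratio) | ratio >= 0),
              "domain error: ratios must be >= 0")
  lev <- c("N0", "N1", "N2", "N3")
  idx <- ifelse(ratio == 0, 1L,
         ifelse(ratio <= cutoffs$c1, 2L,
         ifelse(ratio <= cutoffs$c2, 3L, 4L)))
  factor(lev[idx], levels = lev, ordered = TRUE)
}
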