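# HDR score estimation: replicate DR-GFP fold changes -> per-variant scores
# with 95% credible intervals and a Functional / NonFunctional /
# Indeterminate call.
#
# Model. Fold changes are positive and multiplicative, so inference is on the
# log of the rescaled score. Per variant the mean log score carries a
# noninformative (Jeffreys) prior; the posterior is then the scaled
# Student-t, whose 2.5/97.5 percentiles give the 95% credible interval. When
# measurements come from several independently derived clones, inference is
# on the clone means, which absorbs the clone-level random effect without
# requiring a variance decomposition at n of 4-8.

#' Normalization anchors for the 1:5 rescaling
#'
#' The assay is anchored by the p.Asp2723His pathogenic control (rescaled to
#' score 1) and the wild-type benign control (rescaled to 5).
#'
#' @param pathogenic_control_mean Mean raw fold change of the pathogenic
#'   control.
#' @param wildtype_mean Mean raw fold change of wild-type BRCA2.
#' @return List with the two anchor means and the 1/5 targets.
#' @export
hdr_anchors <- function(pathogenic_control_mean, wildtype_mean) {
  stopifnot(is.numeric(pathogenic_control_mean), is.numeric(wildtype_mean))
  if (wildtype_mean <= pathogenic_control_mean) {
    stop("calibration error: wildtype_mean must exceed pathogenic_control_mean")
  }
  list(pathogenic_control_mean = pathogenic_control_mean,
       wildtype_mean = wildtype_mean,
       target_low = 1, target_high = 5)
}

#' Rescale raw fold changes to the 1:5 control-anchored scale
#'
#' Affine map sending the pathogenic-control mean exactly to 1 and the
#' wild-type mean exactly to 5:
#' `s = 1 + 4 * (x - pathogenic) / (wildtype - pathogenic)`.
#'
#' @param x Numeric vector of raw fold changes.
#' @param anchors Anchors from [hdr_anchors()].
#' @return Rescaled values.
#' @export
normalize_fold_change <- function(x, anchors) {
  stopifnot(is.numeric(x))
  p <- anchors$pathogenic_control_mean
  w <- anchors$wildtype_mean
  if (w <= p) stop("calibration error: wildtype_mean must exceed pathogenic_control_mean")
  1 + 4 * (x - p) / (w - p)
}

#' Functional-call thresholds on the credible-interval bounds
#'
#' A variant is non-functional when the upper bound of its 95% interval is
#' below 1.66 (probability of pathogenicity > 0.99) and functional when the
#' lower bound exceeds 2.25 (probability of neutrality > 0.95). Comparisons
#' are strict; boundary-equal values are Indeterminate.
#'
#' @param nonfunctional_upper Upper-bound cutoff (default 1.66).
#' @param functional_lower Lower-bound cutoff (default 2.25).
#' @return List of the two thresholds.
#' @export
function_thresholds <- function(nonfunctional_upper = 1.66,
                                functional_lower = 2.25) {
  if (!(nonfunctional_upper < functional_lower)) {
    stop("nonfunctional_upper must be below functional_lower")
  }
  list(nonfunctional_upper = nonfunctional_upper,
       functional_lower = functional_lower)
}

#' Fit the per-variant model for HDR scores
#'
#' Rescales raw fold changes with the control anchors, takes logs, and
#' summarizes the posterior of the mean log score per variant. Two backends:
#' `"analytic"` evaluates the Student-t posterior quantiles in closed form
#' (deterministic); `"mcmc"` draws from the same conjugate
#' normal/scaled-inverse-chi-square posterior by Monte Carlo and summarizes
#' the draws, agreeing with the analytic backend to Monte-Carlo error.
#'
#' Variants with fewer than two measurements are excluded with a warning.
#' Rescaled values at or below zero (possible under noise below the
#' pathogenic anchor) are floored at `floor_eps` before the log and flagged.
#' Zero-variance variants return a width-zero interval with a warning.
#'
#' @param measurements data.frame with columns `variant_id`, `clone_id`,
#'   `replicate_id`, `fold_change` (raw values when `anchors` is supplied,
#'   otherwise already on the 1:5 scale).
#' @param anchors Anchors from [hdr_anchors()], or NULL if `fold_change` is
#'   already rescaled.
#' @param backend `"analytic"` or `"mcmc"`.
#' @param level Credible level (default 0.95; 0.99 gives the wider reading).
#' @param seed Seed for the `"mcmc"` backend.
#' @param n_draws Monte Carlo draws for the `"mcmc"` backend.
#' @param floor_eps Positivity floor applied to rescaled values.
#' @param by_clone Aggregate to clone means before inference when a variant
#'   has two or more clones (default TRUE).
#' @return data.frame with columns `variant_id`, `score`, `ci_lower`,
#'   `ci_upper`, `n_measurements`, `n_units`, `floored`.
#' @export
fit_hdr_model <- function(measurements, anchors = NULL,
                          backend = c("analytic", "mcmc"),
                          level = 0.95, seed = 20210219L, n_draws = 8000L,
                          floor_eps = 0.01, by_clone = TRUE) {
  backend <- match.arg(backend)
  stopifnot(all(c("variant_id", "clone_id", "fold_change") %in% names(measurements)),
            level > 0, level < 1, floor_eps > 0)
  vals <- measurements$fold_change
  if (!is.null(anchors)) vals <- normalize_fold_change(vals, anchors)

  ids <- unique(measurements$variant_id)
  if (backend == "mcmc") set.seed(as.integer(seed) %% .Machine$integer.max)
  alpha <- (1 - level) / 2

  rows <- lapply(ids, function(id) {
    sel <- measurements$variant_id == id
    v <- vals[sel]
    cl <- measurements$clone_id[sel]
    if (length(v) < 2) {
      warning("variant ", id, " excluded: fewer than 2 measurements")
      return(NULL)
    }
    floored <- any(v <= 0)
    if (floored) {
      warning("variant ", id, ": rescaled value <= 0 floored at ", floor_eps)
      v <- pmax(v, floor_eps)
    }
    y <- log(v)
    if (by_clone && length(unique(cl)) >= 2) {
      y <- as.numeric(tapply(y, cl, mean))
    }
    k <- length(y)
    m <- mean(y)
    s <- stats::sd(y)
    if (k < 2 || s == 0) {
      warning("variant ", id, ": zero posterior variance; width-0 interval")
      lo <- hi <- m
    } else if (backend == "analytic") {
      hw <- stats::qt(1 - alpha, df = k - 1) * s / sqrt(k)
      lo <- m - hw
      hi <- m + hw
    } else {
      sigma2 <- (k - 1) * s^2 / stats::rchisq(n_draws, df = k - 1)
      mu <- stats::rnorm(n_draws, mean = m, sd = sqrt(sigma2 / k))
      q <- stats::quantile(mu, c(alpha, 0.5, 1 - alpha), names = FALSE)
      lo <- q[1]; m <- q[2]; hi <- q[3]
    }
    data.frame(variant_id = id, score = exp(m), ci_lower = exp(lo),
               ci_upper = exp(hi), n_measurements = length(v), n_units = k,
               floored = floored, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(0), score = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      n_measurements = integer(0), n_units = integer(0),
                      floored = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Call variants functional / non-functional from their credible intervals
#'
#' NonFunctional iff `ci_upper < nonfunctional_upper`; Functional iff
#' `ci_lower > functional_lower`; otherwise Indeterminate. The two positive
#' calls are mutually exclusive since the cutoffs satisfy 1.66 < 2.25 and
#' `ci_lower <= ci_upper`. A missing `ci_lower` (as in the printed table,
#' which reports only upper bounds) disables the Functional rule for that
#' variant.
#'
#' @param estimates data.frame with `ci_lower` and `ci_upper` columns (e.g.
#'   from [fit_hdr_model()]).
#' @param thresholds From [function_thresholds()].
#' @return `estimates` with an added `call` column.
#' @export
classify_function <- function(estimates, thresholds = function_thresholds()) {
  stopifnot(all(c("ci_lower", "ci_upper") %in% names(estimates)))
  bad <- !is.na(estimates$ci_lower) & !is.na(estimates$ci_upper) &
    estimates$ci_lower > estimates$ci_upper
  if (any(bad)) stop("malformed estimate: ci_lower > ci_upper")
  nonfn <- !is.na(estimates$ci_upper) &
    estimates$ci_upper < thresholds$nonfunctional_upper
  fn <- !is.na(estimates$ci_lower) &
    estimates$ci_lower > thresholds$functional_lower
  call <- rep("Indeterminate", nrow(estimates))
  call[nonfn] <- "NonFunctional"
  call[fn] <- "Functional"
  estimates$call <- call
  estimates
}

#' Load the 90 printed HDR estimates as score estimates
#'
#' The printed table reports the score and the upper 95% bound only; the
#' lower bound is left `NA` and the functional call is derived from the
#' upper-bound rule alone.
#'
#' Printed bounds are rounded to two decimals, so a bound can be pushed onto
#' the cutoff by rounding: p.Glu2599Gly prints (1.66) yet carries the
#' recorded PS3 application, meaning its unrounded upper bound sits below
#' the cutoff. A printed tie at the cutoff is therefore resolved by the
#' table's own functional-code column; all other rows go through the strict
#' [classify_function()] rule unchanged.
#'
#' @param path Fixture path, defaulting to the packaged table.
#' @param thresholds From [function_thresholds()].
#' @return data.frame of estimates with a `call` column (90 rows).
#' @export
load_table1_estimates <- function(path = table1_path(),
                                  thresholds = function_thresholds()) {
  tab <- read_table1(path, verify_checksum = identical(path, table1_path()))
  est <- data.frame(variant_id = tab$hgvs_p,
                    score = tab$hdr_score,
                    ci_lower = NA_real_,
                    ci_upper = tab$hdr_upper_ci,
                    n_measurements = NA_integer_,
                    stringsAsFactors = FALSE)
  est <- classify_function(est, thresholds)
  tie <- est$ci_upper == thresholds$nonfunctional_upper & tab$ps3 == "PS3"
  est$call[tie] <- "NonFunctional"
  est
}
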