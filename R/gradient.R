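## Glycerol-gradient deconvolution of BAF subcomplex abundances.
##
## Subtype marker blots (BRD9 -> GBAF, DPF2 -> CBAF, PBRM1 -> PBAF) across
## 24 gradient fractions are each fitted with a Gaussian in fraction index.
## The pan-BAF subunit SMARCC1 is modeled as a convex mixture of the three
## fitted component densities over fractions 12-24, and the integer
## percentage triple (GBAF, CBAF, PBAF) minimizing the sum of squared
## differences over those fractions is found by exhaustive search.

GRADIENT_RANGE <- 12:24

#' Read a densitometry table
#'
#' Tab-separated with header: `marker`, then `f1` .. `f24` intensity
#' columns (densitometry units, nonnegative).
#'
#' @param path TSV file
#' @return data.frame with `marker` and a 24-column intensity matrix
#' @export
read_gradient_profiles <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  fcols <- paste0("f", 1:24)
  miss <- setdiff(c("marker", fcols), names(tab))
  if (length(miss) > 0) stop("densitometry table missing columns: ",
                             paste(miss, collapse = ", "))
  if (any(as.matrix(tab[fcols]) < 0)) stop("negative densitometry intensity")
  tab[c("marker", fcols)]
}

#' Write a densitometry table
#' @param profiles data.frame as returned by [read_gradient_profiles()]
#' @param path output file
#' @export
write_gradient_profiles <- function(profiles, path) {
  write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.profile_vector <- function(profiles, marker) {
  row <- profiles[profiles$marker == marker, , drop = FALSE]
  if (nrow(row) != 1) stop("expected exactly one row for marker ", marker)
  as.numeric(row[1, paste0("f", 1:24)])
}

#' Normalize a gradient profile over the analysis range
#'
#' Restricts to fractions `range` (default 12-24, where assembled BAF
#' complexes sediment) and rescales to unit sum, making profiles
#' comparable across markers regardless of blot exposure.
#'
#' @param intensities 24 nonnegative values (fractions 1-24)
#' @param range fraction indices to keep
#' @return vector over `range` summing to 1
#' @export
normalize_profile <- function(intensities, range = GRADIENT_RANGE) {
  stopifnot(length(intensities) == 24, all(intensities >= 0))
  v <- intensities[range]
  s <- sum(v)
  if (s <= 0) stop("profile has zero total intensity over the analysis range")
  v / s
}

#' Fit a Gaussian component to a marker profile
#'
#' Least-squares fit of `amplitude * exp(-(x - mean)^2 / (2 sd^2))` to the
#' intensities over the analysis range, initialized from intensity-weighted
#' moments. Falls back to the moment estimates if the nonlinear fit fails
#' to converge (the two agree exactly on noise-free Gaussian input).
#'
#' @param intensities 24 intensity values
#' @param subtype label stored on the result (`GBAF`, `CBAF` or `PBAF`)
#' @param range fraction indices used for fitting
#' @return list with `subtype`, `mean`, `sd`, `amplitude`, `converged`
#' @export
fit_component <- function(intensities, subtype = NA_character_,
                          range = GRADIENT_RANGE) {
  y <- intensities[range]
  x <- range
  if (sum(y) <= 0) stop("no signal in the analysis range")
  w <- y / sum(y)
  m0 <- sum(w * x)
  s0 <- sqrt(sum(w * (x - m0)^2))
  if (!is.finite(s0) || s0 < 0.1)
    stop("degenerate profile: fitted sd would collapse below 0.1 fractions")
  a0 <- max(y)
  fit <- tryCatch({
    nl <- minpack.lm::nlsLM(
      y ~ a * exp(-(x - m)^2 / (2 * s^2)),
      start = list(a = a0, m = m0, s = s0),
      lower = c(a = 0, m = 10, s = 0.1),
      upper = c(a = Inf, m = 26, s = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(nl)
    list(mean = unname(cf["m"]), sd = unname(cf["s"]),
         amplitude = unname(cf["a"]), converged = TRUE)
  }, error = function(e) {
    list(mean = m0, sd = s0, amplitude = a0, converged = FALSE)
  })
  if (fit$sd < 0.1) stop("degenerate profile: fitted sd below 0.1 fractions")
  list(subtype = subtype, mean = fit$mean, sd = fit$sd,
       amplitude = fit$amplitude, converged = fit$converged)
}

## Unit-sum component density sampled at the analysis fractions.
.component_phi <- function(component, range = GRADIENT_RANGE) {
  d <- stats::dnorm(range, component$mean, component$sd)
  d / sum(d)
}

#' Predicted SMARCC1 distribution for a candidate mixture
#'
#' Each subtype's unit-normalized density over the analysis fractions is
#' weighted by its candidate percentage; the mixture sums to 1.
#'
#' @param components list of three fitted components, in order
#'   (GBAF, CBAF, PBAF)
#' @param pct integer triple summing to 100
#' @param range fraction indices
#' @return predicted vector over `range`, summing to 1
#' @export
predict_mixture <- function(components, pct, range = GRADIENT_RANGE) {
  stopifnot(length(pct) == 3, sum(pct) == 100, all(pct >= 0))
  phi <- vapply(components, .component_phi, numeric(length(range)),
                range = range)
  as.numeric(phi %*% (pct / 100))
}

## All nonnegative integer triples summing to 100 (5151 of them),
## in lexicographic order on (GBAF, CBAF, PBAF).
.candidate_triples <- function() {
  g <- rep(0:100, times = 101:1)
  c_ <- unlist(lapply(0:100, function(i) 0:(100 - i)))
  cbind(GBAF = g, CBAF = c_, PBAF = 100 - g - c_)
}

#' Estimate subtype percentages by exhaustive integer grid search
#'
#' Tests every integer percentage triple (GBAF, CBAF, PBAF) summing to
#' 100 (5,151 candidates) and returns the one minimizing the sum of
#' squared differences between the predicted mixture and the observed
#' (normalized) SMARCC1 distribution over fractions 12-24. Ties are broken
#' by lexicographic order on (GBAF, CBAF, PBAF).
#'
#' @param components list of three fitted components (GBAF, CBAF, PBAF)
#' @param observed 24 SMARCC1 intensity values
#' @param range fraction indices
#' @return list with `pct` (named integer triple), `sse`, `residuals`
#'   (observed - predicted over `range`), and `observed_norm`
#' @export
fit_mixture <- function(components, observed, range = GRADIENT_RANGE) {
  obs <- normalize_profile(observed, range)
  phi <- vapply(components, .component_phi, numeric(length(range)),
                range = range)
  W <- .candidate_triples()
  pred <- phi %*% t(W / 100)           # |range| x 5151
  sse <- colSums((pred - obs)^2)
  best <- which.min(sse)               # which.min takes the first: lexicographic
  pct <- W[best, ]
  list(pct = pct, sse = sse[best],
       residuals = obs - pred[, best],
       observed_norm = obs)
}

#' Bootstrap intervals for the mixture estimate
#'
#' Residual-resampling bootstrap: residuals of the best fit are resampled
#' with replacement, added to the fitted values, and the grid search is
#' repeated. Percentile intervals per component are returned.
#'
#' @param components list of three fitted components
#' @param observed 24 SMARCC1 intensity values
#' @param n_boot number of bootstrap replicates (>= 100)
#' @param seed integer seed
#' @param level interval coverage (default 0.9)
#' @param range fraction indices
#' @return list with `point` (the data estimate), `lower`, `upper`
#'   (named triples), and the bootstrap `draws` matrix
#' @export
bootstrap_mixture <- function(components, observed, n_boot = 1000, seed = 1,
                              level = 0.9, range = GRADIENT_RANGE) {
  stopifnot(n_boot >= 100)
  est <- fit_mixture(components, observed, range)
  fitted <- est$observed_norm - est$residuals
  k <- length(range)
  draws <- .with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      y <- fitted + sample(est$residuals, k, replace = TRUE)
      y <- pmax(y, 0)
      if (sum(y) <= 0) return(est$pct)
      full <- numeric(24); full[range] <- y
      fit_mixture(components, full, range)$pct
    }, numeric(3)))
  })
  colnames(draws) <- c("GBAF", "CBAF", "PBAF")
  alpha <- (1 - level) / 2
  lower <- apply(draws, 2, stats::quantile, probs = alpha, names = FALSE)
  upper <- apply(draws, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  ## intervals must contain the point estimate
  lower <- pmin(lower, est$pct)
  upper <- pmax(upper, est$pct)
  list(point = est$pct, lower = lower, upper = upper, draws = draws)
}

#' Full gradient deconvolution from a densitometry table
#'
#' Fits the three subtype components from their marker rows and estimates
#' the SMARCC1 mixture percentages.
#'
#' @param profiles densitometry data.frame (see [read_gradient_profiles()])
#' @param markers named character vector mapping marker to subtype,
#'   default `c(BRD9 = "GBAF", DPF2 = "CBAF", PBRM1 = "PBAF")`
#' @param observed_marker pan-BAF marker row, default `"SMARCC1"`
#' @param range fraction indices
#' @param n_boot bootstrap replicates (0 to skip)
#' @param seed seed for the bootstrap
#' @return list with `components`, `estimate` (from [fit_mixture()]), and
#'   optionally `bootstrap`
#' @export
deconvolve_gradient <- function(profiles,
                                markers = c(BRD9 = "GBAF", DPF2 = "CBAF",
                                            PBRM1 = "PBAF"),
                                observed_marker = "SMARCC1",
                                range = GRADIENT_RANGE,
                                n_boot = 0, seed = 1) {
  subtype_order <- c("GBAF", "CBAF", "PBAF")
  stopifnot(setequal(unname(markers), subtype_order))
  components <- lapply(subtype_order, function(s) {
    marker <- names(markers)[markers == s]
    fit_component(.profile_vector(profiles, marker), subtype = s, range = range)
  })
  observed <- .profile_vector(profiles, observed_marker)
  estimate <- fit_mixture(components, observed, range)
  out <- list(components = components, estimate = estimate)
  if (n_boot > 0)
    out$bootstrap <- bootstrap_mixture(components, observed, n_boot, seed,
                                       range = range)
  out
}
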