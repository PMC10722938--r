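# KOOS (Knee injury and Osteoarthritis Outcome Score) scoring and the
# calibrated subscale generator used by the synthetic cohort.

#' KOOS subscale configuration and cohort calibration targets
#'
#' Five subscales with the standard instrument's item counts and the
#' published cohort's mean/SD targets used to calibrate the generator.
#'
#' @return data.frame with columns subscale, n_items, target_mean, target_sd.
#' @export
koos_subscale_info <- function() {
  data.frame(
    subscale = c("Symptoms", "Pain", "ADL", "SportRec", "QOL"),
    n_items = c(7L, 9L, 17L, 5L, 4L),
    target_mean = c(87.72, 90.73, 96.11, 84.32, 83.26),
    target_sd = c(11.61, 9.55, 5.26, 18.67, 19.78),
    stringsAsFactors = FALSE
  )
}

#' Score KOOS subscales from item responses
#'
#' Each item is an ordinal 0 (no problems) to 4 (extreme problems);
#' `subscale = 100 - mean(items) * 25`, so 100 = no problems and 0 =
#' extreme functional deficits. A subscale with more than half of its
#' items missing is undefined (NA), per standard KOOS practice; with at
#' most half missing, the mean of the answered items is used.
#'
#' @param items Numeric matrix (subjects x items) or vector (one subject),
#'   entries in 0..4 or NA.
#' @param subscale Character/factor of length `ncol(items)` assigning each
#'   item to a subscale.
#' @return Matrix (subjects x subscales) of scores in `[0, 100]`, columns
#'   ordered as in [koos_subscale_info()].
#' @export
score_koos <- function(items, subscale) {
  if (is.vector(items)) items <- matrix(items, nrow = 1L)
  if (length(subscale) != ncol(items)) {
    stopf("score_koos: subscale assignment length %d != %d items",
          length(subscale), ncol(items))
  }
  ok <- is.na(items) | (items >= 0 & items <= 4 & items == round(items))
  if (!all(ok)) stopf("score_koos: item responses must be integers in 0..4 or NA")
  subs <- koos_subscale_info()$subscale
  out <- matrix(NA_real_, nrow(items), length(subs),
                dimnames = list(NULL, subs))
  for (s in subs) {
    cols <- which(subscale == s)
    if (!length(cols)) next
    block <- items[, cols, drop = FALSE]
    n_miss <- rowSums(is.na(block))
    m <- rowMeans(block, na.rm = TRUE)
    m[n_miss > length(cols) / 2] <- NA_real_   # > half missing: undefined
    out[, s] <- 100 - m * 25
  }
  out
}

# Latent-Gaussian parameters (mu, sigma) such that the observed subscale
# min(X, 100), after item discretization (grid step 25/n_items), matches
# the target mean/SD. Solved from censored-normal moment equations; the
# lower clip at 0 is negligible for all published targets (>= 4.5 sigma).
koos_latent_params <- function(target_mean, target_sd, n_items) {
  g <- 25 / n_items                         # subscale grid step
  var_target <- target_sd^2 - g^2 / 12      # discretization adds ~g^2/12
  if (var_target <= 0) stopf("koos_latent_params: target SD too small for %d items", n_items)
  cens_moments <- function(mu, sig, cc = 100) {
    a <- (cc - mu) / sig
    Phi <- stats::pnorm(a); phi <- stats::dnorm(a)
    EW <- mu * Phi - sig * phi + cc * (1 - Phi)
    EW2 <- (mu^2 + sig^2) * Phi - sig * (mu + cc) * phi + cc^2 * (1 - Phi)
    c(mean = EW, var = EW2 - EW^2)
  }
  obj <- function(par) {
    m <- cens_moments(par[1], exp(par[2]))
    (m["mean"] - target_mean)^2 + (sqrt(m["var"]) - sqrt(var_target))^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Decompose continuous subscale targets (n-vector) into integer item
# responses on the standard grid. total deficit score = round over the
# item grid; the remainder is assigned to the leading items (a documented
# synthetic convention; real response patterns are not modeled).
koos_items_from_target <- function(target, n_items) {
  target <- pmin(pmax(target, 0), 100)
  total <- round((100 - target) * n_items / 25)
  total <- pmin(pmax(total, 0L), 4L * n_items)
  base <- total %/% n_items
  rem <- total %% n_items
  items <- matrix(base, nrow = length(target), ncol = n_items)
  cols <- matrix(seq_len(n_items), nrow = length(target), ncol = n_items, byrow = TRUE)
  items + (cols <= rem)
}
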