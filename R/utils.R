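#' @importFrom stats plogis qlogis rbinom rnorm runif rpois rgeom uniroot
#'   coef glm binomial predict lm cor quantile median sd aggregate optim
#' @importFrom utils head tail
#' @importFrom data.table data.table as.data.table setorder rbindlist
#'   fwrite fread uniqueN
NULL

.datatable.aware <- TRUE

# numerically safe sigmoid / logit -------------------------------------------

sigmoid <- function(x) plogis(x)

#' Clip probabilities away from 0 and 1
#'
#' All logit transforms in the package go through this guard.
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping bound; values are forced into `[eps, 1 - eps]`.
#' @return clipped numeric vector.
#' @export
clip_probs <- function(p, eps = 1e-15) {
  pmin(pmax(p, eps), 1 - eps)
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  small <- x <= 33.3
  out[small] <- log1p(exp(x[small]))
  out
}

#' Binary cross-entropy (mean log loss)
#'
#' @param y binary labels (0/1).
#' @param p predicted probabilities; clipped before the log.
#' @return mean negative log-likelihood.
#' @export
bce_loss <- function(y, p) {
  p <- clip_probs(p)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

# Named substreams derived from one root seed. Keeps every derived seed a
# valid 32-bit integer regardless of the root seed's magnitude.
derive_seed <- function(seed, stream) {
  stopifnot(length(stream) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Calendar --------------------------------------------------------------------
# Synthetic calendar: day 0 is Jan 1 of `epoch_year`; years are 365 days.

DAYS_PER_YEAR <- 365L

#' Convert an integer day offset to a calendar year
#'
#' The synthetic calendar anchors day 0 at January 1 of `epoch_year` and
#' uses 365-day years throughout.
#'
#' @param day integer day offset(s) from the epoch.
#' @param epoch_year calendar year of day 0.
#' @return integer year(s).
#' @export
day_to_year <- function(day, epoch_year = 2009L) {
  as.integer(epoch_year + day %/% DAYS_PER_YEAR)
}

#' First day offset of a calendar year
#' @inheritParams day_to_year
#' @param year calendar year(s).
#' @export
year_start_day <- function(year, epoch_year = 2009L) {
  as.integer((year - epoch_year) * DAYS_PER_YEAR)
}
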