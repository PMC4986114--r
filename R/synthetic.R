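#' Configuration for synthetic respondent panels
#'
#' Describes a simulated expert panel with the structure of the original
#' study: 85 invited experts of whom 45 completed both instruments, 128
#' stage-1 candidate criteria, 48 stage-2 survivors, four fixed
#' sub-criteria, and sporadic completely-at-random non-response.
#'
#' Stage-1 scores are drawn from per-criterion normal distributions
#' truncated to \[1, 100\] and rounded to integers; stage-2 Likert responses
#' arise from a latent standard-normal shifted by a per-(alternative,
#' sub-criterion) location and discretized by fixed cutpoints, so a higher
#' location yields stochastically larger 1--5 responses.
#'
#' @param n_invited experts invited (default 85).
#' @param n_complete experts completing both instruments (default 45).
#' @param n_stage1_criteria candidate criteria in stage 1 (default 128).
#' @param n_stage2_criteria surviving criteria ranked in stage 2
#'   (default 48).
#' @param stage1_mu,stage1_sigma per-criterion latent mean and sd on the
#'   1--100 importance scale (recycled to \code{n_stage1_criteria});
#'   defaults span means 45--90 and sds 28--16, a band bracketing the
#'   importance levels and spreads typical of expert consensus panels, so
#'   that a default screen retains a non-trivial subset.
#' @param stage2_locations matrix (alternatives x 4) of latent locations
#'   for the Likert model; default an equally spaced gradient from +1 to -1
#'   down the alternatives on every sub-criterion.
#' @param cutpoints four increasing latent thresholds mapping the latent
#'   normal to the 1..5 ordinal scale.
#' @param missing_rate per-cell probability of non-response (default 0.01).
#' @param seed integer seed; stage-1 and stage-2 draws use independent
#'   derived streams so each is reproducible on its own.
#' @return A list of class \code{"panel_config"}.
#' @export
panel_config <- function(n_invited = 85L, n_complete = 45L,
                         n_stage1_criteria = 128L,
                         n_stage2_criteria = 48L,
                         stage1_mu = NULL, stage1_sigma = NULL,
                         stage2_locations = NULL,
                         cutpoints = c(-1.5, -0.5, 0.5, 1.5),
                         missing_rate = 0.01, seed = 1L) {
  if (n_complete > n_invited)
    stop("n_complete must not exceed n_invited", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  if (length(cutpoints) != 4L || is.unsorted(cutpoints, strictly = TRUE))
    stop("cutpoints must be 4 strictly increasing values", call. = FALSE)
  k1 <- n_stage1_criteria
  stage1_mu <- rep_len(stage1_mu %||%
                         seq(90, 45, length.out = max(k1, 1L)), k1)
  stage1_sigma <- rep_len(stage1_sigma %||%
                            seq(16, 28, length.out = max(k1, 1L)), k1)
  if (any(stage1_sigma <= 0))
    stop("stage1_sigma must be > 0", call. = FALSE)
  if (is.null(stage2_locations))
    stage2_locations <- matrix(seq(1, -1, length.out = n_stage2_criteria),
                               nrow = n_stage2_criteria, ncol = 4L)
  stage2_locations <- as.matrix(stage2_locations)
  if (nrow(stage2_locations) != n_stage2_criteria ||
      ncol(stage2_locations) != 4L)
    stop("stage2_locations must be n_stage2_criteria x 4", call. = FALSE)
  structure(list(n_invited = as.integer(n_invited),
                 n_complete = as.integer(n_complete),
                 n_stage1_criteria = as.integer(n_stage1_criteria),
                 n_stage2_criteria = as.integer(n_stage2_criteria),
                 n_subcriteria = 4L,
                 stage1_mu = stage1_mu, stage1_sigma = stage1_sigma,
                 stage2_locations = stage2_locations,
                 cutpoints = cutpoints,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "panel_config")
}

# derive an independent substream seed from (seed, stream name); keeps the
# result in [0, 2^31) so it is a valid R integer seed
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# inverse-CDF draw from Normal(mu, sigma) truncated to [lo, hi]
rtruncnorm <- function(n, mu, sigma, lo, hi) {
  pl <- stats::pnorm(lo, mu, sigma)
  ph <- stats::pnorm(hi, mu, sigma)
  u <- stats::runif(n, pl, ph)
  q <- stats::qnorm(u, mu, sigma)
  pmin(pmax(q, lo), hi)  # guard endpoint rounding
}

#' Simulate a stage-1 importance panel
#'
#' Draws, for each criterion, \code{n_complete} integer scores from its
#' truncated-normal latent distribution on \[1, 100\], then blanks cells at
#' \code{missing_rate}. The same config (same seed) always reproduces the
#' identical panel.
#'
#' @param config a \code{\link{panel_config}}.
#' @return An \code{\link{importance_panel}} of size
#'   \code{n_complete x n_stage1_criteria}.
#' @export
simulate_importance_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  n <- config$n_complete
  k <- config$n_stage1_criteria
  withr_seed(stream_seed(config$seed, "stage1"), {
    scores <- matrix(NA_real_, n, k)
    for (j in seq_len(k)) {
      z <- rtruncnorm(n, config$stage1_mu[j], config$stage1_sigma[j],
                      1, 100)
      scores[, j] <- pmin(pmax(round(z), 1), 100)
    }
    if (config$missing_rate > 0) {
      miss <- stats::runif(n * k) < config$missing_rate
      scores[matrix(miss, n, k)] <- NA_real_
    }
    scores
  }) -> scores
  importance_panel(scores,
                   respondent_ids = paste0("R", seq_len(n)),
                   criterion_ids = paste0("A", seq_len(k)))
}

#' Simulate a stage-2 Likert panel
#'
#' Each response is generated from a latent standard normal centred on the
#' (alternative, sub-criterion) location and cut at the configured
#' thresholds into the ordinal 1..5 scale; cells are then blanked at
#' \code{missing_rate}.
#'
#' @param config a \code{\link{panel_config}}.
#' @param catalog optional \code{\link{criteria_catalog}} supplying the
#'   alternative ids; must have \code{n_stage2_criteria} rows. Defaults to
#'   generated ids \code{A1...}.
#' @return A \code{\link{likert_panel}} of size
#'   \code{n_complete x n_stage2_criteria x 4}.
#' @export
simulate_likert_panel <- function(config, catalog = NULL) {
  stopifnot(inherits(config, "panel_config"))
  n <- config$n_complete
  a <- config$n_stage2_criteria
  s <- config$n_subcriteria
  if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "criteria_catalog"))
    if (catalog_size(catalog) != a)
      stop("catalog size must equal n_stage2_criteria", call. = FALSE)
    alt_ids <- catalog$id
  } else alt_ids <- paste0("A", seq_len(a))
  withr_seed(stream_seed(config$seed, "stage2"), {
    loc <- array(rep(config$stage2_locations, each = n), dim = c(n, a, s))
    z <- array(stats::rnorm(n * a * s), dim = c(n, a, s)) + loc
    resp <- array(1, dim = c(n, a, s))
    for (cp in config$cutpoints) resp <- resp + (z > cp)
    if (config$missing_rate > 0) {
      miss <- stats::runif(n * a * s) < config$missing_rate
      resp[array(miss, dim = c(n, a, s))] <- NA_real_
    }
    resp
  }) -> resp
  likert_panel(resp,
               respondent_ids = paste0("R", seq_len(n)),
               alternative_ids = alt_ids,
               subcriterion_ids = SUBCRITERIA)
}

# run expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
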