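#' Configure a synthetic multi-assessor panel
#'
#' The generator emulates the pilot study design: 46 sheep and 54 goats
#' (100 animals) independently scored by 8 assessors on the registry's
#' indicators. Its rater-error model is deliberately simple so that
#' agreement has a closed form: for each animal and indicator a latent true
#' category is drawn from `true_score_distribution`; each assessor reports
#' the truth with probability `1 - error_rate` and otherwise a uniform draw
#' among the other categories. Errors are independent across assessors,
#' animals and indicators (no rater drift, fatigue, or correlated error —
#' see the methods vignette for what this does and does not emulate).
#'
#' Default per-indicator error rates are calibrated by inverting the
#' model's expected kappa ([expected_agreement()], [calibrate_error_rate()])
#' against the packaged pilot goat reliability values, so a default panel
#' lands near the published agreement bands (low error for Demeanour, high
#' for Panting). The calibration is illustrative — it makes a realistic
#' demonstration fixture, not a reproduction of the on-farm data.
#'
#' @param n_sheep,n_goats Number of animals per species (defaults 46 / 54).
#' @param n_raters Number of assessors (default 8).
#' @param indicators Registry ids to simulate (default: all).
#' @param error_rate Per-rating error probability in \[0, 1\]: a scalar
#'   applied to every indicator, a named vector by indicator id, or `NULL`
#'   for the calibrated defaults.
#' @param true_score_distribution Category probabilities for the latent
#'   true score: a single numeric vector of length `scale_max + 1` applied
#'   to every indicator, a named list by indicator id, or `NULL` for the
#'   default mostly-adequate-welfare herd `c(0.10, 0.25, 0.65)` over
#'   categories 0/1/2.
#' @param seed Integer seed; the same seed and configuration always
#'   produce byte-identical sheets.
#' @inheritParams read_sheets
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sheep = 46, n_goats = 54, n_raters = 8,
                             indicators = NULL, error_rate = NULL,
                             true_score_distribution = NULL, seed = 1L,
                             registry = load_registry()) {
  ind <- registry$indicators
  if (is.null(indicators)) indicators <- ind$id
  unknown <- setdiff(indicators, ind$id)
  if (length(unknown) > 0) {
    abort(paste0("unknown indicator(s): ", paste(unknown, collapse = ", ")),
          class = "asrwi_config_error")
  }
  if (n_sheep < 0 || n_goats < 0 || n_sheep + n_goats < 1) {
    abort("need at least one animal", class = "asrwi_config_error")
  }
  if (n_raters < 2) {
    abort("need at least two raters", class = "asrwi_config_error")
  }

  smax <- setNames(ind$scale_max, ind$id)[indicators]

  # per-indicator error rates
  if (is.null(error_rate)) {
    eps <- default_error_rates(registry)[indicators]
  } else if (is.null(names(error_rate))) {
    stopifnot(length(error_rate) == 1)
    eps <- setNames(rep(error_rate, length(indicators)), indicators)
  } else {
    missing_eps <- setdiff(indicators, names(error_rate))
    if (length(missing_eps) > 0) {
      abort(paste0("error_rate missing for: ",
                   paste(missing_eps, collapse = ", ")),
            class = "asrwi_config_error")
    }
    eps <- error_rate[indicators]
  }
  if (any(eps < 0 | eps > 1)) {
    abort("error_rate must lie in [0, 1]", class = "asrwi_config_error")
  }

  # per-indicator truth distributions
  default_probs <- function(k) {
    if (k == 3) c(0.10, 0.25, 0.65) else rep(1 / k, k)
  }
  if (is.null(true_score_distribution)) {
    probs <- lapply(indicators, function(id) default_probs(smax[[id]] + 1L))
  } else if (is.numeric(true_score_distribution)) {
    probs <- rep(list(true_score_distribution), length(indicators))
  } else {
    missing_p <- setdiff(indicators, names(true_score_distribution))
    if (length(missing_p) > 0) {
      abort(paste0("true_score_distribution missing for: ",
                   paste(missing_p, collapse = ", ")),
            class = "asrwi_config_error")
    }
    probs <- true_score_distribution[indicators]
  }
  names(probs) <- indicators
  for (id in indicators) {
    p <- probs[[id]]
    if (length(p) != smax[[id]] + 1L || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("true_score_distribution for '%s' must be %d probabilities summing to 1",
                    id, smax[[id]] + 1L),
            class = "asrwi_config_error")
    }
  }

  structure(
    list(n_sheep = as.integer(n_sheep), n_goats = as.integer(n_goats),
         n_raters = as.integer(n_raters), indicators = indicators,
         error_rate = eps, true_score_distribution = probs,
         seed = as.integer(seed), scale_max = smax),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %d sheep + %d goats, %d raters, %d indicator(s), seed %d\n",
              x$n_sheep, x$n_goats, x$n_raters, length(x$indicators), x$seed))
  cat(sprintf("  error rates: %.3f-%.3f\n", min(x$error_rate),
              max(x$error_rate)))
  invisible(x)
}

# error rates implied by the pilot goat kappa values under the generator's
# error model (expected kappa inverted with uniroot); memoised per session
default_error_rates <- local({
  cache <- NULL
  function(registry) {
    if (!is.null(cache)) return(cache)
    pr <- pilot_reliability()
    goat <- pr[pr$species == "goat", ]
    ind <- registry$indicators
    eps <- vapply(ind$id, function(id) {
      k <- ind$scale_max[ind$id == id] + 1L
      target <- goat$kappa[goat$indicator_id == id]
      if (length(target) == 0) target <- 0.7
      calibrate_error_rate(target, k = k)
    }, numeric(1))
    cache <<- setNames(eps, ind$id)
    cache
  }
})

#' Closed-form expected agreement under the generator's error model
#'
#' Two assessors of the same animal agree iff both report the true
#' category — probability \eqn{(1-\epsilon)^2} — or both independently err
#' to the same one of the \eqn{k-1} wrong categories — probability
#' \eqn{\epsilon^2/(k-1)}; hence
#' \deqn{\bar{P} = (1-\epsilon)^2 + \epsilon^2/(k-1)}
#' independent of the truth distribution. The marginal probability of a
#' reported category \eqn{j} is
#' \eqn{q_j = p_j(1-\epsilon) + (1-p_j)\,\epsilon/(k-1)}, giving the
#' large-sample chance agreement \eqn{\bar{P}_e = \sum_j q_j^2} and the
#' implied asymptotic kappa. These are population quantities: empirical
#' estimates from finite panels fluctuate around them (and the realized
#' \eqn{\bar{P}_e} carries an \eqn{O(1/(Nn))} finite-sample term).
#'
#' @param config A [synthetic_config()] (or `NULL` to pass `error_rate`,
#'   `k` and `probs` directly).
#' @param indicator Indicator id within `config`.
#' @param error_rate,k,probs Direct parametrization when `config` is
#'   `NULL`: error probability, number of categories, truth probabilities
#'   (default uniform).
#' @return List with `p_bar`, `pe_bar` and `kappa` (the implied
#'   \eqn{(\bar{P}-\bar{P}_e)/(1-\bar{P}_e)}, `NA` when
#'   \eqn{\bar{P}_e = 1}).
#' @export
#' @examples
#' expected_agreement(error_rate = 0, k = 3)$p_bar    # 1
#' expected_agreement(error_rate = 1, k = 2)$p_bar    # 1: the single wrong
#'                                                    # category is shared
expected_agreement <- function(config = NULL, indicator = NULL,
                               error_rate = NULL, k = NULL, probs = NULL) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "synthetic_config"))
    if (is.null(indicator) || !indicator %in% config$indicators) {
      abort("indicator must name an indicator in the config",
            class = "asrwi_config_error")
    }
    error_rate <- config$error_rate[[indicator]]
    probs <- config$true_score_distribution[[indicator]]
    k <- length(probs)
  }
  if (is.null(probs)) probs <- rep(1 / k, k)
  stopifnot(length(probs) == k, abs(sum(probs) - 1) < 1e-9)
  eps <- error_rate
  p_bar <- (1 - eps)^2 + eps^2 / (k - 1)
  q <- probs * (1 - eps) + (1 - probs) * eps / (k - 1)
  pe_bar <- sum(q^2)
  kappa <- if (pe_bar >= 1 - 1e-12) NA_real_ else (p_bar - pe_bar) / (1 - pe_bar)
  list(p_bar = p_bar, pe_bar = pe_bar, kappa = kappa)
}

#' Error rate implied by a target kappa under the generator's model
#'
#' Numerically inverts the monotone map from error rate to the asymptotic
#' kappa of [expected_agreement()] on \eqn{[0, (k-1)/k]} (from perfect
#' raters to truth-independent ratings).
#'
#' @param kappa_target Target kappa in (0, 1\].
#' @inheritParams expected_agreement
#' @return The error rate achieving `kappa_target` in expectation.
#' @export
calibrate_error_rate <- function(kappa_target, k, probs = NULL) {
  if (is.null(probs)) {
    probs <- if (k == 3) c(0.10, 0.25, 0.65) else rep(1 / k, k)
  }
  if (kappa_target >= 1) return(0)
  if (kappa_target <= 0) return((k - 1) / k)
  f <- function(eps) {
    expected_agreement(error_rate = eps, k = k, probs = probs)$kappa -
      kappa_target
  }
  uniroot(f, c(0, (k - 1) / k), tol = 1e-10)$root
}

#' Generate a synthetic scoring sheet
#'
#' Draws a latent true category per animal and indicator, perturbs it
#' independently per assessor under the config's error model, and returns a
#' valid long-format scoring sheet (one row per animal, assessor and
#' indicator). Output is deterministic: the same config and seed give an
#' identical tibble (and, via [write_sheets()], a byte-identical file).
#'
#' @param config A [synthetic_config()].
#' @return Tibble of assessment records (`animal_id`, `species`,
#'   `assessor_id`, `indicator_id`, `score`), with the latent truth
#'   attached as attribute `truth` (tibble `animal_id`, `indicator_id`,
#'   `true_score`) for estimator-validation use.
#' @export
#' @examples
#' cfg <- synthetic_config(n_sheep = 2, n_goats = 2, n_raters = 3,
#'                         indicators = "demeanour", seed = 42)
#' generate_sheet(cfg)
generate_sheet <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  animals <- tibble(
    animal_id = c(sprintf("sheep_%03d", seq_len(config$n_sheep)),
                  sprintf("goat_%03d", seq_len(config$n_goats))),
    species = c(rep("sheep", config$n_sheep), rep("goat", config$n_goats))
  )
  raters <- sprintf("A%d", seq_len(config$n_raters))
  n_a <- nrow(animals)

  withr::with_seed(config$seed, {
    sheets <- lapply(config$indicators, function(id) {
      k <- config$scale_max[[id]] + 1L
      p <- config$true_score_distribution[[id]]
      eps <- config$error_rate[[id]]
      truth <- sample.int(k, n_a, replace = TRUE, prob = p) - 1L
      # each rater: truth with prob 1-eps, else uniform among other k-1
      reported <- matrix(rep(truth, config$n_raters), nrow = n_a)
      err <- matrix(stats::runif(n_a * config$n_raters) < eps, nrow = n_a)
      if (any(err) && k > 1) {
        shift <- matrix(sample.int(k - 1L, n_a * config$n_raters,
                                   replace = TRUE), nrow = n_a)
        reported[err] <- (reported[err] + shift[err]) %% k
      }
      tibble(
        animal_id = rep(animals$animal_id, times = config$n_raters),
        species = rep(animals$species, times = config$n_raters),
        assessor_id = rep(raters, each = n_a),
        indicator_id = id,
        score = as.integer(reported),
        .true_score = rep(truth, times = config$n_raters)
      )
    })
    out <- bind_rows(sheets)
  })

  truth <- distinct(out[, c("animal_id", "indicator_id", ".true_score")])
  truth <- rename(truth, true_score = ".true_score")
  out <- out[order(out$indicator_id, out$animal_id, out$assessor_id),
             c("animal_id", "species", "assessor_id", "indicator_id", "score")]
  out <- as_tibble(out)
  attr(out, "truth") <- truth
  attr(out, "report") <- tibble(row = integer(), animal_id = character(),
                                assessor_id = character(),
                                indicator_id = character(),
                                reason = character())
  out
}
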