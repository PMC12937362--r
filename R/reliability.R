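#' Generalized Fleiss' kappa for a rating matrix
#'
#' Chance-corrected multi-rater agreement, computed by the standard
#' stepwise procedure on the subjects-by-categories count table:
#' \deqn{p_j = \sum_i n_{ij} / \sum_i n_i}
#' \deqn{P_i = \sum_j n_{ij}(n_{ij}-1) / (n_i(n_i-1))}
#' \deqn{\bar{P} = \mathrm{mean}_i P_i, \quad \bar{P}_e = \sum_j p_j^2}
#' \deqn{\kappa = (\bar{P} - \bar{P}_e) / (1 - \bar{P}_e)}
#' The per-subject row sums \eqn{n_i} may differ (subjects only need two or
#' more ratings); with constant \eqn{n_i} this reduces exactly to classic
#' Fleiss' kappa. \eqn{P_i} is the proportion of concordant rater pairs
#' within subject \eqn{i}, so the reported percentage agreement
#' \eqn{100\,\bar{P}} is mean pairwise within-subject agreement — exactly
#' the quantity entering the kappa numerator. (Modal-agreement definitions
#' of "% agreement" give different numbers; this package always means
#' pairwise agreement.)
#'
#' When every rating falls in a single category, \eqn{\bar{P}_e = 1} and
#' kappa is 0/0: this is reported as a classed error
#' (`asrwi_kappa_undefined`, carrying `percent_agreement = 100`), never as
#' kappa 0 or 1 — absence of category variation is not evidence about
#' agreement quality.
#'
#' @param matrix A [rating_matrix()].
#' @return An object of class `reliability_result`: a list with
#'   `indicator_id`, `species`, `kappa`, `percent_agreement` (= 100
#'   \eqn{\bar{P}}), `p_bar`, `pe_bar`, `category_props` (\eqn{p_j}),
#'   `per_subject_agreement` (\eqn{P_i}), `n_subjects`, and `band`
#'   (Landis–Koch label via [interpret_kappa()]).
#' @export
#' @examples
#' m <- rating_matrix(rbind(c(2, 0), c(1, 1)), "demeanour")
#' r <- fleiss_kappa(m)
#' c(r$p_bar, r$pe_bar, r$kappa)   # 0.5, 0.625, -1/3
fleiss_kappa <- function(matrix) {
  if (!inherits(matrix, "rating_matrix")) {
    abort("fleiss_kappa() expects a rating_matrix",
          class = "asrwi_validation_error")
  }
  counts <- unclass(matrix)
  n_i <- rowSums(counts)
  total <- sum(n_i)
  p_j <- colSums(counts) / total
  P_i <- rowSums(counts * (counts - 1)) / (n_i * (n_i - 1))
  p_bar <- mean(P_i)
  pe_bar <- sum(p_j^2)
  if (pe_bar >= 1 - 1e-12) {
    abort(sprintf("kappa undefined: no category variation for indicator '%s'",
                  attr(matrix, "indicator_id")),
          class = "asrwi_kappa_undefined",
          percent_agreement = 100 * p_bar)
  }
  kappa <- (p_bar - pe_bar) / (1 - pe_bar)
  structure(
    list(
      indicator_id = attr(matrix, "indicator_id"),
      species = attr(matrix, "species"),
      kappa = kappa,
      percent_agreement = 100 * p_bar,
      p_bar = p_bar,
      pe_bar = pe_bar,
      category_props = p_j,
      per_subject_agreement = setNames(P_i, rownames(counts)),
      n_subjects = nrow(counts),
      band = interpret_kappa(kappa)
    ),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> %s%s: kappa = %.2f (%.1f%%; %s), N = %d\n",
              x$indicator_id,
              if (is.null(x$species)) "" else paste0(" [", x$species, "]"),
              x$kappa, x$percent_agreement, as.character(x$band),
              x$n_subjects))
  invisible(x)
}

#' Brute-force pairwise agreement (test oracle)
#'
#' Independent check on the observed-agreement component of
#' [fleiss_kappa()]: expands each subject's row of category counts back into
#' the multiset of individual ratings, enumerates every rater pair with
#' `combn()`, counts concordant pairs, and averages the per-subject
#' proportions. Agrees with \eqn{\bar{P}} from the closed-form count
#' identity to machine precision on every valid matrix; kept deliberately
#' naive (O(pairs) enumeration) so the two routes stay independent.
#'
#' @inheritParams fleiss_kappa
#' @return Mean proportion of concordant rater pairs, in \[0, 1\].
#' @export
pairwise_agreement <- function(matrix) {
  counts <- unclass(matrix)
  per_subject <- apply(counts, 1, function(row) {
    ratings <- rep(seq_along(row) - 1L, times = row)
    pairs <- utils::combn(length(ratings), 2)
    mean(ratings[pairs[1, ]] == ratings[pairs[2, ]])
  })
  mean(per_subject)
}

#' Indicator-level reliability table
#'
#' Runs [build_rating_matrix()] + [fleiss_kappa()] for every indicator
#' present in the records, per species, and collects the results in a
#' table mirroring the pilot study's reporting format (indicator, species,
#' kappa, % agreement, band). Indicators whose kappa is undefined (all
#' ratings in one category) appear with `kappa = NA`, their percentage
#' agreement (100), and `note = "kappa undefined"`.
#'
#' @param records Accepted assessment records.
#' @param species Character vector of species to summarize (default: those
#'   present in the records).
#' @inheritParams read_sheets
#' @return A tibble with columns `indicator_id`, `name`, `domain`,
#'   `species`, `n_subjects`, `kappa`, `percent_agreement`, `band`, `note`.
#' @export
reliability_table <- function(records, registry = load_registry(),
                              species = NULL) {
  if (is.null(species)) species <- sort(unique(records$species))
  ind <- registry$indicators
  rows <- list()
  for (sp in species) {
    present <- intersect(ind$id, unique(records$indicator_id[records$species == sp]))
    for (id in present) {
      m <- build_rating_matrix(records, id, species = sp, registry = registry)
      row <- tryCatch({
        r <- fleiss_kappa(m)
        tibble(indicator_id = id, species = sp, n_subjects = r$n_subjects,
               kappa = r$kappa, percent_agreement = r$percent_agreement,
               band = as.character(r$band), note = NA_character_)
      }, asrwi_kappa_undefined = function(e) {
        tibble(indicator_id = id, species = sp, n_subjects = nrow(m),
               kappa = NA_real_,
               percent_agreement = e$percent_agreement,
               band = NA_character_, note = "kappa undefined")
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- bind_rows(rows)
  out <- left_join(out, ind[, c("id", "name", "domain")],
                   by = c(indicator_id = "id"))
  out[, c("indicator_id", "name", "domain", "species", "n_subjects",
          "kappa", "percent_agreement", "band", "note")]
}

#' Domain-level reliability summary
#'
#' Unweighted arithmetic mean of indicator-level kappa and percentage
#' agreement per welfare domain and species — the aggregation used for
#' domain-level reporting. Indicators with undefined kappa are excluded
#' from the kappa mean and counted in `n_undefined`; a domain with no
#' defined kappa at all is omitted with a warning.
#'
#' @param results A reliability table ([reliability_table()] output, or any
#'   tibble with `indicator_id`, `species`, `kappa`, `percent_agreement` —
#'   e.g. [pilot_reliability()]).
#' @param species Optional species filter.
#' @inheritParams read_sheets
#' @return A tibble with `domain`, `species`, `n_indicators`, `n_undefined`,
#'   `mean_kappa`, `mean_percent_agreement`.
#' @export
#' @examples
#' domain_summary(pilot_reliability())
domain_summary <- function(results, registry = load_registry(),
                           species = NULL) {
  res <- as_tibble(results)
  if (!is.null(species)) res <- res[res$species %in% species, ]
  if (!"domain" %in% names(res)) {
    ind <- registry$indicators
    res$domain <- ind$domain[match(res$indicator_id, ind$id)]
  }
  if (any(is.na(res$domain))) {
    abort("results contain indicator ids absent from the registry",
          class = "asrwi_validation_error")
  }
  out <- res %>%
    group_by(.data$domain, .data$species) %>%
    summarise(
      n_indicators = dplyr::n(),
      n_undefined = sum(is.na(.data$kappa)),
      mean_kappa = mean(.data$kappa, na.rm = TRUE),
      mean_percent_agreement = mean(.data$percent_agreement),
      .groups = "drop"
    )
  empty <- is.nan(out$mean_kappa)
  if (any(empty)) {
    warn(paste0("domain(s) with no defined kappa omitted: ",
                paste(unique(out$domain[empty]), collapse = ", ")))
    out <- out[!empty, ]
  }
  out$domain <- factor(out$domain, levels = names(asrwi_domain_weights))
  arrange(out, .data$domain, .data$species)
}
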