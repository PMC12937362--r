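#' Normalized 0-100 score for one welfare domain
#'
#' Each domain score is a weighted mean of its index-member indicators'
#' encoded scores, linearly rescaled to 0-100. With scores encoded on 0-2
#' (0 = worst, 2 = best) and member weights summing to 1, the formula
#' \deqn{D = \frac{\sum_s w_s \, S_s}{2} \times 100}
#' attains exactly 0 when every member is at its worst and exactly 100 when
#' every member is at its best. The division by 2 is the scale
#' normalization: the weighted mean lives on \[0, 2\], and dividing by the
#' common `scale_max` maps it to \[0, 1\] before the percentage scaling —
#' only this reading yields the stated 0-100 range for weights that sum
#' to 1.
#'
#' The four domain formulas (member symbols and weights from the packaged
#' registry) are:
#' \itemize{
#'   \item behaviour: 0.30 S_D + 0.25 S_HAR + 0.25 S_SW + 0.20 S_St
#'   \item environment: 0.40 S_P + 0.25 S_Sh + 0.20 S_Sd + 0.15 S_Dir
#'   \item nutrition: 0.40 S_Ru + 0.35 S_BCS + 0.25 S_Sk
#'   \item health: 0.30 S_L + 0.25 S_Le + 0.15 S_Mu + 0.15 S_Oc + 0.15 S_Ho
#' }
#'
#' @param domain One of `"behaviour_mental"`, `"environment"`,
#'   `"nutrition"`, `"health"`.
#' @param scores Named numeric vector of encoded scores, named by indicator
#'   symbol (e.g. `c(S_D = 2, S_HAR = 1, ...)`) or by indicator id. All of
#'   the domain's index members must be present; herd-level means in
#'   \[0, scale_max\] are valid inputs (the formula is linear).
#' @inheritParams read_sheets
#' @return An object of class `domain_score`: list with `domain`, `value`
#'   (0-100), and `contributing_scores` (named by symbol).
#' @export
#' @examples
#' domain_score("behaviour_mental", c(S_D = 2, S_HAR = 1, S_SW = 2, S_St = 0))
domain_score <- function(domain, scores, registry = load_registry()) {
  domain <- match.arg(domain, names(asrwi_domain_weights))
  ind <- registry$indicators
  members <- ind[ind$domain == domain & !is.na(ind$index_weight), ]
  # accept names by symbol or by registry id
  nm <- names(scores)
  if (is.null(nm)) {
    abort("scores must be a named vector (names = indicator symbols or ids)",
          class = "asrwi_validation_error")
  }
  by_id <- nm %in% members$id
  nm[by_id] <- members$symbol[match(nm[by_id], members$id)]
  names(scores) <- nm
  missing_syms <- setdiff(members$symbol, nm)
  if (length(missing_syms) > 0) {
    abort(sprintf("missing score(s) for %s member symbol(s): %s", domain,
                  paste(missing_syms, collapse = ", ")),
          class = "asrwi_validation_error")
  }
  s <- scores[members$symbol]
  if (any(is.na(s)) || any(s < 0) || any(s > members$scale_max)) {
    abort(sprintf("scores for domain '%s' must lie in [0, scale_max]", domain),
          class = "asrwi_range_error")
  }
  scale_max <- unique(members$scale_max)
  if (length(scale_max) != 1) {
    abort("index members of one domain must share a common scale",
          class = "asrwi_validation_error")
  }
  value <- sum(members$index_weight * s) / scale_max * 100
  structure(list(domain = domain, value = value,
                 contributing_scores = setNames(as.numeric(s), members$symbol)),
            class = "domain_score")
}

#' @export
print.domain_score <- function(x, ...) {
  cat(sprintf("<domain_score> %s = %.1f / 100\n", x$domain, x$value))
  print(round(x$contributing_scores, 3))
  invisible(x)
}

#' Composite welfare index from four domain scores
#'
#' The ASR-WI is the fixed-weight sum of the four normalized domain scores:
#' \deqn{ASR\text{-}WI = 0.20\,B + 0.30\,E + 0.20\,N + 0.30\,H}
#' (behaviour, environment, nutrition, health). Weights are expert-consensus
#' constants and sum to 1, so the index stays on the 0-100 scale.
#'
#' @param domain_scores The four domain scores: either a named numeric
#'   vector / list with names `behaviour_mental`, `environment`,
#'   `nutrition`, `health` (values in \[0, 100\]) or a list of
#'   [domain_score()] objects.
#' @return The composite index value in \[0, 100\].
#' @export
#' @examples
#' asrwi_score(c(behaviour_mental = 100, environment = 50,
#'               nutrition = 80, health = 90))   # 78
asrwi_score <- function(domain_scores) {
  if (is.list(domain_scores) &&
      all(vapply(domain_scores, inherits, logical(1), "domain_score"))) {
    vals <- vapply(domain_scores, function(d) d$value, numeric(1))
    names(vals) <- vapply(domain_scores, function(d) d$domain, character(1))
    domain_scores <- vals
  }
  domain_scores <- unlist(domain_scores)
  missing_d <- setdiff(names(asrwi_domain_weights), names(domain_scores))
  if (length(missing_d) > 0) {
    abort(paste0("missing domain score(s): ", paste(missing_d, collapse = ", ")),
          class = "asrwi_validation_error")
  }
  vals <- domain_scores[names(asrwi_domain_weights)]
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 100)) {
    abort("domain scores must lie in [0, 100]", class = "asrwi_range_error")
  }
  sum(asrwi_domain_weights * vals)
}

#' Reliability-gated indicator selection
#'
#' Two-step inclusion rule for index membership: (1) the indicator's
#' inter-observer reliability must reach Fleiss' kappa >= 0.35 (boundary
#' inclusive — at least moderate agreement); (2) the indicator must be on
#' the registry's curated index-member list, which encodes the protocol's
#' biological-relevance judgement as data. Both flags are carried in the
#' output so exclusions are auditable. Indicators whose kappa is undefined
#' fail the reliability gate with reason `"kappa undefined"`.
#'
#' @param reliability A reliability table ([reliability_table()] or
#'   [pilot_reliability()] output: `indicator_id`, `species`, `kappa`, ...).
#' @param threshold Minimum kappa for the reliability gate (default 0.35).
#' @inheritParams read_sheets
#' @return A tibble of inclusion decisions: `indicator_id`, `species`,
#'   `kappa`, `passed_reliability`, `relevance_retained`, `included`,
#'   `reason` (NA when included).
#' @export
#' @examples
#' dec <- select_indicators(pilot_reliability())
#' sum(dec$included) / 2   # 16 index members per species
select_indicators <- function(reliability, registry = load_registry(),
                              threshold = 0.35) {
  rel <- as_tibble(reliability)
  ind <- registry$indicators
  unknown <- setdiff(unique(rel$indicator_id), ind$id)
  if (length(unknown) > 0) {
    abort(paste0("reliability results for unknown indicator(s): ",
                 paste(unknown, collapse = ", ")),
          class = "asrwi_validation_error")
  }
  out <- tibble(
    indicator_id = rel$indicator_id,
    species = rel$species,
    kappa = rel$kappa,
    passed_reliability = !is.na(rel$kappa) & rel$kappa >= threshold,
    relevance_retained = !is.na(ind$index_weight[match(rel$indicator_id, ind$id)])
  )
  out$included <- out$passed_reliability & out$relevance_retained
  out$reason <- dplyr::case_when(
    out$included ~ NA_character_,
    is.na(out$kappa) ~ "kappa undefined",
    !out$passed_reliability ~ sprintf("kappa %.2f below threshold %.2f",
                                      out$kappa, threshold),
    TRUE ~ "not an index member (measured-only indicator)"
  )
  out
}

# consensus across assessors for one animal x indicator: rounded median,
# half-scores rounded toward the worse-welfare (lower) category
consensus_score <- function(scores) {
  m <- median(scores)
  as.integer(floor(m))
}

#' Welfare index from multi-assessor records
#'
#' End-to-end scoring pipeline. For every animal and indicator the
#' assessors' scores are first collapsed to a consensus — the rounded
#' median, with half-values rounded toward the worse-welfare category
#' (conservative in an audit context). In herd mode the consensus scores
#' are then averaged across animals per indicator and the domain formulas
#' applied to these herd means; because the formulas are linear this equals
#' averaging per-animal indices. In animal mode each animal gets its own
#' four domain scores and index.
#'
#' Indicators that are measured but not index members are never dropped
#' silently: their mean consensus scores are returned in the `appendix`.
#'
#' If a reliability table is supplied, index members failing the
#' kappa >= 0.35 gate trigger a warning (the published formula weights are
#' fixed, so the index is still computed as specified; the inclusion audit
#' lives in [select_indicators()]).
#'
#' @param records Accepted assessment records.
#' @param scope `"herd"` (one index for the assessed unit, default) or
#'   `"animal"` (one index per animal).
#' @param species Optional filter, `"sheep"` or `"goat"`.
#' @param reliability Optional reliability table used to warn about index
#'   members failing the reliability gate.
#' @inheritParams read_sheets
#' @return For `scope = "herd"`: an object of class `welfare_index_result`
#'   — list with `scope`, `species`, `domain_scores` (the four
#'   [domain_score()] objects), `asrwi`, `appendix` (tibble of
#'   measured-only indicators' mean consensus scores), `n_animals`.
#'   For `scope = "animal"`: a tibble with one row per animal (four domain
#'   score columns and `asrwi`).
#' @export
welfare_index <- function(records, registry = load_registry(),
                          scope = c("herd", "animal"), species = NULL,
                          reliability = NULL) {
  scope <- match.arg(scope)
  rec <- as_tibble(records)
  if (!is.null(species)) {
    species <- match.arg(species, c("sheep", "goat"))
    rec <- rec[rec$species == species, ]
  }
  if (nrow(rec) == 0) {
    abort("no records to score", class = "asrwi_validation_error")
  }
  ind <- registry$indicators
  if (!is.null(reliability)) {
    dec <- select_indicators(reliability, registry = registry)
    gated <- dec[dec$relevance_retained & !dec$passed_reliability, ]
    if (!is.null(species)) gated <- gated[gated$species == species, ]
    if (nrow(gated) > 0) {
      warn(paste0("index member(s) below the reliability gate: ",
                  paste(unique(gated$indicator_id), collapse = ", "),
                  " (index computed with the fixed published weights; see select_indicators())"))
    }
  }

  consensus <- rec %>%
    group_by(.data$animal_id, .data$indicator_id) %>%
    summarise(score = consensus_score(.data$score), .groups = "drop")

  members <- ind[!is.na(ind$index_weight), ]
  needed <- members$id
  if (scope == "herd") {
    herd_means <- consensus %>%
      group_by(.data$indicator_id) %>%
      summarise(score = mean(.data$score), .groups = "drop")
    missing_ind <- setdiff(needed, herd_means$indicator_id)
    if (length(missing_ind) > 0) {
      abort(paste0("no scores for index member indicator(s): ",
                   paste(missing_ind, collapse = ", ")),
            class = "asrwi_validation_error")
    }
    scores_by_id <- setNames(herd_means$score, herd_means$indicator_id)
    ds <- lapply(names(asrwi_domain_weights), function(d) {
      ids <- members$id[members$domain == d]
      domain_score(d, scores_by_id[ids], registry = registry)
    })
    names(ds) <- names(asrwi_domain_weights)
    appendix <- herd_means %>%
      filter(!.data$indicator_id %in% needed) %>%
      left_join(ind[, c("id", "name", "domain")],
                by = c(indicator_id = "id")) %>%
      rename(mean_consensus_score = "score")
    structure(
      list(scope = "herd", species = species, domain_scores = ds,
           asrwi = asrwi_score(ds), appendix = appendix,
           n_animals = length(unique(rec$animal_id))),
      class = "welfare_index_result"
    )
  } else {
    animals <- unique(consensus$animal_id)
    rows <- lapply(animals, function(a) {
      sc <- consensus[consensus$animal_id == a, ]
      scores_by_id <- setNames(sc$score, sc$indicator_id)
      if (length(setdiff(needed, names(scores_by_id))) > 0) {
        return(NULL)  # animal not scored on every index member
      }
      ds <- vapply(names(asrwi_domain_weights), function(d) {
        ids <- members$id[members$domain == d]
        domain_score(d, scores_by_id[ids], registry = registry)$value
      }, numeric(1))
      tibble(animal_id = a,
             behaviour_mental = ds[["behaviour_mental"]],
             environment = ds[["environment"]],
             nutrition = ds[["nutrition"]],
             health = ds[["health"]],
             asrwi = asrwi_score(ds))
    })
    incomplete <- animals[vapply(rows, is.null, logical(1))]
    if (length(incomplete) > 0) {
      warn(paste0(length(incomplete),
                  " animal(s) lacking scores on every index member omitted"))
    }
    bind_rows(rows)
  }
}

#' @export
print.welfare_index_result <- function(x, ...) {
  cat(sprintf("<welfare_index_result> %s%s, %d animal(s)\n", x$scope,
              if (is.null(x$species)) "" else paste0(" (", x$species, ")"),
              x$n_animals))
  for (d in names(x$domain_scores)) {
    cat(sprintf("  %-16s %6.1f  (weight %.2f)\n", d,
                x$domain_scores[[d]]$value, asrwi_domain_weights[[d]]))
  }
  cat(sprintf("  ASR-WI           %6.1f / 100\n", x$asrwi))
  if (nrow(x$appendix) > 0) {
    cat("  measured-only indicators (not in the index):",
        nrow(x$appendix), "- see $appendix\n")
  }
  invisible(x)
}
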