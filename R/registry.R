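#' Welfare indicator registry
#'
#' The registry is the catalogue behind every other computation in the
#' package: one row per welfare indicator with its domain (behaviour and
#' mental state, environment, nutrition, health), the species it applies to,
#' the ordinal scale (categories `0..scale_max`, higher encoded score =
#' better welfare), an optional formula symbol, and an optional index weight.
#' Indicators carrying a weight are the members of their domain's index
#' formula; indicators without one (e.g. Condition of Equipment) are measured
#' and reported but never enter the composite index.
#'
#' The packaged default registry holds the protocol's 24 indicators — 4
#' behaviour, 5 environment, 5 nutrition and 10 health — all encoded on a
#' 0–2 ordinal scale (0 = worst, 2 = best; binary presence/absence
#' indicators map "problem present" to 0 and "absent" to 2). Within each
#' domain the index weights of formula members sum to exactly 1, which
#' together with the 0–2 encoding makes every domain score land on a 0–100
#' scale (see [domain_score()]).
#'
#' @param path Path to a registry CSV with columns
#'   `id,name,domain,species,scale_max,symbol,index_weight` (species as a
#'   `;`-separated subset of `sheep;goat`; empty `symbol`/`index_weight` for
#'   non-index indicators). `NULL` (default) loads the packaged registry.
#'
#' @return An object of class `asrwi_registry`: a list with
#'   \describe{
#'     \item{indicators}{tibble of indicator definitions (plus a logical
#'       `polarity` column, `TRUE` = higher encoded score is better, always
#'       true after encoding).}
#'     \item{domains}{tibble of the four domains with their composite-index
#'       weights (behaviour 0.20, environment 0.30, nutrition 0.20,
#'       health 0.30) and ordered member indicator ids.}
#'   }
#' @export
#' @examples
#' reg <- load_registry()
#' nrow(reg$indicators)        # 24
#' reg$domains
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "indicator_registry.csv", package = "asrwi")
  }
  if (!file.exists(path)) {
    abort(paste0("registry file not found: ", path), class = "asrwi_io_error")
  }
  ind <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      name = readr::col_character(),
      domain = readr::col_character(),
      species = readr::col_character(),
      scale_max = readr::col_integer(),
      symbol = readr::col_character(),
      index_weight = readr::col_double()
    ),
    progress = FALSE
  )
  required <- c("id", "name", "domain", "species", "scale_max", "symbol",
                "index_weight")
  missing_cols <- setdiff(required, names(ind))
  if (length(missing_cols) > 0) {
    abort(paste0("registry is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "asrwi_validation_error")
  }
  ind$polarity <- TRUE
  reg <- structure(
    list(indicators = as_tibble(ind), domains = build_domain_table(ind)),
    class = "asrwi_registry"
  )
  validate_registry(reg)
  reg
}

# Composite-index domain weights: fixed expert-consensus constants.
asrwi_domain_weights <- c(
  behaviour_mental = 0.20,
  environment      = 0.30,
  nutrition        = 0.20,
  health           = 0.30
)

build_domain_table <- function(ind) {
  tibble(
    domain = names(asrwi_domain_weights),
    asrwi_weight = unname(asrwi_domain_weights),
    member_indicator_ids = lapply(
      names(asrwi_domain_weights),
      function(d) ind$id[ind$domain == d]
    )
  )
}

validate_registry <- function(reg) {
  ind <- reg$indicators
  dup_id <- unique(ind$id[duplicated(ind$id)])
  if (length(dup_id) > 0) {
    abort(paste0("duplicate indicator id(s): ", paste(dup_id, collapse = ", ")),
          class = "asrwi_validation_error")
  }
  syms <- ind$symbol[!is.na(ind$symbol) & ind$symbol != ""]
  dup_sym <- unique(syms[duplicated(syms)])
  if (length(dup_sym) > 0) {
    abort(paste0("duplicate symbol(s): ", paste(dup_sym, collapse = ", ")),
          class = "asrwi_validation_error")
  }
  bad_domain <- setdiff(unique(ind$domain), names(asrwi_domain_weights))
  if (length(bad_domain) > 0) {
    abort(paste0("unknown domain(s): ", paste(bad_domain, collapse = ", ")),
          class = "asrwi_validation_error")
  }
  bad_species <- setdiff(
    unique(unlist(strsplit(ind$species, ";", fixed = TRUE))),
    c("sheep", "goat")
  )
  if (length(bad_species) > 0) {
    abort(paste0("unknown species token(s): ",
                 paste(bad_species, collapse = ", ")),
          class = "asrwi_validation_error")
  }
  if (any(is.na(ind$scale_max)) || any(ind$scale_max < 1)) {
    abort("scale_max must be an integer >= 1 for every indicator",
          class = "asrwi_validation_error")
  }
  if (any(!is.na(ind$index_weight) & ind$index_weight < 0)) {
    abort("index_weight must be non-negative",
          class = "asrwi_validation_error")
  }
  # within-domain formula weights must sum to exactly 1
  for (d in unique(ind$domain)) {
    w <- ind$index_weight[ind$domain == d]
    w <- w[!is.na(w)]
    if (length(w) > 0 && abs(sum(w) - 1) > 1e-9) {
      abort(sprintf("index weights in domain '%s' sum to %.4f, expected 1.00",
                    d, sum(w)),
            class = "asrwi_validation_error")
    }
  }
  if (abs(sum(reg$domains$asrwi_weight) - 1) > 1e-12) {
    abort("composite index domain weights must sum to 1",
          class = "asrwi_validation_error")
  }
  invisible(reg)
}

#' Write a registry back to CSV
#'
#' Inverse of [load_registry()]: writing and reloading yields an identical
#' registry, so a user can export the default, edit the symbol mapping or
#' weights, and load the edited file.
#'
#' @param registry An `asrwi_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "asrwi_registry"))
  out <- registry$indicators[, c("id", "name", "domain", "species",
                                 "scale_max", "symbol", "index_weight")]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
print.asrwi_registry <- function(x, ...) {
  ind <- x$indicators
  cat("<asrwi_registry> ", nrow(ind), " indicators\n", sep = "")
  tab <- table(ind$domain)[names(asrwi_domain_weights)]
  for (d in names(asrwi_domain_weights)) {
    members <- sum(ind$domain == d & !is.na(ind$index_weight))
    cat(sprintf("  %-16s %2d indicators (%d in index, ASR-WI weight %.2f)\n",
                d, tab[[d]], members, asrwi_domain_weights[[d]]))
  }
  invisible(x)
}

#' Landis–Koch interpretation bands for kappa
#'
#' Verbal agreement bands tiling (-1, 1]: poor (kappa < 0), slight
#' \[0, 0.20\], fair (0.20, 0.40\], moderate (0.40, 0.60\], substantial
#' (0.60, 0.80\], almost perfect (0.80, 1\]. Published descriptions of the
#' scale use discrete-looking bounds ("0.21–0.40"); since kappa is
#' continuous the bands here are half-open and closed on the upper end, so a
#' boundary value such as 0.40 falls in the lower band (fair).
#'
#' @return A tibble with columns `label` (ordered factor), `lower`, `upper`;
#'   each band covers `(lower, upper]`, except slight which is closed at 0
#'   (poor is strictly negative kappa).
#' @export
landis_koch_bands <- function() {
  tibble(
    label = factor(band_levels, levels = band_levels, ordered = TRUE),
    lower = c(-1, 0, 0.20, 0.40, 0.60, 0.80),
    upper = c(0, 0.20, 0.40, 0.60, 0.80, 1)
  )
}

band_levels <- c("poor", "slight", "fair", "moderate", "substantial",
                 "almost_perfect")

#' Interpret a kappa value on the Landis–Koch scale
#'
#' @param kappa Numeric vector of kappa values in \[-1, 1\] (NA allowed and
#'   propagated).
#' @return An ordered factor with levels poor < slight < fair < moderate <
#'   substantial < almost_perfect. Note the band edges: `0.20` is slight,
#'   `0.40` fair, `0.60` moderate, `0.80` substantial (upper-closed bands),
#'   while `0.00` itself counts as slight (poor is strictly below 0).
#' @export
#' @examples
#' interpret_kappa(c(0.75, -0.1, 0.20, 1))
interpret_kappa <- function(kappa) {
  if (!is.numeric(kappa)) {
    abort("kappa must be numeric", class = "asrwi_range_error")
  }
  bad <- is.nan(kappa) | (!is.na(kappa) & (kappa < -1 | kappa > 1))
  if (any(bad)) {
    abort(sprintf("kappa outside [-1, 1]: %s",
                  paste(format(kappa[bad]), collapse = ", ")),
          class = "asrwi_range_error")
  }
  idx <- findInterval(kappa, c(0, 0.20, 0.40, 0.60, 0.80),
                      left.open = FALSE) + 1L
  # findInterval puts exact 0.20/0.40/... in the upper band; the bands are
  # upper-closed, so pull exact boundary hits back down (0 itself stays slight)
  for (b in c(0.20, 0.40, 0.60, 0.80)) {
    idx[!is.na(kappa) & kappa == b] <- idx[!is.na(kappa) & kappa == b] - 1L
  }
  factor(band_levels[idx], levels = band_levels, ordered = TRUE)
}

#' Reliability values from the pilot validation study
#'
#' The on-farm pilot (46 sheep and 54 goats scored by 8 trained assessors)
#' reported a Fleiss' kappa and a percentage agreement for each of the 24
#' indicators in each species. Those published values are shipped as a
#' fixture so that downstream steps that only need reliability numbers —
#' domain summaries, the kappa >= 0.35 selection gate — can be run and
#' checked without the raw rating data (which is not public).
#'
#' @return A tibble with columns `indicator_id`, `species`, `kappa`,
#'   `percent_agreement`, and a derived `band` (Landis–Koch label).
#' @export
#' @examples
#' pr <- pilot_reliability()
#' dplyr::count(pr, band)
pilot_reliability <- function() {
  path <- system.file("extdata", "pilot_reliability.csv", package = "asrwi")
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      indicator_id = readr::col_character(),
      species = readr::col_character(),
      kappa = readr::col_double(),
      percent_agreement = readr::col_double()
    ),
    progress = FALSE
  )
  out$band <- interpret_kappa(out$kappa)
  as_tibble(out)
}
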