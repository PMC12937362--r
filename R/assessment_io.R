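#' Read and validate a multi-assessor scoring sheet
#'
#' Scoring sheets are long-format CSV files, one row per
#' (animal, assessor, indicator) observation, with mandatory header
#' `animal_id,species,assessor_id,indicator_id,score`. Every row is checked
#' against the registry: the species token must be `sheep` or `goat`, the
#' indicator id must exist, the score must be an integer in
#' `0..scale_max` for that indicator, and the (animal, assessor, indicator)
#' triple must be unique. Rows in a duplicated triple are all rejected —
#' conflicting double entries in a welfare audit have no principled keeper,
#' and silently picking one would hide data-entry faults.
#'
#' @param path Path to the CSV sheet.
#' @param registry An `asrwi_registry` (default: packaged registry).
#' @return A tibble of accepted records (columns as in the header, `score`
#'   integer) with attribute `report`: a tibble of rejected rows
#'   (`row`, `animal_id`, `assessor_id`, `indicator_id`, `reason`),
#'   retrievable with [validation_report()].
#' @seealso [write_sheets()], [build_rating_matrix()]
#' @export
read_sheets <- function(path, registry = load_registry()) {
  if (!file.exists(path)) {
    abort(paste0("scoring sheet not found: ", path), class = "asrwi_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      animal_id = readr::col_character(),
      species = readr::col_character(),
      assessor_id = readr::col_character(),
      indicator_id = readr::col_character(),
      score = readr::col_double()
    ),
    progress = FALSE
  )
  required <- c("animal_id", "species", "assessor_id", "indicator_id", "score")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("scoring sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "asrwi_io_error")
  }
  validate_records(raw, registry)
}

#' Validate in-memory assessment records against a registry
#'
#' Workhorse behind [read_sheets()], usable directly on records built in
#' code (e.g. by [generate_sheet()], which always produces valid output).
#'
#' @param records Data frame with columns `animal_id`, `species`,
#'   `assessor_id`, `indicator_id`, `score`.
#' @inheritParams read_sheets
#' @return Accepted records as a tibble with a `report` attribute; see
#'   [read_sheets()].
#' @export
validate_records <- function(records, registry = load_registry()) {
  stopifnot(inherits(registry, "asrwi_registry"))
  rec <- as_tibble(records)
  rec$.row <- seq_len(nrow(rec))
  ind <- registry$indicators

  reason <- rep(NA_character_, nrow(rec))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }

  flag(is.na(rec$animal_id) | is.na(rec$assessor_id) | is.na(rec$indicator_id),
       "missing identifier")
  flag(!rec$species %in% c("sheep", "goat"), "unknown species")
  flag(!rec$indicator_id %in% ind$id, "unknown indicator_id")
  flag(is.na(rec$score) | rec$score %% 1 != 0, "non-integer score")
  smax <- ind$scale_max[match(rec$indicator_id, ind$id)]
  flag(!is.na(smax) & is.na(reason) &
         (rec$score < 0 | rec$score > smax), "score out of range")
  # species must be among the indicator's applicable species
  app <- strsplit(ind$species[match(rec$indicator_id, ind$id)], ";",
                  fixed = TRUE)
  applicable <- mapply(function(sp, ok) !is.null(ok) && sp %in% ok,
                       rec$species, app)
  flag(is.na(reason) & rec$indicator_id %in% ind$id & !applicable,
       "indicator not applicable to species")

  # duplicates are judged among rows that survived the field checks, so a
  # row rejected for another reason cannot drag its twin down with it
  key <- paste(rec$animal_id, rec$assessor_id, rec$indicator_id, sep = "\r")
  live <- key[is.na(reason)]
  dup_keys <- unique(live[duplicated(live)])
  flag(is.na(reason) & key %in% dup_keys,
       "duplicate animal/assessor/indicator")

  rejected <- rec[!is.na(reason), ]
  report <- tibble(
    row = rejected$.row,
    animal_id = rejected$animal_id,
    assessor_id = rejected$assessor_id,
    indicator_id = rejected$indicator_id,
    reason = reason[!is.na(reason)]
  )
  accepted <- rec[is.na(reason), setdiff(names(rec), ".row")]
  accepted$score <- as.integer(accepted$score)
  attr(accepted, "report") <- report
  accepted
}

#' Retrieve the validation report attached to accepted records
#'
#' @param records The tibble returned by [read_sheets()] or
#'   [validate_records()].
#' @return A tibble of rejected rows with reasons (empty if all rows were
#'   accepted).
#' @export
validation_report <- function(records) {
  rep <- attr(records, "report")
  if (is.null(rep)) {
    rep <- tibble(row = integer(), animal_id = character(),
                  assessor_id = character(), indicator_id = character(),
                  reason = character())
  }
  rep
}

#' Write assessment records to a scoring-sheet CSV
#'
#' @param records Tibble of assessment records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sheets <- function(records, path) {
  out <- records[, c("animal_id", "species", "assessor_id", "indicator_id",
                     "score")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Construct a rating matrix directly from counts
#'
#' Low-level constructor for the subjects-by-categories count table that
#' Fleiss' kappa consumes: `counts[i, j]` is the number of raters assigning
#' category `j - 1` to subject `i`. Normally produced from records by
#' [build_rating_matrix()]; exposed for constructing matrices in code.
#'
#' @param counts Non-negative integer matrix, one row per subject, one
#'   column per category `0..k-1`. Every retained subject needs at least two
#'   ratings (row sum >= 2).
#' @param indicator_id Indicator label carried along for reporting.
#' @param species Optional species label.
#' @param subject_ids Subject identifiers (default: rownames or `s1..sN`).
#' @param dropped Tibble of subjects excluded for having fewer than two
#'   ratings (default none).
#' @return An object of class `rating_matrix` (the counts matrix with
#'   metadata attributes).
#' @export
#' @examples
#' m <- rating_matrix(rbind(c(2, 0), c(1, 1)), "demeanour")
#' fleiss_kappa(m)$kappa   # -1/3
rating_matrix <- function(counts, indicator_id, species = NULL,
                          subject_ids = NULL, dropped = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts %% 1 != 0)) {
    abort("counts must be non-negative integers",
          class = "asrwi_validation_error")
  }
  n_i <- rowSums(counts)
  if (nrow(counts) == 0 || any(n_i < 2)) {
    abort(sprintf("insufficient raters for indicator '%s': every retained subject needs >= 2 ratings",
                  indicator_id),
          class = "asrwi_insufficient_raters")
  }
  if (is.null(subject_ids)) {
    subject_ids <- rownames(counts)
    if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(counts)))
  }
  rownames(counts) <- subject_ids
  colnames(counts) <- as.character(seq_len(ncol(counts)) - 1L)
  if (is.null(dropped)) {
    dropped <- tibble(animal_id = character(), n_ratings = integer())
  }
  structure(counts,
            class = c("rating_matrix", "matrix", "array"),
            indicator_id = indicator_id,
            species = species,
            dropped = dropped)
}

#' Build a rating matrix for one indicator from assessment records
#'
#' Tabulates, for each animal, how many assessors assigned each score
#' category, producing the subjects-by-categories table underlying the
#' agreement statistics. Animals rated by fewer than two assessors carry no
#' agreement information and are dropped (recorded in the `dropped`
#' attribute); animals with any number >= 2 of ratings are retained, since
#' the generalized kappa accommodates varying raters per subject.
#'
#' @param records Accepted assessment records ([read_sheets()] /
#'   [validate_records()] output).
#' @param indicator_id Registry id of the indicator to tabulate.
#' @param species Optional filter, `"sheep"` or `"goat"`; `NULL` keeps both.
#' @inheritParams read_sheets
#' @return A [rating_matrix()] with one row per retained animal and
#'   `scale_max + 1` category columns.
#' @export
build_rating_matrix <- function(records, indicator_id, species = NULL,
                                registry = load_registry()) {
  ind <- registry$indicators
  if (!indicator_id %in% ind$id) {
    abort(paste0("unknown indicator_id: ", indicator_id),
          class = "asrwi_validation_error")
  }
  rec <- records[records$indicator_id == indicator_id, ]
  if (!is.null(species)) {
    species <- match.arg(species, c("sheep", "goat"))
    rec <- rec[rec$species == species, ]
  }
  if (nrow(rec) == 0) {
    abort(sprintf("no records for indicator '%s'%s", indicator_id,
                  if (is.null(species)) "" else paste0(" (species ", species, ")")),
          class = "asrwi_insufficient_raters")
  }
  k <- ind$scale_max[ind$id == indicator_id] + 1L
  animals <- sort(unique(rec$animal_id))
  counts <- matrix(0L, nrow = length(animals), ncol = k,
                   dimnames = list(animals, as.character(0:(k - 1L))))
  tab <- table(factor(rec$animal_id, levels = animals),
               factor(rec$score, levels = 0:(k - 1L)))
  counts[] <- as.integer(tab)
  n_i <- rowSums(counts)
  keep <- n_i >= 2
  dropped <- tibble(animal_id = animals[!keep],
                    n_ratings = as.integer(n_i[!keep]))
  if (!any(keep)) {
    abort(sprintf("insufficient raters for indicator '%s': no subject has >= 2 ratings",
                  indicator_id),
          class = "asrwi_insufficient_raters")
  }
  rating_matrix(counts[keep, , drop = FALSE], indicator_id = indicator_id,
                species = species, subject_ids = animals[keep],
                dropped = dropped)
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("<rating_matrix> indicator '%s'%s: %d subjects x %d categories, %d ratings\n",
              attr(x, "indicator_id"),
              if (is.null(attr(x, "species"))) ""
              else paste0(" (", attr(x, "species"), ")"),
              nrow(x), ncol(x), sum(x)))
  dropped <- attr(x, "dropped")
  if (nrow(dropped) > 0) {
    cat("  dropped (fewer than 2 ratings):", nrow(dropped), "subject(s)\n")
  }
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6L, " more subjects\n", sep = "")
  invisible(x)
}
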