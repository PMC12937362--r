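#' Full assessment report
#'
#' Ties the pipeline together for one scoring sheet: per-species
#' indicator-level reliability, domain-level summary, reliability-gated
#' inclusion decisions, and the domain scores and composite index, plus
#' the validation report of rejected rows. This is what the `report` CLI
#' subcommand prints.
#'
#' @param records Accepted assessment records ([read_sheets()] output).
#' @param species Species to report on (default: those present).
#' @inheritParams read_sheets
#' @return An object of class `asrwi_report`: list with `validation`
#'   (rejected rows), `reliability` (indicator table), `domains` (domain
#'   summary), `selection` (inclusion decisions), `index` (named list of
#'   per-species [welfare_index()] results), `species`, and
#'   `species_missing` (requested but absent).
#' @export
asrwi_report <- function(records, registry = load_registry(),
                         species = NULL) {
  present <- sort(unique(records$species))
  requested <- if (is.null(species)) present else species
  missing_sp <- setdiff(requested, present)
  use_sp <- intersect(requested, present)
  if (length(use_sp) == 0) {
    abort("no records for the requested species",
          class = "asrwi_validation_error")
  }
  rel <- reliability_table(records, registry = registry, species = use_sp)
  dom <- domain_summary(rel, registry = registry)
  sel <- select_indicators(rel, registry = registry)
  idx <- lapply(use_sp, function(sp) {
    welfare_index(records, registry = registry, scope = "herd", species = sp,
                  reliability = rel[rel$species == sp, ])
  })
  names(idx) <- use_sp
  structure(
    list(validation = validation_report(records), reliability = rel,
         domains = dom, selection = sel, index = idx, species = use_sp,
         species_missing = missing_sp),
    class = "asrwi_report"
  )
}

#' @export
print.asrwi_report <- function(x, ...) {
  cat("== ASR-WI assessment report ==\n")
  if (nrow(x$validation) > 0) {
    cat(sprintf("Rejected rows: %d (see $validation)\n", nrow(x$validation)))
  }
  if (length(x$species_missing) > 0) {
    cat("Note: no records for species:",
        paste(x$species_missing, collapse = ", "), "\n")
  }
  cat("\n-- Inter-observer reliability --\n")
  rel <- x$reliability
  for (sp in x$species) {
    cat(sprintf("%s:\n", sp))
    sub <- rel[rel$species == sp, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-28s kappa = %5s  (%5.1f%%; %s)\n", sub$name[i],
                  if (is.na(sub$kappa[i])) "  NA"
                  else sprintf("%.2f", sub$kappa[i]),
                  sub$percent_agreement[i],
                  if (is.na(sub$band[i])) sub$note[i] else sub$band[i]))
    }
  }
  cat("\n-- Domain summary (mean of indicator kappa / % agreement) --\n")
  d <- x$domains
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %-16s %-6s mean kappa = %.2f, mean agreement = %.1f%% (%d indicators%s)\n",
                d$domain[i], d$species[i], d$mean_kappa[i],
                d$mean_percent_agreement[i], d$n_indicators[i],
                ifelse(d$n_undefined[i] > 0,
                       sprintf(", %d undefined", d$n_undefined[i]), "")))
  }
  excl <- x$selection[!x$selection$included & x$selection$relevance_retained, ]
  cat("\n-- Indicator selection (kappa >= 0.35 gate) --\n")
  cat(sprintf("  included: %d of %d index-member results\n",
              sum(x$selection$included),
              sum(x$selection$relevance_retained)))
  if (nrow(excl) > 0) {
    for (i in seq_len(nrow(excl))) {
      cat(sprintf("  excluded: %s (%s) - %s\n", excl$indicator_id[i],
                  excl$species[i], excl$reason[i]))
    }
  }
  cat("\n-- Welfare index --\n")
  for (sp in names(x$index)) {
    r <- x$index[[sp]]
    ds <- vapply(r$domain_scores, function(d) d$value, numeric(1))
    cat(sprintf("  %-6s B = %5.1f, E = %5.1f, N = %5.1f, H = %5.1f  =>  ASR-WI = %.1f\n",
                sp, ds[["behaviour_mental"]], ds[["environment"]],
                ds[["nutrition"]], ds[["health"]], r$asrwi))
  }
  invisible(x)
}

#' Serialize a report (or any package result) to JSON
#'
#' Every number shown in the printed report is present in the JSON at full
#' precision, so the text and machine-readable renderings never disagree.
#'
#' @param report An `asrwi_report` (or any jsonlite-serializable object).
#' @param path Optional output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_json <- function(report, path = NULL) {
  x <- report
  if (inherits(x, "asrwi_report")) {
    x <- list(
      validation = x$validation,
      reliability = x$reliability,
      domains = x$domains,
      selection = x$selection,
      index = lapply(x$index, function(r) {
        list(scope = r$scope, species = r$species,
             domain_scores = lapply(r$domain_scores, function(d) {
               list(domain = d$domain, value = d$value,
                    contributing_scores = as.list(d$contributing_scores))
             }),
             asrwi = r$asrwi, appendix = r$appendix,
             n_animals = r$n_animals)
      }),
      species_missing = x$species_missing
    )
  }
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
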