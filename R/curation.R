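# Curation of a raw phenome table into the model-ready matrix: event
# retention, missingness pruning, near-constant filtering, sentinel recoding,
# indicator encoding, imputation, robust z-scoring with winsorization.

new_curation_report <- function() {
  structure(
    list(
      dropped_events = data.frame(variable = character(), event = character(),
                                  coverage = numeric()),
      dropped_missingness = data.frame(variable = character(),
                                       populated_fraction = numeric()),
      dropped_near_constant = data.frame(variable = character(),
                                         top_value_fraction = numeric()),
      recoded_counts = integer(),
      encoded = list(),
      winsorized_counts = integer(),
      retained_events = character(),
      standardization = NULL,
      input_variables = character()
    ),
    class = "curation_report"
  )
}

#' @exportS3Method base::print
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n")
  cat(sprintf("  dropped by event coverage : %d\n", nrow(x$dropped_events)))
  cat(sprintf("  dropped by missingness    : %d\n", nrow(x$dropped_missingness)))
  cat(sprintf("  dropped as near-constant  : %d\n", nrow(x$dropped_near_constant)))
  cat(sprintf("  discrete variables encoded: %d (-> %d indicators)\n",
              length(x$encoded), length(unlist(x$encoded))))
  cat(sprintf("  winsorized entries        : %d\n", sum(x$winsorized_counts)))
  invisible(x)
}

#' Retain variables from well-covered collection events
#'
#' A collection event's coverage is the fraction of participants with at least
#' one observed value among the event's variables. Only variables from events
#' covering at least `min_family_fraction` of the participants present at
#' baseline are kept.
#'
#' @param table A [phenome_table()].
#' @param min_family_fraction Minimum event coverage; default 0.95.
#' @return A list `(table, report)`.
#' @export
retain_events <- function(table, min_family_fraction = 0.95) {
  stopifnot(inherits(table, "phenome_table"))
  assert_proportion(min_family_fraction, "min_family_fraction", allow_zero = FALSE)
  events <- unique(table$meta$event)
  coverage <- vapply(events, function(e) {
    cols <- which(table$meta$event == e)
    mean(rowSums(!is.na(table$values[, cols, drop = FALSE])) > 0)
  }, numeric(1))
  keep_events <- events[coverage >= min_family_fraction]
  if (!length(keep_events)) fail("no collection event reaches coverage %.2f",
                                 min_family_fraction)
  keep <- table$meta$event %in% keep_events
  report <- new_curation_report()
  report$input_variables <- table$meta$name
  report$retained_events <- keep_events
  report$dropped_events <- data.frame(
    variable = table$meta$name[!keep],
    event = table$meta$event[!keep],
    coverage = coverage[match(table$meta$event[!keep], events)]
  )
  list(table = table[, which(keep)], report = report)
}

#' Prune variables by populated fraction
#'
#' Removes variables observed for fewer than `min_populated` of participants.
#'
#' @param table A [phenome_table()].
#' @param min_populated Minimum populated fraction; default 0.80.
#' @return A list `(table, report)`.
#' @export
prune_missingness <- function(table, min_populated = 0.80) {
  stopifnot(inherits(table, "phenome_table"))
  assert_proportion(min_populated, "min_populated", allow_zero = FALSE)
  if (!ncol(table$values) || !nrow(table$values)) fail("empty phenome table")
  populated <- colMeans(!is.na(table$values))
  keep <- populated >= min_populated
  if (!any(keep)) {
    fail("all variables dropped at populated-fraction threshold %.2f",
         min_populated)
  }
  report <- new_curation_report()
  report$input_variables <- table$meta$name
  report$dropped_missingness <- data.frame(
    variable = table$meta$name[!keep],
    populated_fraction = unname(populated[!keep])
  )
  list(table = table[, which(keep)], report = report)
}

top_value_fraction <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(1)
  max(tabulate(match(x, unique(x)))) / length(x)
}

#' Drop near-constant variables
#'
#' Removes variables whose most frequent non-missing value accounts for more
#' than `max_top_fraction` of the non-missing entries (near-zero variance).
#'
#' @param table A [phenome_table()].
#' @param max_top_fraction Frequency threshold; default 0.99.
#' @return A list `(table, report)`.
#' @export
drop_near_constant <- function(table, max_top_fraction = 0.99) {
  stopifnot(inherits(table, "phenome_table"))
  if (!ncol(table$values) || !nrow(table$values)) fail("empty phenome table")
  top <- apply(table$values, 2, top_value_fraction)
  keep <- top <= max_top_fraction
  report <- new_curation_report()
  report$input_variables <- table$meta$name
  report$dropped_near_constant <- data.frame(
    variable = table$meta$name[!keep],
    top_value_fraction = unname(top[!keep])
  )
  list(table = table[, which(keep)], report = report)
}

#' Recode non-compliance sentinel values to missing
#'
#' @param table A [phenome_table()].
#' @param codes Numeric sentinel values (e.g. refusal / don't-know codes) to
#'   treat as missing. Default none.
#' @return A list `(table, report)`.
#' @export
recode_noncompliance <- function(table, codes = numeric(0)) {
  stopifnot(inherits(table, "phenome_table"))
  report <- new_curation_report()
  report$input_variables <- table$meta$name
  if (length(codes)) {
    hits <- table$values %in% codes & !is.na(table$values)
    hits <- matrix(hits, nrow(table$values), ncol(table$values))
    counts <- colSums(hits)
    table$values[hits] <- NA
    report$recoded_counts <- stats::setNames(as.integer(counts), table$meta$name)
    report$recoded_counts <- report$recoded_counts[report$recoded_counts > 0]
  }
  list(table = table, report = report)
}

#' One-hot encode discrete variables
#'
#' Each discrete variable with k observed levels is replaced by k binary
#' indicator columns named `<variable>=<level>`; indicators inherit the
#' parent's category and event, and a missing parent value is missing in all
#' its indicators.
#'
#' @param table A [phenome_table()].
#' @return A list `(table, report)`.
#' @export
encode_discrete <- function(table) {
  stopifnot(inherits(table, "phenome_table"))
  report <- new_curation_report()
  report$input_variables <- table$meta$name
  is_disc <- table$meta$dtype == "discrete"
  if (!any(is_disc)) return(list(table = table, report = report))

  cols <- vector("list", ncol(table$values))
  metas <- vector("list", ncol(table$values))
  for (j in seq_len(ncol(table$values))) {
    if (!is_disc[j]) {
      cols[[j]] <- table$values[, j, drop = FALSE]
      metas[[j]] <- table$meta[j, ]
      next
    }
    x <- table$values[, j]
    lev <- sort(unique(x[!is.na(x)]))
    if (length(lev) < 2) {
      fail("discrete variable '%s' has a single observed level; it should have been dropped by the near-constant filter",
           table$meta$name[j])
    }
    child_names <- sprintf("%s=%s", table$meta$name[j], format(lev, trim = TRUE))
    ind <- outer(x, lev, `==`) * 1  # NA parent propagates to all indicators
    colnames(ind) <- child_names
    cols[[j]] <- ind
    metas[[j]] <- data.frame(
      name = child_names,
      category = table$meta$category[j],
      dtype = "indicator",
      event = table$meta$event[j],
      stringsAsFactors = FALSE
    )
    report$encoded[[table$meta$name[j]]] <- child_names
  }
  values <- do.call(cbind, cols)
  meta <- do.call(rbind, metas)
  out <- phenome_table(values, meta, participant_ids = table$participant_ids,
                       site = table$site, state = table$state,
                       categories = unique(meta$category))
  list(table = out, report = report)
}

#' Impute missing values
#'
#' Continuous variables: column median of observed values. Discrete and
#' indicator variables: column mode (most frequent observed value, ties broken
#' toward the smaller value).
#'
#' @param table A [phenome_table()].
#' @return The imputed [phenome_table()] (no missing entries remain).
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "phenome_table"))
  for (j in seq_len(ncol(table$values))) {
    x <- table$values[, j]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) fail("variable '%s' has no observed values", table$meta$name[j])
    if (table$meta$dtype[j] == "continuous") {
      fill <- stats::median(x[!miss])
    } else {
      vals <- sort(unique(x[!miss]))
      fill <- vals[which.max(tabulate(match(x[!miss], vals)))]
    }
    table$values[miss, j] <- fill
  }
  table
}

#' Robust z-scoring with winsorization
#'
#' For each continuous column: compute the mean and standard deviation over
#' observed values; entries more than `z_max` standard deviations from the
#' mean are replaced by the observed value of largest magnitude among the
#' in-range entries; the column is then z-scored by its post-replacement mean
#' and standard deviation. Indicator and discrete columns are untouched
#' (bounded by construction).
#'
#' @param table A [phenome_table()].
#' @param z_max Winsorization bound in standard deviations; default 4.
#' @param stats_rows Optional row indices over which to compute the
#'   standardization statistics (e.g. the training split, for leakage-sensitive
#'   uses); defaults to all rows.
#' @return A list `(table, report)`.
#' @export
robust_zscore_winsorize <- function(table, z_max = 4, stats_rows = NULL) {
  stopifnot(inherits(table, "phenome_table"))
  if (z_max <= 0) fail("z_max must be > 0")
  rows <- stats_rows %||% seq_len(nrow(table$values))
  report <- new_curation_report()
  report$input_variables <- table$meta$name
  counts <- integer(0)
  for (j in which(table$meta$dtype == "continuous")) {
    ref <- table$values[rows, j]
    m <- mean(ref, na.rm = TRUE)
    s <- stats::sd(ref, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      fail("variable '%s' has zero variance; it should have been dropped by the near-constant filter",
           table$meta$name[j])
    }
    x <- table$values[, j]
    z <- (x - m) / s
    out_of_range <- !is.na(z) & abs(z) > z_max
    if (any(out_of_range)) {
      in_range <- x[!is.na(z) & abs(z) <= z_max]
      if (!length(in_range)) fail("variable '%s': no in-range values", table$meta$name[j])
      replacement <- in_range[which.max(abs(in_range))]
      x[out_of_range] <- replacement
    }
    counts[table$meta$name[j]] <- sum(out_of_range)
    m2 <- mean(x[rows], na.rm = TRUE)
    s2 <- stats::sd(x[rows], na.rm = TRUE)
    table$values[, j] <- (x - m2) / s2
  }
  report$winsorized_counts <- counts
  report$standardization <- list(
    rows = if (is.null(stats_rows)) "all" else "subset", z_max = z_max
  )
  list(table = table, report = report)
}

merge_reports <- function(reports, input_variables) {
  out <- new_curation_report()
  out$input_variables <- input_variables
  for (r in reports) {
    out$dropped_events <- rbind(out$dropped_events, r$dropped_events)
    out$dropped_missingness <- rbind(out$dropped_missingness, r$dropped_missingness)
    out$dropped_near_constant <- rbind(out$dropped_near_constant, r$dropped_near_constant)
    out$recoded_counts <- c(out$recoded_counts, r$recoded_counts)
    out$encoded <- c(out$encoded, r$encoded)
    out$winsorized_counts <- c(out$winsorized_counts, r$winsorized_counts)
    out$retained_events <- unique(c(out$retained_events, r$retained_events))
    if (!is.null(r$standardization)) out$standardization <- r$standardization
  }
  out
}

#' Curation configuration
#'
#' @param min_family_fraction,min_populated,max_top_fraction,z_max Stage
#'   thresholds (see the individual stage functions).
#' @param noncompliance_codes Sentinel values recoded to missing.
#' @param impute `"median-mode"` (default) or `"none"`.
#' @param standardize `"full"` (statistics over the whole curated sample,
#'   matching the study narrative that curates before splitting) or `"train"`
#'   (statistics over `stats_rows` only).
#' @return A `curation_config` list.
#' @export
curation_config <- function(min_family_fraction = 0.95,
                            min_populated = 0.80,
                            max_top_fraction = 0.99,
                            z_max = 4,
                            noncompliance_codes = numeric(0),
                            impute = c("median-mode", "none"),
                            standardize = c("full", "train")) {
  structure(list(
    min_family_fraction = min_family_fraction,
    min_populated = min_populated,
    max_top_fraction = max_top_fraction,
    z_max = z_max,
    noncompliance_codes = noncompliance_codes,
    impute = match.arg(impute),
    standardize = match.arg(standardize)
  ), class = "curation_config")
}

#' Curate a raw phenome table
#'
#' Applies, in order: event retention, missingness pruning, near-constant
#' filtering, non-compliance recoding, indicator encoding of discrete
#' variables, imputation, and robust z-scoring with winsorization. Emits a
#' consolidated report in which every input variable is accounted for exactly
#' once (dropped, encoded, or retained).
#'
#' @param table A raw [phenome_table()].
#' @param config A [curation_config()].
#' @param stats_rows Optional training-row indices used for standardization
#'   when `config$standardize == "train"`.
#' @return A list `(table, report)` with the curated table (no missing
#'   entries; continuous columns standardized) and the consolidated
#'   `curation_report`.
#' @export
curate <- function(table, config = curation_config(), stats_rows = NULL) {
  stopifnot(inherits(table, "phenome_table"), inherits(config, "curation_config"))
  input_vars <- table$meta$name
  reports <- list()

  step <- retain_events(table, config$min_family_fraction)
  table <- step$table; reports <- c(reports, list(step$report))

  step <- prune_missingness(table, config$min_populated)
  table <- step$table; reports <- c(reports, list(step$report))

  step <- drop_near_constant(table, config$max_top_fraction)
  table <- step$table; reports <- c(reports, list(step$report))

  step <- recode_noncompliance(table, config$noncompliance_codes)
  table <- step$table; reports <- c(reports, list(step$report))

  step <- encode_discrete(table)
  table <- step$table; reports <- c(reports, list(step$report))

  if (config$impute == "median-mode") table <- impute_missing(table)

  step <- robust_zscore_winsorize(
    table, config$z_max,
    stats_rows = if (config$standardize == "train") stats_rows else NULL
  )
  table <- step$table; reports <- c(reports, list(step$report))

  report <- merge_reports(reports, input_vars)
  # conservation: every input variable accounted for exactly once
  accounted <- c(report$dropped_events$variable,
                 report$dropped_missingness$variable,
                 report$dropped_near_constant$variable,
                 names(report$encoded),
                 intersect(input_vars, table$meta$name))
  stopifnot(identical(sort(accounted), sort(input_vars)))
  list(table = table, report = report)
}
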