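#' Construct a phenome table
#'
#' The central data container: a participants x variables value matrix with
#' per-variable metadata (name, category, declared type, collection event) and
#' per-participant site and state labels. Missing entries are `NA`.
#'
#' @param values Numeric matrix, participants in rows, variables in columns.
#'   Column names must match `meta$name`.
#' @param meta Data frame with columns `name`, `category`, `dtype`
#'   (`"continuous"`, `"discrete"` or `"indicator"`), `event`.
#' @param participant_ids Character vector of unique participant identifiers.
#' @param site Factor or character vector of per-participant data-collection
#'   site labels (optional, required for conditioning and stratified splits).
#' @param state Factor or character vector of per-participant state-of-residence
#'   labels (optional, required for the state-prediction analysis).
#' @param categories Closed list of allowed category names.
#'
#' @return An object of class `phenome_table`: a list with elements `values`,
#'   `meta`, `participant_ids`, `site`, `state`.
#' @export
phenome_table <- function(values, meta, participant_ids = rownames(values),
                          site = NULL, state = NULL,
                          categories = phenome_categories) {
  values <- as.matrix(values)
  if (!is.numeric(values)) fail("`values` must be a numeric matrix")
  if (is.null(participant_ids)) {
    participant_ids <- sprintf("P%05d", seq_len(nrow(values)))
  }
  participant_ids <- as.character(participant_ids)
  if (anyDuplicated(participant_ids)) fail("duplicate participant ids")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("name", "category", "dtype", "event")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    fail("`meta` is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$name)) fail("duplicate variable names")
  if (ncol(values) != nrow(meta)) {
    fail("%d value columns but %d metadata rows", ncol(values), nrow(meta))
  }
  bad <- setdiff(unique(meta$category), categories)
  if (length(bad)) {
    fail("unknown categories: %s", paste(bad, collapse = ", "))
  }
  bad_dtype <- setdiff(unique(meta$dtype), c("continuous", "discrete", "indicator"))
  if (length(bad_dtype)) {
    fail("unknown dtype values: %s", paste(bad_dtype, collapse = ", "))
  }
  colnames(values) <- meta$name
  rownames(values) <- participant_ids
  if (!is.null(site)) {
    site <- as.factor(site)
    if (length(site) != nrow(values)) fail("`site` length != participants")
  }
  if (!is.null(state)) {
    state <- as.factor(state)
    if (length(state) != nrow(values)) fail("`state` length != participants")
  }
  structure(
    list(values = values, meta = meta, participant_ids = participant_ids,
         site = site, state = state),
    class = "phenome_table"
  )
}

#' @exportS3Method base::print
print.phenome_table <- function(x, ...) {
  cat(sprintf(
    "<phenome_table> %d participants x %d variables (%d continuous, %d discrete, %d indicator)\n",
    nrow(x$values), ncol(x$values),
    sum(x$meta$dtype == "continuous"), sum(x$meta$dtype == "discrete"),
    sum(x$meta$dtype == "indicator")
  ))
  cat(sprintf("  missing entries: %.2f%%\n", 100 * mean(is.na(x$values))))
  if (!is.null(x$site)) {
    cat(sprintf("  sites: %d; states: %s\n", nlevels(x$site),
                if (is.null(x$state)) "none" else nlevels(x$state)))
  }
  invisible(x)
}

#' @export
dim.phenome_table <- function(x) dim(x$values)

#' Subset a phenome table
#'
#' @param x A [phenome_table()].
#' @param i Participant (row) index.
#' @param j Variable (column) index.
#' @param ... Unused.
#' @return A `phenome_table` restricted to the requested rows/columns.
#' @export
`[.phenome_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(j)) j <- match(j, x$meta$name)
  phenome_table(
    values = x$values[i, j, drop = FALSE],
    meta = x$meta[j, , drop = FALSE],
    participant_ids = x$participant_ids[i],
    site = if (!is.null(x$site)) droplevels(x$site[i]),
    state = if (!is.null(x$state)) droplevels(x$state[i]),
    categories = unique(x$meta$category)
  )
}

#' Write / read a phenome table as delimited text
#'
#' The value matrix is written as TSV with `participant_id`, `site`, `state`
#' as leading columns; variable metadata goes to a sidecar TSV with columns
#' `name`, `category`, `dtype`, `event`.
#'
#' @param table A [phenome_table()].
#' @param values_path,meta_path Output (input) file paths.
#' @return `write_phenome()` returns the paths invisibly; `read_phenome()`
#'   returns a `phenome_table`.
#' @export
write_phenome <- function(table, values_path, meta_path) {
  df <- data.table::data.table(
    participant_id = table$participant_ids,
    site = if (is.null(table$site)) NA_character_ else as.character(table$site),
    state = if (is.null(table$state)) NA_character_ else as.character(table$state)
  )
  df <- cbind(df, data.table::as.data.table(table$values))
  data.table::fwrite(df, values_path, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(data.table::as.data.table(table$meta), meta_path,
                     sep = "\t", na = "NA", quote = FALSE)
  invisible(c(values = values_path, meta = meta_path))
}

#' @rdname write_phenome
#' @export
read_phenome <- function(values_path, meta_path) {
  df <- data.table::fread(values_path, sep = "\t", na.strings = "NA",
                          data.table = FALSE)
  meta <- data.table::fread(meta_path, sep = "\t", na.strings = "NA",
                            data.table = FALSE)
  values <- as.matrix(df[, meta$name, drop = FALSE])
  site <- if (all(is.na(df$site))) NULL else df$site
  state <- if (all(is.na(df$state))) NULL else df$state
  phenome_table(values, meta, participant_ids = df$participant_id,
                site = site, state = state,
                categories = unique(meta$category))
}
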