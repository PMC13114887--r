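# Culture-level CBMN scoring records: validation, I/O, frequency
# normalisation and CBPI quality control.

.CULTURE_COLUMNS <- c(
  "donor_id", "experiment_id", "substance", "timing", "solvent",
  "dose_mGy", "n_bc_scored", "mn_count", "n_mono", "n_bi", "n_multi"
)
.MANDATORY_COLUMNS <- setdiff(.CULTURE_COLUMNS, c("n_mono", "n_bi", "n_multi"))
.TIMING_LEVELS <- c("none", "pre", "post")
.SOLVENT_LEVELS <- c("aqueous", "dmso", "undiluted")

#' Construct and validate a table of CBMN culture records
#'
#' A culture record describes one scored culture: the design factors
#' (donor, experiment/replicate, substance, administration timing relative
#' to irradiation, solvent), the delivered gamma dose in mGy, the number of
#' binucleated cells (BC) scored, the total micronucleus (MN) count, and
#' optionally the mono-/bi-/multinucleate tallies used for the
#' cytokinesis-block proliferation index (CBPI).
#'
#' @param df A data frame with columns `donor_id`, `experiment_id`,
#'   `substance`, `timing` (one of `"none"`, `"pre"`, `"post"`), `solvent`
#'   (one of `"aqueous"`, `"dmso"`, `"undiluted"`), `dose_mGy`,
#'   `n_bc_scored`, `mn_count`, and optionally `n_mono`, `n_bi`, `n_multi`.
#' @return The validated data frame with class `culture_records`.
#' @examples
#' rec <- culture_records(data.frame(
#'   donor_id = "d1", experiment_id = "e1", substance = "control",
#'   timing = "none", solvent = "aqueous", dose_mGy = 0,
#'   n_bc_scored = 500, mn_count = 10
#' ))
#' @export
culture_records <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(.MANDATORY_COLUMNS, names(df))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("n_mono", "n_bi", "n_multi")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df$donor_id <- as.character(df$donor_id)
  df$experiment_id <- as.character(df$experiment_id)
  df$substance <- as.character(df$substance)
  df$timing <- as.character(df$timing)
  df$solvent <- as.character(df$solvent)
  for (col in c("dose_mGy", "n_bc_scored", "mn_count",
                "n_mono", "n_bi", "n_multi")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  .validate_culture_records(df)
  df <- df[, .CULTURE_COLUMNS]
  class(df) <- c("culture_records", "data.frame")
  df
}

.validate_culture_records <- function(df) {
  .bad_rows <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows) > 0L) {
      stop("validation error at row(s) ", paste(rows, collapse = ", "),
           ": ", msg, call. = FALSE)
    }
  }
  .bad_rows(!df$timing %in% .TIMING_LEVELS,
            "timing must be one of none/pre/post")
  .bad_rows(!df$solvent %in% .SOLVENT_LEVELS,
            "solvent must be one of aqueous/dmso/undiluted")
  .bad_rows(is.na(df$dose_mGy) | df$dose_mGy < 0, "dose_mGy must be >= 0")
  .bad_rows(is.na(df$n_bc_scored) | df$n_bc_scored < 1,
            "n_bc_scored must be a positive integer")
  .bad_rows(is.na(df$mn_count) | df$mn_count < 0, "mn_count must be >= 0")
  for (col in c("n_mono", "n_bi", "n_multi")) {
    .bad_rows(!is.na(df[[col]]) & df[[col]] < 0,
              paste(col, "must be >= 0 when present"))
  }
  invisible(df)
}

#' Read a CBMN scoring table from a delimited text file
#'
#' Reads a CSV (or other delimited) scoring table into validated culture
#' records. Column names in the file can be mapped onto the canonical
#' record fields through `col_map` or through a YAML/JSON config file.
#' Unknown columns are tolerated and reported via an attribute, never an
#' error; missing mandatory columns and invariant violations are errors
#' that name the offending column or row.
#'
#' @param path Path to the delimited file (header row required).
#' @param col_map Optional named character vector mapping canonical field
#'   names to the column names used in the file, e.g.
#'   `c(donor_id = "Donor")`. Alternatively a path to a YAML or JSON file
#'   with a top-level `columns` mapping.
#' @param sep Field delimiter; `","` by default, use `"\t"` for TSV.
#' @return A `culture_records` data frame. Unknown (unmapped) columns found
#'   in the file are recorded in `attr(, "unknown_columns")`.
#' @export
read_scoring_table <- function(path, col_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(col_map) && length(col_map) == 1L && file.exists(col_map)) {
    col_map <- .read_column_config(col_map)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    stopifnot(!is.null(names(col_map)))
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (src %in% names(raw)) {
        names(raw)[names(raw) == src] <- canon
      }
    }
  }
  unknown <- setdiff(names(raw), .CULTURE_COLUMNS)
  rec <- culture_records(raw[, intersect(names(raw), .CULTURE_COLUMNS),
                             drop = FALSE])
  attr(rec, "unknown_columns") <- unknown
  rec
}

.read_column_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  map <- if (!is.null(cfg$columns)) cfg$columns else cfg
  unlist(map)
}

#' Write culture records back to CSV
#'
#' Inverse of [read_scoring_table()]; the read/write/read round trip
#' preserves all fields.
#'
#' @param records A `culture_records` data frame.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_scoring_table <- function(records, path, sep = ",") {
  utils::write.table(as.data.frame(records), path, sep = sep,
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Micronucleus frequency per 500 binucleated cells
#'
#' The CBMN damage endpoint is reported as micronuclei per 500 binucleated
#' cells (MN/500 BC): exact rational scaling of the observed count, no
#' rounding.
#'
#' @param mn_count Non-negative micronucleus count.
#' @param n_bc_scored Number of binucleated cells scored (>= 1).
#' @return `mn_count * 500 / n_bc_scored`, vectorised.
#' @examples
#' mn_frequency_per_500(156, 3000) # 26
#' @export
mn_frequency_per_500 <- function(mn_count, n_bc_scored) {
  if (any(is.na(n_bc_scored)) || any(n_bc_scored < 1)) {
    stop("undefined frequency: n_bc_scored must be >= 1", call. = FALSE)
  }
  if (any(mn_count < 0)) stop("mn_count must be >= 0", call. = FALSE)
  mn_count * 500 / n_bc_scored
}

#' Cytokinesis-block proliferation index (CBPI)
#'
#' CBPI = (M1 + 2 M2 + 3 M3+) / N over cells with one, two, and three or
#' more nuclei; it lies in \[1, 3\] and equals 1 only when every scored cell
#' is mononucleate.
#'
#' @param n_mono,n_bi,n_multi Non-negative cell tallies (vectorised).
#' @return The proliferation index.
#' @examples
#' cbpi(200, 275, 25) # 1.65
#' @export
cbpi <- function(n_mono, n_bi, n_multi) {
  total <- n_mono + n_bi + n_multi
  if (any(is.na(total)) || any(total < 1)) {
    stop("undefined index: total cell tally must be >= 1", call. = FALSE)
  }
  if (any(c(n_mono, n_bi, n_multi) < 0)) {
    stop("cell tallies must be >= 0", call. = FALSE)
  }
  (n_mono + 2 * n_bi + 3 * n_multi) / total
}

#' CBPI culture-quality flag
#'
#' Cultures are considered adequately proliferating when the CBPI lies in
#' the inclusive band \[1.3, 1.7\]; outside it the condition is flagged, not
#' dropped.
#'
#' @param cbpi_value CBPI value(s) in \[1, 3\].
#' @param lower,upper Inclusive quality bounds.
#' @return `"pass"` or `"fail"` per value.
#' @export
cbpi_quality_flag <- function(cbpi_value, lower = 1.3, upper = 1.7) {
  ifelse(!is.na(cbpi_value) & cbpi_value >= lower & cbpi_value <= upper,
         "pass", "fail")
}

#' Summarise MN frequencies per experimental condition
#'
#' Computes, per group of culture records, the mean and standard error of
#' the per-culture MN/500 BC frequency across experiments (the culture is
#' the replication unit), the group size, the total BC scored, and -- when
#' CBPI tallies are present -- the pooled CBPI and its quality flag.
#' Conditions with fewer than 3000 BC scored in total are flagged with a
#' warning, not removed.
#'
#' @param records A `culture_records` data frame.
#' @param by Character vector of grouping columns (design keys).
#' @param min_bc Minimum total BC per condition before a low-count warning.
#' @return A data frame with one row per group: the group keys, `n`,
#'   `mean_freq`, `se_freq`, `total_bc`, `cbpi`, `cbpi_flag`, `bc_flag`.
#' @export
summarize_conditions <- function(records,
                                 by = c("substance", "timing", "solvent",
                                        "dose_mGy"),
                                 min_bc = 3000) {
  stopifnot(is.data.frame(records))
  absent <- setdiff(by, names(records))
  if (length(absent) > 0L) {
    stop("grouping key(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("no records to summarise", call. = FALSE)
  freq <- mn_frequency_per_500(records$mn_count, records$n_bc_scored)
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(groups, function(idx) {
    g <- records[idx, , drop = FALSE]
    f <- freq[idx]
    n <- length(f)
    has_tallies <- all(!is.na(g$n_mono) & !is.na(g$n_bi) & !is.na(g$n_multi))
    cb <- if (has_tallies) {
      cbpi(sum(g$n_mono), sum(g$n_bi), sum(g$n_multi))
    } else NA_real_
    row <- g[1L, by, drop = FALSE]
    row$n <- n
    row$mean_freq <- mean(f)
    row$se_freq <- if (n > 1L) stats::sd(f) / sqrt(n) else 0
    row$total_bc <- sum(g$n_bc_scored)
    row$cbpi <- cb
    row$cbpi_flag <- if (is.na(cb)) NA_character_ else cbpi_quality_flag(cb)
    row$bc_flag <- if (row$total_bc >= min_bc) "ok" else "low_bc"
    row
  }))
  rownames(out) <- NULL
  if (any(out$bc_flag == "low_bc")) {
    warning(sum(out$bc_flag == "low_bc"),
            " condition(s) below ", min_bc, " total BC scored",
            call. = FALSE)
  }
  out
}
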