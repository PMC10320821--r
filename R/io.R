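#' Read a word-level fixation report
#'
#' Canonical dialect: UTF-8 TSV with a header. Two shapes are accepted and
#' auto-detected: fixation events (`onset`, `duration` columns, one row per
#' fixation) or precomputed measures (`ff`, `gd`, `tf` columns, one row per
#' word). Other dialects (e.g. interest-area reports with different column
#' names) are mapped via `column_map`.
#'
#' @param path File path (TSV by default; `,`-separated files are detected
#'   from the extension `.csv`).
#' @param column_map Named character vector mapping canonical field names
#'   (`participant_id`, `trial_id`, `word_index`, `word`, `onset`,
#'   `duration`, `ff`, `gd`, `tf`, `skipped`) to the column names used in the
#'   file, e.g. `c(word_index = "IA_ID")`. Unmapped fields use their
#'   canonical name.
#' @return Tibble in canonical columns; attribute `report_kind` is
#'   `"events"` or `"measures"`.
#' @export
read_fixation_report <- function(path, column_map = character(0)) {
  if (!file.exists(path)) abort_lexcon(paste("file not found:", path), "lexcon_config_error")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, comment = "#"
  )
  canon <- c(
    "participant_id", "trial_id", "word_index", "word",
    "onset", "duration", "ff", "gd", "tf", "skipped"
  )
  for (field in names(column_map)) {
    src <- column_map[[field]]
    if (!src %in% names(raw)) {
      abort_lexcon(
        sprintf("column '%s' (mapped to field '%s') is missing from %s", src, field, path),
        "lexcon_config_error"
      )
    }
    names(raw)[names(raw) == src] <- field
  }
  need <- c("participant_id", "trial_id", "word_index", "word")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort_lexcon(
      paste("fixation report is missing required columns:", paste(miss, collapse = ", ")),
      "lexcon_config_error"
    )
  }
  kind <- if (all(c("onset", "duration") %in% names(raw))) {
    "events"
  } else if (all(c("ff", "gd", "tf") %in% names(raw))) {
    "measures"
  } else {
    abort_lexcon(
      "report must carry either fixation events (onset, duration) or measures (ff, gd, tf)",
      "lexcon_config_error"
    )
  }
  num_cols <- intersect(c("word_index", "onset", "duration", "ff", "gd", "tf"), names(raw))
  for (col in num_cols) {
    vals <- raw[[col]]
    ok <- is.na(vals) | vals %in% c("NA", "") | !is.na(suppressWarnings(as.numeric(vals)))
    if (!all(ok)) {
      # +1 for the header line
      abort_lexcon(
        sprintf(
          "non-numeric value '%s' in column '%s' on line %d of %s",
          vals[which(!ok)[1]], col, which(!ok)[1] + 1L, path
        ),
        "lexcon_parse_error"
      )
    }
    raw[[col]] <- suppressWarnings(as.numeric(ifelse(vals %in% c("NA", ""), NA, vals)))
  }
  raw$word_index <- as.integer(raw$word_index)
  if ("skipped" %in% names(raw)) raw$skipped <- as.logical(raw$skipped)
  dur_cols <- intersect(c("duration", "ff", "gd", "tf"), names(raw))
  for (col in dur_cols) {
    if (any(!is.na(raw[[col]]) & raw[[col]] <= 0)) {
      abort_lexcon(sprintf("non-positive duration in column '%s'", col), "lexcon_parse_error")
    }
  }
  if (kind == "measures" &&
    anyDuplicated(raw[, c("participant_id", "trial_id", "word_index")])) {
    abort_lexcon("word_index not unique within (participant, trial)", "lexcon_parse_error")
  }
  out <- raw[, intersect(canon, names(raw))]
  attr(out, "report_kind") <- kind
  out
}

#' Read a two-column frequency table
#'
#' Whitespace- or tab-separated `word count` lines (header optional). Counts
#' must be positive integers and words unique (after optional case folding).
#'
#' @param path File path.
#' @param case_fold Lower-case words (duplicates after folding are an
#'   error).
#' @return Tibble `(word, count)` with the token total in `attr(, "total")`.
#' @export
read_frequency_table <- function(path, case_fold = TRUE) {
  if (!file.exists(path)) abort_lexcon(paste("file not found:", path), "lexcon_config_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  tab <- utils::read.table(path,
    header = FALSE, sep = sep, col.names = c("word", "count"),
    colClasses = c("character", "character"), comment.char = "#"
  )
  if (nrow(tab) && tab$word[1] == "word") tab <- tab[-1, , drop = FALSE] # header line
  tab$count <- suppressWarnings(as.numeric(tab$count))
  if (any(is.na(tab$count)) || any(tab$count <= 0) || any(tab$count != round(tab$count))) {
    abort_lexcon("frequency counts must be positive integers", "lexcon_parse_error")
  }
  if (case_fold) tab$word <- tolower(tab$word)
  if (anyDuplicated(tab$word)) {
    abort_lexcon(
      sprintf("duplicate word in frequency table: '%s'", tab$word[duplicated(tab$word)][1]),
      "lexcon_parse_error"
    )
  }
  out <- tibble::tibble(word = tab$word, count = as.integer(tab$count))
  attr(out, "total") <- sum(out$count)
  out
}

#' Write / read a result table stamped with its provenance
#'
#' Result tables are CSVs whose first line is a comment embedding the seed
#' and the hash of the configuration that produced them; the round trip is
#' lossless for all fields.
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @param seed Integer seed used to produce `x`.
#' @param config Configuration object (hashed with [config_hash()]).
#' @return `read_result_table()` returns the tibble with attributes `seed`
#'   and `config_hash`.
#' @export
write_result_table <- function(x, path, seed = NA_integer_, config = list()) {
  header <- sprintf("# lexcon seed=%s config=%s", seed, config_hash(config))
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  first <- readLines(path, n = 1L)
  out <- readr::read_csv(path, comment = "#", progress = FALSE, show_col_types = FALSE)
  m <- regmatches(first, regexec("seed=([^ ]+) config=([0-9a-f]+)", first))[[1]]
  if (length(m) == 3) {
    attr(out, "seed") <- suppressWarnings(as.integer(m[2]))
    attr(out, "config_hash") <- m[3]
  }
  out
}

#' Read a run configuration (YAML or JSON)
#'
#' Paths for the fixation report, frequency table, language model and
#' participant metadata, plus analysis switches: which measures to run,
#' bootstrap replicates `B`, the top-level `seed`, and significance level
#' `alpha`. Defaults are filled for missing switches and validated
#' (`B >= 1`, `0 < alpha < 1`).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_lexcon(paste("file not found:", path), "lexcon_config_error")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- list(
    measures = c("ff", "gd", "tf"), bootstrap_B = 199,
    seed = 1L, alpha = 0.05, case_fold = TRUE
  )
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  if (cfg$bootstrap_B < 1) abort_lexcon("bootstrap_B must be >= 1", "lexcon_config_error")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort_lexcon("alpha must be in (0, 1)", "lexcon_config_error")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}
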