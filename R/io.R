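.screen_columns <- c("plate", "replicate", "condition", "kind", "sirna_id",
                     "viability")

#' Write a screen to long-format CSV
#'
#' One row per well with columns
#' `plate,replicate,condition,kind,sirna_id,viability` and, when the screen
#' carries a simulated truth table, a `truth_label` column.
#'
#' @param screen A `screen_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(screen, path) {
  df <- as.data.frame(screen)[, .screen_columns]
  df$viability <- signif(df$viability, 9)
  truth <- attr(screen, "truth")
  if (!is.null(truth)) {
    df$truth_label <- ifelse(
      df$kind == "active",
      truth$label[match(df$sirna_id, truth$sirna_id)], "")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a screen from long-format CSV
#'
#' Reads and validates a per-well viability table with header
#' `plate,replicate,condition,kind,sirna_id,viability` (`condition` in
#' {treated, untreated}, `kind` in {active, control}; a `truth_label`
#' column, if present, is ignored — real screens carry no ground truth).
#' Validation is strict: unknown tokens, non-numeric or negative
#' viabilities, and plates lacking untreated NS controls are each reported
#' as a named error with row context.
#'
#' @param path CSV file path.
#' @return A `screen_dataset` (without truth table).
#' @export
read_screen_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(.screen_columns, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_cond <- which(!df$condition %in% c("treated", "untreated"))
  if (length(bad_cond)) {
    stop("unknown condition token '", df$condition[bad_cond[1]],
         "' at data row ", bad_cond[1], call. = FALSE)
  }
  bad_kind <- which(!df$kind %in% c("active", "control"))
  if (length(bad_kind)) {
    stop("unknown kind token '", df$kind[bad_kind[1]], "' at data row ",
         bad_kind[1], call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(df$viability))
  bad_num <- which(is.na(v))
  if (length(bad_num)) {
    stop("non-numeric viability '", df$viability[bad_num[1]],
         "' at data row ", bad_num[1], call. = FALSE)
  }
  bad_neg <- which(v < 0)
  if (length(bad_neg)) {
    stop("negative viability (", df$viability[bad_neg[1]], ") at data row ",
         bad_neg[1], call. = FALSE)
  }
  no_id <- which(df$kind == "active" & (is.na(df$sirna_id) | df$sirna_id == ""))
  if (length(no_id)) {
    stop("active well without sirna_id at data row ", no_id[1], call. = FALSE)
  }
  out <- data.frame(
    plate = as.integer(df$plate),
    replicate = as.integer(df$replicate),
    condition = df$condition,
    kind = df$kind,
    sirna_id = ifelse(df$sirna_id == "", NA_character_, df$sirna_id),
    viability = v,
    stringsAsFactors = FALSE
  )
  if (anyNA(out$plate) || anyNA(out$replicate)) {
    stop("non-integer plate or replicate value", call. = FALSE)
  }
  # every plate must carry untreated NS controls, in equal-sized blocks
  ctl <- out[out$kind == "control" & out$condition == "untreated", ]
  plates <- sort(unique(out$plate))
  missing_ctl <- setdiff(plates, unique(ctl$plate))
  if (length(missing_ctl)) {
    stop("plate(s) lacking untreated NS controls: ",
         paste(missing_ctl, collapse = ", "), call. = FALSE)
  }
  blocks <- table(paste(ctl$plate, ctl$replicate))
  if (length(unique(as.integer(blocks))) > 1) {
    stop("unequal untreated NS-control block sizes across ",
         "(plate, replicate) blocks", call. = FALSE)
  }
  structure(out, class = c("screen_dataset", "data.frame"))
}

#' Write a results table as TSV or JSON
#'
#' Output is byte-stable for a fixed input: column order is preserved and
#' floating-point columns are written with 6 significant digits.
#'
#' @param results A data frame (e.g. from [score_all()] or
#'   [sweep_scenarios()]).
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @param allow_empty Permit an empty table (header-only output).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json"),
                          allow_empty = FALSE) {
  format <- match.arg(format)
  if (nrow(results) == 0 && !allow_empty) {
    stop("results table is empty (pass allow_empty = TRUE to permit)",
         call. = FALSE)
  }
  df <- as.data.frame(results)
  attr(df, "ranking") <- NULL
  num <- vapply(df, is.double, logical(1))
  if (format == "tsv") {
    df[num] <- lapply(df[num], function(x) {
      ifelse(is.na(x), NA_character_, sprintf("%.6g", x))
    })
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA")
  } else {
    df[num] <- lapply(df[num], function(x) signif(x, 6))
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
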