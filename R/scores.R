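#' Observer score table
#'
#' Per-case visual stroma percentages from multiple raters, scored in 10%
#' increments, with optional consensus and dichotomized label. The consensus
#' column holds the agreed percentage or the string `"needs_meeting"` when
#' no majority exists and a consensus meeting is required.
#'
#' @param df data.frame with columns `case_id`, `rater1..raterN`
#'   (integers in 0,10,...,100) and optionally `consensus`, `dichotomy`.
#' @return data.frame of class `observer_table`.
#' @export
observer_table <- function(df) {
  df <- as.data.frame(df)
  if (nrow(df) == 0L) {
    if (!"case_id" %in% names(df)) df$case_id <- character(0)
    return(structure(df, class = c("observer_table", "data.frame")))
  }
  if (!"case_id" %in% names(df))
    tsr_stop("tsr_format_error", "score table needs a 'case_id' column")
  rcols <- rater_columns(df)
  if (!length(rcols))
    tsr_stop("tsr_format_error", "score table needs rater1..raterN columns")
  for (cl in rcols) {
    v <- df[[cl]]
    ok <- is.na(v) | (v >= 0 & v <= 100 & v %% 10 == 0)
    if (!all(ok))
      tsr_stop("tsr_validation_error", sprintf(
        "score %s in column %s is not a multiple of 10 in [0,100]",
        format(v[!ok][1]), cl))
    df[[cl]] <- as.integer(v)
  }
  if ("consensus" %in% names(df)) {
    cons <- df$consensus
    num <- suppressWarnings(as.numeric(cons))
    bad <- !is.na(num) & !(num >= 0 & num <= 100 & num %% 10 == 0)
    if (any(bad))
      tsr_stop("tsr_validation_error",
               "consensus percentages must be multiples of 10 in [0,100]")
    if ("dichotomy" %in% names(df)) {
      have <- !is.na(num)
      want <- ifelse(num[have] <= 50, "stroma-low", "stroma-high")
      if (any(df$dichotomy[have] != want))
        tsr_stop("tsr_validation_error",
                 "dichotomy inconsistent with consensus percentage")
    }
  }
  structure(df, class = c("observer_table", "data.frame"))
}

rater_columns <- function(df) grep("^rater[0-9]+$", names(df), value = TRUE)

#' Read observer scores from CSV
#'
#' Columns: `case_id`, `rater1..raterN`, optional `consensus`, `dichotomy`.
#' An empty file yields an empty table.
#'
#' @param path path to a CSV file.
#' @return an [observer_table()].
#' @export
read_scores <- function(path) {
  if (!file.exists(path))
    tsr_stop("tsr_format_error", sprintf("score file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) data.frame())
  observer_table(df)
}

#' Write observer scores to CSV
#'
#' @param tab an [observer_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Fill consensus and dichotomy columns by the majority rule
#'
#' Applies [consensus_score()] per case: when all raters, or a strict
#' majority of them, give the same percentage it becomes the consensus;
#' otherwise the case is flagged `"needs_meeting"`. The dichotomy column is
#' derived from the consensus where available.
#'
#' @param tab an [observer_table()].
#' @return the table with `consensus` and `dichotomy` columns filled.
#' @export
add_consensus <- function(tab) {
  rcols <- rater_columns(tab)
  cons <- apply(as.data.frame(tab)[rcols], 1L,
                function(v) consensus_score(as.numeric(v)))
  tab$consensus <- ifelse(is.na(cons), "needs_meeting",
                          as.character(as.integer(cons)))
  tab$dichotomy <- ifelse(is.na(cons), NA_character_,
                          as.character(dichotomize(cons)))
  tab
}
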