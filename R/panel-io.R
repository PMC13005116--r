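#' Load a rating panel from delimited text
#'
#' Reads either a long-format table (one row per subject x item x wave
#' rating) or a wide-format table (one row per subject, item columns
#' suffixed by wave, e.g. `P1_T0`).
#'
#' @param path Path to a CSV file (UTF-8).
#' @param format `"auto"` detects wide files by the presence of
#'   wave-suffixed columns; otherwise `"long"` or `"wide"`.
#' @param schema Named list mapping roles to column names for long files:
#'   `subject`, `item`, `wave`, `rating`, and optionally `group`, `arm`
#'   (the latter two are also honoured in wide files).
#' @param sep Separator between item code and wave label in wide column
#'   names.
#' @param items Optional [itemSet()] used to restrict/annotate the loaded
#'   items.
#' @return A [panelData()].
#' @examples
#' demo <- system.file("extdata", "synthetic-panel-demo.csv",
#'                     package = "panelnet")
#' pd <- loadPanel(demo)
#' pd
#' @export
loadPanel <- function(path, format = c("auto", "long", "wide"),
                      schema = list(subject = "subject", item = "item",
                                    wave = "wave", rating = "rating",
                                    group = "group", arm = "arm"),
                      sep = "_", items = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
                 error = function(e) stopf("malformed file %s: %s", path,
                                           conditionMessage(e)))
  schema <- modifyList(list(subject = "subject", item = "item",
                            wave = "wave", rating = "rating",
                            group = "group", arm = "arm"), schema)
  isLong <- all(c(schema$subject, schema$item, schema$wave, schema$rating)
                %in% names(df))
  if (format == "auto") format <- if (isLong) "long" else "wide"
  dat <- if (format == "long") parseLong(df, schema) else
    parseWide(df, schema, sep)
  pd <- panelData(dat$ratings, waves = dat$waves, group = dat$group,
                  arm = dat$arm)
  if (!is.null(items)) pd <- selectItems(pd, items)
  pd
}

checkRatingColumn <- function(vals, rows) {
  bad <- !is.na(vals) & (!isWholeNumber(vals) | vals < 1 | vals > 7)
  if (any(bad))
    stopf("rating out of range 1..7 at data row %s (value %s)",
          rows[which(bad)[1]], format(vals[which(bad)[1]]))
}

parseLong <- function(df, schema) {
  need <- c(schema$subject, schema$item, schema$wave, schema$rating)
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("long format: missing column(s) %s",
                          paste(miss, collapse = ", "))
  subj <- as.character(df[[schema$subject]])
  item <- as.character(df[[schema$item]])
  wave <- as.character(df[[schema$wave]])
  rating <- suppressWarnings(as.numeric(df[[schema$rating]]))
  parseFail <- is.na(rating) & !is.na(df[[schema$rating]]) &
    df[[schema$rating]] != ""
  if (any(parseFail))
    stopf("non-numeric rating at data row %d", which(parseFail)[1])
  checkRatingColumn(rating, seq_along(rating))
  subjects <- unique(subj)
  itemCodes <- unique(item)
  waves <- unique(wave)
  ratings <- array(NA_real_, c(length(subjects), length(itemCodes),
                               length(waves)),
                   dimnames = list(subjects, itemCodes, waves))
  ratings[cbind(match(subj, subjects), match(item, itemCodes),
                match(wave, waves))] <- rating
  group <- arm <- NULL
  if (schema$group %in% names(df))
    group <- df[[schema$group]][match(subjects, subj)]
  if (schema$arm %in% names(df))
    arm <- df[[schema$arm]][match(subjects, subj)]
  list(ratings = ratings, waves = waves, group = group, arm = arm)
}

parseWide <- function(df, schema, sep) {
  if (!schema$subject %in% names(df))
    stopf("wide format: missing subject column '%s'", schema$subject)
  meta <- intersect(c(schema$subject, schema$group, schema$arm), names(df))
  valueCols <- setdiff(names(df), meta)
  hasSep <- grepl(sep, valueCols, fixed = TRUE)
  if (!any(hasSep))
    stopf("wide format: no '<item>%s<wave>' columns found", sep)
  valueCols <- valueCols[hasSep]
  # split at the LAST separator so item codes may contain it
  pos <- regexpr(paste0(sep, "[^", sep, "]*$"), valueCols)
  itemPart <- substr(valueCols, 1, pos - 1)
  wavePart <- substring(valueCols, pos + nchar(sep))
  itemCodes <- unique(itemPart)
  waves <- unique(wavePart)
  subjects <- as.character(df[[schema$subject]])
  ratings <- array(NA_real_, c(length(subjects), length(itemCodes),
                               length(waves)),
                   dimnames = list(subjects, itemCodes, waves))
  for (k in seq_along(valueCols)) {
    vals <- suppressWarnings(as.numeric(df[[valueCols[k]]]))
    checkRatingColumn(vals, seq_along(vals))
    ratings[, itemPart[k], wavePart[k]] <- vals
  }
  group <- if (schema$group %in% names(df)) df[[schema$group]]
  arm <- if (schema$arm %in% names(df)) df[[schema$arm]]
  list(ratings = ratings, waves = waves, group = group, arm = arm)
}

#' Write a rating panel to CSV
#'
#' @param data A [panelData()].
#' @param path Output file path.
#' @param format `"long"` or `"wide"`.
#' @param sep Wide-format separator between item code and wave label.
#' @return `path`, invisibly.
#' @export
writePanel <- function(data, path, format = c("long", "wide"), sep = "_") {
  format <- match.arg(format)
  if (format == "long") {
    idx <- expand.grid(subject = data$subjects, item = panelItems(data),
                       wave = data$waves, stringsAsFactors = FALSE)
    idx$rating <- data$ratings[cbind(match(idx$subject, data$subjects),
                                     match(idx$item, panelItems(data)),
                                     match(idx$wave, data$waves))]
    if (!is.null(data$group)) idx$group <- data$group[idx$subject]
    if (!is.null(data$arm)) idx$arm <- data$arm[idx$subject]
    idx <- idx[!is.na(idx$rating), , drop = FALSE]
    write.csv(idx, path, row.names = FALSE)
  } else {
    out <- data.frame(subject = data$subjects, stringsAsFactors = FALSE)
    if (!is.null(data$group)) out$group <- unname(data$group)
    if (!is.null(data$arm)) out$arm <- unname(data$arm)
    for (w in data$waves)
      for (it in panelItems(data))
        out[[paste(it, w, sep = sep)]] <- data$ratings[, it, w]
    write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
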