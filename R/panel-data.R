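#' Construct a panel of ordinal symptom ratings
#'
#' The universal input object: a subject x item x wave array of integer
#' ratings on the 1-7 scale, with optional outcome-group labels and a
#' binary treatment arm.
#'
#' @param ratings 3-d array (subject x item x wave) of integer ratings in
#'   1..7; `NA` marks missing cells. Dimnames, when present, provide
#'   subject ids, item codes and wave labels.
#' @param waves Ordered wave labels; defaults to the third dimnames or
#'   `T0, T1, ...`.
#' @param group Optional per-subject outcome label (e.g. `"remitter"`).
#' @param arm Optional per-subject binary treatment code (0/1).
#' @param items An [itemSet()]; defaults to an unannotated set built from
#'   the item dimension.
#' @param subjects Optional subject ids; defaults to the first dimnames.
#' @return An object of class `panelData`.
#' @export
panelData <- function(ratings, waves = NULL, group = NULL, arm = NULL,
                      items = NULL, subjects = NULL) {
  stopifnot(is.array(ratings), length(dim(ratings)) == 3)
  d <- dim(ratings)
  subjects <- as.character(subjects %||% dimnames(ratings)[[1]] %||%
                             paste0("S", seq_len(d[1])))
  codes <- dimnames(ratings)[[2]] %||% paste0("V", seq_len(d[2]))
  waves <- as.character(waves %||% dimnames(ratings)[[3]] %||%
                          paste0("T", seq_len(d[3]) - 1))
  if (length(subjects) != d[1] || length(waves) != d[3])
    stopf("dimension/label mismatch")
  if (anyDuplicated(waves)) stopf("wave labels must be unique")
  storage.mode(ratings) <- "double"
  bad <- which(!is.na(ratings) &
                 (!isWholeNumber(ratings) | ratings < 1 | ratings > 7),
               arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1, ]
    stopf("rating out of range 1..7: subject %s, item %s, wave %s (value %s)%s",
          subjects[b[1]], codes[b[2]], waves[b[3]],
          format(ratings[b[1], b[2], b[3]]),
          if (nrow(bad) > 1) sprintf(" and %d more", nrow(bad) - 1) else "")
  }
  dimnames(ratings) <- list(subjects, codes, waves)
  if (is.null(items)) items <- itemSet(codes,
                                       remissionItems = intersect(andreasenItems(), codes))
  if (!setequal(items$codes, codes) || !all(items$codes == codes))
    stopf("item set codes must match the item dimension (in order)")
  if (!is.null(group)) {
    stopifnot(length(group) == d[1])
    group <- as.character(group)
    names(group) <- subjects
  }
  if (!is.null(arm)) {
    stopifnot(length(arm) == d[1], all(arm %in% c(0, 1, NA)))
    arm <- as.integer(arm)
    names(arm) <- subjects
  }
  structure(list(ratings = ratings, waves = waves, group = group,
                 arm = arm, items = items, subjects = subjects),
            class = "panelData")
}

#' @export
print.panelData <- function(x, ...) {
  d <- dim(x$ratings)
  cat(sprintf("panelData: %d subjects x %d items x %d waves (%s)\n",
              d[1], d[2], d[3], paste(x$waves, collapse = ", ")))
  if (!is.null(x$group)) {
    tb <- table(x$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  if (!is.null(x$arm)) {
    tb <- table(x$arm)
    cat("  arms:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  nmiss <- sum(is.na(x$ratings))
  if (nmiss) cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
                         100 * nmiss / length(x$ratings)))
  invisible(x)
}

#' Items, waves and subjects of a panel
#' @param data A `panelData`.
#' @return Character vectors.
#' @export
panelItems <- function(data) data$items$codes

#' @rdname panelItems
#' @export
panelWaves <- function(data) data$waves

#' @rdname panelItems
#' @export
panelSubjects <- function(data) data$subjects

checkWave <- function(data, wave) {
  if (!wave %in% data$waves) stopf("unknown wave '%s'", wave)
  wave
}

#' Extract the subject x item rating matrix at one wave
#' @param data A `panelData`.
#' @param wave Wave label.
#' @return Numeric matrix (subjects x items) with `NA` for missing.
#' @export
waveMatrix <- function(data, wave) {
  checkWave(data, wave)
  m <- data$ratings[, , wave, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  dimnames(m) <- dimnames(data$ratings)[1:2]
  m
}

#' Restrict and reorder a panel to an item subset
#'
#' @param data A `panelData`.
#' @param items An [itemSet()] or character vector of item codes, all of
#'   which must be present in `data`.
#' @return A `panelData` over `items`, metadata preserved.
#' @export
selectItems <- function(data, items) {
  codes <- if (inherits(items, "itemSet")) items$codes else as.character(items)
  unknown <- setdiff(codes, panelItems(data))
  if (length(unknown))
    stopf("unknown item %s", paste(unknown, collapse = ", "))
  set <- if (inherits(items, "itemSet")) items else
    itemSet(codes,
            domains = data$items$domains[codes],
            remissionItems = intersect(data$items$remissionItems, codes))
  panelData(data$ratings[, codes, , drop = FALSE], waves = data$waves,
            group = data$group, arm = data$arm, items = set,
            subjects = data$subjects)
}

#' Keep a subset of subjects (internal-facing, exported for resampling)
#' @param data A `panelData`.
#' @param idx Subject indices or ids.
#' @return A `panelData`.
#' @export
subsetSubjects <- function(data, idx) {
  if (is.character(idx)) idx <- match(idx, data$subjects)
  r <- data$ratings[idx, , , drop = FALSE]
  # resampling with replacement duplicates ids; disambiguate
  ids <- make.unique(data$subjects[idx])
  dimnames(r)[[1]] <- ids
  panelData(r, waves = data$waves,
            group = if (!is.null(data$group)) unname(data$group[idx]),
            arm = if (!is.null(data$arm)) unname(data$arm[idx]),
            items = data$items, subjects = ids)
}

#' Andreasen-style remission classification at a wave
#'
#' A subject is classified as a remitter at `wave` when every remission
#' item of the panel's item set is rated at most 3 there.
#'
#' @param data A `panelData` whose item set has non-empty `remissionItems`.
#' @param wave Wave label at which to classify.
#' @param missing Policy when a remission item is missing for a subject:
#'   `"error"` (default) or `"na"` (classify that subject as `NA`).
#' @return Named logical vector over subjects.
#' @export
classifyRemission <- function(data, wave, missing = c("error", "na")) {
  missing <- match.arg(missing)
  checkWave(data, wave)
  ritems <- data$items$remissionItems
  if (!length(ritems)) stopf("item set has no remission items")
  m <- waveMatrix(data, wave)[, ritems, drop = FALSE]
  anyMiss <- apply(m, 1, anyNA)
  if (any(anyMiss) && missing == "error")
    stopf("missing remission item rating(s) at wave %s for subject(s): %s",
          wave, paste(head(names(which(anyMiss)), 5), collapse = ", "))
  out <- apply(m, 1, function(r) all(r <= 3))
  out[anyMiss] <- NA
  out
}

#' Total symptom score at a wave
#'
#' Sum of all item ratings of the panel's item set at one wave; any missing
#' item propagates `NA` for that subject.
#'
#' @param data A `panelData`.
#' @param wave Wave label.
#' @return Named numeric vector over subjects.
#' @export
totalScore <- function(data, wave) {
  checkWave(data, wave)
  rowSums(waveMatrix(data, wave))
}
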