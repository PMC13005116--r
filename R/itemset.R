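#' Define a rating-scale item set
#'
#' An item set names the ordinal items carried by a panel, their symptom
#' domain, and the sublist of items used for the symptomatic remission rule.
#'
#' @param codes Character vector of unique item identifiers (e.g. `"P1"`).
#' @param domains Optional named character vector mapping each code to a
#'   domain label; unnamed items get domain `"Unassigned"`.
#' @param remissionItems Items whose ratings define symptomatic remission;
#'   must be a subset of `codes`. Defaults to the Andreasen criterion items
#'   present in `codes`.
#' @return An object of class `itemSet`.
#' @seealso [panss21ItemSet()] for the shipped 21-item PANSS default.
#' @export
itemSet <- function(codes, domains = NULL,
                    remissionItems = intersect(andreasenItems(), codes)) {
  codes <- as.character(codes)
  if (anyDuplicated(codes))
    stopf("duplicate item codes: %s",
          paste(unique(codes[duplicated(codes)]), collapse = ", "))
  if (!all(remissionItems %in% codes))
    stopf("remission items not in item set: %s",
          paste(setdiff(remissionItems, codes), collapse = ", "))
  dom <- setNames(rep("Unassigned", length(codes)), codes)
  if (!is.null(domains)) {
    unknown <- setdiff(names(domains), codes)
    if (length(unknown))
      stopf("domain labels for unknown items: %s",
            paste(unknown, collapse = ", "))
    dom[names(domains)] <- domains
  }
  structure(list(codes = codes, domains = dom,
                 remissionItems = as.character(remissionItems)),
            class = "itemSet")
}

#' Andreasen remission items
#'
#' The eight PANSS items of the Andreasen symptomatic remission criterion:
#' a subject is in remission when every one of these is rated at most 3
#' ("mild") at the assessment.
#' @return Character vector of item codes.
#' @export
andreasenItems <- function() c("P1", "P2", "P3", "N1", "N4", "N6", "G5", "G9")

#' The 21-item stable PANSS subset
#'
#' Default item set used throughout the package: the 21 PANSS items retained
#' after dropping nine items with unstable community assignment in network
#' analyses, grouped into four symptom domains (Positive,
#' Cognitive/Disorganized, Excited/Aggressive, Negative). The membership is
#' a package default, not a fixed constant: pass your own [itemSet()] (or a
#' JSON file via [readItemSet()]) to override.
#'
#' @return An `itemSet` with 21 items.
#' @export
panss21ItemSet <- function() {
  domains <- c(
    P1 = "Positive", P3 = "Positive", P6 = "Positive", G9 = "Positive",
    P2 = "Cognitive/Disorganized", N5 = "Cognitive/Disorganized",
    N7 = "Cognitive/Disorganized", G5 = "Cognitive/Disorganized",
    G7 = "Cognitive/Disorganized", G10 = "Cognitive/Disorganized",
    G13 = "Cognitive/Disorganized", G15 = "Cognitive/Disorganized",
    P7 = "Excited/Aggressive", G8 = "Excited/Aggressive",
    G14 = "Excited/Aggressive",
    N1 = "Negative", N2 = "Negative", N3 = "Negative",
    N4 = "Negative", N6 = "Negative", G16 = "Negative")
  codes <- c("P1", "P2", "P3", "P6", "P7",
             "N1", "N2", "N3", "N4", "N5", "N6", "N7",
             "G5", "G7", "G8", "G9", "G10", "G13", "G14", "G15", "G16")
  itemSet(codes, domains)
}

#' @export
print.itemSet <- function(x, ...) {
  cat(sprintf("Item set: %d items\n", length(x$codes)))
  for (d in unique(x$domains))
    cat(sprintf("  %s: %s\n", d,
                paste(x$codes[x$domains[x$codes] == d], collapse = ", ")))
  cat(sprintf("  Remission items: %s\n",
              paste(x$remissionItems, collapse = ", ")))
  invisible(x)
}

#' Read / write an item set as JSON
#'
#' @param path File path.
#' @return `readItemSet` returns an `itemSet`; `writeItemSet` returns
#'   `path`, invisibly.
#' @examples
#' readItemSet(system.file("extdata", "panss21-items.json",
#'                         package = "panelnet"))
#' @export
readItemSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  itemSet(obj$codes, domains = unlist(obj$domains),
          remissionItems = obj$remissionItems %||% character())
}

#' @param x An `itemSet`.
#' @rdname readItemSet
#' @export
writeItemSet <- function(x, path) {
  stopifnot(inherits(x, "itemSet"))
  jsonlite::write_json(
    list(codes = x$codes, domains = as.list(x$domains),
         remissionItems = x$remissionItems),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
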