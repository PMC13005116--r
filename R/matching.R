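#' Greedy nearest-neighbour matching of two outcome groups
#'
#' Builds equal-sized subgroups for a sensitivity analysis by 1:1 greedy
#' nearest-neighbour matching without replacement on a per-subject
#' covariate (typically baseline severity, e.g. [totalScore()]). Every
#' subject of the smaller group is matched to the unmatched subject of the
#' larger group with the closest covariate value.
#'
#' The procedure is deterministic: the smaller group is processed in
#' descending covariate order (ties broken by subject id), and distance
#' ties are broken by subject id.
#'
#' @param data A [panelData()] with exactly two (non-`NA`) group labels.
#' @param covariate Named numeric vector over subjects (names = subject
#'   ids), finite for all grouped subjects.
#' @param caliper Optional maximum |covariate difference| allowed for a
#'   match; pairs beyond it are dropped (making groups smaller but still
#'   equal-sized).
#' @return A `matchResult`: list with `pairs` (data.frame: `smaller`,
#'   `larger`, `distance`), `keptIds` (list per group label), `covariate`
#'   name and `caliper`.
#' @export
matchGroups <- function(data, covariate, caliper = NULL) {
  if (is.null(data$group)) stopf("panel has no group labels")
  grp <- data$group[!is.na(data$group)]
  labs <- sort(unique(grp))
  if (length(labs) != 2)
    stopf("matching requires exactly 2 groups, found %d", length(labs))
  ids <- split(names(grp), grp)
  if (!length(ids[[1]]) || !length(ids[[2]])) stopf("empty group")
  if (is.null(names(covariate))) names(covariate) <- data$subjects
  cv <- covariate[names(grp)]
  if (any(!is.finite(cv)))
    stopf("covariate not finite for subject(s): %s",
          paste(head(names(cv)[!is.finite(cv)], 5), collapse = ", "))
  smallLab <- labs[which.min(lengths(ids))]
  largeLab <- setdiff(labs, smallLab)
  small <- ids[[smallLab]]
  large <- ids[[largeLab]]
  ord <- order(-cv[small], small)
  small <- small[ord]
  pairs <- data.frame(smaller = character(), larger = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  pool <- large
  for (s in small) {
    d <- abs(cv[pool] - cv[s])
    pick <- pool[order(d, pool)][1]
    dist <- abs(cv[pick] - cv[s])
    if (!is.null(caliper) && dist > caliper) next
    pairs <- rbind(pairs, data.frame(smaller = s, larger = pick,
                                     distance = unname(dist),
                                     stringsAsFactors = FALSE))
    pool <- setdiff(pool, pick)
  }
  kept <- list(pairs$smaller, pairs$larger)
  names(kept) <- c(smallLab, largeLab)
  structure(list(pairs = pairs, keptIds = kept,
                 covariate = deparse(substitute(covariate)),
                 caliper = caliper),
            class = "matchResult")
}

#' @export
print.matchResult <- function(x, ...) {
  cat(sprintf("matchResult: %d matched pairs (%s)\n", nrow(x$pairs),
              paste(names(x$keptIds), collapse = " vs ")))
  cat(sprintf("  mean |distance| = %.3f, max = %.3f\n",
              mean(x$pairs$distance), max(x$pairs$distance)))
  invisible(x)
}

#' Restrict a panel to the matched subjects
#' @param data A [panelData()].
#' @param match A `matchResult` from [matchGroups()].
#' @return A `panelData` containing only matched subjects.
#' @export
matchedSubset <- function(data, match) {
  subsetSubjects(data, unlist(match$keptIds, use.names = FALSE))
}
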