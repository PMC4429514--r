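# Dice-based evaluation of segmentations.

#' Dice similarity coefficient
#'
#' \deqn{DSC(S_1, S_2) = \frac{2\,N(S_1 \cap S_2)}{N(S_1) + N(S_2)},}
#' where \eqn{N} counts pixels (voxels). 1 means perfect overlap, 0 none.
#' Two empty masks are defined to agree perfectly (Dice 1), with a message;
#' an empty vs a non-empty mask gives 0.
#'
#' @param s1,s2 Logical (or 0/1 numeric) matrices of the same shape.
#' @return Scalar in \eqn{[0, 1]}.
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:3] <- TRUE
#' b <- matrix(FALSE, 4, 4); b[1:2, 2:3] <- TRUE
#' dice(a, b)
#' @export
dice <- function(s1, s2) {
  if (!identical(dim(s1), dim(s2)))
    stop("masks must have the same shape")
  s1 <- s1 != 0; s2 <- s2 != 0
  n1 <- sum(s1); n2 <- sum(s2)
  if (n1 + n2 == 0L) {
    message("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(s1 & s2) / (n1 + n2)
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.permutations(v[-i]), function(p) c(v[i], p)))
  out
}

#' Per-label Dice between two label maps
#'
#' Computes the binary Dice of every label. Because a solver's phase labels
#' carry no canonical order, \code{matching = "best"} searches all label
#' permutations for the one maximizing the mean Dice before reporting
#' (suitable for phantom evaluation); \code{"fixed"} compares labels as
#' given (suitable when label semantics are shared).
#'
#' @param labels1,labels2 Integer label matrices of the same shape.
#' @param matching \code{"best"} (permutation search) or \code{"fixed"}.
#' @return List with \code{perLabel} (named numeric vector, names =
#'   reference labels of \code{labels1}), \code{mean}, and (for
#'   \code{"best"}) \code{permutation}, the relabeling applied to
#'   \code{labels2}.
#' @export
multiLabelDice <- function(labels1, labels2, matching = c("best", "fixed")) {
  matching <- match.arg(matching)
  if (!identical(dim(labels1), dim(labels2)))
    stop("label maps must have the same shape")
  labs <- sort(unique(c(as.vector(labels1), as.vector(labels2))))
  if (length(labs) > 6L && matching == "best")
    stop("best-permutation matching supports at most 6 labels")
  perLabelFor <- function(map2) {
    vapply(labs, function(l) suppressMessages(dice(labels1 == l, map2 == l)),
           numeric(1))
  }
  if (matching == "fixed") {
    pl <- setNames(perLabelFor(labels2), labs)
    return(list(perLabel = pl, mean = mean(pl)))
  }
  best <- NULL; bestPerm <- NULL
  for (p in .permutations(labs)) {
    map2 <- labels2
    for (i in seq_along(labs)) map2[labels2 == p[i]] <- labs[i]
    pl <- perLabelFor(map2)
    if (is.null(best) || mean(pl) > mean(best)) { best <- pl; bestPerm <- p }
  }
  list(perLabel = setNames(best, labs), mean = mean(best),
       permutation = setNames(bestPerm, labs))
}

#' Pairwise-Dice robustness summary
#'
#' Summarizes how similar a set of segmentations of one image are (e.g. runs
#' from different initial contours): the minimum and mean Dice over all
#' unordered mask pairs. High values mean the result barely depends on the
#' initialization.
#'
#' @param masks List of at least two logical matrices of one shape.
#' @return Named numeric vector \code{c(min = ..., mean = ...)}.
#' @export
robustnessSummary <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("need at least 2 masks")
  pairs <- utils::combn(length(masks), 2L)
  d <- apply(pairs, 2L, function(ij)
    suppressMessages(dice(masks[[ij[1]]], masks[[ij[2]]])))
  c(min = min(d), mean = mean(d))
}
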