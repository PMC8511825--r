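#' @name dice-metrics
#' @title Dice similarity metrics
#' @description
#' The Dice similarity coefficient between the predicted pixel set X and the
#' reference (manually delineated) pixel set Y of a structure is
#' `Dice(X, Y) = 2 |X intersect Y| / (|X| + |Y|)`, ranging over `[0, 1]`.
#' Besides the per-structure Dice, a *global* Dice pools the pixel counts of
#' all foreground structures (a micro average), so cross-class confusions are
#' penalized.  The `0/0` case (structure absent from both masks) is reported
#' as `NA` and excluded from aggregation, with the exclusion counted.
NULL

check_same_shape <- function(pred, ref) {
  if (!identical(dim(as.matrix(pred)), dim(as.matrix(ref)))) {
    stop_dfcn("dice: pred and ref must have identical shape")
  }
}

dice_counts <- function(pred, ref, class_id) {
  px <- pred == class_id
  ry <- ref == class_id
  c(inter = sum(px & ry), nx = sum(px), ny = sum(ry))
}

#' Per-structure Dice coefficient
#'
#' @param pred,ref integer label masks of identical shape (matrices or
#'   arrays; 0 = background)
#' @param class_id structure class id
#' @return Dice in `[0, 1]`, or `NA` if the class is absent from both masks
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2)
#' b <- matrix(c(1, 0, 1, 0), 2)
#' dice(a, b, 1)
#' @export
dice <- function(pred, ref, class_id) {
  if (!identical(dim(pred), dim(ref))) check_same_shape(pred, ref)
  n <- dice_counts(pred, ref, class_id)
  den <- n[["nx"]] + n[["ny"]]
  if (den == 0) return(NA_real_)
  2 * n[["inter"]] / den
}

#' Global (micro-averaged) Dice over foreground structures
#'
#' Pools intersection and size counts over all foreground classes:
#' `2 * sum_c |X_c ^ Y_c| / sum_c (|X_c| + |Y_c|)`.  Equals the per-class
#' Dice when a single class is given.
#'
#' @inheritParams dice
#' @param foreground_classes vector of structure class ids (non-empty)
#' @return Dice in `[0, 1]`, or `NA` if every class is absent from both masks
#' @export
global_dice <- function(pred, ref, foreground_classes) {
  if (length(foreground_classes) == 0) {
    stop_dfcn("global_dice: foreground_classes must be non-empty")
  }
  if (!identical(dim(pred), dim(ref))) check_same_shape(pred, ref)
  cnt <- vapply(foreground_classes, function(c) dice_counts(pred, ref, c),
                numeric(3))
  den <- sum(cnt["nx", ]) + sum(cnt["ny", ])
  if (den == 0) return(NA_real_)
  2 * sum(cnt["inter", ]) / den
}

#' Dice report for one prediction/reference pair
#'
#' @inheritParams global_dice
#' @param scope label recorded in the report (`"slice"`, `"case"` or
#'   `"cohort"`)
#' @return a `dice_report`: list with `per_class` (named numeric, `NA` for
#'   0/0 classes), `global`, `scope`, and `n_excluded`
#' @export
dice_report <- function(pred, ref, foreground_classes, scope = "slice") {
  per_class <- vapply(foreground_classes,
                      function(c) dice(pred, ref, c), numeric(1))
  names(per_class) <- as.character(foreground_classes)
  structure(list(per_class = per_class,
                 global = global_dice(pred, ref, foreground_classes),
                 scope = scope,
                 n_excluded = sum(is.na(per_class))),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("<dice_report> scope %s, global %s\n", x$scope,
              format(round(x$global, 4))))
  print(round(x$per_class, 4))
  if (x$n_excluded > 0) {
    cat(sprintf("  (%d class(es) undefined: absent from both masks)\n",
                x$n_excluded))
  }
  invisible(x)
}

#' Aggregate per-case Dice reports into a cohort report
#'
#' Per-class cohort values are means over the cases where the class is
#' defined; the cohort global is the mean of the per-case globals.
#' Undefined (`NA`) entries are excluded, and the number of exclusions per
#' class is reported.
#'
#' @param reports non-empty list of `dice_report` objects
#' @return a `dice_report` with scope `"cohort"` and an extra
#'   `excluded_per_class` count vector
#' @export
aggregate_reports <- function(reports) {
  if (length(reports) == 0) stop_dfcn("aggregate_reports: empty report list")
  stopifnot(all(vapply(reports, inherits, logical(1), "dice_report")))
  pc <- do.call(rbind, lapply(reports, function(r) r$per_class))
  per_class <- colMeans(pc, na.rm = TRUE)
  per_class[is.nan(per_class)] <- NA_real_
  globals <- vapply(reports, function(r) r$global, numeric(1))
  excl <- colSums(is.na(pc))
  structure(list(per_class = per_class,
                 global = mean(globals, na.rm = TRUE),
                 scope = "cohort",
                 n_excluded = sum(excl),
                 excluded_per_class = excl,
                 n_cases = length(reports)),
            class = "dice_report")
}
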