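#' Evaluate detected homology groups against a ground-truth partition
#'
#' Best-overlap protocol: for each true homology group (THG) find the
#' detected group (DHG) with the largest intersection (ties: the smaller
#' DHG, then the lower index); count `tp = |THG intersect DHG|`,
#' `fn = |THG \ DHG|`, `fp = |DHG \ THG|`; sum tp/fp/fn over all THGs and
#' report `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)` and the F-score,
#' their harmonic mean. Each THG is matched independently, so one DHG may
#' be claimed by several THGs (its spurious members then count as fp for
#' each). A THG overlapping no DHG matches the empty set (tp = 0,
#' fn = |THG|, fp = 0).
#'
#' @param true_groups List of non-empty disjoint id sets (ground truth).
#' @param detected_groups List of non-empty disjoint id sets.
#' @return An `EvaluationReport`: list with `TP`, `FP`, `FN`, `recall`,
#'   `precision`, `f_score` (proportions in \[0, 1\]).
#' @export
#' @examples
#' evaluate_groups(list(c("a", "b", "c")), list(c("a", "b"), "c"))
evaluate_groups <- function(true_groups, detected_groups) {
  if (length(true_groups) == 0) stop("true_groups must be non-empty")
  .check_disjoint(true_groups, "true_groups")
  .check_disjoint(detected_groups, "detected_groups")
  TP <- FP <- FN <- 0L
  for (thg in true_groups) {
    best_ov <- 0L; best_size <- Inf; best_fp <- 0L
    for (dhg in detected_groups) {
      ov <- length(intersect(thg, dhg))
      if (ov > best_ov || (ov == best_ov && ov > 0 &&
                           length(dhg) < best_size)) {
        best_ov <- ov
        best_size <- length(dhg)
        best_fp <- length(dhg) - ov
      }
    }
    TP <- TP + best_ov
    FN <- FN + length(thg) - best_ov
    FP <- FP + if (best_ov > 0) best_fp else 0L
  }
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f_score <- if (!is.na(recall) && !is.na(precision) &&
                 recall + precision > 0)
    2 * recall * precision / (recall + precision) else NA_real_
  structure(list(TP = TP, FP = FP, FN = FN, recall = recall,
                 precision = precision, f_score = f_score),
            class = "EvaluationReport")
}

.check_disjoint <- function(groups, what) {
  if (any(lengths(groups) == 0)) stop(what, " contains an empty group")
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids)) {
    stop(what, " groups are not disjoint: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  invisible(TRUE)
}

#' @exportS3Method base::print
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d\n", x$TP, x$FP, x$FN))
  cat(sprintf("recall=%.1f%% precision=%.1f%% F-score=%.1f%%\n",
              100 * x$recall, 100 * x$precision, 100 * x$f_score))
  invisible(x)
}

#' Build a ground-truth partition from an id-mapping source
#'
#' Accepts either a path to a two-column TSV (`protein_id<TAB>group_id`)
#' or, with `convention = "isoform_suffix"`, derives group keys from the
#' protein ids themselves by stripping a trailing `.N` isoform suffix
#' (e.g. `AT3G54340.1` and `AT3G54340.2` fall into one group keyed
#' `AT3G54340`) — the usual recipe when truth is encoded in gene
#' identifiers or locus tags rather than a separate mapping.
#'
#' @param source Path to a mapping TSV, or a character vector of protein
#'   ids when a convention is used.
#' @param convention `"mapping"` (default, TSV file) or
#'   `"isoform_suffix"`.
#' @return List of disjoint id sets.
#' @export
load_truth <- function(source, convention = c("mapping", "isoform_suffix")) {
  convention <- match.arg(convention)
  if (convention == "mapping") {
    groups <- read_groups(source)
    if (length(groups) == 0) stop("empty truth mapping: ", source)
    return(groups)
  }
  ids <- source
  if (length(ids) == 0) stop("no protein ids supplied")
  key <- sub("\\.[0-9]+$", "", ids)
  unname(lapply(split(ids, factor(key, levels = unique(key))),
                as.character))
}
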