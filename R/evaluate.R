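#' Classify one sequence pair with the margin rule
#'
#' A pair is `"similar"` iff the minimum component-wise embedding distance
#' satisfies `z <= delta` (the boundary `z == delta` counts as similar).
#'
#' @param model a trained (or untrained) `lsme_model`.
#' @param s,t sequences of length `model$config$N`.
#' @param delta margin; defaults to the model's configured margin.
#' @return `"similar"` or `"dissimilar"`.
#' @export
classify_pair <- function(model, s, t, delta = model$config$delta) {
  E <- lsme_embed(model, c(s, t))
  if (z_distance(E[, , 1], E[, , 2]) <= delta) "similar" else "dissimilar"
}

#' Per-distance and overall accuracy of a model
#'
#' A labelled pair is correct when `d <= d1` and `z <= delta`, or `d >= d2`
#' and `z > delta`. Overall accuracy aggregates correct pairs over all
#' labelled distances; distances in the open gap `(d1, d2)` are reported
#' descriptively as the fraction classified similar and excluded from the
#' aggregate (the correctness rule does not apply to them). Each fraction
#' carries a binomial 95% Wilson interval.
#'
#' @param model an `lsme_model`.
#' @param data a labelled `pair_dataset`; its stored distances are trusted
#'   because the simulator re-verifies them against the DP oracle.
#' @param delta decision margin; defaults to the model's margin.
#' @return an `lsme_accuracy` report: tibble `per_distance`
#'   (`d`, `n`, `value`, `lo`, `hi`, `type`), `overall`, `overall_n`.
#' @export
evaluate_model <- function(model, data, delta = model$config$delta) {
  stopifnot(inherits(model, "lsme_model"), inherits(data, "pair_dataset"))
  if (all(is.na(data$pairs$y))) {
    stop("dataset is unlabelled; apply label_pairs() first", call. = FALSE)
  }
  pairs <- data$pairs
  z <- z_distance_batch(lsme_embed(model, pairs$s), lsme_embed(model, pairs$t))
  similar <- z <= delta
  correct <- ifelse(is.na(pairs$y), NA,
                    (pairs$y == 1L & similar) | (pairs$y == -1L & !similar))
  ds <- sort(unique(pairs$d))
  per <- lapply(ds, function(d) {
    sel <- pairs$d == d
    n <- sum(sel)
    gap <- all(is.na(pairs$y[sel]))
    x <- if (gap) sum(similar[sel]) else sum(correct[sel])
    ci <- wilson_ci(x, n)
    tibble::tibble(
      d = d, n = n, value = x / n, lo = ci[1], hi = ci[2],
      type = if (gap) "gap" else if (all(pairs$y[sel] == 1L)) "similar" else "dissimilar")
  })
  labelled <- !is.na(correct)
  structure(
    list(per_distance = do.call(rbind, per),
         overall = sum(correct[labelled]) / sum(labelled),
         overall_n = sum(labelled),
         delta = delta, d1 = data$d1, d2 = data$d2,
         config = model$config),
    class = "lsme_accuracy")
}

#' @export
print.lsme_accuracy <- function(x, ...) {
  cat(sprintf("<lsme_accuracy> overall %.4f on %d labelled pairs (delta = %g)\n",
              x$overall, x$overall_n, x$delta))
  print(x$per_distance)
  invisible(x)
}

#' Sweep one hyperparameter, retraining per value
#'
#' Trains one model per value of `m`, `delta` or `k` with every other setting
#' and seed held fixed, evaluates each on the same test set, and returns the
#' reports in input order. If `out_tsv` is given, a `(value, overall)` table
#' is written; on a training failure the rows finished so far are written to
#' `<out_tsv>.partial` before the error propagates.
#'
#' @param param one of `"m"`, `"delta"`, `"k"`.
#' @param values values to sweep (non-empty).
#' @param base_config an [lsme_config()].
#' @param train_data labelled training `pair_dataset`.
#' @param test_data labelled test `pair_dataset`.
#' @param out_tsv optional output path.
#' @return list of `lsme_accuracy` reports.
#' @export
lsme_sweep <- function(param, values, base_config, train_data, test_data,
                       out_tsv = NULL) {
  param <- match.arg(param, c("m", "delta", "k"))
  stopifnot(length(values) >= 1, inherits(base_config, "lsme_config"))
  reports <- vector("list", length(values))
  rows <- list()
  for (i in seq_along(values)) {
    args <- unclass(base_config)
    args[[param]] <- values[[i]]
    cfg <- do.call(lsme_config, args)
    reports[[i]] <- tryCatch({
      model <- lsme_train(cfg, train_data)
      evaluate_model(model, test_data, delta = cfg$delta)
    }, error = function(e) {
      if (!is.null(out_tsv) && length(rows)) {
        write.table(do.call(rbind, rows), paste0(out_tsv, ".partial"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      stop(sprintf("sweep aborted at %s = %s: %s", param,
                   format(values[[i]]), conditionMessage(e)), call. = FALSE)
    })
    rows[[i]] <- data.frame(value = values[[i]], overall = reports[[i]]$overall)
  }
  if (!is.null(out_tsv)) {
    write.table(do.call(rbind, rows), out_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  reports
}
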