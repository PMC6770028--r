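# Activity handling: IC50 -> pIC50 conversion with left-censoring of
# inactives, and the stratified training/test split.

#' Convert IC50 (nM) to pIC50 with left-censoring
#'
#' pIC50 = 9 - log10(IC50/nM). Compounds whose IC50 exceeds the assay
#' quantitation limit (default 100,000 nM), or that are recorded only as
#' "> X", are assigned the fixed censor value (default 5.0) and flagged,
#' which keeps inactives in the dataset.
#'
#' @param ic50 numeric vector of IC50 values in nM, or character vector where
#'   above-limit entries are written `">100000"`.
#' @param censor_limit IC50 (nM) above which activities are censored.
#' @param censor_value pIC50 assigned to censored records.
#' @return data.frame with columns `pic50` and `censored`.
#' @export
#' @examples
#' ic50_to_pic50(c(1, 100, 150000))
ic50_to_pic50 <- function(ic50, censor_limit = 1e5, censor_value = 5.0) {
  above <- rep(FALSE, length(ic50))
  if (is.character(ic50) || is.factor(ic50)) {
    ic50 <- trimws(as.character(ic50))
    above <- startsWith(ic50, ">")
    num <- suppressWarnings(as.numeric(sub("^>", "", ic50)))
  } else {
    num <- as.numeric(ic50)
  }
  bad <- which(!above & (!is.finite(num) | num <= 0))
  if (length(bad)) {
    stopf("invalid IC50 at record(s) %s: must be positive or '> X'",
          paste(bad, collapse = ", "))
  }
  censored <- above | (is.finite(num) & num > censor_limit)
  pic50 <- ifelse(censored, censor_value, 9 - log10(num))
  data.frame(pic50 = pic50, censored = censored)
}

#' @rdname ic50_to_pic50
#' @param pic50 numeric vector of non-censored pIC50 values.
#' @export
pic50_to_ic50 <- function(pic50) 10^(9 - pic50)

#' Read an activity table
#'
#' CSV with columns `compound_id`, `ic50_nM` (numeric or `">100000"`) and
#' optionally `family`; returns the table augmented with `pic50`/`censored`.
#'
#' @param path CSV file path.
#' @inheritParams ic50_to_pic50
#' @return data.frame of activity records.
#' @export
read_activities <- function(path, censor_limit = 1e5, censor_value = 5.0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "ic50_nM") %in% names(df))) {
    stopf("%s must have columns compound_id, ic50_nM", path)
  }
  conv <- ic50_to_pic50(df$ic50_nM, censor_limit, censor_value)
  df$pic50 <- conv$pic50
  df$censored <- conv$censored
  if (is.null(df$family)) df$family <- "all"
  df
}

#' Stratified training/test split
#'
#' Splits activity records so that the test set holds `fraction` of the
#' training-set size (e.g. 176 records at fraction 0.10 give 160 training and
#' 16 test compounds). Sampling is stratified by chemotype family crossed
#' with activity quartile; candidate draws are repeated (deterministically,
#' under `seed`) until (i) both sets cover the activity range [5, 9] whenever
#' the input does, and (ii) every declared family is represented in both
#' sets.
#'
#' @param records data.frame with columns `compound_id`, `pic50` and
#'   optionally `family`.
#' @param fraction test-set size as a fraction of the training-set size.
#' @param seed integer seed; the split is bit-reproducible given it.
#' @return A `split_dataset`: `training_ids`, `test_ids`, `fraction`.
#' @export
split_train_test <- function(records, fraction = 0.10, seed = 1L) {
  records <- as.data.frame(records)
  stopifnot(all(c("compound_id", "pic50") %in% names(records)))
  n <- nrow(records)
  if (n < 20L) stopf("need at least 20 records to split, got %d", n)
  span <- diff(range(records$pic50))
  if (span < 2) stopf("activity span %.2f log units < 2: split criteria unsatisfiable", span)
  fam <- as.character(records$family %||% rep("all", n))
  ids <- as.character(records$compound_id)
  if (fraction == 0) {
    return(structure(list(training_ids = ids, test_ids = character(0),
                          fraction = fraction), class = "split_dataset"))
  }
  stopifnot(fraction > 0, fraction < 1)
  # |test| = round(fraction * |train|) with train + test = n
  n_test <- round(fraction * n / (1 + fraction))
  for (adj in c(0L, -1L, 1L)) {
    if (n_test + adj >= 1L && (n_test + adj) == round(fraction * (n - n_test - adj))) {
      n_test <- n_test + adj; break
    }
  }
  qrt <- cut(rank(records$pic50, ties.method = "first"),
             breaks = 4, labels = FALSE)
  strata <- interaction(fam, qrt, drop = TRUE)
  covers <- function(p) min(p) <= 5 + 1e-9 && max(p) >= 9 - 1e-9
  need_span <- covers(records$pic50)
  with_seed(seed, {
    for (try in 1:500) {
      # proportional allocation over strata, largest-remainder rounding
      tab <- table(strata)
      quota <- n_test * as.numeric(tab) / n
      base <- floor(quota)
      rem <- n_test - sum(base)
      if (rem > 0) {
        # ties in the remainders are broken at random so every stratum can
        # receive a slot across retries
        extra <- order(quota - base + stats::runif(length(base), 0, 1e-6),
                       decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      base <- pmin(base, pmax(as.numeric(tab) - 1, 0))
      test_idx <- integer(0)
      for (s in seq_along(tab)) {
        if (base[s] == 0) next
        members <- which(strata == names(tab)[s])
        test_idx <- c(test_idx,
                      members[sample.int(length(members), base[s])])
      }
      # top up if capping left the quota short
      while (length(test_idx) < n_test) {
        pool <- setdiff(seq_len(n), test_idx)
        test_idx <- c(test_idx, pool[sample.int(length(pool), 1)])
      }
      train_idx <- setdiff(seq_len(n), test_idx)
      ok_fam <- all(unique(fam) %in% fam[train_idx]) &&
        all(unique(fam) %in% fam[test_idx])
      ok_span <- !need_span ||
        (covers(records$pic50[train_idx]) && covers(records$pic50[test_idx]))
      if (ok_fam && ok_span) {
        return(structure(list(training_ids = ids[sort(train_idx)],
                              test_ids = ids[sort(test_idx)],
                              fraction = fraction),
                         class = "split_dataset"))
      }
    }
  })
  stopf("no split satisfying the span/family criteria found in 500 draws")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("<split_dataset> %d training / %d test (fraction %.2f)\n",
              length(x$training_ids), length(x$test_ids), x$fraction))
  invisible(x)
}

#' Annotate an activity table with its split
#'
#' @param records activity data.frame.
#' @param split a [split_train_test] result.
#' @return `records` with a `split` column (`"train"`/`"test"`).
#' @export
apply_split <- function(records, split) {
  records$split <- ifelse(records$compound_id %in% split$test_ids,
                          "test", "train")
  records
}
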