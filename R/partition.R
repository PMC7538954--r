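#' Random train/test/validation partition
#'
#' The two partitioning schemes used when deriving reference models:
#' `"holdback33"` randomly withholds 33% of rows as the internal-validation
#' (test) set; `"pooled-50-25-25"` splits pooled rows 50/25/25 into
#' training, testing and validation; `"external"` reproduces the
#' derive-then-externally-validate design -- rows of the first cohort are
#' split 67/33 into train/test and every row of any other cohort becomes
#' validation (requires `cohort`).
#'
#' @param n Number of rows (>= 4).
#' @param scheme `"holdback33"`, `"pooled-50-25-25"` or `"external"`.
#' @param seed Integer seed; the partition is deterministic given it.
#' @param cohort For `"external"`: a length-`n` vector of cohort labels whose
#'   first (by order of appearance) level is the derivation cohort.
#' @return A factor of length `n` with levels `train`, `test`, `validation`
#'   and attributes `scheme` and `seed`.
#' @examples
#' table(make_partition(100, "holdback33", seed = 1))  # 67 train / 33 test
#' @export
make_partition <- function(n, scheme = c("holdback33", "pooled-50-25-25",
                                         "external"),
                           seed = 1L, cohort = NULL) {
  scheme <- match.arg(scheme)
  if (n < 4) abort("`n` must be >= 4")
  lev <- c("train", "test", "validation")
  lab <- with_seed(seed, {
    if (scheme == "holdback33") {
      n_test <- round(0.33 * n)
      sample(rep(c("test", "train"), c(n_test, n - n_test)))
    } else if (scheme == "pooled-50-25-25") {
      n_train <- round(0.50 * n)
      n_test <- round(0.25 * n)
      sample(rep(lev, c(n_train, n_test, n - n_train - n_test)))
    } else {
      if (is.null(cohort) || length(cohort) != n) {
        abort("scheme 'external' needs a length-n `cohort` vector")
      }
      derivation <- as.character(cohort[1])
      out <- rep("validation", n)
      idx <- which(cohort == derivation)
      n_test <- round(0.33 * length(idx))
      out[idx] <- sample(rep(c("test", "train"),
                             c(n_test, length(idx) - n_test)))
      out
    }
  })
  structure(factor(lab, levels = lev), scheme = scheme, seed = seed)
}

#' @rdname make_partition
#' @param data A cohort table; a `.set` column is appended.
#' @export
add_partition <- function(data, scheme = "holdback33", seed = 1L) {
  cohort <- if (scheme == "external") data[["cohort"]] else NULL
  data$.set <- make_partition(nrow(data), scheme, seed, cohort = cohort)
  data
}
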