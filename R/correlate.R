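# Holm-corrected Pearson correlation screening between subject-level
# prediction scores and behavioural/demographic covariates.

#' Holm step-down adjustment
#'
#' Step-down family-wise error control: sort the p-values ascending,
#' multiply the i-th by (m - i + 1), enforce monotonicity and cap at 1.
#' Input order is preserved in the output.
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  p.adjust(p, method = "holm")
}

#' Correlate prediction scores with metadata covariates
#'
#' Pearson correlation of the subject-level prediction score against each
#' covariate in the family, two-sided p-values, Holm correction applied
#' within the family. Missing values are handled pairwise; covariates
#' with fewer than 3 complete pairs or zero variance are reported as
#' skipped, with a missing correlation value.
#'
#' @param scores named numeric vector of subject scores (names are
#'   subject ids).
#' @param meta metadata data.frame with a `subject_id` column.
#' @param family character vector of covariate column names to screen.
#' @param alpha significance level on the adjusted p-values.
#' @return data.frame: `variable`, `r`, `n`, `p_raw`, `p_adj`,
#'   `significant`, `skipped`.
#' @export
correlate_covariates <- function(scores, meta, family, alpha = 0.05) {
  missing_cols <- setdiff(family, names(meta))
  if (length(missing_cols))
    stop("covariate(s) not in metadata: ",
         paste(missing_cols, collapse = ", "))
  sc <- scores[match(meta$subject_id, names(scores))]
  rows <- lapply(family, function(v) {
    x <- suppressWarnings(as.numeric(meta[[v]]))
    ok <- complete.cases(sc, x)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(sc[ok]) == 0)
      return(data.frame(variable = v, r = NA_real_, n = n,
                        p_raw = NA_real_, stringsAsFactors = FALSE))
    ct <- cor.test(sc[ok], x[ok], method = "pearson",
                   alternative = "two.sided")
    data.frame(variable = v, r = unname(ct$estimate), n = n,
               p_raw = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$skipped <- is.na(out$r)
  out$p_adj <- NA_real_
  out$p_adj[!out$skipped] <- holm_adjust(out$p_raw[!out$skipped])
  out$significant <- !out$skipped & out$p_adj < alpha
  out[, c("variable", "r", "n", "p_raw", "p_adj", "significant",
          "skipped")]
}
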