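# Pipeline configuration: every screening cutoff, significance level and
# stopping rule in one bundle so a single object reproduces the method.

#' Pipeline configuration with the standard cutoffs
#'
#' Bundles every tunable threshold of the item-development pipeline. The
#' defaults are the operating points of the published mood-CAT methodology:
#' item-remainder correlation 0.3, first principal component explaining at
#' least 20% of variance and at least 4 times the second, residual
#' correlations capped at 0.2, Loevinger scalability 0.3, item-fit and DIF
#' screens at alpha 0.01, and adaptive testing stopped at a standard error
#' of measurement of 0.32 (posterior reliability about 0.90) after at least
#' 3 items.
#'
#' @param item_remainder Item-remainder correlation cutoff (exclude below).
#' @param pca_first_proportion Minimum first-component variance proportion.
#' @param pca_ratio Minimum first/second component variance ratio.
#' @param residual_correlation Local-dependence residual cutoff (exclude
#'   pairs above).
#' @param scalability Loevinger `H_i` cutoff (exclude below).
#' @param item_fit_alpha Significance level of the S-X2 item-fit screen.
#' @param dif_alpha Significance level of the DIF screen.
#' @param sem Standard-error-of-measurement stopping threshold of the CAT.
#' @param min_items Minimum number of items administered per CAT session.
#' @param max_items Maximum items per session; `NULL` means the bank size.
#' @param seed Optional integer seed for the stochastic stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(item_remainder = 0.3,
                       pca_first_proportion = 0.20,
                       pca_ratio = 4,
                       residual_correlation = 0.2,
                       scalability = 0.3,
                       item_fit_alpha = 0.01,
                       dif_alpha = 0.01,
                       sem = 0.32,
                       min_items = 3L,
                       max_items = NULL,
                       seed = NULL) {
  stopifnot(item_remainder > 0, pca_first_proportion > 0, pca_ratio > 0,
            residual_correlation > 0, scalability > 0,
            item_fit_alpha > 0, item_fit_alpha < 1,
            dif_alpha > 0, dif_alpha < 1,
            sem >= 0, min_items >= 1L)
  structure(as.list(environment()), class = "run_config")
}
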