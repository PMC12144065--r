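#' @useDynLib vacmorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

# variables used in ggplot2 aes() calls
utils::globalVariables(c("time_s", "ncc", "condition", "mu_lo", "mu_hi",
                         "mu_med", "delta_lo", "delta_hi", "delta_med",
                         "comparison", "mean", "sem", "count"))
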